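# Independent oracles used by the test suite. These deliberately avoid
# the package's own fitting/selection/phasing code paths.

# explicit normal-equation OLS (solve(X'X) X'y), the brute-force
# reference for the QR-based engine
ne_oracle <- function(y, X) {
  Xd <- cbind(1, as.matrix(X))
  coef <- drop(solve(t(Xd) %*% Xd, t(Xd) %*% y))
  fitted <- drop(Xd %*% coef)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  n <- length(y)
  p <- ncol(Xd) - 1L
  r2 <- 1 - rss / tss
  list(coef = coef, fitted = fitted, rss = rss, r2 = r2,
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1))
}

# random genotype panel with independent variants (binomial dosages)
rand_genotypes <- function(n, p, maf = stats::runif(p, 0.1, 0.5),
                           prefix = "v") {
  d <- vapply(seq_len(p), function(j)
    stats::rbinom(n, 2, maf[j]), numeric(n))
  colnames(d) <- sprintf("%s%02d", prefix, seq_len(p))
  rownames(d) <- sprintf("s%04d", seq_len(n))
  genotype_matrix(d)
}

# fast OLS summary on an explicit design (used inside the exhaustive
# search); normal equations are fine at these tiny sizes
sub_fit <- function(y, X) {
  Xd <- cbind(1, X)
  n <- length(y)
  XtX <- crossprod(Xd)
  ci <- tryCatch(solve(XtX), error = function(e) NULL)
  if (is.null(ci)) return(NULL)
  coef <- drop(ci %*% crossprod(Xd, y))
  rss <- sum((y - drop(Xd %*% coef))^2)
  df <- n - ncol(Xd)
  se <- sqrt(diag(ci) * rss / df)
  tp <- 2 * stats::pt(abs(coef / se), df, lower.tail = FALSE)
  list(rss = rss, term_p = tp[-1])
}

# exhaustive best-subset chain under the same alpha rules as forward
# entry: for each size take the minimum-RSS subset, accept the step up
# if its 1-df RSS-ratio test beats alpha_entry and every term of the
# new subset stays below alpha_stay; stop otherwise
best_subset_oracle <- function(y, X, kmax = 4L, alpha_entry = 0.05,
                               alpha_stay = 0.05) {
  n <- length(y)
  vars <- colnames(X)
  best <- character(0)
  rss_prev <- sum((y - mean(y))^2)
  for (k in seq_len(min(kmax, ncol(X)))) {
    subs <- utils::combn(vars, k, simplify = FALSE)
    fits <- lapply(subs, function(s) sub_fit(y, X[, s, drop = FALSE]))
    ok <- !vapply(fits, is.null, logical(1))
    subs <- subs[ok]; fits <- fits[ok]
    if (!length(fits)) break
    rssv <- vapply(fits, `[[`, numeric(1), "rss")
    i <- which.min(rssv)
    p_step <- stats::pchisq(n * log(rss_prev / rssv[i]), 1,
                            lower.tail = FALSE)
    if (p_step >= alpha_entry) break
    if (any(fits[[i]]$term_p >= alpha_stay)) break
    best <- subs[[i]]
    rss_prev <- rssv[i]
  }
  best
}

# brute-force 2-SNP haplotype frequency MLE: maximize the multinomial
# genotype likelihood over the 4-frequency simplex with multi-start
# quasi-Newton optimization on softmax parameters
phase_oracle_2snp <- function(dosages) {
  haps <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  hap_str <- apply(haps, 1, paste, collapse = "")
  class_prob <- function(f) {
    pr <- matrix(0, 3, 3)
    for (a in 1:4) for (b in 1:4) {
      g <- haps[a, ] + haps[b, ]
      pr[g[1] + 1, g[2] + 1] <- pr[g[1] + 1, g[2] + 1] + f[a] * f[b]
    }
    pr
  }
  counts <- matrix(0, 3, 3)
  for (i in seq_len(nrow(dosages)))
    counts[dosages[i, 1] + 1, dosages[i, 2] + 1] <-
      counts[dosages[i, 1] + 1, dosages[i, 2] + 1] + 1
  nll <- function(par) {
    f <- exp(c(par, 0)); f <- f / sum(f)
    pr <- class_prob(f)
    -sum(counts[counts > 0] * log(pr[counts > 0]))
  }
  best <- NULL
  for (s in 1:5) {
    set.seed(s)
    o <- tryCatch(stats::optim(stats::rnorm(3, 0, s / 2), nll,
                               method = "BFGS",
                               control = list(maxit = 500)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  f <- exp(c(best$par, 0)); f <- f / sum(f)
  stats::setNames(f, hap_str)
}
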