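#' Ordinary least squares fit of expression on variant dosages
#'
#' Fits `y ~ intercept + dosages` by QR decomposition and returns the
#' inference used throughout the package: per-term two-sided t tests,
#' the model F test against the intercept-only model, adjusted
#' r-squared, and the Gaussian profile log-likelihood
#' (sigma-hat-squared = RSS / n) that feeds the likelihood-ratio test.
#'
#' Exact collinearity among the requested dosage columns is an error
#' naming the dependent columns; the design matrix is never normal-
#' equation inverted.
#'
#' @param y named numeric vector (names are sample ids), or unnamed with
#'   the same length and order as the genotype samples.
#' @param g a [genotype_matrix()].
#' @param vids variants to include (empty for the intercept-only model).
#' @param response label stored with the fit.
#' @return object of class `linear_model_fit`.
#' @export
fit_ols <- function(y, g, vids = character(0), response = "y") {
  stopifnot(inherits(g, "genotype_matrix"))
  missing_v <- setdiff(vids, colnames(g$dosages))
  if (length(missing_v))
    stop("variant(s) not genotyped: ", paste(missing_v, collapse = ", "))
  if (is.null(names(y))) {
    if (length(y) != nrow(g$dosages))
      stop("unnamed response must match genotype sample count")
    names(y) <- rownames(g$dosages)
  }
  common <- intersect(names(y), rownames(g$dosages))
  if (!length(common)) stop("no samples shared between response and genotypes")
  X <- g$dosages[common, vids, drop = FALSE]
  yv <- y[common]
  ok <- stats::complete.cases(cbind(yv, X))
  if (sum(!ok))
    warning(sum(!ok), " sample(s) dropped for missing data")
  ols_fit(yv[ok], X[ok, , drop = FALSE], response = response)
}

# core OLS on an explicit predictor matrix (no intercept column included)
ols_fit <- function(y, X, response = "y", term_names = colnames(X)) {
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1L)
    stop("too few samples (n = ", n, ") for ", p, " predictor(s)")
  Xd <- cbind(`(Intercept)` = 1, X)
  qrd <- qr(Xd)
  if (qrd$rank < ncol(Xd)) {
    dep <- colnames(Xd)[qrd$pivot[-seq_len(qrd$rank)]]
    stop("exactly collinear design; dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  coef <- qr.coef(qrd, y)
  fitted <- drop(Xd %*% coef)
  res <- y - fitted
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  df_res <- n - p - 1L
  sigma2 <- rss / df_res
  XtXinv <- chol2inv(qr.R(qrd))
  se <- sqrt(diag(XtXinv) * sigma2)
  names(se) <- colnames(Xd)
  tstat <- coef / se
  pt2 <- 2 * stats::pt(abs(tstat), df_res, lower.tail = FALSE)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  adj_r2 <- 1 - (1 - r2) * (n - 1) / df_res
  if (p > 0L && tss > 0) {
    fstat <- ((tss - rss) / p) / (rss / df_res)
    f_p <- stats::pf(fstat, p, df_res, lower.tail = FALSE)
  } else {
    fstat <- NA_real_; f_p <- NA_real_
  }
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  structure(list(
    response = response,
    variant_ids = if (is.null(term_names)) character(0) else term_names,
    n = n,
    coefficients = coef,
    se = se,
    t = tstat,
    p = pt2,
    r2 = r2,
    adj_r2 = adj_r2,
    fstat = fstat,
    f_p = f_p,
    rss = rss,
    loglik = ll,
    fitted = stats::setNames(fitted, names(y)),
    residuals = stats::setNames(res, names(y)),
    sample_ids = names(y)), class = "linear_model_fit")
}

#' @export
print.linear_model_fit <- function(x, ...) {
  cat(sprintf("linear_model_fit: %s ~ %s\n", x$response,
              if (length(x$variant_ids))
                paste(x$variant_ids, collapse = " + ") else "1"))
  cat(sprintf("  n = %d, adj r2 = %.3f, model P = %s\n", x$n, x$adj_r2,
              format.pval(x$f_p, digits = 3)))
  tab <- data.frame(estimate = x$coefficients, se = x$se, t = x$t,
                    p = x$p)
  print(signif(tab, 4))
  invisible(x)
}

#' Serialize a fit as a per-term table
#'
#' @param fit a [fit_ols()] result.
#' @return `data.frame` with columns `term`, `estimate`, `se`, `t`, `p`.
#' @export
fit_table <- function(fit) {
  data.frame(term = names(fit$coefficients),
             estimate = unname(fit$coefficients),
             se = unname(fit$se), t = unname(fit$t), p = unname(fit$p),
             stringsAsFactors = FALSE)
}

#' Significance stars for model comparisons
#'
#' Maps a P value onto the conventional verdict scale used in the
#' cross-check displays: `n.s.` for P at or above 0.05, then `*`, `**`,
#' `***`, `****` below 0.05, 0.01, 0.001 and 0.0001 respectively.
#'
#' @param p numeric vector of P values in \[0, 1\].
#' @return character vector of verdicts.
#' @export
stars <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("P value(s) outside [0, 1]")
  vapply(p, function(x) {
    if (x < 1e-4) "****"
    else if (x < 1e-3) "***"
    else if (x < 1e-2) "**"
    else if (x < 0.05) "*"
    else "n.s."
  }, character(1))
}

new_comparison <- function(kind, direction, statistic, df, p,
                           note = NA_character_) {
  structure(list(kind = kind, direction = direction,
                 statistic = statistic, df = df, p = p,
                 stars = if (is.na(p)) "n.s." else stars(p),
                 note = note), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s [%s]: stat = %.4g, df = %s, P = %s (%s)%s\n",
              x$kind, x$direction, x$statistic,
              if (is.na(x$df)) "-" else x$df,
              format.pval(x$p, digits = 3), x$stars,
              if (!is.na(x$note)) paste0(" - ", x$note) else ""))
  invisible(x)
}

#' Likelihood-ratio test between nested OLS fits
#'
#' The statistic is `2 * (ll_large - ll_small) = n * log(RSS_small /
#' RSS_large)` under the Gaussian profile likelihood, referred to a
#' chi-square with as many degrees of freedom as added predictors.
#' An F-change calibration is available as an alternative reference.
#'
#' @param small,large [fit_ols()] results on identical samples, with the
#'   small model's predictors a subset of the large model's.
#' @param calibration `"chisq"` (default) or `"F"`.
#' @return a `comparison_result`.
#' @export
lrt_nested <- function(small, large, calibration = c("chisq", "F")) {
  calibration <- match.arg(calibration)
  stopifnot(inherits(small, "linear_model_fit"),
            inherits(large, "linear_model_fit"))
  if (!setequal(small$sample_ids, large$sample_ids))
    stop("nested comparison requires identical sample sets")
  if (!all(small$variant_ids %in% large$variant_ids))
    stop("models are not nested (small is not a subset of large)")
  df <- length(large$variant_ids) - length(small$variant_ids)
  n <- small$n
  stat <- n * log(small$rss / large$rss)
  if (df == 0L)
    return(new_comparison("nested_LRT", "small_vs_large", 0, 0L, 1))
  if (calibration == "chisq") {
    p <- stats::pchisq(stat, df, lower.tail = FALSE)
  } else {
    df2 <- n - length(large$variant_ids) - 1L
    fch <- ((small$rss - large$rss) / df) / (large$rss / df2)
    p <- stats::pf(fch, df, df2, lower.tail = FALSE)
    stat <- fch
  }
  new_comparison(if (calibration == "chisq") "nested_LRT" else "nested_F",
                 "small_vs_large", stat, df, p)
}

#' Davidson-MacKinnon J-test for non-nested OLS models
#'
#' For two non-nested predictor sets A and B over the same response, the
#' J-test augments each model's design with the other model's fitted
#' values and t-tests that proxy coefficient. A significant proxy in
#' direction A means model A fails to capture signal that model B does.
#' Both directions are always computed; they are not symmetric and are
#' never combined.
#'
#' @param y named response vector.
#' @param g a [genotype_matrix()].
#' @param a_ids,b_ids the two predictor sets (neither may contain the
#'   other; nested sets are an error instructing use of [lrt_nested()]).
#' @return list with elements `a` and `b`, each a `comparison_result`
#'   (direction `a` tests A's adequacy against B's fitted values).
#' @export
jtest <- function(y, g, a_ids, b_ids) {
  if (all(a_ids %in% b_ids) || all(b_ids %in% a_ids))
    stop("predictor sets are nested; use lrt_nested()")
  fa <- fit_ols(y, g, a_ids)
  fb <- fit_ols(y, g, b_ids)
  if (!setequal(fa$sample_ids, fb$sample_ids))
    stop("J-test requires identical sample sets for both models")
  ids <- fa$sample_ids
  one_direction <- function(base_ids, other_fit, label) {
    X <- cbind(g$dosages[ids, base_ids, drop = FALSE],
               proxy = other_fit$fitted[ids])
    qrd <- qr(cbind(1, X))
    if (qrd$rank < ncol(X) + 1L)
      stop("degenerate J-test comparison: the rival fitted values are ",
           "collinear with the base design (", label, ")")
    fit <- ols_fit(y[ids], X)
    k <- length(fit$p)
    new_comparison("jtest", label, unname(fit$t[k]), NA_integer_,
                   unname(fit$p[k]))
  }
  list(a = one_direction(a_ids, fb, "a_with_b_proxy"),
       b = one_direction(b_ids, fa, "b_with_a_proxy"))
}
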