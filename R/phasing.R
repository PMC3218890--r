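#' Haplotype phasing by expectation-maximisation
#'
#' Estimates haplotype frequencies at a small set of tag variants by
#' maximum likelihood under Hardy-Weinberg equilibrium
#' (Excoffier-Slatkin style EM), then assigns each sample its most
#' probable haplotype pair and its expected per-haplotype dosage.
#'
#' The E step distributes each multilocus genotype over all compatible
#' ordered haplotype pairs in proportion to `2 f_a f_b` (or `f_a^2` for a
#' homozygous pair); the M step re-estimates frequencies from expected
#' haplotype counts. The log-likelihood is non-decreasing across
#' iterations and convergence is declared when its increase falls below
#' `tol`.
#'
#' @param g a [genotype_matrix()] with no more than `2^k` enumeration
#'   work per sample; at most 12 tag variants are allowed.
#' @param tag_variant_ids variants to phase (order defines the allele
#'   string).
#' @param tol convergence threshold on the log-likelihood increase.
#' @param max_iter maximum EM iterations; non-convergence is an error
#'   reporting the final log-likelihood delta.
#' @return an object of class `haplotype_set`: list with
#'   `tag_variant_ids`, `haplotypes` (`data.frame`: `haplotype_id`,
#'   `alleles`, `frequency`), `allele_matrix` (haplotypes x tags),
#'   `diplotypes` (`data.frame`: `sample_id`, `hap1`, `hap2`,
#'   `posterior`), `expected_dosage` and `hard_dosage` (samples x
#'   haplotypes), and `loglik_trace`.
#' @export
em_phase <- function(g, tag_variant_ids, tol = 1e-8, max_iter = 10000L) {
  if (length(tag_variant_ids) > 12L)
    stop("tag set too large for enumeration (", length(tag_variant_ids),
         " > 12)")
  missing_tags <- setdiff(tag_variant_ids, colnames(g$dosages))
  if (length(missing_tags))
    stop("tag variant(s) not in genotype matrix: ",
         paste(missing_tags, collapse = ", "))
  d <- g$dosages[, tag_variant_ids, drop = FALSE]
  drop <- apply(d, 1, anyNA)
  if (any(drop)) {
    warning(sum(drop), " sample(s) with missing tag genotypes excluded ",
            "from phasing")
    d <- d[!drop, , drop = FALSE]
  }
  if (nrow(d) == 0L) stop("no samples with complete tag genotypes")
  L <- ncol(d)

  # enumerate compatible unordered haplotype pairs per sample
  pairs_of <- function(geno) {
    het <- which(geno == 1)
    base <- ifelse(geno == 2, 1L, 0L)
    if (length(het) == 0L) {
      h <- paste(base, collapse = "")
      return(matrix(c(h, h), ncol = 2))
    }
    k <- length(het)
    # first heterozygous allele fixed on hap1: each unordered pair once
    n_assign <- 2L^(k - 1L)
    out <- matrix("", n_assign, 2)
    for (idx in seq_len(n_assign)) {
      bits <- as.integer(intToBits(idx - 1L))[seq_len(max(k - 1L, 1L))]
      a1 <- base; a2 <- base
      a1[het[1]] <- 0L; a2[het[1]] <- 1L
      if (k > 1L) {
        a1[het[-1]] <- bits[seq_len(k - 1L)]
        a2[het[-1]] <- 1L - bits[seq_len(k - 1L)]
      }
      out[idx, ] <- c(paste(a1, collapse = ""), paste(a2, collapse = ""))
    }
    out
  }
  plist <- lapply(seq_len(nrow(d)), function(i) pairs_of(d[i, ]))
  universe <- sort(unique(unlist(plist)))
  H <- length(universe)
  hidx <- stats::setNames(seq_len(H), universe)

  f <- rep(1 / H, H)
  n <- nrow(d)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    counts <- numeric(H)
    ll <- 0
    post_best <- vector("list", n)
    for (i in seq_len(n)) {
      pp <- plist[[i]]
      ia <- hidx[pp[, 1]]; ib <- hidx[pp[, 2]]
      w <- f[ia] * f[ib] * ifelse(ia == ib, 1, 2)
      tot <- sum(w)
      if (tot <= 0) { w <- rep(1 / length(w), length(w)); tot <- 1 }
      ll <- ll + log(tot)
      post <- w / tot
      for (p in seq_along(post)) {
        counts[ia[p]] <- counts[ia[p]] + post[p]
        counts[ib[p]] <- counts[ib[p]] + post[p]
      }
      post_best[[i]] <- post
    }
    if (length(ll_trace) && ll < ll_old - 1e-9)
      stop("EM log-likelihood decreased; numerical failure")
    ll_trace <- c(ll_trace, ll)
    f <- counts / (2 * n)
    if (is.finite(ll_old) && (ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  if (!converged)
    stop(sprintf(
      "EM did not converge in %d iterations (final log-likelihood delta %.3g)",
      max_iter, ll_trace[length(ll_trace)] - ll_old))

  # order haplotypes by estimated frequency, assign stable ids
  ord <- order(-f, universe)
  universe <- universe[ord]
  f <- f[ord]
  hidx <- stats::setNames(seq_len(H), universe)
  hap_ids <- sprintf("hap%02d", seq_len(H))
  names(f) <- hap_ids

  amat <- do.call(rbind, lapply(strsplit(universe, ""), as.integer))
  dimnames(amat) <- list(hap_ids, tag_variant_ids)

  expected <- matrix(0, n, H, dimnames = list(rownames(d), hap_ids))
  dip <- data.frame(sample_id = rownames(d), hap1 = "", hap2 = "",
                    posterior = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    pp <- plist[[i]]
    ia <- hidx[pp[, 1]]; ib <- hidx[pp[, 2]]
    w <- f[ia] * f[ib] * ifelse(ia == ib, 1, 2)
    post <- w / sum(w)
    for (p in seq_along(post)) {
      expected[i, ia[p]] <- expected[i, ia[p]] + post[p]
      expected[i, ib[p]] <- expected[i, ib[p]] + post[p]
    }
    best <- which.max(post)
    dip$hap1[i] <- hap_ids[ia[best]]
    dip$hap2[i] <- hap_ids[ib[best]]
    dip$posterior[i] <- post[best]
  }
  hard <- matrix(0, n, H, dimnames = list(rownames(d), hap_ids))
  for (i in seq_len(n)) {
    hard[i, dip$hap1[i]] <- hard[i, dip$hap1[i]] + 1
    hard[i, dip$hap2[i]] <- hard[i, dip$hap2[i]] + 1
  }
  structure(list(
    tag_variant_ids = tag_variant_ids,
    haplotypes = data.frame(haplotype_id = hap_ids, alleles = universe,
                            frequency = unname(f),
                            stringsAsFactors = FALSE),
    allele_matrix = amat,
    diplotypes = dip,
    expected_dosage = expected,
    hard_dosage = hard,
    loglik_trace = ll_trace), class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d haplotypes over %d tags, %d samples\n",
              nrow(x$haplotypes), length(x$tag_variant_ids),
              nrow(x$diplotypes)))
  print(utils::head(x$haplotypes, 10))
  invisible(x)
}

#' Per-sample dosage of one haplotype
#'
#' @param hs a [em_phase()] result.
#' @param haplotype_id haplotype to count.
#' @param mode `"hard"` counts copies in the most probable diplotype
#'   (0/1/2); `"expected"` returns the posterior-expected copy number in
#'   \[0, 2\].
#' @return named numeric vector over samples.
#' @export
haplotype_dosage <- function(hs, haplotype_id, mode = c("hard", "expected")) {
  mode <- match.arg(mode)
  m <- if (mode == "hard") hs$hard_dosage else hs$expected_dosage
  if (!haplotype_id %in% colnames(m))
    stop("unknown haplotype id: ", haplotype_id)
  m[, haplotype_id]
}

#' Relabel phased haplotypes against a reference pool
#'
#' Matches estimated haplotypes to a [haplotype_pool()] by allele vector
#' at the shared tags and renames them accordingly; unmatched estimated
#' haplotypes keep their `hapNN` labels.
#'
#' @param hs a [em_phase()] result.
#' @param pool a [haplotype_pool()] whose `variant_ids` include the tags
#'   of `hs` (in the same order).
#' @return `hs` with haplotype identifiers replaced where matched.
#' @export
relabel_haplotypes <- function(hs, pool) {
  idx <- match(hs$tag_variant_ids, pool$variant_ids)
  if (anyNA(idx))
    stop("pool does not cover tag variants: ",
         paste(hs$tag_variant_ids[is.na(idx)], collapse = ", "))
  pool_str <- apply(pool$alleles[, idx, drop = FALSE], 1, paste,
                    collapse = "")
  map <- stats::setNames(rownames(pool$alleles), pool_str)
  new_ids <- map[hs$haplotypes$alleles]
  keep <- is.na(new_ids)
  new_ids[keep] <- hs$haplotypes$haplotype_id[keep]
  old <- hs$haplotypes$haplotype_id
  ren <- function(x) stats::setNames(new_ids, old)[x]
  hs$haplotypes$haplotype_id <- unname(new_ids)
  colnames(hs$expected_dosage) <- unname(ren(colnames(hs$expected_dosage)))
  colnames(hs$hard_dosage) <- unname(ren(colnames(hs$hard_dosage)))
  rownames(hs$allele_matrix) <- unname(ren(rownames(hs$allele_matrix)))
  hs$diplotypes$hap1 <- unname(ren(hs$diplotypes$hap1))
  hs$diplotypes$hap2 <- unname(ren(hs$diplotypes$hap2))
  hs
}

#' Write per-sample phasing results as TSV
#'
#' @param hs a [em_phase()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(hs, path) {
  utils::write.table(hs$diplotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
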