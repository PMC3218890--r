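#' Pairwise linkage disequilibrium as squared dosage correlation
#'
#' LD is measured as the squared Pearson correlation between the additive
#' dosage vectors of two variants, computed over samples non-missing at
#' both. This genotypic r-squared requires no phasing and directly
#' quantifies the collinearity that matters for regression designs.
#'
#' @param g a [genotype_matrix()]
#' @param v1,v2 variant identifiers.
#' @return a list with `v1`, `v2`, `r2` and `n` (samples used).
#' @export
ld_r2 <- function(g, v1, v2) {
  for (v in c(v1, v2))
    if (!v %in% colnames(g$dosages)) stop("unknown variant: ", v)
  x <- g$dosages[, v1]
  y <- g$dosages[, v2]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2L)
    stop("LD undefined: zero dosage variance at ", v1)
  if (length(unique(y)) < 2L)
    stop("LD undefined: zero dosage variance at ", v2)
  list(v1 = v1, v2 = v2, r2 = stats::cor(x, y)^2, n = sum(ok))
}

#' All-pairs LD matrix
#'
#' @param g a [genotype_matrix()]
#' @return symmetric matrix of squared pairwise dosage correlations
#'   (pairwise-complete observations); monomorphic variants yield `NA`
#'   rows/columns.
#' @export
ld_r2_matrix <- function(g) {
  suppressWarnings(stats::cor(g$dosages, use = "pairwise.complete.obs")^2)
}

#' Prune variants in high linkage disequilibrium
#'
#' Greedy scan in genomic position order: while any pair of retained
#' variants has r-squared at or above `threshold`, the member with the
#' lower minor allele frequency is removed (ties broken by keeping the
#' smaller position). Variants listed in `keep_ids` are never removed;
#' their high-LD partners are removed instead (two protected variants in
#' mutual high LD are both retained, with a warning).
#'
#' @param g a [genotype_matrix()]
#' @param threshold r-squared at or above which one of a pair is dropped
#'   (default 0.90).
#' @param keep_ids variants exempt from removal (for example declared
#'   functional polymorphisms that later analyses must see).
#' @return list with `kept` (variant ids, positional order), `report`
#'   (`data.frame` of `removed_id`, `kept_id`, `r2`) and `g` (the pruned
#'   [genotype_matrix()]).
#' @export
prune_by_ld <- function(g, threshold = 0.90, keep_ids = character()) {
  stopifnot(threshold > 0, threshold <= 1)
  ids <- g$variant_meta$variant_id       # positional order
  if (length(ids) == 0L)
    return(list(kept = character(0),
                report = data.frame(removed_id = character(0),
                                    kept_id = character(0),
                                    r2 = numeric(0)),
                g = g))
  unknown <- setdiff(keep_ids, ids)
  if (length(unknown))
    stop("keep_ids not in genotype matrix: ", paste(unknown, collapse = ", "))
  r2m <- ld_r2_matrix(g)[ids, ids, drop = FALSE]
  fr <- maf(g)[ids]
  active <- ids
  removed <- kept_for <- character(0)
  r2rec <- numeric(0)
  repeat {
    hit <- NULL
    for (a in seq_along(active)) {
      for (b in seq_len(a - 1L)) {
        r2 <- r2m[active[b], active[a]]
        if (!is.na(r2) && r2 >= threshold) { hit <- c(b, a); break }
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) break
    vi <- active[hit[1]]; vj <- active[hit[2]]   # vi earlier position
    pi_ <- vi %in% keep_ids; pj <- vj %in% keep_ids
    if (pi_ && pj) {
      warning("protected variants in high LD kept together: ", vi, ", ", vj)
      r2m[vi, vj] <- r2m[vj, vi] <- NA            # stop revisiting the pair
      next
    }
    drop_id <- if (pi_) vj else if (pj) vi else {
      if (fr[vi] > fr[vj]) vj
      else if (fr[vj] > fr[vi]) vi
      else vj                                     # tie: keep smaller position
    }
    keep_id <- setdiff(c(vi, vj), drop_id)
    removed <- c(removed, drop_id)
    kept_for <- c(kept_for, keep_id)
    r2rec <- c(r2rec, r2m[vi, vj])
    active <- setdiff(active, drop_id)
  }
  list(kept = active,
       report = data.frame(removed_id = removed, kept_id = kept_for,
                           r2 = r2rec, stringsAsFactors = FALSE),
       g = g[, active])
}
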