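#' Expression dataset
#'
#' Samples-by-probes expression values with probe annotation. Probe
#' annotation carries the targeted feature and whether the probe targets
#' an intron (such probes are removed before analysis, since intronic
#' signal does not track mature transcript abundance).
#'
#' @param values numeric matrix, samples in rows, probes in columns.
#' @param probe_meta optional `data.frame` with columns `probe_id`,
#'   `target` and `targets_intron` (logical).
#' @param standardized logical flag; set by [standardize()].
#' @return object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, probe_meta = NULL,
                               standardized = FALSE) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("sample%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("probe%02d", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values))) stop("duplicated sample ids")
  if (anyDuplicated(colnames(values))) stop("duplicated probe ids")
  if (is.null(probe_meta))
    probe_meta <- data.frame(probe_id = colnames(values),
                             target = NA_character_,
                             targets_intron = FALSE,
                             stringsAsFactors = FALSE)
  req <- c("probe_id", "target", "targets_intron")
  miss <- setdiff(req, names(probe_meta))
  if (length(miss))
    stop("probe_meta lacks column(s): ", paste(miss, collapse = ", "))
  if (!setequal(probe_meta$probe_id, colnames(values)))
    stop("probe_meta ids do not match probe columns")
  probe_meta <- probe_meta[match(colnames(values), probe_meta$probe_id),
                           req, drop = FALSE]
  rownames(probe_meta) <- NULL
  structure(list(values = values, probe_meta = probe_meta,
                 standardized = standardized),
            class = "expression_dataset")
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d samples x %d probes%s\n",
              nrow(x$values), ncol(x$values),
              if (x$standardized) " (standardized)" else ""))
  invisible(x)
}

#' Standardize each probe to mean 0 and standard deviation 1
#'
#' Every probe column is replaced by its z-scores (subtract the sample
#' mean, divide by the sample standard deviation), removing scale
#' differences between array platforms before any cross-probe or
#' cross-study comparison. Idempotent; the raw values are retained in
#' the `raw` element for provenance.
#'
#' @param e an [expression_dataset()].
#' @return the standardized dataset.
#' @export
standardize <- function(e) {
  stopifnot(inherits(e, "expression_dataset"))
  if (nrow(e$values) < 2L) stop("standardization needs at least 2 samples")
  sds <- apply(e$values, 2, stats::sd, na.rm = TRUE)
  zero <- which(!is.na(sds) & sds == 0)
  if (length(zero))
    stop("zero-variance probe(s): ",
         paste(colnames(e$values)[zero], collapse = ", "))
  raw <- if (is.null(e$raw)) e$values else e$raw
  z <- scale(e$values)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  out <- expression_dataset(z, e$probe_meta, standardized = TRUE)
  out$raw <- raw
  out
}

#' Remove probes that target introns
#'
#' @param e an [expression_dataset()].
#' @return the dataset without intron-targeting probes; the number
#'   removed is reported via `message()`, and an all-intron input yields
#'   an empty dataset with a warning.
#' @export
filter_intron_probes <- function(e) {
  stopifnot(inherits(e, "expression_dataset"))
  drop <- e$probe_meta$targets_intron
  message(sum(drop), " intron-targeting probe(s) removed, ",
          sum(!drop), " retained")
  if (all(drop)) warning("all probes target introns; empty dataset")
  keep <- e$probe_meta$probe_id[!drop]
  out <- expression_dataset(e$values[, keep, drop = FALSE],
                            e$probe_meta[!drop, , drop = FALSE],
                            standardized = e$standardized)
  out$raw <- if (!is.null(e$raw)) e$raw[, keep, drop = FALSE]
  out
}

#' Pairwise probe correlation (r-squared) matrix
#'
#' @param e an [expression_dataset()].
#' @param min_shared minimum shared samples for a defined entry
#'   (default 3); pairs below it get `NA` with a warning.
#' @return symmetric probe-by-probe matrix of squared Pearson
#'   correlations with unit diagonal.
#' @export
probe_r2_matrix <- function(e, min_shared = 3L) {
  stopifnot(inherits(e, "expression_dataset"))
  v <- e$values
  nshared <- crossprod(!is.na(v))
  r2 <- suppressWarnings(stats::cor(v, use = "pairwise.complete.obs")^2)
  low <- nshared < min_shared
  if (any(low & upper.tri(low))) {
    warning("probe pair(s) with fewer than ", min_shared,
            " shared samples set to NA")
    r2[low] <- NA
  }
  diag(r2) <- 1
  r2
}

#' Select a representative group of mutually correlated probes
#'
#' Greedy agglomeration: seed with the pair of highest r-squared, then
#' repeatedly add the probe with the highest mean r-squared to the
#' current group, as long as (a) that probe's mean r-squared with the
#' current members is at or above `min_mean_r2` and (b) the group's mean
#' pairwise r-squared stays at or above `min_mean_r2`. The cohesion
#' condition (a) prevents a large tight group from absorbing unrelated
#' probes by diluting the group mean down to the threshold. Ties are
#' broken by lexicographic probe id.
#' Multi-probe arrays typically contain a majority group tracking the
#' mature transcript plus outlier probes (alternative first exons, rare
#' splice variants); this recovers the majority group.
#'
#' @param r2_matrix symmetric probe r-squared matrix.
#' @param min_mean_r2 minimum acceptable group mean pairwise r-squared
#'   (default 0.5).
#' @return list with `members` (probe ids; empty if no pair qualifies),
#'   `mean_r2` and `excluded`.
#' @export
select_representative_group <- function(r2_matrix, min_mean_r2 = 0.5) {
  p <- colnames(r2_matrix)
  if (is.null(p)) p <- colnames(r2_matrix) <- rownames(r2_matrix) <-
      sprintf("probe%02d", seq_len(ncol(r2_matrix)))
  if (length(p) < 2L)
    return(list(members = character(0), mean_r2 = NA_real_, excluded = p))
  off <- r2_matrix
  diag(off) <- NA
  # seed: highest off-diagonal r2; ties -> lexicographically first pair
  best <- -Inf; seed <- NULL
  for (a in seq_along(p)) for (b in seq_along(p)) {
    if (a >= b || is.na(off[a, b])) next
    if (off[a, b] > best + 1e-15) { best <- off[a, b]; seed <- c(a, b) }
  }
  if (is.null(seed) || best < min_mean_r2)
    return(list(members = character(0), mean_r2 = NA_real_, excluded = p,
                note = "no probe pair reaches the threshold"))
  grp <- p[seed]
  mean_r2_of <- function(members) {
    sub <- r2_matrix[members, members]
    mean(sub[upper.tri(sub)])
  }
  repeat {
    cand <- setdiff(p, grp)
    if (!length(cand)) break
    gain <- vapply(cand, function(q)
      mean(r2_matrix[q, grp], na.rm = TRUE), numeric(1))
    ord <- order(-gain, cand)
    q <- cand[ord[1]]
    if (gain[ord[1]] < min_mean_r2 ||
        mean_r2_of(c(grp, q)) < min_mean_r2) break
    grp <- c(grp, q)
  }
  grp <- sort(grp)
  list(members = grp, mean_r2 = mean_r2_of(grp), excluded = setdiff(p, grp))
}

#' Composite expression signal
#'
#' Arithmetic mean of standardized member signals per sample. Members may
#' be probes of one dataset or representative signals of several studies;
#' all members must cover the same samples unless `allow_partial` is set,
#' in which case the intersection is used (and reported).
#'
#' @param members named list of per-sample numeric vectors (names are
#'   sample ids), or a single [expression_dataset()] together with
#'   `probe_ids`.
#' @param name label for the composite (for example `"K8"`, `"KSC"`).
#' @param allow_partial use the sample intersection instead of requiring
#'   identical sample sets.
#' @return object of class `composite_signal`: list with `name`,
#'   `members`, `value` (named vector) and `dropped_samples`.
#' @export
composite_signal <- function(members, name, allow_partial = FALSE) {
  if (!length(members)) stop("empty member list")
  ids <- lapply(members, names)
  if (any(vapply(ids, is.null, logical(1))))
    stop("composite members must be named per-sample vectors")
  common <- Reduce(intersect, ids)
  all_ids <- Reduce(union, ids)
  if (!allow_partial && length(common) != length(all_ids))
    stop("composite members cover different samples; ",
         "use allow_partial = TRUE to take the intersection")
  if (!length(common)) stop("no shared samples across composite members")
  m <- vapply(members, function(x) x[common], numeric(length(common)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(common))
  structure(list(name = name,
                 members = if (!is.null(names(members))) names(members)
                           else sprintf("member%d", seq_along(members)),
                 value = stats::setNames(rowMeans(m), common),
                 dropped_samples = setdiff(all_ids, common)),
            class = "composite_signal")
}

#' @rdname composite_signal
#' @param e an [expression_dataset()] (standardized).
#' @param probe_ids member probes.
#' @export
make_composite <- function(e, probe_ids, name) {
  stopifnot(inherits(e, "expression_dataset"))
  if (!length(probe_ids)) stop("empty member list")
  missing_p <- setdiff(probe_ids, colnames(e$values))
  if (length(missing_p))
    stop("unknown probe(s): ", paste(missing_p, collapse = ", "))
  if (!e$standardized)
    warning("composite computed from non-standardized probes")
  members <- lapply(probe_ids, function(p)
    stats::setNames(e$values[, p], rownames(e$values)))
  names(members) <- probe_ids
  composite_signal(members, name)
}

#' @export
print.composite_signal <- function(x, ...) {
  cat(sprintf("composite_signal '%s': mean of %d member(s), %d samples\n",
              x$name, length(x$members), length(x$value)))
  invisible(x)
}

#' Classical MDS display coordinates from a probe r-squared matrix
#'
#' Probes are embedded via classical (Torgerson) multidimensional scaling
#' of the distance d = sqrt(1 - r2), so perfectly correlated probes
#' coincide. Display only: coordinates are defined up to rotation and
#' reflection.
#'
#' @param r2_matrix complete symmetric r-squared matrix.
#' @param dims number of dimensions (default 2).
#' @return matrix of coordinates, one row per probe.
#' @export
mds_coordinates <- function(r2_matrix, dims = 2L) {
  if (!isSymmetric(unname(as.matrix(r2_matrix)), tol = 1e-8))
    stop("r2 matrix must be symmetric")
  if (anyNA(r2_matrix)) stop("r2 matrix must be complete for MDS")
  d <- sqrt(pmax(1 - r2_matrix, 0))
  stats::cmdscale(stats::as.dist(d), k = dims)
}

#' Read and write expression TSV
#'
#' Plain table, sample ids in the first column, one probe per remaining
#' column; probe annotation travels in a separate TSV with columns
#' `probe_id`, `target`, `targets_intron`.
#'
#' @param path expression TSV.
#' @param meta_path optional probe annotation TSV.
#' @return an [expression_dataset()].
#' @export
read_expression <- function(path, meta_path = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  meta <- if (!is.null(meta_path))
    utils::read.table(meta_path, header = TRUE, sep = "\t",
                      check.names = FALSE, stringsAsFactors = FALSE)
  expression_dataset(m, meta)
}

#' @rdname read_expression
#' @param e an [expression_dataset()].
#' @return `path`, invisibly.
#' @export
write_expression <- function(e, path, meta_path = NULL) {
  tab <- data.frame(sample = rownames(e$values), e$values,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(meta_path))
    utils::write.table(e$probe_meta, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
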