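#' Forward-entry selection of cis-regulatory variants
#'
#' Builds a multiple linear regression of an expression signal on variant
#' dosages by forward entry: the first entrant is the most associated
#' variant (smallest univariate P; equivalently the largest absolute
#' correlation), and each later step adds the candidate with the smallest
#' nested-improvement P (likelihood-ratio test against the current
#' model). Selection stops when the best improvement P reaches
#' `alpha_entry`, when after an entry any term's P reaches `alpha_stay`
#' (that entry is rolled back and, by default, selection stops), or when
#' candidates are exhausted. Ties are broken by the larger absolute t of
#' the entering term, then by genomic position.
#'
#' The candidate panel should be LD-pruned first ([prune_by_ld()]):
#' near-duplicate dosage columns make entry order arbitrary and inflate
#' standard errors. Candidates that would make the design exactly
#' collinear with the current model are skipped.
#'
#' @param y named response vector (standardized expression signal).
#' @param g a [genotype_matrix()] of candidate variants.
#' @param alpha_entry significance level an addition must beat to enter.
#' @param alpha_stay level every term must stay below after each entry.
#' @param on_lost `"stop"` (default: roll the offending entry back and
#'   stop) or `"continue"` (roll back, discard that candidate, and keep
#'   scanning the rest).
#' @return object of class `selection_trace`: list with `steps`
#'   (`data.frame`: `step`, `variant_id`, `entry_p`, `model_p`),
#'   `term_p` (per-term P values after each step), `stop_reason`
#'   (`no_significant_improvement`, `term_lost_significance` or
#'   `exhausted`) and `fit` (the final [fit_ols()]).
#' @export
forward_select <- function(y, g, alpha_entry = 0.05, alpha_stay = 0.05,
                           on_lost = c("stop", "continue")) {
  on_lost <- match.arg(on_lost)
  stopifnot(inherits(g, "genotype_matrix"))
  pos <- stats::setNames(g$variant_meta$pos, g$variant_meta$variant_id)
  selected <- character(0)
  banned <- character(0)
  steps <- data.frame(step = integer(0), variant_id = character(0),
                      entry_p = numeric(0), model_p = numeric(0),
                      stringsAsFactors = FALSE)
  term_p <- list()
  stop_reason <- "exhausted"
  current <- fit_ols(y, g, selected)
  repeat {
    cand <- setdiff(colnames(g$dosages), c(selected, banned))
    if (!length(cand)) { stop_reason <- "exhausted"; break }
    trial <- lapply(cand, function(v) {
      fit <- tryCatch(fit_ols(y, g, c(selected, v)),
                      error = function(e) NULL)
      if (is.null(fit)) return(NULL)          # collinear with current model
      cmp <- lrt_nested(current, fit)
      list(v = v, fit = fit, p = cmp$p,
           t = abs(unname(fit$t[length(fit$t)])))
    })
    trial <- Filter(Negate(is.null), trial)
    if (!length(trial)) { stop_reason <- "exhausted"; break }
    ps <- vapply(trial, `[[`, numeric(1), "p")
    ts <- vapply(trial, `[[`, numeric(1), "t")
    vp <- vapply(trial, `[[`, character(1), "v")
    ord <- order(ps, -ts, pos[vp])
    best <- trial[[ord[1]]]
    if (best$p >= alpha_entry) { stop_reason <- "no_significant_improvement"; break }
    tp <- best$fit$p[-1]                       # drop intercept
    if (any(tp >= alpha_stay)) {
      if (on_lost == "stop") { stop_reason <- "term_lost_significance"; break }
      banned <- c(banned, best$v)
      next
    }
    selected <- c(selected, best$v)
    current <- best$fit
    steps <- rbind(steps, data.frame(step = length(selected),
                                     variant_id = best$v,
                                     entry_p = best$p,
                                     model_p = current$f_p,
                                     stringsAsFactors = FALSE))
    term_p[[length(selected)]] <- stats::setNames(unname(tp), names(tp))
  }
  structure(list(steps = steps, term_p = term_p,
                 stop_reason = stop_reason, fit = current,
                 alpha_entry = alpha_entry, alpha_stay = alpha_stay),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("selection_trace: %d variant(s), stop reason: %s\n",
              nrow(x$steps), x$stop_reason))
  if (nrow(x$steps)) print(x$steps)
  invisible(x)
}

#' Refit a fixed variant composition on a dataset
#'
#' No reselection: the given composition is fitted as-is, which is how
#' model compositions travel between datasets in the cross-check grid.
#'
#' @param vids variant composition (may be empty: intercept-only).
#' @param y named response vector.
#' @param g a [genotype_matrix()].
#' @return a [fit_ols()] result.
#' @export
evaluate_composition <- function(vids, y, g) fit_ols(y, g, vids)

# compare composition m against the dataset's proper best composition b
compare_to_best <- function(m, b, y, g) {
  if (setequal(m, b))
    return(new_comparison("self", "identical", 0, 0L, NA_real_,
                          note = "same composition"))
  if (length(m) == 0L || all(m %in% b)) {
    fit_m <- fit_ols(y, g, m); fit_b <- fit_ols(y, g, b)
    return(lrt_nested(fit_m, fit_b))
  }
  if (length(b) == 0L || all(b %in% m)) {
    fit_b <- fit_ols(y, g, b); fit_m <- fit_ols(y, g, m)
    cmp <- lrt_nested(fit_b, fit_m)
    # the travelling model contains the best: it cannot be inferior
    return(new_comparison(cmp$kind, "contains_best", cmp$statistic,
                          cmp$df, 1, note = "composition contains the best model"))
  }
  res <- tryCatch(jtest(y, g, m, b), error = function(e) e)
  if (inherits(res, "error"))
    return(new_comparison("jtest", "degenerate", NA_real_, NA_integer_,
                          NA_real_, note = conditionMessage(res)))
  res$a
}

#' Cross-check grid of model compositions across datasets
#'
#' Every best-model composition is refitted on every dataset and
#' compared with that dataset's own best model: likelihood-ratio test
#' when one composition nests the other, Davidson-MacKinnon J-test
#' otherwise. A cell's verdict says whether the travelling composition
#' is significantly inferior to the proper best model; a composition
#' that contains the proper best model cannot be inferior in the nested
#' direction and is reported `n.s.` with a note.
#'
#' @param best_models named list of variant-id compositions, one per
#'   dataset (names are dataset labels).
#' @param responses named list of response vectors, same names.
#' @param genotypes a single [genotype_matrix()] shared by all datasets,
#'   or a named list of genotype matrices parallel to `responses`.
#' @return object of class `cross_check_grid`: list with `table`
#'   (long-format `data.frame`: `model`, `dataset`, `model_p`,
#'   `neglog10_p`, `adj_r2`, `comparison_p`, `verdict`, `kind`) and
#'   `comparisons` (nested list of `comparison_result`s).
#' @export
cross_check <- function(best_models, responses, genotypes) {
  if (length(responses) < 2L) stop("cross-check needs at least 2 datasets")
  dn <- names(responses)
  if (is.null(dn) || !setequal(dn, names(best_models)))
    stop("best_models and responses must share dataset names")
  g_of <- function(d) if (inherits(genotypes, "genotype_matrix"))
    genotypes else genotypes[[d]]
  rows <- list(); comps <- list()
  for (m in dn) for (d in dn) {
    g <- g_of(d); y <- responses[[d]]
    fit <- evaluate_composition(best_models[[m]], y, g)
    cmp <- compare_to_best(best_models[[m]], best_models[[d]], y, g)
    comps[[m]][[d]] <- cmp
    rows[[length(rows) + 1L]] <- data.frame(
      model = m, dataset = d,
      model_p = fit$f_p,
      neglog10_p = if (is.na(fit$f_p)) NA_real_ else -log10(fit$f_p),
      adj_r2 = fit$adj_r2,
      comparison_p = cmp$p,
      verdict = cmp$stars,
      kind = cmp$kind,
      stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, rows), comparisons = comps),
            class = "cross_check_grid")
}

#' @export
print.cross_check_grid <- function(x, ...) {
  cat("cross_check_grid (rows: travelling model, columns: dataset)\n")
  tab <- x$table
  wide <- stats::reshape(
    tab[, c("model", "dataset", "verdict")],
    idvar = "model", timevar = "dataset", direction = "wide")
  names(wide) <- sub("^verdict\\.", "", names(wide))
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Models restricted to declared functional polymorphisms
#'
#' Fits every size-1 and size-2 subset of a declared functional-variant
#' panel, compares each with the dataset's proper best model (LRT or
#' J-test as appropriate) and ranks by model P. This quantifies how much
#' of the cis-regulatory signal the known functional candidates alone
#' can carry.
#'
#' @param y named response vector.
#' @param g a [genotype_matrix()]; must contain every functional variant
#'   (exempt them from pruning via `keep_ids`).
#' @param functional_ids the functional panel.
#' @param best_ids the dataset's proper best composition.
#' @param max_size largest subset size (1 or 2).
#' @return `data.frame` ranked by model P with columns `model`,
#'   `adj_r2`, `model_p`, `comparison_p`, `verdict`, `kind`.
#' @export
functional_panel_models <- function(y, g, functional_ids, best_ids,
                                    max_size = 2L) {
  stopifnot(max_size %in% 1:2)
  missing_v <- setdiff(functional_ids, colnames(g$dosages))
  if (length(missing_v))
    stop("functional variant(s) not genotyped: ",
         paste(missing_v, collapse = ", "))
  subsets <- as.list(functional_ids)
  if (max_size == 2L && length(functional_ids) >= 2L) {
    cc <- utils::combn(functional_ids, 2L, simplify = FALSE)
    subsets <- c(subsets, cc)
  }
  rows <- lapply(subsets, function(s) {
    fit <- tryCatch(fit_ols(y, g, s), error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    cmp <- compare_to_best(s, best_ids, y, g)
    data.frame(model = paste(s, collapse = "+"),
               adj_r2 = fit$adj_r2, model_p = fit$f_p,
               comparison_p = cmp$p, verdict = cmp$stars,
               kind = cmp$kind, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  out[order(out$model_p), , drop = FALSE]
}

#' Render best-model summaries as a text table
#'
#' One block per dataset listing the selected polymorphisms in entry
#' order with the model's adjusted r-squared, model P and per-term P
#' values.
#'
#' @param traces named list of [forward_select()] results.
#' @return character vector of table lines (also printed).
#' @export
render_best_model_table <- function(traces) {
  lines <- c(sprintf("%-10s %-8s %-10s %-14s %-12s",
                     "Data set", "Adj r2", "Model P", "Polymorphism",
                     "Term P"))
  for (d in names(traces)) {
    tr <- traces[[d]]
    fit <- tr$fit
    if (!nrow(tr$steps)) {
      lines <- c(lines, sprintf("%-10s (empty model)", d))
      next
    }
    tp <- fit$p[-1]
    for (k in seq_len(nrow(tr$steps))) {
      v <- tr$steps$variant_id[k]
      lines <- c(lines, sprintf(
        "%-10s %-8s %-10s %-14s %-12s",
        if (k == 1L) d else "",
        if (k == 1L) sprintf("%.2f", fit$adj_r2) else "",
        if (k == 1L) format(fit$f_p, digits = 2) else "",
        v, format(unname(tp[v]), digits = 2)))
    }
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
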