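#' Analysis configuration
#'
#' Builds and validates the configuration driving [run_pipeline()].
#' Thresholds default to the package's analysis conventions: LD pruning
#' at r-squared 0.90, forward-entry and stay levels of 0.05, and a
#' representative probe-group threshold of 0.5 on mean pairwise
#' r-squared.
#'
#' @param datasets list of dataset entries; each entry is a list with
#'   `name`, `expression` (path to TSV or an [expression_dataset()]),
#'   optional `probes` (annotation TSV path), `genotypes` (a key into
#'   the `genotypes` argument) and `representative` (one of `"group"`,
#'   `"auto"`, `"reference:<dataset>"`, `"probe:<probe_id>"`).
#' @param genotypes named list of genotype sources (paths or
#'   [genotype_matrix()] objects).
#' @param ld_prune_threshold,alpha_entry,alpha_stay,min_mean_r2 analysis
#'   thresholds, all in (0, 1\].
#' @param functional_ids declared functional variants (exempt from
#'   pruning, used for the restricted-panel models).
#' @param tag_ids haplotype tag panel for phasing.
#' @param haplotypes optional predefined haplotype table (a
#'   [haplotype_pool()]); estimated haplotypes matching its allele
#'   vectors at the tags are renamed accordingly, which keeps haplotype
#'   labels comparable across genotype sets.
#' @param min_hap_freq haplotypes rarer than this are skipped in the
#'   association stage (default 0.05).
#' @param seed integer seed recorded in the manifest.
#' @param out_dir optional output directory for serialized results.
#' @return validated config list of class `analysis_config`.
#' @export
analysis_config <- function(datasets, genotypes,
                            ld_prune_threshold = 0.90,
                            alpha_entry = 0.05, alpha_stay = 0.05,
                            min_mean_r2 = 0.5,
                            functional_ids = character(0),
                            tag_ids = character(0),
                            haplotypes = NULL,
                            min_hap_freq = 0.05,
                            seed = 1L, out_dir = NULL) {
  if (!is.null(haplotypes) && !inherits(haplotypes, "haplotype_pool"))
    stop("haplotypes must be a haplotype_pool")
  if (!length(datasets)) stop("config needs at least one dataset")
  for (th in c(ld_prune_threshold, alpha_entry, alpha_stay, min_mean_r2))
    if (!is.numeric(th) || th <= 0 || th > 1)
      stop("thresholds must lie in (0, 1]")
  nm <- vapply(datasets, function(d) d$name %||% "", character(1))
  if (any(nm == "") || anyDuplicated(nm))
    stop("every dataset needs a unique name")
  names(datasets) <- nm
  if (is.null(names(genotypes)) || any(names(genotypes) == ""))
    stop("genotype sources must be named")
  for (d in datasets) {
    gk <- d$genotypes %||% names(genotypes)[1]
    if (!gk %in% names(genotypes))
      stop("dataset ", d$name, " refers to unknown genotype set ", gk)
  }
  structure(list(datasets = datasets, genotypes = genotypes,
                 ld_prune_threshold = ld_prune_threshold,
                 alpha_entry = alpha_entry, alpha_stay = alpha_stay,
                 min_mean_r2 = min_mean_r2,
                 functional_ids = functional_ids, tag_ids = tag_ids,
                 haplotypes = haplotypes,
                 min_hap_freq = min_hap_freq,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "analysis_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an analysis configuration from YAML
#'
#' @param path YAML file with the fields of [analysis_config()].
#' @return an `analysis_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.character(p) && !file.exists(p) &&
                           file.exists(file.path(base, p)))
    file.path(base, p) else p
  y$datasets <- lapply(y$datasets, function(d) {
    d$expression <- rel(d$expression)
    if (!is.null(d$probes)) d$probes <- rel(d$probes)
    d
  })
  y$genotypes <- lapply(y$genotypes, rel)
  do.call(analysis_config, y)
}

load_genotype_source <- function(x) {
  if (inherits(x, "genotype_matrix")) x else read_genotypes(x)
}

load_expression_source <- function(d) {
  if (inherits(d$expression, "expression_dataset")) d$expression
  else read_expression(d$expression, d$probes)
}

# choose the representative per-sample signal for one dataset
representative_signal <- function(e, rule, min_mean_r2, reference = NULL,
                                  name = "rep") {
  vals <- e$values
  pick_probe <- function(p) stats::setNames(vals[, p], rownames(vals))
  if (!is.null(rule) && grepl("^probe:", rule)) {
    p <- sub("^probe:", "", rule)
    if (!p %in% colnames(vals)) stop("declared probe not found: ", p)
    return(list(value = pick_probe(p), members = p, how = "declared"))
  }
  if (!is.null(rule) && grepl("^reference:", rule)) {
    if (is.null(reference))
      stop("reference signal required for rule '", rule, "'")
    shared <- intersect(names(reference), rownames(vals))
    if (length(shared) < 3L)
      stop("reference rule needs shared samples with the reference signal")
    r2 <- vapply(colnames(vals), function(p)
      stats::cor(vals[shared, p], reference[shared])^2, numeric(1))
    p <- names(which.max(r2))
    return(list(value = pick_probe(p), members = p,
                how = sprintf("max r2 vs reference (r2 = %.2f)", max(r2)),
                reference_r2 = r2))
  }
  if (ncol(vals) == 1L)
    return(list(value = pick_probe(colnames(vals)[1]),
                members = colnames(vals)[1], how = "only probe"))
  r2m <- probe_r2_matrix(e)
  grp <- select_representative_group(r2m, min_mean_r2)
  if (length(grp$members) >= 2L) {
    comp <- make_composite(e, grp$members, name)
    return(list(value = comp$value, members = grp$members,
                how = sprintf("probe group (mean pairwise r2 = %.2f)",
                              grp$mean_r2),
                group = grp, r2_matrix = r2m))
  }
  if (identical(rule, "group"))
    stop("no probe group reaches the mean-r2 threshold")
  # fall back to the probe best connected to the others
  mean_r2 <- rowMeans(r2m, na.rm = TRUE)
  p <- names(which.max(mean_r2))
  list(value = pick_probe(p), members = p, how = "best-connected probe",
       r2_matrix = r2m)
}

#' Run the full cis-regulation analysis
#'
#' Per dataset: standardize expression, drop intron probes, compute the
#' probe r-squared matrix, select the representative signal (probe group
#' composite, declared probe, or best correlate of a reference dataset),
#' LD-prune the genotype panel (declared functional variants exempt) and
#' run forward-entry selection. Across datasets: the cross-check grid of
#' exchanged best models, restricted functional-panel models, EM
#' phasing at the tag panel, univariate haplotype and risk-tag
#' associations, and model-haplotype correlations. All tabular results
#' are serialized to `out_dir` (when set) together with a JSON manifest.
#'
#' @param config an [analysis_config()] (or path to a YAML file).
#' @return a result bundle (list) with elements `datasets`,
#'   `composites`, `pruning`, `selection`, `best_models`, `grid`,
#'   `functional`, `phasing`, `associations`, `model_hap_r2`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "analysis_config"))
  gsets <- lapply(config$genotypes, load_genotype_source)

  pruned <- list(); prune_reports <- list()
  for (gk in names(gsets)) {
    pr <- prune_by_ld(gsets[[gk]], config$ld_prune_threshold,
                      keep_ids = intersect(config$functional_ids,
                                           variant_ids(gsets[[gk]])))
    message(sprintf("[prune:%s] %d -> %d variants", gk,
                    ncol(gsets[[gk]]$dosages), length(pr$kept)))
    pruned[[gk]] <- pr$g
    prune_reports[[gk]] <- pr$report
  }

  composites <- list(); dsinfo <- list(); traces <- list()
  responses <- list(); dsg <- list()
  reference <- NULL
  for (d in config$datasets) {
    e <- load_expression_source(d)
    e <- standardize(e)
    e <- filter_intron_probes(e)
    if (ncol(e$values) == 0L) stop("dataset ", d$name,
                                   ": no probes left after intron filter")
    rep_sig <- representative_signal(e, d$representative %||% "auto",
                                     config$min_mean_r2,
                                     reference = reference, name = d$name)
    message(sprintf("[represent:%s] %s (%d probe(s))", d$name,
                    rep_sig$how, length(rep_sig$members)))
    y <- rep_sig$value
    y <- (y - mean(y)) / stats::sd(y)       # composite back to unit scale
    if (is.null(reference)) reference <- y
    gk <- d$genotypes %||% names(gsets)[1]
    g <- pruned[[gk]]
    keep <- intersect(names(y), rownames(g$dosages))
    tr <- forward_select(y[keep], g[keep, ], config$alpha_entry,
                         config$alpha_stay)
    message(sprintf("[select:%s] %d variant(s), stop: %s", d$name,
                    nrow(tr$steps), tr$stop_reason))
    composites[[d$name]] <- rep_sig
    responses[[d$name]] <- y[keep]
    dsg[[d$name]] <- g[keep, ]
    traces[[d$name]] <- tr
    dsinfo[[d$name]] <- list(expression = e, genotype_key = gk)
  }

  best <- lapply(traces, function(tr) tr$steps$variant_id)
  grid <- if (length(best) >= 2L) cross_check(best, responses, dsg)

  functional <- NULL
  if (length(config$functional_ids)) {
    functional <- lapply(names(responses), function(dn)
      functional_panel_models(responses[[dn]], dsg[[dn]],
                              intersect(config$functional_ids,
                                        variant_ids(dsg[[dn]])),
                              best[[dn]]))
    names(functional) <- names(responses)
  }

  phasing <- NULL; associations <- NULL; mh_r2 <- NULL
  if (length(config$tag_ids)) {
    phasing <- lapply(gsets, function(g) {
      hs <- em_phase(g, intersect(config$tag_ids, variant_ids(g)))
      if (!is.null(config$haplotypes))
        hs <- relabel_haplotypes(hs, config$haplotypes)
      hs
    })
    assoc_rows <- list(); mh_rows <- list()
    for (dn in names(responses)) {
      gk <- dsinfo[[dn]]$genotype_key
      hs <- phasing[[gk]]
      common_h <- hs$haplotypes$haplotype_id[
        hs$haplotypes$frequency >= config$min_hap_freq]
      for (h in common_h) {
        dos <- haplotype_dosage(hs, h)
        ids <- intersect(names(responses[[dn]]), names(dos))
        if (length(ids) < 3L || stats::var(dos[ids]) == 0) next
        assoc_rows[[length(assoc_rows) + 1L]] <-
          haplotype_association(responses[[dn]], dos, h, dn)
        mh_rows[[length(mh_rows) + 1L]] <- cbind(
          dataset = dn,
          model_haplotype_r2(traces[[dn]]$fit, dos, h))
      }
    }
    associations <- do.call(rbind, assoc_rows)
    mh_r2 <- do.call(rbind, mh_rows)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cisreg")),
    r_version = R.version.string,
    seed = config$seed,
    thresholds = list(ld_prune = config$ld_prune_threshold,
                      alpha_entry = config$alpha_entry,
                      alpha_stay = config$alpha_stay,
                      min_mean_r2 = config$min_mean_r2),
    datasets = names(responses),
    n_samples = vapply(responses, length, integer(1)),
    best_models = best)

  bundle <- list(datasets = dsinfo, composites = composites,
                 pruning = prune_reports, selection = traces,
                 best_models = best, grid = grid,
                 functional = functional, phasing = phasing,
                 associations = associations, model_hap_r2 = mh_r2,
                 responses = responses, genotypes_pruned = dsg,
                 manifest = manifest)
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  for (gk in names(bundle$pruning))
    wt(bundle$pruning[[gk]], paste0("pruning_", gk, ".tsv"))
  for (dn in names(bundle$selection)) {
    wt(bundle$selection[[dn]]$steps, paste0("selection_", dn, ".tsv"))
    wt(fit_table(bundle$selection[[dn]]$fit), paste0("fit_", dn, ".tsv"))
  }
  if (!is.null(bundle$grid)) wt(bundle$grid$table, "cross_check.tsv")
  if (!is.null(bundle$functional))
    for (dn in names(bundle$functional))
      wt(bundle$functional[[dn]], paste0("functional_", dn, ".tsv"))
  if (!is.null(bundle$phasing))
    for (gk in names(bundle$phasing)) {
      write_haplotypes(bundle$phasing[[gk]],
                       file.path(dir, paste0("diplotypes_", gk, ".tsv")))
      wt(bundle$phasing[[gk]]$haplotypes,
         paste0("haplotypes_", gk, ".tsv"))
    }
  if (!is.null(bundle$associations)) wt(bundle$associations,
                                        "haplotype_associations.tsv")
  if (!is.null(bundle$model_hap_r2)) wt(bundle$model_hap_r2,
                                        "model_haplotype_r2.tsv")
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Human-readable summary of a pipeline result bundle
#'
#' Prints the best-model table (one block per dataset), the
#' star-annotated cross-check grid, the restricted functional-panel
#' rankings and the haplotype association forest table.
#'
#' @param bundle a [run_pipeline()] result.
#' @return the summary lines, invisibly.
#' @export
report <- function(bundle) {
  out <- utils::capture.output({
    cat("== Best cis-regulatory models ==\n")
    render_best_model_table(bundle$selection)
    cat("\n== Cross-check grid ==\n")
    if (is.null(bundle$grid)) cat("(fewer than two datasets: no grid)\n")
    else print(bundle$grid)
    if (!is.null(bundle$functional)) {
      cat("\n== Functional-panel models ==\n")
      for (dn in names(bundle$functional)) {
        cat("--", dn, "--\n")
        print(bundle$functional[[dn]], row.names = FALSE)
      }
    }
    if (!is.null(bundle$associations)) {
      cat("\n== Haplotype associations (per copy, standardized scale) ==\n")
      print(rescale_for_panel(bundle$associations), row.names = FALSE)
    }
  })
  cat(paste(out, collapse = "\n"), "\n")
  invisible(out)
}
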