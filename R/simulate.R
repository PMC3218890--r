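#' Haplotype pool
#'
#' A set of haplotypes over an ordered variant panel with population
#' frequencies, the generative unit for synthetic genotypes: each
#' simulated chromosome is one draw from the pool (Hardy-Weinberg
#' random mating, no inbreeding).
#'
#' @param variant_ids ordered variant identifiers.
#' @param alleles 0/1 matrix, one row per haplotype (row names are
#'   haplotype ids), one column per variant.
#' @param frequencies per-haplotype population frequencies; must sum to
#'   1 within 1e-9.
#' @param tag_ids optional subset of `variant_ids` designated as the
#'   phasing tag panel.
#' @return object of class `haplotype_pool`.
#' @export
haplotype_pool <- function(variant_ids, alleles, frequencies,
                           tag_ids = NULL) {
  alleles <- as.matrix(alleles)
  if (is.null(rownames(alleles)))
    rownames(alleles) <- sprintf("H%d", seq_len(nrow(alleles)))
  if (anyDuplicated(rownames(alleles))) stop("duplicated haplotype ids")
  if (ncol(alleles) != length(variant_ids))
    stop("allele vectors must have one entry per variant")
  if (!all(alleles %in% c(0, 1))) stop("alleles must be 0/1")
  if (length(frequencies) != nrow(alleles))
    stop("one frequency per haplotype required")
  if (abs(sum(frequencies) - 1) > 1e-9)
    stop("haplotype frequencies must sum to 1 (got ",
         format(sum(frequencies), digits = 12), ")")
  if (any(frequencies < 0)) stop("negative haplotype frequency")
  colnames(alleles) <- variant_ids
  if (!is.null(tag_ids)) {
    bad <- setdiff(tag_ids, variant_ids)
    if (length(bad)) stop("tag ids not in panel: ", paste(bad, collapse = ", "))
  }
  structure(list(variant_ids = variant_ids, alleles = alleles,
                 frequencies = stats::setNames(frequencies,
                                               rownames(alleles)),
                 tag_ids = tag_ids), class = "haplotype_pool")
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat(sprintf("haplotype_pool: %d haplotypes x %d variants\n",
              nrow(x$alleles), length(x$variant_ids)))
  print(round(x$frequencies, 4))
  invisible(x)
}

#' Simulate unphased genotypes from a haplotype pool
#'
#' Each sample receives two independent haplotype draws (Hardy-Weinberg
#' random mating); the dosage at a variant is the summed allele count.
#' The true haplotype pair is returned so phasing recovery can be scored
#' against it.
#'
#' @param pool a [haplotype_pool()].
#' @param n_samples number of diploid samples.
#' @param seed RNG seed (the generator is fully deterministic given it).
#' @param sample_prefix prefix for generated sample ids.
#' @param variant_meta optional variant metadata passed to
#'   [genotype_matrix()].
#' @return list with `genotypes` (a [genotype_matrix()]), `diplotypes`
#'   (`data.frame`: `sample_id`, `hap1`, `hap2`), `hap_dosage` (samples
#'   x haplotypes true copy counts) and `hap1_alleles`/`hap2_alleles`
#'   (phased 0/1 matrices, for phased VCF output).
#' @export
simulate_genotypes <- function(pool, n_samples, seed = 1L,
                               sample_prefix = "sample",
                               variant_meta = NULL) {
  stopifnot(inherits(pool, "haplotype_pool"), n_samples >= 1)
  set.seed(seed)
  hap_ids <- rownames(pool$alleles)
  i1 <- sample.int(length(hap_ids), n_samples, replace = TRUE,
                   prob = pool$frequencies)
  i2 <- sample.int(length(hap_ids), n_samples, replace = TRUE,
                   prob = pool$frequencies)
  sid <- sprintf("%s%03d", sample_prefix, seq_len(n_samples))
  a1 <- pool$alleles[i1, , drop = FALSE]
  a2 <- pool$alleles[i2, , drop = FALSE]
  rownames(a1) <- rownames(a2) <- sid
  dos <- a1 + a2
  hd <- vapply(hap_ids, function(h) (hap_ids[i1] == h) + (hap_ids[i2] == h),
               numeric(n_samples))
  if (is.null(dim(hd))) hd <- matrix(hd, nrow = n_samples)
  dimnames(hd) <- list(sid, hap_ids)
  list(genotypes = genotype_matrix(dos, variant_meta),
       diplotypes = data.frame(sample_id = sid, hap1 = hap_ids[i1],
                               hap2 = hap_ids[i2], stringsAsFactors = FALSE),
       hap_dosage = hd,
       hap1_alleles = a1, hap2_alleles = a2)
}

#' Simulate expression from genotypes under an additive model
#'
#' The latent expression signal is the additive genetic value
#' (sum of per-copy effects times dosages) plus Gaussian biological
#' noise; each probe measures the latent signal plus independent
#' Gaussian probe noise. Both the probes and the latent signal are
#' returned.
#'
#' @param g a [genotype_matrix()].
#' @param effects named numeric vector of per-dosage-unit effects; all
#'   names must be genotyped variants.
#' @param noise_sd standard deviation of the shared (biological) noise.
#' @param n_probes number of probes measuring the latent signal.
#' @param probe_noise_sd per-probe noise standard deviation (scalar or
#'   one value per probe).
#' @param seed RNG seed.
#' @param probe_prefix prefix for generated probe ids.
#' @return list with `dataset` (an [expression_dataset()], raw scale)
#'   and `latent` (named vector).
#' @export
simulate_expression <- function(g, effects, noise_sd, n_probes = 1L,
                                probe_noise_sd = 0, seed = 1L,
                                probe_prefix = "probe") {
  stopifnot(inherits(g, "genotype_matrix"), noise_sd > 0, n_probes >= 1)
  unknown <- setdiff(names(effects), colnames(g$dosages))
  if (length(unknown))
    stop("causal variant(s) not genotyped: ", paste(unknown, collapse = ", "))
  set.seed(seed)
  n <- nrow(g$dosages)
  gval <- if (length(effects))
    drop(g$dosages[, names(effects), drop = FALSE] %*% effects)
  else rep(0, n)
  latent <- gval + stats::rnorm(n, 0, noise_sd)
  psd <- rep(probe_noise_sd, length.out = n_probes)
  probes <- vapply(seq_len(n_probes), function(j)
    latent + stats::rnorm(n, 0, psd[j]), numeric(n))
  if (is.null(dim(probes))) probes <- matrix(probes, nrow = n)
  dimnames(probes) <- list(rownames(g$dosages),
                           sprintf("%s%02d", probe_prefix,
                                   seq_len(n_probes)))
  list(dataset = expression_dataset(probes),
       latent = stats::setNames(latent, rownames(g$dosages)))
}

#' Helpers linking effect sizes, noise and explained variance
#'
#' `effect_for_h2` sizes a single-variant effect so genotype explains a
#' target fraction `h2` of latent variance given the dosage variance and
#' noise; `noise_sd_for_h2` sizes the noise for a fixed genetic
#' variance; `probe_sd_for_pair_r2` sizes probe noise so two probes
#' sharing a latent signal have a target squared pairwise correlation
#' (r2 = (VarL / (VarL + sigma_p^2))^2, the attenuation identity).
#'
#' @param dosage_var variance of the causal dosage.
#' @param h2 target genotype-explained fraction of variance.
#' @param noise_sd residual standard deviation.
#' @return a scalar.
#' @export
effect_for_h2 <- function(dosage_var, h2, noise_sd = 1) {
  stopifnot(h2 > 0, h2 < 1, dosage_var > 0)
  noise_sd * sqrt(h2 / ((1 - h2) * dosage_var))
}

#' @rdname effect_for_h2
#' @param genetic_var variance of the additive genetic value.
#' @export
noise_sd_for_h2 <- function(genetic_var, h2) {
  stopifnot(h2 > 0, h2 < 1, genetic_var > 0)
  sqrt(genetic_var * (1 - h2) / h2)
}

#' @rdname effect_for_h2
#' @param latent_var variance of the shared latent signal.
#' @param pair_r2 target squared correlation between two probes.
#' @export
probe_sd_for_pair_r2 <- function(latent_var, pair_r2) {
  stopifnot(pair_r2 > 0, pair_r2 <= 1, latent_var > 0)
  sqrt(latent_var * (1 / sqrt(pair_r2) - 1))
}

# default pool used by the four-study fixture: six haplotypes over a
# 24-variant cis block built from four distinct variant incidence
# patterns (every non-core variant duplicates a core pattern, giving
# perfect-LD groups for pruning to exercise)
fixture_pool <- function() {
  freqs <- c(H1 = 0.26, H2 = 0.12, H3 = 0.20, H4 = 0.11, H5 = 0.09,
             H6 = 0.22)
  core <- cbind(P1 = c(1, 1, 0, 0, 0, 0),   # H1, H2
                P2 = c(0, 1, 0, 1, 0, 0),   # H2, H4
                P3 = c(0, 0, 0, 1, 1, 0),   # H4, H5
                P4 = c(0, 0, 0, 0, 0, 1))   # H6
  rownames(core) <- names(freqs)
  pattern <- rep(1:4, 6)                    # 24 variants, interleaved
  alleles <- core[, pattern]
  vids <- sprintf("v%02d", seq_along(pattern))
  colnames(alleles) <- vids
  pool <- haplotype_pool(vids, alleles, freqs, tag_ids = vids[1:8])
  pool
}

fixture_variant_meta <- function(pool) {
  vids <- pool$variant_ids
  meta <- data.frame(
    variant_id = vids, chrom = "7",
    pos = 128158000L + 6000L * seq_along(vids),
    ref = "A", alt = "G", type = "SNP", stringsAsFactors = FALSE)
  meta$ref[meta$variant_id == "v02"] <- "C"
  meta$alt[meta$variant_id == "v02"] <- "CGGGG"
  meta$type[meta$variant_id == "v02"] <- "indel"
  meta
}

#' Four-study synthetic fixture with known cis-regulatory truth
#'
#' Generates the package's reference scenario: three expression studies
#' of one cell-line collection (60 samples, three array designs with 17,
#' 2 and 1 probes, of which the first three studies use 57, 60 and 58 of
#' the samples) plus an independent fourth collection (181 samples, 3
#' probes). Genotypes come from a six-haplotype pool (H1-H6) over a
#' 24-variant cis block carrying four distinct dosage patterns; every
#' pattern's first variant is causal (effects -1.05, +1.05, -1.30,
#' +1.45 per copy), so the pruned candidate panel contains no truly
#' null variants. H6 is the sole haplotype carrying the strong positive
#' effect (the simulated risk haplotype); H3 carries no minor alleles at
#' all (the deliberately decoupled haplotype). Per-dataset noise is
#' solved so the genotype-explained variance of the representative
#' signal is approximately 0.31, 0.80, 0.55 and 0.28, and probe noise in
#' the first study is solved so its eight signal probes have expected
#' pairwise r-squared 0.79.
#'
#' @param seed RNG seed; the fixture is byte-identical for equal seeds.
#' @return list with `genotypes` (list `CEU`, `D` of
#'   [genotype_matrix()]), `expression` (named list of raw
#'   [expression_dataset()]s for studies `K`, `S`, `C`, `D`), and
#'   `truth` (pool, causal effects, per-dataset latent signals and h2
#'   targets, true diplotypes and haplotype dosages, tag/functional ids,
#'   risk and decoupled haplotype labels, study sample ids).
#' @export
make_four_study_fixture <- function(seed = 1L) {
  pool <- fixture_pool()
  meta <- fixture_variant_meta(pool)
  effects <- c(v01 = -1.05, v02 = 1.05, v03 = -1.30, v04 = 1.45)
  h2 <- c(K = 0.31, S = 0.80, C = 0.55, D = 0.28)

  gc <- simulate_genotypes(pool, 60, seed = seed, sample_prefix = "CEU",
                           variant_meta = meta)
  gd <- simulate_genotypes(pool, 181, seed = seed + 1000L,
                           sample_prefix = "AST", variant_meta = meta)

  gval <- function(sim) drop(sim$genotypes$dosages[, names(effects)] %*%
                               effects)
  # population genetic variance from pool moments
  f <- pool$frequencies
  A <- pool$alleles[, names(effects)]
  ab <- colSums(f * A)
  Sig <- 2 * (t(A) %*% diag(f) %*% A - outer(ab, ab))
  Vg <- drop(t(effects) %*% Sig %*% effects)

  study <- function(sim, samples, h2d, n_signal, pair_r2, n_other,
                    n_intron, seed_offset, probe_prefix, targets) {
    g <- sim$genotypes[samples, ]
    gv <- gval(sim)[samples]
    m <- n_signal
    cfrac <- if (m > 1L) 1 / sqrt(pair_r2) - 1 else 0.02
    bio_var <- Vg / h2d / (1 + cfrac / m) - Vg
    set.seed(seed + seed_offset)
    n <- length(samples)
    latent <- gv + stats::rnorm(n, 0, sqrt(bio_var))
    var_l <- Vg + bio_var
    sig <- vapply(seq_len(m), function(j)
      latent + stats::rnorm(n, 0, sqrt(cfrac * var_l)), numeric(n))
    oth <- if (n_other + n_intron > 0L)
      vapply(seq_len(n_other + n_intron), function(j)
        stats::rnorm(n, 0, sqrt(var_l)), numeric(n))
    else NULL
    vals <- cbind(sig, oth)
    pid <- sprintf("%s%02d", probe_prefix, seq_len(ncol(vals)))
    dimnames(vals) <- list(rownames(g$dosages), pid)
    pm <- data.frame(probe_id = pid, target = targets,
                     targets_intron = grepl("^intron", targets),
                     stringsAsFactors = FALSE)
    list(dataset = expression_dataset(vals, pm),
         latent = stats::setNames(latent, rownames(g$dosages)),
         genotypes = g, signal_probes = pid[seq_len(m)])
  }

  kT <- c("exon2", "exon3", "exon5", "exon6", "exon7", "exon8", "exon9",
          "utr3_pre", "exon1A", "exon1C", "exon4", "exon6_v5",
          "utr3_post", paste0("intron", 1:4))
  K <- study(gc, 1:57, h2["K"], 8L, 0.79, 5L, 4L, 1L, "K", kT)
  S <- study(gc, 1:60, h2["S"], 1L, NA, 1L, 0L, 2L, "S",
             c("utr3_pre", "exon1A"))
  C <- study(gc, 1:58, h2["C"], 1L, NA, 0L, 0L, 3L, "C", "exon9_utr3")
  D <- study(gd, 1:181, h2["D"], 1L, NA, 2L, 0L, 4L, "D",
             c("exon9_utr3", "exon1A", "exon4"))

  list(
    genotypes = list(CEU = gc$genotypes, D = gd$genotypes),
    expression = list(K = K$dataset, S = S$dataset, C = C$dataset,
                      D = D$dataset),
    truth = list(
      pool = pool,
      effects = effects,
      genetic_var = Vg,
      h2_target = h2,
      latent = list(K = K$latent, S = S$latent, C = C$latent,
                    D = D$latent),
      signal_probes = list(K = K$signal_probes, S = S$signal_probes,
                           C = C$signal_probes, D = D$signal_probes),
      diplotypes = list(CEU = gc$diplotypes, D = gd$diplotypes),
      hap_dosage = list(CEU = gc$hap_dosage, D = gd$hap_dosage),
      phased = list(CEU = list(hap1 = gc$hap1_alleles,
                               hap2 = gc$hap2_alleles),
                    D = list(hap1 = gd$hap1_alleles,
                             hap2 = gd$hap2_alleles)),
      tag_ids = pool$tag_ids,
      functional_ids = c("v01", "v02", "v04"),
      risk_haplotype = "H6",
      decoupled_haplotype = "H3",
      samples = list(K = rownames(K$genotypes$dosages),
                     S = rownames(S$genotypes$dosages),
                     C = rownames(C$genotypes$dosages),
                     D = rownames(D$genotypes$dosages)),
      genotype_of = c(K = "CEU", S = "CEU", C = "CEU", D = "D"),
      seed = seed))
}

#' Write a fixture to disk in plain-text formats
#'
#' Genotypes go out as dosage TSV plus minimal VCF (unphased for
#' analysis; a second, phased VCF records the simulation truth),
#' expression as TSV with a probe-annotation sidecar, and the remaining
#' ground truth as JSON.
#'
#' @param fix a [make_four_study_fixture()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (gset in names(fix$genotypes)) {
    g <- fix$genotypes[[gset]]
    write_genotypes(g, file.path(dir, paste0("genotypes_", gset, ".tsv")))
    write_genotypes(g, file.path(dir, paste0("genotypes_", gset, ".vcf")),
                    format = "vcf")
    write_genotypes(g, file.path(dir,
                                 paste0("genotypes_", gset, "_phased.vcf")),
                    format = "vcf", phased = fix$truth$phased[[gset]])
  }
  for (ds in names(fix$expression)) {
    e <- fix$expression[[ds]]
    write_expression(e, file.path(dir, paste0("expression_", ds, ".tsv")),
                     file.path(dir, paste0("probes_", ds, ".tsv")))
  }
  truth <- fix$truth
  json <- list(
    effects = as.list(truth$effects),
    genetic_var = truth$genetic_var,
    h2_target = as.list(truth$h2_target),
    haplotype_frequencies = as.list(truth$pool$frequencies),
    tag_ids = truth$tag_ids,
    functional_ids = truth$functional_ids,
    risk_haplotype = truth$risk_haplotype,
    decoupled_haplotype = truth$decoupled_haplotype,
    seed = truth$seed)
  jsonlite::write_json(json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
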