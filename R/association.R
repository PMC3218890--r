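#' Univariate association of expression with a haplotype dosage
#'
#' Ordinary least squares of (standardized) expression on a 0/1/2
#' haplotype dosage. The coefficient is the expression change per
#' haplotype copy with its t-based 95 percent confidence interval
#' (n - 2 degrees of freedom).
#'
#' @param y named response vector.
#' @param dosage named 0-2 dosage vector (hard counts by default
#'   upstream; expected dosages are equally accepted).
#' @param haplotype_id label for the output.
#' @param dataset label for the output.
#' @param conf_level confidence level (default 0.95).
#' @return object of class `haplotype_association`: one-row `data.frame`
#'   with `dataset`, `haplotype_id`, `beta`, `ci_lo`, `ci_hi`, `p`, `n`.
#' @export
haplotype_association <- function(y, dosage, haplotype_id = "hap",
                                  dataset = "data", conf_level = 0.95) {
  if (is.null(names(dosage)) && length(dosage) == length(y))
    names(dosage) <- names(y)
  common <- intersect(names(y), names(dosage))
  if (length(common) < 3L) stop("too few shared samples")
  yv <- y[common]; dv <- dosage[common]
  ok <- !is.na(yv) & !is.na(dv)
  yv <- yv[ok]; dv <- dv[ok]
  if (stats::var(dv) == 0)
    stop("monomorphic dosage for ", haplotype_id, ": association undefined")
  n <- length(yv)
  fit <- stats::lm(yv ~ dv)
  sm <- summary(fit)$coefficients
  beta <- sm["dv", "Estimate"]
  se <- sm["dv", "Std. Error"]
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = n - 2)
  out <- data.frame(dataset = dataset, haplotype_id = haplotype_id,
                    beta = beta, ci_lo = beta - tcrit * se,
                    ci_hi = beta + tcrit * se,
                    p = sm["dv", "Pr(>|t|)"], n = n,
                    stringsAsFactors = FALSE)
  class(out) <- c("haplotype_association", "data.frame")
  out
}

#' Single-variant association oriented to the minor allele
#'
#' Applies the same univariate machinery to one variant's dosage,
#' re-oriented so the coefficient is per copy of the minor allele in the
#' analyzed samples (recorded in the output to avoid orientation
#' ambiguity).
#'
#' @param y named response vector.
#' @param g a [genotype_matrix()].
#' @param variant_id variant to test.
#' @param dataset label for the output.
#' @return a `haplotype_association`-shaped `data.frame` with an extra
#'   `minor_is_alt` column.
#' @export
allele_association <- function(y, g, variant_id, dataset = "data") {
  if (!variant_id %in% colnames(g$dosages))
    stop("unknown variant: ", variant_id)
  dos <- g$dosages[, variant_id]
  common <- intersect(names(y), names(dos))
  af <- mean(dos[common], na.rm = TRUE) / 2
  if (is.na(af) || af == 0 || af == 1)
    stop("monomorphic variant: ", variant_id)
  minor_is_alt <- af <= 0.5
  dd <- if (minor_is_alt) dos else 2 - dos
  out <- haplotype_association(y, dd, haplotype_id = variant_id,
                               dataset = dataset)
  out$minor_is_alt <- minor_is_alt
  out
}

#' Correlation between a model's fitted values and a haplotype dosage
#'
#' Squared Pearson correlation between the fitted values of a
#' cis-regulatory model and a haplotype's dosage, over the fit's
#' samples. Low values mean the model's compound genetic signal is not
#' carried by that haplotype.
#'
#' @param fit a [fit_ols()] result.
#' @param dosage named dosage vector covering the fit's samples.
#' @param haplotype_id label.
#' @return `data.frame` with `haplotype_id`, `r2`, `n`.
#' @export
model_haplotype_r2 <- function(fit, dosage, haplotype_id = "hap") {
  ids <- intersect(fit$sample_ids, names(dosage))
  if (length(ids) < 3L) stop("too few shared samples")
  fv <- fit$fitted[ids]; dv <- dosage[ids]
  if (stats::sd(fv) == 0) stop("constant fitted values: r2 undefined")
  if (stats::sd(dv) == 0) stop("constant dosage: r2 undefined")
  data.frame(haplotype_id = haplotype_id,
             r2 = stats::cor(fv, dv)^2, n = length(ids),
             stringsAsFactors = FALSE)
}

#' Rescale association coefficients per dataset for a shared display axis
#'
#' Divides every coefficient and confidence bound within a dataset by
#' that dataset's maximum absolute coefficient, so several datasets fit
#' one y-axis. Display only: signs, P values and zero-crossing status
#' are unchanged and the scaled values must never feed back into
#' analysis.
#'
#' @param assoc `data.frame` of stacked [haplotype_association()] rows.
#' @return the same `data.frame` with `beta`, `ci_lo`, `ci_hi` rescaled
#'   and a `scale` column recording the per-dataset divisor.
#' @export
rescale_for_panel <- function(assoc) {
  stopifnot(all(c("dataset", "beta", "ci_lo", "ci_hi") %in% names(assoc)))
  out <- assoc
  out$scale <- NA_real_
  for (d in unique(assoc$dataset)) {
    i <- assoc$dataset == d
    s <- max(abs(assoc$beta[i]))
    if (s == 0) {
      warning("all-zero coefficients in dataset ", d, "; scale left at 1")
      s <- 1
    }
    out$beta[i] <- assoc$beta[i] / s
    out$ci_lo[i] <- assoc$ci_lo[i] / s
    out$ci_hi[i] <- assoc$ci_hi[i] / s
    out$scale[i] <- s
  }
  out
}

#' Forest-style plot of haplotype associations
#'
#' Point estimates with confidence intervals, grouped by dataset, with a
#' dashed reference line at zero. Intended for the rescaled panel
#' produced by [rescale_for_panel()], but accepts raw associations.
#'
#' @param assoc stacked association `data.frame`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the plotting positions.
#' @export
plot_haplotype_forest <- function(assoc, ...) {
  assoc$key <- paste(assoc$dataset, assoc$haplotype_id, sep = ":")
  k <- nrow(assoc)
  graphics::plot(NA, xlim = c(0.5, k + 0.5),
                 ylim = range(c(assoc$ci_lo, assoc$ci_hi, 0)),
                 xaxt = "n", xlab = "", ylab = "coefficient per copy", ...)
  graphics::abline(h = 0, lty = 2)
  graphics::points(seq_len(k), assoc$beta, pch = 19)
  graphics::arrows(seq_len(k), assoc$ci_lo, seq_len(k), assoc$ci_hi,
                   angle = 90, code = 3, length = 0.03)
  graphics::axis(1, at = seq_len(k), labels = assoc$key, las = 2,
                 cex.axis = 0.7)
  invisible(seq_len(k))
}
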