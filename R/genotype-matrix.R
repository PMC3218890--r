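#' Genotype matrix with additive dosage coding
#'
#' Container for a samples-by-variants table of additive allele dosages
#' (0, 1, 2 copies of the alternate allele, or `NA` for missing) together
#' with per-variant metadata. Variants are stored sorted by chromosome and
#' position so that downstream position-ordered scans (for example LD
#' pruning) are deterministic.
#'
#' @param dosages numeric matrix, samples in rows and variants in columns.
#'   Row names are sample identifiers, column names variant identifiers;
#'   all values must be in \{0, 1, 2\} or `NA`.
#' @param variant_meta optional `data.frame` with columns `variant_id`,
#'   `chrom`, `pos` (1-based), `ref`, `alt` and `type` (`"SNP"` or
#'   `"indel"`). When omitted, placeholder metadata with consecutive
#'   positions on one chromosome is generated.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages` (the matrix, variants in positional order) and
#'   `variant_meta`.
#' @examples
#' d <- matrix(c(0, 1, 2, 1, 0, 1), nrow = 3,
#'             dimnames = list(paste0("s", 1:3), c("v1", "v2")))
#' g <- genotype_matrix(d)
#' dim(g)
#' @export
genotype_matrix <- function(dosages, variant_meta = NULL) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("sample%03d", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- sprintf("var%03d", seq_len(ncol(dosages)))
  if (anyDuplicated(rownames(dosages)))
    stop("duplicated sample ids in genotype matrix")
  if (anyDuplicated(colnames(dosages)))
    stop("duplicated variant ids in genotype matrix")
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad))
    stop("dosages must be 0, 1, 2 or NA; offending variant(s): ",
         paste(unique(colnames(dosages)[which(bad, arr.ind = TRUE)[, 2]]),
               collapse = ", "))
  if (is.null(variant_meta)) {
    variant_meta <- data.frame(
      variant_id = colnames(dosages),
      chrom = "1",
      pos = seq_len(ncol(dosages)),
      ref = "A", alt = "G", type = "SNP",
      stringsAsFactors = FALSE)
  }
  req <- c("variant_id", "chrom", "pos", "ref", "alt", "type")
  miss <- setdiff(req, names(variant_meta))
  if (length(miss))
    stop("variant_meta lacks column(s): ", paste(miss, collapse = ", "))
  if (!setequal(variant_meta$variant_id, colnames(dosages)))
    stop("variant_meta ids do not match dosage column names")
  ord <- order(variant_meta$chrom, variant_meta$pos)
  variant_meta <- variant_meta[ord, req, drop = FALSE]
  rownames(variant_meta) <- NULL
  dosages <- dosages[, variant_meta$variant_id, drop = FALSE]
  structure(list(dosages = dosages, variant_meta = variant_meta),
            class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  cat(sprintf("  missing dosages: %d\n", sum(is.na(x$dosages))))
  invisible(x)
}

#' Sample and variant identifiers of a genotype matrix
#' @param g a [genotype_matrix()]
#' @return character vector of identifiers.
#' @export
sample_ids <- function(g) rownames(g$dosages)

#' @rdname sample_ids
#' @export
variant_ids <- function(g) colnames(g$dosages)

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()]
#' @param i sample index (ids, positions or logical)
#' @param j variant index (ids, positions or logical)
#' @param ... ignored
#' @return a `genotype_matrix` restricted to the requested samples/variants.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_len(ncol(x$dosages))
  d <- x$dosages[i, j, drop = FALSE]
  meta <- x$variant_meta[match(colnames(d), x$variant_meta$variant_id), ,
                         drop = FALSE]
  genotype_matrix(d, meta)
}

#' Minor allele frequency per variant
#'
#' The frequency of the less common allele, computed from non-missing
#' dosages (alternate-allele frequency folded at 0.5).
#'
#' @param g a [genotype_matrix()]
#' @return named numeric vector in \[0, 0.5\].
#' @export
maf <- function(g) {
  p <- colMeans(g$dosages, na.rm = TRUE) / 2
  stats::setNames(pmin(p, 1 - p), colnames(g$dosages))
}

#' Read genotypes from VCF or dosage TSV
#'
#' VCF input is parsed with \pkg{vcfR} and restricted to the GT field;
#' genotypes `0/0`, `0/1`, `1/1` (or their phased `|` forms) map to
#' dosages 0, 1, 2 and `./.` to missing. Multi-allelic records are
#' rejected. TSV input is a plain table with sample ids in the first
#' column and one variant per remaining column; optional variant metadata
#' may accompany it.
#'
#' @param path file to read.
#' @param format `"vcf"`, `"tsv"` or `"auto"` (by file extension).
#' @param variant_meta optional metadata `data.frame` for TSV input.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv"),
                           variant_meta = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  if (format == "vcf") read_genotypes_vcf(path) else
    read_genotypes_tsv(path, variant_meta)
}

read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("VCF contains no variant records: ", path)
  multi <- grepl(",", fix$ALT)
  if (any(multi))
    stop("multi-allelic site(s) unsupported: ",
         paste(fix$ID[multi], collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_real_, length(x))
    out[x == "0/0"] <- 0
    out[x %in% c("0/1", "1/0")] <- 1
    out[x == "1/1"] <- 2
    bad <- !is.na(x) & x != "./." & is.na(out)
    if (any(bad))
      stop("malformed GT value(s) '", paste(unique(x[bad]), collapse = "', '"),
           "' in ", path)
    out
  }
  d <- apply(gt, 2, code)
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  dos <- t(d)
  colnames(dos) <- fix$ID
  rownames(dos) <- colnames(gt)
  meta <- data.frame(
    variant_id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    type = ifelse(nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L,
                  "SNP", "indel"),
    stringsAsFactors = FALSE)
  genotype_matrix(dos, meta)
}

read_genotypes_tsv <- function(path, variant_meta = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("dosage TSV needs a sample column plus variants")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  genotype_matrix(m, variant_meta)
}

#' Write genotypes as dosage TSV or minimal VCF
#'
#' The VCF writer emits a minimal GT-only VCFv4.2 body. When the true
#' haplotype pair per sample is supplied (a two-column matrix of
#' haplotype allele vectors per variant is not needed; the per-variant
#' phased alleles are), genotypes are written phased with `|`; otherwise
#' unphased with `/`.
#'
#' @param g a [genotype_matrix()]
#' @param path output file.
#' @param format `"tsv"` or `"vcf"`.
#' @param phased optional list with elements `hap1` and `hap2`, each a
#'   samples-by-variants 0/1 allele matrix, used to write phased GT.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("tsv", "vcf"),
                            phased = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- data.frame(sample = rownames(g$dosages), g$dosages,
                      check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  meta <- g$variant_meta
  samples <- rownames(g$dosages)
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(meta)), function(k) {
    vid <- meta$variant_id[k]
    dos <- g$dosages[, vid]
    if (is.null(phased)) {
      gt <- c("0/0", "0/1", "1/1")[dos + 1L]
      gt[is.na(dos)] <- "./."
    } else {
      gt <- paste(phased$hap1[, vid], phased$hap2[, vid], sep = "|")
      gt[is.na(dos)] <- ".|."
    }
    paste(c(meta$chrom[k], meta$pos[k], vid, meta$ref[k], meta$alt[k],
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
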