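#' Dosage matrix with variant metadata
#'
#' The genotype container used throughout QC and association: an
#' `n_samples x n_variants` ALT-allele dosage matrix (entries 0, 1, 2 or `NA`
#' for missing) plus a variant table (`id, chr, pos, ref, alt`, 1-based bp).
#' Positions must be sorted within chromosome and `(chr, pos, ref, alt)` keys
#' unique.
#'
#' @param dosages Numeric/integer matrix, samples in rows (rownames = sample
#'   ids), variants in columns.
#' @param variants data.frame with columns `id, chr, pos, ref, alt`.
#' @param info Optional numeric vector of per-variant imputation-quality
#'   scores.
#' @return An object of class `genotype_set`.
#' @export
genotype_set <- function(dosages, variants, info = NULL) {
  stopifnot(is.matrix(dosages), is.data.frame(variants))
  if (ncol(dosages) != nrow(variants))
    stop_config("dosages columns (%d) != variants rows (%d)",
                ncol(dosages), nrow(variants))
  need <- c("id", "chr", "pos", "ref", "alt")
  if (!all(need %in% names(variants)))
    stop_config("variants needs columns: %s", paste(need, collapse = ", "))
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) stop_config("dosages must be 0, 1, 2 or NA")
  key <- paste(variants$chr, variants$pos, variants$ref, variants$alt)
  if (anyDuplicated(key)) stop_config("duplicate (chr,pos,ref,alt) keys")
  for (ch in unique(variants$chr)) {
    p <- variants$pos[variants$chr == ch]
    if (is.unsorted(p)) stop_config("positions not sorted within chr %s", ch)
  }
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("S%04d", seq_len(nrow(dosages)))
  if (!is.null(info) && length(info) != nrow(variants))
    stop_config("info length must equal number of variants")
  structure(list(dosages = dosages, variants = variants, info = info),
            class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat(sprintf("genotype_set: %d samples x %d variants (%s)\n",
              nrow(x$dosages), ncol(x$dosages),
              paste(unique(x$variants$chr), collapse = ",")))
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missingness %.3f%%, MAF range %.3f-%.3f\n", 100 * miss,
              suppressWarnings(min(variant_maf(x), na.rm = TRUE)),
              suppressWarnings(max(variant_maf(x), na.rm = TRUE))))
  invisible(x)
}

#' Per-variant allele frequencies and minor allele frequencies
#'
#' Computed on observed (non-missing) dosages only.
#'
#' @param g A [genotype_set()].
#' @return For `variant_maf`, the per-variant minor allele frequency;
#'   for `variant_alt_freq`, the ALT-allele frequency.
#' @export
variant_maf <- function(g) {
  af <- variant_alt_freq(g)
  pmin(af, 1 - af)
}

#' @rdname variant_maf
#' @export
variant_alt_freq <- function(g) {
  colMeans(g$dosages, na.rm = TRUE) / 2
}

# Subset helper keeping dosages/variants/info aligned.
subset_variants <- function(g, keep) {
  genotype_set(g$dosages[, keep, drop = FALSE],
               g$variants[keep, , drop = FALSE],
               info = if (is.null(g$info)) NULL else g$info[keep])
}

subset_samples <- function(g, keep) {
  genotype_set(g$dosages[keep, , drop = FALSE], g$variants, info = g$info)
}
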