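# Readers/writers for the interchange formats: TSV tables (tab-separated,
# UTF-8, "." for missing), VCF genotypes, a plain dosage-TSV dialect, NIfTI
# volumes, and the flat YAML pipeline configuration.

#' Read and write the tab-separated interchange tables
#'
#' All pipeline tables are TSV with a header, UTF-8, and `"."` for missing
#' values.
#'
#' @param x data.frame to write.
#' @param path File path.
#' @return `read_tsv_table` returns a data.frame; `write_tsv_table` returns
#'   `path` invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  if (!file.exists(path)) stop_config("input file not found: %s", path)
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = ".",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write or read a dosage-matrix TSV
#'
#' Dialect: columns `id, chr, pos, ref, alt` then one column per sample with
#' ALT dosages 0/1/2, `"."` for missing; variants in rows.
#'
#' @param g A [genotype_set()].
#' @param path File path.
#' @return `read_dosage_tsv` returns a `genotype_set`.
#' @export
write_dosage_tsv <- function(g, path) {
  stopifnot(inherits(g, "genotype_set"))
  tab <- cbind(g$variants, as.data.frame(t(g$dosages)))
  write_tsv_table(tab, path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  tab <- read_tsv_table(path)
  meta_cols <- c("id", "chr", "pos", "ref", "alt")
  variants <- tab[meta_cols]
  variants$chr <- sub("^chr", "", as.character(variants$chr))
  D <- t(as.matrix(tab[setdiff(names(tab), meta_cols)]))
  rownames(D) <- setdiff(names(tab), meta_cols)
  colnames(D) <- variants$id
  genotype_set(D, variants)
}

#' Write or read genotypes as VCF
#'
#' VCFv4.2 with a GT field; dosages are ALT-allele counts, written as
#' unphased genotypes (`0/0`, `0/1`, `1/1`, `./.`). Positions 1-based;
#' chromosome labels are stored without a `chr` prefix (tolerated on input).
#' Reading goes through the `vcfR` parser.
#'
#' @param g A [genotype_set()].
#' @param path File path (a `.gz` suffix writes a gzipped file).
#' @return `read_vcf_genotypes` returns a `genotype_set`.
#' @export
write_vcf_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_set"))
  gt_code <- c("0/0", "0/1", "1/1")
  D <- g$dosages
  body <- matrix("./.", ncol(D), nrow(D))
  for (i in seq_len(nrow(D))) {
    ok <- !is.na(D[i, ])
    body[ok, i] <- gt_code[D[i, ok] + 1]
  }
  header <- c("##fileformat=VCFv4.2",
              "##source=neuroslope",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(D)), collapse = "\t"))
  lines <- apply(cbind(g$variants$chr, g$variants$pos, g$variants$id,
                       g$variants$ref, g$variants$alt, ".", "PASS", ".",
                       "GT", body), 1, paste, collapse = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(header, lines), con)
  invisible(path)
}

#' @rdname write_vcf_genotypes
#' @export
read_vcf_genotypes <- function(path) {
  if (!file.exists(path)) stop_config("input file not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- gsub("[|]", "/", gt)
  D <- matrix(NA_real_, ncol(gt), nrow(gt))
  count_alt <- function(s) {
    if (is.na(s) || s %in% c("./.", ".")) return(NA_real_)
    sum(as.integer(strsplit(s, "/")[[1]]) > 0)
  }
  for (i in seq_len(nrow(gt)))
    D[, i] <- vapply(alleles[i, ], count_alt, numeric(1), USE.NAMES = FALSE)
  rownames(D) <- colnames(gt)
  variants <- data.frame(
    id = unname(fx[, "ID"]),
    chr = sub("^chr", "", unname(fx[, "CHROM"])),
    pos = as.integer(unname(fx[, "POS"])),
    ref = unname(fx[, "REF"]), alt = unname(fx[, "ALT"]),
    stringsAsFactors = FALSE)
  colnames(D) <- variants$id
  genotype_set(D, variants)
}

#' Write or read a volume as NIfTI
#'
#' @param volume 3D numeric array.
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_volume_nifti` returns a plain 3D array.
#' @export
write_volume_nifti <- function(volume, path) {
  RNifti::writeNifti(RNifti::asNifti(volume), path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  if (!file.exists(path)) stop_config("input file not found: %s", path)
  arr <- as.array(RNifti::readNifti(path))
  attributes(arr) <- list(dim = dim(arr))
  arr
}

#' Read the flat YAML pipeline configuration
#'
#' Unknown keys are an error; missing keys take the documented defaults of
#' [pipeline_config()]. The configuration round-trips through
#' [yaml::write_yaml()] unchanged.
#'
#' @param path YAML file path.
#' @return A validated `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_config("input file not found: %s", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop_config("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}
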