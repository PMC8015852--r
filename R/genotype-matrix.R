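#' In-memory genotype container
#'
#' A `genotype_matrix` bundles biallelic SNP genotypes for a sample panel:
#' a variant table, a diploid dosage matrix (0/1/2 counts of the alternate
#' allele, `NA` for missing calls), and optionally the phased haplotypes the
#' dosages were collapsed from.  Haplotype-based scans (iHS) require the
#' haplotype matrix; all frequency-based statistics work from dosages.
#'
#' @param variants Tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`;
#'   positions must be strictly increasing within a chromosome.
#' @param dosage Integer matrix, samples x variants, values 0/1/2 or `NA`.
#' @param samples Character vector of unique sample ids (one per dosage row).
#' @param haplotypes Optional 0/1 integer matrix with `2 * length(samples)`
#'   rows (rows `2i - 1` and `2i` are the two phased haplotypes of sample
#'   `i`) and one column per variant.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(variants, dosage, samples, haplotypes = NULL) {
  variants <- as_tibble(variants)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  if (!is.matrix(dosage)) dosage <- matrix(dosage, nrow = length(samples))
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) != length(samples))
    abort("dosage must have one row per sample")
  if (ncol(dosage) != nrow(variants))
    abort("dosage must have one column per variant")
  if (anyDuplicated(samples)) abort("sample ids must be unique")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    abort("dosages must be 0, 1, 2 or NA")
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      abort(paste0("positions must be strictly increasing within ", ch))
  }
  if (!is.null(haplotypes)) {
    storage.mode(haplotypes) <- "integer"
    if (nrow(haplotypes) != 2L * length(samples) ||
        ncol(haplotypes) != nrow(variants))
      abort("haplotypes must be (2 * samples) x variants")
    d2 <- haplotypes[seq(1L, nrow(haplotypes), 2L), , drop = FALSE] +
      haplotypes[seq(2L, nrow(haplotypes), 2L), , drop = FALSE]
    ok <- is.na(dosage) | d2 == dosage
    if (!all(ok)) abort("dosage must equal the column-pair sum of haplotypes")
  }
  rownames(dosage) <- samples
  structure(
    list(variants = variants, dosage = dosage, samples = samples,
         haplotypes = haplotypes),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants (%s)\n",
              n_samples(x), n_variants(x),
              if (is.null(x$haplotypes)) "unphased" else "phased"))
  invisible(x)
}

#' Panel dimensions
#' @param geno A [genotype_matrix()].
#' @return Integer count.
#' @export
n_samples <- function(geno) length(geno$samples)

#' @rdname n_samples
#' @export
n_variants <- function(geno) nrow(geno$variants)

#' Per-variant allele counts
#'
#' Alternate-allele count and called-allele number per variant, computed on
#' called genotypes only (missing dosages are excluded from both).
#'
#' @param geno A [genotype_matrix()].
#' @param samples Optional character vector restricting to a sample subset.
#' @return Tibble with columns `chrom`, `pos`, `alt_count`, `called_n`.
#' @export
allele_counts <- function(geno, samples = NULL) {
  d <- subset_dosage(geno, samples)
  tibble(chrom = geno$variants$chrom, pos = geno$variants$pos,
         alt_count = as.integer(colSums(d, na.rm = TRUE)),
         called_n = as.integer(2L * colSums(!is.na(d))))
}

subset_dosage <- function(geno, samples = NULL) {
  if (is.null(samples)) return(geno$dosage)
  miss <- setdiff(samples, geno$samples)
  if (length(miss))
    abort(paste0("unknown sample id(s): ", paste(miss, collapse = ", ")))
  geno$dosage[match(samples, geno$samples), , drop = FALSE]
}

subset_haplotypes <- function(geno, samples = NULL) {
  if (is.null(geno$haplotypes)) abort("phased haplotypes required")
  if (is.null(samples)) return(geno$haplotypes)
  miss <- setdiff(samples, geno$samples)
  if (length(miss))
    abort(paste0("unknown sample id(s): ", paste(miss, collapse = ", ")))
  idx <- match(samples, geno$samples)
  rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  geno$haplotypes[rows, , drop = FALSE]
}

#' Restrict a genotype matrix to a sample subset and/or variant subset
#'
#' @param geno A [genotype_matrix()].
#' @param samples Character vector of sample ids to keep (default all).
#' @param variants Integer vector of variant column indices to keep.
#' @return A [genotype_matrix()].
#' @export
subset_genotypes <- function(geno, samples = NULL, variants = NULL) {
  samples <- samples %||% geno$samples
  variants <- variants %||% seq_len(n_variants(geno))
  d <- subset_dosage(geno, samples)[, variants, drop = FALSE]
  h <- if (!is.null(geno$haplotypes))
    subset_haplotypes(geno, samples)[, variants, drop = FALSE]
  genotype_matrix(geno$variants[variants, , drop = FALSE], d, samples, h)
}
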