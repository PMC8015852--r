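#' Read a VCF into a genotype matrix
#'
#' Parses biallelic SNP records from a VCFv4.x file (other records are
#' skipped with a logged count), applies minor-allele-frequency and
#' missingness filters, and returns a [genotype_matrix()].  Haplotypes are
#' populated only when every genotype call is phased (`|` separator).
#'
#' MAF is computed on called alleles only; the missing rate is the fraction
#' of samples without a genotype call at the site.  Filter order does not
#' matter: both filters are evaluated on the unfiltered site.
#'
#' @param path VCF file path (plain text or gzipped).
#' @param maf_min Minimum minor allele frequency; sites strictly below are
#'   removed. Default 0 keeps everything polymorphic or not.
#' @param max_missing Maximum per-site missing-call rate; sites at or above
#'   are removed.
#' @param require_phase Error if any genotype is unphased (needed for iHS).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, maf_min = 0, max_missing = 1, require_phase = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0 || ncol(v@gt) < 2) abort("VCF contains no samples or no records")
  snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skip <- sum(!snp)
  if (n_skip > 0)
    inform(sprintf("read_vcf: skipped %d non-biallelic-SNP record(s)", n_skip))

  gt <- v@gt[snp, -1, drop = FALSE]
  samples <- colnames(v@gt)[-1]
  if (length(samples) == 0) abort("VCF contains no samples")
  gt <- sub(":.*", "", gt)
  phased <- !grepl("/", gt, fixed = TRUE)
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  a1[!a1 %in% c("0", "1")] <- NA
  a2[!a2 %in% c("0", "1")] <- NA
  h1 <- matrix(as.integer(a1), nrow(gt), ncol(gt))
  h2 <- matrix(as.integer(a2), nrow(gt), ncol(gt))
  dos <- h1 + h2 # variants x samples

  all_phased <- all(phased[!is.na(dos)])
  if (require_phase && !all_phased)
    abort("phased haplotypes required for iHS")

  called <- colSums(t(!is.na(dos)))            # per variant, samples called
  an <- 2L * called
  ac <- rowSums(dos, na.rm = TRUE)
  af <- ifelse(an > 0, ac / an, 0)
  maf <- pmin(af, 1 - af)
  miss_rate <- 1 - called / length(samples)
  keep <- maf >= maf_min & miss_rate < max_missing
  n_filt <- sum(!keep)
  if (n_filt > 0)
    inform(sprintf("read_vcf: removed %d site(s) failing MAF/missingness filters",
                   n_filt))

  variants <- tibble(chrom = fix$CHROM[snp][keep],
                     pos = as.integer(fix$POS[snp])[keep],
                     ref = fix$REF[snp][keep], alt = fix$ALT[snp][keep])
  dos <- t(dos[keep, , drop = FALSE])
  hap <- NULL
  if (all_phased && !anyNA(dos)) {
    hap <- matrix(0L, 2L * length(samples), nrow(variants))
    hap[seq(1, nrow(hap), 2), ] <- t(h1[keep, , drop = FALSE])
    hap[seq(2, nrow(hap), 2), ] <- t(h2[keep, , drop = FALSE])
  }
  genotype_matrix(variants, dos, samples, hap)
}

#' Write a genotype matrix as VCFv4.2
#'
#' Genotypes are written phased (`|`) when haplotypes are present, otherwise
#' unphased (`/`) with heterozygotes as `0/1`; missing calls become `./.`.
#'
#' @param geno A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  n <- n_samples(geno)
  v <- geno$variants
  if (!is.null(geno$haplotypes)) {
    h1 <- geno$haplotypes[seq(1, 2 * n, 2), , drop = FALSE]
    h2 <- geno$haplotypes[seq(2, 2 * n, 2), , drop = FALSE]
    gt <- matrix(paste0(h1, "|", h2), n, nrow(v))
    gt[is.na(geno$dosage)] <- ".|."
  } else {
    gt <- matrix("./.", n, nrow(v))
    gt[geno$dosage == 0L] <- "0/0"
    gt[geno$dosage == 1L] <- "0/1"
    gt[geno$dosage == 2L] <- "1/1"
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=adaptscan",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", geno$samples), collapse = "\t"))
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".", "GT",
                sep = "\t")
  lines <- paste(body, apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read and cross-validate the sample, environment and phenotype tables
#'
#' Reads the TSV tables emitted by [write_dataset()] (or equivalent), checks
#' that every genotyped sample is described, drops rows for samples absent
#' from the genotype panel (with a warning), and harmonizes row order to the
#' genotype matrix's sample order.
#'
#' @param sample_path TSV with columns `sample`, `group`, `lat`, `lon`,
#'   `altitude`.
#' @param env_path TSV with `sample` plus numeric EV columns.
#' @param pheno_path TSV with `sample`, `year`, `bloom_doy`.
#' @param geno Optional [genotype_matrix()] to validate and order against.
#' @return List of tibbles `samples`, `env`, `pheno`.
#' @export
read_tables <- function(sample_path, env_path, pheno_path, geno = NULL) {
  samples <- readr::read_tsv(sample_path, show_col_types = FALSE)
  env <- readr::read_tsv(env_path, show_col_types = FALSE,
                         col_types = readr::cols(sample = "c", .default = "c"))
  pheno <- readr::read_tsv(pheno_path, show_col_types = FALSE)
  ev_cols <- setdiff(names(env), "sample")
  for (cc in ev_cols) {
    parsed <- suppressWarnings(as.numeric(env[[cc]]))
    bad <- which(is.na(parsed) & !is.na(env[[cc]]))
    if (length(bad))
      abort(sprintf("non-numeric EV value in column '%s', row %d", cc, bad[1]))
    env[[cc]] <- parsed
  }
  if (!is.null(geno)) {
    absent <- setdiff(geno$samples, samples$sample)
    if (length(absent))
      abort(paste0("genotyped sample(s) missing from sample table: ",
                   paste(absent, collapse = ", ")))
    extra <- setdiff(samples$sample, geno$samples)
    if (length(extra))
      warn(sprintf("dropping %d table sample(s) absent from genotypes",
                   length(extra)))
    samples <- samples[match(geno$samples, samples$sample), , drop = FALSE]
    extra_env <- setdiff(env$sample, geno$samples)
    if (length(extra_env))
      warn(sprintf("dropping %d EV row(s) absent from genotypes",
                   length(extra_env)))
    env <- env[match(geno$samples, env$sample), , drop = FALSE]
    if (anyNA(env$sample)) abort("EV table is missing genotyped samples")
    pheno <- pheno[pheno$sample %in% geno$samples, , drop = FALSE]
  }
  list(samples = samples, env = env, pheno = pheno)
}

#' Read gene spans from a GFF3 file
#'
#' Keeps `gene` features only.  Coordinates are converted from GFF3 1-based
#' closed intervals to the package's internal 0-based half-open convention.
#' Non-comment lines that do not have nine tab-separated fields raise an
#' error naming the line number.
#'
#' @param path GFF3 path.
#' @return Tibble: `gene_id`, `chrom`, `start` (0-based), `end` (exclusive),
#'   `strand`.
#' @export
read_gff_genes <- function(path) {
  raw <- readLines(path)
  data_lines <- which(!grepl("^#", raw) & nzchar(raw))
  nf <- vapply(strsplit(raw[data_lines], "\t", fixed = TRUE), length, integer(1))
  if (any(nf != 9L))
    abort(sprintf("malformed GFF line %d: expected 9 tab-separated fields",
                  data_lines[which(nf != 9L)[1]]))
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(seq_along(gr))
  tibble(gene_id = ids,
         chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr),
         strand = as.character(GenomicRanges::strand(gr)))
}

#' Write regions as BED3(+)
#'
#' Input coordinates are the package's internal 0-based half-open intervals,
#' which is also the BED convention, so values pass through unchanged.  An
#' empty region set produces a file holding only the header comment.
#'
#' @param regions Tibble with `chrom`, `start`, `end` (plus optional extra
#'   columns written as additional BED fields).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  hdr <- "# chrom\tstart\tend"
  if (nrow(regions) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  extra <- setdiff(names(regions), c("chrom", "start", "end"))
  cols <- c(list(regions$chrom, regions$start, regions$end),
            lapply(extra, function(cc) {
              x <- regions[[cc]]
              if (is.list(x)) vapply(x, paste, character(1), collapse = ",") else x
            }))
  writeLines(c(hdr, do.call(paste, c(cols, sep = "\t"))), path)
  invisible(path)
}

#' Write a complete simulated dataset to disk
#'
#' Runs the generators of a [sim_scenario()] end to end and writes the VCF,
#' the sample/EV/phenotype/conductance/hourly-temperature TSV tables, and the
#' ground truth as JSON.  Identical scenarios (including seed) write
#' byte-identical files.
#'
#' @param scenario A [sim_scenario()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_dataset <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pop <- simulate_population(scenario)
  env <- simulate_environment(scenario, pop$samples)
  ph <- simulate_phenotypes(pop$geno, pop$truth, scenario)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             samples = file.path(dir, "samples.tsv"),
             env = file.path(dir, "env.tsv"),
             pheno = file.path(dir, "bloom_dates.tsv"),
             conductance = file.path(dir, "conductance.tsv"),
             hourly = file.path(dir, "hourly_temps.tsv"),
             truth = file.path(dir, "truth.json"))
  write_vcf(pop$geno, paths["vcf"])
  readr::write_tsv(pop$samples, paths["samples"])
  readr::write_tsv(env, paths["env"])
  readr::write_tsv(ph$pheno, paths["pheno"])
  readr::write_tsv(ph$conductance, paths["conductance"])
  readr::write_tsv(ph$hourly, paths["hourly"])
  tr <- ph$truth
  jsonlite::write_json(
    list(sweeps = tr$sweeps, causal = tr$causal, abd = tr$abd,
         lt50 = tr$lt50),
    paths["truth"], digits = NA, dataframe = "columns")
  invisible(paths)
}
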