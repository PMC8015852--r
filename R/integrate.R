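#' Genes overlapping candidate regions
#'
#' A gene is reported when its span overlaps any region by at least 1 bp;
#' both inputs use 0-based half-open coordinates, so a gene ending where a
#' region starts does not overlap.  Strand is ignored.
#'
#' @param regions Tibble with `chrom`, `start`, `end` (e.g. from
#'   [consensus_regions()]).
#' @param genes Tibble from [read_gff_genes()] (`gene_id`, `chrom`,
#'   `start`, `end`).
#' @return Sorted character vector of overlapping gene ids.
#' @export
genes_in_regions <- function(regions, genes) {
  if (nrow(regions) == 0 || nrow(genes) == 0) return(character())
  gr_r <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1, regions$end))
  gr_g <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1, genes$end))
  hits <- GenomicRanges::findOverlaps(gr_g, gr_r, minoverlap = 1)
  sort(unique(genes$gene_id[S4Vectors::queryHits(hits)]))
}

#' Overlap between sweep genes and association genes
#'
#' @param csr_genes Character vector of genes in candidate selection
#'   regions, or a named list of such vectors (one per group) for a
#'   per-group breakdown.
#' @param assoc_genes Character vector of association genes, or a named
#'   list (one per EV/trait).
#' @return An `overlap_report` list: the two gene universes, `shared`,
#'   counts, `fraction_shared` (shared / association genes), and optional
#'   `by_group` / `by_trait` breakdown tibbles.
#' @export
overlap_sweeps_associations <- function(csr_genes, assoc_genes) {
  sweep_all <- unique(unlist(csr_genes))
  assoc_all <- unique(unlist(assoc_genes))
  if (length(sweep_all) == 0 || length(assoc_all) == 0)
    abort("gene universes must be non-empty")
  shared <- intersect(sweep_all, assoc_all)
  rep_ <- list(
    sweep_genes = sort(sweep_all), assoc_genes = sort(assoc_all),
    shared = sort(shared),
    n_sweep = length(sweep_all), n_assoc = length(assoc_all),
    n_shared = length(shared),
    fraction_shared = length(shared) / length(assoc_all))
  if (is.list(csr_genes) && !is.null(names(csr_genes)))
    rep_$by_group <- purrr::imap_dfr(csr_genes, function(gs, nm)
      tibble(group = nm, n_genes = length(unique(gs)),
             n_shared = length(intersect(gs, assoc_all))))
  if (is.list(assoc_genes) && !is.null(names(assoc_genes)))
    rep_$by_trait <- purrr::imap_dfr(assoc_genes, function(gs, nm)
      tibble(trait = nm, n_genes = length(unique(gs)),
             n_shared = length(intersect(gs, sweep_all))))
  structure(rep_, class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("%d sweep genes, %d association genes, %d shared (%.1f%% of association genes)\n",
              x$n_sweep, x$n_assoc, x$n_shared, 100 * x$fraction_shared))
  invisible(x)
}

#' Genetic distance from kinship
#'
#' `1 - IBS` pairwise distances from [kinship_matrix()].
#'
#' @param K A [kinship_matrix()] (or any similarity matrix with unit
#'   diagonal).
#' @return A symmetric distance matrix with zero diagonal.
#' @export
genetic_distance <- function(K) {
  D <- 1 - unclass(K)
  diag(D) <- 0
  D
}

#' Environmental distance
#'
#' Euclidean distances on standardized EVs.
#'
#' @param env Tibble with `sample` plus numeric EV columns.
#' @return A symmetric distance matrix (sample ids as dimnames).
#' @export
env_distance <- function(env) {
  ev <- as.matrix(env[setdiff(names(env), "sample")])
  ev <- ev[, apply(ev, 2, sd) > 0, drop = FALSE]
  D <- as.matrix(dist(scale(ev)))
  dimnames(D) <- list(env$sample, env$sample)
  D
}

#' Mantel test between two distance matrices
#'
#' The statistic is the Pearson correlation of the upper-triangle entries;
#' significance comes from jointly permuting rows and columns of the second
#' matrix, with the one-sided p-value
#' `(1 + #{permuted r >= observed r}) / (1 + n_perm)` (the test is
#' directional for positive correlation).
#'
#' @param d1,d2 Symmetric distance matrices over the same samples.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Optional seed for reproducible permutations.
#' @return Tibble: `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = NULL) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!all(dim(d1) == dim(d2))) abort("distance matrices must match")
  if (n_perm < 99) abort("n_perm must be >= 99")
  ut <- upper.tri(d1)
  v1 <- d1[ut]
  if (sd(v1) == 0 || sd(d2[ut]) == 0) abort("zero variance")
  robs <- cor(v1, d2[ut])
  n <- nrow(d1)
  run <- function() {
    count <- 0L
    for (b in seq_len(n_perm)) {
      pp <- sample.int(n)
      rp <- cor(v1, d2[pp, pp][ut])
      if (rp >= robs) count <- count + 1L
    }
    (1 + count) / (1 + n_perm)
  }
  p <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  tibble(r = robs, p = p, n_perm = as.integer(n_perm))
}
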