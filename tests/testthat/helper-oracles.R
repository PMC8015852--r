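# Independent brute-force oracles used to freeze expected values.  These are
# written against first principles (pair enumeration, explicit loops) and
# deliberately share no code with the package implementations they check.

# per-site pairwise diversity by exhaustive pair enumeration over alleles
oracle_site_pi <- function(alleles) {
  n <- length(alleles)
  diff <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      diff <- diff + as.integer(alleles[i] != alleles[j])
  diff / choose(n, 2)
}

# Tajima's D from first principles (1989 constants evaluated directly)
oracle_tajima_d <- function(pi_sum, S, n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Weir & Cockerham (1984) two-population components, explicit per-site loop
oracle_wc_fst <- function(dA, dB) {
  m <- ncol(dA)
  out <- numeric(m)
  for (s in seq_len(m)) {
    gA <- dA[, s][!is.na(dA[, s])]
    gB <- dB[, s][!is.na(dB[, s])]
    nA <- length(gA); nB <- length(gB)
    pA <- sum(gA) / (2 * nA); pB <- sum(gB) / (2 * nB)
    hA <- mean(gA == 1); hB <- mean(gB == 1)
    r <- 2
    nbar <- (nA + nB) / r
    nc <- (r * nbar - (nA^2 + nB^2) / (r * nbar)) / (r - 1)
    pbar <- (nA * pA + nB * pB) / (r * nbar)
    s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
    hbar <- (nA * hA + nB * hB) / (r * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 / r - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    out[s] <- a / (a + b + cc)
  }
  out
}

# IBS kinship entry by explicit per-pair loop
oracle_kinship <- function(D) {
  n <- nrow(D)
  K <- matrix(NA_real_, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n)) {
      ok <- !is.na(D[i, ]) & !is.na(D[j, ])
      K[i, j] <- mean((2 - abs(D[i, ok] - D[j, ok])) / 2)
    }
  K
}

# Mantel statistic as a flat-vector correlation
oracle_mantel_r <- function(d1, d2) {
  ut <- upper.tri(d1)
  cor(d1[ut], d2[ut])
}

# one-sided iHH by brute-force pairwise homozygosity: EHH(x) is the fraction
# of haplotype pairs identical at every site between the core and x
oracle_ihh_side <- function(H, positions, core_idx, side_idx, cutoff = 0.05) {
  n <- nrow(H)
  if (n < 2) return(NA_real_)
  xs <- 0; ys <- 1; ihh <- 0
  seen <- integer(0)
  for (s in side_idx) {
    seen <- c(seen, s)
    idpairs <- 0
    for (i in seq_len(n - 1))
      for (j in (i + 1):n)
        if (all(H[i, seen] == H[j, seen])) idpairs <- idpairs + 1
    ehh <- idpairs / choose(n, 2)
    d <- abs(positions[s] - positions[core_idx])
    ihh <- ihh + (d - xs) * (ys + ehh) / 2
    xs <- d; ys <- ehh
    if (ehh < cutoff) break
  }
  ihh
}

# build a small genotype_matrix from a dosage matrix (and optional haplotypes)
toy_geno <- function(dosage, pos = NULL, haplotypes = NULL, chrom = "chr1") {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  pos <- if (is.null(pos)) seq_len(m) * 10L else pos
  samples <- sprintf("s%02d", seq_len(nrow(dosage)))
  genotype_matrix(
    tibble::tibble(chrom = chrom, pos = as.integer(pos),
                   ref = rep("A", m), alt = rep("T", m)),
    dosage, samples, haplotypes)
}

# haplotype matrix -> toy phased genotype_matrix
toy_phased <- function(H, pos = NULL, chrom = "chr1") {
  H <- as.matrix(H)
  n <- nrow(H) / 2
  d <- H[seq(1, 2 * n, 2), , drop = FALSE] + H[seq(2, 2 * n, 2), , drop = FALSE]
  toy_geno(d, pos = pos, haplotypes = H, chrom = chrom)
}

`%||%` <- rlang::`%||%`
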