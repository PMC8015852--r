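#' Sliding-window specification
#'
#' @param window Window size in bp (default 10 kb).
#' @param step Step between window starts in bp (default 1 kb); must not
#'   exceed `window`.
#' @param min_snps Minimum SNPs for a window to receive a value; `NULL`
#'   defers to each metric's default (1 for diversity and FST, 3 for
#'   Tajima's D).  Thinner windows carry `NaN` and never enter outlier
#'   ranking.
#' @return A `window_spec` list.
#' @export
window_spec <- function(window = 10000, step = 1000, min_snps = NULL) {
  if (window <= 0) abort("window must be > 0")
  if (step > window) abort("step must be <= window")
  structure(list(window = window, step = step, min_snps = min_snps),
            class = "window_spec")
}

# full windows tiling [0, L); the partial tail window is dropped
window_grid <- function(chrom, L, spec) {
  if (L < spec$window) {
    starts <- 0
  } else {
    starts <- seq(0, L - spec$window, by = spec$step)
  }
  tibble(chrom = chrom, start = starts,
         end = pmin(starts + spec$window, L))
}

# sum per-site values and counts into windows via cumulative sums
window_aggregate <- function(wins, pos0, values) {
  o <- order(pos0)
  pos0 <- pos0[o]
  values <- values[o]
  cs <- c(0, cumsum(values))
  cn <- c(0, seq_along(values))
  lo <- findInterval(wins$start - 0.5, pos0) + 1L
  hi <- findInterval(wins$end - 0.5, pos0)
  n <- pmax(hi - lo + 1L, 0L)
  s <- ifelse(n > 0, cs[hi + 1L] - cs[lo], 0)
  list(sum = s, n = as.integer(n), lo = lo, hi = hi, order = o)
}

site_pi <- function(ac, an) {
  ifelse(an >= 2, 2 * ac * (an - ac) / (an * (an - 1)), NA_real_)
}

resolve_chrom_length <- function(geno, chrom_length) {
  chroms <- unique(geno$variants$chrom)
  if (is.null(chrom_length)) {
    chrom_length <- vapply(chroms, function(ch)
      max(geno$variants$pos[geno$variants$chrom == ch]), numeric(1))
  }
  if (is.null(names(chrom_length))) names(chrom_length) <- chroms
  chrom_length
}

new_track <- function(df, metric) {
  df$metric <- metric
  structure(df, class = c("window_track", class(tibble())))
}

#' Windowed nucleotide diversity
#'
#' Per-site diversity is `2 c (n - c) / (n (n - 1))` with `c` the alternate
#' allele count and `n` the called allele number in the sample subset; the
#' window value is the per-site sum divided by the full window span in bp
#' (no callability mask is applied).
#'
#' @param geno A [genotype_matrix()].
#' @param samples Optional sample-id subset (default: all samples).
#' @param spec A [window_spec()].
#' @param chrom_length Optional named vector of chromosome lengths in bp;
#'   defaults to the last variant position per chromosome.
#' @return A window track tibble: `chrom`, `start` (0-based), `end`,
#'   `n_snps`, `value`, `metric`.
#' @export
windowed_pi <- function(geno, samples = NULL, spec = window_spec(),
                        chrom_length = NULL) {
  d <- subset_dosage(geno, samples)
  if (nrow(d) < 2) abort("windowed_pi needs at least 2 samples")
  min_snps <- spec$min_snps %||% 1L
  ac <- colSums(d, na.rm = TRUE)
  an <- 2 * colSums(!is.na(d))
  pi_s <- site_pi(ac, an)
  chrom_length <- resolve_chrom_length(geno, chrom_length)
  out <- purrr::map_dfr(names(chrom_length), function(ch) {
    # count every evaluable site (monomorphic-in-subset sites contribute 0);
    # windows with no sites at all carry NaN and never enter outlier ranking
    sel <- which(geno$variants$chrom == ch & !is.na(pi_s))
    wins <- window_grid(ch, chrom_length[[ch]], spec)
    agg <- window_aggregate(wins, geno$variants$pos[sel] - 1, pi_s[sel])
    wins$n_snps <- agg$n
    wins$value <- ifelse(agg$n >= min_snps,
                         agg$sum / (wins$end - wins$start), NaN)
    wins
  })
  new_track(out, "pi")
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D
#'
#' For each window with at least `min_snps` segregating sites, computes
#' `D = (pi_sum - S / a1) / sqrt(e1 S + e2 S (S - 1))` using the classical
#' constants evaluated at `n` = the modal called-allele number among the
#' window's segregating sites; `pi_sum` is the per-site pairwise diversity
#' summed over the window (counts, not per-bp).  Sites with fewer than four
#' called alleles are not evaluated.  Thin windows carry `NaN`.
#'
#' @inheritParams windowed_pi
#' @return A window track tibble (see [windowed_pi()]).
#' @export
tajimas_d <- function(geno, samples = NULL, spec = window_spec(),
                      chrom_length = NULL) {
  d <- subset_dosage(geno, samples)
  min_snps <- spec$min_snps %||% 3L
  ac <- colSums(d, na.rm = TRUE)
  an <- 2 * colSums(!is.na(d))
  seg <- an >= 4 & ac > 0 & ac < an
  pi_s <- site_pi(ac, an)
  chrom_length <- resolve_chrom_length(geno, chrom_length)
  out <- purrr::map_dfr(names(chrom_length), function(ch) {
    sel <- which(geno$variants$chrom == ch & seg)
    wins <- window_grid(ch, chrom_length[[ch]], spec)
    pos0 <- geno$variants$pos[sel] - 1
    o <- order(pos0)
    pos0 <- pos0[o]
    pi_site <- pi_s[sel][o]
    an_site <- an[sel][o]
    lo <- findInterval(wins$start - 0.5, pos0) + 1L
    hi <- findInterval(wins$end - 0.5, pos0)
    nsnp <- pmax(hi - lo + 1L, 0L)
    cs <- c(0, cumsum(pi_site))
    val <- rep(NaN, nrow(wins))
    ok <- which(nsnp >= max(min_snps, 1L))
    for (w in ok) {
      idx <- lo[w]:hi[w]
      S <- length(idx)
      n_mode <- as.integer(names(which.max(table(an_site[idx]))))
      k <- tajima_constants(n_mode)
      denom <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
      val[w] <- ((cs[hi[w] + 1] - cs[lo[w]]) - S / k$a1) / denom
    }
    wins$n_snps <- nsnp
    wins$value <- val
    wins
  })
  new_track(out, "tajd")
}

# Weir & Cockerham (1984) two-population variance components per SNP.
# Returns a data frame of a, b, c; the per-SNP estimate is a/(a+b+c).
wc_components <- function(dA, dB) {
  nA <- colSums(!is.na(dA))
  nB <- colSums(!is.na(dB))
  pA <- colSums(dA, na.rm = TRUE) / (2 * nA)
  pB <- colSums(dB, na.rm = TRUE) / (2 * nB)
  hA <- colSums(dA == 1L, na.rm = TRUE) / nA
  hB <- colSums(dB == 1L, na.rm = TRUE) / nB
  r <- 2
  nbar <- (nA + nB) / r
  nc <- (r * nbar - (nA^2 + nB^2) / (r * nbar)) / (r - 1)
  pbar <- (nA * pA + nB * pB) / (r * nbar)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nA * hA + nB * hB) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  data.frame(a = a, b = b, c = cc)
}

#' Weir-Cockerham FST between two groups
#'
#' Per-SNP variance components `a` (among populations), `b` (among
#' individuals within populations) and `c` (within individuals) from
#' genotype counts; the per-SNP estimate is `a / (a + b + c)` and the
#' windowed estimate is the ratio of sums `sum(a) / sum(a + b + c)` over the
#' SNPs in each window.  Sites monomorphic across both groups are `NaN`
#' per-SNP and excluded from window sums.  Windowed values are clamped to
#' `[0, 1]` on report; per-SNP estimates are not (slightly negative values
#' are meaningful evidence of no differentiation).
#'
#' @param geno A [genotype_matrix()].
#' @param group_a,group_b Character vectors of sample ids.
#' @param spec A [window_spec()].
#' @param chrom_length See [windowed_pi()].
#' @return List with `per_snp` (tibble: `chrom`, `pos`, `fst`) and `windows`
#'   (window track tibble).
#' @export
weir_cockerham_fst <- function(geno, group_a, group_b, spec = window_spec(),
                               chrom_length = NULL) {
  dA <- subset_dosage(geno, group_a)
  dB <- subset_dosage(geno, group_b)
  if (nrow(dA) < 2 || nrow(dB) < 2)
    abort("each group needs at least 2 samples")
  min_snps <- spec$min_snps %||% 1L
  comp <- wc_components(dA, dB)
  acAB <- colSums(dA, na.rm = TRUE) + colSums(dB, na.rm = TRUE)
  anAB <- 2 * (colSums(!is.na(dA)) + colSums(!is.na(dB)))
  poly <- acAB > 0 & acAB < anAB
  denom <- comp$a + comp$b + comp$c
  fst <- ifelse(poly & denom != 0, comp$a / denom, NaN)
  per_snp <- tibble(chrom = geno$variants$chrom, pos = geno$variants$pos,
                    fst = fst)
  chrom_length <- resolve_chrom_length(geno, chrom_length)
  wins <- purrr::map_dfr(names(chrom_length), function(ch) {
    sel <- which(geno$variants$chrom == ch & poly & !is.na(denom) & denom != 0)
    w <- window_grid(ch, chrom_length[[ch]], spec)
    aggA <- window_aggregate(w, geno$variants$pos[sel] - 1, comp$a[sel])
    aggD <- window_aggregate(w, geno$variants$pos[sel] - 1, denom[sel])
    w$n_snps <- aggA$n
    v <- ifelse(aggA$n >= min_snps & aggD$sum != 0, aggA$sum / aggD$sum, NaN)
    w$value <- pmin(1, pmax(0, v))
    w
  })
  list(per_snp = per_snp, windows = new_track(wins, "fst"))
}

#' Reduction of diversity between matched tracks
#'
#' `ROD = 1 - pi_target / pi_reference` per window; `NaN` where the
#' reference diversity is zero.  The two tracks must share an identical
#' window grid (as produced by [windowed_pi()] on the same spec).
#'
#' @param pi_target,pi_rest Window tracks from [windowed_pi()], the focal
#'   group and the pooled remaining groups respectively.
#' @return A window track tibble with metric `"rod"`.
#' @export
rod <- function(pi_target, pi_rest) {
  if (nrow(pi_target) != nrow(pi_rest) ||
      !all(pi_target$chrom == pi_rest$chrom) ||
      !all(pi_target$start == pi_rest$start) ||
      !all(pi_target$end == pi_rest$end))
    abort("pi_target and pi_rest must share an identical window grid")
  out <- pi_target
  out$n_snps <- pi_target$n_snps + pi_rest$n_snps
  out$value <- ifelse(pi_rest$value > 0, 1 - pi_target$value / pi_rest$value,
                      NaN)
  new_track(dplyr::select(out, -"metric"), "rod")
}
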