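#' Genome-wide site-frequency spectrum
#'
#' Counts of derived (alternate) allele frequencies over all polymorphic
#' sites, used as the background spectrum for the composite-likelihood sweep
#' scan.  When missingness makes the called-allele number vary across sites,
#' only sites at the modal called-allele number are used (with a warning).
#'
#' @param geno A [genotype_matrix()].
#' @param samples Optional sample-id subset.
#' @param folded Collapse counts `i` and `n - i` (no ancestral-state
#'   information).
#' @return An `sfs` list: `n` (allele sample size), `counts` (`xi_1` ...
#'   `xi_{n-1}`, or the folded first half), `folded`.
#' @export
background_sfs <- function(geno, samples = NULL, folded = FALSE) {
  d <- subset_dosage(geno, samples)
  ac <- colSums(d, na.rm = TRUE)
  an <- 2 * colSums(!is.na(d))
  if (max(an) < 4) abort("background_sfs needs at least 4 allele copies")
  n <- as.integer(names(which.max(table(an[an > 0]))))
  use <- an == n & ac > 0 & ac < an
  if (any(an != n & ac > 0 & ac < an))
    warn("background_sfs: sites away from the modal called-allele number were excluded")
  if (!any(use)) abort("no polymorphic sites for the SFS")
  xi <- tabulate(ac[use], nbins = n - 1)
  if (folded) {
    half <- floor(n / 2)
    eta <- vapply(seq_len(half), function(i)
      if (i < n - i) xi[i] + xi[n - i] else xi[i], numeric(1))
    structure(list(n = n, counts = eta, folded = TRUE), class = "sfs")
  } else {
    structure(list(n = n, counts = xi, folded = FALSE), class = "sfs")
  }
}

# spectrum probabilities conditioned on polymorphism, as a full unfolded
# vector over derived counts 1..n-1 (a folded SFS is symmetrized)
sfs_probs <- function(sfs) {
  n <- sfs$n
  if (!sfs$folded) return(sfs$counts / sum(sfs$counts))
  xi <- numeric(n - 1)
  for (i in seq_along(sfs$counts)) {
    if (i < n - i) {
      xi[i] <- sfs$counts[i] / 2
      xi[n - i] <- sfs$counts[i] / 2
    } else xi[i] <- sfs$counts[i]
  }
  xi / sum(xi)
}

#' Composite-likelihood-ratio sweep scan
#'
#' At each grid position the site pattern near a putative sweep is modeled by
#' distorting the genome-wide background spectrum: a lineage at distance `d`
#' bp escapes the sweep with probability `1 - exp(-alpha d)`; the escaped
#' lineages plus the single sweeping haplotype are a hypergeometric draw from
#' the background configuration, with the sweeping haplotype's allele copied
#' to every non-escaped lineage.  The composite likelihood combines the
#' conditional spectrum at polymorphic sites with an invariant-position term
#' (positions without a SNP support the sweep model strongly inside the
#' diversity trough it predicts), using the chromosome's per-bp polymorphism
#' rate as the background.  `alpha` (inversely related to sweep strength, so
#' the `alpha -> Inf` limit is the neutral background) is maximized per grid
#' point over a log grid followed by golden-section refinement, and
#' `CLR = 2 (logL_sweep - logL_background)` over the positions within
#' `max_dist` of the grid point (truncated at chromosome ends).
#'
#' @param geno A [genotype_matrix()].
#' @param samples Optional sample-id subset (must match the SFS's panel).
#' @param sfs Background spectrum from [background_sfs()] on the same subset.
#' @param grid_step Spacing of test positions in bp.
#' @param max_dist Sites farther than this from a grid point are ignored
#'   (their sweep and background likelihoods coincide to numerical
#'   precision).
#' @param alpha_range Search bounds for `alpha` (per bp); `1 / alpha` is
#'   roughly the hitchhiking footprint the model can describe, so the range
#'   spans footprints from a few hundred bp to several Mb.
#' @param spec,chrom_length Window grid for the summary track (value = max
#'   CLR of grid points in each window); see [windowed_pi()].
#' @return List with `fits` (tibble: `chrom`, `pos`, `alpha`, `ll_sweep`,
#'   `ll_bg`, `clr`) and `track` (window track tibble, metric `"clr"`).
#' @export
clr_scan <- function(geno, samples = NULL, sfs = background_sfs(geno, samples),
                     grid_step = 2000, max_dist = 2e5,
                     alpha_range = c(1e-7, 1e-2),
                     spec = window_spec(), chrom_length = NULL) {
  if (grid_step <= 0) abort("grid_step must be > 0")
  d <- subset_dosage(geno, samples)
  ac <- colSums(d, na.rm = TRUE)
  an <- 2 * colSums(!is.na(d))
  n <- sfs$n
  use <- an == n & ac > 0 & ac < an
  q <- sfs_probs(sfs)
  logq <- log(q)

  # lookup tables on a log grid of x = alpha * d: conditional spectrum and
  # polymorphism mass under the sweep transform
  xgrid <- exp(seq(log(1e-4), log(25), length.out = 72))
  tabs <- clr_prob_table_cpp(q, 1 - exp(-xgrid))
  # probability floors keep the composite likelihood finite: without them a
  # single recovery mutation inside the predicted trough vetoes the sweep
  tab <- log(pmax(tabs$cond, 1e-12))
  lmass <- log(pmax(tabs$mass, 1e-12))
  B <- length(xgrid)
  xedge <- c(0, xgrid[-1], max(xgrid)) # ring b covers x in [xedge[b], xedge[b+1])
  xmax <- max(xgrid)

  chrom_length <- resolve_chrom_length(geno, chrom_length)
  fits <- purrr::map_dfr(names(chrom_length), function(ch) {
    sel <- which(geno$variants$chrom == ch & use)
    L <- chrom_length[[ch]]
    # test only positions with full flanking coverage: a truncated flank
    # makes the invariant term incomparable across grid points
    grid <- seq(grid_step / 2, L, by = grid_step)
    grid <- grid[grid > max_dist & grid < L - max_dist]
    if (!length(sel) || !length(grid)) return(tibble())
    pos <- geno$variants$pos[sel]
    k <- ac[sel]
    rho <- length(sel) / L # per-bp polymorphism rate, background
    l1m_rho <- log1p(-rho)
    l1m_mass <- log1p(-rho * tabs$mass)
    purrr::map_dfr(grid, function(gp) {
      near <- which(abs(pos - gp) <= max_dist)
      if (length(near) < 2)
        return(tibble(chrom = ch, pos = gp, alpha = NA_real_,
                      ll_sweep = NA_real_, ll_bg = NA_real_, clr = 0))
      dd <- pmax(abs(pos[near] - gp), 1)
      kk <- k[near]
      avail_l <- min(max_dist, gp - 1)
      avail_r <- min(max_dist, L - gp)
      obj <- function(la) {
        a <- exp(la)
        x <- a * dd
        inx <- x < xmax
        bin <- pmin(pmax(findInterval(x[inx], xgrid), 1L), B)
        # polymorphic positions: conditional spectrum + polymorphism mass
        ll_poly_s <- sum(tab[cbind(kk[inx], bin)]) + sum(lmass[bin])
        ll_poly_b <- sum(logq[kk[inx]])
        # invariant positions, counted per distance ring on each side
        de <- xedge / a
        bp_ring <- pmax(0, pmin(avail_l, de[-1]) - pmin(avail_l, de[-(B + 1)])) +
          pmax(0, pmin(avail_r, de[-1]) - pmin(avail_r, de[-(B + 1)]))
        n_ring <- tabulate(bin, nbins = B)
        inv_ring <- pmax(bp_ring - n_ring, 0)
        ll_inv_s <- sum(inv_ring * l1m_mass)
        ll_inv_b <- sum(inv_ring) * l1m_rho
        (ll_poly_s + ll_inv_s) - (ll_poly_b + ll_inv_b)
      }
      las <- seq(log(alpha_range[1]), log(alpha_range[2]), length.out = 19)
      vals <- vapply(las, obj, numeric(1))
      i <- which.max(vals)
      lo <- las[max(1, i - 1)]; hi <- las[min(length(las), i + 1)]
      opt <- optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-3)
      dl <- max(opt$objective, vals[i])
      la_hat <- if (opt$objective >= vals[i]) opt$maximum else las[i]
      ll_bg <- sum(logq[kk])
      tibble(chrom = ch, pos = gp, alpha = exp(la_hat),
             ll_sweep = ll_bg + dl, ll_bg = ll_bg,
             clr = max(0, 2 * dl))
    })
  })

  wins <- purrr::map_dfr(names(chrom_length), function(ch) {
    w <- window_grid(ch, chrom_length[[ch]], spec)
    f <- fits[fits$chrom == ch, ]
    w$n_snps <- vapply(seq_len(nrow(w)), function(i)
      sum(f$pos > w$start[i] & f$pos <= w$end[i]), integer(1))
    w$value <- vapply(seq_len(nrow(w)), function(i) {
      v <- f$clr[f$pos > w$start[i] & f$pos <= w$end[i]]
      if (length(v)) max(v) else NaN
    }, numeric(1))
    w
  })
  list(fits = fits, track = new_track(wins, "clr"))
}

#' Mu-type composite sweep statistic over SNP-driven windows
#'
#' Sliding windows of `snps_per_window` consecutive SNPs combine three sweep
#' signals multiplicatively: `mu_var`, the window span relative to its
#' expectation under uniform SNP density; `mu_sfs`, the pseudo-counted
#' fraction of singleton plus highest-frequency sites, normalized by its
#' genome-wide mean; and `mu_ld`, the ratio of within-half to cross-half
#' mean r-squared (`epsilon = 0.01` guards empty terms).  r-squared is
#' computed on haplotypes when present, else on dosages (composite LD).
#'
#' @param geno A [genotype_matrix()].
#' @param samples Optional sample-id subset.
#' @param snps_per_window Even window size in SNPs, at least 4.
#' @param step_snps Slide between window starts, in SNPs.
#' @param ld_max_haps r-squared is estimated from at most this many
#'   haplotype rows (the estimate is stable well below typical panel
#'   sizes and the correlation matrices dominate the scan's cost).
#' @param chrom_length See [windowed_pi()].
#' @return Tibble: `chrom`, `start`, `end` (bp of the first/last SNP),
#'   `center`, `span`, `mu_var`, `mu_sfs`, `mu_ld`, `mu`.
#' @export
mu_scan <- function(geno, samples = NULL, snps_per_window = 50,
                    step_snps = 1, ld_max_haps = 200, chrom_length = NULL) {
  W <- as.integer(snps_per_window)
  if (W < 4 || W %% 2 != 0) abort("snps_per_window must be even and >= 4")
  d <- subset_dosage(geno, samples)
  ac <- colSums(d, na.rm = TRUE)
  an <- 2 * colSums(!is.na(d))
  poly <- ac > 0 & ac < an
  X <- if (!is.null(geno$haplotypes)) subset_haplotypes(geno, samples) else d
  if (nrow(X) > ld_max_haps) X <- X[seq_len(ld_max_haps), , drop = FALSE]
  eps <- 0.01
  chrom_length <- resolve_chrom_length(geno, chrom_length)
  out <- purrr::map_dfr(names(chrom_length), function(ch) {
    sel <- which(geno$variants$chrom == ch & poly)
    if (length(sel) < W) return(tibble())
    pos <- geno$variants$pos[sel]
    L <- chrom_length[[ch]]
    S <- length(sel)
    starts <- seq(1, S - W + 1, by = step_snps)
    rare <- ac[sel] == 1 | ac[sel] == an[sel] - 1
    crare <- c(0, cumsum(rare))
    half <- W / 2
    purrr::map_dfr(starts, function(i) {
      idx <- sel[i:(i + W - 1)]
      span <- pos[i + W - 1] - pos[i]
      mu_var <- (span / L) * (S / W)
      sfs_raw <- (crare[i + W] - crare[i] + 1) / (W + 2)
      Xi <- X[, idx, drop = FALSE]
      cm <- suppressWarnings(
        if (anyNA(Xi)) cor(Xi, use = "pairwise.complete.obs") else cor(Xi))
      r2 <- cm^2
      li <- 1:half; ri <- (half + 1):W
      wl <- mean(r2[li, li][upper.tri(r2[li, li])], na.rm = TRUE)
      wr <- mean(r2[ri, ri][upper.tri(r2[ri, ri])], na.rm = TRUE)
      xc <- mean(r2[li, ri], na.rm = TRUE)
      if (!is.finite(wl)) wl <- 0
      if (!is.finite(wr)) wr <- 0
      if (!is.finite(xc)) xc <- 0
      mu_ld <- (wl + wr + eps) / (2 * xc + eps)
      tibble(chrom = ch, start = pos[i], end = pos[i + W - 1],
             center = (pos[i] + pos[i + W - 1]) / 2, span = span,
             mu_var = mu_var, sfs_raw = sfs_raw, mu_ld = mu_ld)
    })
  })
  if (nrow(out) == 0)
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  center = numeric(), span = numeric(), mu_var = numeric(),
                  mu_sfs = numeric(), mu_ld = numeric(), mu = numeric()))
  out$mu_sfs <- out$sfs_raw / mean(out$sfs_raw)
  out$sfs_raw <- NULL
  out$mu <- out$mu_var * out$mu_sfs * out$mu_ld
  out
}

#' Project mu-statistic SNP windows onto a bp window grid
#'
#' Summarizes [mu_scan()] output on the common sliding-window grid used by
#' the other metrics (value = max `mu` of SNP windows whose center falls in
#' the bp window), so it can enter [consensus_regions()].
#'
#' @param mu Output of [mu_scan()].
#' @param geno The [genotype_matrix()] the scan was run on.
#' @param spec,chrom_length See [windowed_pi()].
#' @return A window track tibble, metric `"mu"`.
#' @export
mu_track <- function(mu, geno, spec = window_spec(), chrom_length = NULL) {
  chrom_length <- resolve_chrom_length(geno, chrom_length)
  wins <- purrr::map_dfr(names(chrom_length), function(ch) {
    w <- window_grid(ch, chrom_length[[ch]], spec)
    m <- mu[mu$chrom == ch, ]
    w$n_snps <- vapply(seq_len(nrow(w)), function(i)
      sum(m$center > w$start[i] & m$center <= w$end[i]), integer(1))
    w$value <- vapply(seq_len(nrow(w)), function(i) {
      v <- m$mu[m$center > w$start[i] & m$center <= w$end[i]]
      if (length(v)) max(v) else NaN
    }, numeric(1))
    w
  })
  new_track(wins, "mu")
}

# EHH decay outward from a core over one side; returns the trapezoidal
# integral (iHH) for one allele class
ihh_one_side <- function(hap_rows, positions, core_pos, side_idx, cutoff) {
  n <- nrow(hap_rows)
  if (n < 2) return(NA_real_)
  pairs_tot <- choose(n, 2)
  x <- 0
  y <- 1
  g <- rep(1L, n)
  xs <- 0; ys <- 1
  ihh <- 0
  for (s in side_idx) {
    g <- g * 2L + hap_rows[, s]
    g <- match(g, unique(g))
    tab <- tabulate(g)
    ehh <- sum(choose(tab, 2)) / pairs_tot
    d <- abs(positions[s] - core_pos)
    ihh <- ihh + (d - xs) * (ys + ehh) / 2
    xs <- d; ys <- ehh
    if (ehh < cutoff) break
  }
  ihh
}

#' Integrated haplotype score scan
#'
#' For each core SNP with derived-allele frequency inside `freq_range`,
#' extended haplotype homozygosity (EHH) is the probability that two random
#' haplotypes carrying the core allele are identical over the interval from
#' the core to a flanking site.  EHH is integrated (trapezoid, physical bp)
#' outward on each side until it decays below `ehh_cutoff`, summed into
#' `iHH_A` (ancestral) and `iHH_D` (derived); the unstandardized score is
#' `ln(iHH_A / iHH_D)` and scores are standardized to z-scores within
#' derived-frequency bins.  Bins with fewer than `min_bin` scores are set
#' `NaN` with a warning.
#'
#' @param geno A phased [genotype_matrix()] (errors otherwise).
#' @param samples Optional sample-id subset.
#' @param freq_bin_width Width of the derived-frequency standardization bins.
#' @param ehh_cutoff EHH level at which integration stops.
#' @param freq_range Admissible derived frequency for core SNPs.
#' @param min_bin Minimum scores per bin for standardization.
#' @return Tibble: `chrom`, `pos`, `derived_freq`, `ihh_a`, `ihh_d`,
#'   `uihs` (unstandardized), `ihs` (standardized).
#' @export
ihs_scan <- function(geno, samples = NULL, freq_bin_width = 0.05,
                     ehh_cutoff = 0.05, freq_range = c(0.05, 0.95),
                     min_bin = 10) {
  if (is.null(geno$haplotypes))
    abort("phased haplotypes required for iHS")
  H <- subset_haplotypes(geno, samples)
  daf <- colMeans(H)
  cores <- which(daf >= freq_range[1] & daf <= freq_range[2])
  res <- purrr::map_dfr(split(cores, geno$variants$chrom[cores]), function(cc) {
    purrr::map_dfr(cc, function(ci) {
      ch <- geno$variants$chrom[ci]
      on_ch <- geno$variants$chrom == ch
      pos <- geno$variants$pos
      left <- which(on_ch & pos < pos[ci])
      right <- which(on_ch & pos > pos[ci])
      left <- left[order(pos[left], decreasing = TRUE)]
      right <- right[order(pos[right])]
      der <- H[, ci] == 1L
      hd <- H[der, , drop = FALSE]
      ha <- H[!der, , drop = FALSE]
      ihh_d <- ihh_one_side(hd, pos, pos[ci], left, ehh_cutoff) +
        ihh_one_side(hd, pos, pos[ci], right, ehh_cutoff)
      ihh_a <- ihh_one_side(ha, pos, pos[ci], left, ehh_cutoff) +
        ihh_one_side(ha, pos, pos[ci], right, ehh_cutoff)
      tibble(chrom = ch, pos = pos[ci], derived_freq = daf[ci],
             ihh_a = ihh_a, ihh_d = ihh_d,
             uihs = ifelse(ihh_a > 0 & ihh_d > 0, log(ihh_a / ihh_d),
                           NA_real_))
    })
  })
  if (nrow(res) == 0) {
    res$ihs <- numeric()
    return(res)
  }
  bins <- floor(res$derived_freq / freq_bin_width)
  res$ihs <- NA_real_
  thin <- FALSE
  for (b in unique(bins)) {
    i <- which(bins == b & !is.na(res$uihs))
    if (length(i) < min_bin) {
      thin <- TRUE
      res$ihs[bins == b] <- NaN
      next
    }
    res$ihs[i] <- (res$uihs[i] - mean(res$uihs[i])) / sd(res$uihs[i])
  }
  if (thin)
    warn("ihs_scan: frequency bins with too few scores were set to NaN")
  res
}

# merge marked windows (touching or overlapping) into regions
merge_marked <- function(chrom, start, end) {
  if (!length(start))
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  purrr::map_dfr(split(seq_along(start), chrom), function(i) {
    o <- i[order(start[i])]
    s <- start[o]; e <- end[o]
    grp <- cumsum(c(1, as.integer(s[-1] > cummax(e[-length(e)]))))
    tibble(chrom = chrom[o[1]],
           start = as.numeric(tapply(s, grp, min)),
           end = as.numeric(tapply(e, grp, max)))
  })
}

#' Consensus candidate-selection-region caller
#'
#' Per metric, windows at or beyond the empirical `1 - tail_fraction`
#' quantile (ties at the threshold included; lower tail for metrics whose
#' `tail_side` is `"low"`) are marked as selective outliers, and
#' overlapping or adjacent marked windows are merged into per-metric outlier
#' regions.  Merged spans of the union over metrics become candidate
#' selection regions when at least `min_metrics` metrics contribute at least
#' 1 bp of overlap.
#'
#' @param tracks Named list of window tracks (identical window grids
#'   required); names default to each track's `metric` column.
#' @param tail_fraction Outlier tail mass per metric (default 0.05).
#' @param tail_side Named character vector, `"high"` or `"low"` per metric.
#'   Defaults: high for `rod`, `fst`, `clr`, `mu`; low for `pi` and `tajd`
#'   (post-sweep diversity and D are depressed; pass `tajd = "high"` to
#'   reproduce an upper-tail D scan).
#' @param min_metrics Minimum supporting metrics per region.
#' @return Tibble of regions: `chrom`, `start`, `end`, `n_metrics`,
#'   `metrics` (list column), `windows` (list column of member window
#'   indices into the grid).
#' @export
consensus_regions <- function(tracks, tail_fraction = 0.05, tail_side = NULL,
                              min_metrics = 2) {
  if (is.null(names(tracks)) || !any(nzchar(names(tracks))))
    names(tracks) <- vapply(tracks, function(t) t$metric[1], character(1))
  if (length(tracks) < 2) abort("consensus_regions needs >= 2 tracks")
  ref <- tracks[[1]]
  for (t in tracks[-1]) {
    if (nrow(t) != nrow(ref) || !all(t$chrom == ref$chrom) ||
        !all(t$start == ref$start) || !all(t$end == ref$end))
      abort("tracks must share an identical window grid")
  }
  defaults <- c(pi = "low", tajd = "low", rod = "high", fst = "high",
                clr = "high", mu = "high")
  side <- setNames(rep("high", length(tracks)), names(tracks))
  known <- names(tracks) %in% names(defaults)
  side[known] <- defaults[names(tracks)[known]]
  if (!is.null(tail_side)) side[names(tail_side)] <- tail_side

  per_metric <- purrr::imap(tracks, function(t, nm) {
    v <- t$value
    ok <- is.finite(v)
    if (side[[nm]] == "high") {
      thr <- quantile(v[ok], 1 - tail_fraction, names = FALSE)
      marked <- ok & v >= thr
    } else {
      thr <- quantile(v[ok], tail_fraction, names = FALSE)
      marked <- ok & v <= thr
    }
    list(marked = marked,
         regions = merge_marked(t$chrom[marked], t$start[marked],
                                t$end[marked]),
         threshold = thr)
  })

  all_marked <- Reduce(`|`, lapply(per_metric, `[[`, "marked"))
  union_regions <- merge_marked(ref$chrom[all_marked], ref$start[all_marked],
                                ref$end[all_marked])
  if (nrow(union_regions) == 0)
    return(structure(tibble(chrom = character(), start = numeric(),
                            end = numeric(), n_metrics = integer(),
                            metrics = list(), windows = list()),
                     thresholds = lapply(per_metric, `[[`, "threshold"),
                     class = c("sweep_regions", class(tibble()))))
  supports <- purrr::map(seq_len(nrow(union_regions)), function(i) {
    r <- union_regions[i, ]
    names(which(vapply(per_metric, function(pm) {
      any(pm$regions$chrom == r$chrom & pm$regions$start < r$end &
            pm$regions$end > r$start)
    }, logical(1))))
  })
  member <- purrr::map(seq_len(nrow(union_regions)), function(i) {
    r <- union_regions[i, ]
    which(ref$chrom == r$chrom & ref$start < r$end & ref$end > r$start &
            all_marked)
  })
  out <- union_regions
  out$n_metrics <- lengths(supports)
  out$metrics <- supports
  out$windows <- member
  out <- out[out$n_metrics >= min_metrics, , drop = FALSE]
  structure(out, thresholds = lapply(per_metric, `[[`, "threshold"),
            class = c("sweep_regions", class(tibble())))
}
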