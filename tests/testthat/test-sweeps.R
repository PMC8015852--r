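test_that("the site-frequency spectrum counts and folds correctly", {
  # 3 sites with derived counts 1, 1, 2 at n = 4
  H <- rbind(c(1, 0, 1), c(0, 0, 1), c(0, 1, 0), c(0, 0, 0))
  g <- toy_phased(H)
  sfs <- background_sfs(g)
  expect_equal(sfs$n, 4L)
  expect_equal(sfs$counts, c(2, 1, 0))
  folded <- background_sfs(g, folded = TRUE)
  expect_equal(folded$counts, c(2, 1))
})

test_that("the sweep spectrum transform reduces to the background at full escape", {
  q <- c(2, 1, 0) / 3
  tab <- adaptscan:::clr_prob_table_cpp(q, c(1, 0.3))
  # p_e = 1: every lineage escapes, the background is returned exactly;
  # a site with derived count 2 has probability 1/3
  expect_equal(tab$cond[, 1], q, tolerance = 1e-12)
  expect_equal(tab$cond[2, 1], 1 / 3, tolerance = 1e-12)
  expect_equal(tab$mass[1], 1, tolerance = 1e-12)
  # any escape level yields a proper conditional distribution
  expect_equal(sum(tab$cond[, 2]), 1, tolerance = 1e-12)
  expect_true(tab$mass[2] < 1)
})

test_that("the sweep model approaches the background as alpha grows", {
  # on fixed data the per-grid-point likelihood gap must vanish for weak
  # sweeps (large alpha); i.e. CLR computed with alpha forced large is ~ 0
  withr::with_seed(41, {
    H <- matrix(rbinom(20 * 200, 1, 0.3), 20, 200)
    H <- H[, colSums(H) > 0 & colSums(H) < 20, drop = FALSE]
    g <- toy_phased(H, pos = sort(sample(1e5, ncol(H))))
    sfs <- background_sfs(g)
    q <- adaptscan:::sfs_probs(sfs)
    tab <- adaptscan:::clr_prob_table_cpp(q, 1 - exp(-c(0.5, 2, 10, 24)))
    ac <- colSums(H)
    # distance fixed: likelihood ratio per site at increasing x = alpha * d
    lr <- vapply(seq_len(ncol(tab$cond)), function(i)
      sum(log(tab$cond[ac, i]) - log(q[ac])), numeric(1))
    expect_lt(abs(lr[4]), abs(lr[1]))
    expect_lt(abs(lr[4]), 0.05 * ncol(H))
  })
})

test_that("mu components respond to spectrum shape and SNP spacing", {
  withr::with_seed(42, {
    n <- 20
    # singleton-heavy region followed by intermediate-frequency region
    mk_col <- function(k) sample(c(rep(1L, k), rep(0L, n - k)))
    H <- cbind(sapply(rep(1, 12), mk_col), sapply(rep(10, 12), mk_col))
    g <- toy_phased(H, pos = c(1:12 * 100L, 5000L + 1:12 * 100L))
    mu <- mu_scan(g, snps_per_window = 12, step_snps = 12,
                  chrom_length = c(chr1 = 10000))
    expect_equal(nrow(mu), 2L)
    expect_gt(mu$mu_sfs[1], mu$mu_sfs[2]) # singleton window scores higher
  })
})

test_that("mu_var reflects relative window span", {
  withr::with_seed(43, {
    n <- 10
    H <- matrix(rbinom(n * 40, 1, 0.5), n, 40)
    H[1, ] <- 1L; H[2, ] <- 0L # keep every column polymorphic
    # 20 SNPs packed tightly, 20 spread widely
    pos <- c(1:20 * 10L, 1000L + 1:20 * 500L)
    g <- toy_phased(H, pos = pos)
    mu <- mu_scan(g, snps_per_window = 20, step_snps = 20,
                  chrom_length = c(chr1 = 11000))
    expect_gt(mu$mu_var[2], mu$mu_var[1])
  })
})

test_that("iHS equals zero when derived and ancestral flanks are identical", {
  # core splits haplotypes 4/4; both classes share the same flanking pattern
  flank <- rbind(c(1, 0, 1), c(0, 1, 0), c(1, 1, 0), c(0, 0, 1))
  H <- cbind(rbind(flank, flank)[, 1, drop = FALSE],
             c(1, 1, 1, 1, 0, 0, 0, 0),
             rbind(flank, flank)[, 2:3])
  g <- toy_phased(H, pos = c(100L, 200L, 300L, 400L))
  res <- ihs_scan(g, freq_bin_width = 1, min_bin = 1)
  core <- res[res$pos == 200, ]
  expect_equal(core$uihs, 0, tolerance = 1e-12)
})

test_that("iHH matches the brute-force pairwise-homozygosity oracle", {
  withr::with_seed(44, {
    for (rep in 1:4) {
      H <- matrix(rbinom(8 * 7, 1, 0.5), 8, 7)
      H[, 4] <- c(1, 1, 1, 0, 0, 0, 1, 0) # core at derived freq 0.5
      pos <- c(50L, 120L, 260L, 400L, 470L, 590L, 800L)
      g <- toy_phased(H, pos = pos)
      res <- ihs_scan(g, freq_bin_width = 1, min_bin = 1, ehh_cutoff = 0.05)
      row <- res[res$pos == 400, ]
      der <- H[, 4] == 1
      exp_d <- oracle_ihh_side(H[der, , drop = FALSE], pos, 4, 3:1) +
        oracle_ihh_side(H[der, , drop = FALSE], pos, 4, 5:7)
      exp_a <- oracle_ihh_side(H[!der, , drop = FALSE], pos, 4, 3:1) +
        oracle_ihh_side(H[!der, , drop = FALSE], pos, 4, 5:7)
      expect_equal(row$ihh_d, exp_d, tolerance = 1e-12)
      expect_equal(row$ihh_a, exp_a, tolerance = 1e-12)
      if (exp_a > 0 && exp_d > 0)
        expect_equal(row$uihs, log(exp_a / exp_d), tolerance = 1e-12)
    }
  })
})

test_that("unphased input is rejected for iHS", {
  g <- toy_geno(matrix(c(0L, 1L, 2L, 1L), 4, 3))
  expect_error(ihs_scan(g), "phased")
})

test_that("consensus caller reproduces the hand-enumerated merging rule", {
  mk <- function(outliers, fillers, metric) {
    v <- seq(0.001, 0.099, length.out = 100) # distinct low baseline
    v[outliers] <- 100
    v[fillers] <- 50 # isolated single-window outliers, non-adjacent
    tibble::tibble(chrom = "chr1", start = (0:99) * 1000,
                   end = (0:99) * 1000 + 1000,
                   n_snps = 5L, value = v, metric = metric)
  }
  # metric A outliers at windows 10-12 (1-based 11:13), metric B at 11 and 90
  tA <- mk(11:13, c(21, 41), "fst")
  tB <- mk(c(12, 91), c(61, 81, 86), "rod")
  cs <- consensus_regions(list(fst = tA, rod = tB), tail_fraction = 0.05,
                          min_metrics = 2)
  expect_equal(nrow(cs), 1L)
  expect_equal(cs$start, 10000) # merged union w10-w12, supported at w11
  expect_equal(cs$end, 13000)
  expect_setequal(cs$metrics[[1]], c("fst", "rod"))

  # a single supporting metric is never enough
  tC <- mk(51, c(3, 5, 7, 9), "clr")
  cs2 <- consensus_regions(list(fst = tA, clr = tC), tail_fraction = 0.05,
                           min_metrics = 2)
  expect_false(any(cs2$start == 50000))

  # all three metrics on one window -> one region with three supports
  tD <- mk(51, c(21, 23, 25, 27), "fst")
  tE <- mk(51, c(71, 73, 75, 77), "rod")
  cs3 <- consensus_regions(list(fst = tD, rod = tE, clr = tC),
                           tail_fraction = 0.05, min_metrics = 2)
  expect_equal(nrow(cs3), 1L)
  expect_equal(cs3$n_metrics, 3L)
})

test_that("consensus regions stay within the union of per-metric outliers", {
  withr::with_seed(45, {
    mk <- function() tibble::tibble(chrom = "chr1", start = (0:199) * 1000,
                                    end = (0:199) * 1000 + 1000,
                                    n_snps = 5L, value = rnorm(200), metric = "fst")
    tracks <- list(fst = mk(), rod = mk(), clr = mk())
    tracks$rod$metric <- "rod"; tracks$clr$metric <- "clr"
    cs <- consensus_regions(tracks, tail_fraction = 0.05, min_metrics = 2)
    expect_true(all(cs$n_metrics >= 2))
    # every region window is an outlier for at least one metric
    thr <- attr(cs, "thresholds")
    for (i in seq_len(nrow(cs))) {
      w <- cs$windows[[i]]
      any_mark <- Reduce(`|`, lapply(names(tracks), function(nm)
        tracks[[nm]]$value[w] >= thr[[nm]]))
      expect_true(all(any_mark))
    }
    # flagged fraction per metric is ~ the tail fraction
    for (nm in names(tracks))
      expect_equal(mean(tracks[[nm]]$value >= thr[[nm]]), 0.05, tolerance = 0.02)
  })
})
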