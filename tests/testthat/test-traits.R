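test_that("AMMI reconstructs cell means exactly and partitions the variance", {
  withr::with_seed(61, {
    g <- 8; e <- 6
    M <- outer(rnorm(g, 100, 4), rep(1, e)) + outer(rep(1, g), rnorm(e, 0, 2)) +
      matrix(rnorm(g * e, 0, 1.5), g, e)
    panel <- tidyr::expand_grid(sample = sprintf("a%02d", 1:g), year = 2001:2006)
    panel$bloom_doy <- as.vector(t(M))
    fit <- ammi_decompose(panel)
    # exact reconstruction with all components kept
    K <- length(fit$lambda)
    rec <- fit$grand_mean +
      outer(fit$genotype_effects$effect, rep(1, e)) +
      outer(rep(1, g), fit$year_effects$effect) +
      fit$scores_g %*% diag(fit$lambda, K, K) %*% t(fit$scores_e)
    expect_equal(unname(rec), unname(fit$cell_means), tolerance = 1e-10)
    # SS additivity: G + E + interaction components = total SS of cell means
    ss_tot <- sum((fit$cell_means - mean(fit$cell_means))^2)
    ss_parts <- sum(fit$anova$ss[fit$anova$term %in% c("genotype", "year")]) +
      sum(fit$lambda^2)
    expect_equal(ss_parts, ss_tot, tolerance = 1e-8)
    # main effects are centered
    expect_equal(sum(fit$genotype_effects$effect), 0, tolerance = 1e-10)
    expect_equal(sum(fit$year_effects$effect), 0, tolerance = 1e-10)
  })
})

test_that("purely additive data has zero interaction singular values", {
  g <- 5; e <- 4
  M <- outer(c(1, 3, 5, 7, 9), rep(1, e)) + outer(rep(1, g), c(10, 20, 30, 40))
  panel <- tidyr::expand_grid(sample = sprintf("a%d", 1:g), year = 1:e)
  panel$bloom_doy <- as.vector(t(M))
  fit <- ammi_decompose(panel)
  expect_true(all(fit$lambda < 1e-10))
})

test_that("the yearly covariate share recovers a generative warming driver", {
  withr::with_seed(62, {
    g <- 30; years <- 1983:2011
    dT <- 0.05 * (years - 1983)
    gamma <- -0.357 / 0.05
    M <- outer(rnorm(g, 100, 3), rep(1, length(years))) +
      outer(rep(1, g), gamma * dT) +
      matrix(rnorm(g * length(years), 0, 1), g, length(years))
    panel <- tidyr::expand_grid(sample = sprintf("a%02d", 1:g), year = years)
    panel$bloom_doy <- as.vector(t(M))
    fit <- ammi_decompose(panel, covariate = tibble::tibble(year = years, delta_t = dT))
    expect_gt(fit$covariate_r2, 0.9)
    # the year-effect trend matches the imposed warming slope within 10%
    sl <- coef(lm(fit$year_effects$effect ~ years))[[2]]
    expect_equal(sl, gamma * 0.05, tolerance = 0.1)
  })
})

test_that("bloom-advance slopes: fixed points and the ~10-day construction", {
  years <- 1983:2011
  flat <- tidyr::expand_grid(sample = c("a1", "a2", "a3", "a4", "a5"),
                             year = years)
  flat$bloom_doy <- 100
  res <- abd_slopes(flat)
  expect_equal(res$slope, rep(0, 5), tolerance = 1e-12)
  expect_equal(res$abd, rep(0, 5), tolerance = 1e-12)

  lin <- tidyr::expand_grid(sample = c("a1", "a2", "a3", "a4", "a5"),
                            year = years)
  lin$bloom_doy <- 100 - 0.357 * (lin$year - 1983)
  res2 <- abd_slopes(lin)
  expect_equal(res2$abd, rep(0.357 * 28, 5), tolerance = 1e-10)
  expect_equal(attr(res2, "mean_abd"), 9.996, tolerance = 1e-3)

  # location shift leaves slopes unchanged
  lin2 <- lin; lin2$bloom_doy <- lin2$bloom_doy + 50
  expect_equal(abd_slopes(lin2)$slope, res2$slope, tolerance = 1e-12)
})

test_that("noisy bloom panels recover the constructed 10-day advance", {
  years <- 1983:2011
  errs <- withr::with_seed(63, {
    vapply(1:20, function(rep) {
      panel <- tidyr::expand_grid(sample = sprintf("a%02d", 1:40), year = years)
      panel$bloom_doy <- 100 - 0.357 * (panel$year - 1983) + rnorm(nrow(panel), 0, 3)
      attr(abd_slopes(panel), "mean_abd")
    }, numeric(1))
  })
  expect_lt(abs(mean(errs) - 10), 1.5)
})

test_that("LT50 fitting recovers generating parameters", {
  temps <- c(-10, -15, -20, -25, -30, -35)
  rc <- 1 / (1 + exp(0.4 * (temps - (-22.5))))
  fit <- fit_lt50(tibble::tibble(temperature = temps, rel_conductance = rc))
  expect_equal(fit$lt50, -22.5, tolerance = 1e-6)
  expect_equal(fit$k, 0.4, tolerance = 1e-6)

  # fitted curve is monotone decreasing in temperature for k > 0
  tt <- seq(-40, 0, length.out = 100)
  curve <- 1 / (1 + exp(fit$k * (tt - fit$lt50)))
  expect_true(all(diff(curve) < 0))

  # symmetric design with RC exactly 0.5 at a measured temperature
  rc2 <- c(0.9, 0.8, 0.5, 0.2, 0.1)
  fit2 <- fit_lt50(tibble::tibble(temperature = c(-30, -25, -20, -15, -10),
                                  rel_conductance = rc2))
  expect_equal(fit2$lt50, -20, tolerance = 1e-3)
})

test_that("LT50 recovery stays within half a degree under measurement noise", {
  temps <- c(-10, -15, -20, -25, -30, -35)
  ests <- withr::with_seed(64, {
    vapply(1:20, function(rep) {
      rc <- 1 / (1 + exp(0.4 * (temps - (-22.5)))) + rnorm(6, 0, 0.05)
      rc <- pmin(1, pmax(0, rc))
      fit_lt50(tibble::tibble(temperature = temps, rel_conductance = rc))$lt50
    }, numeric(1))
  })
  expect_lt(abs(mean(ests) - (-22.5)), 0.5)
  expect_lt(max(abs(ests - (-22.5))), 2.5)
})

test_that("LT50 rejects flat curves", {
  expect_error(
    fit_lt50(tibble::tibble(temperature = c(-10, -20, -30, -35),
                            rel_conductance = rep(0.4, 4))),
    "no transition")
})

test_that("chilling hours use an open lower and closed upper bound", {
  x <- c(rep(5, 300), rep(-3, 100), rep(12, 50))
  expect_equal(chilling_hours(x), 300)
  expect_equal(chilling_hours(c(0, 7.2)), 1)    # 0 out, 7.2 in
  expect_equal(chilling_hours(c(0)), 0)
  expect_equal(chilling_hours(rep(3, 900)), 900)
  expect_error(chilling_hours(numeric(0)), "empty")
})

test_that("stability classes partition SNPs by years significant", {
  counts <- c(1, 1, 1, 2, 3, 5, 6, 6, 8, 1)
  years <- paste0("y", 1:8)
  per_year <- lapply(seq_along(years), function(j) {
    tibble::tibble(variant = paste0("snp", which(counts >= j)), p = 1e-10)
  })
  names(per_year) <- years
  # snp i appears in exactly counts[i] yearly lists
  res <- classify_yearly_associations(per_year)
  tab <- table(res$class)
  expect_equal(unname(tab[c("temporary", "recurrent", "stable")]),
               c(4L, 3L, 3L), ignore_attr = TRUE)
  # disjoint and exhaustive over the union of significant SNPs
  expect_equal(sort(res$variant), sort(paste0("snp", 1:10)))
  expect_equal(res$n_years[match(paste0("snp", 1:10), res$variant)],
               as.integer(counts))
})
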