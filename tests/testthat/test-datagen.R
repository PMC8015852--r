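test_that("no mutation means no polymorphism", {
  sc <- sim_scenario(n_demes = 1, deme_size = 20, n_generations = 50,
                     seq_length = 1e4, mut_rate = 0, seed = 1)
  pop <- simulate_population(sc)
  expect_equal(n_variants(pop$geno), 0L)
})

test_that("identical scenarios write byte-identical datasets", {
  sc <- sim_scenario(n_demes = 2, deme_size = c(A = 12, B = 12),
                     n_generations = 100, seq_length = 3e4,
                     mut_rate = 2e-6, seed = 99)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(sc, d1)
  write_dataset(sc, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  # a different seed produces different data
  sc2 <- sim_scenario(n_demes = 2, deme_size = c(A = 12, B = 12),
                      n_generations = 100, seq_length = 3e4,
                      mut_rate = 2e-6, seed = 100)
  d3 <- withr::local_tempdir()
  write_dataset(sc2, d3)
  expect_false(identical(readLines(file.path(d1, "genotypes.vcf")),
                         readLines(file.path(d3, "genotypes.vcf"))))
})

test_that("scenario validation enforces its invariants", {
  expect_error(sim_scenario(migration_rate = 0.5), "migration_rate")
  expect_error(sim_scenario(deme_size = 5), ">= 10")
  expect_error(sim_scenario(
    sweep_specs = list(list(deme = 1, pos = 2e6, s = 0.1)),
    seq_length = 1e6), "positions")
  expect_error(sim_scenario(
    sweep_specs = list(list(deme = 1, pos = 100, s = -0.1))), "s must be")
})

test_that("environmental variables follow deme structure", {
  sc <- sim_scenario(n_demes = 3, deme_size = 15, n_generations = 60,
                     seq_length = 1e4, mut_rate = 1e-6,
                     env_spec = list(n_evs = 51, noise_sd = 0.3,
                                     shared_frac = 0.7), seed = 5)
  pop <- simulate_population(sc)
  env <- simulate_environment(sc, pop$samples)
  expect_equal(sum(grepl("^ev", names(env))), 51L) # the full EV complement

  # zero noise: identical EV rows within a deme
  sc0 <- sim_scenario(n_demes = 3, deme_size = 15, n_generations = 60,
                      seq_length = 1e4, mut_rate = 1e-6,
                      env_spec = list(noise_sd = 0), seed = 5)
  env0 <- simulate_environment(sc0, pop$samples)
  one <- env0[pop$samples$group == pop$samples$group[1], -1]
  expect_true(all(apply(one, 2, function(x) diff(range(x)) == 0)))

  # EVs sharing the deme gradient are strongly correlated
  scs <- sim_scenario(n_demes = 3, deme_size = 15, n_generations = 60,
                      seq_length = 1e4, mut_rate = 1e-6,
                      env_spec = list(noise_sd = 0.2), seed = 5)
  envs <- simulate_environment(scs, pop$samples)
  means <- attr(envs, "deme_means")
  shared <- which(abs(cor(means[, 1], means)) > 0.999)[1:2]
  r <- cor(envs[[paste0("ev", sprintf("%02d", shared[1]))]],
           envs[[paste0("ev", sprintf("%02d", shared[2]))]])
  expect_gt(abs(r), 0.9)

  expect_error(simulate_environment(sc, transform(pop$samples, group = "zz")),
               "unknown")
})

test_that("phenotype generator honours its deterministic limits", {
  sc <- sim_scenario(n_demes = 1, deme_size = 20, n_generations = 80,
                     seq_length = 2e4, mut_rate = 2e-6,
                     pheno_spec = list(gamma_bd = 0, residual_sd = 0),
                     seed = 7)
  pop <- simulate_population(sc)
  ph <- simulate_phenotypes(pop$geno, pop$truth, sc)
  per_acc <- tapply(ph$pheno$bloom_doy, ph$pheno$sample, function(x) diff(range(x)))
  expect_true(all(per_acc == 0)) # no warming, no noise: constant bloom dates

  # default warming scenario encodes a ten-day advance over the span
  sc2 <- sim_scenario(n_demes = 1, deme_size = 20, n_generations = 80,
                      seq_length = 2e4, mut_rate = 2e-6, seed = 7)
  ph2 <- simulate_phenotypes(pop$geno, pop$truth, sc2)
  expect_equal(unique(ph2$truth$abd$true_abd), 10, tolerance = 1e-10)

  expect_error(simulate_phenotypes(pop$geno, pop$truth,
    sim_scenario(n_demes = 1, deme_size = 20, seq_length = 2e4,
                 pheno_spec = list(years = integer()))), "year range")
})

test_that("conductance curves are recovered by the LT50 fitter", {
  sc <- sim_scenario(n_demes = 1, deme_size = 15, n_generations = 60,
                     seq_length = 1e4, mut_rate = 1e-6, seed = 8)
  pop <- simulate_population(sc)
  ph <- simulate_phenotypes(pop$geno, pop$truth, sc)
  fits <- fit_lt50_all(ph$conductance[ph$conductance$sample %in%
                                        pop$samples$sample[1:8], ])
  truth <- ph$truth$lt50
  err <- fits$lt50 - truth$true_lt50[match(fits$sample, truth$sample)]
  expect_lt(max(abs(err)), 0.5)
})

test_that("isolated demes accumulate differentiation consistent with allele frequencies", {
  sc <- sim_scenario(n_demes = 2, deme_size = c(A = 30, B = 30),
                     n_generations = 500, migration_rate = 0,
                     seq_length = 1e5, mut_rate = 2e-6, seed = 9)
  pop <- simulate_population(sc)
  a <- pop$samples$sample[pop$samples$group == "A"]
  b <- pop$samples$sample[pop$samples$group == "B"]
  # genome-wide ratio-of-sums estimate (a single window spanning the region)
  whole <- window_spec(1e5, 1e5)
  mean_fst <- weir_cockerham_fst(pop$geno, a, b, whole,
                                 chrom_length = c(chr1 = 1e5))$windows$value[1]

  # control: an arbitrary split of one panmictic deme
  sc1 <- sim_scenario(n_demes = 1, deme_size = 60, n_generations = 500,
                      seq_length = 1e5, mut_rate = 2e-6, seed = 9)
  pop1 <- simulate_population(sc1)
  f1 <- weir_cockerham_fst(pop1$geno, pop1$geno$samples[1:30],
                           pop1$geno$samples[31:60], whole,
                           chrom_length = c(chr1 = 1e5))$windows$value[1]
  expect_gt(mean_fst, f1 + 0.05)

  # allele-frequency-variance oracle: between-deme variance share
  dA <- pop$geno$dosage[match(a, pop$geno$samples), ]
  dB <- pop$geno$dosage[match(b, pop$geno$samples), ]
  p1 <- colMeans(dA) / 2; p2 <- colMeans(dB) / 2
  pbar <- (p1 + p2) / 2
  poly <- pbar > 0 & pbar < 1
  oracle <- 1 - mean((p1 * (1 - p1) + p2 * (1 - p2))[poly] / 2) /
    mean((pbar * (1 - pbar))[poly])
  expect_equal(mean_fst, oracle, tolerance = 0.15)
  expect_gt(oracle, 0.05)
})

test_that("a strong sweep depresses diversity around its site", {
  hits <- vapply(1:20, function(seed) {
    sc <- sim_scenario(n_demes = 2, deme_size = c(A = 100, B = 30),
                       n_generations = 700, migration_rate = 0,
                       seq_length = 5e5, mut_rate = 2e-6,
                       sweep_specs = list(list(deme = 1, pos = 2.5e5, s = 0.1,
                                               start = 480)),
                       seed = 100 + seed)
    pop <- simulate_population(sc)
    a <- pop$samples$sample[pop$samples$group == "A"]
    tr <- windowed_pi(pop$geno, a, window_spec(10000, 1000),
                      chrom_length = c(chr1 = 5e5))
    at_sweep <- tr$value[tr$start == 245000] # window centred on the site
    at_sweep < median(tr$value, na.rm = TRUE)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("segregating sites match Watterson's expectation", {
  sc <- sim_scenario(n_demes = 1, deme_size = 50, n_generations = 600,
                     seq_length = 2e5, mut_rate = 2e-6, seed = 12)
  pop <- simulate_population(sc)
  S <- n_variants(pop$geno)
  theta <- 4 * 50 * 2e-6 * 2e5
  an <- sum(1 / seq_len(99))
  bn <- sum(1 / seq_len(99)^2)
  ES <- theta * an
  SD <- sqrt(theta * an + theta^2 * bn)
  expect_lt(abs(S - ES), 3 * SD)
})

test_that("sweep establishment errors after exhausting retries", {
  # s = 0 in a tiny deme with a tight retry cap cannot establish
  sc <- sim_scenario(n_demes = 1, deme_size = 10, n_generations = 400,
                     seq_length = 1e4, mut_rate = 1e-7,
                     sweep_specs = list(list(deme = 1, pos = 5000, s = 0,
                                             start = 5)),
                     sweep_retry_cap = 2, seed = 13)
  expect_error(simulate_population(sc), "not establishable")
})
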