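#' Define a simulation scenario
#'
#' Bundles every parameter of the benchmark generator: a forward-time
#' Wright-Fisher population split into demes exchanging migrants under a
#' symmetric island model, optional hard selective sweeps, deme-structured
#' environmental variables, and polygenic bloom-date phenotypes observed over
#' a multiyear warming trend.
#'
#' The default panel emulates a seven-group peach landrace collection: group
#' sizes of the three groups with published counts are fixed (NE 19, ST 14,
#' TB 45) and the remaining four are chosen so the six landrace groups total
#' 211 accessions.
#'
#' @param n_demes Number of demes.
#' @param deme_size Diploid count per deme; scalar or length-`n_demes`
#'   vector, optionally named with group labels.
#' @param n_generations Generations to run; at least `4 * mean(deme_size)` is
#'   recommended so diversity approaches mutation-drift equilibrium.
#' @param migration_rate Per-generation probability that a gamete's parent is
#'   drawn from another deme (island model); must lie in `[0, 0.5)`.
#' @param seq_length Chromosome length in bp.
#' @param mut_rate,rec_rate Per-bp per-generation mutation and recombination
#'   rates (infinite sites; single crossover per gamete).
#' @param sweep_specs List of sweeps, each `list(deme =, pos =, s =, start =)`
#'   with 1-based deme index, position in bp, selection coefficient `s >= 0`
#'   acting as fitness `1 + s * dosage` within that deme, and start
#'   generation.  Establishment is enforced by re-injection (up to
#'   `sweep_retry_cap` retries).
#' @param env_spec Environmental-variable generator settings: `n_evs` (51 by
#'   default), `noise_sd` (within-deme Gaussian noise on standardized deme
#'   means), `shared_frac` (fraction of EVs loading on one shared deme
#'   gradient, which makes them mutually collinear).
#' @param pheno_spec Phenotype generator settings: `n_causal` loci, `beta`
#'   (per-allele effect in days; recycled), `years`, `warming_rate` (degC per
#'   year), `gamma_bd` (days of bloom-date shift per degC; negative means
#'   warming advances bloom), `residual_sd` (days), `mu` (baseline bloom
#'   day-of-year), `lt50_mean`, `lt50_sd`, `lt50_k`, `rc_noise_sd` for the
#'   conductance curves, and `maf_min` for eligible causal loci.
#' @param missing_rate Fraction of genotype calls masked to missing after
#'   simulation.
#' @param chrom Chromosome name used on output.
#' @param sweep_retry_cap Maximum sweep re-injections before erroring.
#' @param seed Integer seed; identical scenarios reproduce identical output.
#'
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(n_demes = 7,
                         deme_size = c(YG = 60, NW = 38, NP = 46, NE = 19,
                                       YT = 34, ST = 14, TB = 45),
                         n_generations = NULL,
                         migration_rate = 0.02,
                         seq_length = 1e6,
                         mut_rate = 2.5e-7,
                         rec_rate = 2.5e-7,
                         sweep_specs = list(),
                         env_spec = list(),
                         pheno_spec = list(),
                         missing_rate = 0,
                         chrom = "chr1",
                         sweep_retry_cap = 100,
                         seed = 1) {
  if (length(deme_size) == 1L) deme_size <- rep(deme_size, n_demes)
  if (length(deme_size) != n_demes)
    abort("deme_size must be scalar or length n_demes")
  if (is.null(names(deme_size)) || anyDuplicated(names(deme_size)))
    names(deme_size) <- paste0("deme", seq_len(n_demes))
  if (any(deme_size < 10)) abort("deme_size must be >= 10")
  if (migration_rate < 0 || migration_rate >= 0.5)
    abort("migration_rate must lie in [0, 0.5)")
  n_generations <- n_generations %||% ceiling(4 * mean(deme_size))
  for (sw in sweep_specs) {
    stopifnot(all(c("deme", "pos", "s") %in% names(sw)))
    if (sw$s < 0) abort("selection coefficient s must be >= 0")
    if (sw$pos < 1 || sw$pos > seq_length)
      abort("sweep positions must lie in [1, seq_length]")
    if (sw$deme < 1 || sw$deme > n_demes) abort("sweep deme out of range")
  }
  env_spec <- utils::modifyList(
    list(n_evs = 51L, noise_sd = 0.3, shared_frac = 0.7), env_spec)
  pheno_spec <- utils::modifyList(
    list(n_causal = 5L, beta = 2, years = 1983:2011, warming_rate = 0.05,
         gamma_bd = -10 / (0.05 * 28), residual_sd = 3, mu = 95,
         lt50_mean = -22.5, lt50_sd = 3, lt50_k = 0.4, rc_noise_sd = 0.02,
         maf_min = 0.1), pheno_spec)
  structure(
    list(n_demes = n_demes, deme_size = deme_size,
         n_generations = as.integer(n_generations),
         migration_rate = migration_rate, seq_length = seq_length,
         mut_rate = mut_rate, rec_rate = rec_rate, sweep_specs = sweep_specs,
         env_spec = env_spec, pheno_spec = pheno_spec,
         missing_rate = missing_rate, chrom = chrom,
         sweep_retry_cap = as.integer(sweep_retry_cap),
         seed = as.integer(seed)),
    class = "sim_scenario")
}

#' Run the forward Wright-Fisher simulation
#'
#' Simulates the scenario's subdivided population forward in time and returns
#' the final generation as a phased [genotype_matrix()] together with ground
#' truth for recovery tests.  Each sweep is conditioned on establishment: a
#' lost sweep allele is re-injected (counted as a retry) until it has fixed
#' within its deme; exceeding the retry cap raises
#' `"sweep not establishable"`.
#'
#' @param scenario A [sim_scenario()].
#' @return A list with elements `geno` (phased [genotype_matrix()]), `samples`
#'   (tibble: `sample`, `group`, `lat`, `lon`, `altitude`) and `truth` (list:
#'   sweep table with trajectories, causal-locus table, per-accession true
#'   bloom-advance slope, true LT50s, and the EV/deme structure, filled in by
#'   the downstream generators).
#' @export
simulate_population <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sw <- scenario$sweep_specs
  res <- withr::with_seed(scenario$seed,
    wf_simulate_cpp(
      as.integer(scenario$deme_size), scenario$n_generations,
      scenario$migration_rate, scenario$seq_length,
      scenario$mut_rate, scenario$rec_rate,
      vapply(sw, function(x) as.integer(x$deme) - 1L, integer(1)),
      vapply(sw, function(x) as.integer(x$pos), integer(1)),
      vapply(sw, function(x) as.numeric(x$s), numeric(1)),
      vapply(sw, function(x) as.integer(x$start %||%
               max(1L, scenario$n_generations - 10L * ceiling(2 / max(x$s, 0.01)))),
             integer(1)),
      scenario$sweep_retry_cap))

  n <- sum(scenario$deme_size)
  sample_ids <- sprintf("acc%03d", seq_len(n))
  groups <- rep(names(scenario$deme_size), scenario$deme_size)

  hap <- res$haplotypes
  s_var <- ncol(hap)
  post <- withr::with_seed(scenario$seed + 1000L, {
    nts <- c("A", "C", "G", "T")
    ref <- sample(nts, s_var, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(nts, r), 1), character(1))
    # deme geography: a latitudinal gradient with within-deme jitter
    lat0 <- seq(45, 24, length.out = scenario$n_demes)
    lon0 <- seq(125, 90, length.out = scenario$n_demes)
    alt0 <- c(seq(100, 800, length.out = scenario$n_demes - 1), 3500)
    list(ref = ref, alt = alt,
         lat = lat0[match(groups, names(scenario$deme_size))] + rnorm(n, 0, 0.5),
         lon = lon0[match(groups, names(scenario$deme_size))] + rnorm(n, 0, 0.5),
         altitude = pmax(1, alt0[match(groups, names(scenario$deme_size))] +
                           rnorm(n, 0, 50)),
         miss = if (scenario$missing_rate > 0)
           matrix(runif(n * s_var) < scenario$missing_rate, n, s_var))
  })

  variants <- tibble(chrom = scenario$chrom, pos = as.integer(res$positions),
                     ref = unname(post$ref), alt = unname(post$alt))
  dos <- hap[seq(1, nrow(hap), 2), , drop = FALSE] +
    hap[seq(2, nrow(hap), 2), , drop = FALSE]
  haplotypes <- hap
  if (!is.null(post$miss)) {
    dos[post$miss] <- NA_integer_
    haplotypes <- NULL # phase unknown at masked calls; drop haplotypes
  }
  geno <- genotype_matrix(variants, dos, sample_ids, haplotypes)

  samples <- tibble(sample = sample_ids, group = groups,
                    lat = post$lat, lon = post$lon, altitude = post$altitude)

  sweeps <- if (length(sw)) tibble(
    deme = vapply(sw, function(x) as.integer(x$deme), integer(1)),
    group = names(scenario$deme_size)[vapply(sw, function(x) as.integer(x$deme), integer(1))],
    pos = vapply(sw, function(x) as.numeric(x$pos), numeric(1)),
    s = vapply(sw, function(x) as.numeric(x$s), numeric(1)),
    established = as.logical(res$sweep_established),
    final_freq = as.numeric(res$sweep_final_freq),
    retries = as.integer(res$sweep_retries)
  ) else tibble(deme = integer(), group = character(), pos = numeric(),
                s = numeric(), established = logical(),
                final_freq = numeric(), retries = integer())

  causal <- withr::with_seed(scenario$seed + 2000L, {
    ps <- scenario$pheno_spec
    ac <- colSums(dos, na.rm = TRUE)
    an <- 2 * colSums(!is.na(dos))
    maf <- pmin(ac / pmax(an, 1), 1 - ac / pmax(an, 1))
    elig <- which(maf >= ps$maf_min)
    k <- min(ps$n_causal, length(elig))
    idx <- if (k > 0) sort(sample(elig, k)) else integer()
    tibble(variant = idx, chrom = scenario$chrom,
           pos = variants$pos[idx],
           beta = rep_len(ps$beta, k) * rep_len(c(1, -1), k))
  })

  truth <- list(
    sweeps = sweeps,
    sweep_trajectories = res$sweep_trajectory,
    causal = causal,
    scenario = scenario)
  list(geno = geno, samples = samples, truth = truth)
}

#' Generate deme-structured environmental variables
#'
#' Each environmental variable (EV) is a per-deme mean plus Gaussian noise.
#' A fraction `shared_frac` of the EVs load (with unit coefficient, random
#' sign) on a single shared deme gradient, making them strongly collinear --
#' the situation that motivates summarizing EVs by their first principal
#' component; the remainder get independent random deme means.
#'
#' @param scenario A [sim_scenario()].
#' @param samples Sample table from [simulate_population()] (needs `sample`
#'   and `group`).
#' @param seed Seed; defaults to `scenario$seed + 1`.
#' @return A tibble: `sample` plus `n_evs` numeric EV columns (`ev01` ...).
#'   Attribute `deme_means` holds the deme x EV mean matrix used.
#' @export
simulate_environment <- function(scenario, samples, seed = scenario$seed + 1L) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!all(samples$group %in% names(scenario$deme_size)))
    abort("unknown sample group label")
  es <- scenario$env_spec
  withr::with_seed(seed, {
    demes <- names(scenario$deme_size)
    gradient <- scale(seq_along(demes))[, 1] # the shared latitudinal axis
    n_shared <- round(es$n_evs * es$shared_frac)
    means <- sapply(seq_len(es$n_evs), function(e) {
      if (e <= n_shared) sample(c(-1, 1), 1) * gradient
      else rnorm(length(demes))
    })
    dimnames(means) <- list(demes, sprintf("ev%02d", seq_len(es$n_evs)))
    vals <- means[match(samples$group, demes), , drop = FALSE] +
      matrix(rnorm(nrow(samples) * es$n_evs, 0, es$noise_sd),
             nrow(samples), es$n_evs)
    out <- as_tibble(as.data.frame(vals))
    out <- dplyr::bind_cols(tibble(sample = samples$sample), out)
    attr(out, "deme_means") <- means
    out
  })
}

#' Generate phenotype panels with known ground truth
#'
#' Bloom dates follow `BD[i, y] = mu + sum_k beta_k g[i, k] +
#' gamma_bd * dT[y] + eps`, where `dT[y] = warming_rate * (y - first year)`
#' is a linear spring-warming series and `eps` is Gaussian residual noise.
#' Relative-conductance curves are generated from the logistic freezing-damage
#' model fitted by [fit_lt50()] with a known per-accession LT50, and an
#' hourly winter temperature series is produced for chilling-hour counting.
#'
#' @param geno A [genotype_matrix()] from [simulate_population()].
#' @param truth Truth list from [simulate_population()] (supplies the causal
#'   loci and effects).
#' @param scenario The [sim_scenario()].
#' @param seed Seed; defaults to `scenario$seed + 2`.
#' @return List with `pheno` (tibble: `sample`, `year`, `bloom_doy`),
#'   `conductance` (tibble: `sample`, `temperature`, `rel_conductance`),
#'   `hourly` (tibble: `hour`, `temperature`), `delta_t` (tibble: `year`,
#'   `delta_t`), and `truth` (the input truth augmented with per-accession
#'   true bloom-advance slope and true LT50).
#' @export
simulate_phenotypes <- function(geno, truth, scenario, seed = scenario$seed + 2L) {
  ps <- scenario$pheno_spec
  years <- ps$years
  if (length(years) == 0) abort("year range must be non-empty")
  n <- n_samples(geno)
  withr::with_seed(seed, {
    g <- geno$dosage[, truth$causal$variant, drop = FALSE]
    g[is.na(g)] <- 0L
    gen_val <- as.vector(g %*% truth$causal$beta)
    dT <- ps$warming_rate * (years - years[1])
    bd <- outer(ps$mu + gen_val, rep(1, length(years))) +
      outer(rep(1, n), ps$gamma_bd * dT) +
      matrix(rnorm(n * length(years), 0, ps$residual_sd), n, length(years))
    pheno <- tibble(
      sample = rep(geno$samples, times = length(years)),
      year = rep(years, each = n),
      bloom_doy = as.vector(bd))

    lt50 <- rnorm(n, ps$lt50_mean, ps$lt50_sd)
    temps <- c(-10, -15, -20, -25, -30, -35)
    rc <- outer(seq_len(n), seq_along(temps), function(i, j)
      1 / (1 + exp(ps$lt50_k * (temps[j] - lt50[i]))))
    rc <- pmin(1, pmax(0, rc + matrix(rnorm(n * length(temps), 0, ps$rc_noise_sd),
                                      n, length(temps))))
    conductance <- tibble(
      sample = rep(geno$samples, times = length(temps)),
      temperature = rep(temps, each = n),
      rel_conductance = as.vector(rc))

    # 90 winter days: seasonal dip plus a diurnal cycle, hourly noise
    hrs <- seq_len(90 * 24)
    day <- (hrs - 1) / 24
    temp <- 5 - 4 * sin(pi * day / 90) + 5 * sin(2 * pi * (hrs %% 24) / 24) +
      rnorm(length(hrs), 0, 1)
    hourly <- tibble(hour = hrs, temperature = temp)

    truth$abd <- tibble(sample = geno$samples,
                        true_slope = ps$gamma_bd * ps$warming_rate,
                        true_abd = -ps$gamma_bd * ps$warming_rate *
                          (max(years) - min(years)))
    truth$lt50 <- tibble(sample = geno$samples, true_lt50 = lt50,
                         k = ps$lt50_k)
    list(pheno = pheno, conductance = conductance, hourly = hourly,
         delta_t = tibble(year = years, delta_t = dT), truth = truth)
  })
}
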