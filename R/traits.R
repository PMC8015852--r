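#' AMMI decomposition of a genotype-by-year phenotype panel
#'
#' Additive main effects and multiplicative interaction analysis of cell
#' means: replicates are averaged, missing cells are imputed as row mean +
#' column mean - grand mean (and flagged), the two-way ANOVA gives genotype
#' and year main effects, and the doubly-centered interaction matrix is
#' decomposed by SVD into IPCA terms.  IPCA degrees of freedom follow
#' Gollob (`(g-1) + (e-1) - 2k + 1`); each IPCA is F-tested against the
#' pooled remaining interaction, and the main effects against the full
#' interaction mean square.  When a yearly covariate (for example a spring
#' temperature anomaly series) is supplied, its explanatory share is the
#' squared correlation with the year main effects (set
#' `driver = "ipca1"` to correlate with the first IPCA year scores
#' instead).
#'
#' @param panel Tibble: `sample`, `year`, `bloom_doy`, optional `replicate`.
#' @param covariate Optional tibble `year`, `delta_t` (or any numeric
#'   second column) on the panel's years.
#' @param driver Which year-level signal the covariate is correlated with.
#' @return An `ammi` object: `grand_mean`, `genotype_effects`,
#'   `year_effects`, `lambda`, `scores_g`, `scores_e`, `anova` (tibble),
#'   `cell_means`, `imputed`, `covariate_r2`.
#' @export
ammi_decompose <- function(panel, covariate = NULL,
                           driver = c("year_effects", "ipca1")) {
  driver <- match.arg(driver)
  cm <- panel |>
    dplyr::group_by(.data$sample, .data$year) |>
    dplyr::summarise(bd = mean(.data$bloom_doy), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "year", values_from = "bd")
  acc <- cm$sample
  M <- as.matrix(cm[, -1])
  rownames(M) <- acc
  years <- as.numeric(colnames(M))
  g <- nrow(M); e <- ncol(M)
  if (g < 3 || e < 3) abort("AMMI needs at least 3 accessions and 3 years")
  imputed <- which(is.na(M), arr.ind = TRUE)
  if (nrow(imputed)) {
    rm_ <- rowMeans(M, na.rm = TRUE)
    cm_ <- colMeans(M, na.rm = TRUE)
    gm_ <- mean(M, na.rm = TRUE)
    M[imputed] <- rm_[imputed[, 1]] + cm_[imputed[, 2]] - gm_
  }
  mu <- mean(M)
  gi <- rowMeans(M) - mu
  ej <- colMeans(M) - mu
  Z <- M - mu - outer(gi, rep(1, e)) - outer(rep(1, g), ej)
  sv <- svd(Z)
  K <- min(g - 1, e - 1)
  lambda <- sv$d[seq_len(K)]

  ss_g <- e * sum(gi^2)
  ss_e <- g * sum(ej^2)
  ss_int <- sum(Z^2)
  df_g <- g - 1; df_e <- e - 1; df_int <- (g - 1) * (e - 1)
  ms_int <- ss_int / df_int
  df_k <- (g - 1) + (e - 1) - 2 * seq_len(K) + 1
  ss_k <- lambda^2
  f_k <- p_k <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    rss <- ss_int - sum(ss_k[seq_len(k)])
    rdf <- df_int - sum(df_k[seq_len(k)])
    if (rdf > 0 && rss > 1e-12) {
      f_k[k] <- (ss_k[k] / df_k[k]) / (rss / rdf)
      p_k[k] <- stats::pf(f_k[k], df_k[k], rdf, lower.tail = FALSE)
    }
  }
  anova <- dplyr::bind_rows(
    tibble(term = "genotype", df = df_g, ss = ss_g, ms = ss_g / df_g,
           statistic = (ss_g / df_g) / ms_int,
           p = stats::pf((ss_g / df_g) / ms_int, df_g, df_int,
                         lower.tail = FALSE)),
    tibble(term = "year", df = df_e, ss = ss_e, ms = ss_e / df_e,
           statistic = (ss_e / df_e) / ms_int,
           p = stats::pf((ss_e / df_e) / ms_int, df_e, df_int,
                         lower.tail = FALSE)),
    tibble(term = paste0("IPCA", seq_len(K)), df = df_k, ss = ss_k,
           ms = ss_k / df_k, statistic = f_k, p = p_k))

  covariate_r2 <- NA_real_
  if (!is.null(covariate)) {
    cv <- covariate[match(years, covariate$year), ]
    cvv <- cv[[setdiff(names(cv), "year")[1]]]
    target <- if (driver == "year_effects") ej else sv$v[, 1]
    if (sd(cvv, na.rm = TRUE) > 0 && sd(target) > 0)
      covariate_r2 <- cor(target, cvv, use = "complete.obs")^2
  }

  structure(
    list(grand_mean = mu,
         genotype_effects = tibble(sample = acc, effect = unname(gi)),
         year_effects = tibble(year = years, effect = unname(ej)),
         lambda = lambda,
         scores_g = sv$u[, seq_len(K), drop = FALSE],
         scores_e = sv$v[, seq_len(K), drop = FALSE],
         anova = anova, cell_means = M,
         imputed = imputed, covariate_r2 = covariate_r2),
    class = "ammi")
}

#' @export
print.ammi <- function(x, ...) {
  cat(sprintf("AMMI decomposition: %d accessions x %d years\n",
              nrow(x$cell_means), ncol(x$cell_means)))
  print(x$anova)
  if (!is.na(x$covariate_r2))
    cat(sprintf("covariate R2 on year effects: %.3f\n", x$covariate_r2))
  invisible(x)
}

#' Advance-in-bloom-date regression per accession
#'
#' Ordinary least squares of bloom day-of-year on calendar year per
#' accession (replicates averaged within accession-year).  The advance in
#' bloom date is `-slope * (last year - first year)`, so a positive value
#' means bloom got earlier over the observation span.  Accessions observed
#' in fewer than `min_years` years are skipped with a warning.
#'
#' @param panel Tibble: `sample`, `year`, `bloom_doy`.
#' @param min_years Minimum distinct years per accession.
#' @return Tibble: `sample`, `slope` (days/year), `se`, `abd` (days);
#'   attribute `mean_abd` holds the population mean.
#' @export
abd_slopes <- function(panel, min_years = 5) {
  cm <- panel |>
    dplyr::group_by(.data$sample, .data$year) |>
    dplyr::summarise(bd = mean(.data$bloom_doy), .groups = "drop")
  ny <- table(cm$sample)
  drop_acc <- names(ny)[ny < min_years]
  if (length(drop_acc))
    warn(sprintf("abd_slopes: skipping %d accession(s) with < %d years",
                 length(drop_acc), min_years))
  cm <- cm[!cm$sample %in% drop_acc, ]
  out <- cm |>
    dplyr::group_by(.data$sample) |>
    dplyr::group_modify(function(df, key) {
      fit <- lm(bd ~ year, data = df)
      sl <- coef(fit)[["year"]]
      se <- sqrt(diag(stats::vcov(fit)))[["year"]]
      tibble(slope = sl, se = se,
             abd = -sl * (max(df$year) - min(df$year)))
    }) |>
    dplyr::ungroup()
  attr(out, "mean_abd") <- mean(out$abd)
  out
}

#' Fit the logistic freezing-damage curve and LT50
#'
#' Fits `RC(T) = 1 / (1 + exp(k (T - LT50)))` with `k > 0` (relative
#' conductance rises as temperature falls) by nonlinear least squares,
#' multi-started over `k` in `{0.1, 0.3, 1.0}` with LT50 initialized at the
#' measured temperature whose conductance is nearest 0.5.  LT50 is bounded
#' to the tested temperature range widened by 10 degrees C.
#'
#' @param curve Tibble: `temperature` (degrees C), `rel_conductance` in
#'   `[0, 1]`, for a single accession.
#' @return An `lt50_fit` list: `lt50`, `k`, `rss`, `converged`, `data`.
#' @export
fit_lt50 <- function(curve) {
  tt <- curve$temperature
  rc <- curve$rel_conductance
  if (length(unique(tt)) < 4) abort("fit_lt50 needs >= 4 distinct temperatures")
  if (any(rc < 0 | rc > 1)) abort("relative conductance must lie in [0, 1]")
  if (diff(range(rc)) == 0) abort("no transition observed")
  lt50_0 <- tt[which.min(abs(rc - 0.5))]
  lo <- c(lt50 = min(tt) - 10, k = 1e-3)
  hi <- c(lt50 = max(tt) + 10, k = 10)
  best <- NULL
  for (k0 in c(0.1, 0.3, 1.0)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        rc ~ 1 / (1 + exp(k * (tt - lt50))),
        start = list(lt50 = lt50_0, k = k0),
        lower = lo, upper = hi,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(lt50 = coef(fit)[["lt50"]], k = coef(fit)[["k"]],
                   rss = rss, converged = fit$convInfo$isConv)
  }
  if (is.null(best)) abort("LT50 fit failed for all starts")
  structure(c(best, list(data = tibble(temperature = tt,
                                       rel_conductance = rc))),
            class = "lt50_fit")
}

#' @export
print.lt50_fit <- function(x, ...) {
  cat(sprintf("LT50 = %.2f C, k = %.3f (RSS %.4g)\n", x$lt50, x$k, x$rss))
  invisible(x)
}

#' Fit LT50 for every accession in a conductance panel
#'
#' @param conductance Tibble: `sample`, `temperature`, `rel_conductance`.
#' @return Tibble: `sample`, `lt50`, `k`, `rss`, `converged`.
#' @export
fit_lt50_all <- function(conductance) {
  conductance |>
    dplyr::group_by(.data$sample) |>
    dplyr::group_modify(function(df, key) {
      f <- fit_lt50(df)
      tibble(lt50 = f$lt50, k = f$k, rss = f$rss, converged = f$converged)
    }) |>
    dplyr::ungroup()
}

#' Chilling hours in a temperature band
#'
#' Counts hours with temperature in `(lo, hi]`: the lower bound is
#' excluded, the upper bound included (the 0-7.2 degrees C chilling model
#' counts an hour at exactly 7.2 but not one at exactly 0).
#'
#' @param hourly Tibble with a `temperature` column, or a numeric vector of
#'   hourly temperatures.
#' @param lo,hi Band limits in degrees C.
#' @return Integer count of qualifying hours.
#' @export
chilling_hours <- function(hourly, lo = 0, hi = 7.2) {
  temp <- if (is.data.frame(hourly)) hourly$temperature else hourly
  if (length(temp) == 0) abort("empty temperature series")
  sum(temp > lo & temp <= hi)
}

#' Classify multiyear association stability
#'
#' Counts, per SNP, the number of years in which it is significant and
#' partitions the union of significant SNPs into `temporary` (exactly 1
#' year), `recurrent` (2 to 5 years) and `stable` (strictly more than 5
#' years).
#'
#' @param per_year Named list of per-year association tibbles (columns
#'   `variant` and `p` at minimum).
#' @param threshold Optional p-value threshold applied to each year's table;
#'   if `NULL` the tables are assumed pre-thresholded.
#' @return Tibble: `variant`, `n_years`, `class`.
#' @export
classify_yearly_associations <- function(per_year, threshold = NULL) {
  if (length(per_year) < 2) abort("need results from at least 2 years")
  sig <- purrr::map(per_year, function(df) {
    if (!is.null(threshold)) df <- df[!is.na(df$p) & df$p < threshold, ]
    unique(df$variant)
  })
  counts <- table(unlist(sig))
  if (length(counts) == 0)
    return(tibble(variant = character(), n_years = integer(),
                  class = character()))
  tibble(variant = names(counts), n_years = as.integer(counts)) |>
    dplyr::mutate(class = dplyr::case_when(
      .data$n_years == 1 ~ "temporary",
      .data$n_years > 5 ~ "stable",
      TRUE ~ "recurrent"))
}
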