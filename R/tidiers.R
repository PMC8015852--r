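#' @export
tidy.emmax_fit <- function(x, ...) {
  tibble(term = c("delta", "h2"), estimate = c(x$delta, x$h2))
}

#' @export
glance.emmax_fit <- function(x, ...) {
  tibble(delta = x$delta, h2 = x$h2, reml = x$reml, n = x$n,
         n_pcs = x$n_pcs, trait = x$trait)
}

#' @export
tidy.lfmm_fit <- function(x, ...) {
  tibble(term = paste0("factor", seq_len(x$k)),
         scale = apply(x$U, 2, sd))
}

#' @export
glance.lfmm_fit <- function(x, ...) {
  tibble(k = x$k, lambda_gif = x$lambda_gif, converged = x$converged,
         n_iter = x$n_iter, trait = x$trait)
}

#' @export
tidy.ammi <- function(x, ...) x$anova

#' @export
glance.ammi <- function(x, ...) {
  ss_tot <- sum(x$anova$ss)
  tibble(grand_mean = x$grand_mean,
         n_accessions = nrow(x$cell_means), n_years = ncol(x$cell_means),
         ss_genotype = x$anova$ss[x$anova$term == "genotype"],
         ss_year = x$anova$ss[x$anova$term == "year"],
         ss_interaction = sum(x$lambda^2),
         covariate_r2 = x$covariate_r2)
}

#' @export
tidy.lt50_fit <- function(x, ...) {
  tibble(term = c("lt50", "k"), estimate = c(x$lt50, x$k))
}

#' @export
glance.lt50_fit <- function(x, ...) {
  tibble(lt50 = x$lt50, k = x$k, rss = x$rss, converged = x$converged)
}

#' @export
tidy.env_pca <- function(x, ...) {
  tibble(component = paste0("PC", seq_along(x$var_frac)),
         var_frac = x$var_frac)
}
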