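#' Identity-by-state kinship matrix
#'
#' Pairwise mean of `(2 - |d_i - d_j|) / 2` over jointly called sites, so
#' identical genotypes give 1 and opposite homozygotes 0.  The matrix is
#' bent to positive semidefiniteness by flooring negative eigenvalues at
#' `1e-6` and rescaling back to a unit diagonal.
#'
#' @param geno A [genotype_matrix()].
#' @param samples Optional sample-id subset.
#' @return A samples x samples numeric matrix (class `kinship_matrix`).
#' @export
kinship_matrix <- function(geno, samples = NULL) {
  D <- subset_dosage(geno, samples)
  if (nrow(D) < 2 || ncol(D) < 1)
    abort("kinship needs >= 2 samples and >= 1 variant")
  M <- !is.na(D)
  A0 <- (D == 0L) & M; A1 <- (D == 1L) & M; A2 <- (D == 2L) & M
  A0[is.na(A0)] <- FALSE; A1[is.na(A1)] <- FALSE; A2[is.na(A2)] <- FALSE
  storage.mode(A0) <- storage.mode(A1) <- storage.mode(A2) <- "double"
  Mn <- M * 1
  C <- Mn %*% t(Mn)
  if (any(C == 0))
    abort("a sample pair shares no jointly called sites")
  S <- A1 %*% t(A0 + A2) + (A0 + A2) %*% t(A1) +
    2 * (A0 %*% t(A2) + A2 %*% t(A0))
  K <- 1 - S / (2 * C)
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < 1e-6) {
    v <- pmax(e$values, 1e-6)
    K <- e$vectors %*% (v * t(e$vectors))
    dsc <- 1 / sqrt(diag(K))
    K <- K * tcrossprod(dsc)
  }
  dimnames(K) <- list(rownames(D), rownames(D))
  structure(K, class = c("kinship_matrix", "matrix", "array"))
}

# genotype principal components (mean-imputed, centered dosages)
genotype_pcs <- function(D, n_pcs) {
  if (n_pcs == 0) return(NULL)
  X <- apply(D, 2, function(col) {
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    col
  })
  X <- scale(X, center = TRUE, scale = FALSE)
  X <- X[, apply(X, 2, function(cc) any(cc != 0)), drop = FALSE]
  sv <- svd(X, nu = n_pcs, nv = 0)
  sv$u[, seq_len(n_pcs), drop = FALSE] %*% diag(sv$d[seq_len(n_pcs)],
                                                n_pcs, n_pcs)
}

# restricted log-likelihood of the variance-ratio delta given the spectral
# decomposition of K and the fixed-effect design
reml_ll <- function(log_delta, ytil, Xtil, Svals, XtX_logdet) {
  delta <- exp(log_delta)
  w <- Svals + delta
  n <- length(ytil)
  p <- ncol(Xtil)
  Xw <- Xtil / w
  XtWX <- crossprod(Xtil, Xw)
  bh <- solve(XtWX, crossprod(Xw, ytil))
  r <- ytil - Xtil %*% bh
  R <- sum(r^2 / w)
  0.5 * ((n - p) * log((n - p) / (2 * pi)) - (n - p) - (n - p) * log(R) -
           sum(log(w)) - determinant(XtWX)$modulus[1] + XtX_logdet)
}

#' Mixed-model association scan (EMMAX-style)
#'
#' Fits the null model `y = X beta + u + e` with `cov(u) = sigma_g^2 K` once
#' by REML (grid of 100 points over `ln delta` in `[-10, 10]`, then
#' golden-section refinement; `delta = sigma_e^2 / sigma_g^2`), then tests
#' each variant by generalized least squares in the rotated space reusing
#' the null `delta` (the population-parameters-previously-determined
#' approximation).  Fixed effects are an intercept plus `n_pcs` genotype
#' principal components.  Missing dosages are mean-imputed per variant for
#' association.
#'
#' @param geno A [genotype_matrix()].
#' @param y Numeric response (one per sample): a phenotype or an
#'   environmental variable.
#' @param K [kinship_matrix()] for the same samples.
#' @param n_pcs Number of genotype PCs used as fixed covariates.
#' @param trait Label recorded in the result rows.
#' @param per_marker_reml Re-maximize REML for every marker instead of
#'   reusing the null variance components (slower, near-identical p-values).
#' @return Tibble: `variant`, `chrom`, `pos`, `beta`, `se`, `statistic`,
#'   `p`, `trait`; the null-model fit is attached as attribute `fit`
#'   (class `emmax_fit`, with [tidy()]/[glance()] methods).
#' @export
emmax_scan <- function(geno, y, K = kinship_matrix(geno), n_pcs = 3,
                       trait = "trait", per_marker_reml = FALSE) {
  n <- n_samples(geno)
  if (length(y) != n) abort("y must have one value per sample")
  if (sd(y) == 0) abort("y is constant")
  D <- geno$dosage
  G <- apply(D, 2, function(col) {
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    col
  })
  X0 <- cbind(`(Intercept)` = rep(1, n), genotype_pcs(D, n_pcs))
  if (qr(X0)$rank < ncol(X0))
    abort("singular fixed-effect design: genotype PCs are collinear")

  e <- eigen(unclass(K), symmetric = TRUE)
  U <- e$vectors
  Svals <- pmax(e$values, 0)
  ytil <- drop(crossprod(U, y))
  Xtil <- crossprod(U, X0)
  XtX_logdet <- determinant(crossprod(X0))$modulus[1]

  grid <- seq(-10, 10, length.out = 100)
  ll <- vapply(grid, reml_ll, numeric(1), ytil = ytil, Xtil = Xtil,
               Svals = Svals, XtX_logdet = XtX_logdet)
  i <- which.max(ll)
  opt <- optimize(reml_ll, c(grid[max(1, i - 1)], grid[min(100, i + 1)]),
                  maximum = TRUE, tol = 1e-6, ytil = ytil, Xtil = Xtil,
                  Svals = Svals, XtX_logdet = XtX_logdet)
  log_delta <- if (opt$objective >= ll[i]) opt$maximum else grid[i]
  delta <- exp(log_delta)

  scan_one_delta <- function(delta, cols = seq_len(ncol(G))) {
    w <- Svals + delta
    sw <- 1 / sqrt(w)
    ys <- ytil * sw
    Xs <- Xtil * sw
    Gs <- crossprod(U, G[, cols, drop = FALSE]) * sw
    qx <- qr(Xs)
    yr <- qr.resid(qx, ys)
    Gr <- qr.resid(qx, Gs)
    gg <- colSums(Gr^2)
    gy <- colSums(Gr * yr)
    beta <- ifelse(gg > 0, gy / gg, NA_real_)
    df <- n - ncol(Xs) - 1
    rss <- pmax(sum(yr^2) - beta^2 * gg, 0)
    se <- sqrt(rss / df / gg)
    tt <- beta / se
    list(beta = beta, se = se, statistic = tt,
         p = 2 * pt(-abs(tt), df))
  }

  if (!per_marker_reml) {
    r <- scan_one_delta(delta)
  } else {
    parts <- lapply(seq_len(ncol(G)), function(j) {
      Xj <- cbind(X0, G[, j])
      Xjt <- crossprod(U, Xj)
      llj <- vapply(grid, reml_ll, numeric(1), ytil = ytil, Xtil = Xjt,
                    Svals = Svals,
                    XtX_logdet = determinant(crossprod(Xj))$modulus[1])
      dj <- exp(grid[which.max(llj)])
      lapply(scan_one_delta(dj, j), `[[`, 1)
    })
    r <- list(beta = vapply(parts, `[[`, numeric(1), "beta"),
              se = vapply(parts, `[[`, numeric(1), "se"),
              statistic = vapply(parts, `[[`, numeric(1), "statistic"),
              p = vapply(parts, `[[`, numeric(1), "p"))
  }

  fit <- structure(
    list(delta = delta, reml = max(opt$objective, ll[i]),
         h2 = 1 / (1 + delta), n = n, n_pcs = n_pcs, trait = trait),
    class = "emmax_fit")
  out <- tibble(
    variant = paste0(geno$variants$chrom, ":", geno$variants$pos),
    chrom = geno$variants$chrom, pos = geno$variants$pos,
    beta = r$beta, se = r$se, statistic = r$statistic, p = r$p,
    trait = trait)
  attr(out, "fit") <- fit
  out
}

#' Principal components of the environmental variables
#'
#' Standardizes every EV to zero mean and unit variance (zero-variance
#' columns are dropped with a warning) and decomposes the result by SVD.
#'
#' @param env Tibble with a `sample` column plus numeric EV columns.
#' @return An `env_pca` list: `loadings`, `scores` (tibble with `sample`),
#'   `var_frac` (per-component variance fractions, summing to 1), `sdev`.
#' @export
env_pca <- function(env) {
  ev <- as.matrix(env[setdiff(names(env), "sample")])
  if (ncol(ev) < 2) abort("env_pca needs at least 2 EVs")
  keep <- apply(ev, 2, sd) > 0
  if (!all(keep)) {
    warn(sprintf("env_pca: dropping %d zero-variance EV column(s)",
                 sum(!keep)))
    ev <- ev[, keep, drop = FALSE]
  }
  Z <- scale(ev)
  sv <- svd(Z)
  scores <- Z %*% sv$v
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  colnames(sv$v) <- colnames(scores)
  rownames(sv$v) <- colnames(ev)
  structure(
    list(loadings = sv$v,
         scores = dplyr::bind_cols(tibble(sample = env$sample),
                                   as_tibble(as.data.frame(scores))),
         var_frac = sv$d^2 / sum(sv$d^2),
         sdev = sv$d / sqrt(nrow(Z) - 1)),
    class = "env_pca")
}

#' Latent-factor association scan
#'
#' Ridge-penalized alternating least squares for
#' `Y = x b' + U V' + E`, where `Y` holds centered (mean-imputed) dosages,
#' `x` is the environmental predictor and `U` (samples x K) are latent
#' factors absorbing unobserved structure.  `U` is initialized from the top
#' left singular vectors of `Y` residualized on `x`; iteration alternates
#' `(V | U)`, `(U | V)`, `(b | U, V)` until the relative objective change
#' drops below `tol`.  Per-locus z-scores come from regressing
#' `Y - U V'` on `x`; squared z-scores are calibrated by the genomic
#' inflation factor (`median(z^2) / 0.456`) and referred to chi-square(1).
#'
#' @param geno A [genotype_matrix()].
#' @param x Numeric predictor per sample (an EV or the EV-PCA PC1).
#' @param k_factors Number of latent factors (must be < samples - 2).
#' @param max_iter,tol Convergence controls.
#' @param ridge Ridge penalty.
#' @param trait Label recorded in the result rows.
#' @return Tibble like [emmax_scan()]'s, with attribute `fit` (class
#'   `lfmm_fit`: `k`, `U`, `V`, `b`, `lambda_gif`, `converged`, `n_iter`).
#' @export
lfmm_scan <- function(geno, x, k_factors = 3, max_iter = 100, tol = 1e-8,
                      ridge = 1e-4, trait = "env") {
  n <- n_samples(geno)
  if (length(x) != n) abort("x must have one value per sample")
  if (k_factors >= n - 2) abort("k_factors must be < samples - 2")
  D <- geno$dosage
  Y <- apply(D, 2, function(col) {
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    col
  })
  Y <- scale(Y, center = TRUE, scale = FALSE)
  x <- x - mean(x)
  xx <- sum(x^2)
  K <- as.integer(k_factors)

  if (K > 0) {
    Y1 <- Y - x %*% (crossprod(x, Y) / xx)
    sv <- svd(Y1, nu = K, nv = 0)
    U <- sv$u[, seq_len(K), drop = FALSE] %*%
      diag(sv$d[seq_len(K)], K, K) / sqrt(nrow(Y))
    b <- drop(crossprod(Y1, x)) * 0
    V <- matrix(0, ncol(Y), K)
    obj_old <- Inf
    converged <- FALSE
    it <- 0
    while (it < max_iter) {
      it <- it + 1
      Rb <- Y - tcrossprod(x, b)
      V <- t(solve(crossprod(U) + ridge * diag(K), crossprod(U, Rb)))
      U <- Rb %*% V %*% solve(crossprod(V) + ridge * diag(K))
      Rv <- Y - tcrossprod(U, V)
      b <- drop(crossprod(Rv, x)) / (xx + ridge)
      E <- Y - tcrossprod(x, b) - tcrossprod(U, V)
      obj <- sum(E^2) + ridge * (sum(U^2) + sum(V^2) + sum(b^2))
      if (is.finite(obj_old) && abs(obj_old - obj) < tol * obj_old) {
        converged <- TRUE
        break
      }
      obj_old <- obj
    }
    if (!converged)
      warn("lfmm_scan: alternating minimization did not converge")
    Rv <- Y - tcrossprod(U, V)
  } else {
    U <- matrix(0, n, 0)
    V <- matrix(0, ncol(Y), 0)
    Rv <- Y
    converged <- TRUE
    it <- 0
  }

  bhat <- drop(crossprod(Rv, x)) / xx
  res <- Rv - tcrossprod(x, bhat)
  df <- n - 2 - K
  sigma2 <- colSums(res^2) / df
  se <- sqrt(sigma2 / xx)
  z <- bhat / se
  med <- median(z^2, na.rm = TRUE)
  lambda_gif <- med / qchisq(0.5, 1)
  z2_cal <- z^2 / lambda_gif
  p <- pchisq(z2_cal, 1, lower.tail = FALSE)

  fit <- structure(
    list(k = K, U = U, V = V, b = bhat, lambda_gif = lambda_gif,
         converged = converged, n_iter = it, trait = trait),
    class = "lfmm_fit")
  out <- tibble(
    variant = paste0(geno$variants$chrom, ":", geno$variants$pos),
    chrom = geno$variants$chrom, pos = geno$variants$pos,
    beta = bhat, se = se, statistic = sign(z) * sqrt(z2_cal), p = p,
    trait = trait)
  attr(out, "fit") <- fit
  out
}

#' Bonferroni significance threshold
#'
#' @param n_tests Number of tests (post-filter variant count).
#' @param alpha Family-wise error rate.
#' @return List: `p_threshold` (`alpha / n_tests`) and `neg_log10`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1) abort("n_tests must be >= 1")
  thr <- alpha / n_tests
  list(p_threshold = thr, neg_log10 = -log10(thr))
}

#' Multi-EV association hotspots
#'
#' Significant SNPs (the inputs must already be thresholded) within
#' `cluster_bp` of each other are merged into loci; a locus is a hotspot
#' when it is associated with strictly more than `min_evs` distinct EVs.
#'
#' @param results A tibble of significant associations with columns `chrom`,
#'   `pos`, `trait` -- or a list of such tibbles (one per EV), which is
#'   row-bound first.
#' @param cluster_bp Merge distance in bp.
#' @param min_evs Strict lower bound on the number of distinct EVs.
#' @return Tibble: `chrom`, `start`, `end` (bp of first/last member SNP),
#'   `n_snps`, `n_evs`, `evs` (list column).
#' @export
hotspot_loci <- function(results, cluster_bp = 10000, min_evs = 5) {
  if (is.data.frame(results)) res <- results else res <- dplyr::bind_rows(results)
  if (nrow(res) == 0)
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_snps = integer(), n_evs = integer(), evs = list()))
  res <- dplyr::arrange(res, .data$chrom, .data$pos)
  out <- res |>
    dplyr::distinct(.data$chrom, .data$pos, .data$trait) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(locus = cumsum(c(1, diff(.data$pos) > cluster_bp))) |>
    dplyr::group_by(.data$chrom, .data$locus) |>
    dplyr::summarise(start = min(.data$pos), end = max(.data$pos),
                     n_snps = dplyr::n_distinct(.data$pos),
                     n_evs = dplyr::n_distinct(.data$trait),
                     evs = list(sort(unique(.data$trait))),
                     .groups = "drop") |>
    dplyr::select(-"locus")
  out[out$n_evs > min_evs, , drop = FALSE]
}
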