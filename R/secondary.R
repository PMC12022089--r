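#' Secondary-expansion test
#'
#' An asymmetric source-to-target contact probe: a Gaussian-process
#' probit model is fitted to the source-region languages alone, its
#' posterior expected latent values `Z` are computed at the target
#' locations, and the target languages' observed features are regressed
#' on `Z`. Because `Z` never sees the target feature values, a predictive
#' relationship is evidence of directional influence, unlike a symmetric
#' contact term.
#'
#' @name glossarea-secondary
NULL

#' Point-in-polygon test
#'
#' Ray casting with an inclusive boundary rule: points on a polygon edge
#' or vertex count as inside.
#'
#' @param pts points matrix (one per row).
#' @param poly polygon vertex matrix (closed or open ring).
#' @return logical vector.
#' @export
point_in_polygon <- function(pts, poly) {
  if (!all(poly[1, ] == poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  nv <- nrow(poly) - 1
  apply(pts, 1, function(p) {
    inside <- FALSE
    for (i in seq_len(nv)) {
      a <- poly[i, ]; b <- poly[i + 1, ]
      # inclusive boundary: on-segment counts as inside
      cr <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
      if (abs(cr) < 1e-9 * (abs(b[1] - a[1]) + abs(b[2] - a[2]) + 1) &&
          p[1] >= min(a[1], b[1]) - 1e-12 && p[1] <= max(a[1], b[1]) + 1e-12 &&
          p[2] >= min(a[2], b[2]) - 1e-12 && p[2] <= max(a[2], b[2]) + 1e-12)
        return(TRUE)
      if ((a[2] > p[2]) != (b[2] > p[2])) {
        xint <- a[1] + (p[2] - a[2]) * (b[1] - a[1]) / (b[2] - a[2])
        if (p[1] < xint) inside <- !inside
      }
    }
    inside
  })
}

#' Split languages into source and target regions
#'
#' Point-in-polygon assignment with an inclusive boundary; languages in
#' neither region are excluded, and a language falling in both polygons
#' is assigned to the source region (the sets stay disjoint).
#'
#' @param records a `language_records` data.frame (or any data.frame with
#'   `id`); coordinates are taken from `xy` when given, else from
#'   `lon`/`lat`.
#' @param source_poly,target_poly polygon vertex matrices.
#' @param xy optional coordinate matrix aligned with `records` rows.
#' @return object of class `source_target_split`: `source_ids`,
#'   `target_ids`, and the polygons.
#' @export
split_source_target <- function(records, source_poly, target_poly, xy = NULL) {
  if (is.null(xy)) xy <- cbind(records$lon, records$lat)
  in_s <- point_in_polygon(xy, source_poly)
  in_t <- point_in_polygon(xy, target_poly) & !in_s
  if (!any(in_s)) stop("empty source region")
  if (!any(in_t)) stop("empty target region")
  structure(list(source_ids = records$id[in_s], target_ids = records$id[in_t],
                 source_poly = source_poly, target_poly = target_poly),
            class = "source_target_split")
}

#' Posterior expected source influence Z at target locations
#'
#' Per feature, fits a Gaussian-process probit model (intercept plus
#' spatial term) to the source languages only, with a wide lengthscale
#' prior (half-Cauchy with scale equal to the maximum pairwise distance,
#' over a grid extended well beyond the observed range), and evaluates
#' the posterior expected latent value at the target locations via the GP
#' conditional mean, averaged over draws. `Z` is independent of the
#' target languages' feature values by construction.
#'
#' @param split a [split_source_target()].
#' @param traits a `trait_matrix` over all languages.
#' @param distances a `distance_set` over all languages.
#' @param chains,iterations,seed sampler settings.
#' @param scale `"latent"` (default) or `"probability"`.
#' @param n_draws draws averaged per feature.
#' @return targets-by-features matrix `Z`.
#' @export
compute_Z <- function(split, traits, distances, chains = 1,
                      iterations = 600, seed = 1,
                      scale = c("latent", "probability"), n_draws = 200) {
  scale <- match.arg(scale)
  src <- split$source_ids; tgt <- split$target_ids
  xs <- unclass(traits)[src, , drop = FALSE]
  if (any(colSums(!is.na(xs)) == 0)) stop("all-missing source feature")
  pw <- distances$pairwise
  cross <- pw[tgt, src, drop = FALSE]
  spec <- model_spec(include_phylo = FALSE, include_spatial = TRUE,
                     priors = list(ell_prior = "halfcauchy",
                                   ell_hi_factor = 10))
  Z <- matrix(0, length(tgt), ncol(traits),
              dimnames = list(tgt, colnames(traits)))
  for (j in seq_len(ncol(traits))) {
    tmj <- new_trait_matrix(xs[, j, drop = FALSE])
    m <- assemble_model(spec, tmj, distance_set(pw[src, src]))
    post <- fit(m, chains = chains, iterations = iterations,
                seed = derive_seed(seed, paste0("Z", j)))
    nd <- min(n_draws, nrow(post$draws))
    use <- seq(nrow(post$draws) - nd + 1, nrow(post$draws))
    grid <- post$pre$ell$grid
    acc <- numeric(length(tgt))
    for (k in use) {
      g <- which.min(abs(grid - post$draws[k, "lengthscale"]))
      eg <- post$pre$ell$eig[[g]]
      kc <- kernel_cor(cross, grid[g], spec$kernel)
      ustar <- kc %*% (eg$vectors %*%
                         (crossprod(eg$vectors, post$u[, 1, k]) / eg$values))
      lat <- post$draws[k, "alpha[1]"] + drop(ustar)
      acc <- acc + if (scale == "latent") lat else stats::pnorm(lat)
    }
    Z[, j] <- acc / nd
  }
  Z
}

#' Regress target features on Z
#'
#' Per feature, a Bayesian univariate probit regression of the target
#' languages' observed values on the corresponding `Z` column
#' (Albert-Chib data augmentation, N(0, 2.5^2) priors on intercept and
#' slope). Features whose `Z` column has zero variance are skipped with a
#' log entry. The verdict counts features whose 95% interval excludes
#' zero.
#'
#' @param Z targets-by-features matrix from [compute_Z()].
#' @param target_traits `trait_matrix` rows for the target languages,
#'   aligned with `Z`.
#' @param n_draws posterior draws per feature (half discarded as warmup).
#' @param seed integer seed.
#' @return list: `summary` (per-feature slope mean, 95% interval,
#'   `p_positive`, `excludes_zero`), `verdict` (count of features with
#'   intervals excluding zero), `n_tested`, and `combined` — the
#'   posterior of the across-feature mean standardised slope (the pooled
#'   detection statistic): its mean, 95% interval and `p_positive`.
#' @export
test_secondary_effect <- function(Z, target_traits, n_draws = 2000,
                                  seed = 1) {
  if (!all(dim(Z) == dim(target_traits))) stop("dimension mismatch")
  rows <- list()
  std_draws <- list()
  for (j in seq_len(ncol(Z))) {
    zj <- Z[, j]
    if (stats::sd(zj) < 1e-12) {
      ga_log("secondary_expansion", "info",
             paste("zero-variance Z for feature", colnames(Z)[j], "- skipped"))
      next
    }
    y <- unclass(target_traits)[, j]
    ok <- !is.na(y)
    if (sum(ok) < 3 || length(unique(y[ok])) < 2) next
    b <- probit_reg_gibbs(zj[ok], y[ok], n_draws,
                          derive_seed(seed, paste0("sec", j)))
    qs <- stats::quantile(b, c(0.025, 0.975))
    rows[[length(rows) + 1L]] <- data.frame(
      feature = colnames(Z)[j], slope_mean = mean(b),
      lower = qs[1], upper = qs[2], p_positive = mean(b > 0),
      excludes_zero = qs[1] > 0 | qs[2] < 0, row.names = NULL)
    std_draws[[length(std_draws) + 1L]] <- b * stats::sd(zj[ok])
  }
  summ <- do.call(rbind, rows)
  combined <- NULL
  if (length(std_draws)) {
    avg <- rowMeans(do.call(cbind, std_draws))
    combined <- list(mean = mean(avg),
                     interval = stats::quantile(avg, c(0.025, 0.975)),
                     p_positive = mean(avg > 0))
  }
  list(summary = summ,
       verdict = if (is.null(summ)) 0L else sum(summ$excludes_zero),
       n_tested = if (is.null(summ)) 0L else nrow(summ),
       combined = combined)
}

# Albert-Chib Gibbs sampler for univariate probit regression; returns
# post-warmup slope draws.
probit_reg_gibbs <- function(zcov, y, n_draws, seed) {
  set.seed(seed)
  X <- cbind(1, (zcov - mean(zcov)) / max(stats::sd(zcov), 1e-12))
  n <- length(y)
  P0 <- diag(1 / 2.5^2, 2)
  V <- chol2inv(chol(crossprod(X) + P0))
  cV <- t(chol(V))
  b <- c(0, 0)
  lo <- ifelse(y == 1, 0, -Inf); hi <- ifelse(y == 1, Inf, 0)
  keep <- numeric(n_draws)
  for (it in seq_len(2 * n_draws)) {
    zlat <- rtruncnorm_vec(drop(X %*% b), 1, lo, hi)
    b <- drop(V %*% crossprod(X, zlat) + cV %*% stats::rnorm(2))
    if (it > n_draws) keep[it - n_draws] <- b[2]
  }
  keep / max(stats::sd(zcov), 1e-12)  # slope on the original Z scale
}
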