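#' Cartographic post-processing
#'
#' Turns posterior draws into the result surfaces: per-feature predicted
#' probabilities over a geographic grid (marginal fields), PCA-to-RGB
#' compression of those fields, agglomerative clustering of grid points,
#' coefficient summaries of the expansion slopes, posterior overlap
#' between sample sets, and the stable-vs-unstable feature effect-size
#' comparison under a log-normal model.
#'
#' @name glossarea-cartography
NULL

#' Grid marginal effects
#'
#' Projects a rectangular grid over the study region (optionally clipped
#' to a polygon land mask), predicts every feature's probability at each
#' grid point for `n_draws` posterior samples and averages.
#'
#' @param post a `posterior_draws`.
#' @param grid_spec list: `xlim`, `ylim`, `step` (same units as the
#'   coordinates used to build the model's distances), `xy_lang`
#'   (languages-by-2 coordinate matrix in model row order), optional
#'   `path` (a [dispersal_path()], required when the model has an
#'   expansion term), optional `mask_poly` (polygon matrix, points outside
#'   are dropped), optional `crs` (default `"planar"`).
#' @param n_draws posterior samples to average over.
#' @return object of class `marginal_field`: `points` (grid coordinates),
#'   `values` (points-by-features probabilities), `n_draws`.
#' @export
grid_marginal_effects <- function(post, grid_spec, n_draws = 500) {
  crs <- if (is.null(grid_spec$crs)) "planar" else grid_spec$crs
  gx <- seq(grid_spec$xlim[1], grid_spec$xlim[2], by = grid_spec$step)
  gy <- seq(grid_spec$ylim[1], grid_spec$ylim[2], by = grid_spec$step)
  pts <- as.matrix(expand.grid(x = gx, y = gy))
  if (!is.null(grid_spec$mask_poly))
    pts <- pts[point_in_polygon(pts, grid_spec$mask_poly), , drop = FALSE]
  if (!nrow(pts)) stop("empty grid")
  xy <- grid_spec$xy_lang
  cross <- vapply(seq_len(nrow(xy)), function(i)
    horiz_dist(pts, matrix(xy[i, ], nrow(pts), 2, byrow = TRUE), crs),
    numeric(nrow(pts)))
  cross <- matrix(cross, nrow(pts))
  targets <- list(cross_dist = cross)
  if (post$model$spec$include_expansion) {
    if (is.null(grid_spec$path))
      stop("grid_spec$path required: grid points have undefined distance-to-entry")
    targets$d_entry <- vapply(seq_len(nrow(pts)), function(i)
      distance_to_entry(grid_spec$path, pts[i, ]), 0)
  }
  vals <- posterior_predict(post, targets, n_draws = n_draws)
  structure(list(points = pts, values = vals, n_draws = n_draws),
            class = "marginal_field")
}

#' PCA-to-RGB compression of a marginal field
#'
#' Centres the per-feature probabilities, runs PCA, min-max rescales the
#' first three component scores to `[0, 1]` and maps them to red, green
#' and blue. Absolute colours carry no meaning; similar colours mean
#' similar predicted feature profiles.
#'
#' @param field a `marginal_field`.
#' @return list: `rgb` (points-by-3 in `[0,1]`), `explained_variance`
#'   (ratios for all components), `scores`, `loadings`.
#' @export
pca_rgb <- function(field) {
  v <- field$values
  keep <- apply(v, 2, stats::sd) > 1e-12
  if (sum(keep) < 3) stop("fewer than 3 non-constant features")
  pc <- stats::prcomp(v[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  sc <- pc$x[, 1:3, drop = FALSE]
  rgb <- apply(sc, 2, function(s) {
    r <- range(s)
    if (diff(r) < 1e-15) rep(0.5, length(s)) else (s - r[1]) / diff(r)
  })
  list(rgb = rgb, explained_variance = pc$sdev^2 / sum(pc$sdev^2),
       scores = pc$x, loadings = pc$rotation)
}

#' Hierarchical clustering of a marginal field
#'
#' Ward-linkage agglomerative clustering on Euclidean distances between
#' grid points' feature-probability vectors; labels are returned for every
#' cluster count from `k_min` to `k_max` and are hierarchically nested by
#' construction.
#'
#' @param field a `marginal_field`.
#' @param k_min,k_max cluster-count range (default 2 to 11).
#' @param linkage `stats::hclust` method, default `"ward.D2"`.
#' @return matrix: points by cluster counts, column `k<i>` holding labels.
#' @export
cluster_field <- function(field, k_min = 2, k_max = 11, linkage = "ward.D2") {
  if (k_max < k_min) stop("k_max < k_min")
  if (k_max > nrow(field$values)) stop("k_max exceeds number of grid points")
  hc <- stats::hclust(stats::dist(field$values), method = linkage)
  ks <- k_min:k_max
  lab <- stats::cutree(hc, k = ks)
  lab <- matrix(lab, nrow(field$values), length(ks),
                dimnames = list(NULL, paste0("k", ks)))
  lab
}

#' Summarise expansion coefficients
#'
#' Per-feature posterior mean, median, 50% and 95% credible intervals,
#' posterior probability of a positive slope, and a zero-overlap flag set
#' when the 95% interval excludes zero.
#'
#' @param post a `posterior_draws` from a model with an expansion term.
#' @param level outer interval level, default 0.95.
#' @return data.frame, one row per feature.
#' @export
coefficient_summary <- function(post, level = 0.95) {
  J <- post$model$J
  cn <- paste0("beta[", 1:J, "]")
  if (!all(cn %in% colnames(post$draws)))
    stop("no expansion coefficients in these draws (Model 1?)")
  b <- post$draws[, cn, drop = FALSE]
  a <- (1 - level) / 2
  data.frame(
    feature = colnames(post$model$x),
    mean = colMeans(b),
    median = apply(b, 2, stats::median),
    q25 = apply(b, 2, stats::quantile, 0.25),
    q75 = apply(b, 2, stats::quantile, 0.75),
    lower = apply(b, 2, stats::quantile, a),
    upper = apply(b, 2, stats::quantile, 1 - a),
    p_positive = colMeans(b > 0),
    zero_overlap = apply(b, 2, function(v)
      stats::quantile(v, a) > 0 | stats::quantile(v, 1 - a) < 0),
    row.names = NULL)
}

#' Overlapping coefficient of two sample sets
#'
#' `integral of min(f_a, f_b)` over a common 512-point grid, with kernel
#' density estimates (Silverman bandwidth). Zero-variance inputs are
#' treated as point masses: overlap 1 if both sit on the same point, else
#' 0 against another point mass and the other density's total mass is not
#' counted.
#'
#' @param samples_a,samples_b numeric vectors.
#' @return overlap coefficient in `[0, 1]`.
#' @export
posterior_overlap <- function(samples_a, samples_b) {
  if (!length(samples_a) || !length(samples_b)) stop("empty sample set")
  sa <- stats::sd(samples_a); sb <- stats::sd(samples_b)
  if (is.na(sa)) sa <- 0
  if (is.na(sb)) sb <- 0
  if (sa < 1e-12 || sb < 1e-12) {
    return(as.numeric(sa < 1e-12 && sb < 1e-12 &&
                        abs(mean(samples_a) - mean(samples_b)) < 1e-12))
  }
  lo <- min(samples_a, samples_b) - 3 * max(sa, sb)
  hi <- max(samples_a, samples_b) + 3 * max(sa, sb)
  da <- stats::density(samples_a, from = lo, to = hi, n = 512)
  db <- stats::density(samples_b, from = lo, to = hi, n = 512)
  y <- pmin(da$y, db$y)
  sum((y[-1] + y[-length(y)]) / 2 * diff(da$x))
}

#' Stable-vs-unstable feature effect comparison
#'
#' Log-normal model of per-feature expansion effect sizes (posterior mean
#' `|beta_j|`) with a group indicator for externally assessed feature
#' stability: `log(effect) ~ Normal(mu_group, sigma^2)` with conjugate
#' normal-inverse-gamma updates. Reports the posterior of the difference
#' of group means on the effect-size scale,
#' `exp(mu_stable + sigma^2/2) - exp(mu_unstable + sigma^2/2)`.
#'
#' @param table data.frame with columns `effect` (>= 0) and `stable`
#'   (logical); zero effects are floored at `eps`.
#' @param n_draws posterior draws.
#' @param eps floor for zero effect sizes.
#' @param seed integer seed.
#' @return list: `difference` (posterior mean), `interval` (95%), `draws`
#'   (difference draws), `log_difference` (mu_stable - mu_unstable draws).
#' @export
stability_effect_model <- function(table, n_draws = 4000, eps = 1e-6,
                                   seed = 1) {
  stopifnot(all(c("effect", "stable") %in% names(table)))
  g <- as.logical(table$stable)
  if (!any(g) || all(g)) stop("one group empty")
  y <- log(pmax(table$effect, eps))
  set.seed(derive_seed(seed, "stability"))
  mu0 <- 0; k0 <- 1e-4; a0 <- 0.01; b0 <- 0.01
  ys <- y[g]; yu <- y[!g]
  ns <- length(ys); nu <- length(yu)
  mu_s <- mean(ys); mu_u <- mean(yu)
  s2 <- max(stats::var(y), 1e-6)
  out <- matrix(0, n_draws, 3)
  for (it in seq_len(n_draws)) {
    vs <- 1 / (k0 + ns / s2); vu <- 1 / (k0 + nu / s2)
    mu_s <- stats::rnorm(1, vs * (k0 * mu0 + sum(ys) / s2), sqrt(vs))
    mu_u <- stats::rnorm(1, vu * (k0 * mu0 + sum(yu) / s2), sqrt(vu))
    sse <- sum((ys - mu_s)^2) + sum((yu - mu_u)^2)
    s2 <- 1 / stats::rgamma(1, a0 + (ns + nu) / 2, b0 + sse / 2)
    out[it, ] <- c(mu_s, mu_u, s2)
  }
  diff_draws <- exp(out[, 1] + out[, 3] / 2) - exp(out[, 2] + out[, 3] / 2)
  list(difference = mean(diff_draws),
       interval = stats::quantile(diff_draws, c(0.025, 0.975)),
       draws = diff_draws, log_difference = out[, 1] - out[, 2])
}
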