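#' Fitting the multivariate probit model
#'
#' Posterior sampling uses data augmentation: the latent normal variables
#' behind each observed cell are drawn from truncated-normal full
#' conditionals (missing cells are drawn unconstrained, which marginalises
#' them), the intercepts, slopes and Gaussian-process effects have
#' conjugate normal updates (the GP blocks are diagonal in the
#' eigenbasis of their covariance, precomputed per lengthscale grid
#' value), the scale hyperparameters are slice-sampled under half-normal
#' priors, the lengthscale uses griddy Gibbs over a log-spaced grid with
#' inverse-gamma prior weights calibrated to the observed pairwise
#' distances, the per-language distance errors use vectorised
#' reflective-walk Metropolis steps under a half-Cauchy prior, and the
#' residual correlation matrix uses a parameter-expanded inverse-Wishart
#' update projected to a correlation matrix.
#'
#' @name glossarea-fit
NULL

# Lengthscale grid for griddy Gibbs. Default prior: inverse-gamma
# calibrated so ~95% of the mass lies between the 1st percentile and the
# maximum of the observed pairwise distances. The "halfcauchy" option
# (scale = max pairwise distance) with ell_hi_factor > 1 gives the wide
# prior used by the secondary-expansion probe.
ell_grid_setup <- function(pairwise, kernel, priors) {
  grid_size <- priors$ell_grid_size
  d <- pairwise[upper.tri(pairwise)]
  # floor at the design's resolvable scale (median nearest-neighbour
  # spacing): below it the GP degenerates into per-language noise that
  # the probit scale cannot identify
  diag_inf <- pairwise + diag(Inf, nrow(pairwise))
  nn <- apply(diag_inf, 1, min)
  lo <- max(stats::quantile(d[d > 0], 0.01), 1.2 * stats::median(nn),
            max(d) * 1e-4)
  hi <- max(max(d) * priors$ell_hi_factor, 2 * lo)
  grid <- exp(seq(log(lo), log(hi), length.out = grid_size))
  if (identical(priors$ell_prior, "halfcauchy")) {
    logprior <- ldhalfcauchy(grid, max(d))
  } else {
    obj <- function(par) {
      a <- exp(par[1]); b <- exp(par[2])
      (stats::pgamma(b / lo, a, lower.tail = FALSE) - 0.025)^2 +
        (stats::pgamma(b / hi, a, lower.tail = FALSE) - 0.975)^2
    }
    fit <- stats::optim(c(log(2), log(2 * sqrt(lo * hi))), obj)
    a <- exp(fit$par[1]); b <- exp(fit$par[2])
    logprior <- -(a + 1) * log(grid) - b / grid
  }
  eig <- lapply(grid, function(ell) {
    C <- kernel_cor(pairwise, ell, kernel) + diag(1e-9, nrow(pairwise))
    e <- eigen(C, symmetric = TRUE)
    e$values <- pmax(e$values, 1e-12)
    e$logdet <- sum(log(e$values))
    e$C <- C
    e
  })
  list(grid = grid, logprior = logprior - max(logprior), eig = eig)
}

# Vectorised truncated-normal draw via inverse CDF, robust in the tails.
rtruncnorm_vec <- function(mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  u <- pl + stats::runif(length(mean)) * (pu - pl)
  z <- stats::qnorm(pmin(pmax(u, 1e-15), 1 - 1e-15), mean, sd)
  pmin(pmax(z, mean - 8 * sd, lower), mean + 8 * sd, upper)
}

ldhalfcauchy <- function(x, tau) log(2 / pi) - log(tau) - log1p((x / tau)^2)

#' Fit a model by MCMC
#'
#' Augmented Gibbs sampling (see the package vignette for the update
#' schedule). Reproducible given `seed`; chains run sequentially with
#' derived sub-seeds.
#'
#' @param model a [assemble_model()] result.
#' @param chains number of chains.
#' @param iterations iterations per chain (including warmup).
#' @param warmup warmup iterations discarded per chain.
#' @param seed integer seed.
#' @param thin keep every `thin`-th post-warmup draw.
#' @return object of class `posterior_draws`: `draws` (matrix of scalar
#'   parameters, one row per kept draw), `chain` (index per row), arrays
#'   `p`, `u` (language x feature x draw) and `delta` (language x draw),
#'   `pmiss` (Rao-Blackwellised posterior predictive probability for each
#'   missing cell, conditioned on the language's observed features), the
#'   `model`, and `diagnostics` (effective sample sizes, split R-hat when
#'   multiple chains, divergence count — identically zero for this Gibbs
#'   scheme, reported for interface compatibility).
#' @export
fit <- function(model, chains = 2, iterations = 1000,
                warmup = floor(iterations / 2), seed = 1, thin = 1) {
  stopifnot(inherits(model, "ga_model"), iterations > warmup)
  spec <- model$spec
  pre <- list(tree = NULL, ell = NULL)
  if (spec$include_phylo) {
    e <- eigen(model$Sigma_tree, symmetric = TRUE)
    e$values <- pmax(e$values, 0)
    pre$tree <- e
  }
  if (spec$include_spatial)
    pre$ell <- ell_grid_setup(model$pairwise, spec$kernel, spec$priors)
  res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(derive_seed(seed, paste0("chain", ch)))
    res[[ch]] <- gibbs_chain(model, pre, iterations, warmup, thin)
  }
  draws <- do.call(rbind, lapply(res, `[[`, "draws"))
  chain <- rep(seq_len(chains), vapply(res, function(r) nrow(r$draws), 0L))
  p_arr <- if (spec$include_phylo)
    array(unlist(lapply(res, `[[`, "p")),
          c(model$n, model$J, length(chain))) else NULL
  u_arr <- if (spec$include_spatial)
    array(unlist(lapply(res, `[[`, "u")),
          c(model$n, model$J, length(chain))) else NULL
  delta_arr <- if (spec$include_distance_error)
    matrix(unlist(lapply(res, `[[`, "delta")), model$n) else NULL
  pmiss <- Reduce(`+`, lapply(res, `[[`, "pmiss")) / chains
  dimnames(pmiss) <- dimnames(model$x)
  out <- structure(list(draws = draws, chain = chain, p = p_arr, u = u_arr,
                        delta = delta_arr, pmiss = pmiss, model = model,
                        pre = pre, seed = seed),
                   class = "posterior_draws")
  out$diagnostics <- mcmc_diagnostics(out)
  out
}

gibbs_chain <- function(model, pre, iterations, warmup, thin) {
  spec <- model$spec; pri <- spec$priors
  n <- model$n; J <- model$J
  x <- model$x
  has_b <- spec$include_expansion
  has_p <- spec$include_phylo
  has_u <- spec$include_spatial
  has_d <- spec$include_distance_error
  d0 <- if (has_b) model$d_std else rep(0, n)

  alpha <- rep(0, J); beta <- rep(0, J)
  p <- matrix(0, n, J); u <- matrix(0, n, J)
  sigma_p <- rep(0.5, J); sigma_sp <- 0.5
  g <- if (has_u) ceiling(length(pre$ell$grid) / 2) else NA
  delta <- rep(0, n); tau <- 0.1
  R <- diag(J)
  lo <- ifelse(is.na(x) | x == 0, -Inf, 0)
  hi <- ifelse(is.na(x) | x == 1, Inf, 0)
  d_eff <- d0 + delta
  mu <- matrix(alpha, n, J, byrow = TRUE) + outer(d_eff, beta) + p + u
  z <- matrix(0, n, J)
  for (j in seq_len(J)) z[, j] <- rtruncnorm_vec(mu[, j], 1, lo[, j], hi[, j])

  keep <- seq(warmup + 1, iterations, by = thin)
  nk <- length(keep)
  cn <- c(paste0("alpha[", 1:J, "]"),
          if (has_b) paste0("beta[", 1:J, "]"),
          if (has_p) paste0("sigma_phylo[", 1:J, "]"),
          if (has_u) c("sigma_sp", "lengthscale"),
          if (has_d) "tau",
          if (J > 1) paste0("R[", which(upper.tri(R), arr.ind = TRUE)[, 1],
                            ",", which(upper.tri(R), arr.ind = TRUE)[, 2], "]"))
  draws <- matrix(NA_real_, nk, length(cn), dimnames = list(NULL, cn))
  p_keep <- if (has_p) array(NA_real_, c(n, J, nk)) else NULL
  u_keep <- if (has_u) array(NA_real_, c(n, J, nk)) else NULL
  delta_keep <- if (has_d) matrix(NA_real_, n, nk) else NULL
  pm_acc <- matrix(0, n, J)
  ki <- 0L
  lp_sig <- function(s) -s^2 / (2 * pri$sigma_sd^2)
  Tv <- if (has_p) pre$tree$vectors
  lamT <- if (has_p) pre$tree$values

  for (it in seq_len(iterations)) {
    Q <- chol2inv(chol(R))
    qd <- diag(Q)
    # latent normals: truncated-normal full conditionals per feature;
    # post-warmup, Rao-Blackwellised P(z_ij > 0 | rest) is accumulated for
    # missing cells (the model's predictive for a masked observation)
    for (j in seq_len(J)) {
      E <- z - mu
      cm <- if (J > 1)
        mu[, j] - (E %*% Q[, j] - E[, j] * qd[j]) / qd[j] else mu[, j]
      cs <- sqrt(1 / qd[j])
      z[, j] <- rtruncnorm_vec(cm, cs, lo[, j], hi[, j])
      if (it > warmup) pm_acc[, j] <- pm_acc[, j] + stats::pnorm(cm / cs)
    }
    # Per-feature block: the MVN row density reduces to a univariate
    # pseudo-likelihood N(ystar; mu_j, 1/Q_jj) for feature j's mean. Both
    # Gaussian-process effects are integrated out when updating the
    # phylogenetic scale and the intercept/slope, then redrawn jointly
    # from their exact conditional (Matheron's rule).
    Su <- if (has_u) sigma_sp^2 * pre$ell$eig[[g]]$C
    for (j in seq_len(J)) {
      w2 <- 1 / qd[j]
      E <- z - mu
      ystar <- if (J > 1) z[, j] + (E %*% Q[, j]) / qd[j] - E[, j] else z[, j]
      Xj <- if (has_b) cbind(1, d_eff) else matrix(1, n, 1)
      P0 <- diag(1 / c(pri$alpha_sd, if (has_b) pri$beta_sd)^2, ncol(Xj))
      base <- (if (has_u) Su else matrix(0, n, n)) + diag(w2, n)
      ab <- c(alpha[j], if (has_b) beta[j])
      if (has_p) {
        r0 <- ystar - drop(Xj %*% ab)
        sigma_p[j] <- slice_sample1(max(sigma_p[j], 1e-4), function(s) {
          cA <- chol(s^2 * model$Sigma_tree + base)
          -sum(log(diag(cA))) -
            0.5 * sum(backsolve(cA, r0, transpose = TRUE)^2) + lp_sig(s)
        }, w = 0.5, lower = 1e-6)
      }
      Sp <- if (has_p) sigma_p[j]^2 * model$Sigma_tree
      A <- (if (has_p) Sp else matrix(0, n, n)) + base
      cA <- chol(A)
      Xa <- backsolve(cA, Xj, transpose = TRUE)
      ya <- backsolve(cA, ystar, transpose = TRUE)
      Vp <- chol2inv(chol(crossprod(Xa) + P0))
      mp <- Vp %*% crossprod(Xa, ya)
      ab <- drop(mp + t(chol(Vp)) %*% stats::rnorm(ncol(Xj)))
      alpha[j] <- ab[1]
      if (has_b) beta[j] <- ab[2]
      # joint conditional draw of (p_j, u_j) given the new coefficients
      r <- ystar - drop(Xj %*% ab)
      p0 <- if (has_p) rmvn_eigen(1, rep(0, n),
              list(values = sigma_p[j]^2 * lamT, vectors = Tv)) else 0
      u0 <- if (has_u) {
        eg <- pre$ell$eig[[g]]
        rmvn_eigen(1, rep(0, n),
                   list(values = sigma_sp^2 * eg$values, vectors = eg$vectors))
      } else 0
      e0 <- stats::rnorm(n, 0, sqrt(w2))
      cvec <- backsolve(cA, backsolve(cA, r - p0 - u0 - e0,
                                      transpose = TRUE))
      if (has_p) p[, j] <- p0 + drop(Sp %*% cvec)
      if (has_u) u[, j] <- u0 + drop(Su %*% cvec)
      mu[, j] <- drop(Xj %*% ab) + p[, j] + u[, j]
    }
    # Shared spatial block: all features' spatial effects are integrated
    # out jointly. With residual covariance R (x) I_n and prior
    # I_J (x) sigma^2 C, the Kronecker sum diagonalises in the product
    # eigenbasis, so the collapsed conditionals of the scale and the
    # lengthscale, and the joint redraw of U, are O(n^2 J).
    if (has_u) {
      eigR <- eigen(R, symmetric = TRUE)
      lamR <- pmax(eigR$values, 1e-10)
      PR <- eigR$vectors
      Y <- (z - mu) + u                       # residual without U
      YtP <- Y %*% PR
      lamC <- pre$ell$eig[[g]]$values
      Yt <- crossprod(pre$ell$eig[[g]]$vectors, YtP)
      lamR_row <- matrix(lamR, n, J, byrow = TRUE)
      sigma_sp <- slice_sample1(max(sigma_sp, 1e-4), function(s) {
        vd <- lamR_row + s^2 * lamC
        -0.5 * sum(log(vd) + Yt^2 / vd) + lp_sig(s)
      }, w = 0.5, lower = 1e-6)
      lg <- vapply(seq_along(pre$ell$grid), function(gg) {
        eg <- pre$ell$eig[[gg]]
        Ytg <- crossprod(eg$vectors, YtP)
        vd <- lamR_row + sigma_sp^2 * eg$values
        -0.5 * sum(log(vd) + Ytg^2 / vd) + pre$ell$logprior[gg]
      }, 0)
      pg <- exp(lg - max(lg)); g <- sample.int(length(pg), 1, prob = pg)
      eg <- pre$ell$eig[[g]]
      Yt <- crossprod(eg$vectors, YtP)
      prec <- 1 / lamR_row + 1 / (sigma_sp^2 * eg$values)
      mt <- (Yt / lamR_row) / prec
      Ut <- mt + stats::rnorm(n * J) / sqrt(prec)
      u <- eg$vectors %*% Ut %*% t(PR)
      mu <- (z - Y) + u                  # z - Y = mu without the old U
    }
    if (has_d) {
      prop <- abs(delta + stats::rnorm(n, 0, 0.3))
      mu_prop <- mu + outer(prop - delta, beta)
      E0 <- z - mu; E1 <- z - mu_prop
      la0 <- -0.5 * rowSums((E0 %*% Q) * E0) + ldhalfcauchy(delta, tau)
      la1 <- -0.5 * rowSums((E1 %*% Q) * E1) + ldhalfcauchy(prop, tau)
      acc <- log(stats::runif(n)) < la1 - la0
      delta[acc] <- prop[acc]
      mu[acc, ] <- mu_prop[acc, ]
      d_eff <- d0 + delta
      tau <- slice_sample1(max(tau, 1e-4), function(t)
        sum(ldhalfcauchy(delta, t)) - t^2 / (2 * pri$tau_sd^2),
        w = 0.2, lower = 1e-6)
    }
    if (J > 1) {
      E <- z - mu
      S <- diag(J) + crossprod(E)
      W <- stats::rWishart(1, J + 2 + n, chol2inv(chol(S)))[, , 1]
      R <- stats::cov2cor(chol2inv(chol(W)))
    }
    if (it > warmup && (it - warmup - 1) %% thin == 0) {
      ki <- ki + 1L
      row <- c(alpha, if (has_b) beta, if (has_p) sigma_p,
               if (has_u) c(sigma_sp, pre$ell$grid[g]),
               if (has_d) tau,
               if (J > 1) R[upper.tri(R)])
      draws[ki, ] <- row
      if (has_p) p_keep[, , ki] <- p
      if (has_u) u_keep[, , ki] <- u
      if (has_d) delta_keep[, ki] <- delta
    }
  }
  pmiss <- pm_acc / (iterations - warmup)
  pmiss[!is.na(x)] <- NA_real_
  list(draws = draws, p = p_keep, u = u_keep, delta = delta_keep,
       pmiss = pmiss)
}

# Effective sample size by initial-positive-sequence autocovariance sums,
# and split R-hat when at least two chains are present.
mcmc_diagnostics <- function(post) {
  d <- post$draws
  ess1 <- function(v) {
    v <- v - mean(v)
    m <- length(v)
    if (stats::sd(v) < 1e-12) return(m)
    ac <- stats::acf(v, lag.max = min(m - 1, 100), plot = FALSE)$acf[-1]
    s <- 0
    for (k in seq(1, length(ac) - 1, by = 2)) {
      pair <- ac[k] + ac[k + 1]
      if (is.na(pair) || pair < 0) break
      s <- s + pair
    }
    m / (1 + 2 * s)
  }
  ess <- apply(d, 2, ess1)
  rhat <- NULL
  if (length(unique(post$chain)) >= 2) {
    rhat <- apply(d, 2, function(v) {
      ch <- split(v, post$chain)
      halves <- unlist(lapply(ch, function(w) {
        h <- floor(length(w) / 2)
        list(w[1:h], w[(h + 1):(2 * h)])
      }), recursive = FALSE)
      m <- length(halves); nn <- length(halves[[1]])
      mns <- vapply(halves, mean, 0); vrs <- vapply(halves, stats::var, 0)
      W <- mean(vrs); B <- nn * stats::var(mns)
      if (W < 1e-12) return(1)
      sqrt((nn - 1) / nn + B / (W * nn))
    })
  }
  list(ess = ess, rhat = rhat, divergences = 0L)
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws: %d draws x %d parameters, %d chain(s)>\n",
              nrow(x$draws), ncol(x$draws), length(unique(x$chain))))
  cat(sprintf("  min ESS %.0f%s, divergences %d\n",
              min(x$diagnostics$ess),
              if (!is.null(x$diagnostics$rhat))
                sprintf(", max split R-hat %.3f", max(x$diagnostics$rhat))
              else "",
              x$diagnostics$divergences))
  invisible(x)
}

#' Posterior predictive probabilities
#'
#' For each target and feature, the mean over posterior draws of
#' `Phi(latent mean)`. At the sampled languages the stored phylogenetic
#' and spatial effects are used directly; at new points the spatial effect
#' is extended by the noise-free Gaussian-process conditional mean
#' (kriging) and the phylogenetic effect takes its prior mean of zero (a
#' grid point has no lineage).
#'
#' @param post a `posterior_draws`.
#' @param targets `NULL` for the sampled languages, or a list with
#'   `cross_dist` (targets-by-languages distance matrix, m) and, when the
#'   model has an expansion term, `d_entry` (per-target metres).
#' @param n_draws number of most recent draws to average over.
#' @return targets-by-features matrix of probabilities in `[0, 1]`.
#' @export
posterior_predict <- function(post, targets = NULL, n_draws = 500) {
  model <- post$model; spec <- model$spec
  nd <- min(n_draws, nrow(post$draws))
  use <- seq(nrow(post$draws) - nd + 1, nrow(post$draws))
  J <- model$J
  has_b <- spec$include_expansion
  alpha <- post$draws[use, paste0("alpha[", 1:J, "]"), drop = FALSE]
  beta <- if (has_b) post$draws[use, paste0("beta[", 1:J, "]"), drop = FALSE]
  if (is.null(targets)) {
    m <- model$n
    dstd <- if (has_b) model$d_std else NULL
    acc <- matrix(0, m, J)
    for (k in seq_along(use)) {
      i <- use[k]
      d_eff <- if (has_b) {
        dl <- if (!is.null(post$delta)) post$delta[, i] else 0
        dstd + dl
      } else NULL
      muk <- matrix(alpha[k, ], m, J, byrow = TRUE)
      if (has_b) muk <- muk + outer(d_eff, beta[k, ])
      if (!is.null(post$p)) muk <- muk + post$p[, , i]
      if (!is.null(post$u)) muk <- muk + post$u[, , i]
      acc <- acc + stats::pnorm(muk)
    }
    out <- acc / nd
    rownames(out) <- model$ids
  } else {
    cross <- targets$cross_dist
    m <- nrow(cross)
    if (has_b) {
      if (is.null(targets$d_entry))
        stop("targets need d_entry when the expansion term is present")
      dstd <- (targets$d_entry - model$center) / model$scale
    }
    grid <- post$pre$ell$grid
    acc <- matrix(0, m, J)
    for (k in seq_along(use)) {
      i <- use[k]
      muk <- matrix(alpha[k, ], m, J, byrow = TRUE)
      if (has_b) muk <- muk + outer(dstd, beta[k, ])
      if (!is.null(post$u)) {
        g <- which.min(abs(grid - post$draws[i, "lengthscale"]))
        eg <- post$pre$ell$eig[[g]]
        kc <- kernel_cor(cross, grid[g], spec$kernel)
        A <- eg$vectors %*% (crossprod(eg$vectors, post$u[, , i]) / eg$values)
        muk <- muk + kc %*% A
      }
      acc <- acc + stats::pnorm(muk)
    }
    out <- acc / nd
  }
  colnames(out) <- colnames(model$x)
  out
}

#' Persist posterior draws
#'
#' Writes a long-format CSV (chain, iteration, parameter, value) of the
#' scalar parameters, a diagnostics summary CSV, and a JSON run manifest
#' echoing the model specification.
#'
#' @param post a `posterior_draws`.
#' @param dir output directory.
#' @export
write_posterior_draws <- function(post, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- post$draws
  long <- data.frame(chain = rep(post$chain, ncol(d)),
                     iteration = rep(seq_len(nrow(d)), ncol(d)),
                     parameter = rep(colnames(d), each = nrow(d)),
                     value = as.vector(d))
  utils::write.csv(long, file.path(dir, "draws.csv"), row.names = FALSE)
  diag <- data.frame(parameter = colnames(d), ess = post$diagnostics$ess,
                     rhat = if (is.null(post$diagnostics$rhat)) NA
                            else post$diagnostics$rhat)
  utils::write.csv(diag, file.path(dir, "diagnostics.csv"), row.names = FALSE)
  spec <- post$model$spec
  manifest <- list(spec = spec[c("include_phylo", "include_spatial",
                                 "include_expansion", "include_distance_error",
                                 "kernel")],
                   priors = spec$priors, seed = post$seed,
                   n_lang = post$model$n, n_feat = post$model$J,
                   draws = nrow(d), version = "0.1.0")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
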