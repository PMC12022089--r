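#' Multivariate probit likelihood
#'
#' The observation model: each language's observed binary features select
#' an orthant of a latent multivariate normal `N(mu_i, R)` (unit variances,
#' `R` a correlation matrix); missing features are marginalised out by
#' dropping their coordinates from the orthant. Orthant probabilities use
#' exact nested 1-D quadrature up to three dimensions and the GHK
#' sequential-conditioning simulator beyond.
#'
#' @name glossarea-probit
NULL

# CDF of the standard bivariate normal at (b1, b2) with correlation rho,
# by 1-D quadrature over the first coordinate.
pnorm2 <- function(b1, b2, rho) {
  if (abs(rho) >= 1 - 1e-12) {
    return(if (rho > 0) stats::pnorm(min(b1, b2))
           else max(0, stats::pnorm(b1) - stats::pnorm(-b2)))
  }
  if (b1 == -Inf || b2 == -Inf) return(0)
  s <- sqrt(1 - rho^2)
  f <- function(t) stats::dnorm(t) * stats::pnorm((b2 - rho * t) / s)
  stats::integrate(f, -Inf, b1, rel.tol = 1e-10, abs.tol = 1e-13)$value
}

# Trivariate normal CDF by conditioning on the first coordinate.
pnorm3 <- function(b, R) {
  if (any(b == -Inf)) return(0)
  r12 <- R[1, 2]; r13 <- R[1, 3]; r23 <- R[2, 3]
  s2 <- sqrt(1 - r12^2); s3 <- sqrt(1 - r13^2)
  rho23.1 <- (r23 - r12 * r13) / (s2 * s3)
  f <- function(t) {
    vapply(t, function(ti)
      stats::dnorm(ti) *
        pnorm2((b[2] - r12 * ti) / s2, (b[3] - r13 * ti) / s3, rho23.1),
      0)
  }
  stats::integrate(f, -Inf, b[1], rel.tol = 1e-9, abs.tol = 1e-12)$value
}

# GHK simulator for P(Z < b), Z ~ N(0, R), using a fixed local RNG stream.
ghk_prob <- function(b, R, n_draws = 4000, seed = 17) {
  J <- length(b)
  L <- t(chol(R))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  U <- matrix(stats::runif(n_draws * J), n_draws, J)
  w <- rep(1, n_draws)
  e <- matrix(0, n_draws, J)
  for (j in seq_len(J)) {
    upper <- (b[j] - if (j > 1) e[, seq_len(j - 1), drop = FALSE] %*%
                L[j, seq_len(j - 1)] else 0) / L[j, j]
    pj <- stats::pnorm(upper)
    w <- w * pj
    pu <- pmin(pmax(U[, j] * pj, 1e-300), 1 - 1e-16)
    e[, j] <- stats::qnorm(pu)
  }
  mean(w)
}

#' Orthant probability of a multivariate normal
#'
#' `P(sign(z_j) matches x_j for all j)` for `z ~ N(mu, R)`. Exact
#' quadrature for up to three dimensions, GHK simulation beyond.
#'
#' @param mu mean vector.
#' @param R correlation matrix.
#' @param x binary vector (same length) selecting the orthant.
#' @param ghk_draws number of GHK draws for dimensions above three.
#' @return probability.
#' @export
orthant_prob <- function(mu, R, x, ghk_draws = 4000) {
  J <- length(mu)
  s <- 2 * x - 1
  b <- s * mu
  if (J == 1) return(stats::pnorm(b))
  Rs <- R * tcrossprod(s)
  if (J == 2) return(pnorm2(b[1], b[2], Rs[1, 2]))
  if (J == 3) return(pnorm3(b, Rs))
  ghk_prob(b, Rs, n_draws = ghk_draws)
}

#' Multivariate probit log-likelihood
#'
#' Sum over languages of the log orthant probability of
#' `N(latent_mean_i, R)` selected by the observed features; missing cells
#' are dropped from the orthant (marginalised).
#'
#' @param latent_mean languages-by-features matrix of latent means.
#' @param R feature correlation matrix (positive definite, unit diagonal).
#' @param x trait matrix (0/1/NA), same dimensions.
#' @param ghk_draws GHK draws used when more than three features are
#'   observed for a language.
#' @return total log-likelihood.
#' @export
probit_loglik <- function(latent_mean, R, x, ghk_draws = 4000) {
  stopifnot(all(dim(latent_mean) == dim(x)))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("R is not positive-definite")
  ll <- 0
  for (i in seq_len(nrow(x))) {
    obs <- which(!is.na(x[i, ]))
    if (!length(obs)) next
    p <- orthant_prob(latent_mean[i, obs], R[obs, obs, drop = FALSE],
                      as.numeric(x[i, obs]), ghk_draws = ghk_draws)
    ll <- ll + log(max(p, 1e-300))
  }
  ll
}
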