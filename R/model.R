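#' Model specification and covariance construction
#'
#' Three nested specifications: Model 1 has a phylogenetic term and a
#' spatial/contact Gaussian process; Model 2 adds a linear expansion term
#' on the (standardised) distance-to-entry; Model 3 adds a strictly
#' positive per-language measurement error on that distance, with a
#' half-Cauchy prior. The probit scale is fixed at 1 and the residual
#' covariance constrained to a correlation matrix for identification.
#'
#' @name glossarea-model
NULL

#' Specify a model
#'
#' @param model 1, 2 or 3 (shorthand for the standard nesting), or `NULL`
#'   to set flags directly.
#' @param include_phylo,include_spatial,include_expansion,include_distance_error
#'   component flags; a distance-error term requires the expansion term.
#' @param kernel spatial kernel: `"exp_quad"` (exponentiated quadratic,
#'   default) or `"matern32"`.
#' @param priors named list overriding prior scales: `alpha_sd` (1.5),
#'   `beta_sd` (1), `sigma_sd` (1, half-normal for phylogenetic and
#'   spatial scales), `tau_sd` (0.5, half-normal for the half-Cauchy scale
#'   on standardised distance error), `ell_grid_size` (12).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(model = NULL, include_phylo = TRUE,
                       include_spatial = TRUE, include_expansion = FALSE,
                       include_distance_error = FALSE,
                       kernel = c("exp_quad", "matern32"), priors = list()) {
  kernel <- match.arg(kernel)
  if (!is.null(model)) {
    stopifnot(model %in% 1:3)
    include_phylo <- TRUE; include_spatial <- TRUE
    include_expansion <- model >= 2
    include_distance_error <- model == 3
  }
  if (include_distance_error && !include_expansion)
    stop("a distance-error term requires the expansion term")
  defaults <- list(alpha_sd = 1.5, beta_sd = 1, sigma_sd = 1, tau_sd = 0.5,
                   ell_grid_size = 12, ell_prior = "invgamma",
                   ell_hi_factor = 1)
  pri <- utils::modifyList(defaults, priors)
  structure(list(include_phylo = include_phylo,
                 include_spatial = include_spatial,
                 include_expansion = include_expansion,
                 include_distance_error = include_distance_error,
                 kernel = kernel, priors = pri),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  terms <- c(if (x$include_phylo) "phylo", if (x$include_spatial) "spatial",
             if (x$include_expansion) "expansion",
             if (x$include_distance_error) "distance-error")
  cat("<model_spec:", paste(terms, collapse = " + "),
      sprintf("| kernel=%s>\n", x$kernel))
  invisible(x)
}

#' Phylogenetic covariance from a forest
#'
#' `Sigma[a, b]` is the shared root-to-MRCA branch length of tips `a` and
#' `b`; entries across trees are zero (isolates are independent). By
#' default the matrix is scaled to unit maximum diagonal.
#'
#' @param phy a `phylogeny`.
#' @param ids language ids giving row/column order; every id must map to
#'   at most one tip, unmapped ids get an independent unit variance.
#' @param scale scale to unit maximum diagonal?
#' @return symmetric PSD matrix.
#' @export
phylo_covariance <- function(phy, ids, scale = TRUE) {
  n <- length(ids)
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  id_of_tip <- phy$tip_map
  for (tr in phy$trees) {
    tips <- tr$tip.label
    lang <- id_of_tip[tips]
    keep <- which(!is.na(lang) & lang %in% ids)
    if (!length(keep)) next
    if (length(tips) == 1) {
      S[lang[1], lang[1]] <- tr$edge.length[1]
    } else {
      V <- ape::vcv(tr)
      pos <- match(lang[keep], ids)
      S[pos, pos] <- V[keep, keep]
    }
  }
  absent <- setdiff(ids, id_of_tip)
  if (length(absent)) {
    unit <- if (max(diag(S)) > 0) max(diag(S)) else 1
    diag(S)[match(absent, ids)] <- unit
  }
  if (scale && max(diag(S)) > 0) S <- S / max(diag(S))
  S
}

#' Spatial covariance kernel
#'
#' `K(d) = sigma^2 * k(d / ell)` with `k(0) = 1`, strictly decreasing and
#' vanishing at infinity; a jitter of `1e-9 * sigma^2` is added to the
#' diagonal for numerical positive-definiteness.
#'
#' @param pairwise symmetric distance matrix (m), zero diagonal.
#' @param sigma_sp marginal scale (>= 0).
#' @param lengthscale kernel lengthscale (m, > 0).
#' @param kernel `"exp_quad"` (`exp(-d^2 / (2 ell^2))`) or `"matern32"`.
#' @return covariance matrix.
#' @export
spatial_kernel <- function(pairwise, sigma_sp, lengthscale,
                           kernel = c("exp_quad", "matern32")) {
  kernel <- match.arg(kernel)
  if (lengthscale <= 0) stop("non-positive lengthscale")
  K <- sigma_sp^2 * kernel_cor(pairwise, lengthscale, kernel)
  K + diag(1e-9 * sigma_sp^2, nrow(K))
}

kernel_cor <- function(d, ell, kernel) {
  if (kernel == "exp_quad") {
    exp(-d^2 / (2 * ell^2))
  } else {
    a <- sqrt(3) * d / ell
    (1 + a) * exp(-a)
  }
}

#' Assemble a fittable model
#'
#' Binds a specification to data and covariance structure. The latent mean
#' under the full Model 3 is
#' `alpha_j + beta_j * (D_i + delta_i - m) / s + p_j(i) + u_j(i)` with
#' `m`, `s` the mean and standard deviation of the observed
#' distance-to-entry (fixed constants), `delta_i >= 0` half-Cauchy, the
#' phylogenetic effects `p_j` tree-correlated, and the spatial effects
#' `u_j` drawn independently per feature from one shared kernel.
#'
#' The free parameter count for a model with all terms is
#' `3J + 2nJ + n + 3 + J(J-1)/2`: per feature an intercept, a slope and a
#' phylogenetic scale; per feature-language a phylogenetic and a spatial
#' effect; per language a distance error; the shared spatial scale,
#' lengthscale and error scale; and the residual correlations.
#'
#' @param spec a [model_spec()].
#' @param traits a `trait_matrix`.
#' @param distances a `distance_set` over the same languages (pairwise
#'   required when `include_spatial`; `d_entry` when `include_expansion`).
#' @param phylogeny a `phylogeny` (required when `include_phylo`).
#' @param standardize optional `c(center, scale)` for the distance
#'   predictor; defaults to mean/sd of the observed `d_entry`.
#' @return object of class `ga_model` with a `param_table` data.frame.
#' @export
assemble_model <- function(spec, traits, distances = NULL, phylogeny = NULL,
                           standardize = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  ids <- rownames(traits)
  n <- nrow(traits); J <- ncol(traits)
  Sigma_tree <- NULL; pairwise <- NULL; d_std <- NULL
  center <- 0; scl <- 1
  if (spec$include_phylo) {
    if (is.null(phylogeny)) stop("phylogeny required for the phylogenetic term")
    Sigma_tree <- phylo_covariance(phylogeny, ids, scale = TRUE)
  }
  if (spec$include_spatial) {
    if (is.null(distances)) stop("distances required for the spatial term")
    pairwise <- distances$pairwise[ids, ids]
  }
  if (spec$include_expansion) {
    if (is.null(distances$d_entry)) stop("d_entry required for the expansion term")
    D <- distances$d_entry[ids]
    if (is.null(standardize)) {
      center <- mean(D); scl <- stats::sd(D)
      if (!is.finite(scl) || scl == 0) scl <- 1
    } else {
      center <- standardize[1]; scl <- standardize[2]
    }
    d_std <- (D - center) / scl
  }
  pt <- model_param_table(spec, n, J)
  structure(list(spec = spec, x = unclass(traits), ids = ids, n = n, J = J,
                 Sigma_tree = Sigma_tree, pairwise = pairwise,
                 d_std = d_std, center = center, scale = scl,
                 param_table = pt),
            class = "ga_model")
}

model_param_table <- function(spec, n, J) {
  blocks <- list(data.frame(block = "alpha", count = J))
  if (spec$include_expansion)
    blocks <- c(blocks, list(data.frame(block = "beta", count = J)))
  if (spec$include_phylo)
    blocks <- c(blocks, list(data.frame(block = "sigma_phylo", count = J),
                             data.frame(block = "p", count = n * J)))
  if (spec$include_spatial)
    blocks <- c(blocks, list(data.frame(block = "sigma_sp", count = 1),
                             data.frame(block = "lengthscale", count = 1),
                             data.frame(block = "u", count = n * J)))
  if (spec$include_distance_error)
    blocks <- c(blocks, list(data.frame(block = "tau", count = 1),
                             data.frame(block = "delta", count = n)))
  if (J > 1)
    blocks <- c(blocks, list(data.frame(block = "R", count = J * (J - 1) / 2)))
  do.call(rbind, blocks)
}

#' @export
print.ga_model <- function(x, ...) {
  cat(sprintf("<ga_model: %d languages x %d features, %d free parameters>\n",
              x$n, x$J, sum(x$param_table$count)))
  print(x$spec)
  invisible(x)
}
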