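#' Synthetic datasets with known ground truth
#'
#' The generator inverts the fitted model exactly: latent
#' `z_ij = alpha_j + beta_j * std(D_i + delta_i) + p_j(i) + u_j(i) + eps_ij`
#' with tree-structured `p_j`, spatial GP `u_j` sharing one kernel across
#' features, residual correlation `R` across features, probit observation
#' `x_ij = 1{z_ij > 0}`, and MCAR missingness. The realised latent
#' components are retained for recovery tests.
#'
#' @name glossarea-synthetic
NULL

#' Generative parameter set
#'
#' Defaults mirror the study conditions: 102 languages, 77 binary
#' features, ~8% missing cells, phylogenetic and spatial effect scales of
#' comparable magnitude, a 1500 km spatial lengthscale and a 200 km
#' half-Cauchy scale for per-language distance error.
#'
#' @param n_lang,n_feat dimensions.
#' @param alpha per-feature intercepts (recycled).
#' @param beta per-feature expansion slopes on standardised distance.
#' @param sigma_phylo per-feature phylogenetic scales (>= 0, recycled).
#' @param sigma_sp shared spatial scale (>= 0).
#' @param lengthscale_sp shared spatial lengthscale (m, > 0).
#' @param residual_corr feature-by-feature correlation matrix, unit
#'   diagonal; default identity.
#' @param error_scale half-Cauchy scale tau (m) for per-language distance
#'   error `delta_i >= 0`.
#' @param missing_rate MCAR missingness rate in `[0, 1)`.
#' @param seed integer seed.
#' @return list of class `generative_params`.
#' @export
generative_params <- function(n_lang = 102, n_feat = 77,
                              alpha = 0, beta = 0,
                              sigma_phylo = 0.8, sigma_sp = 0.8,
                              lengthscale_sp = 1.5e6,
                              residual_corr = NULL,
                              error_scale = 2e5,
                              missing_rate = 0.08, seed = 1) {
  if (is.null(residual_corr)) residual_corr <- diag(n_feat)
  stopifnot(n_lang >= 1, n_feat >= 1, missing_rate >= 0, missing_rate < 1,
            sigma_sp >= 0, lengthscale_sp > 0, error_scale >= 0,
            all(sigma_phylo >= 0))
  if (nrow(residual_corr) != n_feat ||
      max(abs(diag(residual_corr) - 1)) > 1e-12 ||
      max(abs(residual_corr - t(residual_corr))) > 1e-12)
    stop("residual_corr must be a symmetric unit-diagonal matrix")
  ev <- eigen(residual_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("residual_corr is not positive-definite")
  structure(list(n_lang = n_lang, n_feat = n_feat,
                 alpha = rep_len(alpha, n_feat),
                 beta = rep_len(beta, n_feat),
                 sigma_phylo = rep_len(sigma_phylo, n_feat),
                 sigma_sp = sigma_sp, lengthscale_sp = lengthscale_sp,
                 residual_corr = residual_corr, error_scale = error_scale,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "generative_params")
}

#' Simulate a pure-birth phylogeny
#'
#' Yule tree with the stated number of tips, total depth normalised to 1;
#' tips are labelled `L001, L002, ...` and map to themselves.
#'
#' @param n_tips number of tips (>= 1).
#' @param seed integer seed.
#' @return a `phylogeny` with one tree.
#' @export
simulate_tree <- function(n_tips, seed = 1) {
  stopifnot(n_tips >= 1)
  ids <- sprintf("L%03d", seq_len(n_tips))
  set.seed(derive_seed(seed, "tree"))
  if (n_tips == 1) {
    tr <- read_single_newick(paste0(ids, ":1;"))
  } else {
    tr <- ape::rphylo(n_tips, birth = 1, death = 0)
    tr$tip.label <- ids
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length / depth
  }
  phylogeny_from_trees(list(tr))
}

# Default synthetic dispersal corridor: a gently winding north-to-south
# polyline ~24,000 km long in planar metre coordinates (y = north).
default_path_spec <- function() {
  list(entry = c(0, 2.4e7),
       waypoints = rbind(c(4e5, 1.8e7), c(-3e5, 1.2e7), c(3e5, 6e6),
                         c(0, 0)),
       buffer = 1e6, step = 5e4)
}

# Display coordinates for the synthetic corridor: a linear map of planar
# metres onto plausible lat/lon so records satisfy their range invariants.
planar_to_lonlat <- function(xy) {
  cbind(lon = -100 + xy[, 1] / 111320,
        lat = -55 + 127 * xy[, 2] / 2.4e7)
}

#' Simulate language geography along a dispersal corridor
#'
#' Scatters languages within a buffer of a synthetic dispersal path on
#' flat terrain, and computes their distance set: pairwise straight-line
#' distances (the flat-raster least-cost limit) and the along-path
#' distance-to-entry `D_i`.
#'
#' @param n_lang number of languages.
#' @param path_spec list with `entry`, `waypoints`, `buffer` (m), `step`
#'   (m); default a ~24,000 km north-to-south corridor.
#' @param seed integer seed.
#' @return list: `records` (language_records with synthetic lon/lat),
#'   `xy` (planar metre coordinates), `path` (dispersal_path),
#'   `distances` (distance_set with `d_entry`).
#' @export
simulate_geography <- function(n_lang, path_spec = NULL, seed = 1) {
  if (is.null(path_spec)) path_spec <- default_path_spec()
  if (path_spec$buffer <= 0) stop("buffer too small, no points fit")
  set.seed(derive_seed(seed, "geography"))
  path <- dispersal_path(path_spec$entry, path_spec$waypoints,
                         step = path_spec$step, crs = "planar")
  npts <- nrow(path$points)
  anchor <- path$points[sample.int(npts, n_lang, replace = TRUE), , drop = FALSE]
  theta <- stats::runif(n_lang, 0, 2 * pi)
  rad <- path_spec$buffer * sqrt(stats::runif(n_lang))
  xy <- anchor + cbind(rad * cos(theta), rad * sin(theta))
  ids <- sprintf("L%03d", seq_len(n_lang))
  rownames(xy) <- ids
  d_entry <- vapply(seq_len(n_lang),
                    function(i) distance_to_entry(path, xy[i, ]), 0)
  names(d_entry) <- ids
  pw <- as.matrix(stats::dist(xy))
  dimnames(pw) <- list(ids, ids)
  ll <- planar_to_lonlat(xy)
  rec <- validate_language_records(data.frame(
    id = ids, name = ids, lat = ll[, "lat"], lon = ll[, "lon"],
    family_path = "", stringsAsFactors = FALSE))
  list(records = rec, xy = xy, path = path,
       distances = distance_set(pw, d_entry = d_entry))
}

#' Simulate a dataset from the generative model
#'
#' @param params a [generative_params()].
#' @param geography result of [simulate_geography()] (or compatible list);
#'   default simulated from `params$seed`.
#' @param phylogeny a `phylogeny`; default simulated from `params$seed`.
#' @return list of class `synthetic_dataset`: `traits` (trait_matrix with
#'   missing cells), `records`, `phylogeny`, `path`, `distances`, and
#'   `truth` (all realised latent components plus `params`).
#' @export
simulate_dataset <- function(params, geography = NULL, phylogeny = NULL) {
  n <- params$n_lang; J <- params$n_feat
  if (is.null(geography)) geography <- simulate_geography(n, seed = params$seed)
  if (is.null(phylogeny)) phylogeny <- simulate_tree(n, seed = params$seed)
  ids <- geography$records$id
  stopifnot(length(ids) == n)
  set.seed(derive_seed(params$seed, "dataset"))

  Sigma_tree <- phylo_covariance(phylogeny, ids, scale = TRUE)
  D <- geography$distances$d_entry[ids]
  delta <- abs(params$error_scale * stats::rcauchy(n))
  mD <- mean(D); sD <- stats::sd(D)
  if (!is.finite(sD) || sD == 0) sD <- 1
  d_std <- (D + delta - mD) / sD

  eig_tree <- eigen(Sigma_tree, symmetric = TRUE)
  K <- spatial_kernel(geography$distances$pairwise[ids, ids],
                      params$sigma_sp, params$lengthscale_sp)
  eig_sp <- eigen(K, symmetric = TRUE)
  p <- vapply(seq_len(J), function(j)
    rmvn_eigen(1, rep(0, n), list(values = eig_tree$values * params$sigma_phylo[j]^2,
                                  vectors = eig_tree$vectors)), numeric(n))
  u <- vapply(seq_len(J), function(j)
    rmvn_eigen(1, rep(0, n), eig_sp), numeric(n))
  cR <- chol(params$residual_corr)
  eps <- matrix(stats::rnorm(n * J), n, J) %*% cR
  z <- matrix(params$alpha, n, J, byrow = TRUE) +
    outer(d_std, params$beta) + p + u + eps
  x <- matrix(as.integer(z > 0), n, J,
              dimnames = list(ids, sprintf("F%02d", seq_len(J))))

  mask <- matrix(stats::runif(n * J) < params$missing_rate, n, J)
  # never remove the last observation of a language or a feature
  for (i in which(rowSums(!mask) == 0)) mask[i, sample.int(J, 1)] <- FALSE
  for (j in which(colSums(!mask) == 0)) mask[sample.int(n, 1), j] <- FALSE
  xm <- x; xm[mask] <- NA_integer_

  structure(list(
    traits = new_trait_matrix(xm), records = geography$records,
    phylogeny = phylogeny, path = geography$path,
    distances = geography$distances, xy = geography$xy,
    truth = list(params = params, z = z, x_full = x, p = p, u = u,
                 eps = eps, delta = delta, d_std = d_std,
                 D = D, center = mD, scale = sD, mask = mask)),
    class = "synthetic_dataset")
}

#' Write a synthetic dataset to disk
#'
#' Emits the same formats the readers consume (trait CSV, metadata CSV,
#' Newick, distance CSVs) plus a truth CSV of the realised latent
#' components for recovery tests.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trait_matrix(ds$traits, file.path(dir, "traits.csv"))
  utils::write.csv(as.data.frame(ds$records), file.path(dir, "languages.csv"),
                   row.names = FALSE)
  ape::write.tree(ds$phylogeny$trees, file.path(dir, "trees.nwk"))
  write_distance_set(ds$distances, file.path(dir, "distances.csv"))
  tr <- ds$truth
  truth <- data.frame(id = ds$records$id, D = tr$D, delta = tr$delta,
                      d_std = tr$d_std)
  for (j in seq_len(ncol(tr$z))) {
    truth[[paste0("z_", j)]] <- tr$z[, j]
    truth[[paste0("p_", j)]] <- tr$p[, j]
    truth[[paste0("u_", j)]] <- tr$u[, j]
  }
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
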