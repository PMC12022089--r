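# Small fixtures built in code; nothing is stored on disk.

tiny_traits <- function(vals, ids = NULL, feats = NULL) {
  m <- as.matrix(vals)
  if (is.null(ids)) ids <- sprintf("L%03d", seq_len(nrow(m)))
  if (is.null(feats)) feats <- sprintf("F%02d", seq_len(ncol(m)))
  dimnames(m) <- list(ids, feats)
  storage.mode(m) <- "integer"
  glossarea:::new_trait_matrix(m)
}

write_tmp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

flat_raster <- function(nr = 3, nc = 3, cellsize = 1000, elev = 0) {
  elevation_raster(matrix(elev, nr, nc), cellsize, crs = "planar")
}

# independent oracle: shortest path between two cells of a small grid by
# exhaustive enumeration of simple paths (8-neighbour moves, 3-D weights)
brute_force_grid_distance <- function(values, cellsize, from, to) {
  nr <- nrow(values); nc <- ncol(values)
  best <- Inf
  moves <- expand.grid(dr = -1:1, dc = -1:1)
  moves <- moves[!(moves$dr == 0 & moves$dc == 0), ]
  rec <- function(r, c, dist, visited) {
    if (dist >= best) return()
    if (r == to[1] && c == to[2]) { best <<- dist; return() }
    for (k in seq_len(nrow(moves))) {
      r2 <- r + moves$dr[k]; c2 <- c + moves$dc[k]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (is.na(values[r2, c2]) || visited[r2, c2]) next
      h <- cellsize * sqrt(moves$dr[k]^2 + moves$dc[k]^2)
      w <- sqrt(h^2 + (values[r2, c2] - values[r, c])^2)
      visited[r2, c2] <- TRUE
      rec(r2, c2, dist + w, visited)
      visited[r2, c2] <- FALSE
    }
  }
  vis <- matrix(FALSE, nr, nc)
  vis[from[1], from[2]] <- TRUE
  rec(from[1], from[2], 0, vis)
  best
}

# independent oracle for MVN orthant probabilities: brute-force nested
# adaptive quadrature of the raw density over the (truncated) orthant box
oracle_orthant <- function(mu, R, x) {
  J <- length(mu)
  if (J == 1) return(stats::pnorm((2 * x - 1) * mu))
  lim <- 8.5
  Rinv <- solve(R); dt <- det(R)
  dens <- function(z) {
    exp(-sum(z * (Rinv %*% z)) / 2) / ((2 * pi)^(J / 2) * sqrt(dt))
  }
  lims <- lapply(seq_len(J), function(j)
    if (x[j] == 1) c(-mu[j], lim) else c(-lim, -mu[j]))
  if (J == 2) {
    f1 <- function(z1v) vapply(z1v, function(z1)
      stats::integrate(function(z2v) vapply(z2v, function(z2)
        dens(c(z1, z2)), 0), lims[[2]][1], lims[[2]][2],
        rel.tol = 1e-10, abs.tol = 1e-13)$value, 0)
    return(stats::integrate(f1, lims[[1]][1], lims[[1]][2],
                            rel.tol = 1e-9, abs.tol = 1e-12)$value)
  }
  f1 <- function(z1v) vapply(z1v, function(z1) {
    f2 <- function(z2v) vapply(z2v, function(z2)
      stats::integrate(function(z3v) vapply(z3v, function(z3)
        dens(c(z1, z2, z3)), 0), lims[[3]][1], lims[[3]][2],
        rel.tol = 1e-9, abs.tol = 1e-12)$value, 0)
    stats::integrate(f2, lims[[2]][1], lims[[2]][2],
                     rel.tol = 1e-8, abs.tol = 1e-11)$value
  }, 0)
  stats::integrate(f1, lims[[1]][1], lims[[1]][2],
                   rel.tol = 1e-8, abs.tol = 1e-11)$value
}

# two-region world for the secondary-expansion tests. Under the null,
# source and target features are independent random binaries. Under
# transfer, one long-lengthscale Gaussian latent field spans both regions
# and both sides threshold it (targets with a small flip rate), emulating
# a structural influence radiating from the staging area.
make_secondary_world <- function(seed, transfer = FALSE, n_src = 30,
                                 n_tgt = 40, J = 4) {
  set.seed(seed)
  xy_s <- cbind(runif(n_src, 0, 3e6), runif(n_src, 0, 3e6))
  xy_t <- cbind(runif(n_tgt, 3e6, 4.5e6), runif(n_tgt, 0, 3e6))
  xy <- rbind(xy_s, xy_t)
  ids <- sprintf("L%03d", seq_len(n_src + n_tgt))
  rownames(xy) <- ids
  pw <- as.matrix(dist(xy)); dimnames(pw) <- list(ids, ids)
  if (transfer) {
    C <- 1.5^2 * exp(-pw^2 / (2 * 1.5e6^2)) + diag(1e-6, nrow(pw))
    L <- t(chol(C))
    lat <- L %*% matrix(rnorm(nrow(pw) * J), ncol = J)
    xall <- matrix(as.integer(lat > 0), nrow(pw), J)
    flip <- matrix(runif(n_tgt * J) < 0.05, n_tgt, J)
    tg <- xall[(n_src + 1):(n_src + n_tgt), , drop = FALSE]
    tg[flip] <- 1L - tg[flip]
    xall[(n_src + 1):(n_src + n_tgt), ] <- tg
  } else {
    xall <- matrix(rbinom((n_src + n_tgt) * J, 1, 0.5), n_src + n_tgt, J)
  }
  traits <- tiny_traits(xall, ids = ids)
  split <- structure(list(source_ids = ids[1:n_src],
                          target_ids = ids[(n_src + 1):(n_src + n_tgt)]),
                     class = "source_target_split")
  list(traits = traits, distances = distance_set(pw), split = split,
       xy = xy)
}

# quick synthetic dataset for model-level tests
quick_dataset <- function(n = 24, J = 6, beta = 0, seed = 1, ...) {
  params <- generative_params(n_lang = n, n_feat = J, beta = beta,
                              seed = seed, ...)
  simulate_dataset(params)
}
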