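test_that("pure-birth trees are deterministic, ultrametric and depth-normalised", {
  phy <- simulate_tree(50, seed = 7)
  tr <- phy$trees[[1]]
  expect_equal(length(tr$tip.label), 50)
  depths <- ape::node.depth.edgelength(tr)[1:50]
  expect_true(all(abs(depths - 1) < 1e-9))
  phy2 <- simulate_tree(50, seed = 7)
  expect_identical(ape::write.tree(phy$trees[[1]]),
                   ape::write.tree(phy2$trees[[1]]))
  expect_equal(length(simulate_tree(1, seed = 1)$trees[[1]]$tip.label), 1)
})

test_that("synthetic geography stays in the corridor and is deterministic", {
  geo <- simulate_geography(102, seed = 3)
  expect_equal(nrow(geo$records), 102)
  spec <- glossarea:::default_path_spec()
  expect_lte(max(geo$distances$d_entry),
             max(geo$path$arc) + spec$buffer + 1e-6)
  expect_true(all(geo$distances$d_entry >= 0))
  geo2 <- simulate_geography(102, seed = 3)
  expect_identical(geo$xy, geo2$xy)
  # on a straight corridor, languages on the path have D equal to their
  # arc length (a winding path admits off-path shortcuts)
  straight <- list(entry = c(0, 1e6), waypoints = rbind(c(0, 0)),
                   buffer = 1e5, step = 1e4)
  geo_s <- simulate_geography(20, path_spec = straight, seed = 2)
  i <- c(5, 40, 80)
  on_path <- geo_s$path$points[i, , drop = FALSE]
  D <- vapply(1:3, function(k) distance_to_entry(geo_s$path, on_path[k, ]), 0)
  expect_equal(D, geo_s$path$arc[i], tolerance = 1e-9)
})

test_that("all-zero parameters give independent Bernoulli(0.5) features", {
  params <- generative_params(n_lang = 400, n_feat = 5, alpha = 0, beta = 0,
                              sigma_phylo = 0, sigma_sp = 0,
                              error_scale = 0, missing_rate = 0, seed = 9)
  ds <- simulate_dataset(params)
  freq <- colMeans(ds$traits == 1)
  expect_true(all(abs(freq - 0.5) < 3 * sqrt(0.25 / 400)))
})

test_that("a large intercept saturates the features", {
  params <- generative_params(n_lang = 60, n_feat = 4, alpha = 10,
                              sigma_phylo = 0, sigma_sp = 0,
                              error_scale = 0, missing_rate = 0, seed = 2)
  ds <- simulate_dataset(params)
  expect_true(all(ds$truth$x_full == 1L))
})

test_that("expansion slopes produce the closed-form probit cline", {
  params <- generative_params(n_lang = 80, n_feat = 40, alpha = 0, beta = 2,
                              sigma_phylo = 0, sigma_sp = 0,
                              error_scale = 0, missing_rate = 0, seed = 5)
  ds <- simulate_dataset(params)
  d <- ds$truth$d_std
  qs <- quantile(d, c(0.25, 0.75))
  north <- d <= qs[1]; south <- d >= qs[2]  # small D = near entry = north
  emp_n <- mean(ds$traits[north, ] == 1)
  emp_s <- mean(ds$traits[south, ] == 1)
  exp_n <- mean(pnorm(2 * d[north]))
  exp_s <- mean(pnorm(2 * d[south]))
  # expectation per cell varies; binomial error bound on the pooled mean
  tol_n <- 4 * sqrt(0.25 / (sum(north) * 40))
  tol_s <- 4 * sqrt(0.25 / (sum(south) * 40))
  expect_lt(abs(emp_n - exp_n), tol_n)
  expect_lt(abs(emp_s - exp_s), tol_s)
  expect_gt(emp_s, emp_n)  # positive slope: prevalence rises southward
})

test_that("datasets are bit-identical given identical parameters and seed", {
  p <- generative_params(n_lang = 25, n_feat = 6, beta = 1, seed = 13)
  d1 <- simulate_dataset(p)
  d2 <- simulate_dataset(p)
  expect_identical(unclass(d1$traits), unclass(d2$traits))
  expect_identical(d1$truth$z, d2$truth$z)
  expect_identical(d1$truth$delta, d2$truth$delta)
})

test_that("observed cells equal the sign of the latent variable before masking", {
  ds <- quick_dataset(n = 30, J = 6, beta = 0.5, seed = 4)
  expect_identical(ds$truth$x_full, matrix(as.integer(ds$truth$z > 0), 30, 6,
                                           dimnames = dimnames(ds$truth$x_full)))
  obs <- !is.na(ds$traits)
  expect_identical(unclass(ds$traits)[obs], ds$truth$x_full[obs])
})

test_that("masking never removes the last observation of a language or feature", {
  for (s in 1:5) {
    params <- generative_params(n_lang = 12, n_feat = 4, missing_rate = 0.45,
                                seed = s)
    ds <- simulate_dataset(params)
    expect_true(all(rowSums(!is.na(ds$traits)) >= 1))
    expect_true(all(colSums(!is.na(ds$traits)) >= 1))
  }
})

test_that("observed frequencies converge to the probit of the latent mean", {
  # fixed geography, all random effects off: the latent mean is a known
  # constant per cell and replicate datasets only redraw the residual
  geo <- simulate_geography(3, seed = 21)
  phy <- simulate_tree(3, seed = 21)
  base <- generative_params(n_lang = 3, n_feat = 2, alpha = c(0.4, -0.8),
                            beta = c(1, 0), sigma_phylo = 0, sigma_sp = 0,
                            error_scale = 0, missing_rate = 0, seed = 1)
  D <- geo$distances$d_entry
  d_std <- (D - mean(D)) / sd(D)
  expected <- pnorm(matrix(base$alpha, 3, 2, byrow = TRUE) +
                      outer(d_std, base$beta))
  reps <- 1e4
  acc <- matrix(0, 3, 2)
  for (r in seq_len(reps)) {
    base$seed <- r
    acc <- acc + (simulate_dataset(base, geo, phy)$traits == 1)
  }
  expect_true(all(abs(acc / reps - expected) < 4 * sqrt(0.25 / reps) + 0.005))
})

test_that("synthetic datasets round-trip through the io readers", {
  ds <- quick_dataset(n = 15, J = 4, seed = 8)
  dir <- tempfile()
  write_synthetic_dataset(ds, dir)
  tm <- read_trait_matrix(file.path(dir, "traits.csv"))
  expect_identical(unclass(tm), unclass(ds$traits))
  phy <- read_phylogeny(file.path(dir, "trees.nwk"))
  expect_equal(sum(phy$trees[[1]]$edge.length),
               sum(ds$phylogeny$trees[[1]]$edge.length), tolerance = 1e-6)
  truth <- read.csv(file.path(dir, "truth.csv"))
  expect_equal(truth$delta, unname(ds$truth$delta))
})
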