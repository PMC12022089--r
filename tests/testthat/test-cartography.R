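make_field <- function(values, pts = NULL) {
  if (is.null(pts)) pts <- cbind(seq_len(nrow(values)), 0)
  structure(list(points = pts, values = values, n_draws = 1),
            class = "marginal_field")
}

test_that("a null posterior yields a constant 0.5 field on the grid", {
  ds <- quick_dataset(n = 12, J = 3, seed = 7)
  m <- assemble_model(model_spec(model = 2), ds$traits, ds$distances,
                      ds$phylogeny)
  post <- fit(m, chains = 1, iterations = 100, seed = 2)
  post$draws[, ] <- 0
  post$draws[, "lengthscale"] <- post$pre$ell$grid[3]
  post$u[, , ] <- 0; post$p[, , ] <- 0
  gs <- list(xlim = range(ds$xy[, 1]), ylim = range(ds$xy[, 2]),
             step = diff(range(ds$xy[, 1])) / 4, xy_lang = ds$xy,
             path = ds$path)
  field <- grid_marginal_effects(post, gs, n_draws = 40)
  expect_true(all(abs(field$values - 0.5) < 1e-12))
  expect_true(all(field$values >= 0 & field$values <= 1))
})

test_that("a grid point at a sampled language matches posterior_predict there", {
  ds <- quick_dataset(n = 10, J = 3, seed = 8)
  m <- assemble_model(model_spec(model = 2), ds$traits, ds$distances,
                      ds$phylogeny)
  post <- fit(m, chains = 1, iterations = 120, seed = 3)
  tg <- list(cross_dist = ds$distances$pairwise[2, , drop = FALSE],
             d_entry = ds$distances$d_entry[2])
  direct <- posterior_predict(post, tg, n_draws = 50)
  gs <- list(xlim = ds$xy[2, 1] + c(0, 1), ylim = ds$xy[2, 2] + c(0, 1),
             step = 10, xy_lang = ds$xy, path = ds$path)
  field <- grid_marginal_effects(post, gs, n_draws = 50)
  expect_equal(unname(field$values[1, ]), unname(direct[1, ]),
               tolerance = 1e-6)
})

test_that("PCA-RGB recovers three orthogonal spatial patterns", {
  n <- 60
  t1 <- sin(seq(0, 2 * pi, length.out = n))
  t2 <- cos(seq(0, 4 * pi, length.out = n))
  t3 <- seq(-1, 1, length.out = n)
  basis <- qr.Q(qr(cbind(t1, t2, t3)))
  v <- 0.5 + 0.3 * basis %*% diag(c(3, 2, 1))
  field <- make_field(v)
  out <- pca_rgb(field)
  expect_equal(dim(out$rgb), c(n, 3L))
  expect_true(all(out$rgb >= 0 & out$rgb <= 1))
  # each channel aligns with one injected pattern up to sign
  cors <- abs(cor(out$scores[, 1:3], basis))
  expect_true(all(apply(cors, 1, max) > 0.99))
  expect_equal(sum(out$explained_variance), 1, tolerance = 1e-12)
  # component scores are mutually orthogonal
  g <- crossprod(out$scores[, 1:3])
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
})

test_that("PCA-RGB rejects degenerate fields and ignores feature order", {
  expect_error(pca_rgb(make_field(matrix(0.5, 10, 4))),
               "fewer than 3 non-constant")
  set.seed(5)
  v <- matrix(runif(80), 20, 4)
  a <- pca_rgb(make_field(v))
  b <- pca_rgb(make_field(v[, c(3, 1, 4, 2)]))
  expect_equal(abs(a$scores[, 1:3]), abs(b$scores[, 1:3]), tolerance = 1e-8)
})

test_that("clustering separates well-separated blocks and nests hierarchically", {
  set.seed(6)
  v <- rbind(matrix(rnorm(25 * 4, 0, 0.01), 25),
             matrix(rnorm(25 * 4, 1, 0.01), 25))
  field <- make_field(v)
  lab <- cluster_field(field, k_min = 2, k_max = 6)
  l2 <- lab[, "k2"]
  expect_equal(length(unique(l2[1:25])), 1)
  expect_equal(length(unique(l2[26:50])), 1)
  expect_false(l2[1] == l2[26])
  # oracle: the best 2-partition by within-cluster variance is the blocks
  # (verified by construction: separation 1 vs noise 0.01)
  for (k in 2:5) {
    cross <- table(lab[, k - 1], lab[, k])
    expect_true(all(colSums(cross > 0) == 1))  # each finer cluster in one coarser
  }
  labN <- cluster_field(make_field(v[1:8, ]), k_min = 8, k_max = 8)
  expect_equal(sort(unique(labN[, 1])), 1:8)
  expect_error(cluster_field(field, k_min = 5, k_max = 2), "k_max")
})

test_that("cluster labels are permutation-invariant up to relabelling", {
  set.seed(9)
  v <- matrix(rnorm(40 * 3), 40)
  perm <- sample(40)
  a <- cluster_field(make_field(v), 2, 4)
  b <- cluster_field(make_field(v[perm, ]), 2, 4)
  for (k in c("k2", "k3", "k4")) {
    expect_equal(length(unique(paste(a[perm, k], b[, k]))),
                 length(unique(b[, k])))
  }
})

test_that("coefficient summaries flag intervals excluding zero", {
  ds <- quick_dataset(n = 10, J = 2, seed = 3)
  m <- assemble_model(model_spec(model = 2), ds$traits, ds$distances,
                      ds$phylogeny)
  post <- fit(m, chains = 1, iterations = 60, seed = 2)
  post$draws[, "beta[1]"] <- 0.3                       # point mass
  post$draws[, "beta[2]"] <- rep(c(-1, 1), length.out = nrow(post$draws))
  cs <- coefficient_summary(post)
  expect_true(cs$zero_overlap[1])
  expect_equal(cs$lower[1], 0.3)
  expect_false(cs$zero_overlap[2])
  expect_equal(cs$p_positive[1], 1)
  m1 <- assemble_model(model_spec(model = 1), ds$traits, ds$distances,
                       ds$phylogeny)
  p1 <- fit(m1, chains = 1, iterations = 60, seed = 2)
  expect_error(coefficient_summary(p1), "Model 1")
})

test_that("the zero-overlap flag is monotone in the interval level", {
  set.seed(4)
  ds <- quick_dataset(n = 10, J = 2, seed = 3)
  m <- assemble_model(model_spec(model = 2), ds$traits, ds$distances,
                      ds$phylogeny)
  post <- fit(m, chains = 1, iterations = 100, seed = 2)
  post$draws[, "beta[1]"] <- rnorm(nrow(post$draws), 0.6, 0.4)
  for (lv in c(0.5, 0.8, 0.95)) {
    wide <- coefficient_summary(post, level = 0.99)$zero_overlap[1]
    narrow <- coefficient_summary(post, level = lv)$zero_overlap[1]
    expect_true(narrow >= wide)  # widening can only clear the flag
  }
})

test_that("posterior overlap matches closed forms and is symmetric and bounded", {
  set.seed(8)
  a <- rnorm(1e5)
  expect_equal(posterior_overlap(a, a), 1, tolerance = 0.02)
  b <- rnorm(1e5, 1)
  ov <- posterior_overlap(a, b)
  expect_equal(ov, 2 * pnorm(-0.5), tolerance = 0.02)
  expect_equal(ov, posterior_overlap(b, a), tolerance = 1e-12)
  far <- rnorm(1e4, 100)
  expect_lte(posterior_overlap(a, far), 0.001)
  expect_equal(posterior_overlap(rep(1, 5), rep(1, 5)), 1)
  expect_equal(posterior_overlap(rep(1, 5), rep(2, 5)), 0)
})

test_that("the stability model recovers group differences on the effect scale", {
  tab0 <- data.frame(effect = rep(c(0.1, 0.1), each = 25),
                     stable = rep(c(TRUE, FALSE), each = 25))
  out0 <- stability_effect_model(tab0, seed = 2)
  expect_gt(out0$interval[2], -1e-6)
  expect_lt(out0$interval[1], 1e-6)
  # group B exactly twice group A: difference approaches mean(A)
  set.seed(3)
  aa <- exp(rnorm(50, log(0.1), 0.001))
  tab2 <- data.frame(effect = c(aa, 2 * aa),
                     stable = rep(c(FALSE, TRUE), each = 50))
  out2 <- stability_effect_model(tab2, seed = 2)
  expect_equal(out2$difference, 0.1, tolerance = 0.005)
  # simulation oracle: known log-means
  set.seed(4)
  tab3 <- data.frame(effect = c(exp(rnorm(200, -2, 0.3)),
                                exp(rnorm(200, -1.5, 0.3))),
                     stable = rep(c(FALSE, TRUE), each = 200))
  out3 <- stability_effect_model(tab3, seed = 2)
  want <- exp(-1.5 + 0.09 / 2) - exp(-2 + 0.09 / 2)
  expect_lt(abs(out3$difference - want), 0.015)
  expect_error(stability_effect_model(
    data.frame(effect = 1:3, stable = c(TRUE, TRUE, TRUE))), "empty")
})
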