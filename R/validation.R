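#' Cross-validation and the null-coefficient simulation
#'
#' Two tenfold cross-validation schemes: CV-1 leaves whole languages out;
#' CV-2 masks 10% of observed cells as missing while guaranteeing that
#' every language keeps at least one observed cell in every training set.
#' Predictions are posterior predictive probabilities thresholded at 0.5
#' and scored by balanced accuracy per feature.
#'
#' @name glossarea-validation
NULL

#' Build a cross-validation fold plan
#'
#' @param traits a `trait_matrix`.
#' @param scheme `"cv1"` (partition languages, fold sizes differing by at
#'   most one) or `"cv2"` (partition observed cells; a language's cells
#'   are dealt across distinct folds, and a language with a single
#'   observed cell is never held out).
#' @param k number of folds, default 10.
#' @param seed integer seed.
#' @return object of class `fold_plan`: for CV-1 a language-to-fold map;
#'   for CV-2 a languages-by-features fold matrix (`NA` = never held out).
#' @export
make_folds <- function(traits, scheme = c("cv1", "cv2"), k = 10, seed = 1) {
  scheme <- match.arg(scheme)
  n <- nrow(traits)
  set.seed(derive_seed(seed, paste0("folds-", scheme)))
  if (scheme == "cv1") {
    if (n < k) stop("fewer languages than folds")
    asg <- stats::setNames(rep_len(seq_len(k), n)[sample.int(n)],
                           rownames(traits))
    plan <- list(scheme = "cv1", k = k, languages = asg, seed = seed)
  } else {
    obs <- which(!is.na(unclass(traits)), arr.ind = TRUE)
    if (nrow(obs) < k) stop("fewer observed cells than folds")
    fm <- matrix(NA_integer_, n, ncol(traits),
                 dimnames = dimnames(traits))
    offset <- 0L
    for (i in seq_len(n)) {
      cells <- which(!is.na(traits[i, ]))
      m <- length(cells)
      if (m < 2) next  # single observed cell: never held out
      cells <- cells[sample.int(m)]
      fm[i, cells] <- ((offset + seq_len(m) - 1L) %% k) + 1L
      offset <- offset + m
    }
    plan <- list(scheme = "cv2", k = k, cells = fm, seed = seed)
  }
  structure(plan, class = "fold_plan")
}

#' Balanced accuracy
#'
#' `(sensitivity + specificity) / 2`. When the truth contains a single
#' class the accuracy on the present class is returned with a logged
#' caveat.
#'
#' @param truth,predicted equal-length binary vectors.
#' @return value in `[0, 1]`.
#' @export
balanced_accuracy <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  ok <- !is.na(truth) & !is.na(predicted)
  truth <- truth[ok]; predicted <- predicted[ok]
  if (!length(truth)) return(NA_real_)
  if (all(truth == truth[1])) {
    ga_log("validation", "info",
           "single-class truth: returning accuracy on the present class")
    return(mean(predicted == truth))
  }
  sens <- mean(predicted[truth == 1] == 1)
  spec <- mean(predicted[truth == 0] == 0)
  (sens + spec) / 2
}

#' Cross-validate one or more model specifications
#'
#' For each fold, refits each model on the training portion (CV-1: the
#' held-out languages' rows removed; CV-2: the held-out cells re-coded as
#' missing), predicts the held-out observed cells by posterior predictive
#' probability thresholded at 0.5, and scores balanced accuracy per
#' feature. CV-1 predictions at held-out languages use the
#' Gaussian-process conditional mean for the spatial term; CV-2
#' predictions use the model's conditional predictive for a missing cell,
#' which draws on the language's other observed features through the
#' residual correlations and shared per-language terms.
#'
#' @param traits a `trait_matrix`.
#' @param distances a `distance_set` over all languages.
#' @param phylogeny a `phylogeny`.
#' @param specs named list of [model_spec()]s.
#' @param plan a [make_folds()] plan.
#' @param chains,iterations,seed sampler settings for the refits (short
#'   chains are customary here; settings land in the result).
#' @param n_draws posterior draws per prediction.
#' @return object of class `cv_result`: `table` (feature, fold, model,
#'   balanced_accuracy), `model_means`, `feature_means`, and `settings`.
#' @export
crossvalidate <- function(traits, distances, phylogeny, specs, plan,
                          chains = 1, iterations = 600, seed = 1,
                          n_draws = 200) {
  stopifnot(inherits(plan, "fold_plan"))
  if (is.null(names(specs))) names(specs) <- paste0("model", seq_along(specs))
  ids <- rownames(traits)
  rows <- list()
  for (f in seq_len(plan$k)) {
    if (plan$scheme == "cv1") {
      hold <- names(plan$languages)[plan$languages == f]
      train <- setdiff(ids, hold)
      tr_traits <- new_trait_matrix(unclass(traits)[train, , drop = FALSE])
      tr_dist <- distance_set(distances$pairwise[train, train],
                              d_entry = distances$d_entry[train])
      targets <- list(cross_dist = distances$pairwise[hold, train, drop = FALSE],
                      d_entry = distances$d_entry[hold])
      truth_m <- unclass(traits)[hold, , drop = FALSE]
    } else {
      held <- !is.na(plan$cells) & plan$cells == f
      if (!any(held)) stop("fold with no held-out observed cells")
      xm <- unclass(traits); xm[held] <- NA_integer_
      tr_traits <- new_trait_matrix(xm)
      tr_dist <- distances
      targets <- NULL
      truth_m <- unclass(traits); truth_m[!held] <- NA_integer_
    }
    for (s in names(specs)) {
      m <- assemble_model(specs[[s]], tr_traits, tr_dist, phylogeny)
      post <- fit(m, chains = chains, iterations = iterations,
                  seed = derive_seed(seed, paste0("cv", f, s)))
      if (plan$scheme == "cv1") {
        prob <- posterior_predict(post, targets, n_draws = n_draws)
      } else {
        prob <- post$pmiss
      }
      pred <- ifelse(prob >= 0.5, 1L, 0L)
      for (j in seq_len(ncol(traits))) {
        tj <- truth_m[, j]
        if (all(is.na(tj))) next
        ba <- suppressMessages(balanced_accuracy(tj, pred[, j]))
        rows[[length(rows) + 1L]] <- data.frame(
          feature = colnames(traits)[j], fold = f, model = s,
          balanced_accuracy = ba)
      }
    }
  }
  tab <- do.call(rbind, rows)
  fm <- stats::aggregate(balanced_accuracy ~ feature + model, tab, mean)
  mm <- stats::aggregate(balanced_accuracy ~ model, fm, mean)
  structure(list(table = tab, feature_means = fm, model_means = mm,
                 settings = list(scheme = plan$scheme, k = plan$k,
                                 chains = chains, iterations = iterations,
                                 seed = seed)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %s, %d folds>\n", x$settings$scheme,
              x$settings$k))
  print(x$model_means)
  invisible(x)
}

#' Export a cross-validation result
#'
#' Writes the per-feature/fold/model table and, when two models are
#' present, a per-feature difference table (second minus first).
#'
#' @param cv a `cv_result`.
#' @param path output CSV.
#' @param diff_models optional character pair `c(base, alt)` for the
#'   per-feature difference table written beside `path`.
#' @export
write_cv_result <- function(cv, path, diff_models = NULL) {
  utils::write.csv(cv$table, path, row.names = FALSE)
  if (!is.null(diff_models)) {
    fm <- cv$feature_means
    a <- fm[fm$model == diff_models[1], ]
    b <- fm[fm$model == diff_models[2], ]
    m <- merge(a, b, by = "feature", suffixes = c("_base", "_alt"))
    m$difference <- m$balanced_accuracy_alt - m$balanced_accuracy_base
    utils::write.csv(m, sub("\\.csv$", "_diff.csv", path), row.names = FALSE)
  }
  invisible(path)
}

#' Null-coefficient simulation
#'
#' For each replicate, draws independent Bernoulli(0.5) outcomes over the
#' observations and fits a univariate logistic regression on the raw
#' (metre-scale) distances, recording the slope. The distribution of
#' slopes quantifies how large a distance effect arises by chance alone.
#' A replicate with separation falls back to a small ridge penalty on the
#' slope (rarely triggered at these sample sizes).
#'
#' @param n_reps number of replicates, default 10000.
#' @param distances per-observation distance vector (m).
#' @param seed integer seed.
#' @param n_obs number of observations; defaults to `length(distances)`.
#' @return list: `slopes` (length `n_reps`), `max_abs_slope`, and the
#'   analytic null standard error `1 / (0.5 * sd(distances) * sqrt(n))`.
#' @export
null_simulation <- function(n_reps = 10000, distances, seed = 1,
                            n_obs = length(distances)) {
  stopifnot(length(distances) == n_obs)
  if (stats::sd(distances) == 0) stop("degenerate design: distances all equal")
  set.seed(derive_seed(seed, "nullsim"))
  X <- cbind(1, distances)
  slopes <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    y <- stats::rbinom(n_obs, 1, 0.5)
    co <- tryCatch({
      f <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
      if (!f$converged) stop("no convergence")
      f$coefficients
    }, error = function(e) ridge_logit(X, y))
    slopes[r] <- co[2]
  }
  list(slopes = slopes, max_abs_slope = max(abs(slopes)),
       null_se = 1 / (0.5 * stats::sd(distances) * sqrt(n_obs)))
}

# IRLS with a small ridge penalty, used only when the plain fit separates.
ridge_logit <- function(X, y, lambda = 1e-4, iters = 50) {
  b <- rep(0, ncol(X))
  sc <- c(1, stats::sd(X[, 2]))
  Xs <- sweep(X, 2, sc, "/")
  for (i in seq_len(iters)) {
    eta <- drop(Xs %*% b)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-10)
    A <- crossprod(Xs, w * Xs) + diag(lambda, ncol(X))
    b <- drop(solve(A, crossprod(Xs, w * eta + (y - p))))
  }
  b / sc
}
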