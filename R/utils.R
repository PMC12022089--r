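#' @keywords internal
"_PACKAGE"

# Mean Earth radius (authalic), metres. All great-circle distances use it.
EARTH_RADIUS_M <- 6371008.8

#' Log a structured message
#'
#' Lightweight logger used across the package: every line carries the
#' emitting module, a level and a message. Controlled by
#' `options(glossarea.verbose = TRUE/FALSE)`; warnings always surface.
#'
#' @param module character scalar, e.g. `"geodesy"`.
#' @param level one of `"info"`, `"warn"`, `"error"`.
#' @param msg message text.
#' @keywords internal
ga_log <- function(module, level = "info", msg) {
  line <- sprintf("[%s] %s: %s", module, toupper(level), msg)
  if (identical(level, "warn")) {
    warning(line, call. = FALSE)
  } else if (identical(level, "error")) {
    stop(line, call. = FALSE)
  } else if (isTRUE(getOption("glossarea.verbose", FALSE))) {
    message(line)
  }
  invisible(line)
}

#' Round half-up
#'
#' `round()` in R rounds half to even; reported percentages follow the
#' half-up convention instead (12.25 -> 12.3 at one decimal).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Read a nested key-value configuration file
#'
#' YAML configuration controlling module parameters. Returns a named list;
#' missing file is an error.
#'
#' @param path path to a YAML file.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

# Derive a reproducible sub-seed from a base seed and a stage label,
# staying far below .Machine$integer.max.
derive_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1009 + offs) %% 2147480000L)
}

# Draw from MVN(mu, V) given a precomputed eigen(V) (values floored at 0).
rmvn_eigen <- function(n = 1, mu, eig) {
  lam <- pmax(eig$values, 0)
  d <- length(lam)
  z <- matrix(stats::rnorm(n * d), d, n) * sqrt(lam)
  drop(mu + eig$vectors %*% z)
}

# Univariate slice sampler (Neal 2003, stepping out + shrinkage).
slice_sample1 <- function(x0, logf, w = 1, lower = -Inf, upper = Inf,
                          max_steps = 50) {
  fx0 <- logf(x0)
  if (!is.finite(fx0)) stop("slice_sample1: non-finite density at x0")
  logy <- fx0 - stats::rexp(1)
  u <- stats::runif(1) * w
  L <- max(x0 - u, lower)
  R <- min(L + w, upper)
  k <- max_steps
  while (k > 0 && L > lower && logf(L) > logy) { L <- max(L - w, lower); k <- k - 1 }
  k <- max_steps
  while (k > 0 && R < upper && logf(R) > logy) { R <- min(R + w, upper); k <- k - 1 }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) >= logy) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}
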