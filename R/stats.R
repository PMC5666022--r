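#' Fluctuation function and scaling exponent
#'
#' Quantifies how the fluctuations of an interval series grow with scale.
#' The series is integrated after mean subtraction,
#' `Y[k] = sum_{i<=k} (dt[i] - mean(dt))`, and the fluctuation function is
#' the root-mean-square profile displacement over windows of size `n`,
#' `F(n) = sqrt(mean_k (Y[k+n] - Y[k])^2)`.  The scaling exponent `alpha`
#' is the least-squares slope of `log F(n)` against `log n`.  Uncorrelated
#' intervals give `alpha` near 0.5 (the profile is a random walk); a flat
#' `F(n)` (`alpha` near 0) indicates strongly anti-persistent intervals
#' whose cumulative sum stays locked to its trend.
#'
#' @param dt Numeric interval series.
#' @param scales Integer window sizes; defaults to up to 20 log-spaced
#'   values in `fit_range`.
#' @param fit_range `c(n_min, n_max)` range used both for the default
#'   scales and for the log-log fit; defaults to `c(2, floor(length(dt)/4))`.
#' @return An object of class `fluctuation_result`: `scales`, `f_values`,
#'   `alpha` (NA with a warning flag for a constant series), `fit_range`.
#' @examples
#' set.seed(1)
#' fr <- fluctuation_function(rexp(2000))
#' fr$alpha  # near 0.5 for i.i.d. intervals
#' @export
fluctuation_function <- function(dt, scales = NULL, fit_range = NULL) {
  dt <- as.numeric(dt)
  n_len <- length(dt)
  if (is.null(fit_range)) fit_range <- c(2L, max(2L, floor(n_len / 4)))
  if (n_len < max(fit_range) + 1)
    stop("series too short for the requested scales")
  if (is.null(scales)) {
    scales <- unique(round(exp(seq(log(fit_range[1]), log(fit_range[2]),
                                   length.out = 20))))
  }
  scales <- sort(unique(as.integer(scales)))
  if (any(scales < 1) || max(scales) >= n_len)
    stop("scales must lie in [1, length(dt) - 1]")
  y <- cumsum(dt - mean(dt))
  f <- vapply(scales, function(n) {
    d <- y[(1 + n):n_len] - y[1:(n_len - n)]
    # mean subtraction pins the profile to zero at the series end (a bridge),
    # shrinking displacements by (1 - n/N); undo that finite-sample bias
    sqrt(mean(d^2) / (1 - n / n_len))
  }, numeric(1))
  in_fit <- scales >= fit_range[1] & scales <= fit_range[2] & f > 0
  alpha <- NA_real_
  degenerate <- all(f == 0)
  if (!degenerate && sum(in_fit) >= 3)
    alpha <- unname(coef(lm(log(f[in_fit]) ~ log(scales[in_fit])))[2])
  out <- list(scales = scales, f_values = f, alpha = alpha,
              fit_range = fit_range, degenerate = degenerate)
  class(out) <- "fluctuation_result"
  out
}

#' @export
print.fluctuation_result <- function(x, ...) {
  cat(sprintf("<fluctuation_result> %d scales in [%d, %d]; alpha = %s\n",
              length(x$scales), min(x$scales), max(x$scales),
              if (is.na(x$alpha)) "NA (degenerate)" else sprintf("%.3f", x$alpha)))
  invisible(x)
}

new_fit_result <- function(model, parameter, x_min, log_likelihood, n_obs) {
  out <- list(model = model, parameter = parameter, x_min = x_min,
              log_likelihood = log_likelihood, n_obs = n_obs,
              aic = 2 * 1 - 2 * log_likelihood)
  class(out) <- "fit_result"
  out
}

#' @export
print.fit_result <- function(x, ...) {
  lab <- if (x$model == "power_law") "mu" else "lambda"
  cat(sprintf("<fit_result> %s: %s = %.4f (x_min = %g, n = %d, logLik = %.2f, AIC = %.2f)\n",
              x$model, lab, x$parameter, x$x_min, x$n_obs, x$log_likelihood,
              x$aic))
  invisible(x)
}

#' Maximum-likelihood power-law (Pareto) fit
#'
#' Fits the continuous Pareto density
#' `p(x) = ((mu - 1) / x_min) * (x / x_min)^(-mu)` on `x >= x_min` by its
#' closed-form MLE `mu = 1 + n / sum(log(x / x_min))`.
#'
#' @param x Magnitudes, all `>= x_min`; zeros must be excluded beforehand.
#' @param x_min Lower support bound (> 0); defaults to 1, the smallest
#'   nonzero integer increment magnitude.
#' @return A `fit_result` with `parameter` = mu, the log-likelihood and AIC.
#' @examples
#' fit_power_law(c(2, 3, 5, 9, 17, 2, 4))
#' @export
fit_power_law <- function(x, x_min = 1) {
  x <- as.numeric(x)
  if (length(x) < 5) stop("refusing to fit a power law to fewer than 5 observations")
  if (x_min <= 0) stop("x_min must be > 0")
  if (any(x < x_min)) stop("all observations must be >= x_min")
  slog <- sum(log(x / x_min))
  if (slog == 0)
    stop("all observations equal x_min; power-law exponent undefined")
  n <- length(x)
  mu <- 1 + n / slog
  ll <- n * log((mu - 1) / x_min) - mu * slog
  new_fit_result("power_law", mu, x_min, ll, n)
}

#' Maximum-likelihood shifted-exponential fit
#'
#' Fits `p(x) = lambda * exp(-lambda * (x - x_min))` on `x >= x_min` by the
#' closed-form MLE `lambda = 1 / mean(x - x_min)`.
#'
#' @inheritParams fit_power_law
#' @return A `fit_result` with `parameter` = lambda.
#' @examples
#' fit_exponential(c(1, 2, 2, 5, 9, 1, 8))
#' @export
fit_exponential <- function(x, x_min = 1) {
  x <- as.numeric(x)
  if (length(x) < 5) stop("refusing to fit fewer than 5 observations")
  if (any(x < x_min)) stop("all observations must be >= x_min")
  m <- mean(x - x_min)
  if (m == 0)
    stop("all observations equal x_min; exponential rate undefined")
  n <- length(x)
  lambda <- 1 / m
  ll <- n * log(lambda) - lambda * sum(x - x_min)
  new_fit_result("exponential", lambda, x_min, ll, n)
}

#' Akaike weights for a set of fitted models
#'
#' `w_i = exp(-(AIC_i - min AIC)/2) / sum_j exp(-(AIC_j - min AIC)/2)`:
#' the normalised relative likelihood of each candidate model.  All fits
#' must be on the same data.
#'
#' @param fits List of `fit_result` objects (>= 2) fitted to identical data.
#' @return Named numeric vector of weights summing to 1 (names taken from
#'   each fit's `model`).
#' @examples
#' x <- c(1, 1, 2, 3, 8, 1, 2, 1, 5, 1)
#' akaike_weights(list(fit_power_law(x), fit_exponential(x)))
#' @export
akaike_weights <- function(fits) {
  if (length(fits) < 2) stop("need at least two fits to compare")
  n_obs <- vapply(fits, function(f) f$n_obs, numeric(1))
  if (length(unique(n_obs)) != 1)
    stop("fits were made on different numbers of observations")
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  d <- aic - min(aic)
  w <- exp(-d / 2) / sum(exp(-d / 2))
  names(w) <- vapply(fits, function(f) f$model, character(1))
  w
}

#' Likelihood-ratio G statistic
#'
#' `G = 2 sum O ln(O/E)` over bins; zero-observation bins contribute 0.
#' `G = 0` exactly when observed equals expected in every bin.
#'
#' @param observed,expected Aligned bin counts (expected all > 0).
#' @return The G statistic.
#' @examples
#' g_statistic(c(50, 30, 20), c(40, 40, 20))  # about 5.05
#' @export
g_statistic <- function(observed, expected) {
  stopifnot(length(observed) == length(expected), all(expected > 0))
  pos <- observed > 0
  2 * sum(observed[pos] * log(observed[pos] / expected[pos]))
}

#' Log-binned G-test goodness of fit
#'
#' Likelihood-ratio goodness-of-fit test `G = 2 sum O ln(O/E)` of a fitted
#' power-law or exponential model, with observations grouped into
#' logarithmically spaced bins over `[x_min, max(x)]` (edge ratio
#' `bin_ratio`), expected counts taken from the fitted distribution
#' conditioned on that range, and bins with expected count below 1 merged
#' into their left neighbour.  Degrees of freedom are
#' `n_bins - 1 - n_fitted_params` (one fitted parameter here); the p-value
#' is the upper chi-square tail.
#'
#' @param x Magnitudes used in the fit.
#' @param fit A `fit_result` from [fit_power_law()] or [fit_exponential()].
#' @param bin_ratio Ratio between consecutive log-bin edges (default 2).
#' @return List with `g_statistic`, `df`, `p_value` and `significant`
#'   (`p < 0.05`).
#' @examples
#' set.seed(1)
#' x <- round(1 / runif(200)^1.4)
#' x <- x[x >= 1]
#' g_test_gof(x, fit_power_law(x))
#' @export
g_test_gof <- function(x, fit, bin_ratio = 2) {
  x <- as.numeric(x)
  stopifnot(inherits(fit, "fit_result"), bin_ratio > 1)
  x_min <- fit$x_min
  xmax <- max(x)
  if (xmax <= x_min) stop("degenerate data: no spread above x_min")
  n_edge <- max(1L, ceiling(log(xmax / x_min) / log(bin_ratio)))
  edges <- x_min * bin_ratio^(0:n_edge)
  edges[length(edges)] <- xmax * (1 + 1e-9) # close the last bin at the maximum
  obs <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                  nbins = length(edges) - 1)
  cdf <- switch(fit$model,
    power_law = function(t) 1 - (t / x_min)^(1 - fit$parameter),
    exponential = function(t) 1 - exp(-fit$parameter * (t - x_min)),
    stop("unknown model"))
  pr <- diff(cdf(edges))
  pr <- pr / (cdf(edges[length(edges)]) - cdf(edges[1]))
  expd <- length(x) * pr
  # merge sparse bins leftward, tail first
  j <- length(expd)
  while (j >= 2) {
    if (expd[j] < 1) {
      expd[j - 1] <- expd[j - 1] + expd[j]
      obs[j - 1] <- obs[j - 1] + obs[j]
      expd <- expd[-j]; obs <- obs[-j]
    }
    j <- j - 1
  }
  if (length(expd) >= 2 && expd[1] < 1) {
    expd[2] <- expd[2] + expd[1]; obs[2] <- obs[2] + obs[1]
    expd <- expd[-1]; obs <- obs[-1]
  }
  if (length(expd) < 3)
    stop("fewer than 3 bins after merging; G-test not meaningful")
  g <- g_statistic(obs, expd)
  df <- length(obs) - 1L - 1L
  p <- pchisq(g, df, lower.tail = FALSE)
  list(g_statistic = g, df = df, p_value = p, significant = p < 0.05)
}

#' Power-law versus exponential comparison of increment magnitudes
#'
#' The full model-selection protocol for a set of interdrop increments:
#' drops zeros, takes magnitudes `|I(n)|`, fits the power-law and
#' shifted-exponential candidates by maximum likelihood, computes Akaike
#' weights, and runs the log-binned G-test on the AIC-preferred model.
#'
#' @param increments Vector of interdrop increments `I(n)` (signed; zeros
#'   are discarded) or an `interval_series`.
#' @param x_min Lower support bound for both fits (default 1).
#' @return An object of class `model_comparison`: both `fit_result`s,
#'   `akaike_weights`, the preferred model name, and the G-test fields
#'   (`g_statistic`, `df`, `p_value`, `significant`).
#' @examples
#' set.seed(2)
#' inc <- diff(rexp(300, 0.1))
#' compare_increment_models(inc)
#' @export
compare_increment_models <- function(increments, x_min = 1) {
  if (inherits(increments, "interval_series"))
    increments <- increments$increments$i
  mag <- abs(as.numeric(increments))
  mag <- mag[mag > 0]
  pl <- fit_power_law(mag, x_min)
  ex <- fit_exponential(mag, x_min)
  w <- akaike_weights(list(pl, ex))
  preferred <- if (w["power_law"] >= w["exponential"]) pl else ex
  gof <- g_test_gof(mag, preferred)
  out <- list(power_law = pl, exponential = ex, akaike_weights = w,
              preferred = preferred$model, n_obs = pl$n_obs,
              g_statistic = gof$g_statistic, df = gof$df,
              p_value = gof$p_value, significant = gof$significant)
  class(out) <- "model_comparison"
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> n = %d nonzero |I|\n", x$n_obs))
  cat(sprintf("  power law  : mu = %.3f (AIC %.2f)\n",
              x$power_law$parameter, x$power_law$aic))
  cat(sprintf("  exponential: lambda = %.3f (AIC %.2f)\n",
              x$exponential$parameter, x$exponential$aic))
  cat(sprintf("  Akaike weight (power law) = %.3f -> %s preferred\n",
              x$akaike_weights["power_law"], x$preferred))
  cat(sprintf("  GOF: G = %.2f, df = %d, p = %.3f%s\n", x$g_statistic, x$df,
              x$p_value, if (!x$significant) ", NS" else ""))
  invisible(x)
}
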