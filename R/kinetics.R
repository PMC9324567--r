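# Population growth statistics: exponential doubling time and growth
# rate, cross-species normalisation, and sigmoidal (Gompertz/logistic)
# curve fits in the Zwietering reparameterisation, where the fitted
# response is y(t) = ln(B_t / B_0) and the parameters are the asymptote
# A, the maximum specific growth rate mu and the lag time lambda.

#' Doubling (generation) time
#'
#' `G = t * log(2) / (log(Bn) - log(B0))`, the elapsed time divided by
#' the number of generations; reduces to `t / log2(Bn)` when `B0 = 1`.
#'
#' @param t Elapsed time in minutes (> 0).
#' @param B0 Initial population count (>= 1).
#' @param Bn Final population count (> B0 for a defined value).
#' @return Doubling time in minutes; `NA` (undefined) when `Bn <= B0`.
#' @examples
#' doubling_time(100, 1, 74)   # 16.10
#' doubling_time(150, 1, 76)   # 24.01
#' @export
doubling_time <- function(t, B0, Bn) {
  stopifnot(t > 0, B0 >= 1)
  ifelse(Bn > B0, t * log(2) / (log(Bn) - log(B0)), NA_real_)
}

#' Exponential growth rate
#'
#' `K = log2(Bn) / t`, in doublings per minute, under the `B0 = 1`
#' convention; satisfies `doubling_time(t, 1, Bn) * growth_rate(t, Bn)
#' = 1` exactly.
#'
#' @param t Elapsed time in minutes (> 0).
#' @param Bn Final population count (>= 1).
#' @return Growth rate per minute.
#' @examples
#' growth_rate(100, 74)
#' @export
growth_rate <- function(t, Bn) {
  stopifnot(t > 0, all(Bn >= 1))
  log2(Bn) / t
}

#' Normalise doubling times to a reference species
#'
#' @param times Numeric vector of doubling times (minutes).
#' @param reference Reference doubling time (> 0).
#' @param digits Rounding for reporting (default 2 decimal places).
#' @return Ratios `times / reference`, rounded.
#' @examples
#' normalize_times(c(17, 26, 66), 17)  # 1.00 1.53 3.88
#' @export
normalize_times <- function(times, reference, digits = 2) {
  if (reference <= 0) stop("reference must be > 0", call. = FALSE)
  round(times / reference, digits)
}

#' Growth census container
#'
#' @param census A data frame with columns `run` (replicate id),
#'   `iteration` (minutes, starting at 0) and `cells` (count >= 1).
#' @param B0 Initial count (1 in all shipped protocols).
#' @return A tibble of class `growth_census`.
#' @export
growth_census <- function(census, B0 = 1) {
  census <- tibble::as_tibble(census)
  stopifnot(all(c("run", "iteration", "cells") %in% names(census)))
  bad <- census |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(dec = any(diff(.data$cells[order(.data$iteration)]) < 0),
                     .groups = "drop")
  if (any(bad$dec)) {
    warning("cell counts decrease within run(s) ",
            paste(bad$run[bad$dec], collapse = ", "))
  }
  attr(census, "B0") <- B0
  class(census) <- c("growth_census", class(census))
  census
}

mean_census <- function(census) {
  census |>
    dplyr::group_by(.data$iteration) |>
    dplyr::summarise(cells = mean(.data$cells), .groups = "drop")
}

zw_gompertz <- function(t, A, mu, lambda) {
  A * exp(-exp(mu * exp(1) / A * (lambda - t) + 1))
}

zw_logistic <- function(t, A, mu, lambda) {
  A / (1 + exp(4 * mu / A * (lambda - t) + 2))
}

#' Fit a growth model to a census
#'
#' Least-squares fit of the Zwietering-reparameterised Gompertz
#' `y = A exp(-exp(mu e / A (lambda - t) + 1))` or logistic
#' `y = A / (1 + exp(4 mu / A (lambda - t) + 2))` model to the
#' log-count response `y = ln(B_t / B_0)` of the mean census across
#' runs. The exponential model fits `y = K t` by linear least squares
#' (through the origin), with `K` in natural-log units per minute.
#'
#' @param census A [growth_census()] (or a compatible data frame).
#' @param model `"gompertz"`, `"logistic"` or `"exponential"`.
#' @return A `growth_fit` object: list with `model`, `parameters`
#'   (named vector), `rss`, `converged`, `degenerate` (TRUE when the
#'   census never grows, mu ~ 0), and `data` (the fitted mean series).
#' @examples
#' tt <- 0:30
#' y <- exp(4 * exp(-exp(1 * exp(1) / 4 * (8 - tt) + 1)))
#' cen <- growth_census(data.frame(run = 1, iteration = tt, cells = y))
#' fit_growth(cen, "gompertz")
#' @export
fit_growth <- function(census, model = c("gompertz", "logistic",
                                         "exponential")) {
  model <- match.arg(model)
  B0 <- attr(census, "B0") %||% 1
  m <- mean_census(census)
  if (nrow(m) < 4) stop("need at least 4 time points", call. = FALSE)
  t <- m$iteration
  y <- log(m$cells / B0)
  degenerate <- max(y) - min(y) < 1e-8
  if (model == "exponential") {
    K <- if (degenerate) 0 else sum(t * y) / sum(t * t)
    rss <- sum((y - K * t)^2)
    return(new_growth_fit(model, c(K = K), rss, TRUE, degenerate, m))
  }
  if (degenerate) {
    return(new_growth_fit(model, c(A = max(y), mu = 0, lambda = 0),
                          sum((y - mean(y))^2), TRUE, TRUE, m))
  }
  # starting values: asymptote from the plateau, slope from the steepest
  # rise, lag from the tangent intercept
  A0 <- max(y) * 1.05
  dy <- diff(y) / diff(t)
  i <- which.max(dy)
  mu0 <- max(dy)
  lam0 <- max(t[i] - y[i] / mu0, 0)
  fml <- if (model == "gompertz") {
    y ~ A * exp(-exp(mu * exp(1) / A * (lambda - t) + 1))
  } else {
    y ~ A / (1 + exp(4 * mu / A * (lambda - t) + 2))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = data.frame(t = t, y = y),
                      start = list(A = A0, mu = mu0, lambda = lam0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new_growth_fit(model, c(A = NA, mu = NA, lambda = NA), NA,
                          FALSE, FALSE, m))
  }
  est <- stats::coef(fit)
  new_growth_fit(model, est[c("A", "mu", "lambda")],
                 sum(stats::resid(fit)^2), TRUE, FALSE, m)
}

new_growth_fit <- function(model, parameters, rss, converged, degenerate,
                           data) {
  structure(list(model = model, parameters = parameters, rss = rss,
                 converged = converged, degenerate = degenerate,
                 data = data),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit>", x$model, "model;",
      if (!x$converged) "DID NOT CONVERGE;" else NULL,
      if (x$degenerate) "degenerate (no growth);" else NULL, "\n")
  print(round(x$parameters, 4))
  cat("RSS:", signif(x$rss, 4), "\n")
  invisible(x)
}

#' Tidy a growth fit
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble::tibble(term = names(x$parameters),
                 estimate = as.numeric(x$parameters))
}

#' One-row summary of a growth fit
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return A tibble: model, rss, converged, degenerate, n.
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(model = x$model, rss = x$rss, converged = x$converged,
                 degenerate = x$degenerate, n = nrow(x$data))
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Predicted mean census of a fitted growth model
#'
#' @param object A `growth_fit`.
#' @param newdata Optional data frame with column `iteration`.
#' @param ... Unused.
#' @return Numeric vector of predicted cell counts.
#' @export
predict.growth_fit <- function(object, newdata = NULL, ...) {
  t <- (newdata %||% object$data)$iteration
  p <- object$parameters
  y <- switch(object$model,
              exponential = p[["K"]] * t,
              gompertz = zw_gompertz(t, p[["A"]], p[["mu"]], p[["lambda"]]),
              logistic = zw_logistic(t, p[["A"]], p[["mu"]], p[["lambda"]]))
  exp(y)
}
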