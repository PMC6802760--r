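# Evaluate a single (3-parameter) or dual (6-parameter) Gaussian curve.
gaussian_curve <- function(x, par) {
  y <- par[[1L]] * exp(-(x - par[[2L]])^2 / (2 * par[[3L]]^2))
  if (length(par) == 6L) {
    y <- y + par[[4L]] * exp(-(x - par[[5L]])^2 / (2 * par[[6L]]^2))
  }
  y
}

param_names <- function(model) {
  if (model == "single") c("A", "mu", "sigma")
  else c("A1", "mu1", "sigma1", "A2", "mu2", "sigma2")
}

# Parameter box constraints on the percent-accuracy scale. Amplitudes may
# overshoot 100% slightly; sigma is kept away from 0 and from values so
# large the curve would be flat over the display.
fit_bounds <- function(model) {
  lo1 <- c(0, -9, 0.3)
  hi1 <- c(110, 9, 12)
  if (model == "single") list(lower = lo1, upper = hi1)
  else list(lower = c(lo1, lo1), upper = c(hi1, hi1))
}

#' Construct a profile fit from known parameters
#'
#' Builds a `vs_fit` object directly from curve parameters, optionally
#' attaching observed data (in which case r-squared is computed). Useful for
#' evaluating closed-form cases and for testing span extraction separately
#' from least-squares fitting.
#'
#' @param model `"single"` or `"double"`.
#' @param params Numeric vector of length 3 (`A`, `mu`, `sigma`) or 6
#'   (`A1`, `mu1`, `sigma1`, `A2`, `mu2`, `sigma2`). Amplitudes in percent,
#'   means and standard deviations in character positions.
#' @param data Optional data frame with columns `position` and
#'   `accuracy_pct`.
#' @return A `vs_fit` object.
#' @export
profile_fit <- function(model = c("single", "double"), params, data = NULL) {
  model <- match.arg(model)
  k <- if (model == "single") 3L else 6L
  if (length(params) != k) {
    stop("`params` must have length ", k, " for the ", model, " model",
         call. = FALSE)
  }
  params <- stats::setNames(as.numeric(params), param_names(model))
  sig <- params[grep("sigma", names(params))]
  amp <- params[grep("^A", names(params))]
  if (any(sig <= 0)) stop("sigma parameters must be positive", call. = FALSE)
  if (any(amp < 0)) stop("amplitudes must be non-negative", call. = FALSE)
  r2 <- NA_real_
  if (!is.null(data)) {
    y <- data$accuracy_pct
    ssr <- sum((y - gaussian_curve(data$position, params))^2)
    r2 <- r_squared_of(ssr, y)
  }
  structure(list(model = model, par = params, r_squared = r2,
                 converged = TRUE, data = data),
            class = "vs_fit")
}

r_squared_of <- function(ssr, y) {
  sst <- sum((y - mean(y))^2)
  if (sst > 0) 1 - ssr / sst else if (ssr < 1e-8) 1 else 0
}

#' Fit a Gaussian profile curve by bounded least squares
#'
#' Fits either a single Gaussian (amplitude, mean, standard deviation) or
#' the sum of two Gaussians (six parameters) to a visual-span profile by
#' Levenberg-Marquardt least squares with box constraints and multiple
#' starting points. The bounded fit prevents the runaway-sigma solutions a
#' free single-Gaussian fit can drift into on plateau-shaped profiles.
#'
#' @param profile Data frame with columns `position` and `accuracy_pct`
#'   (one profile, typically the 15 scored positions).
#' @param model `"single"` or `"double"`.
#'
#' @return A `vs_fit` object: `model`, named `par` vector, `r_squared`,
#'   `converged` flag and the fitted `data`. When no start converges the
#'   best attempt is returned with `converged = FALSE`.
#' @export
fit_gaussian <- function(profile, model = c("single", "double")) {
  model <- match.arg(model)
  x <- profile$position
  y <- profile$accuracy_pct
  k <- if (model == "single") 3L else 6L
  if (length(x) < k + 2L || anyNA(x) || anyNA(y)) {
    stop("profile must provide at least ", k + 2L,
         " complete (position, accuracy) pairs", call. = FALSE)
  }
  b <- fit_bounds(model)
  ymax <- max(y)
  xmode <- x[which.max(y)]
  starts <- if (model == "single") {
    list(c(ymax, xmode, 2), c(ymax, 0, 4))
  } else {
    # symmetric perturbations about the mode, plus a core + pedestal start
    # for profiles with a narrow peak on a shallow tail
    list(c(0.6 * ymax, xmode - 2, 2, 0.6 * ymax, xmode + 2, 2),
         c(0.6 * ymax, xmode - 3, 3, 0.6 * ymax, xmode + 3, 3),
         c(ymax, xmode, 2, 0.3 * ymax, xmode, 8))
  }
  clamp_start <- function(p) pmin(pmax(p, b$lower + 1e-6), b$upper - 1e-6)
  resid_fn <- function(p) y - gaussian_curve(x, p)

  best <- NULL
  for (s in starts) {
    out <- tryCatch(
      minpack.lm::nls.lm(par = clamp_start(s), lower = b$lower,
                         upper = b$upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(out)) next
    ssr <- sum(out$fvec^2)
    ok <- out$info %in% 1:4
    if (is.null(best) || ssr < best$ssr - 1e-12) {
      best <- list(par = out$par, ssr = ssr, converged = ok)
    }
  }
  if (is.null(best)) {
    # last resort: bounded quasi-Newton on the sum of squares
    obj <- function(p) sum(resid_fn(p)^2)
    out <- stats::optim(clamp_start(starts[[1L]]), obj, method = "L-BFGS-B",
                        lower = b$lower, upper = b$upper)
    best <- list(par = out$par, ssr = out$value,
                 converged = out$convergence == 0)
  }
  structure(list(model = model,
                 par = stats::setNames(as.numeric(best$par),
                                       param_names(model)),
                 r_squared = r_squared_of(best$ssr, y),
                 converged = isTRUE(best$converged),
                 data = data.frame(position = x, accuracy_pct = y)),
            class = "vs_fit")
}

#' Evaluate a fitted profile curve
#'
#' @param object A `vs_fit` object.
#' @param x Positions (real-valued) at which to evaluate the curve; defaults
#'   to the positions the fit was computed on.
#' @param ... Unused.
#' @return Fitted accuracy (percent) at `x`.
#' @export
predict.vs_fit <- function(object, x = NULL, ...) {
  if (is.null(x)) x <- object$data$position
  gaussian_curve(x, object$par)
}

#' @export
print.vs_fit <- function(x, ...) {
  cat(if (x$model == "single") "Single-Gaussian" else "Dual-Gaussian",
      "profile fit\n")
  print(round(x$par, 4))
  cat("  r^2 =", format(x$r_squared, digits = 4),
      if (!x$converged) " (did not converge)" else "", "\n")
  invisible(x)
}

# TRUE if the region where the curve is at or above `criterion` is one
# contiguous interval of the 0.001-position grid over [-9, 9] (vacuously
# true for a curve that never reaches the criterion: its span is zero).
criterion_region_is_interval <- function(fit, criterion) {
  xs <- seq(-9, 9, by = 0.001)
  above <- which(gaussian_curve(xs, fit$par) >= criterion)
  length(above) == 0L || all(diff(above) == 1L)
}

#' Choose between single- and dual-Gaussian fits of one profile
#'
#' Replaces by-eye model selection with a deterministic rule: the dual
#' Gaussian is adopted only when it improves r-squared by at least
#' `delta_r2` **and** is admissible as a span profile — both amplitudes
#' strictly positive, both means inside the scored range (-7 ... +7), and
#' the region at or above the span criterion forming a single interval (a
#' span is reported as one width, so a disconnected supra-criterion region
#' disqualifies the curve). Otherwise the single Gaussian is kept.
#'
#' @param fit_single,fit_double `vs_fit` objects for the same profile.
#' @param delta_r2 Minimum r-squared improvement required of the dual fit.
#' @param criterion Accuracy criterion (percent) used for the
#'   single-interval admissibility check.
#' @return The selected `vs_fit`.
#' @export
select_best_fit <- function(fit_single, fit_double, delta_r2 = 0.01,
                            criterion = 80) {
  stopifnot(inherits(fit_single, "vs_fit"), inherits(fit_double, "vs_fit"))
  if (fit_single$model != "single" || fit_double$model != "double") {
    stop("arguments must be a single-model and a double-model fit, in order",
         call. = FALSE)
  }
  if (!fit_single$converged && !fit_double$converged) {
    stop("model selection failed: neither fit converged", call. = FALSE)
  }
  r2s <- if (fit_single$converged) fit_single$r_squared else -Inf
  r2d <- if (fit_double$converged) fit_double$r_squared else -Inf
  p <- fit_double$par
  admissible <- fit_double$converged &&
    p[["A1"]] > 0 && p[["A2"]] > 0 &&
    p[["mu1"]] >= -7 && p[["mu1"]] <= 7 &&
    p[["mu2"]] >= -7 && p[["mu2"]] <= 7 &&
    criterion_region_is_interval(fit_double, criterion)
  if (admissible && (r2d - r2s >= delta_r2)) fit_double else fit_single
}
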