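#' Legendre orthogonal polynomial basis
#'
#' Evaluates the Legendre polynomials \eqn{L_0(x), \ldots, L_r(x)} at points in
#' \eqn{[-1, 1]} using the standard three-term recurrence
#' \eqn{(n+1) L_{n+1}(x) = (2n+1) x L_n(x) - n L_{n-1}(x)}.
#'
#' @param x numeric vector with values in \eqn{[-1, 1]}.
#' @param order non-negative integer, highest polynomial degree \eqn{r}.
#' @return a `length(x)` by `order + 1` matrix; column `j` holds
#'   \eqn{L_{j-1}(x)}.
#' @examples
#' legendre_basis(0.5, 2)   # 1, 0.5, -0.125
#' @export
legendre_basis <- function(x, order) {
  stopifnot(is.numeric(x), length(order) == 1L, order >= 0)
  if (any(!is.finite(x)) || any(x < -1 - 1e-12) || any(x > 1 + 1e-12)) {
    stop("legendre_basis: x must be finite and within [-1, 1]")
  }
  n <- length(x)
  B <- matrix(0, n, order + 1L)
  B[, 1L] <- 1
  if (order >= 1L) B[, 2L] <- x
  if (order >= 2L) {
    for (k in 2:order) {
      B[, k + 1L] <- ((2 * k - 1) * x * B[, k] - (k - 1) * B[, k - 1L]) / k
    }
  }
  B
}

# Legendre basis without domain check: used internally where curve fits are
# evaluated outside the fitting window (polynomials extrapolate smoothly).
legendre_basis_unsafe <- function(x, order) {
  n <- length(x)
  B <- matrix(0, n, order + 1L)
  B[, 1L] <- 1
  if (order >= 1L) B[, 2L] <- x
  if (order >= 2L) {
    for (k in 2:order) {
      B[, k + 1L] <- ((2 * k - 1) * x * B[, k] - (k - 1) * B[, k - 1L]) / k
    }
  }
  B
}

# derivative basis dL_n/dx via (x^2-1)/n * dL_n/dx = x L_n - L_{n-1}
legendre_basis_deriv <- function(x, order) {
  B <- legendre_basis_unsafe(x, order)
  D <- matrix(0, length(x), order + 1L)
  if (order >= 1L) {
    for (k in 1:order) {
      num <- k * (x * B[, k + 1L] - B[, k])
      den <- x^2 - 1
      near <- abs(den) < 1e-10
      D[!near, k + 1L] <- num[!near] / den[!near]
      if (any(near)) {
        # at x = +-1, dL_n/dx = (+-1)^(n+1) n(n+1)/2
        D[near, k + 1L] <- sign(x[near])^(k + 1) * k * (k + 1) / 2
      }
    }
  }
  D
}

#' Construct a Legendre-polynomial curve
#'
#' A `lop_curve` represents a smooth function on a time window
#' \eqn{[t_0, t_T]} as a linear combination of Legendre polynomials; the
#' window is mapped affinely onto \eqn{[-1, 1]} so that uneven measurement
#' schedules pose no difficulty.
#'
#' @param coefficients numeric vector of length `order + 1` (constant term
#'   first).
#' @param t_min,t_max the time window; `t_max > t_min`.
#' @return an object of class `lop_curve`.
#' @export
lop_curve <- function(coefficients, t_min, t_max) {
  stopifnot(is.numeric(coefficients), length(coefficients) >= 1L,
            t_max > t_min, all(is.finite(coefficients)))
  structure(
    list(order = length(coefficients) - 1L,
         coefficients = as.numeric(coefficients),
         t_min = as.numeric(t_min), t_max = as.numeric(t_max)),
    class = "lop_curve"
  )
}

# map times in [t_min, t_max] onto [-1, 1]; extrapolates linearly beyond.
lop_rescale_time <- function(curve, t) {
  (2 * t - (curve$t_min + curve$t_max)) / (curve$t_max - curve$t_min)
}

#' @export
predict.lop_curve <- function(object, t, deriv = 0L, ...) {
  x <- lop_rescale_time(object, t)
  if (deriv == 0L) {
    drop(legendre_basis_unsafe(x, object$order) %*% object$coefficients)
  } else if (deriv == 1L) {
    # chain rule through the affine time map
    scale <- 2 / (object$t_max - object$t_min)
    drop(legendre_basis_deriv(x, object$order) %*% object$coefficients) * scale
  } else {
    stop("only deriv = 0 or 1 supported")
  }
}

#' @export
print.lop_curve <- function(x, ...) {
  cat(sprintf("Legendre curve, order %d on [%g, %g]\n", x$order, x$t_min, x$t_max))
  cat("coefficients:", signif(x$coefficients, 4), "\n")
  invisible(x)
}

#' Fit a Legendre-polynomial curve to a plasticity series
#'
#' Least-squares fit of an order-`r` Legendre expansion to values observed on
#' the design time grid. This is the nonparametric smoother used for every
#' plasticity trajectory (genes and traits alike): the fitted curve is the
#' expectation part of the series and the residuals are measurement error.
#'
#' @param values numeric vector of plasticity values, one per time point.
#' @param times strictly increasing numeric vector of measurement times.
#' @param order polynomial order `r`; requires `length(times) >= order + 1`.
#' @return a [lop_curve()].
#' @export
fit_lop_curve <- function(values, times, order = 4L) {
  stopifnot(length(values) == length(times), all(diff(times) > 0))
  if (!all(is.finite(values))) stop("fit_lop_curve: non-finite values")
  if (length(times) < order + 1L) {
    stop(sprintf("fit_lop_curve: under-determined fit (%d points, order %d)",
                 length(times), order))
  }
  t_min <- times[1L]; t_max <- times[length(times)]
  x <- (2 * times - (t_min + t_max)) / (t_max - t_min)
  B <- legendre_basis(x, order)
  coef <- qr.coef(qr(B), values)
  coef[is.na(coef)] <- 0
  out <- lop_curve(coef, t_min, t_max)
  # keep the fitted data: downstream stages need the design grid and the
  # residual scale of the fit
  out$data_times <- times
  out$data_values <- values
  out$rss <- sum((drop(B %*% coef) - values)^2)
  out
}

#' Select a Legendre fitting order by AIC
#'
#' Fits candidate orders and returns the curve minimizing
#' \eqn{\mathrm{AIC} = n \log(\mathrm{RSS}/n) + 2 (r + 2)} (Gaussian residual
#' model with unknown variance).
#'
#' @param values,times as in [fit_lop_curve()].
#' @param orders candidate orders; defaults to 2..6 truncated to what the
#'   number of time points supports.
#' @return a [lop_curve()] with attribute `"aic"` (the selected value).
#' @export
select_lop_order <- function(values, times, orders = 2:6) {
  orders <- orders[orders + 1L <= length(times)]
  if (!length(orders)) stop("select_lop_order: no feasible order")
  n <- length(values)
  best <- NULL; best_aic <- Inf
  for (r in orders) {
    cur <- fit_lop_curve(values, times, r)
    rss <- sum((predict(cur, times) - values)^2)
    aic <- n * log(max(rss, 1e-300) / n) + 2 * (r + 2)
    if (aic < best_aic) { best_aic <- aic; best <- cur }
  }
  attr(best, "aic") <- best_aic
  best
}
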