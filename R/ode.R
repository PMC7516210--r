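#' Classical 4th-order Runge--Kutta integration
#'
#' Integrates `d state / dt = derivative_field(t, state)` across an output
#' grid, sub-stepping each interval with a fixed internal step.
#'
#' @param derivative_field function of `(t, state)` returning the derivative
#'   vector.
#' @param initial_state numeric state vector at `time_grid[1]`.
#' @param time_grid strictly increasing output times.
#' @param h internal step size; each grid interval is split into
#'   `ceiling(interval / h)` equal sub-steps. Defaults to 1/300 of the span.
#' @return matrix with `length(time_grid)` rows (states at grid times).
#' @export
integrate_rk4 <- function(derivative_field, initial_state, time_grid,
                          h = diff(range(time_grid)) / 300) {
  stopifnot(all(diff(time_grid) > 0), h > 0)
  n <- length(time_grid)
  out <- matrix(NA_real_, n, length(initial_state))
  state <- as.numeric(initial_state)
  out[1L, ] <- state
  for (j in seq_len(n - 1L)) {
    span <- time_grid[j + 1L] - time_grid[j]
    nstep <- max(1L, ceiling(span / h))
    hh <- span / nstep
    t <- time_grid[j]
    for (s in seq_len(nstep)) {
      k1 <- derivative_field(t, state)
      k2 <- derivative_field(t + hh / 2, state + hh / 2 * k1)
      k3 <- derivative_field(t + hh / 2, state + hh / 2 * k2)
      k4 <- derivative_field(t + hh, state + hh * k3)
      if (any(!is.finite(k4))) {
        stop(sprintf("integrate_rk4: non-finite derivative near t = %g", t))
      }
      state <- state + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + hh
    }
    out[j + 1L, ] <- state
  }
  out
}

# Legendre -> monomial coefficient transform: row n+1 gives the monomial
# coefficients of L_n. Small fixed orders only.
legendre_monomial_matrix <- function(order) {
  M <- matrix(0, order + 1L, order + 1L)
  M[1L, 1L] <- 1
  if (order >= 1L) M[2L, 2L] <- 1
  if (order >= 2L) {
    for (k in 2:order) {
      shifted <- c(0, M[k, seq_len(order)])           # x * L_{k-1}
      M[k + 1L, ] <- ((2 * k - 1) * shifted - (k - 1) * M[k - 1L, ]) / k
    }
  }
  M
}

# Integration lattice over the design times: every design interval split into
# equal sub-steps of size <= h. Knots include all design times; mids are the
# sub-step midpoints needed by RK4 stages.
ode_grid <- function(times, h_steps = 300L) {
  h <- diff(range(times)) / h_steps
  knots <- times[1L]; hs <- numeric(0); design_idx <- 1L
  for (j in seq_len(length(times) - 1L)) {
    span <- times[j + 1L] - times[j]
    nstep <- max(1L, ceiling(span / h))
    hh <- span / nstep
    knots <- c(knots, times[j] + hh * seq_len(nstep))
    hs <- c(hs, rep(hh, nstep))
    design_idx <- c(design_idx, length(knots))
  }
  mids <- knots[-length(knots)] + hs / 2
  list(knots = knots, mids = mids, hs = hs, design_idx = design_idx)
}

# Scalar RK4 over the precomputed lattice with a monomial Q (in the rescaled
# argument x = alpha * g + beta) plus time-tabulated dependent input. Also
# accumulates the independent integral P_i and, via Simpson weights shared
# with the RK4 stages, each regulator's dependent integral.
# dep_knot / dep_mid: total dependent input at knots / mids (vectors).
# Returns list(g = values at knots, p_ind = independent integral at knots).
rk4_scalar_decomp <- function(g0, mono, alpha, beta, dep_knot, dep_mid, hs) {
  S <- length(hs)
  g <- numeric(S + 1L); g[1L] <- g0
  p_ind <- numeric(S + 1L)
  deg <- length(mono) - 1L
  qeval <- function(gv) {
    x <- alpha * gv + beta
    acc <- mono[deg + 1L]
    if (deg >= 1L) for (k in deg:1L) acc <- acc * x + mono[k]
    acc
  }
  for (s in seq_len(S)) {
    h <- hs[s]
    d1 <- dep_knot[s]; dm <- dep_mid[s]; d2 <- dep_knot[s + 1L]
    gs <- g[s]
    q1 <- qeval(gs);                k1 <- q1 + d1
    g1 <- gs + h / 2 * k1
    q2 <- qeval(g1);                k2 <- q2 + dm
    g2 <- gs + h / 2 * k2
    q3 <- qeval(g2);                k3 <- q3 + dm
    g3 <- gs + h * k3
    q4 <- qeval(g3);                k4 <- q4 + d2
    g[s + 1L] <- gs + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    p_ind[s + 1L] <- p_ind[s] + h / 6 * (q1 + 2 * q2 + 2 * q3 + q4)
    if (!is.finite(g[s + 1L])) return(NULL)
  }
  list(g = g, p_ind = p_ind)
}

# Precompute the per-regulator basis tables on an integration lattice. Each
# regulator curve is evaluated at the knots and mids, its values affinely
# rescaled to [-1, 1] by their own observed range, and expanded in Legendre
# orders 1..q. Every column is centered at the image of zero plasticity so
# that Q_ii'(0) = 0: a regulator showing no treatment response contributes
# nothing, and all constants belong to the independent term.
regulator_tables <- function(regulator_curves, grid, q_order) {
  lapply(regulator_curves, function(cv) {
    vk <- predict(cv, grid$knots); vm <- predict(cv, grid$mids)
    lo <- min(vk); hi <- max(vk)
    list(
      Bk = dep_basis(vk, lo, hi, q_order),
      Bm = dep_basis(vm, lo, hi, q_order),
      lo = lo, hi = hi)
  })
}

# dependent-component basis: Legendre orders 1..q of the range-rescaled
# argument, anchored so each column vanishes at argument zero
dep_basis <- function(v, lo, hi, q_order) {
  B <- legendre_basis_unsafe(rescale_to_range(v, lo, hi),
                             q_order)[, -1L, drop = FALSE]
  B0 <- legendre_basis_unsafe(rescale_to_range(0, lo, hi),
                              q_order)[, -1L, drop = FALSE]
  sweep(B, 2L, drop(B0))
}

#' Fit one row of the game-theoretic ODE system
#'
#' Estimates the independent component function \eqn{Q_i} and one dependent
#' component function \eqn{Q_{ii'}} per selected regulator in
#' \deqn{dg_i/dt = Q_i(g_i(t)) + \sum_{i'} Q_{ii'}(g_{i'}(t)),}
#' with every \eqn{Q} a Legendre expansion in its argument gene's expression
#' value (arguments affinely rescaled to \eqn{[-1,1]} by each curve's
#' observed range). Estimation is two-stage: a linear derivative-matching
#' regression of the focal curve's analytic derivative supplies starting
#' values, then trajectory-matching nonlinear least squares
#' (Levenberg--Marquardt) minimizes the SSE between the RK4-integrated
#' solution and the observed series at the design times, over `n_starts`
#' jittered starts. Regulator curves are treated as known inputs (their
#' fitted curves), which makes the system row-separable.
#'
#' @param values observed plasticity series of the target at `times`.
#' @param times strictly increasing design times.
#' @param regulator_curves named list of [lop_curve()] for the selected
#'   regulators (possibly empty).
#' @param q_order Legendre order of each component function.
#' @param target_order Legendre order of the stage-1 fit of the target curve.
#' @param n_starts number of optimization starts (first is the stage-2
#'   estimate, the rest jittered).
#' @param h_steps internal RK4 resolution: step = span / `h_steps`.
#' @param seed seed for the jittered starts.
#' @param target_id identifier stored in the fit.
#' @param max_iter Levenberg--Marquardt iteration cap per start.
#' @return an `ode_fit` object: coefficient blocks `theta_i` (independent)
#'   and `theta_dep` (per regulator), `g0`, `sse`, `fitted` values at design
#'   times, argument ranges, and the inputs needed by [decompose()].
#' @export
fit_ode <- function(values, times, regulator_curves = list(), q_order = 3L,
                    target_order = min(4L, length(times) - 1L),
                    n_starts = 8L, h_steps = 300L, seed = 1L,
                    target_id = "target", max_iter = 50L) {
  stopifnot(length(values) == length(times), all(diff(times) > 0))
  d <- length(regulator_curves)
  if (d > 0L && is.null(names(regulator_curves))) {
    names(regulator_curves) <- paste0("reg_", seq_len(d))
  }
  tcurve <- fit_lop_curve(values, times, target_order)
  grid <- ode_grid(times, h_steps)
  gk <- predict(tcurve, grid$knots)
  lo <- min(gk); hi <- max(gk)
  alpha <- if (hi - lo < 1e-12) 0 else 2 / (hi - lo)
  beta <- if (hi - lo < 1e-12) 0 else -(lo + hi) / (hi - lo)
  Mleg <- legendre_monomial_matrix(q_order)
  tabs <- regulator_tables(regulator_curves, grid, q_order)
  Bk <- if (d) do.call(cbind, lapply(tabs, `[[`, "Bk")) else NULL
  Bm <- if (d) do.call(cbind, lapply(tabs, `[[`, "Bm")) else NULL
  p_i <- q_order + 1L
  q <- q_order                      # columns per regulator (orders 1..q)
  g0 <- predict(tcurve, times[1L])

  traj <- function(theta) {
    mono <- drop(theta[seq_len(p_i)] %*% Mleg)
    if (d) {
      td <- theta[-seq_len(p_i)]
      dk <- drop(Bk %*% td); dm <- drop(Bm %*% td)
    } else {
      dk <- numeric(length(grid$knots)); dm <- numeric(length(grid$mids))
    }
    rk4_scalar_decomp(g0, mono, alpha, beta, dk, dm, grid$hs)
  }
  resid_fun <- function(theta) {
    sol <- traj(theta)
    if (is.null(sol)) return(rep(1e6, length(values)))
    sol$g[grid$design_idx] - values
  }

  # stage 2: integral-matching linear regression for starting values
  # (observed increments on integrated basis expansions)
  tt <- seq(times[1L], times[length(times)], length.out = 301L)
  di <- vapply(times, function(x) which.min(abs(tt - x)), 1L)
  yinc <- diff(values)
  Bown <- legendre_basis_unsafe(rescale_to_range(predict(tcurve, tt), lo, hi),
                                q_order)
  X0 <- apply(apply(Bown, 2L, cumtrapz, tt = tt)[di, , drop = FALSE], 2L, diff)
  Xg <- if (d) do.call(cbind, lapply(regulator_curves, function(cv) {
    v <- predict(cv, tt)
    Bm <- dep_basis(v, min(v), max(v), q_order)
    apply(apply(Bm, 2L, cumtrapz, tt = tt)[di, , drop = FALSE], 2L, diff)
  })) else NULL
  X <- cbind(X0, Xg)
  th0 <- qr.coef(qr(X), yinc); th0[is.na(th0)] <- 0

  set.seed(seed)
  # only parameter vectors whose trajectory integrates finitely may win
  sse_of <- function(theta) {
    sol <- traj(theta)
    if (is.null(sol) || any(!is.finite(sol$g))) return(Inf)
    sum((sol$g[grid$design_idx] - values)^2)
  }
  # a start must integrate: shrink the regression init geometrically until
  # it does (the zero vector yields a constant, always-finite trajectory)
  for (k in 0:12) {
    if (is.finite(sse_of(th0))) break
    th0 <- th0 * 0.5
  }
  if (!is.finite(sse_of(th0))) th0 <- 0 * th0
  best <- list(par = th0, sse = sse_of(th0))
  scale0 <- max(abs(th0), 0.1)
  for (s in seq_len(max(1L, n_starts))) {
    st <- if (s == 1L) th0 else th0 + rnorm(length(th0), 0, 0.25 * scale0)
    if (!is.finite(sse_of(st))) next
    fit <- tryCatch(
      minpack.lm::nls.lm(st, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter, ptol = 1e-10, ftol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sse_of(fit$par)
    if (sse < best$sse) best <- list(par = fit$par, sse = sse)
  }
  if (!is.finite(best$sse)) {
    stop("fit_ode: no optimization start produced a finite trajectory")
  }

  theta <- best$par
  theta_dep <- if (d) {
    split(theta[-seq_len(p_i)],
          rep(names(regulator_curves), each = q))[names(regulator_curves)]
  } else list()
  sol <- traj(theta)
  structure(
    list(target_id = target_id, regulators = names(regulator_curves),
         theta_i = theta[seq_len(p_i)], theta_dep = theta_dep,
         q_order = q_order, g0 = g0, sse = best$sse,
         fitted = sol$g[grid$design_idx], times = times, values = values,
         target_curve = tcurve, target_range = c(lo, hi),
         regulator_curves = regulator_curves, h_steps = h_steps),
    class = "ode_fit"
  )
}

#' @export
print.ode_fit <- function(x, ...) {
  cat(sprintf("ode_fit for %s: %d regulator(s) [%s], SSE %.4g\n",
              x$target_id, length(x$regulators),
              paste(x$regulators, collapse = ", "), x$sse))
  invisible(x)
}

#' Decompose a fitted trajectory into independent and dependent integrals
#'
#' Integrates the fitted ODE row once more on a dense lattice, accumulating
#' alongside the solution the independent integral
#' \eqn{P_i(t) = g_i(t_0) + \int_{t_0}^t Q_i(\hat g_i(s))\,ds} and each
#' regulator's dependent integral
#' \eqn{P_{ii'}(t) = \int_{t_0}^t Q_{ii'}(\hat g_{i'}(s))\,ds}. All integrals
#' share the RK4 stage values, so the additivity
#' \eqn{P_i(t) + \sum_{i'} P_{ii'}(t) = \hat g_i(t)} holds to rounding error
#' at every lattice point. At the start time all expression is attributed to
#' the independent component: \eqn{P_i(t_0) = g_i(t_0)},
#' \eqn{P_{ii'}(t_0) = 0}.
#'
#' @param fit an `ode_fit`.
#' @param n_grid lattice resolution (sub-steps across the time span);
#'   defaults to the resolution the fit was computed at.
#' @return a `decomposed_trajectory`: list with `time` (lattice), `g_hat`,
#'   `p_ind`, and matrix `p_dep` (one column per regulator).
#' @export
decompose <- function(fit, n_grid = fit$h_steps) {
  stopifnot(inherits(fit, "ode_fit"))
  grid <- ode_grid(fit$times, n_grid)
  Mleg <- legendre_monomial_matrix(fit$q_order)
  mono <- drop(fit$theta_i %*% Mleg)
  lo <- fit$target_range[1L]; hi <- fit$target_range[2L]
  alpha <- if (hi - lo < 1e-12) 0 else 2 / (hi - lo)
  beta <- if (hi - lo < 1e-12) 0 else -(lo + hi) / (hi - lo)
  d <- length(fit$regulators)
  tabs <- regulator_tables(fit$regulator_curves, grid, fit$q_order)
  S <- length(grid$hs)
  p_dep <- matrix(0, S + 1L, d,
                  dimnames = list(NULL, fit$regulators))
  if (d) {
    dk_each <- lapply(seq_len(d), function(j)
      drop(tabs[[j]]$Bk %*% fit$theta_dep[[j]]))
    dm_each <- lapply(seq_len(d), function(j)
      drop(tabs[[j]]$Bm %*% fit$theta_dep[[j]]))
    dk <- Reduce(`+`, dk_each); dm <- Reduce(`+`, dm_each)
  } else {
    dk <- numeric(S + 1L); dm <- numeric(S)
  }
  sol <- rk4_scalar_decomp(fit$g0, mono, alpha, beta, dk, dm, grid$hs)
  if (is.null(sol)) stop("decompose: trajectory diverged")
  if (d) {
    for (j in seq_len(d)) {
      # Simpson increments matching the RK4 stages (time-only integrand)
      inc <- grid$hs / 6 * (dk_each[[j]][-(S + 1L)] + 4 * dm_each[[j]] +
                              dk_each[[j]][-1L])
      p_dep[, j] <- c(0, cumsum(inc))
    }
  }
  structure(
    list(target_id = fit$target_id, time = grid$knots, g_hat = sol$g,
         p_ind = sol$p_ind + fit$g0, p_dep = p_dep,
         regulators = fit$regulators),
    class = "decomposed_trajectory"
  )
}

#' @export
print.decomposed_trajectory <- function(x, ...) {
  cat(sprintf("decomposed trajectory for %s on %d grid points; regulators: %s\n",
              x$target_id, length(x$time),
              if (length(x$regulators)) paste(x$regulators, collapse = ", ")
              else "(none)"))
  invisible(x)
}

# dependent integral value(s) at an arbitrary time, by linear interpolation
# on the decomposition lattice
p_dep_at <- function(decomp, t) {
  if (!length(decomp$regulators)) return(numeric(0))
  vapply(seq_along(decomp$regulators), function(j)
    approx(decomp$time, decomp$p_dep[, j], xout = t, rule = 2)$y, numeric(1)) |>
    setNames(decomp$regulators)
}
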