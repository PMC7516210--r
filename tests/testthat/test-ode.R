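test_that("RK4 reproduces closed-form solutions", {
  # constant field
  tr <- integrate_rk4(function(t, s) 0 * s, 2, seq(0, 5, 1))
  expect_equal(as.vector(tr), rep(2, 6))
  # exponential growth: g' = g, g(0) = 1 -> e at t = 1
  tr <- integrate_rk4(function(t, s) s, 1, c(0, 1), h = 0.01)
  expect_equal(tr[2, 1], exp(1), tolerance = 1e-6)
  # error on divergence
  expect_error(integrate_rk4(function(t, s) s^3 * 1e6, 10, c(0, 5), h = 0.5),
               "non-finite")
})

test_that("RK4 converges at fourth order", {
  err <- vapply(c(0.1, 0.05, 0.025), function(h) {
    abs(integrate_rk4(function(t, s) s, 1, c(0, 1), h = h)[2, 1] - exp(1))
  }, numeric(1))
  ratios <- err[-length(err)] / err[-1]
  expect_true(all(ratios > 12 & ratios < 20))
})

test_that("a zero-regulator series generated from a known Q is fitted exactly", {
  times <- seq(0, 4, length.out = 25)
  g <- oracle_integrate(function(t, g) 0.3 - 0.25 * g, 1.2, times)
  fit <- fit_ode(g, times, target_order = 12, n_starts = 2, seed = 1)
  expect_lt(fit$sse, 1e-6)
  dec <- decompose(fit)
  # no regulators: the independent integral is the whole trajectory
  expect_equal(dec$p_ind, dec$g_hat, tolerance = 1e-10)
  expect_equal(ncol(dec$p_dep), 0L)
})

test_that("decomposition is additive, anchored at the initial condition", {
  gt <- simulate_system(m = 6, n_edges = 7, delta_sq = 0.005, T = 20,
                        seed = 21)
  fit <- suppressWarnings(
    infer_network(gt$dtp, gt$times,
                  noise_var = estimate_noise_variance(gt$dataset),
                  n_starts = 2, h_steps = 100, max_iter = 40))
  for (id in names(fit$decomps)) {
    d <- fit$decomps[[id]]
    total <- d$p_ind + if (ncol(d$p_dep)) rowSums(d$p_dep) else 0
    expect_lt(max(abs(total - d$g_hat)), 1e-6)
    expect_equal(d$p_ind[1], d$g_hat[1])              # P_i(t0) = g(t0)
    if (ncol(d$p_dep)) expect_true(all(d$p_dep[1, ] == 0))
  }
})

test_that("component recovery on a noiseless two-gene system", {
  # g2 is one leg of a damped oscillator (so its shape is informative),
  # g1 is driven by g2; all generating terms are known
  times <- seq(0, 8, length.out = 30)
  osc <- integrate_rk4(function(t, s) c(0.1 * (0.5 - s[1]) + 1.2 * s[2],
                                        0.1 * (-0.3 - s[2]) - 1.2 * s[1]),
                       c(1.2, -0.4), times, h = 0.01)
  g2 <- osc[, 1]
  g2f <- approxfun(times, g2, rule = 2)
  q1 <- function(g) 0.4 * (-1 - g)
  q12 <- function(g2v) 0.9 * g2v
  g1 <- oracle_integrate(function(t, g) q1(g) + q12(g2f(t)), 1.5, times)
  cv2 <- fit_lop_curve(g2, times, 12)
  fit <- fit_ode(g1, times, regulator_curves = list(g2 = cv2),
                 target_order = 12, n_starts = 4, seed = 2, max_iter = 150)
  dec <- decompose(fit, n_grid = 300)
  # generating integrals on the same lattice
  p12_true <- segnet:::cumtrapz(q12(g2f(dec$time)), dec$time)
  g1_dense <- oracle_integrate(function(t, g) q1(g) + q12(g2f(t)), 1.5,
                               dec$time)
  p1_true <- 1.5 + segnet:::cumtrapz(q1(g1_dense), dec$time)
  rngP <- diff(range(p12_true))
  expect_lt(max(abs(dec$p_dep[, "g2"] - p12_true)) / rngP, 0.05)
  expect_lt(max(abs(dec$p_ind - p1_true)) / diff(range(p1_true)), 0.05)
  expect_lt(max(abs(dec$g_hat - g1_dense)) / diff(range(g1_dense)), 0.05)
})

test_that("linear specialization matches the least-squares oracle", {
  # noiseless linear system: the fitted Q functions, mapped back to slopes,
  # agree with ordinary least squares on the true derivative regression
  times <- seq(0, 8, length.out = 40)
  g2 <- oracle_integrate(function(t, g) 0.6 * (1.5 - g), -2, times)
  g2f <- approxfun(times, g2, rule = 2)
  a0 <- 0.8; a1 <- -0.5; b <- 0.7
  g1 <- oracle_integrate(function(t, g) a0 + a1 * g + b * g2f(t), 0.5, times)
  cv2 <- fit_lop_curve(g2, times, 12)
  fit <- fit_ode(g1, times, regulator_curves = list(g2 = cv2), q_order = 1,
                 target_order = 12, n_starts = 2, seed = 1, max_iter = 150)
  # oracle: OLS of the exact derivative on (1, g1, g2)
  dg <- a0 + a1 * g1 + b * g2
  cf <- qr.coef(qr(cbind(1, g1, g2)), dg)
  # map the fitted Legendre-in-rescaled-argument terms back to raw slopes
  lo1 <- fit$target_range[1]; hi1 <- fit$target_range[2]
  slope_own <- fit$theta_i[2] * 2 / (hi1 - lo1)
  v2 <- predict(cv2, segnet:::ode_grid(times, 300)$knots)
  slope_dep <- fit$theta_dep[["g2"]][1] * 2 / (max(v2) - min(v2))
  expect_equal(slope_own, unname(cf[2]), tolerance = 0.02)
  expect_equal(slope_dep, unname(cf[3]), tolerance = 0.02)
})

test_that("rescaling the data rescales fitted trajectories and components", {
  times <- seq(0, 6, length.out = 20)
  g2 <- oracle_integrate(function(t, g) 0.4 * (1 - g), -1, times)
  g2f <- approxfun(times, g2, rule = 2)
  g1 <- oracle_integrate(function(t, g) 0.3 * (0.5 - g) + 0.6 * g2f(t), 1,
                         times)
  fit1 <- fit_ode(g1, times, list(g2 = fit_lop_curve(g2, times, 10)),
                  target_order = 10, n_starts = 1, seed = 1)
  cc <- 3.5
  fit2 <- fit_ode(cc * g1, times,
                  list(g2 = fit_lop_curve(cc * g2, times, 10)),
                  target_order = 10, n_starts = 1, seed = 1)
  d1 <- decompose(fit1); d2 <- decompose(fit2)
  expect_equal(d2$g_hat, cc * d1$g_hat, tolerance = 1e-2)
  expect_equal(d2$p_dep[, 1], cc * d1$p_dep[, 1], tolerance = 5e-2)
})
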