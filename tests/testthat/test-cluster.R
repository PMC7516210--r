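make_module_data <- function(G_per, shapes, times, noise = 1, seed = 1) {
  set.seed(seed)
  truth <- rep(seq_len(nrow(shapes)), each = G_per)
  dtp <- shapes[truth, , drop = FALSE] +
    matrix(rnorm(length(truth) * length(times), 0, noise), length(truth))
  rownames(dtp) <- paste0("g", seq_along(truth))
  colnames(dtp) <- times
  list(dtp = dtp, truth = truth)
}

test_that("a single-component mixture reduces to the pooled fit", {
  times <- seq(0, 6, length.out = 10)
  d <- make_module_data(20, rbind(4 * sin(times / 2)), times, seed = 2)
  part <- em_cluster(d$dtp, L = 1, times = times, n_restarts = 1)
  expect_equal(part$weights, 1)
  expect_equal(dim(part$posterior), c(20L, 1L))
  expect_true(all(part$posterior == 1))
  # the Skellam mean curve tracks the pooled (rounded) column means
  pooled <- colMeans(round(d$dtp))
  expect_lt(max(abs(part$mean_dtp[1, ] - pooled)), 1)
})

test_that("well-separated clusters are recovered almost perfectly", {
  times <- seq(0, 8, length.out = 12)
  shapes <- rbind(9 * sin(times / 8 * pi), -7 + 1.5 * times)
  d <- make_module_data(25, shapes, times, noise = 1, seed = 5)
  part <- em_cluster(d$dtp, L = 2, times = times, n_restarts = 2, seed = 3)
  ari <- mclust::adjustedRandIndex(part$assignment, d$truth)
  expect_gt(ari, 0.95)
  # posterior rows sum to one; weights sum to one
  expect_equal(rowSums(part$posterior), rep(1, nrow(d$dtp)), tolerance = 1e-10)
  expect_equal(sum(part$weights), 1, tolerance = 1e-10)
  # module mean curves equal the Skellam means mu1 - mu2
  B <- legendre_basis(
    (2 * times - (times[1] + times[12])) / (times[12] - times[1]),
    part$lop_order)
  for (c in 1:2) {
    mu1 <- segnet:::softplus(drop(B %*% part$params[[c]]$a1))
    mu2 <- segnet:::softplus(drop(B %*% part$params[[c]]$a2))
    expect_equal(part$mean_dtp[c, ], mu1 - mu2)
  }
})

test_that("duplicating every gene leaves the mean curves essentially unchanged", {
  times <- seq(0, 8, length.out = 10)
  shapes <- rbind(6 * cos(times / 3), -5 + times)
  d <- make_module_data(15, shapes, times, noise = 1, seed = 7)
  p1 <- em_cluster(d$dtp, L = 2, times = times, n_restarts = 1, seed = 2)
  dup <- rbind(d$dtp, d$dtp)
  rownames(dup) <- paste0("g", seq_len(nrow(dup)))
  p2 <- em_cluster(dup, L = 2, times = times, n_restarts = 1, seed = 2)
  # match clusters by mean-curve proximity, then compare
  d11 <- max(abs(p1$mean_dtp[1, ] - p2$mean_dtp[1, ]))
  d12 <- max(abs(p1$mean_dtp[1, ] - p2$mean_dtp[2, ]))
  perm <- if (d11 < d12) 1:2 else 2:1
  expect_lt(max(abs(p1$mean_dtp - p2$mean_dtp[perm, ])), 0.2)
})

test_that("AIC bookkeeping follows the free-parameter count", {
  times <- seq(0, 6, length.out = 10)
  d <- make_module_data(12, rbind(3 * sin(times), -3 * sin(times)), times,
                        seed = 4)
  part <- em_cluster(d$dtp, L = 2, times = times, lop_order = 3,
                     n_restarts = 1)
  n_free <- (2 - 1) + 2 * 2 * (3 + 1)
  expect_equal(part$n_free, n_free)
  expect_equal(part$aic, -2 * part$loglik + 2 * n_free)
})

test_that("model selection by AIC identifies the module count", {
  times <- seq(0, 8, length.out = 10)
  # two clearly distinct shapes -> L = 2 beats 1..4
  shapes <- rbind(8 * sin(times / 8 * pi), -6 + 1.4 * times)
  d <- make_module_data(20, shapes, times, noise = 1, seed = 6)
  part <- select_module_count(d$dtp, L_range = 1:4, times = times, seed = 2)
  expect_equal(part$L, 2L)
  prof <- attr(part, "aic_profile")
  expect_equal(prof$L, 1:4)
  # homogeneous data -> L = 1
  d1 <- make_module_data(25, rbind(5 * cos(times / 4)), times, noise = 1,
                         seed = 8)
  p1 <- select_module_count(d1$dtp, L_range = 1:3, times = times, seed = 2)
  expect_equal(p1$L, 1L)
})

test_that("the Gaussian emission fallback clusters non-count data", {
  times <- seq(0, 8, length.out = 10)
  shapes <- rbind(0.9 * sin(times / 2), -0.8 + 0.2 * times)  # sub-integer scale
  d <- make_module_data(20, shapes, times, noise = 0.1, seed = 9)
  part <- em_cluster(d$dtp, L = 2, times = times, emission = "gaussian",
                     n_restarts = 2, seed = 1)
  expect_gt(mclust::adjustedRandIndex(part$assignment, d$truth), 0.95)
})
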