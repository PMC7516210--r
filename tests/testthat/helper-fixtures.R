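# Shared fixture builders. Everything is generated in code at test time.

# A set of smooth, mutually distinct curves (random phases and explicitly
# distinct frequencies, plus a random trend) on a common window — used
# wherever tests need diverse regulator candidates without running the full
# simulator.
random_curve_set <- function(n, times, order = 10, seed = 1, scale = 3) {
  set.seed(seed)
  ws <- 0.4 + 2 * (sample(n) - 1) / n + runif(n, -0.05, 0.05)
  out <- lapply(seq_len(n), function(i) {
    ph <- runif(1, 0, 2 * pi)
    vals <- scale * (runif(1, 0.6, 1) * sin(ws[i] * times + ph) +
                       runif(1, -0.4, 0.4) * times / max(times) +
                       rnorm(1, 0, 0.4))
    fit_lop_curve(vals, times, min(order, length(times) - 1))
  })
  names(out) <- sprintf("c%02d", seq_len(n))
  out
}

# Integrate dg/dt = rhs(t, g) with very fine RK4 and return values on times
# (independent of the package's ode_grid bookkeeping, same classical scheme
# written directly for oracle use).
oracle_integrate <- function(rhs, g0, times, nsub = 80) {
  g <- g0
  out <- numeric(length(times))
  out[1] <- g0
  for (j in seq_len(length(times) - 1)) {
    h <- (times[j + 1] - times[j]) / nsub
    t <- times[j]
    for (s in seq_len(nsub)) {
      k1 <- rhs(t, g)
      k2 <- rhs(t + h / 2, g + h / 2 * k1)
      k3 <- rhs(t + h / 2, g + h / 2 * k2)
      k4 <- rhs(t + h, g + h * k3)
      g <- g + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    out[j + 1] <- g
  }
  out
}

# Write a tiny expression matrix + sample sheet to tempfiles; returns paths.
write_toy_dataset <- function(n_genes = 2, times = c(0, 1, 2), n_reps = 2,
                              seed = 1) {
  set.seed(seed)
  sheet <- expand.grid(replicate = seq_len(n_reps), time = times,
                       treatment = 1:2)
  sheet$sample_id <- sprintf("s%02d", seq_len(nrow(sheet)))
  sheet <- sheet[, c("sample_id", "treatment", "time", "replicate")]
  M <- matrix(round(runif(n_genes * nrow(sheet), 1, 20), 3), n_genes,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              sheet$sample_id))
  mp <- tempfile(fileext = ".tsv"); sp <- tempfile(fileext = ".tsv")
  df <- data.frame(id = rownames(M), M, check.names = FALSE)
  write.table(df, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sheet, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  list(matrix = mp, sheet = sp, M = M, sheet_df = sheet)
}
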