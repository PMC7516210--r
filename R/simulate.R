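#' Simulate a ground-truth game-theoretic gene network
#'
#' Samples a sparse random directed network, assigns smooth component
#' functions (mixed activation/inhibition signs), integrates the coupled ODE
#' system forward with RK4 from randomized initial plasticity values, and
#' emits a two-treatment observation set: treatment 1 is a constant baseline
#' expression level plus Gaussian noise, treatment 2 adds the integrated
#' plasticity trajectory, so that the replicate-averaged difference (DTP)
#' recovers the trajectory. With `n_reps = 2` replicates per treatment and
#' per-observation noise variance `delta_sq`, the DTP noise variance equals
#' `delta_sq` exactly.
#'
#' Component functions: independent terms are mean-reverting,
#' \eqn{Q_i(g) = a_i (e_i - g)} with slow decay rates
#' \eqn{a_i \sim U(0.1, 0.35)} and equilibria \eqn{e_i \sim U(-a, a)}
#' (`amplitude` \eqn{a}). A fraction of the edge budget is laid down as
#' reciprocal pairs with antisymmetric linear coupling (\eqn{+c} one way,
#' \eqn{-c} the other, \eqn{c \sim U(0.5, 3)}): each such pair is a damped
#' oscillator, which keeps the system stable while giving every gene a
#' distinct frequency and phase — the curve diversity that real expression
#' modules show and that network recovery depends on. The remaining edges
#' are single directed links with \eqn{|b| \sim U(0.5, 1.2)} and random
#' sign, and every edge carries a small quadratic term
#' (\eqn{U(-0.05, 0.05)}). Self-decay is shifted uniformly so the linear
#' part's spectral abscissa is negative (guaranteed stability); runs whose
#' trajectories still exceed a bound are resampled (capped retries).
#'
#' @param m number of genes.
#' @param n_edges number of true directed edges (no self-loops).
#' @param delta_sq per-observation Gaussian noise variance.
#' @param T number of time points (evenly spaced on `[0, t_max]`).
#' @param seed integer seed; the whole output is reproducible from it.
#' @param n_reps replicates per (treatment, time) cell.
#' @param t_max end of the time window.
#' @param amplitude scale of equilibria and initial values.
#' @param pair_frac fraction of the edge budget laid down as reciprocal
#'   pairs (capped by `m %/% 2` pairs).
#' @return a `ground_truth`: list with `edges` (data frame `from`, `to`,
#'   `b`), `adjacency` (logical m x m, `[i, iprime]` = edge iprime -> i),
#'   `params`, `times`, `trajectory` (m x T noiseless DTP), `dtp`
#'   (replicate-averaged noisy DTP), `dataset` (a `segnet_dataset`),
#'   `delta_sq`, `seed`.
#' @export
simulate_system <- function(m = 33L, n_edges = 45L, delta_sq = 0.01,
                            T = 30L, seed = 1L, n_reps = 2L, t_max = 8,
                            amplitude = 8, pair_frac = 0.75) {
  stopifnot(n_edges <= m * (m - 1L), delta_sq >= 0, T >= 2L, m >= 2L)
  set.seed(seed)
  ids <- sprintf("g%02d", seq_len(m))
  times <- seq(0, t_max, length.out = T)
  n_pairs <- min(floor(pair_frac * n_edges / 2), m %/% 2L, n_edges %/% 2L)
  ok <- FALSE
  for (try in seq_len(20L)) {
    n_single <- n_edges - 2L * n_pairs
    B <- matrix(0, m, m)
    perm <- sample(m)
    if (n_pairs > 0L) {
      pr <- matrix(perm[seq_len(2L * n_pairs)], ncol = 2L)
      cc <- runif(n_pairs, 0.5, 3)
      for (p in seq_len(n_pairs)) {
        B[pr[p, 1L], pr[p, 2L]] <- cc[p]
        B[pr[p, 2L], pr[p, 1L]] <- -cc[p]
      }
    }
    if (n_single > 0L) {
      empty <- which(B == 0 & diag(m) == 0)
      sgl <- sample(empty, n_single)
      B[sgl] <- sample(c(-1, 1), n_single, replace = TRUE) *
        runif(n_single, 0.5, 1.2)
    }
    A <- B != 0
    dimnames(A) <- list(ids, ids)                     # A[i, iprime]
    B2 <- matrix(0, m, m)
    B2[A] <- runif(sum(A), -0.05, 0.05)
    a_rate <- runif(m, 0.1, 0.35)
    a_eq <- runif(m, -amplitude, amplitude)
    # uniform damping shift: push the linear spectral abscissa below zero
    sh <- max(Re(eigen(B - diag(a_rate), only.values = TRUE)$values))
    if (sh > -0.05) a_rate <- a_rate + sh + 0.15
    g0 <- runif(m, -amplitude, amplitude)
    field <- function(t, g) a_rate * (a_eq - g) + drop(B %*% g) +
      drop(B2 %*% g^2)
    traj <- tryCatch(integrate_rk4(field, g0, times, h = t_max / 600),
                     error = function(e) NULL)
    if (!is.null(traj) && max(abs(traj)) <= 3 * amplitude + 3) {
      ok <- TRUE; break
    }
  }
  if (!ok) stop("simulate_system: dynamics kept diverging; lower n_edges")
  traj <- t(traj)                                     # genes x times
  dimnames(traj) <- list(ids, as.character(times))
  baseline <- runif(m, 5, 10)
  sd_e <- sqrt(delta_sq)
  cells <- vector("list", m); names(cells) <- ids
  for (i in seq_len(m)) {
    c1 <- lapply(seq_len(T), function(k) baseline[i] + rnorm(n_reps, 0, sd_e))
    c2 <- lapply(seq_len(T), function(k)
      baseline[i] + traj[i, k] + rnorm(n_reps, 0, sd_e))
    cells[[i]] <- list("1" = c1, "2" = c2)
  }
  dataset <- structure(list(entity_ids = ids, times = times, cells = cells,
                            n_reps = n_reps), class = "segnet_dataset")
  dtp <- plasticity_matrix(dataset)
  ei <- which(A, arr.ind = TRUE)
  edges <- data.frame(from = ids[ei[, 2L]], to = ids[ei[, 1L]],
                      b = B[ei])
  structure(list(edges = edges, adjacency = A,
                 params = list(a_rate = a_rate, a_eq = a_eq, B = B, B2 = B2,
                               g0 = g0, baseline = baseline),
                 times = times, trajectory = traj, dtp = dtp,
                 dataset = dataset, delta_sq = delta_sq, seed = seed),
            class = "ground_truth")
}

#' Score inferred edges against a ground truth
#'
#' Confusion counts over all ordered gene pairs (self-pairs excluded):
#' TPR = TP/(TP+FN), FPR = FP/(FP+TN).
#'
#' @param inferred data frame with `from`, `to` columns (e.g.
#'   [inferred_edges()]), or a logical adjacency matrix `[to, from]`.
#' @param truth a `ground_truth`.
#' @return list with TP, FP, TN, FN, TPR, FPR.
#' @export
score_recovery <- function(inferred, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  ids <- rownames(truth$adjacency)
  if (is.data.frame(inferred)) {
    if (nrow(inferred) &&
        !all(c(inferred$from, inferred$to) %in% ids)) {
      stop("score_recovery: inferred edges name unknown nodes")
    }
    P <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
    if (nrow(inferred)) P[cbind(inferred$to, inferred$from)] <- TRUE
  } else {
    if (!identical(dim(inferred), dim(truth$adjacency))) {
      stop("score_recovery: node-set mismatch")
    }
    P <- inferred
  }
  off <- !diag(length(ids))
  tpos <- truth$adjacency & off
  tp <- sum(P & tpos); fn <- sum(!P & tpos)
  fp <- sum(P & !tpos & off); tn <- sum(!P & !tpos & off)
  list(TP = tp, FP = fp, TN = tn, FN = fn,
       TPR = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       FPR = if (fp + tn > 0) fp / (fp + tn) else NA_real_)
}

#' ROC curve and AUC for edge scores
#'
#' Sweeps a threshold over the distinct scores (every ordered pair must be
#' scored; pairs never selected score 0) and traces (FPR, TPR); the AUC is
#' the trapezoid area, which equals the tie-corrected Mann--Whitney
#' statistic divided by `n_pos * n_neg`.
#'
#' @param scores numeric matrix `[target, regulator]` of edge scores (e.g.
#'   `segn_fit$score`), or a numeric vector aligned with `labels`.
#' @param truth a `ground_truth`, or a logical vector of labels when
#'   `scores` is a vector.
#' @return list with `auc` and `roc` (data frame `threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, truth) {
  if (is.matrix(scores)) {
    stopifnot(inherits(truth, "ground_truth"))
    off <- !diag(nrow(scores))
    s <- scores[off]
    y <- truth$adjacency[off]
  } else {
    s <- as.numeric(scores)
    y <- as.logical(truth)
    stopifnot(length(s) == length(y))
  }
  npos <- sum(y); nneg <- sum(!y)
  if (npos == 0L || nneg == 0L) {
    stop("roc_auc: AUC undefined when truth has a single class")
  }
  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- vapply(thr, function(th) sum(s >= th & y) / npos, numeric(1))
  fpr <- vapply(thr, function(th) sum(s >= th & !y) / nneg, numeric(1))
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  if (roc$fpr[nrow(roc)] < 1 || roc$tpr[nrow(roc)] < 1) {
    roc <- rbind(roc, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  list(auc = auc, roc = roc)
}

#' Run the edge-recovery simulation benchmark
#'
#' Generates `n_replicates` independent ground-truth systems, runs the full
#' inference pipeline on each noisy dataset, and scores edge recovery
#' (confusion counts, TPR, FPR and ROC/AUC). Per-replicate seeds are derived
#' deterministically from the master seed.
#'
#' @param n_replicates number of simulation replicates.
#' @param m,n_edges,delta_sq,T,t_max passed to [simulate_system()].
#' @param d_max,curve_order,q_order,n_starts,h_steps,max_iter passed to
#'   [infer_network()].
#' @param epsilon_frac relative zero-threshold for edge decisions.
#' @param seed master seed.
#' @param verbose print one line per replicate.
#' @return data frame with one row per replicate (`replicate`, `TP`, `FP`,
#'   `TN`, `FN`, `TPR`, `FPR`, `AUC`) plus attribute `"summary"` holding the
#'   across-replicate mean and SD of each column.
#' @export
run_benchmark <- function(n_replicates = 10L, m = 33L, n_edges = 45L,
                          delta_sq = 0.01, T = 30L, t_max = 8,
                          d_max = 5L, curve_order = "auto", q_order = 3L,
                          n_starts = 3L, h_steps = 150L, max_iter = 60L,
                          epsilon_frac = 0.05, seed = 1L, verbose = FALSE) {
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    rep_seed <- (seed * 1009L + r * 9973L) %% 2147483647L
    gt <- simulate_system(m = m, n_edges = n_edges, delta_sq = delta_sq,
                          T = T, seed = rep_seed, t_max = t_max)
    nv <- estimate_noise_variance(gt$dataset)
    fit <- infer_network(gt$dtp, gt$times, d_max = d_max,
                         curve_order = curve_order, q_order = q_order,
                         noise_var = nv, n_starts = n_starts,
                         h_steps = h_steps,
                         seed = rep_seed, max_iter = max_iter)
    ed <- inferred_edges(fit, epsilon_frac = epsilon_frac)
    sc <- score_recovery(ed, gt)
    auc <- roc_auc(fit$score, gt)$auc
    rows[[r]] <- data.frame(replicate = r, TP = sc$TP, FP = sc$FP,
                            TN = sc$TN, FN = sc$FN, TPR = sc$TPR,
                            FPR = sc$FPR, AUC = auc)
    if (verbose) {
      message(sprintf("replicate %d: TP %d FP %d TPR %.3f FPR %.4f AUC %.3f",
                      r, sc$TP, sc$FP, sc$TPR, sc$FPR, auc))
    }
  }
  out <- do.call(rbind, rows)
  summ <- rbind(mean = colMeans(out[, -1L]),
                sd = apply(out[, -1L], 2L, sd))
  attr(out, "summary") <- summ
  out
}
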