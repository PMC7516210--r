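#' Infer the full gene (or module) ODE network
#'
#' Runs the row-wise inference over every entity of a plasticity matrix:
#' stage-1 Legendre curve fits, group-lasso regulator selection against all
#' other entities, trajectory-matching ODE estimation, and decomposition
#' into independent and dependent integrals. In coarse-grained mode pass
#' module mean curves (rows = modules); in fine-grained mode pass the genes
#' of one module.
#'
#' @param dtp plasticity matrix, entities x time points (rownames required;
#'   column names give times unless `times` is supplied).
#' @param times measurement times.
#' @param d_max maximum regulators per target.
#' @param curve_order stage-1 Legendre order. The default `"auto"` scales
#'   with the series length (`max(4, min(16, T - 14))`): regulator selection
#'   needs stage-1 fits rich enough to preserve the distinctions between
#'   entity trajectories, while leaving residual degrees of freedom to gauge
#'   the noise. `"aic"` selects per entity over orders 2..6.
#' @param q_order component-function order.
#' @param noise_var per-observation noise variance (scalar or named per
#'   entity), e.g. from [estimate_noise_variance()]; `NULL` estimates it
#'   from stage-1 residuals.
#' @param n_starts,h_steps,seed,max_iter passed to [fit_ode()].
#' @return a `segn_fit`: list with `curves`, `fits`, `decomps` (all named by
#'   entity), `times`, and `score` — the matrix of dependent-integral
#'   magnitudes \eqn{|P_{ii'}(t_T)|} (rows = targets, columns = regulators;
#'   zero for unselected pairs) used for edge decisions and ROC scoring.
#' @export
infer_network <- function(dtp, times = as.numeric(colnames(dtp)), d_max = 5L,
                          curve_order = "auto", q_order = 3L,
                          noise_var = NULL, n_starts = 3L,
                          h_steps = 300L, seed = 1L, max_iter = 50L) {
  stopifnot(is.matrix(dtp), !is.null(rownames(dtp)), nrow(dtp) >= 2L)
  ids <- rownames(dtp)
  if (identical(curve_order, "auto")) {
    curve_order <- max(4L, min(16L, ncol(dtp) - 14L))
  }
  curves <- fit_plasticity_curves(dtp, times, order = curve_order)
  fits <- decomps <- vector("list", length(ids))
  names(fits) <- names(decomps) <- ids
  score <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  pmat <- score   # signed P_ii'(t_T)
  for (i in ids) {
    nv <- if (is.null(noise_var)) NULL else
      if (length(noise_var) > 1L) unname(noise_var[i]) else noise_var
    sel <- select_regulators(curves[[i]], curves[setdiff(ids, i)],
                             d_max = d_max, q_order = q_order,
                             noise_var = nv)
    fits[[i]] <- fit_ode(dtp[i, ], times, regulator_curves = curves[sel],
                         q_order = q_order,
                         target_order = curves[[i]]$order,
                         n_starts = n_starts, h_steps = h_steps,
                         seed = seed, target_id = i, max_iter = max_iter)
    decomps[[i]] <- decompose(fits[[i]], n_grid = h_steps)
    if (length(sel)) {
      pT <- decomps[[i]]$p_dep[nrow(decomps[[i]]$p_dep), ]
      pmat[i, names(pT)] <- pT
      score[i, names(pT)] <- abs(pT)
    }
  }
  structure(list(curves = curves, fits = fits, decomps = decomps,
                 times = times, score = score, p_final = pmat),
            class = "segn_fit")
}

#' @export
print.segn_fit <- function(x, ...) {
  nsel <- vapply(x$fits, function(f) length(f$regulators), 1L)
  cat(sprintf("segn_fit: %d entities, %d selected edges\n",
              length(x$fits), sum(nsel)))
  invisible(x)
}

#' Edge decisions from a fitted network
#'
#' A directed edge \eqn{i' \to i} is declared when \eqn{i'} was selected by
#' variable selection for target \eqn{i} and \eqn{|P_{ii'}(t_T)|} exceeds
#' the zero-threshold. The default threshold is relative to the dominant
#' fitted plasticity magnitude (`epsilon_frac * max |ĝ|` over all targets
#' and times): a regulator must contribute at least that share of the
#' strongest trajectory to count as an edge. This scale is stable because
#' fitted trajectories are bounded by the data, whereas individual
#' dependent integrals can take extreme values when two components nearly
#' cancel.
#'
#' @param fit a `segn_fit`.
#' @param epsilon zero-threshold; `NULL` applies the relative default.
#' @param epsilon_frac fraction for the relative default.
#' @return data frame `from`, `to`, `weight` (signed \eqn{P_{ii'}(t_T)}).
#' @export
inferred_edges <- function(fit, epsilon = NULL, epsilon_frac = 0.05) {
  stopifnot(inherits(fit, "segn_fit"))
  if (is.null(epsilon)) {
    traj_scale <- max(vapply(fit$decomps, function(d) max(abs(d$g_hat)),
                             numeric(1)))
    epsilon <- epsilon_frac * traj_scale
  }
  idx <- which(fit$score > epsilon, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(from = character(0), to = character(0),
                      weight = numeric(0)))
  }
  data.frame(from = rownames(fit$score)[idx[, 2L]],
             to = rownames(fit$score)[idx[, 1L]],
             weight = fit$p_final[idx])
}
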