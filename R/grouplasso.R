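# Group-lasso solver by block coordinate descent.
#
# Minimizes  0.5 * ||y - X0 b0 - sum_g X_g b_g||^2 + lambda * sum_g sqrt(p_g) ||b_g||
# where X0 is an unpenalized block. Each penalized group is orthonormalized
# (thin QR) so the block update has the closed form groupwise soft-threshold;
# coefficients are mapped back to the original scale afterwards.

group_lasso_path <- function(y, X0, groups, lambda = NULL, n_lambda = 30L,
                             lambda_min_ratio = 1e-3, max_iter = 200L,
                             tol = 1e-7) {
  n <- length(y)
  G <- length(groups)
  P0 <- if (!is.null(X0) && ncol(X0) > 0L) {
    q0 <- qr(X0)
    function(v) qr.fitted(q0, v)
  } else function(v) 0 * v
  # profile out the unpenalized block, then orthonormalize each group within
  # the complement (thin QR, rank-deficient directions dropped) so the block
  # update is an exact groupwise soft-threshold
  y_t <- y - P0(y)
  qrs <- lapply(groups, function(X) {
    Xp <- X - apply(X, 2L, P0)
    qd <- qr(Xp)
    if (qd$rank == 0L) {  # group lies in the unpenalized span: dead group
      return(list(Q = matrix(0, length(y), 1L), rank = 1L, p = ncol(X)))
    }
    list(Q = qr.Q(qd)[, seq_len(qd$rank), drop = FALSE], rank = qd$rank,
         p = ncol(X))
  })
  Qs <- lapply(qrs, `[[`, "Q")
  pg <- vapply(qrs, function(q) q$p, 1L)
  w <- sqrt(pg)

  if (is.null(lambda)) {
    lam_max <- max(vapply(seq_len(G), function(g)
      sqrt(sum(crossprod(Qs[[g]], y_t)^2)) / w[g], numeric(1)))
    lam_max <- max(lam_max, 1e-12)
    lambda <- exp(seq(log(lam_max * 1.0001), log(lam_max * lambda_min_ratio),
                      length.out = n_lambda))
  }
  beta <- lapply(seq_len(G), function(g) numeric(qrs[[g]]$rank))
  r <- y_t
  fits <- vector("list", length(lambda))
  for (li in seq_along(lambda)) {
    lam <- lambda[li]
    for (it in seq_len(max_iter)) {
      delta <- 0
      for (g in seq_len(G)) {
        Qg <- Qs[[g]]
        z <- crossprod(Qg, r) + beta[[g]]
        nz <- sqrt(sum(z^2))
        new_b <- if (nz <= lam * w[g]) numeric(length(z)) else
          drop(z) * (1 - lam * w[g] / nz)
        db <- new_b - beta[[g]]
        if (any(db != 0)) {
          r <- r - Qg %*% db
          delta <- max(delta, max(abs(db)))
          beta[[g]] <- new_b
        }
      }
      if (delta < tol) break
    }
    norms <- vapply(beta, function(b) sqrt(sum(b^2)), numeric(1))
    rss <- sum((y_t - Reduce(`+`, Map(function(Q, b) Q %*% b, Qs, beta),
                             accumulate = FALSE))^2)
    df <- sum(vapply(seq_len(G), function(g)
      if (norms[g] > 0) qrs[[g]]$rank else 0L, numeric(1))) +
      (if (!is.null(X0)) ncol(X0) else 0L)
    fits[[li]] <- list(lambda = lam, norms = norms, rss = rss, df = df,
                       beta = beta)
  }
  list(lambda = lambda, fits = fits, n = n, qrs = qrs)
}

# BIC over the path: n log(rss/n) + log(n) df
group_lasso_bic <- function(path) {
  n <- path$n
  vapply(path$fits, function(f)
    n * log(max(f$rss, 1e-300) / n) + log(n) * f$df, numeric(1))
}

#' Select the significant regulators of a focal entity
#'
#' Sparse regulator discovery for one row of the ODE system, by integral
#' (antiderivative) matching: over each interval between consecutive design
#' times, the observed increment of the focal series is regressed on the
#' integrated Legendre expansions of every candidate curve's value, with the
#' focal entity's own integrated value entering unpenalized as the
#' independent-term screen. Matching increments of the integrated equation,
#' rather than pointwise derivatives, avoids differentiating a noisy fit and
#' keeps the regression errors at the observation-noise scale.
#'
#' The subset is chosen by best-subset search (greedy forward additions
#' followed by swap/drop refinement) under the extended BIC
#' \deqn{\mathrm{EBIC} = \mathrm{RSS}/\sigma^2 + \log(n)\,\mathrm{df}
#'   + 2 \log(p)\, k,}
#' with \eqn{n} the number of design times, \eqn{p} the number of candidate
#' groups and \eqn{k} the number of selected groups; the \eqn{2\log p} term
#' guards against false selections among many correlated candidates. The
#' noise scale \eqn{\sigma^2} (variance of one observed increment,
#' \eqn{2\times} the per-observation noise variance) is taken from
#' `noise_var` when supplied, otherwise estimated from the stage-1 curve-fit
#' residuals, and is then calibrated for overdispersion: if even a generous
#' pilot model (the `d_max` individually best candidates together) cannot
#' bring the residual down to the noise floor, the excess — typically
#' smoothing error propagated from the stage-1 fits — inflates
#' \eqn{\sigma^2} by the quasi-likelihood factor
#' \eqn{\hat\phi = \max(1, \mathrm{RSS}_{pilot}/(\sigma^2 df))}.
#'
#' The default search (`method = "dual"`) refines two starting supports —
#' the empty set (pure greedy) and the best support along a group-lasso
#' path — and keeps whichever refined subset scores the lower EBIC;
#' `"greedy"` and `"grouplasso"` force a single strategy.
#'
#' Candidate expansions use Legendre orders 1..`q_order` only: a constant
#' term in a dependent component is not attributable to any particular
#' regulator (it is absorbed by the independent term), so it is excluded for
#' identifiability. `d_max` caps the regulator count; network theory limits
#' the number of links a node can sustain, which is what the bound encodes.
#'
#' @param target_curve [lop_curve()] of the focal entity, as returned by
#'   [fit_lop_curve()] (it must carry its design data).
#' @param candidate_curves named list of [lop_curve()] for candidate
#'   regulators (the focal entity must not be among them).
#' @param d_max maximum number of regulators retained.
#' @param q_order Legendre order of the component-function expansions.
#' @param noise_var per-observation noise variance of the target series
#'   (e.g. estimated from replicates); `NULL` falls back to the stage-1
#'   residual variance.
#' @param method `"dual"` (default), `"greedy"` or `"grouplasso"`.
#' @param n_grid resolution of the quadrature grid for the integrals.
#' @return character vector of selected candidate names (strongest first by
#'   fitted contribution norm), with attribute `"group_norms"` (named over
#'   all candidates: contribution norms in the final refit, zero for
#'   unselected).
#' @export
select_regulators <- function(target_curve, candidate_curves, d_max = 5L,
                              q_order = 3L, noise_var = NULL,
                              method = c("dual", "greedy", "grouplasso"),
                              n_grid = 301L) {
  method <- match.arg(method)
  stopifnot(inherits(target_curve, "lop_curve"), length(candidate_curves) >= 1L,
            d_max >= 0L)
  empty_out <- function() {
    out <- character(0)
    attr(out, "group_norms") <- setNames(rep(0, length(candidate_curves)),
                                         names(candidate_curves))
    out
  }
  if (d_max == 0L) return(empty_out())
  if (is.null(target_curve$data_values)) {
    stop("select_regulators: target curve carries no design data; ",
         "fit it with fit_lop_curve()")
  }
  times <- target_curve$data_times
  values <- target_curve$data_values
  TT <- length(times)
  if (diff(range(values)) < 1e-10) {
    warning("select_regulators: degenerate (constant) target series")
    return(empty_out())
  }
  if (is.null(noise_var)) {
    df <- max(TT - (target_curve$order + 1L), 1L)
    noise_var <- max(target_curve$rss / df, 1e-12)
  }
  sigma2 <- 2 * noise_var          # variance of one observed increment
  tt <- seq(times[1L], times[TT], length.out = n_grid)
  di <- vapply(times, function(x) which.min(abs(tt - x)), 1L)
  y <- diff(values)
  gv <- predict(target_curve, tt)
  X0 <- cbind(diff(tt[di]), diff(cumtrapz(gv, tt)[di]))
  groups <- lapply(candidate_curves, function(cv) {
    v <- predict(cv, tt)
    Bm <- dep_basis(v, min(v), max(v), q_order)
    apply(apply(Bm, 2L, cumtrapz, tt = tt)[di, , drop = FALSE], 2L, diff)
  })
  p_cand <- length(groups)
  # quasi-likelihood overdispersion: gauge the achievable residual floor
  # from a pilot model holding the d_max individually strongest candidates
  if (p_cand > 0L) {
    rss1 <- vapply(names(groups), function(j)
      sum(qr.resid(qr(cbind(X0, groups[[j]])), y)^2), numeric(1))
    pilot <- names(sort(rss1))[seq_len(min(d_max, p_cand))]
    Xf <- do.call(cbind, c(list(X0), groups[pilot]))
    dff <- length(y) - ncol(Xf)
    if (dff > 2L) {
      phi <- max(1, sum(qr.resid(qr(Xf), y)^2) / (sigma2 * dff))
      sigma2 <- sigma2 * phi
    }
  }
  critf <- function(sel) {
    Xs <- do.call(cbind, c(list(X0), groups[sel]))
    sum(qr.resid(qr(Xs), y)^2) / sigma2 + log(TT) * ncol(Xs) +
      2 * log(p_cand) * length(sel)
  }
  lasso_start <- function() {
    path <- group_lasso_path(y, X0, groups)
    best <- character(0); bc <- critf(character(0)); seen <- ""
    for (f in path$fits) {
      sup <- names(groups)[f$norms > 1e-10]
      if (length(sup) > d_max) break
      key <- paste(sort(sup), collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      cc <- critf(sup)
      if (cc < bc) { bc <- cc; best <- sup }
    }
    best
  }
  sel <- switch(method,
    greedy = refine_subset(character(0), critf, names(groups), d_max),
    grouplasso = refine_subset(lasso_start(), critf, names(groups), d_max),
    dual = {
      s1 <- refine_subset(character(0), critf, names(groups), d_max)
      s2 <- refine_subset(lasso_start(), critf, names(groups), d_max)
      if (critf(s2) < critf(s1)) s2 else s1
    })
  # order by fitted contribution norm in the final refit
  norms <- setNames(rep(0, p_cand), names(groups))
  if (length(sel)) {
    Xs <- do.call(cbind, c(list(X0), groups[sel]))
    cf <- qr.coef(qr(Xs), y); cf[is.na(cf)] <- 0
    off <- ncol(X0)
    for (k in seq_along(sel)) {
      idx <- off + (k - 1L) * q_order + seq_len(q_order)
      norms[sel[k]] <- sqrt(sum((do.call(cbind, groups[sel[k]]) %*%
                                   cf[idx])^2))
    }
    sel <- names(sort(norms[sel], decreasing = TRUE))
  }
  attr(sel, "group_norms") <- norms
  sel
}

# greedy forward additions + swap/drop refinement of a candidate subset
# under an arbitrary criterion (smaller is better)
refine_subset <- function(sel, critf, cand_names, d_max) {
  crit <- critf(sel)
  repeat {
    if (length(sel) >= d_max) break
    rem <- setdiff(cand_names, sel)
    if (!length(rem)) break
    cand <- vapply(rem, function(j) critf(c(sel, j)), numeric(1))
    if (min(cand) >= crit - 1e-9) break
    sel <- c(sel, names(which.min(cand))); crit <- min(cand)
  }
  improved <- TRUE
  while (improved && length(sel)) {
    improved <- FALSE
    for (sidx in seq_along(sel)) {
      rem <- setdiff(cand_names, sel)
      cand <- if (length(rem))
        vapply(rem, function(j) critf(replace(sel, sidx, j)), numeric(1))
      else Inf
      dropc <- critf(sel[-sidx])
      if (min(c(cand, dropc)) < crit - 1e-9) {
        if (dropc <= min(cand)) sel <- sel[-sidx]
        else sel <- replace(sel, sidx, names(which.min(cand)))
        crit <- min(c(cand, dropc)); improved <- TRUE
        break
      }
    }
    if (!improved && length(sel) < d_max) {
      rem <- setdiff(cand_names, sel)
      if (length(rem)) {
        cand <- vapply(rem, function(j) critf(c(sel, j)), numeric(1))
        if (min(cand) < crit - 1e-9) {
          sel <- c(sel, names(which.min(cand))); crit <- min(cand)
          improved <- TRUE
        }
      }
    }
  }
  sel
}

# cumulative trapezoid integral along tt, starting at 0
cumtrapz <- function(v, tt) {
  c(0, cumsum((v[-length(v)] + v[-1L]) / 2 * diff(tt)))
}

# affine map of a value vector onto [-1, 1] by its own range; constants map
# to 0. Used to feed expression values into Legendre component functions.
rescale_to_range <- function(v, lo = min(v), hi = max(v)) {
  if (hi - lo < 1e-12) return(rep(0, length(v)))
  (2 * v - (lo + hi)) / (hi - lo)
}
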