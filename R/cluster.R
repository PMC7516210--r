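#' Functional clustering of plasticity trajectories
#'
#' Groups genes into functional modules by fitting a finite mixture over whole
#' plasticity time courses. The default emission is Skellam — plasticity is a
#' difference of (averaged) expression counts, modelled as the difference of
#' two Poisson variables whose intensity curves are Legendre expansions passed
#' through a softplus positivity link. A Gaussian emission is available for
#' data that are not count-like. Fitting is by (generalized) EM: the M-step
#' takes a bounded quasi-Newton improvement step from the current parameters,
#' so the observed-data log-likelihood never decreases.
#'
#' @param dtp numeric matrix, genes x time points; column names give times
#'   unless `times` is supplied. Values are rounded to integers for the
#'   Skellam emission.
#' @param L number of modules (mixture components).
#' @param times measurement times.
#' @param lop_order Legendre order of the per-module intensity (or mean)
#'   curves.
#' @param emission `"skellam"` or `"gaussian"`.
#' @param n_restarts random restarts (k-means based initialization).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap.
#' @param seed integer seed for initialization.
#' @return a `module_partition`: list with `L`, `weights`, `params` (per
#'   module), `assignment` (argmax posterior, integer per gene), `posterior`
#'   (genes x L), `mean_dtp` (L x T module mean curves, Skellam mean
#'   \eqn{\mu_1(t) - \mu_2(t)}), `loglik`, `aic`, `times`, `emission`.
#' @export
em_cluster <- function(dtp, L, times = as.numeric(colnames(dtp)),
                       lop_order = 3L, emission = c("skellam", "gaussian"),
                       n_restarts = 5L, tol = 1e-6, max_iter = 500L,
                       seed = 1L) {
  emission <- match.arg(emission)
  stopifnot(is.matrix(dtp), L >= 1L, nrow(dtp) >= L,
            length(times) == ncol(dtp))
  G <- nrow(dtp); TT <- ncol(dtp)
  Y <- if (emission == "skellam") round(dtp) else dtp
  x <- (2 * times - (times[1L] + times[TT])) / (times[TT] - times[1L])
  B <- legendre_basis(x, lop_order)
  p <- lop_order + 1L

  # per-gene LOP coefficients drive the k-means initialization
  gene_coef <- t(apply(dtp, 1L, function(v) {
    fit_lop_curve(v, times, min(lop_order, TT - 1L))$coefficients
  }))
  if (is.vector(gene_coef)) gene_coef <- matrix(gene_coef, ncol = 1L)

  loglik_matrix <- function(params) {
    ll <- matrix(0, G, L)
    for (c in seq_len(L)) {
      if (emission == "skellam") {
        mu1 <- softplus(drop(B %*% params[[c]]$a1))
        mu2 <- softplus(drop(B %*% params[[c]]$a2))
        v <- skellam_logpmf(as.vector(t(Y)), rep_len(mu1, G * TT),
                            rep_len(mu2, G * TT))
        ll[, c] <- rowSums(matrix(v, G, TT, byrow = TRUE))
      } else {
        m <- drop(B %*% params[[c]]$coef)
        s <- params[[c]]$sigma
        ll[, c] <- rowSums(dnorm(t(t(Y) - m), mean = 0, sd = s, log = TRUE))
      }
    }
    ll
  }

  init_params <- function(assign0) {
    lapply(seq_len(L), function(c) {
      idx <- which(assign0 == c)
      mbar <- if (length(idx) > 1L) colMeans(Y[idx, , drop = FALSE]) else
        Y[idx[1L], ]
      if (emission == "skellam") {
        mu1 <- pmax(mbar, 0) + 1; mu2 <- pmax(-mbar, 0) + 1
        list(a1 = qr.coef(qr(B), inv_softplus(mu1)),
             a2 = qr.coef(qr(B), inv_softplus(mu2)))
      } else {
        cf <- qr.coef(qr(B), mbar)
        res <- t(t(Y[idx, , drop = FALSE]) - drop(B %*% cf))
        list(coef = cf, sigma = max(sd(as.vector(res)), 0.05))
      }
    })
  }

  mstep_component <- function(par_c, w) {
    if (emission == "skellam") {
      obj <- function(theta) {
        mu1 <- softplus(drop(B %*% theta[1:p]))
        mu2 <- softplus(drop(B %*% theta[(p + 1):(2 * p)]))
        if (any(mu1 <= 0) || any(mu2 <= 0)) return(1e10)
        v <- skellam_logpmf(as.vector(t(Y)), rep_len(mu1, G * TT),
                            rep_len(mu2, G * TT))
        -sum(w * rowSums(matrix(v, G, TT, byrow = TRUE)))
      }
      th0 <- c(par_c$a1, par_c$a2)
      opt <- tryCatch(
        optim(th0, obj, method = "BFGS", control = list(maxit = 25L)),
        error = function(e) list(par = th0, value = obj(th0)))
      if (obj(th0) < opt$value) opt$par <- th0  # never move downhill
      list(a1 = opt$par[1:p], a2 = opt$par[(p + 1):(2 * p)])
    } else {
      # weighted least squares for the mean curve, then pooled variance
      num <- crossprod(B, colSums(w * Y)) ; den <- crossprod(B) * sum(w)
      cf <- solve(den, num)
      res2 <- t(t(Y) - drop(B %*% cf))^2
      list(coef = drop(cf), sigma = sqrt(max(sum(w * rowSums(res2)) /
                                               (sum(w) * TT), 1e-6)))
    }
  }

  run_once <- function(rs) {
    assign0 <- if (L == 1L) rep(1L, G) else {
      km <- tryCatch(kmeans(gene_coef, centers = L, nstart = 3L),
                     error = function(e) NULL)
      if (is.null(km)) sample(rep_len(seq_len(L), G)) else km$cluster
    }
    if (length(unique(assign0)) < L) assign0 <- rep_len(seq_len(L), G)
    params <- init_params(assign0)
    weights <- as.numeric(table(factor(assign0, levels = seq_len(L)))) / G
    weights <- pmax(weights, 1e-6); weights <- weights / sum(weights)
    ll_prev <- -Inf; post <- NULL; ll_obs <- NA_real_
    for (it in seq_len(max_iter)) {
      lm <- loglik_matrix(params)
      a <- sweep(lm, 2L, log(weights), "+")
      mx <- apply(a, 1L, max)
      lse <- mx + log(rowSums(exp(a - mx)))
      ll_obs <- sum(lse)
      post <- exp(a - lse)
      if (any(colSums(post) < 1e-8)) return(NULL)  # empty cluster -> restart
      weights <- colMeans(post)
      for (c in seq_len(L)) params[[c]] <- mstep_component(params[[c]], post[, c])
      if (is.finite(ll_prev) &&
          abs(ll_obs - ll_prev) < tol * (abs(ll_prev) + 1e-8)) break
      ll_prev <- ll_obs
    }
    list(params = params, weights = weights, post = post, loglik = ll_obs)
  }

  best <- NULL
  set.seed(seed)
  for (rs in seq_len(max(n_restarts, 1L))) {
    fit <- run_once(rs)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) best <- fit
  }
  if (is.null(best)) stop("em_cluster: all restarts produced empty clusters")

  mean_dtp <- t(vapply(best$params, function(pc) {
    if (emission == "skellam") {
      softplus(drop(B %*% pc$a1)) - softplus(drop(B %*% pc$a2))
    } else drop(B %*% pc$coef)
  }, numeric(TT)))
  n_free <- if (emission == "skellam") (L - 1L) + L * 2L * p else
    (L - 1L) + L * (p + 1L)
  structure(
    list(L = L, weights = best$weights, params = best$params,
         assignment = max.col(best$post), posterior = best$post,
         mean_dtp = mean_dtp, loglik = best$loglik,
         aic = -2 * best$loglik + 2 * n_free,
         n_free = n_free, times = times, lop_order = lop_order,
         emission = emission, gene_ids = rownames(dtp)),
    class = "module_partition"
  )
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d genes in %d modules (%s emission)\n",
              nrow(x$posterior), x$L, x$emission))
  cat(sprintf("log-likelihood %.3f, AIC %.3f\n", x$loglik, x$aic))
  print(table(module = x$assignment))
  invisible(x)
}

#' Select the number of modules by AIC
#'
#' Fits [em_cluster()] for each candidate module count and returns the
#' partition minimizing \eqn{\mathrm{AIC} = -2 \log\hat L + 2 q}, where the
#' free-parameter count is \eqn{q = (L - 1) + 2 L (r + 1)} for the Skellam
#' emission (mixture weights plus two intensity curves per module).
#'
#' @param dtp,times,lop_order,emission,seed,... passed to [em_cluster()].
#' @param L_range candidate module counts.
#' @return the best `module_partition`; the AIC profile is attached as
#'   attribute `"aic_profile"`.
#' @export
select_module_count <- function(dtp, L_range = 1:6,
                                times = as.numeric(colnames(dtp)),
                                lop_order = 3L, emission = "skellam",
                                seed = 1L, ...) {
  stopifnot(length(L_range) >= 1L)
  fits <- list(); aics <- rep(NA_real_, length(L_range))
  for (k in seq_along(L_range)) {
    fits[[k]] <- tryCatch(
      em_cluster(dtp, L_range[k], times = times, lop_order = lop_order,
                 emission = emission, seed = seed + k, ...),
      error = function(e) NULL)
    if (!is.null(fits[[k]])) aics[k] <- fits[[k]]$aic
  }
  if (all(is.na(aics))) stop("select_module_count: every fit failed")
  best <- fits[[which.min(aics)]]
  attr(best, "aic_profile") <- data.frame(L = L_range, aic = aics)
  best
}

#' Module mean curves as Legendre fits
#'
#' @param partition a `module_partition`.
#' @param order Legendre order for the refit of the module mean values.
#' @return named list of [lop_curve()], one per module.
#' @export
module_curves <- function(partition, order = partition$lop_order) {
  stopifnot(inherits(partition, "module_partition"))
  out <- lapply(seq_len(partition$L), function(c) {
    fit_lop_curve(partition$mean_dtp[c, ], partition$times, order)
  })
  names(out) <- paste0("module_", seq_len(partition$L))
  out
}
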