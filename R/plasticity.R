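#' Compute dynamic plasticity from a two-treatment time course
#'
#' Plasticity at each time point is the mean over replicates under treatment 2
#' (stress) minus the mean over replicates under treatment 1 (control). For a
#' gene this is its dynamic transcriptional plasticity (DTP)
#' \eqn{y_i(t) = Y_{i2}(t) - Y_{i1}(t)}; for a phenotypic trait its dynamic
#' phenotypic plasticity (DPP) \eqn{z_j(t)}. Replicates are averaged within
#' each (treatment, time) cell before differencing: clonal replicates are
#' exchangeable, so no pairing is assumed.
#'
#' @param series_t1,series_t2 lists of numeric vectors, one vector of
#'   replicate values per time point, under treatment 1 and 2 respectively.
#'   Both must cover the same time grid (same length, same order).
#' @param entity_id identifier attached to the result.
#' @param kind `"gene"` or `"trait"`.
#' @return a `plasticity_series`: list with `entity_id`, `values` (one per
#'   time point) and `kind`.
#' @examples
#' compute_plasticity(list(c(1, 3), 3, 4), list(c(4, 6), 7, 9))$values
#' @export
compute_plasticity <- function(series_t1, series_t2, entity_id = "entity",
                               kind = c("gene", "trait")) {
  kind <- match.arg(kind)
  if (length(series_t1) != length(series_t2)) {
    stop("compute_plasticity: treatments cover different time grids")
  }
  n1 <- vapply(series_t1, length, 1L); n2 <- vapply(series_t2, length, 1L)
  if (any(n1 == 0L) || any(n2 == 0L)) {
    stop(sprintf("compute_plasticity: empty replicate cell at time index %d",
                 which(n1 == 0L | n2 == 0L)[1L]))
  }
  m1 <- vapply(series_t1, mean, numeric(1))
  m2 <- vapply(series_t2, mean, numeric(1))
  vals <- m2 - m1
  if (any(!is.finite(vals))) stop("compute_plasticity: non-finite values")
  structure(list(entity_id = entity_id, values = vals, kind = kind),
            class = "plasticity_series")
}

#' Plasticity matrix from a validated expression dataset
#'
#' Applies [compute_plasticity()] to every entity of a dataset returned by
#' [read_expression()].
#'
#' @param dataset a `segnet_dataset`.
#' @return numeric matrix, entities in rows, time points in columns (named by
#'   time).
#' @export
plasticity_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "segnet_dataset"))
  times <- dataset$times
  out <- matrix(NA_real_, length(dataset$entity_ids), length(times),
                dimnames = list(dataset$entity_ids, as.character(times)))
  for (e in dataset$entity_ids) {
    s1 <- lapply(seq_along(times), function(k) dataset$cells[[e]][["1"]][[k]])
    s2 <- lapply(seq_along(times), function(k) dataset$cells[[e]][["2"]][[k]])
    out[e, ] <- compute_plasticity(s1, s2, e)$values
  }
  out
}

#' Estimate the noise variance of a plasticity series from replicates
#'
#' The variance of the replicate-averaged treatment difference at one time
#' point is \eqn{s_1^2/R_1 + s_2^2/R_2}; pooling the within-cell sample
#' variances over times gives a per-entity estimate of the plasticity
#' noise variance that is independent of any curve fit.
#'
#' @param dataset a `segnet_dataset`.
#' @return named numeric vector, one variance per entity. Entities without
#'   any replicated cell get `NA`.
#' @export
estimate_noise_variance <- function(dataset) {
  stopifnot(inherits(dataset, "segnet_dataset"))
  out <- setNames(rep(NA_real_, length(dataset$entity_ids)),
                  dataset$entity_ids)
  for (e in dataset$entity_ids) {
    v <- c()
    for (k in seq_along(dataset$times)) {
      r1 <- dataset$cells[[e]][["1"]][[k]]
      r2 <- dataset$cells[[e]][["2"]][[k]]
      if (length(r1) > 1L && length(r2) > 1L) {
        v <- c(v, var(r1) / length(r1) + var(r2) / length(r2))
      }
    }
    if (length(v)) out[e] <- mean(v)
  }
  out
}

#' Fit smooth curves to every row of a plasticity matrix
#'
#' @param dtp plasticity matrix (entities x times), column names giving times,
#'   or numeric times passed via `times`.
#' @param times measurement times; defaults to numeric column names.
#' @param order Legendre order, or `"aic"` to select per entity over 2..6.
#' @return named list of [lop_curve()] objects.
#' @export
fit_plasticity_curves <- function(dtp, times = as.numeric(colnames(dtp)),
                                  order = 4L) {
  stopifnot(is.matrix(dtp), length(times) == ncol(dtp))
  curves <- vector("list", nrow(dtp))
  names(curves) <- rownames(dtp)
  for (i in seq_len(nrow(dtp))) {
    curves[[i]] <- if (identical(order, "aic")) {
      select_lop_order(dtp[i, ], times)
    } else {
      fit_lop_curve(dtp[i, ], times, order)
    }
  }
  curves
}
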