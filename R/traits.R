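#' Fit the trait-level causal ODE system
#'
#' Each phenotypic trait's plasticity obeys
#' \deqn{du_j/dt = R_j(u_j) + \sum_{j'} R_{jj'}(u_{j'}) + \sum_i S_{ji}(g_i),}
#' decomposing its change into an independent component, dependent
#' components from other traits, and dependent components from gene (or
#' module mean) expression curves. Selection and estimation reuse the gene
#' machinery ([select_regulators()], [fit_ode()]) with the candidate pool
#' being all other traits plus all supplied gene/module curves — variable
#' selection runs jointly over the pooled candidates.
#'
#' @param dpp numeric matrix of trait plasticity, traits x time points
#'   (column names give times unless `times` is supplied).
#' @param gene_curves named list of [lop_curve()] for gene or module mean
#'   curves entering the \eqn{S_{ji}} terms.
#' @param times measurement times.
#' @param d_max maximum number of selected predictors per trait.
#' @param q_order,target_order,n_starts,h_steps,seed passed to [fit_ode()].
#' @param curve_order Legendre order of the stage-1 trait curve fits.
#' @return named list (one element per trait) of lists with the `ode_fit`
#'   (`fit`), its [decompose()] result (`decomp`), and the predictor kinds
#'   (`kind`: `"trait"` or `"gene"` per selected regulator).
#' @export
fit_trait_system <- function(dpp, gene_curves = list(),
                             times = as.numeric(colnames(dpp)), d_max = 5L,
                             q_order = 3L, curve_order = 4L,
                             target_order = curve_order, n_starts = 4L,
                             h_steps = 300L, seed = 1L) {
  stopifnot(is.matrix(dpp), !is.null(rownames(dpp)),
            length(times) == ncol(dpp))
  trait_ids <- rownames(dpp)
  trait_curves <- fit_plasticity_curves(dpp, times,
                                        order = min(curve_order, ncol(dpp) - 1L))
  out <- vector("list", length(trait_ids)); names(out) <- trait_ids
  for (j in trait_ids) {
    cands <- c(trait_curves[setdiff(trait_ids, j)], gene_curves)
    sel <- select_regulators(trait_curves[[j]], cands, d_max = d_max,
                             q_order = q_order)
    fit <- fit_ode(dpp[j, ], times, regulator_curves = cands[sel],
                   q_order = q_order,
                   target_order = min(target_order, ncol(dpp) - 1L),
                   n_starts = n_starts, h_steps = h_steps,
                   seed = seed, target_id = j)
    dec <- decompose(fit, n_grid = h_steps)
    kind <- ifelse(sel %in% trait_ids, "trait", "gene")
    out[[j]] <- list(fit = fit, decomp = dec,
                     kind = setNames(kind, sel))
  }
  out
}

#' Causal gene/module-to-trait edge table
#'
#' @param trait_fits result of [fit_trait_system()].
#' @param t snapshot time (defaults to the end of the window).
#' @param epsilon zero-threshold on \eqn{|P|}; default 0 keeps all selected
#'   edges.
#' @return data frame: `source_kind`, `source`, `target_trait`, `weight`,
#'   `sign`.
#' @export
causal_edge_table <- function(trait_fits, t = NULL, epsilon = 0) {
  rows <- list()
  for (j in names(trait_fits)) {
    dec <- trait_fits[[j]]$decomp
    tt <- if (is.null(t)) max(dec$time) else t
    pv <- p_dep_at(dec, tt)
    for (src in names(pv)) {
      if (abs(pv[[src]]) > epsilon) {
        rows[[length(rows) + 1L]] <- data.frame(
          source_kind = unname(trait_fits[[j]]$kind[src]), source = src,
          target_trait = j, weight = unname(pv[[src]]),
          sign = sign(unname(pv[[src]])))
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(source_kind = character(0), source = character(0),
                      target_trait = character(0), weight = numeric(0),
                      sign = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Layer upstream genes by distance to the causal set
#'
#' Genes with a direct edge into a trait form layer 0 of the hierarchy;
#' every other gene's layer is its shortest directed-path distance (along
#' the gene network's edges, following edge direction) to any causal gene.
#' Genes with no directed path to the causal set are flagged unreachable.
#'
#' @param network a gene-level `signed_network`.
#' @param causal_genes character vector of genes with direct trait edges
#'   (must be a subset of the network's nodes).
#' @return data frame: `id`, `layer` (integer, `NA` when unreachable),
#'   `reachable`.
#' @export
layer_upstream <- function(network, causal_genes) {
  stopifnot(inherits(network, "signed_network"))
  ids <- network$nodes$id
  if (!all(causal_genes %in% ids)) {
    stop("layer_upstream: causal set contains unknown nodes")
  }
  if (!length(causal_genes)) {
    return(data.frame(id = ids, layer = NA_integer_, reachable = FALSE))
  }
  g <- as_igraph(network)
  d <- igraph::distances(g, v = ids, to = causal_genes, mode = "out",
                         weights = NA)
  layer <- apply(d, 1L, min)
  lay_int <- rep(NA_integer_, length(layer))
  lay_int[is.finite(layer)] <- as.integer(layer[is.finite(layer)])
  data.frame(id = ids, layer = lay_int, reachable = is.finite(layer))
}
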