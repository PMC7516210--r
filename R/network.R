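#' The eleven interaction classes
#'
#' @return character vector of the class labels.
#' @export
edge_classes <- function() c(
  "symmetric_synergism", "asymmetric_synergism",
  "directional_synergism_toward_i", "directional_synergism_toward_iprime",
  "altruism_toward_i", "altruism_toward_iprime",
  "symmetric_antagonism", "asymmetric_antagonism",
  "directional_antagonism_toward_i", "directional_antagonism_toward_iprime",
  "coexistence")

#' Classify a gene pair from its dependent expression levels
#'
#' Maps the pair of cumulative dependent expression levels
#' (\eqn{P_{ii'}(t)}: the effect of gene \eqn{i'} on gene \eqn{i};
#' \eqn{P_{i'i}(t)}: the reverse) onto the eleven-class interaction taxonomy.
#' Positive means activation, negative inhibition, and values within
#' `epsilon` of zero are treated as neutral. Mutual activation is synergism
#' (symmetric when the two magnitudes are equal within `equal_tol` relative
#' difference, asymmetric otherwise), mutual inhibition antagonism (same
#' split), one-sided effects are directional toward the receiving gene,
#' opposite signs are altruism toward the activated gene (equivalently,
#' exploitation by it), and mutual neutrality is coexistence.
#'
#' @param p_ii dependent expression of gene i by gene i' (\eqn{P_{ii'}(t)}).
#' @param p_i_i dependent expression of gene i' by gene i (\eqn{P_{i'i}(t)}).
#' @param epsilon absolute zero-threshold (values with `|x| <= epsilon` are
#'   neutral); must be `>= 0`.
#' @param equal_tol relative tolerance for the equal-magnitude test that
#'   separates symmetric from asymmetric classes.
#' @return one label from [edge_classes()].
#' @examples
#' classify_pair(0.5, 0.5)    # symmetric_synergism
#' classify_pair(0.5, 0)      # directional_synergism_toward_i
#' classify_pair(0.3, -0.2)   # altruism_toward_i
#' @export
classify_pair <- function(p_ii, p_i_i, epsilon = 0, equal_tol = 0.1) {
  stopifnot(epsilon >= 0, is.finite(p_ii), is.finite(p_i_i))
  s1 <- if (abs(p_ii) <= epsilon) 0L else sign(p_ii)
  s2 <- if (abs(p_i_i) <= epsilon) 0L else sign(p_i_i)
  equal_mag <- function(a, b) {
    m <- max(abs(a), abs(b))
    m == 0 || abs(abs(a) - abs(b)) / m < equal_tol
  }
  if (s1 == 0L && s2 == 0L) return("coexistence")
  if (s1 > 0L && s2 > 0L) {
    return(if (equal_mag(p_ii, p_i_i)) "symmetric_synergism"
           else "asymmetric_synergism")
  }
  if (s1 < 0L && s2 < 0L) {
    return(if (equal_mag(p_ii, p_i_i)) "symmetric_antagonism"
           else "asymmetric_antagonism")
  }
  if (s1 > 0L && s2 == 0L) return("directional_synergism_toward_i")
  if (s1 == 0L && s2 > 0L) return("directional_synergism_toward_iprime")
  if (s1 < 0L && s2 == 0L) return("directional_antagonism_toward_i")
  if (s1 == 0L && s2 < 0L) return("directional_antagonism_toward_iprime")
  if (s1 > 0L && s2 < 0L) return("altruism_toward_i")
  "altruism_toward_iprime"
}

#' Assemble a signed network snapshot at time t
#'
#' The network at time `t` has one node per entity carrying its independent
#' expression \eqn{P_i(t)}, and a directed edge \eqn{i' \to i} whenever
#' \eqn{i'} is a selected regulator of \eqn{i} and \eqn{|P_{ii'}(t)|}
#' exceeds the zero-threshold; the edge weight is \eqn{P_{ii'}(t)} (positive
#' = activation, negative = inhibition). Every unordered pair also receives
#' its taxonomy class, and hubs are flagged by [detect_hubs()].
#'
#' @param decomps named list of [decompose()] results, one per target entity
#'   (names are the target ids; the node set is the union of targets and
#'   regulators).
#' @param t snapshot time within the common time window.
#' @param epsilon zero-threshold. The default, `NULL`, uses
#'   `epsilon_frac * max |P|` over all pairs at `t` (relative rule).
#' @param epsilon_frac fraction for the relative default threshold.
#' @param equal_tol passed to [classify_pair()].
#' @return a `signed_network`: list with `time`, `nodes` (data frame:
#'   `id`, `p_ind`, `hub`), `edges` (data frame: `from`, `to`, `weight`,
#'   `sign`), `pairs` (data frame: `i`, `iprime`, `p_ii`, `p_i_i`, `class`)
#'   and `epsilon`.
#' @export
build_network <- function(decomps, t, epsilon = NULL, epsilon_frac = 0.05,
                          equal_tol = 0.1) {
  stopifnot(length(decomps) >= 1L)
  if (is.null(names(decomps))) {
    names(decomps) <- vapply(decomps, `[[`, "", "target_id")
  }
  t0 <- min(decomps[[1L]]$time); tT <- max(decomps[[1L]]$time)
  if (t < t0 - 1e-9 || t > tT + 1e-9) {
    stop(sprintf("build_network: t = %g outside [%g, %g]", t, t0, tT))
  }
  ids <- union(names(decomps),
               unlist(lapply(decomps, `[[`, "regulators"), use.names = FALSE))
  # dependent matrix D[i, i'] = P_ii'(t), effect of i' on target i
  D <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (tg in names(decomps)) {
    pv <- p_dep_at(decomps[[tg]], t)
    if (length(pv)) D[tg, names(pv)] <- pv
  }
  if (is.null(epsilon)) epsilon <- epsilon_frac * max(abs(D))
  p_ind <- setNames(rep(NA_real_, length(ids)), ids)
  for (tg in names(decomps)) {
    p_ind[tg] <- approx(decomps[[tg]]$time, decomps[[tg]]$p_ind, xout = t,
                        rule = 2)$y
  }
  # directed edges above threshold, restricted to selected regulators
  ef <- list()
  for (tg in names(decomps)) {
    regs <- decomps[[tg]]$regulators
    for (rg in regs) {
      w <- D[tg, rg]
      if (abs(w) > epsilon) {
        ef[[length(ef) + 1L]] <- data.frame(from = rg, to = tg, weight = w,
                                            sign = sign(w))
      }
    }
  }
  edges <- if (length(ef)) do.call(rbind, ef) else
    data.frame(from = character(0), to = character(0), weight = numeric(0),
               sign = numeric(0))
  # per unordered pair classification
  pr <- t(combn(ids, 2L))
  pairs <- data.frame(i = pr[, 1L], iprime = pr[, 2L],
                      p_ii = D[cbind(pr[, 1L], pr[, 2L])],
                      p_i_i = D[cbind(pr[, 2L], pr[, 1L])])
  pairs$class <- mapply(classify_pair, pairs$p_ii, pairs$p_i_i,
                        MoreArgs = list(epsilon = epsilon,
                                        equal_tol = equal_tol))
  net <- structure(
    list(time = t, nodes = data.frame(id = ids, p_ind = unname(p_ind),
                                      hub = FALSE),
         edges = edges, pairs = pairs, epsilon = epsilon),
    class = "signed_network")
  hubs <- detect_hubs(net)
  net$nodes$hub <- net$nodes$id %in% hubs
  net
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf("signed_network at t = %g: %d nodes, %d edges (epsilon %.4g)\n",
              x$time, nrow(x$nodes), nrow(x$edges), x$epsilon))
  if (any(x$nodes$hub)) cat("hubs:", x$nodes$id[x$nodes$hub], "\n")
  invisible(x)
}

#' Flag hub nodes
#'
#' A node is a hub when it shows more regulation than the average: its total
#' degree (in + out) strictly exceeds the mean total degree over all nodes.
#'
#' @param network a `signed_network`.
#' @return character vector of hub node ids (possibly empty).
#' @export
detect_hubs <- function(network) {
  stopifnot(inherits(network, "signed_network"))
  ids <- network$nodes$id
  deg <- setNames(rep(0L, length(ids)), ids)
  if (nrow(network$edges)) {
    tab <- table(c(network$edges$from, network$edges$to))
    deg[names(tab)] <- as.integer(tab)
  }
  ids[deg > mean(deg)]
}

#' Convert a signed network to an igraph object
#'
#' @param network a `signed_network`.
#' @return directed [igraph::graph] with `weight`, `sign` edge attributes and
#'   `p_ind`, `hub` vertex attributes.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "signed_network"))
  g <- igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                     vertices = network$nodes)
  g
}

#' Write a signed network as GraphML
#'
#' @param network a `signed_network`.
#' @param path output file.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' Edge list of a signed network as a data frame
#'
#' @param network a `signed_network`.
#' @return data frame with time, source, target, weight, sign and the pair
#'   class of the connected pair.
#' @export
edge_table <- function(network) {
  e <- network$edges
  if (!nrow(e)) {
    return(data.frame(time = numeric(0), source = character(0),
                      target = character(0), weight = numeric(0),
                      sign = numeric(0), pair_class = character(0)))
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  cls <- setNames(network$pairs$class, key(network$pairs$i,
                                           network$pairs$iprime))
  data.frame(time = network$time, source = e$from, target = e$to,
             weight = e$weight, sign = e$sign,
             pair_class = unname(cls[key(e$from, e$to)]))
}
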