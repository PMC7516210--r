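make_trait_fixture <- function(seed) {
  times <- seq(0, 8, length.out = 25)
  gene_curves <- random_curve_set(6, times, seed = seed, scale = 3)
  gdrvf <- approxfun(times, predict(gene_curves[["c02"]], times), rule = 2)
  set.seed(seed)
  w1 <- runif(1, 0.5, 1); w2 <- runif(1, 1.6, 2.4)
  u2 <- 3 * sin(w1 * times + seed %% 5) + 1.5 * sin(w2 * times + 1)
  u2f <- approxfun(times, u2, rule = 2)
  u1 <- oracle_integrate(function(t, u) 0.25 * (1 - u) + 1.0 * gdrvf(t), 0.5,
                         times)
  u3 <- oracle_integrate(function(t, u) 0.25 * (-1 - u) + 1.1 * u2f(t), -0.5,
                         times)
  dpp <- rbind(t1 = u1, t2 = u2, t3 = u3) +
    matrix(rnorm(3 * length(times), 0, 0.05), 3)
  colnames(dpp) <- times
  list(times = times, gene_curves = gene_curves, dpp = dpp)
}

test_that("trait ODEs recover their trait and gene drivers", {
  hit_gene <- hit_trait <- 0; n_seeds <- 8
  for (s in seq_len(n_seeds)) {
    fx <- make_trait_fixture(300 + s)
    tf <- suppressWarnings(
      fit_trait_system(fx$dpp, fx$gene_curves, times = fx$times,
                       d_max = 3, curve_order = 10, n_starts = 2))
    if ("c02" %in% tf$t1$fit$regulators &&
        unname(tf$t1$kind["c02"]) == "gene") hit_gene <- hit_gene + 1
    if ("t2" %in% tf$t3$fit$regulators &&
        unname(tf$t3$kind["t2"]) == "trait") hit_trait <- hit_trait + 1
    # three-component additivity at every lattice point
    for (j in names(tf)) {
      d <- tf[[j]]$decomp
      total <- d$p_ind + if (ncol(d$p_dep)) rowSums(d$p_dep) else 0
      expect_lt(max(abs(total - d$g_hat)), 1e-6)
    }
  }
  expect_gte(hit_gene, n_seeds - 1)
  expect_gte(hit_trait, n_seeds - 1)
})

test_that("a trait with no selected predictors is fully independent", {
  times <- seq(0, 8, length.out = 20)
  gene_curves <- random_curve_set(4, times, seed = 77)
  u <- oracle_integrate(function(t, x) 0.5 * (2 - x), -1, times)
  set.seed(2)
  dpp <- rbind(solo = u + rnorm(20, 0, 0.05),
               other = 3 * cos(times / 2) + rnorm(20, 0, 0.05))
  colnames(dpp) <- times
  tf <- suppressWarnings(
    fit_trait_system(dpp, gene_curves, times = times, d_max = 3,
                     curve_order = 8, n_starts = 2))
  d <- tf$solo$decomp
  if (!length(tf$solo$fit$regulators)) {
    expect_equal(d$p_ind, d$g_hat, tolerance = 1e-10)
  }
  tab <- causal_edge_table(tf)
  expect_true(all(c("source_kind", "source", "target_trait", "weight",
                    "sign") %in% names(tab)))
})

test_that("upstream layering equals directed shortest-path distances", {
  mknet <- function(edges, ids) {
    structure(list(time = 1,
                   nodes = data.frame(id = ids, p_ind = 0, hub = FALSE),
                   edges = cbind(edges, weight = 1, sign = 1),
                   pairs = NULL, epsilon = 0), class = "signed_network")
  }
  # chain a -> b -> c with c causal
  chain <- mknet(data.frame(from = c("a", "b"), to = c("b", "c")),
                 c("a", "b", "c"))
  lay <- layer_upstream(chain, "c")
  expect_equal(lay$layer[match(c("c", "b", "a"), lay$id)], c(0L, 1L, 2L))
  # disconnected gene flagged unreachable
  iso <- mknet(data.frame(from = "a", to = "b"), c("a", "b", "z"))
  li <- layer_upstream(iso, "b")
  expect_false(li$reachable[li$id == "z"])
  expect_true(is.na(li$layer[li$id == "z"]))
  # empty causal set: everything unreachable
  l0 <- layer_upstream(iso, character(0))
  expect_true(all(!l0$reachable))
  expect_error(layer_upstream(iso, "nope"), "unknown")
  # random DAG vs a hand-rolled BFS recount
  set.seed(31)
  ids <- paste0("n", 1:12)
  e <- data.frame(from = ids[sample(1:11, 15, TRUE)],
                  to = ids[sample(2:12, 15, TRUE)])
  e <- unique(e[match(e$from, ids) < match(e$to, ids), ])  # forward edges only
  net <- mknet(e, ids)
  causal <- c("n11", "n12")
  lay <- layer_upstream(net, causal)
  # oracle: breadth-first over explicit adjacency
  bfs_dist <- function(src) {
    d <- 0L; frontier <- src; seen <- src
    repeat {
      if (any(frontier %in% causal)) return(d)
      nxt <- unique(e$to[e$from %in% frontier])
      nxt <- setdiff(nxt, seen)
      if (!length(nxt)) return(NA_integer_)
      seen <- c(seen, nxt); frontier <- nxt; d <- d + 1L
    }
  }
  for (v in ids) {
    expect_identical(lay$layer[lay$id == v], bfs_dist(v),
                     info = paste("node", v))
  }
})
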