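test_that("the printed sign patterns map to their interaction classes", {
  expect_equal(classify_pair(0.5, 0.5), "symmetric_synergism")
  expect_equal(classify_pair(0.5, 0), "directional_synergism_toward_i")
  expect_equal(classify_pair(0.3, -0.2), "altruism_toward_i")
  expect_equal(classify_pair(0, 0), "coexistence")
  expect_equal(classify_pair(0.5, 0.9), "asymmetric_synergism")
  expect_equal(classify_pair(-0.5, -0.5), "symmetric_antagonism")
  expect_equal(classify_pair(-0.5, -0.1), "asymmetric_antagonism")
  expect_equal(classify_pair(-0.5, 0), "directional_antagonism_toward_i")
  expect_equal(classify_pair(0, -0.4), "directional_antagonism_toward_iprime")
  expect_equal(classify_pair(0, 0.4), "directional_synergism_toward_iprime")
  expect_equal(classify_pair(-0.3, 0.2), "altruism_toward_iprime")
})

test_that("classification is total and covers exactly the eleven classes", {
  # enumerate sign patterns x magnitude relations
  vals <- c(-0.9, -0.3, 0, 0.3, 0.9)
  seen <- character(0)
  for (a in vals) for (b in vals) {
    lab <- classify_pair(a, b)
    expect_true(lab %in% edge_classes())
    seen <- union(seen, lab)
  }
  expect_setequal(seen, edge_classes())
  # near-equal magnitudes use the relative tolerance
  expect_equal(classify_pair(0.50, 0.52), "symmetric_synergism")
  expect_equal(classify_pair(-0.50, -0.52), "symmetric_antagonism")
})

test_that("swapping the pair mirrors the directional labels", {
  mirror <- c(directional_synergism_toward_i = "directional_synergism_toward_iprime",
              directional_synergism_toward_iprime = "directional_synergism_toward_i",
              directional_antagonism_toward_i = "directional_antagonism_toward_iprime",
              directional_antagonism_toward_iprime = "directional_antagonism_toward_i",
              altruism_toward_i = "altruism_toward_iprime",
              altruism_toward_iprime = "altruism_toward_i",
              symmetric_synergism = "symmetric_synergism",
              asymmetric_synergism = "asymmetric_synergism",
              symmetric_antagonism = "symmetric_antagonism",
              asymmetric_antagonism = "asymmetric_antagonism",
              coexistence = "coexistence")
  set.seed(6)
  for (i in 1:40) {
    a <- sample(c(-1, 0, 1), 1) * runif(1, 0.1, 1)
    b <- sample(c(-1, 0, 1), 1) * runif(1, 0.1, 1)
    expect_equal(classify_pair(b, a),
                 unname(mirror[classify_pair(a, b)]))
  }
})

# a hand-built decomposition: p_dep columns are linear ramps ending at the
# requested final values
fake_decomp <- function(id, regulators, finals, times = seq(0, 4, 0.1)) {
  p_dep <- if (length(regulators)) {
    sapply(finals, function(f) f * (times - times[1]) / diff(range(times)))
  } else matrix(0, length(times), 0)
  if (length(regulators)) colnames(p_dep) <- regulators
  structure(list(target_id = id, time = times,
                 g_hat = 1 + 0 * times, p_ind = 1 + 0 * times,
                 p_dep = as.matrix(p_dep), regulators = regulators),
            class = "decomposed_trajectory")
}

test_that("network snapshots respect thresholds and initial conditions", {
  decs <- list(a = fake_decomp("a", "b", 2),
               b = fake_decomp("b", c("a", "c"), c(-1, 0.5)),
               c = fake_decomp("c", character(0), numeric(0)))
  # at t0 all dependent integrals vanish: edgeless network
  net0 <- build_network(decs, 0)
  expect_equal(nrow(net0$edges), 0L)
  expect_true(all(net0$pairs$class == "coexistence"))
  # epsilon above the largest |P|: edgeless again
  netbig <- build_network(decs, 4, epsilon = 10)
  expect_equal(nrow(netbig$edges), 0L)
  # at the final time the generating adjacency is reproduced
  net <- build_network(decs, 4, epsilon = 0.01)
  got <- sort(paste(net$edges$from, net$edges$to))
  expect_equal(got, sort(c("b a", "a b", "c b")))
  expect_equal(net$edges$weight[net$edges$from == "b" & net$edges$to == "a"], 2)
  expect_error(build_network(decs, 99), "outside")
})

test_that("hubs are the nodes with above-average total degree", {
  star <- structure(list(
    time = 1,
    nodes = data.frame(id = c("hub", paste0("leaf", 1:5)), p_ind = 0,
                       hub = FALSE),
    edges = data.frame(from = rep("hub", 5), to = paste0("leaf", 1:5),
                       weight = 1, sign = 1),
    pairs = NULL, epsilon = 0), class = "signed_network")
  expect_equal(detect_hubs(star), "hub")
  ring <- structure(list(
    time = 1,
    nodes = data.frame(id = paste0("n", 1:6), p_ind = 0, hub = FALSE),
    edges = data.frame(from = paste0("n", 1:6),
                       to = paste0("n", c(2:6, 1)), weight = 1, sign = 1),
    pairs = NULL, epsilon = 0), class = "signed_network")
  expect_length(detect_hubs(ring), 0)
  # random graph vs a direct recount
  set.seed(12)
  ids <- paste0("v", 1:10)
  ed <- data.frame(from = sample(ids, 18, TRUE), to = sample(ids, 18, TRUE))
  ed <- ed[ed$from != ed$to, ]
  g <- structure(list(time = 1,
                      nodes = data.frame(id = ids, p_ind = 0, hub = FALSE),
                      edges = cbind(ed, weight = 1, sign = 1),
                      pairs = NULL, epsilon = 0), class = "signed_network")
  deg <- vapply(ids, function(v) sum(ed$from == v) + sum(ed$to == v), 1L)
  expect_setequal(detect_hubs(g), ids[deg > mean(deg)])
})

test_that("edge tables and GraphML export carry the snapshot", {
  decs <- list(a = fake_decomp("a", "b", 2),
               b = fake_decomp("b", "a", -1))
  net <- build_network(decs, 4, epsilon = 0.1)
  tab <- edge_table(net)
  expect_named(tab, c("time", "source", "target", "weight", "sign",
                      "pair_class"))
  expect_equal(nrow(tab), 2L)
  expect_true(all(tab$pair_class == "altruism_toward_i"))
  f <- tempfile(fileext = ".graphml")
  write_graphml(net, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::gsize(g), 2)
  expect_setequal(igraph::V(g)$name, c("a", "b"))
})
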