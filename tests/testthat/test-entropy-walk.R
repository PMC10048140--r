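test_that("gene entropy follows the normalized Shannon form", {
  m <- rbind(uniform = c(4, 4, 4, 4),
             spread = c(1, 2, 4, 1))
  colnames(m) <- paste0("s", 1:4)
  E <- gene_entropy(m)
  expect_equal(unname(E["uniform"]), 1, tolerance = 1e-9)

  # row (1, 2, 4): shifted masses (0, 1, 3)/4, entropy -(sum p ln p)/ln 3
  m2 <- rbind(g = c(1, 2, 4))
  colnames(m2) <- paste0("s", 1:3)
  p <- c(1, 3) / 4
  expected <- -sum(p * log(p)) / log(3)
  expect_equal(unname(gene_entropy(m2)["g"]), expected, tolerance = 1e-6)
  expect_equal(expected, 0.5119, tolerance = 1e-4)

  # shifted mass concentrated on one sample: entropy near 0
  m3 <- rbind(g = c(0, 0, 0, 1000))
  colnames(m3) <- paste0("s", 1:4)
  expect_lt(unname(gene_entropy(m3)["g"]), 0.05)

  expect_error(gene_entropy(m2[, 1, drop = FALSE]), "2 samples")
})

test_that("entropy weights are (1 - E) normalized to sum one", {
  expect_equal(unname(entropy_weights(c(0.5, 0.5))), c(0.5, 0.5))
  expect_equal(unname(entropy_weights(c(0.2, 0.6))), c(2 / 3, 1 / 3))
  set.seed(20)
  ew <- entropy_weights(runif(50))
  expect_equal(sum(ew), 1, tolerance = 1e-12)
  expect_error(entropy_weights(c(1, 1, 1)), "no information")
})

test_that("entropy transition allocates mass by target weight and stays
           row-stochastic", {
  net <- pathway_network("toy", rbind(c("u", "v1"), c("u", "v2"),
                                      c("v1", "v2")))
  ew <- c(u = 0.1, v1 = 2 / 3, v2 = 1 / 3)
  netT <- build_entropy_transition(net, ew)
  trans <- as.matrix(netT$transition)
  expect_equal(trans["u", c("v1", "v2")], c(v1 = 2 / 3, v2 = 1 / 3),
               tolerance = 1e-12)
  # dangling node v2 gets a self-loop
  expect_equal(trans["v2", "v2"], 1)
  expect_equal(unname(Matrix::rowSums(netT$transition)), rep(1, 3),
               tolerance = 1e-12)
})

test_that("equal entropy weights reduce to out-degree normalization", {
  set.seed(21)
  net <- random_walk_net(12, seed = 21)
  nodes <- net$nodes
  eq <- build_entropy_transition(net, setNames(rep(0.3, length(nodes)), nodes))
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (e in seq_len(nrow(net$edges))) A[net$edges[e, 1], net$edges[e, 2]] <- 1
  manual <- A / pmax(rowSums(A), 1)
  diag(manual)[rowSums(A) == 0] <- 1
  expect_equal(as.matrix(eq$transition), manual, tolerance = 1e-12)
})

test_that("zero-weight out-neighborhoods fall back to uniform rows", {
  net <- pathway_network("z", rbind(c("a", "b"), c("a", "c"), c("b", "a")))
  ew <- c(a = 1, b = 0, c = 0)
  expect_message(netT <- build_entropy_transition(net, ew), "uniform fallback")
  expect_equal(as.matrix(netT$transition)["a", c("b", "c")],
               c(b = 0.5, c = 0.5))
})

test_that("restart-dominated and symmetric walks hit their fixed points", {
  net <- pathway_network("cyc", rbind(c("A", "B"), c("B", "A")))
  netT <- build_entropy_transition(net, c(A = 0.4, B = 0.6))
  h0 <- c(A = 0.3, B = 0.7)
  w1 <- walk_with_restart(netT, h0, r = 1)
  expect_equal(w1$h_inf, h0)

  sym <- walk_with_restart(netT, c(A = 0.5, B = 0.5), r = 0.37)
  expect_equal(unname(sym$h_inf), c(0.5, 0.5), tolerance = 1e-9)

  expect_error(walk_with_restart(netT, c(A = 0.9, B = 0.5), r = 0.5),
               "probability vector")
  expect_error(walk_with_restart(netT, h0, r = 0), "restart probability")
  expect_error(walk_with_restart(net, h0, r = 0.5), "no transition")
})

test_that("power iteration matches the closed-form solve on a chain", {
  net <- pathway_network("chain", rbind(c("A", "B"), c("B", "C")))
  netT <- build_entropy_transition(net, c(A = 0.2, B = 0.3, C = 0.5))
  h0 <- c(A = 1, B = 0, C = 0)
  w <- walk_with_restart(netT, h0, r = 0.5)
  expect_true(w$converged)
  expect_equal(unname(w$h_inf), solve_walk(netT$transition, h0, 0.5),
               tolerance = 1e-8)
})

test_that("walks are equivariant under node permutation", {
  set.seed(22)
  for (s in 1:5) {
    net <- random_walk_net(10, seed = 100 + s)
    h0 <- runif(10)
    h0 <- setNames(h0 / sum(h0), net$nodes)
    w <- walk_with_restart(net, h0, r = 0.4)
    perm <- sample(net$nodes)
    net2 <- build_entropy_transition(
      pathway_network("perm", net$edges, nodes = perm),
      attr_ew <- setNames(rep(1 / 10, 10), net$nodes))
    # rebuild both with equal weights for a clean comparison
    net1 <- build_entropy_transition(
      pathway_network("orig", net$edges, nodes = net$nodes),
      attr_ew)
    w1 <- walk_with_restart(net1, h0, r = 0.4)
    w2 <- walk_with_restart(net2, h0[perm], r = 0.4)
    expect_equal(w2$h_inf[net$nodes], w1$h_inf, tolerance = 1e-12)
  }
})

test_that("adding start mass to a node never lowers its stationary weight", {
  set.seed(23)
  for (s in 1:10) {
    net <- random_walk_net(8, seed = 200 + s)
    h0 <- runif(8)
    h0 <- setNames(h0 / sum(h0), net$nodes)
    target <- sample(net$nodes, 1)
    h1 <- h0
    h1[target] <- h1[target] + 0.5
    h1 <- h1 / sum(h1)
    w0 <- walk_with_restart(net, h0, r = 0.3)
    w1 <- walk_with_restart(net, h1, r = 0.3)
    expect_gte(w1$h_inf[target] + 1e-12, w0$h_inf[target])
  }
})

test_that("the bi-walk runs two independent seeded walks", {
  co <- small_cohort(seed = 31)
  expr <- co$expr
  E <- gene_entropy(expr)
  gs <- score_genes(expr, co$labels)
  w0 <- setNames(gs$w0, gs$gene_id)
  nets <- lapply(co$networks, function(net) {
    common <- intersect(net$nodes, names(E))
    build_entropy_transition(net, entropy_weights(E[common]))
  })
  walks <- bi_random_walk(nets[[1]], nets[[2]], w0, r = 0.5)
  expect_named(walks, c("KEGG", "PID"))
  for (w in walks) {
    expect_true(w$converged)
    expect_equal(sum(w$h_inf), 1, tolerance = 1e-9)
    expect_true(all(w$h_inf >= 0))
  }
  # identical networks and start vector give identical results
  again <- bi_random_walk(nets[[1]], nets[[1]], w0, r = 0.5)
  expect_equal(again[[1]]$h_inf, again[[2]]$h_inf)

  alien <- build_entropy_transition(
    pathway_network("alien", rbind(c("x1", "x2"))),
    c(x1 = 0.5, x2 = 0.5))
  expect_error(bi_random_walk(nets[[1]], alien, w0, r = 0.5),
               "alien")
})
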