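# minimal hand-wired inputs for direct formula checks
activity_fixture <- function() {
  zn <- rbind(gA = c(1, -1, 2), gB = c(0.5, 0.2, -0.3))
  colnames(zn) <- paste0("s", 1:3)
  walk <- structure(list(network = "toy", r = 0.5,
                         h_inf = c(gA = 0.5, gB = 0.5),
                         iterations = 1L, converged = TRUE),
                    class = "edrw_walk")
  gs <- data.frame(gene_id = c("gA", "gB"), t = c(3, -2),
                   p_value = c(0.01, 0.02), rho_pb = c(0.5, -0.4),
                   pct = c(9.5, 4.4), w0 = c(0, 1))
  list(zn = zn, walk = walk, gs = gs)
}

test_that("single-gene pathway activity reduces to H * PCT * z / ew", {
  fx <- activity_fixture()
  fx$walk$h_inf <- c(gA = 0.5)
  gs <- data.frame(gene_id = "gA", t = 2, p_value = 0.01, rho_pb = 0.3,
                   pct = 2, w0 = 0)
  zn <- fx$zn["gA", , drop = FALSE]
  zn["gA", ] <- 1
  pa <- infer_pathway_activity(pathway_collection(list(pw = "gA")),
                               fx$walk, gs, zn, ew = c(gA = 0.1))
  expect_equal(unname(pa$activity["pw", ]), rep(10, 3))
})

test_that("two-gene activity matches a spreadsheet-style recomputation", {
  fx <- activity_fixture()
  ew <- c(gA = 0.7, gB = 0.3)
  pa <- infer_pathway_activity(pathway_collection(list(pw = c("gA", "gB"))),
                               fx$walk, fx$gs, fx$zn, ew)
  manual <- (0.5 * 9.5 * fx$zn["gA", ] + 0.5 * 4.4 * fx$zn["gB", ]) /
    sqrt(0.7^2 + 0.3^2)
  expect_equal(pa$activity["pw", ], manual, tolerance = 1e-12)

  signed <- infer_pathway_activity(
    pathway_collection(list(pw = c("gA", "gB"))),
    fx$walk, fx$gs, fx$zn, ew, sign_adjust = TRUE)
  manual_signed <- (0.5 * 9.5 * fx$zn["gA", ] - 0.5 * 4.4 * fx$zn["gB", ]) /
    sqrt(0.7^2 + 0.3^2)
  expect_equal(signed$activity["pw", ], manual_signed, tolerance = 1e-12)
})

test_that("genes failing the p-value filter drop out, and empty pathways
           are removed", {
  fx <- activity_fixture()
  fx$gs$p_value <- c(0.01, 0.8)
  ew <- c(gA = 0.7, gB = 0.3)
  expect_message(
    pa <- infer_pathway_activity(
      pathway_collection(list(both = c("gA", "gB"), onlyB = "gB")),
      fx$walk, fx$gs, fx$zn, ew),
    "onlyB")
  expect_identical(rownames(pa$activity), "both")
  expect_identical(pa$genes_used$both, "gA")
  expect_error(infer_pathway_activity(
    pathway_collection(list(pw = "gA")), fx$walk, fx$gs, fx$zn, ew,
    alpha = 1.5), "alpha")
})

test_that("activity scales linearly with the walk vector", {
  fx <- activity_fixture()
  ew <- c(gA = 0.6, gB = 0.4)
  pc <- pathway_collection(list(pw = c("gA", "gB")))
  a1 <- infer_pathway_activity(pc, fx$walk, fx$gs, fx$zn, ew)
  fx$walk$h_inf <- fx$walk$h_inf * 3
  a3 <- infer_pathway_activity(pc, fx$walk, fx$gs, fx$zn, ew)
  expect_equal(a3$activity, 3 * a1$activity, tolerance = 1e-12)
})

test_that("network profiles combine by prefixed row concatenation", {
  fx <- activity_fixture()
  ew <- c(gA = 0.6, gB = 0.4)
  a <- infer_pathway_activity(
    pathway_collection(list(p1 = c("gA", "gB"), p2 = "gA", p3 = "gB")),
    fx$walk, fx$gs, fx$zn, ew)
  b <- a
  b$network <- "other"
  comb <- combine_network_profiles(a, b)
  expect_equal(nrow(comb$activity), 6L)
  expect_identical(rownames(comb$activity)[c(1, 4)], c("toy:p1", "other:p1"))

  empty <- structure(list(
    activity = matrix(numeric(0), 0, 3,
                      dimnames = list(NULL, colnames(fx$zn))),
    genes_used = list(), network = "none"), class = "pathway_activity")
  just_a <- combine_network_profiles(a, empty)
  expect_equal(nrow(just_a$activity), 3L)

  colnames(b$activity) <- paste0("x", 1:3)
  expect_error(combine_network_profiles(a, b), "sample mismatch")
})

test_that("pathway ranking puts a planted pathway first and breaks ties
           lexicographically", {
  co <- small_cohort(seed = 61, delta = 2, n_per_class = 30)
  expr <- co$expr
  labels <- co$labels
  E <- gene_entropy(expr)
  gs <- score_genes(expr, labels)
  w0 <- setNames(gs$w0, gs$gene_id)
  zn <- znormalize(expr)
  nets <- lapply(co$networks, function(net) {
    build_entropy_transition(net,
      entropy_weights(E[intersect(net$nodes, names(E))]))
  })
  walks <- bi_random_walk(nets[[1]], nets[[2]], w0, r = 0.5)
  acts <- suppressMessages(lapply(1:2, function(i) {
    ewn <- entropy_weights(E[intersect(co$networks[[i]]$nodes, names(E))])
    infer_pathway_activity(co$pathways[[i]], walks[[i]], gs, zn, ewn)
  }))
  comb <- combine_network_profiles(acts[[1]], acts[[2]])
  ranked <- rank_top_pathways(comb, labels, seq_along(labels), k = 10)
  expect_true(ranked[1] %in% paste0("KEGG:", co$planted))

  # k larger than available returns everything
  all_ranked <- rank_top_pathways(comb, labels, seq_along(labels), k = 1e6)
  expect_equal(length(all_ranked), nrow(comb$activity))

  # identical rows tie and fall back to id order
  dup <- comb
  dup$activity <- rbind(zzz = comb$activity[1, ], aaa = comb$activity[1, ])
  r2 <- rank_top_pathways(dup, labels, seq_along(labels), k = 2)
  expect_identical(r2, c("aaa", "zzz"))

  expect_error(rank_top_pathways(comb, labels, which(labels == 1)),
               "single class")
})

test_that("sign adjustment does not weaken incoherently planted pathways", {
  worse <- 0
  for (s in 1:10) {
    co <- small_cohort(seed = 300 + s, delta = 1.5, coherence = 0.5)
    expr <- co$expr
    labels <- co$labels
    E <- gene_entropy(expr)
    gs <- score_genes(expr, labels)
    zn <- znormalize(expr)
    net <- co$networks[[1]]
    ewn <- entropy_weights(E[intersect(net$nodes, names(E))])
    netT <- build_entropy_transition(net, ewn)
    w0 <- setNames(gs$w0, gs$gene_id)
    h0 <- setNames(numeric(length(netT$nodes)), netT$nodes)
    h0[intersect(names(w0), netT$nodes)] <-
      w0[intersect(names(w0), netT$nodes)]
    walk <- walk_with_restart(netT, h0 / sum(h0), r = 0.5)
    planted_pc <- pathway_collection(
      co$pathways[[1]]$members[co$planted], source = "KEGG")
    t_of <- function(sign_adjust) {
      pa <- suppressMessages(infer_pathway_activity(
        planted_pc, walk, gs, zn, ewn, sign_adjust = sign_adjust))
      abs(edrw:::row_ttest(pa$activity, labels)$t)
    }
    if (any(t_of(TRUE) < t_of(FALSE) - 1e-9)) worse <- worse + 1
  }
  expect_lte(worse, 1)
})
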