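test_that("rooted topology counts follow the double factorial", {
  expect_equal(count_rooted_topologies(3), 3)
  expect_equal(count_rooted_topologies(5), 105)
  expect_error(count_rooted_topologies(1), "at least 2")
  for (n in 2:6) {
    catalog <- enumerate_rooted_topologies(letters[1:n])
    expect_equal(length(catalog$topologies), count_rooted_topologies(n))
    expect_false(anyDuplicated(catalog$topologies) > 0)
  }
})

test_that("three-taxon enumeration is exactly the three resolutions", {
  catalog <- enumerate_rooted_topologies(c("a", "b", "c"))
  expect_setequal(catalog$topologies,
                  c("((a,b),c)", "((a,c),b)", "(a,(b,c))"))
  expect_error(enumerate_rooted_topologies(letters[1:9]), "force")
})

test_that("weighting is exact on hand-solved trees", {
  catalog <- enumerate_rooted_topologies(c("A", "B", "C", "O"))
  # all one-tip-per-group subtrees isomorphic: full weight on one topology
  t1 <- ape::read.tree(text = "((((a1,a2),b1),c1),o1);")
  g1 <- stats::setNames(c("A", "A", "B", "C", "O"),
                        c("a1", "a2", "b1", "c1", "o1"))
  w1 <- weight_gene_tree(t1, g1, catalog, mode = "exhaustive")
  expect_equal(unname(w1["(((A,B),C),O)"]), 1)
  expect_equal(sum(w1), 1)

  # the two tip combinations split the weight evenly
  t2 <- ape::read.tree(text = "(((a1,b1),(a2,c1)),o1);")
  w2 <- weight_gene_tree(t2, g1, catalog, mode = "exhaustive")
  expect_equal(unname(w2["(((A,B),C),O)"]), 0.5)
  expect_equal(unname(w2["(((A,C),B),O)"]), 0.5)

  # sampled mode converges (binomial error bound at n_iter = 10000)
  set.seed(1)
  w2s <- weight_gene_tree(t2, g1, catalog, mode = "sampled",
                          n_iter = 10000)
  expect_lt(max(abs(w2s - w2)), 3 * sqrt(0.25 / 10000) + 0.005)
})

test_that("weighting refuses empty groups and polytomies by default", {
  catalog <- enumerate_rooted_topologies(c("A", "B", "C"))
  t1 <- ape::read.tree(text = "((a1,b1),c1);")
  g_bad <- stats::setNames(c("A", "B", "C"), c("a1", "b1", "zz"))
  expect_error(weight_gene_tree(t1, g_bad, catalog), "no tips")
  tp <- ape::read.tree(text = "((a1,b1,c1),d1);")
  gp <- stats::setNames(c("A", "B", "C", "C"), c("a1", "b1", "c1", "d1"))
  expect_error(weight_gene_tree(tp, gp, catalog), "polytom")
  w <- weight_gene_tree(tp, gp, catalog, resolve_polytomies = TRUE)
  expect_equal(sum(w), 1)
})

test_that("exhaustive weights match the brute-force RF oracle", {
  skip_if_not_installed("phangorn")
  set.seed(42)
  for (i in 1:10) {
    rt <- random_grouped_tree(n_tips = 8, n_groups = 4)
    catalog <- enumerate_rooted_topologies(unique(rt$groups))
    w <- weight_gene_tree(rt$phy, rt$groups, catalog, mode = "exhaustive")
    expect_equal(unname(as.numeric(w)),
                 oracle_weights(rt$phy, rt$groups, catalog))
  }
})

test_that("weight vectors over random coalescent trees sum to one", {
  set.seed(7)
  catalog <- enumerate_rooted_topologies(LETTERS[1:5])
  for (i in 1:15) {
    rt <- random_grouped_tree(n_tips = 10, n_groups = 5)
    w <- weight_gene_tree(rt$phy, rt$groups, catalog)
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1, tolerance = 1e-9)
  }
})

test_that("clade aggregation sums weights over matching topologies", {
  catalog <- enumerate_rooted_topologies(c("A", "B", "C", "O"))
  t1 <- ape::read.tree(text = "((((a1,a2),b1),c1),o1);")
  t2 <- ape::read.tree(text = "(((a1,b1),(a2,c1)),o1);")
  g1 <- stats::setNames(c("A", "A", "B", "C", "O"),
                        c("a1", "a2", "b1", "c1", "o1"))
  wt <- weight_table(list(t1, t2), g1, catalog,
                     region_ids = c("r1", "r2"))
  ab <- aggregate_clade_support(wt, catalog, c("A", "B"))
  expect_equal(unname(ab), c(1, 0.5))
  ac <- aggregate_clade_support(wt, catalog, c("A", "C"))
  expect_equal(unname(ac["r2"]), 0.5)
  # with the outgroup position fixed, the three ingroup pair supports
  # are exhaustive and exclusive
  bc <- aggregate_clade_support(wt, catalog, c("B", "C"))
  expect_equal(unname(ab + ac + bc), c(1, 1))
  expect_error(aggregate_clade_support(wt, catalog, "A"), "at least 2")
  expect_error(aggregate_clade_support(wt, catalog, c("A", "B", "C", "O")),
               "proper subset")
})

test_that("window averaging follows the stride-1 gene-window definition", {
  catalog <- enumerate_rooted_topologies(c("A", "B", "C"))
  topo <- catalog$topologies
  W <- matrix(0, 6, 3, dimnames = list(sprintf("r%d", 1:6), topo))
  W[, 1] <- c(1, 0, 1, 0, 1, 0)
  W[, 2] <- 1 - W[, 1]
  wt <- structure(W, class = c("weight_table", "matrix"))
  rs <- region_set(sprintf("r%d", 1:6), "chr1",
                   seq(0, 500, by = 100), seq(50, 550, by = 100))
  sm5 <- window_average_weights(wt[1:5, ], rs[1:5, ], window = 5)
  expect_equal(nrow(sm5), 1L)
  expect_equal(sm5[[topo[1]]], 0.6)
  expect_equal(sm5$midpoint, 225)  # median region midpoint

  sm6 <- window_average_weights(wt, rs, window = 5)
  expect_equal(nrow(sm6), 2L)  # genes 1-5 and 2-6

  # constant weights are unchanged by smoothing
  Wc <- matrix(1 / 3, 6, 3, dimnames = dimnames(W))
  smc <- window_average_weights(
    structure(Wc, class = c("weight_table", "matrix")), rs, window = 5)
  expect_true(all(abs(as.matrix(smc[, topo]) - 1 / 3) < 1e-12))

  # short chromosome: one whole-chromosome window
  sm_short <- window_average_weights(wt[1:3, ], rs[1:3, ], window = 5)
  expect_equal(nrow(sm_short), 1L)
  expect_equal(sm_short$n_genes, 3)
})

test_that("quartet concordance counts matching splits across trees", {
  trees <- read_newick(textConnection(c(
    "((a1,b1),(c1,d1));", "(((a1,b1),c1),d1);", "((a1,c1),(b1,d1));")))
  g <- stats::setNames(c("A", "B", "C", "D"), c("a1", "b1", "c1", "d1"))
  q <- quartet_concordance(trees, g,
                           quartet = list(c("A", "B"), c("C", "D")))
  expect_equal(q$q, 2 / 3)
  q_same <- quartet_concordance(trees[1:1], g,
                                quartet = list(c("A", "B"), c("C", "D")))
  expect_equal(q_same$q, 1)
})

test_that("quartet concordance matches the closed-form ILS expectation", {
  # ((A,B),C) with internal branch T = 1 CU plus outgroup for the fourth
  # group: q(AB|CO) = 1 - (2/3) e^{-T}
  Ne <- 1e4
  sc <- sim_scenario(
    data.frame(pop = c("A", "B", "C", "O", "AB", "ABC", "R"),
               parent = c("AB", "AB", "ABC", "R", "ABC", "R", NA),
               t_join = c(2e4, 2e4, 4e4, 4e5, 4e4, 4e5, Inf), Ne = Ne),
    samples_per_taxon = c(A = 1, B = 1, C = 1, O = 1), ploidy = 1,
    n_regions = 10)
  n_loci <- 4000
  gt <- simulate_gene_trees(sc, n_loci, seed = 14)
  grp <- stats::setNames(c("A", "B", "C", "O"),
                         c("A_1", "B_1", "C_1", "O_1"))
  q <- quartet_concordance(gt$trees, grp,
                           quartet = list(c("A", "B"), c("C", "O")))
  expected <- 1 - (2 / 3) * exp(-1)
  mc_se <- sqrt(expected * (1 - expected) / n_loci)
  expect_lt(abs(q$q - expected), 3 * mc_se)
})

test_that("genome-wide summaries pool subtrees or average trees", {
  catalog <- enumerate_rooted_topologies(c("A", "B", "C", "O"))
  t1 <- ape::read.tree(text = "((((a1,a2),b1),c1),o1);")  # 2 combinations
  t2 <- ape::read.tree(text = "(((a1,b1),c1),o1);")       # 1 combination
  g1 <- stats::setNames(c("A", "A", "B", "C", "O"),
                        c("a1", "a2", "b1", "c1", "o1"))
  g2 <- g1[-2]
  wt <- weight_table(list(t1, t2), g1, catalog)
  s <- summarize_weights(wt)
  i <- match("(((A,B),C),O)", s$topology)
  expect_equal(s$mean_tree_weight[i], 1)
  expect_equal(s$pooled_subtree_share[i], 1)
})
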