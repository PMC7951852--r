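test_that("frequency-weighted pattern products match hand evaluation", {
  # single site: p = (0, 0.5, 1, 0) -> ABBA 0.5, BABA 0
  gm <- make_gm(matrix(c(0L, 1L, 2L, 0L), 1, 4))
  counts <- count_site_patterns(
    gm, c(P1 = "s1", P2 = "s2", P3 = "s3", O = "s4"), n_blocks = 1)
  expect_equal(counts$ABBA, 0.5)
  expect_equal(counts$BABA, 0)
  expect_equal(patterson_d(counts), 1)

  # p3 = 0 contributes nothing to either pattern
  gm0 <- make_gm(matrix(c(2L, 1L, 0L, 0L), 1, 4))
  c0 <- count_site_patterns(
    gm0, c(P1 = "s1", P2 = "s2", P3 = "s3", O = "s4"), n_blocks = 1)
  expect_equal(c0$ABBA + c0$BABA, 0)

  # missing outgroup call excludes the site entirely
  gmm <- make_gm(rbind(c(0L, 1L, 2L, NA), c(0L, 2L, 2L, 0L)))
  cm <- count_site_patterns(
    gmm, c(P1 = "s1", P2 = "s2", P3 = "s3", O = "s4"), n_blocks = 1)
  expect_equal(cm$n_sites, 1)
  expect_equal(attr(cm, "n_excluded"), 1L)
})

test_that("Patterson's D has the symmetry and boundary behavior", {
  d_of <- function(a, b) {
    patterson_d(data.frame(ABBA = a, BABA = b))
  }
  expect_equal(d_of(4, 4), 0)
  expect_equal(d_of(10, 0), 1)
  expect_warning(expect_true(is.na(d_of(0, 0))), "undefined")
  # invariant under rescaling of counts
  expect_equal(d_of(3, 1), d_of(300, 100))
})

test_that("role swap P1 <-> P2 negates D exactly", {
  set.seed(3)
  geno <- matrix(sample(0:2, 400, replace = TRUE), 100, 4)
  gm <- make_gm(geno)
  roles <- c(P1 = "s1", P2 = "s2", P3 = "s3", O = "s4")
  swapped <- c(P1 = "s2", P2 = "s1", P3 = "s3", O = "s4")
  d1 <- patterson_d(count_site_patterns(gm, roles, n_blocks = 5))
  d2 <- patterson_d(count_site_patterns(gm, swapped, n_blocks = 5))
  expect_equal(d1, -d2)
  expect_true(abs(d1) <= 1)
})

test_that("the delete-one block jackknife reproduces the worked example", {
  counts <- data.frame(block = 1:3, ABBA = c(3, 2, 3), BABA = c(1, 2, 1),
                       n_sites = c(4, 4, 4))
  res <- block_jackknife(counts)
  expect_equal(res$D, 1 / 3)
  expect_equal(res$SE, 1 / 6)
  expect_equal(res$z, 2)
  expect_equal(res$p, 2 * pnorm(-2))
  expect_false(res$degenerate)

  # identical blocks: SE = 0 flagged degenerate, not infinite z
  same <- data.frame(block = 1:4, ABBA = rep(3, 4), BABA = rep(1, 4),
                     n_sites = rep(4, 4))
  res0 <- block_jackknife(same)
  expect_true(res0$degenerate)
  expect_true(is.na(res0$z))
  expect_error(block_jackknife(counts[1, ]), "at least 2")
})

test_that("frequency path equals discrete pattern counting when all calls
           are homozygous", {
  set.seed(9)
  geno <- matrix(2L * rbinom(400, 1, 0.4), 100, 4)
  gm <- make_gm(geno)
  counts <- count_site_patterns(
    gm, c(P1 = "s1", P2 = "s2", P3 = "s3", O = "s4"), n_blocks = 1)
  # oracle: enumerate sites, count discrete ABBA / BABA patterns
  p <- geno / 2
  abba <- sum(p[, 1] == 0 & p[, 2] == 1 & p[, 3] == 1 & p[, 4] == 0)
  baba <- sum(p[, 1] == 1 & p[, 2] == 0 & p[, 3] == 1 & p[, 4] == 0)
  expect_equal(counts$ABBA, abba)
  expect_equal(counts$BABA, baba)
})

test_that("pairwise scan produces one test per accession pair", {
  set.seed(11)
  geno <- matrix(sample(0:2, 700, replace = TRUE), 100, 7)
  gm <- make_gm(geno, samples = sprintf("s%d", 1:7),
                taxa = c("A", "A", "B", "B", "B", "P", "O"))
  tab <- pairwise_d_scan(gm, "A", "B", p1 = "s6", outgroup = "s7",
                         n_blocks = 5)
  expect_equal(nrow(tab), 6L)
  expect_true(all(diff(abs(tab$z)) <= 0))  # sorted by |z|
  expect_true("p_adj" %in% names(tab))
})

test_that("D_FOIL is zero under fully symmetric counts and classifies
           signatures from the published sign table", {
  blocks <- data.frame(block = 1:4)
  for (pat in introgressr:::dfoil_patterns) blocks[[pat]] <- 2
  blocks$n_sites <- 10
  class(blocks) <- c("pattern_counts5", "data.frame")
  res <- dfoil(blocks)
  expect_true(all(res$components$estimate == 0))
  expect_equal(res$classification, "none")

  expect_equal(classify_dfoil_signature(c(0, 0, 0, 0)), "none")
  expect_equal(classify_dfoil_signature(c(1, 1, 0, 0)), "ancestral")
  expect_equal(classify_dfoil_signature(c(-1, -1, 0, 0)), "ancestral")
  expect_equal(classify_dfoil_signature(c(1, 1, 1, 0)), "P1-P3")
  expect_equal(classify_dfoil_signature(c(0, 1, -1, -1)), "P2-P3")
  expect_equal(classify_dfoil_signature(c(1, -1, 0, 0)), "ambiguous")
})

test_that("five-taxon pattern weights multiply per-role frequencies", {
  # site with p = (1, 0, 1, 0, 0): pure BABAA
  gm <- make_gm(matrix(c(2L, 0L, 2L, 0L, 0L), 1, 5))
  roles <- c(P1 = "s1", P2 = "s2", P3 = "s3", P4 = "s4", O = "s5")
  c5 <- count_site_patterns5(gm, roles, n_blocks = 1)
  expect_equal(c5$BABAA, 1)
  other <- setdiff(introgressr:::dfoil_patterns, "BABAA")
  expect_true(all(unlist(c5[, other]) == 0))

  # heterozygous site spreads weight: p = (0.5, 0, 1, 0, 0)
  gmh <- make_gm(matrix(c(1L, 0L, 2L, 0L, 0L), 1, 5))
  ch <- count_site_patterns5(gmh, roles, n_blocks = 1)
  expect_equal(ch$BABAA, 0.5)
  expect_equal(ch$ABBAA, 0)
  expect_equal(ch$AABAA, 0.5)
})
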