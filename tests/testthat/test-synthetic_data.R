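# scenario helpers used across simulator tests
three_taxon_scenario <- function(T_cu, Ne = 1e4, tip_len = 2e4) {
  t1 <- tip_len
  t2 <- tip_len + T_cu * 2 * Ne
  sim_scenario(
    data.frame(pop = c("A", "B", "C", "AB", "R"),
               parent = c("AB", "AB", "R", "R", NA),
               t_join = c(t1, t1, t2, t2, Inf), Ne = Ne),
    samples_per_taxon = c(A = 1, B = 1, C = 1), ploidy = 1,
    n_regions = 10)
}

topology_freqs <- function(trees, labels = c("A_1", "B_1", "C_1")) {
  catalog <- enumerate_rooted_topologies(c("A", "B", "C"))
  grp <- stats::setNames(c("A", "B", "C"), labels)
  colMeans(weight_table(trees, grp, catalog))
}

test_that("scenario validation rejects inconsistent histories", {
  pops <- data.frame(pop = c("A", "B", "R"), parent = c("R", "R", NA),
                     t_join = c(100, 100, Inf), Ne = 10)
  expect_error(
    sim_scenario(pops, data.frame(donor = "A", recipient = "B",
                                  time = 150, gamma = 0.5),
                 samples_per_taxon = c(A = 1, B = 1)),
    "existence")
  expect_error(
    sim_scenario(pops, data.frame(donor = "A", recipient = "B",
                                  time = 50, gamma = 1.5),
                 samples_per_taxon = c(A = 1, B = 1)),
    "gamma")
  expect_error(sim_scenario(pops[1:2, ], samples_per_taxon = c(A = 1)),
               "root")
})

test_that("a long internal branch gives near-complete concordance", {
  sc <- three_taxon_scenario(T_cu = 20)
  gt <- simulate_gene_trees(sc, 2000, seed = 2)
  freqs <- topology_freqs(gt$trees)
  expect_gte(freqs[["((A,B),C)"]], 0.999)
})

test_that("a gamma = 1 event reroutes and flags every locus", {
  Ne <- 1e4
  pops <- data.frame(pop = c("A", "B", "C", "AB", "R"),
                     parent = c("AB", "AB", "R", "R", NA),
                     t_join = c(4e4, 4e4, 1e5, 1e5, Inf), Ne = Ne)
  ev <- data.frame(donor = "C", recipient = "B", time = 2e4, gamma = 1)
  sc <- sim_scenario(pops, ev, c(A = 1, B = 1, C = 1), ploidy = 1,
                     n_regions = 10)
  gt <- simulate_gene_trees(sc, 300, seed = 3)
  expect_true(all(gt$truth$introgressed))
  # with all B lineages rerouted into C well before the species split,
  # B and C coalesce first in nearly every genealogy
  freqs <- topology_freqs(gt$trees)
  expect_gt(freqs[["(A,(B,C))"]], 0.95)
})

test_that("introgressed-locus fraction tracks gamma", {
  Ne <- 1e4
  pops <- data.frame(pop = c("A", "B", "C", "AB", "R"),
                     parent = c("AB", "AB", "R", "R", NA),
                     t_join = c(4e4, 4e4, 1e5, 1e5, Inf), Ne = Ne)
  ev <- data.frame(donor = "C", recipient = "B", time = 2e4, gamma = 0.3)
  sc <- sim_scenario(pops, ev, c(A = 1, B = 1, C = 1), ploidy = 1,
                     n_regions = 10)
  gt <- simulate_gene_trees(sc, 2000, seed = 4)
  frac <- mean(gt$truth$introgressed)
  se <- sqrt(0.3 * 0.7 / 2000)
  expect_lt(abs(frac - 0.3), 3 * se)
})

test_that("mutation layer respects mu and the infinite-sites model", {
  sc0 <- sim_scenario(
    data.frame(pop = "A", parent = NA, t_join = Inf, Ne = 1e4),
    samples_per_taxon = c(A = 2), mu = 0, n_regions = 20,
    sites_per_region = 100,
    chromosome_layout = list(list(length = 1e6, rates = 1)))
  sim0 <- simulate_dataset(sc0, seed = 8)
  expect_equal(nrow(sim0$gm$sites), 0L)

  sc <- sim_scenario(
    data.frame(pop = "A", parent = NA, t_join = Inf, Ne = 1e4),
    samples_per_taxon = c(A = 3), mu = 1e-7, n_regions = 50,
    sites_per_region = 500,
    chromosome_layout = list(list(length = 5e6, rates = rep(1, 5))))
  sim <- simulate_dataset(sc, seed = 9)
  # biallelic, positions strictly increasing, within regions
  expect_true(all(sim$gm$sites$alt %in% c("A", "C", "G", "T")))
  expect_true(all(sim$gm$sites$ref != sim$gm$sites$alt))
  expect_true(all(diff(sim$gm$sites$pos) > 0))
})

test_that("neutral diversity matches theta = 4 Ne mu", {
  Ne <- 1e4
  mu <- 1e-7
  sc <- sim_scenario(
    data.frame(pop = "A", parent = NA, t_join = Inf, Ne = Ne),
    samples_per_taxon = c(A = 1), mu = mu, n_regions = 400,
    sites_per_region = 1000,
    chromosome_layout = list(list(length = 50e6, rates = rep(1, 50))))
  sim <- simulate_dataset(sc, seed = 10)
  pi_hat <- mean(region_pi(sim$gm, sim$regions, "A"), na.rm = TRUE)
  theta <- 4 * Ne * mu
  # per-locus pi is approximately exponential: sd ~ theta per locus
  mc_se <- theta / sqrt(400)
  expect_lt(abs(pi_hat - theta), 3 * mc_se + 0.1 * theta)
})

test_that("a fixed seed reproduces byte-identical artifacts", {
  sc <- preset_scenario("recent_sierran", n_regions = 30)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_dataset(sc, seed = 12, out_dir = d1)
  simulate_dataset(sc, seed = 12, out_dir = d2)
  for (f in c("genotypes.vcf", "regions.bed", "gene_trees.nwk",
              "map.tsv", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  d3 <- tempfile()
  simulate_dataset(sc, seed = 13, out_dir = d3)
  expect_false(identical(readLines(file.path(d1, "genotypes.vcf")),
                         readLines(file.path(d3, "genotypes.vcf"))))
})

test_that("region layout is non-overlapping with bin-rate annotation", {
  sc <- preset_scenario("recomb_coupled", n_regions = 400)
  rs <- layout_regions(sc, seed = 6)
  expect_equal(nrow(rs), 400L)
  for (chr in unique(rs$chrom)) {
    sub <- rs[rs$chrom == chr, ]
    expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
    expect_true(all(sub$end <= 20e6))
  }
  expect_true(all(rs$rec_rate >= 0.25 & rs$rec_rate <= 8))
  # coupling multiplier is monotone in the local rate
  o <- order(rs$rec_rate)
  expect_true(all(diff(rs$gamma_mult[o]) >= 0))
})

test_that("unknown presets are refused with the available list", {
  expect_error(preset_scenario("nope"), "ils_only")
  expect_null(preset_scenario("ils_only")$events)
})
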