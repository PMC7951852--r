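test_that("taxon map enforces a single, non-empty taxon per sample", {
  tm <- taxon_map(c("s1", "s2", "s3"), c("A", "A", "B"))
  expect_equal(tm$taxa, c("A", "B"))
  expect_equal(unname(tm$entries["s2"]), "A")
  expect_error(taxon_map(c("s1", "s1"), c("A", "B")), "duplicated")
  expect_error(taxon_map("s1", ""), "empty")
})

test_that("VCF reading filters multi-allelic records and codes dosage", {
  f <- tempfile(fileext = ".vcf")
  gt <- rbind(c("0/0", "0/1", "1/1", "0/0"),
              c("0/1", "0/0", "0/0", "1/1"),
              c("0/0", "1/2", "0/0", "0/0"),   # tri-allelic record
              c("1|0", "0|0", "./.", "0/1"))
  write_test_vcf(f, rep("chr1", 4), c(10, 20, 30, 40),
                 c("A", "C", "G", "T"), c("T", "G", "A,C", "C"),
                 gt, sprintf("s%d", 1:4))
  tm <- taxon_map(sprintf("s%d", 1:4), c("X", "X", "Y", "Y"))
  gm <- read_genotype_vcf(f, tm)
  expect_equal(nrow(gm$sites), 3L)  # tri-allelic dropped
  expect_equal(gm$sites$pos, c(9L, 19L, 39L))  # 0-based conversion
  expect_equal(unname(gm$geno[1, ]), c(0L, 1L, 2L, 0L))
  # "0/1" means dosage 1, per-sample frequency 0.5
  expect_equal(unname(gm$geno[1, 2]) / 2, 0.5)
  # half-call and ./. are missing; phased haplotype retained
  expect_true(is.na(gm$geno[3, 3]))
  expect_equal(unname(gm$hap1[3, 1]), 1L)
})

test_that("invariant records are kept only on request", {
  f <- tempfile(fileext = ".vcf")
  gt <- rbind(c("0/1", "0/0"), c("0/0", "0/0"), c("1/1", "0/1"),
              c("0/0", "0/0"), c("0/1", "1/1"))
  write_test_vcf(f, rep("chr1", 5), c(1, 2, 3, 4, 5),
                 rep("A", 5), c("T", ".", "G", ".", "C"),
                 gt, c("s1", "s2"))
  tm <- taxon_map(c("s1", "s2"), c("X", "Y"))
  expect_equal(nrow(read_genotype_vcf(f, tm)$sites), 3L)
  gm_inv <- read_genotype_vcf(f, tm, keep_invariant = TRUE)
  expect_equal(nrow(gm_inv$sites), 5L)
  expect_true(gm_inv$includes_invariant)
})

test_that("VCF reading errors name missing samples and detect disorder", {
  f <- tempfile(fileext = ".vcf")
  write_test_vcf(f, "chr1", 10, "A", "T",
                 matrix("0/1", 1, 2), c("s1", "s2"))
  tm <- taxon_map(c("s1", "s2", "s9"), c("X", "Y", "Z"))
  expect_error(read_genotype_vcf(f, tm), "s9")
  f2 <- tempfile(fileext = ".vcf")
  write_test_vcf(f2, c("chr1", "chr1"), c(20, 10), c("A", "C"),
                 c("T", "G"), matrix("0/1", 2, 2), c("s1", "s2"))
  expect_error(
    read_genotype_vcf(f2, taxon_map(c("s1", "s2"), c("X", "Y"))),
    "not sorted")
})

test_that("BED regions round-trip and are validated", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tg1", "chr1\t150\t300\tg2",
               "chr2\t0\t50\tg3"), f)
  rs <- read_regions_bed(f)
  expect_s3_class(rs, "region_set")
  expect_equal(rs$region_id, c("g1", "g2", "g3"))
  expect_equal(rs$start[1], 100L)
  expect_equal(rs$end[1], 200L)

  f2 <- tempfile(fileext = ".bed")
  write_bed(rs, f2)
  expect_equal(read_regions_bed(f2), rs)

  writeLines(c("chr1\t100\t200\tg1", "chr1\t10\t20\tg1"), f)
  expect_error(read_regions_bed(f), "duplicate")
  writeLines("chr1\t200\t100\tbad", f)
  expect_error(read_regions_bed(f), "start >= end")
  writeLines(character(0), f)
  expect_equal(nrow(read_regions_bed(f)), 0L)
})

test_that("Newick reading preserves structure and flags bad input", {
  f <- tempfile(fileext = ".nwk")
  writeLines(c("((a,b),c);", "((a:1,b:2):0.5,c:3);", "((a,b,c),d);"), f)
  trees <- read_newick(f)
  expect_length(trees, 3L)
  expect_equal(ape::Ntip(trees[[1]]), 3L)
  expect_equal(sort(trees[[2]]$edge.length), c(0.5, 1, 2, 3))
  expect_false(ape::is.binary(trees[[3]]))  # polytomy parsed, not fixed
  writeLines("((a,b),c;", f)
  expect_error(read_newick(f), "line 1")
})

test_that("linkage map reading sorts, validates and flags reversals", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("marker\tchrom\tbp\tcM", "m2\tchr1\t900000\t17.7",
               "m1\tchr1\t200000\t10"), f)
  lm <- read_linkage_map(f)
  expect_equal(lm$marker, c("m1", "m2"))
  expect_equal(attr(lm, "n_monotonicity_violations"), 0L)

  writeLines(c("marker\tchrom\tbp\tcM", "m1\tchr1\t100\t5",
               "m2\tchr1\t200\t3"), f)
  expect_equal(attr(read_linkage_map(f), "n_monotonicity_violations"), 1L)

  writeLines(c("marker\tchrom\tbp", "m1\tchr1\t100"), f)
  expect_error(read_linkage_map(f), "columns")
  writeLines(c("marker\tchrom\tbp\tcM", "m1\tchr1\t100\t-2"), f)
  expect_error(read_linkage_map(f), "negative")
})

test_that("gene alignment export writes variable sites with IUPAC hets", {
  geno <- rbind(c(0L, 1L, 2L), c(2L, 0L, 2L), c(0L, 0L, 0L),
                c(1L, 2L, 2L), c(0L, 2L, 2L))
  gm <- make_gm(geno, accessible = c(r1 = 5))
  gm$sites$ref <- c("A", "C", "G", "T", "A")
  gm$sites$alt <- c("G", "T", "A", "C", "T")
  out <- tempfile()
  export_gene_alignments(gm, one_region(5), out)
  lines <- readLines(file.path(out, "r1.fasta"))
  expect_length(lines, 6L)
  # site 3 is invariant: sequences have 4 characters
  expect_equal(nchar(lines[2]), 4L)
  # sample 3 is homozygous-derived at all variable sites -> all ALT
  expect_equal(lines[6], "GTCT")
  # sample 1: ancestral, derived, het (IUPAC Y for C/T), ancestral
  expect_equal(lines[2], "ATYA")

  # region with no variable sites is skipped
  gm0 <- make_gm(matrix(0L, 3, 2), accessible = c(r1 = 3))
  out0 <- tempfile()
  files <- export_gene_alignments(gm0, one_region(3), out0)
  expect_length(files, 0L)
})

test_that("phased haplotype export splits heterozygotes", {
  geno <- rbind(c(1L, 0L), c(1L, 2L))
  hap1 <- rbind(c(1L, 0L), c(0L, 1L))
  gm <- make_gm(geno, hap1 = hap1, accessible = c(r1 = 2))
  out <- tempfile()
  export_gene_alignments(gm, one_region(2), out, haplotype = 1)
  lines <- readLines(file.path(out, "r1.fasta"))
  expect_equal(lines[2], "TA")  # hap1 of s1: derived, ancestral
  out2 <- tempfile()
  export_gene_alignments(gm, one_region(2), out2, haplotype = 2)
  expect_equal(readLines(file.path(out2, "r1.fasta"))[2], "AT")
})

test_that("simulated VCF round-trips to the in-memory dosage matrix", {
  sc <- preset_scenario("ils_only", n_regions = 40)
  sim <- simulate_dataset(sc, seed = 5)
  f <- tempfile(fileext = ".vcf")
  write_vcf(sim$gm, f)
  gm2 <- read_genotype_vcf(f, sim$gm$taxon_map)
  expect_equal(gm2$geno, sim$gm$geno)
  expect_equal(gm2$sites$pos, sim$gm$sites$pos)
  expect_equal(gm2$hap1, sim$gm$hap1)
})
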