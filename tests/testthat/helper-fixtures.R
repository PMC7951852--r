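# Shared fixtures, all built in code at test time.

options(introgressr.quiet = TRUE)

# minimal VCF text from a site table and GT string matrix
write_test_vcf <- function(path, chrom, pos, ref, alt, gt, samples) {
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  for (i in seq_along(pos)) {
    lines <- c(lines, paste(c(chrom[i], pos[i], ".", ref[i], alt[i], ".",
                              ".", ".", "GT", gt[i, ]), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

# genotype_matrix from a bare dosage matrix (one chromosome, unit spacing)
make_gm <- function(geno, samples = NULL, taxa = NULL, chrom = "chr1",
                    accessible = NULL, hap1 = NULL) {
  geno <- as.matrix(geno)
  samples <- samples %||% sprintf("s%d", seq_len(ncol(geno)))
  taxa <- taxa %||% samples
  sites <- data.frame(chrom = chrom, pos = seq_len(nrow(geno)) - 1L,
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
  genotype_matrix(sites, geno, samples, taxon_map(samples, taxa),
                  accessible = accessible, hap1 = hap1,
                  phased = !is.null(hap1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one-region region_set covering the first `n` unit positions
one_region <- function(n, id = "r1", chrom = "chr1") {
  region_set(id, chrom, 0L, n)
}

# random rooted binary tree with tips assigned to groups round-robin
random_grouped_tree <- function(n_tips, n_groups) {
  phy <- ape::rtree(n_tips, rooted = TRUE)
  phy$tip.label <- sprintf("t%d", seq_len(n_tips))
  groups <- stats::setNames(
    LETTERS[rep_len(seq_len(n_groups), n_tips)], phy$tip.label)
  list(phy = phy, groups = groups)
}

# Brute-force topology-weight oracle: for every one-tip-per-group
# combination, prune with ape::keep.tip, relabel tips by group, and find
# the unique catalog topology at Robinson-Foulds distance zero (rooted,
# via phangorn) after re-parsing both trees from Newick text.
oracle_weights <- function(phy, groups, catalog) {
  glev <- sort(unique(groups), method = "radix")
  tip_sets <- lapply(glev, function(g) names(groups)[groups == g])
  combos <- expand.grid(tip_sets, stringsAsFactors = FALSE)
  cat_phys <- lapply(catalog$topologies, function(s) {
    ape::read.tree(text = paste0("(", s, ",ORACLE_ROOT);"))
  })
  w <- numeric(length(catalog$topologies))
  for (i in seq_len(nrow(combos))) {
    tips <- unlist(combos[i, ])
    sub <- ape::keep.tip(phy, tips)
    sub$tip.label <- glev[match(sub$tip.label, tips)]
    sub <- ape::read.tree(text = ape::write.tree(sub))  # naive re-parse
    sub$edge.length <- NULL
    core <- sub(";$", "", ape::write.tree(sub))
    sub_rooted <- ape::read.tree(
      text = paste0("(", core, ",ORACLE_ROOT);"))
    hits <- which(vapply(cat_phys, function(ct) {
      phangorn::RF.dist(sub_rooted, ct) == 0
    }, logical(1)))
    stopifnot(length(hits) == 1L)
    w[hits] <- w[hits] + 1
  }
  w / nrow(combos)
}
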