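# Topology weighting: the weight of topology T for a gene tree is the
# fraction of one-tip-per-group subtrees (one sampled tip per taxon) whose
# induced rooted topology is T.

# topological depth (edges from root) of every node
node_depths <- function(phy) {
  n <- ape::Ntip(phy)
  depth <- integer(n + phy$Nnode)
  e <- ape::reorder.phylo(phy, "cladewise")$edge
  for (k in seq_len(nrow(e))) depth[e[k, 2L]] <- depth[e[k, 1L]] + 1L
  depth
}

# tip x tip matrix of MRCA topological depths
mrca_depth_matrix <- function(phy) {
  M <- ape::mrca(phy)
  d <- node_depths(phy)
  D <- matrix(d[M], nrow(M), ncol(M))
  storage.mode(D) <- "integer"
  rownames(D) <- colnames(D) <- phy$tip.label
  D
}

# tips per group, in deterministic group order
group_tips <- function(phy, groups) {
  glev <- radix_sort(unique(groups))
  out <- lapply(glev, function(g) {
    tips <- names(groups)[groups == g]
    tips <- tips[tips %in% phy$tip.label]
    match(tips, phy$tip.label)
  })
  names(out) <- glev
  empty <- lengths(out) == 0L
  if (any(empty)) {
    stop("group(s) with no tips in tree: ",
         paste(glev[empty], collapse = ", "))
  }
  out
}

#' Topology weights for a single gene tree
#'
#' Evaluates, exhaustively or by uniform sampling, all combinations of one
#' tip per group, prunes the gene tree to each combination, and tallies the
#' induced rooted topology against the catalog.
#'
#' @param phy A rooted binary `phylo` gene tree (tips are typically
#'   haplotypes).
#' @param groups Named character vector: tip label -> group (taxon) label.
#'   Tips absent from `groups` are ignored.
#' @param catalog A [enumerate_rooted_topologies()] catalog over the group
#'   labels.
#' @param mode `"auto"` (exhaustive when the number of combinations is at
#'   most `max_exhaustive`, sampled otherwise), `"exhaustive"`, or
#'   `"sampled"`.
#' @param n_iter Number of sampled combinations in sampled mode.
#' @param max_exhaustive Combination-count threshold for auto mode.
#' @param resolve_polytomies If `TRUE`, polytomies are resolved uniformly at
#'   random once per tree; the default is to refuse non-binary trees.
#' @return Numeric weight vector over `catalog$topologies` summing to 1,
#'   with attributes `n_combinations` (total one-tip-per-group
#'   combinations) and `method`.
#' @export
weight_gene_tree <- function(phy, groups, catalog,
                             mode = c("auto", "exhaustive", "sampled"),
                             n_iter = 10000L, max_exhaustive = 10000L,
                             resolve_polytomies = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(catalog, "topology_catalog"))
  if (!ape::is.binary(phy)) {
    if (!resolve_polytomies) {
      stop("gene tree contains polytomies; set resolve_polytomies = TRUE ",
           "to resolve them uniformly at random")
    }
    phy <- ape::multi2di(phy)
  }
  gt <- group_tips(phy, groups)
  if (!setequal(names(gt), catalog$taxa)) {
    stop("group labels do not match catalog taxa")
  }
  gt <- gt[catalog$taxa]
  sizes <- lengths(gt)
  n_comb <- prod(sizes)
  use_exhaustive <- switch(mode,
                           exhaustive = TRUE,
                           sampled = FALSE,
                           auto = n_comb <= max_exhaustive)
  D <- mrca_depth_matrix(phy)
  if (use_exhaustive) {
    combos <- as.matrix(expand.grid(gt, KEEP.OUT.ATTRS = FALSE))
    denom <- nrow(combos)
    method <- "exhaustive"
  } else {
    combos <- vapply(gt, function(tips) {
      tips[sample.int(length(tips), n_iter, replace = TRUE)]
    }, integer(n_iter))
    denom <- n_iter
    method <- "sampled"
  }
  storage.mode(combos) <- "integer"
  induced <- induce_topologies(D, combos, catalog$taxa)
  idx <- match(induced, catalog$topologies)
  if (anyNA(idx)) {
    stop("internal error: induced topology not found in catalog ",
         "(canonicalization bug)")
  }
  w <- tabulate(idx, nbins = length(catalog$topologies)) / denom
  names(w) <- catalog$topologies
  attr(w, "n_combinations") <- n_comb
  attr(w, "method") <- method
  w
}

#' Topology weight table for a set of gene trees
#'
#' Applies [weight_gene_tree()] to each tree; rows follow the input order
#' (use the region order of the associated [region_set()]).
#'
#' @param trees `multiPhylo` (or list of `phylo`).
#' @param groups Named character vector tip -> group, or a [taxon_map()]
#'   whose samples are tip-label prefixes (haplotype tips `<sample>_A/_B`
#'   are matched to their sample automatically).
#' @param catalog Topology catalog over the groups.
#' @param region_ids Optional row names (defaults to `tree_<i>`).
#' @param seed Seed used for sampled mode (set once before the loop).
#' @inheritParams weight_gene_tree
#' @return Matrix of class `weight_table` (regions x topologies, rows sum
#'   to 1) with attributes `method`, `n_iter`, `seed` and per-region
#'   `n_combinations`.
#' @export
weight_table <- function(trees, groups, catalog, region_ids = NULL,
                         mode = "auto", n_iter = 10000L,
                         max_exhaustive = 10000L, seed = 1L,
                         resolve_polytomies = FALSE) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (inherits(groups, "taxon_map")) {
    groups <- expand_taxon_map_to_tips(groups, trees[[1L]]$tip.label)
  }
  set.seed(seed)
  n <- length(trees)
  W <- matrix(0, n, length(catalog$topologies),
              dimnames = list(region_ids %||% sprintf("tree_%d", seq_len(n)),
                              catalog$topologies))
  ncomb <- numeric(n)
  meth <- character(n)
  for (i in seq_len(n)) {
    w <- weight_gene_tree(trees[[i]], groups, catalog, mode = mode,
                          n_iter = n_iter, max_exhaustive = max_exhaustive,
                          resolve_polytomies = resolve_polytomies)
    W[i, ] <- w
    ncomb[i] <- attr(w, "n_combinations")
    meth[i] <- attr(w, "method")
  }
  structure(W, class = c("weight_table", "matrix"),
            method = if (all(meth == "exhaustive")) "exhaustive" else
              if (all(meth == "sampled")) "sampled" else "mixed",
            n_iter = n_iter, seed = seed, n_combinations = ncomb)
}

#' @export
`[.weight_table` <- function(x, i, j, drop = FALSE) {
  nc <- attr(x, "n_combinations")
  y <- unclass(x)[i, j, drop = FALSE]
  structure(y, class = c("weight_table", "matrix"),
            method = attr(x, "method"), n_iter = attr(x, "n_iter"),
            seed = attr(x, "seed"),
            n_combinations = if (!is.null(nc) && !missing(i)) nc[i] else nc)
}

# map haplotype tip labels "<sample>_A"/"<sample>_B" (or bare sample
# labels) to the sample's taxon
expand_taxon_map_to_tips <- function(tm, tip_labels) {
  base <- sub("_[AB]$", "", tip_labels)
  taxon <- tm$entries[base]
  if (anyNA(taxon)) {
    stop("tip label(s) not resolvable to a mapped sample: ",
         paste(tip_labels[is.na(taxon)], collapse = ", "))
  }
  stats::setNames(as.character(taxon), tip_labels)
}

#' Aggregate topology weights by a clade of interest
#'
#' Per region, sums the weights of all catalog topologies in which `clade`
#' is monophyletic — e.g. support for a "species tree" class defined by one
#' diagnostic clade rather than a single fully resolved topology.
#'
#' @param wt A [weight_table()].
#' @param catalog The catalog the table was computed against.
#' @param clade Character vector of group labels, with
#'   `2 <= length(clade) < n`.
#' @return Named numeric vector, one aggregated weight per region.
#' @export
aggregate_clade_support <- function(wt, catalog, clade) {
  stopifnot(inherits(wt, "weight_table"),
            inherits(catalog, "topology_catalog"))
  clade <- as.character(clade)
  if (!all(clade %in% catalog$taxa)) stop("clade labels not in catalog")
  if (length(clade) < 2L || length(clade) >= length(catalog$taxa)) {
    stop("clade must be a proper subset with at least 2 taxa")
  }
  sel <- vapply(catalog$topologies, topology_has_clade, logical(1),
                clade = clade)
  rowSums(wt[, sel, drop = FALSE])
}

#' Average topology weights in sliding windows of consecutive genes
#'
#' Windows of `window` consecutive regions per chromosome with stride 1;
#' each window's weight vector is the mean of its members (still summing
#' to 1) and its coordinate is the median of the member regions' midpoints.
#' Chromosomes with fewer regions than `window` contribute one
#' whole-chromosome window (logged).
#'
#' @param wt A [weight_table()] whose rows follow `rs`.
#' @param rs The [region_set()] the rows correspond to.
#' @param window Window size in genes (default 5).
#' @return data.frame with `chrom`, `midpoint`, `n_genes`, and one column
#'   per topology.
#' @export
window_average_weights <- function(wt, rs, window = 5L) {
  stopifnot(inherits(wt, "weight_table"), inherits(rs, "region_set"),
            nrow(wt) == nrow(rs))
  out <- list()
  mid <- (rs$start + rs$end) / 2
  for (chr in unique(rs$chrom)) {
    idx <- which(rs$chrom == chr)
    if (length(idx) < window) {
      ig_log("chromosome %s has %d < %d genes: single window emitted",
             chr, length(idx), window)
      starts <- 1L
      len <- length(idx)
    } else {
      starts <- seq_len(length(idx) - window + 1L)
      len <- window
    }
    for (s in starts) {
      rows <- idx[s:(s + len - 1L)]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr,
        midpoint = stats::median(mid[rows]),
        n_genes = len,
        t(colMeans(wt[rows, , drop = FALSE])),
        check.names = FALSE, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genome-wide weight summaries
#'
#' Two aggregations of per-tree weights into a genome-wide "percent of
#' subtrees" figure: the combination-count-weighted mean (pooling all
#' one-tip-per-group subtrees across trees) and the unweighted mean of
#' per-tree weights.
#'
#' @param wt A [weight_table()].
#' @return data.frame with one row per topology and columns
#'   `pooled_subtree_share` and `mean_tree_weight`.
#' @export
summarize_weights <- function(wt) {
  stopifnot(inherits(wt, "weight_table"))
  nc <- attr(wt, "n_combinations") %||% rep(1, nrow(wt))
  pooled <- colSums(wt * nc) / sum(nc)
  data.frame(topology = colnames(wt),
             pooled_subtree_share = as.numeric(pooled),
             mean_tree_weight = as.numeric(colMeans(wt)),
             stringsAsFactors = FALSE)
}

#' Quartet concordance for a species-tree branch
#'
#' For a branch expressed as the quartet bipartition
#' `{g1, g2} | {g3, g4}` of four groups, computes per gene tree the
#' exhaustive one-tip-per-group weight of the matching unrooted quartet and
#' averages over trees: the proportion of gene-tree signal supporting the
#' branch.
#'
#' @param trees `multiPhylo`.
#' @param groups Named character vector tip -> group (or [taxon_map()]).
#' @param quartet list of two character vectors of two group labels each.
#' @return list of class `quartet_support`: `q` (mean support),
#'   `per_tree`, `n_trees_used`.
#' @export
quartet_concordance <- function(trees, groups, quartet) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0L) stop("no usable trees")
  if (inherits(groups, "taxon_map")) {
    groups <- expand_taxon_map_to_tips(groups, trees[[1L]]$tip.label)
  }
  stopifnot(length(quartet) == 2L, lengths(quartet) == c(2L, 2L))
  g4 <- unlist(quartet)
  catalog <- enumerate_rooted_topologies(g4)
  # topologies whose unrooted reduction is g1g2 | g3g4: those where either
  # pair forms a cherry (clade)
  match_split <- vapply(catalog$topologies, function(s) {
    topology_has_clade(s, quartet[[1L]]) || topology_has_clade(s, quartet[[2L]])
  }, logical(1))
  sub_groups <- groups[groups %in% g4]
  per_tree <- vapply(trees, function(phy) {
    w <- weight_gene_tree(phy, sub_groups, catalog, mode = "exhaustive")
    sum(w[match_split])
  }, numeric(1))
  structure(list(q = mean(per_tree), per_tree = per_tree,
                 n_trees_used = length(trees), quartet = quartet),
            class = "quartet_support")
}

#' @export
print.quartet_support <- function(x, ...) {
  cat(sprintf("quartet support {%s}|{%s}: q = %.4f over %d trees\n",
              paste(x$quartet[[1L]], collapse = ","),
              paste(x$quartet[[2L]], collapse = ","),
              x$q, x$n_trees_used))
  invisible(x)
}
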