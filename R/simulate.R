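# Coalescent machinery: one non-recombining locus per region, lineages
# traced backward through the population tree, introgression as per-lineage
# Bernoulli(gamma) rerouting at event times.

# per-scenario constants hoisted out of the per-locus loop; populations are
# recoded as integers so the hot loop is free of name lookups
sim_context <- function(sc) {
  pop_names <- sc$pops$pop
  code <- stats::setNames(seq_along(pop_names), pop_names)
  fin <- is.finite(sc$pops$t_join)
  tl <- data.frame(time = sc$pops$t_join[fin],
                   is_join = rep(TRUE, sum(fin)),
                   pop = unname(code[sc$pops$pop[fin]]),
                   donor = rep(NA_integer_, sum(fin)),
                   gamma = rep(NA_real_, sum(fin)))
  if (!is.null(sc$events) && nrow(sc$events)) {
    tl <- rbind(tl, data.frame(time = sc$events$time, is_join = FALSE,
                               pop = unname(code[sc$events$recipient]),
                               donor = unname(code[sc$events$donor]),
                               gamma = sc$events$gamma))
  }
  tl <- tl[order(tl$time, tl$is_join), ]  # intro before join at ties
  haps <- scenario_haplotypes(sc)
  list(
    tl_time = tl$time, tl_join = tl$is_join, tl_pop = tl$pop,
    tl_donor = tl$donor, tl_gamma = tl$gamma,
    lin_pop0 = unname(code[rep(names(haps), lengths(haps))]),
    labels = unlist(haps, use.names = FALSE),
    two_ne = 2 * sc$pops$Ne,
    parent = unname(code[sc$pops$parent]),
    n_pops = length(pop_names))
}

# Simulate one gene tree. Returns list(newick, introgressed).
sim_locus_tree <- function(sc, gamma_mult = 1, ctx = sim_context(sc)) {
  lin_pop <- ctx$lin_pop0
  lin_str <- ctx$labels
  n_lin <- length(lin_str)
  lin_h <- rep(0, n_lin)
  alive <- rep(TRUE, n_lin)
  counts <- tabulate(lin_pop, ctx$n_pops)
  two_ne <- ctx$two_ne
  introgressed <- FALSE
  t <- 0
  n_alive <- n_lin
  n_ev <- length(ctx$tl_time)
  bounds <- c(ctx$tl_time, Inf)

  for (ev in seq_len(n_ev + 1L)) {
    t_end <- bounds[ev]
    # coalesce within populations until the next demographic event
    repeat {
      if (n_alive <= 1L) break
      rates <- counts * (counts - 1L) / 2 / two_ne
      total <- sum(rates)
      if (total == 0) break
      wait <- stats::rexp(1L, total)
      if (t + wait >= t_end) break
      t <- t + wait
      pop <- sample.int(ctx$n_pops, 1L, prob = rates)
      members <- which(alive & lin_pop == pop)
      pair <- members[sample.int(length(members), 2L)]
      i <- pair[1L]; j <- pair[2L]
      lin_str[i] <- sprintf("(%s:%.8f,%s:%.8f)", lin_str[i], t - lin_h[i],
                            lin_str[j], t - lin_h[j])
      lin_h[i] <- t
      alive[j] <- FALSE
      counts[pop] <- counts[pop] - 1L
      n_alive <- n_alive - 1L
    }
    if (ev > n_ev) break
    t <- t_end
    pop <- ctx$tl_pop[ev]
    if (ctx$tl_join[ev]) {
      members <- alive & lin_pop == pop
      if (any(members)) {
        lin_pop[members] <- ctx$parent[pop]
        counts[ctx$parent[pop]] <- counts[ctx$parent[pop]] + counts[pop]
        counts[pop] <- 0L
      }
    } else {
      g <- min(1, ctx$tl_gamma[ev] * gamma_mult)
      in_rec <- which(alive & lin_pop == pop)
      if (length(in_rec)) {
        switch_idx <- in_rec[stats::runif(length(in_rec)) < g]
        if (length(switch_idx)) {
          lin_pop[switch_idx] <- ctx$tl_donor[ev]
          counts[pop] <- counts[pop] - length(switch_idx)
          counts[ctx$tl_donor[ev]] <- counts[ctx$tl_donor[ev]] +
            length(switch_idx)
          introgressed <- TRUE
        }
      }
    }
  }
  list(newick = paste0(lin_str[alive], ";"), introgressed = introgressed)
}

#' Simulate gene trees under the network coalescent
#'
#' Each locus is a single non-recombining genealogy: lineages coalesce
#' within species-tree branches at rate `k(k-1)/2 / (2 Ne)` and, at each
#' introgression event, every lineage currently in the recipient branch
#' switches to the donor independently with probability
#' `gamma * gamma_mult[locus]`. Trees are binary and ultrametric with
#' branch lengths in generations.
#'
#' @param sc A [sim_scenario()].
#' @param n_loci Number of loci.
#' @param seed Integer seed.
#' @param gamma_mult Numeric vector (recycled) of per-locus multipliers on
#'   every event's `gamma` (used for recombination-coupled introgression).
#' @return list with `trees` (a `multiPhylo`) and `truth`, a data.frame
#'   with per-locus columns `introgressed` and `gamma_mult`.
#' @export
simulate_gene_trees <- function(sc, n_loci, seed, gamma_mult = 1) {
  stopifnot(inherits(sc, "sim_scenario"))
  set.seed(seed)
  gamma_mult <- rep_len(gamma_mult, n_loci)
  ctx <- sim_context(sc)
  res <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    res[[i]] <- sim_locus_tree(sc, gamma_mult[i], ctx)
  }
  nw <- vapply(res, `[[`, character(1), "newick")
  trees <- ape::read.tree(text = paste(nw, collapse = "\n"))
  if (inherits(trees, "phylo")) trees <- c(trees)
  truth <- data.frame(
    locus = seq_len(n_loci),
    introgressed = vapply(res, `[[`, logical(1), "introgressed"),
    gamma_mult = gamma_mult)
  list(trees = trees, truth = truth)
}

# per-node tip-descendant lists (indices into tip labels)
node_tip_descendants <- function(phy) {
  n <- ape::Ntip(phy)
  m <- phy$Nnode
  sets <- vector("list", n + m)
  for (i in seq_len(n)) sets[[i]] <- i
  e <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in seq_len(nrow(e))) {
    sets[[e[k, 1L]]] <- c(sets[[e[k, 1L]]], sets[[e[k, 2L]]])
  }
  sets
}

#' Overlay infinite-sites mutations on simulated gene trees
#'
#' Mutations fall on tree branches as a Poisson process with rate `mu` per
#' site per generation; each mutation occupies a distinct position within
#' its region (collisions resolved by redrawing the position) and defines
#' the derived (ALT) allele. Haplotypes are paired into diploid samples.
#'
#' @param trees `multiPhylo` from [simulate_gene_trees()].
#' @param sc The scenario that produced them.
#' @param seed Integer seed.
#' @param regions Optional [region_set()] giving each locus its genomic
#'   location (defaults to [layout_regions()] with a seed derived from
#'   `seed`).
#' @return list with `gm` (a [genotype_matrix()], `accessible` filled with
#'   the region lengths) and `regions`.
#' @export
simulate_genotypes <- function(trees, sc, seed, regions = NULL) {
  stopifnot(inherits(sc, "sim_scenario"))
  set.seed(seed)
  if (is.null(regions)) {
    regions <- layout_regions(sc, seed = sample.int(2^31 - 1, 1L))
  }
  n_loci <- length(trees)
  stopifnot(nrow(regions) == n_loci)
  haps <- unlist(scenario_haplotypes(sc), use.names = FALSE)
  nh <- length(haps)
  L <- sc$sites_per_region
  chrom_l <- character(0); pos_l <- integer(0)
  H_l <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    phy <- trees[[i]]
    elen <- phy$edge.length
    n_mut <- stats::rpois(1L, sc$mu * L * sum(elen))
    n_mut <- min(n_mut, L)  # finite region: at most one mutation per site
    if (n_mut == 0L) { H_l[[i]] <- NULL; next }
    pos <- sort(sample.int(L, n_mut))  # distinct positions (infinite sites)
    edge_of <- sample.int(nrow(phy$edge), n_mut, replace = TRUE,
                          prob = elen)
    sets <- node_tip_descendants(phy)
    tip_idx <- match(haps, phy$tip.label)
    H <- matrix(0L, n_mut, nh)
    for (k in seq_len(n_mut)) {
      carriers <- sets[[phy$edge[edge_of[k], 2L]]]
      H[k, match(carriers, tip_idx)] <- 1L
    }
    H_l[[i]] <- list(pos = regions$start[i] + pos - 1L,
                     chrom = regions$chrom[i], H = H)
  }
  keep <- !vapply(H_l, is.null, logical(1))
  if (any(keep)) {
    chrom_l <- unlist(lapply(H_l[keep], function(x) {
      rep(x$chrom, nrow(x$H))
    }))
    pos_l <- unlist(lapply(H_l[keep], `[[`, "pos"))
    H <- do.call(rbind, lapply(H_l[keep], `[[`, "H"))
  } else {
    H <- matrix(0L, 0L, nh)
  }
  nsite <- nrow(H)
  acgt <- c("A", "C", "G", "T")
  ref <- acgt[sample.int(4L, nsite, replace = TRUE)]
  alt <- acgt[(match(ref, acgt) + sample.int(3L, nsite, replace = TRUE) -
                 1L) %% 4L + 1L]
  tm <- scenario_taxon_map(sc)
  samples <- names(tm$entries)
  if (sc$ploidy == 2L) {
    a_cols <- seq(1L, nh, by = 2L)
    geno <- H[, a_cols, drop = FALSE] + H[, a_cols + 1L, drop = FALSE]
    hap1 <- H[, a_cols, drop = FALSE]
  } else {
    geno <- 2L * H   # haploid lineages reported as homozygous diploids
    hap1 <- H
  }
  sites <- data.frame(chrom = chrom_l, pos = pos_l, ref = ref, alt = alt,
                      stringsAsFactors = FALSE)
  o <- order(sites$chrom, sites$pos)
  gm <- genotype_matrix(sites[o, , drop = FALSE],
                        geno[o, , drop = FALSE], samples, tm,
                        includes_invariant = FALSE,
                        hap1 = hap1[o, , drop = FALSE], phased = TRUE,
                        accessible = stats::setNames(
                          rep(L, nrow(regions)), regions$region_id))
  list(gm = gm, regions = regions)
}

#' Lay regions out along the scenario's chromosomes
#'
#' Regions are spread over chromosomes proportionally to length and placed
#' on an evenly spaced grid with uniform jitter (non-overlapping). Each
#' region is annotated with the recombination rate of the 1-Mbp bin holding
#' its midpoint and with the introgression multiplier obtained by passing
#' that rate through the scenario's coupling function (1 when no coupling).
#'
#' @param sc A [sim_scenario()] with a `chromosome_layout`.
#' @param seed Integer seed.
#' @return A [region_set()] with extra columns `rec_rate` and `gamma_mult`.
#' @export
layout_regions <- function(sc, seed) {
  stopifnot(inherits(sc, "sim_scenario"))
  if (is.null(sc$chromosome_layout)) {
    stop("scenario has no chromosome_layout")
  }
  set.seed(seed)
  lens <- vapply(sc$chromosome_layout, `[[`, numeric(1), "length")
  n_chr <- length(lens)
  chr_names <- names(sc$chromosome_layout) %||% sprintf("chr%d", 1:n_chr)
  n_per <- floor(sc$n_regions * lens / sum(lens))
  rem <- sc$n_regions - sum(n_per)
  if (rem > 0) n_per[seq_len(rem)] <- n_per[seq_len(rem)] + 1L
  L <- sc$sites_per_region
  out <- vector("list", n_chr)
  for (c_i in seq_len(n_chr)) {
    n <- n_per[c_i]
    if (n == 0L) next
    slot <- lens[c_i] / n
    if (slot < L) stop("too many regions for chromosome length")
    jitter <- floor(stats::runif(n) * (slot - L))
    start <- as.integer(floor((seq_len(n) - 1) * slot) + jitter)
    rates <- sc$chromosome_layout[[c_i]]$rates
    bin <- pmin(floor((start + L / 2) / 1e6) + 1L, length(rates))
    out[[c_i]] <- data.frame(
      region_id = sprintf("%s_g%04d", chr_names[c_i], seq_len(n)),
      chrom = chr_names[c_i], start = start, end = start + L,
      rec_rate = rates[bin], stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rs <- region_set(df$region_id, df$chrom, df$start, df$end)
  rs$rec_rate <- df$rec_rate[match(rs$region_id, df$region_id)]
  rs$gamma_mult <- if (is.null(sc$coupling)) 1 else sc$coupling(rs$rec_rate)
  rs
}

#' Simulate a linkage map from the scenario's recombination landscape
#'
#' Markers are placed uniformly at random along each chromosome; the
#' genetic position of a marker is the cumulative integral of the per-bin
#' cM/Mbp rates up to its physical position, so the realized per-bin rate
#' is recoverable from the emitted map.
#'
#' @param sc A [sim_scenario()] with a `chromosome_layout`.
#' @param seed Integer seed.
#' @param markers_per_mbp Average marker density (default 10 / Mbp).
#' @return A `linkage_map`.
#' @export
simulate_linkage_map <- function(sc, seed, markers_per_mbp = 10) {
  stopifnot(inherits(sc, "sim_scenario"))
  if (is.null(sc$chromosome_layout)) {
    stop("scenario has no chromosome_layout")
  }
  set.seed(seed)
  chr_names <- names(sc$chromosome_layout) %||%
    sprintf("chr%d", seq_along(sc$chromosome_layout))
  out <- vector("list", length(chr_names))
  for (i in seq_along(chr_names)) {
    cl <- sc$chromosome_layout[[i]]
    n_m <- max(2L, round(cl$length / 1e6 * markers_per_mbp))
    bp <- sort(sample.int(cl$length, n_m))
    cum <- c(0, cumsum(cl$rates))  # cM at bin boundaries (bins are 1 Mbp)
    bin <- pmin(floor((bp - 1) / 1e6), length(cl$rates) - 1L)
    cm <- cum[bin + 1L] + cl$rates[bin + 1L] * (bp - bin * 1e6) / 1e6
    out[[i]] <- data.frame(marker = sprintf("%s_m%04d", chr_names[i],
                                            seq_len(n_m)),
                           chrom = chr_names[i], bp = bp, cM = cm,
                           stringsAsFactors = FALSE)
  }
  linkage_map(do.call(rbind, out))
}

#' Simulate a complete data set (regions, gene trees, genotypes, map)
#'
#' Expands `seed` deterministically into per-stage child seeds, lays out
#' regions, simulates gene trees (with recombination-coupled effective
#' gamma when the scenario defines a coupling), drops mutations, and builds
#' the linkage map. Optionally serializes VCF/BED/Newick/TSV to `out_dir`.
#'
#' @param sc A [sim_scenario()].
#' @param seed Integer seed; a run with the same scenario and seed is
#'   byte-identical.
#' @param out_dir Optional output directory for on-disk artifacts.
#' @return list with `gm`, `regions`, `trees`, `truth` (per-region tree
#'   index, introgression flag, bin recombination rate, effective-gamma
#'   multiplier), `map`, and `scenario`.
#' @export
simulate_dataset <- function(sc, seed, out_dir = NULL) {
  stopifnot(inherits(sc, "sim_scenario"))
  set.seed(seed)
  child <- sample.int(2^31 - 1, 4L)
  regions <- layout_regions(sc, child[1L])
  gt <- simulate_gene_trees(sc, nrow(regions), child[2L],
                            gamma_mult = regions$gamma_mult)
  sim <- simulate_genotypes(gt$trees, sc, child[3L], regions = regions)
  map <- if (is.null(sc$chromosome_layout)) NULL else {
    simulate_linkage_map(sc, child[4L])
  }
  truth <- data.frame(region_id = regions$region_id,
                      introgressed = gt$truth$introgressed,
                      rec_rate = regions$rec_rate,
                      gamma_mult = regions$gamma_mult,
                      stringsAsFactors = FALSE)
  res <- list(gm = sim$gm, regions = regions, trees = gt$trees,
              truth = truth, map = map, scenario = sc)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_vcf(sim$gm, file.path(out_dir, "genotypes.vcf"))
    write_bed(regions, file.path(out_dir, "regions.bed"))
    write_newick(gt$trees, file.path(out_dir, "gene_trees.nwk"))
    if (!is.null(map)) write_linkage_map(map, file.path(out_dir, "map.tsv"))
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  res
}
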