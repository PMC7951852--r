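# Per-region nucleotide diversity and divergence from per-site allele
# counts, with denominators over accessible (callable) sites so that
# invariant positions count toward the per-site scaling.

# accessible-site count per region: explicit vector on gm, else all sites
# present in gm (requires invariant sites to be meaningful)
region_accessible <- function(gm, rs, idx_list) {
  if (!is.null(gm$accessible)) {
    acc <- gm$accessible[rs$region_id]
    if (anyNA(acc)) stop("accessible-site counts missing for region(s): ",
                         paste(rs$region_id[is.na(acc)], collapse = ", "))
    return(as.numeric(acc))
  }
  if (!gm$includes_invariant) {
    stop("pi/dxy need invariant sites in the genotype matrix or an ",
         "`accessible` annotation for correct per-site denominators")
  }
  vapply(idx_list, length, numeric(1))
}

# derived allele count and called-haplotype count per site for a sample set
site_allele_counts <- function(gm, samples) {
  cols <- match(samples, gm$samples)
  if (anyNA(cols)) {
    stop("sample(s) not in genotype matrix: ",
         paste(samples[is.na(cols)], collapse = ", "))
  }
  sub <- gm$geno[, cols, drop = FALSE]
  list(derived = rowSums(sub, na.rm = TRUE),
       called = 2L * rowSums(!is.na(sub)))
}

#' Per-region nucleotide diversity (pi)
#'
#' Mean pairwise per-site difference among the `2k` haplotypes of a group's
#' `k` diploids, from per-site allele counts:
#' `pi = sum_sites 2 p (1 - p) * n / (n - 1) / n_accessible` with `n` the
#' called haplotype count and `p` the derived-allele frequency — the
#' unbiased allele-count form of the average over all haplotype pairs.
#'
#' @param gm A [genotype_matrix()] that includes invariant sites, or
#'   carries an `accessible` per-region site count (the simulator provides
#'   one).
#' @param rs A [region_set()].
#' @param group Taxon label (resolved through the taxon map) or character
#'   vector of sample ids.
#' @return Named numeric vector of per-region pi (NA where no accessible
#'   sites).
#' @export
region_pi <- function(gm, rs, group) {
  samples <- if (length(group) == 1L && group %in% gm$taxon_map$taxa) {
    taxon_samples(gm$taxon_map, group)
  } else {
    group
  }
  if (2L * length(samples) < 2L) stop("pi needs at least 2 haplotypes")
  ac <- site_allele_counts(gm, samples)
  idx_list <- lapply(seq_len(nrow(rs)), function(i) {
    region_site_index(gm, rs$chrom[i], rs$start[i], rs$end[i])
  })
  acc <- region_accessible(gm, rs, idx_list)
  out <- vapply(seq_len(nrow(rs)), function(i) {
    idx <- idx_list[[i]]
    if (acc[i] == 0) return(NA_real_)
    idx <- idx[ac$called[idx] >= 2L]
    p <- ac$derived[idx] / ac$called[idx]
    n <- ac$called[idx]
    sum(2 * p * (1 - p) * n / (n - 1)) / acc[i]
  }, numeric(1))
  stats::setNames(out, rs$region_id)
}

#' Per-region nucleotide divergence (dxy)
#'
#' Mean per-site difference over all between-group haplotype pairs:
#' `dxy = sum_sites [pX (1 - pY) + pY (1 - pX)] / n_accessible`.
#'
#' @param gm A [genotype_matrix()] (see [region_pi()] for denominators).
#' @param rs A [region_set()].
#' @param groupX,groupY Taxon labels or sample-id vectors; must be
#'   disjoint.
#' @return Named numeric vector of per-region dxy.
#' @export
region_dxy <- function(gm, rs, groupX, groupY) {
  resolve <- function(g) {
    if (length(g) == 1L && g %in% gm$taxon_map$taxa) {
      taxon_samples(gm$taxon_map, g)
    } else {
      g
    }
  }
  sx <- resolve(groupX)
  sy <- resolve(groupY)
  if (length(intersect(sx, sy))) stop("groups overlap: ",
                                      paste(intersect(sx, sy),
                                            collapse = ", "))
  acx <- site_allele_counts(gm, sx)
  acy <- site_allele_counts(gm, sy)
  idx_list <- lapply(seq_len(nrow(rs)), function(i) {
    region_site_index(gm, rs$chrom[i], rs$start[i], rs$end[i])
  })
  acc <- region_accessible(gm, rs, idx_list)
  out <- vapply(seq_len(nrow(rs)), function(i) {
    idx <- idx_list[[i]]
    if (acc[i] == 0) return(NA_real_)
    idx <- idx[acx$called[idx] >= 1L & acy$called[idx] >= 1L]
    px <- acx$derived[idx] / acx$called[idx]
    py <- acy$derived[idx] / acy$called[idx]
    sum(px * (1 - py) + py * (1 - px)) / acc[i]
  }, numeric(1))
  stats::setNames(out, rs$region_id)
}

#' D2 test for the direction of introgression
#'
#' Under the network coalescent, introgression from the inner taxon of the
#' species tree into the third taxon leaves the recipient carrying donor
#' alleles at introgression-topology genes, reducing the recipient's
#' divergence from the remaining taxon at exactly those genes; gene flow in
#' the opposite direction does not. D2 is the difference in the diagnostic
#' pair's mean dxy between genes fully supporting the species topology and
#' genes fully supporting the introgression topology, tested with a Welch
#' two-sample t-test.
#'
#' @param dxy_pair Named numeric vector: per-region dxy for the diagnostic
#'   pair (from [region_dxy()]).
#' @param wt A [weight_table()] over the simplified (three-group) catalog,
#'   rows matching `names(dxy_pair)`.
#' @param catalog The three-group catalog.
#' @param species_topology,intro_topology Canonical topology strings of
#'   the two classes (must differ).
#' @param weight_threshold Minimum topology weight for class membership
#'   (default 1: full weighting; lower it to admit near-full weights, class
#'   sizes are logged either way).
#' @return list of class `d2_result`: `D2` (mean species-class dxy minus
#'   mean introgression-class dxy), `t`, `df`, `p`, `n_species`, `n_intro`,
#'   and the class means.
#' @export
d2_test <- function(dxy_pair, wt, catalog, species_topology,
                    intro_topology, weight_threshold = 1) {
  stopifnot(inherits(catalog, "topology_catalog"))
  for (topo in c(species_topology, intro_topology)) {
    if (!topo %in% catalog$topologies) {
      stop("topology not in catalog: ", topo)
    }
  }
  if (species_topology == intro_topology) {
    stop("species and introgression topologies must differ")
  }
  stopifnot(nrow(wt) == length(dxy_pair))
  sp_class <- wt[, species_topology] >= weight_threshold
  in_class <- wt[, intro_topology] >= weight_threshold
  ok <- !is.na(dxy_pair)
  x <- dxy_pair[sp_class & ok]
  y <- dxy_pair[in_class & ok]
  ig_log("D2 classes: %d species-tree, %d introgression-tree genes",
         length(x), length(y))
  if (length(x) < 2L || length(y) < 2L) {
    stop(sprintf(
      "D2 class too small (species: %d, introgression: %d genes)",
      length(x), length(y)))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  structure(list(D2 = mean(x) - mean(y),
                 mean_dxy_species_tree = mean(x),
                 mean_dxy_intro_tree = mean(y),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value,
                 n_species = length(x), n_intro = length(y),
                 weight_threshold = weight_threshold),
            class = "d2_result")
}

#' @export
print.d2_result <- function(x, ...) {
  cat(sprintf(
    "D2 = %.5f (dxy %.5f vs %.5f; t_%.1f = %.3f, p = %.3g; n = %d/%d)\n",
    x$D2, x$mean_dxy_species_tree, x$mean_dxy_intro_tree, x$df, x$t, x$p,
    x$n_species, x$n_intro))
  invisible(x)
}

#' Per-region diversity/divergence table
#'
#' Convenience wrapper producing the usual per-gene summary: pi for each
#' listed group and dxy for each listed pair.
#'
#' @param gm A [genotype_matrix()].
#' @param rs A [region_set()].
#' @param pi_groups Character vector of taxa for pi.
#' @param dxy_pairs List of 2-vectors of taxa for dxy.
#' @return data.frame of class `divergence_table`, one row per region.
#' @export
divergence_table <- function(gm, rs, pi_groups = NULL, dxy_pairs = NULL) {
  out <- data.frame(region_id = rs$region_id, stringsAsFactors = FALSE)
  for (g in pi_groups) {
    out[[paste0("pi_", g)]] <- unname(region_pi(gm, rs, g))
  }
  for (pair in dxy_pairs) {
    out[[paste0("dxy_", pair[1L], "_", pair[2L])]] <-
      unname(region_dxy(gm, rs, pair[1L], pair[2L]))
  }
  class(out) <- c("divergence_table", "data.frame")
  out
}
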