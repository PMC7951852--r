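# Site-pattern counting and Patterson's D with block-jackknife errors.
# Frequency-weighted (Durand-style) pattern products: with per-role derived
# allele frequencies p_i, a site contributes
#   ABBA += (1-p1) p2 p3 (1-pO)      BABA += p1 (1-p2) p3 (1-pO)
# which for single diploid accessions (p in {0, 0.5, 1}) allows
# heterozygosity without hard polarization.

# per-site derived-allele frequency for one role (sample id or taxon label)
role_frequencies <- function(gm, role, mode) {
  if (mode == "single") {
    j <- match(role, gm$samples)
    if (is.na(j)) stop("role sample not found: ", role)
    gm$geno[, j] / 2
  } else {
    cols <- match(taxon_samples(gm$taxon_map, role), gm$samples)
    sub <- gm$geno[, cols, drop = FALSE]
    rowMeans(sub, na.rm = TRUE) / 2   # NaN when all samples missing
  }
}

# split n usable sites into `n_blocks` contiguous blocks of (near-)equal
# informative-site count
block_assignment <- function(n, n_blocks) {
  if (n == 0L) return(integer(0))
  n_blocks <- max(1L, min(n_blocks, n))
  as.integer(ceiling(seq_len(n) * n_blocks / n))
}

# region index (row of rs) containing each site, NA outside all regions
site_region_index <- function(sites, rs) {
  idx <- rep(NA_integer_, nrow(sites))
  for (chr in unique(sites$chrom)) {
    sel <- which(sites$chrom == chr)
    sub <- which(rs$chrom == chr)
    if (!length(sub)) next
    h <- findInterval(sites$pos[sel], rs$start[sub])
    ok <- h >= 1L & sites$pos[sel] < rs$end[sub][pmax(h, 1L)]
    idx[sel[ok]] <- sub[h[ok]]
  }
  idx
}

# contiguous blocks of near-equal site count whose boundaries never split
# a region (sites sharing one genealogy stay in one jackknife block)
region_block_assignment <- function(region_idx, n_blocks) {
  n <- length(region_idx)
  if (n == 0L) return(integer(0))
  # sites arrive in genome order: each region is one run; NA sites (outside
  # any region) become singleton runs
  key <- ifelse(is.na(region_idx), -seq_along(region_idx), region_idx)
  runs <- rle(key)
  cum <- cumsum(runs$lengths)
  blk <- ceiling(cum / cum[length(cum)] * min(n_blocks, length(cum)))
  blk <- match(blk, unique(blk))  # renumber contiguously
  rep(blk, runs$lengths)
}

#' Count four-taxon (ABBA/BABA) site patterns in genomic blocks
#'
#' Sites with a missing call in any role are excluded; the remaining sites
#' are split into `n_blocks` contiguous genomic blocks of near-equal
#' informative-site count (genome order), the unit of the block jackknife.
#' When a [region_set()] is supplied, block boundaries are snapped to
#' region boundaries so that the tightly linked sites of one gene never
#' straddle two blocks (this keeps the jackknife SE honest at gene-sized
#' linkage scales).
#'
#' @param gm A [genotype_matrix()].
#' @param roles Named character vector with entries `P1`, `P2`, `P3`, `O`:
#'   sample ids (`mode = "single"`) or taxon labels
#'   (`mode = "taxon-frequency"`).
#' @param n_blocks Number of jackknife blocks (default 50).
#' @param mode `"single"` (one diploid accession per role; the default) or
#'   `"taxon-frequency"` (taxon allele frequencies).
#' @param regions Optional [region_set()] used to align block boundaries.
#' @return data.frame of class `pattern_counts4` with per-block columns
#'   `ABBA`, `BABA`, `n_sites`.
#' @export
count_site_patterns <- function(gm, roles, n_blocks = 50L,
                                mode = c("single", "taxon-frequency"),
                                regions = NULL) {
  mode <- match.arg(mode)
  mode_key <- if (mode == "single") "single" else "taxon"
  stopifnot(all(c("P1", "P2", "P3", "O") %in% names(roles)))
  p1 <- role_frequencies(gm, roles[["P1"]], mode_key)
  p2 <- role_frequencies(gm, roles[["P2"]], mode_key)
  p3 <- role_frequencies(gm, roles[["P3"]], mode_key)
  pO <- role_frequencies(gm, roles[["O"]], mode_key)
  usable <- !(is.na(p1) | is.na(p2) | is.na(p3) | is.na(pO))
  p1 <- p1[usable]; p2 <- p2[usable]; p3 <- p3[usable]; pO <- pO[usable]
  abba <- (1 - p1) * p2 * p3 * (1 - pO)
  baba <- p1 * (1 - p2) * p3 * (1 - pO)
  blk <- if (is.null(regions)) {
    block_assignment(length(p1), n_blocks)
  } else {
    region_block_assignment(
      site_region_index(gm$sites, regions)[usable], n_blocks)
  }
  counts <- data.frame(
    block = sort(unique(blk)),
    ABBA = as.numeric(tapply(abba, blk, sum)),
    BABA = as.numeric(tapply(baba, blk, sum)),
    n_sites = as.numeric(tapply(abba, blk, length)))
  if (nrow(counts) == 0L) {
    counts <- data.frame(block = integer(0), ABBA = numeric(0),
                         BABA = numeric(0), n_sites = numeric(0))
  }
  structure(counts, class = c("pattern_counts4", "data.frame"),
            n_excluded = sum(!usable), roles = roles, mode = mode)
}

#' Patterson's D from aggregated pattern counts
#'
#' `D = (sum ABBA - sum BABA) / (sum ABBA + sum BABA)`; positive D means
#' excess derived-allele sharing between the P2 and P3 roles.
#'
#' @param counts A `pattern_counts4` (or any data.frame with `ABBA`,
#'   `BABA`).
#' @return D, or `NA` with a warning when no discordant signal exists
#'   (zero denominator).
#' @export
patterson_d <- function(counts) {
  A <- sum(counts$ABBA)
  B <- sum(counts$BABA)
  if (A + B == 0) {
    warning("D undefined: no ABBA/BABA signal (zero denominator)")
    return(NA_real_)
  }
  (A - B) / (A + B)
}

# Generic delete-one block jackknife over a per-block count matrix.
# stat_fn maps a vector of column totals to the scalar statistic.
# Weighted variant (Busing, Meijer & van der Leeden 1999) uses block sizes
# m_i as weights.
jackknife_blocks <- function(block_mat, stat_fn, weights = NULL) {
  block_mat <- as.matrix(block_mat)
  nonempty <- rowSums(block_mat != 0) > 0
  if (is.null(weights)) weights_all <- NULL else weights_all <- weights
  block_mat <- block_mat[nonempty, , drop = FALSE]
  if (!is.null(weights)) weights <- weights[nonempty]
  g <- nrow(block_mat)
  if (g < 2L) stop("block jackknife needs at least 2 non-empty blocks")
  totals <- colSums(block_mat)
  theta <- unname(stat_fn(totals))
  loo <- unname(vapply(seq_len(g), function(i) {
    stat_fn(totals - block_mat[i, ])
  }, numeric(1)))
  if (is.null(weights)) {
    se <- sqrt((g - 1) / g * sum((loo - mean(loo))^2))
  } else {
    M <- sum(weights)
    h <- M / weights
    theta_j <- g * theta - sum((1 - weights / M) * loo)
    ps <- h * theta - (h - 1) * loo
    se <- sqrt(sum((ps - theta_j)^2 / (h - 1)) / g)
  }
  degenerate <- se == 0 || !is.finite(se)
  z <- if (degenerate) NA_real_ else theta / se
  list(estimate = theta, se = se, z = z,
       p = if (degenerate) NA_real_ else 2 * stats::pnorm(-abs(z)),
       n_blocks = g, degenerate = degenerate, pseudovalues = loo)
}

#' Block-jackknife significance for Patterson's D
#'
#' Delete-one-block pseudo-estimates of D give
#' `SE^2 = (g-1)/g * sum_i (theta_(i) - mean(theta))^2`, `z = D / SE`, and
#' a two-sided normal p-value — the standard genomic-window jackknife that
#' respects linkage within blocks. A weighted variant (block site counts as
#' weights) is available.
#'
#' @param counts A `pattern_counts4` from [count_site_patterns()].
#' @param weighted Use the weighted jackknife (weights = block site
#'   counts)? Default `FALSE` (unweighted delete-one).
#' @return list of class `dstat_result`: `D`, `SE`, `z`, `p`, `n_blocks`,
#'   `n_sites`, `degenerate` (TRUE when all blocks are identical, in which
#'   case z is flagged rather than infinite).
#' @export
block_jackknife <- function(counts, weighted = FALSE) {
  stopifnot(is.data.frame(counts), all(c("ABBA", "BABA") %in% names(counts)))
  stat_fn <- function(tot) {
    if (tot[1] + tot[2] == 0) return(NA_real_)
    (tot[1] - tot[2]) / (tot[1] + tot[2])
  }
  jk <- jackknife_blocks(counts[, c("ABBA", "BABA")], stat_fn,
                         weights = if (weighted) counts$n_sites else NULL)
  structure(list(D = jk$estimate, SE = jk$se, z = jk$z, p = jk$p,
                 n_blocks = jk$n_blocks, n_sites = sum(counts$n_sites),
                 degenerate = jk$degenerate),
            class = "dstat_result")
}

#' @export
print.dstat_result <- function(x, ...) {
  cat(sprintf("Patterson's D = %.4f (SE %.4f, z = %.3f, p = %.3g, %d blocks, %g sites)%s\n",
              x$D, x$SE, if (is.na(x$z)) NA else x$z, x$p, x$n_blocks,
              x$n_sites, if (x$degenerate) " [DEGENERATE]" else ""))
  invisible(x)
}

#' Pairwise D scan over accessions of two taxa
#'
#' One Patterson's D test per (accession of `taxonA`) x (accession of
#' `taxonB`) pair, with the P1 and O roles fixed; sites are re-filtered for
#' missingness per pair. Detects geographically restricted introgression
#' that a frequency-based test would average away.
#'
#' @param gm A [genotype_matrix()].
#' @param taxonA,taxonB Taxon labels whose accessions fill the P2 / P3
#'   roles respectively.
#' @param p1,outgroup Sample ids for the fixed P1 and O roles.
#' @param n_blocks Jackknife blocks per test.
#' @param weighted Weighted jackknife flag, as in [block_jackknife()].
#' @param regions Optional [region_set()] for block alignment.
#' @return data.frame sorted by decreasing `|z|`, one row per pair, with a
#'   Benjamini-Hochberg `p_adj` column added as a convenience (the raw
#'   per-pair p-values are the primary output).
#' @export
pairwise_d_scan <- function(gm, taxonA, taxonB, p1, outgroup,
                            n_blocks = 50L, weighted = FALSE,
                            regions = NULL) {
  a_samples <- taxon_samples(gm$taxon_map, taxonA)
  b_samples <- taxon_samples(gm$taxon_map, taxonB)
  rows <- list()
  for (a in a_samples) {
    for (b in b_samples) {
      counts <- count_site_patterns(
        gm, c(P1 = p1, P2 = a, P3 = b, O = outgroup),
        n_blocks = n_blocks, regions = regions)
      res <- block_jackknife(counts, weighted = weighted)
      rows[[length(rows) + 1L]] <- data.frame(
        P2 = a, P3 = b, D = res$D, SE = res$SE, z = res$z, p = res$p,
        n_blocks = res$n_blocks, n_sites = res$n_sites,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$z)), ]
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
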