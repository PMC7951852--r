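# Recombination-rate landscape from a linkage map, and its relationship
# with topology weights along the genome.

#' Estimate per-bin recombination rates from a linkage map
#'
#' Non-overlapping bins of `bin_size` bp anchored at coordinate 0 on each
#' chromosome. The rate of a bin is the genetic distance (cM) between its
#' two most distal markers divided by their physical distance (Mbp) — the
#' marker-spanned distance, not the bin width. Bins with fewer than two
#' markers (or zero marker span) are `NA`; bins exceeding `max_rate` are
#' flagged as filtered (marker mislocalization produces such extreme
#' estimates) and excluded from downstream statistics.
#'
#' @param lm A `linkage_map`.
#' @param bin_size Bin width in bp (default 1 Mbp).
#' @param max_rate Filtering threshold in cM/Mbp (default 100).
#' @return data.frame of class `recombination_bins` with columns `chrom`,
#'   `start`, `end`, `rate`, `n_markers`, `filtered`.
#' @export
estimate_bin_rates <- function(lm, bin_size = 1e6, max_rate = 100) {
  stopifnot(inherits(lm, "linkage_map"))
  out <- list()
  for (chr in unique(lm$chrom)) {
    sub <- lm[lm$chrom == chr, ]
    bin <- floor(sub$bp / bin_size)
    for (b in sort(unique(bin))) {
      m <- sub[bin == b, ]
      rate <- NA_real_
      if (nrow(m) >= 2L) {
        span_bp <- max(m$bp) - min(m$bp)
        if (span_bp == 0) {
          warning("bin with >= 2 markers at identical position on ", chr)
        } else {
          rate <- (m$cM[which.max(m$bp)] - m$cM[which.min(m$bp)]) /
            (span_bp / 1e6)
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = b * bin_size, end = (b + 1) * bin_size,
        rate = rate, n_markers = nrow(m),
        filtered = !is.na(rate) && rate > max_rate,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  n_filt <- sum(res$filtered)
  if (n_filt) {
    ig_log("%d bin(s) exceeded %g cM/Mbp and were flagged", n_filt,
           max_rate)
  }
  class(res) <- c("recombination_bins", "data.frame")
  res
}

# bin row index containing a (chrom, position) pair, NA if none
bin_of_position <- function(bins, chrom, pos) {
  idx <- rep(NA_integer_, length(pos))
  for (chr in unique(chrom)) {
    sel <- chrom == chr
    sub <- which(bins$chrom == chr)
    if (!length(sub)) next
    hit <- findInterval(pos[sel], bins$start[sub])
    hit[hit == 0L] <- NA_integer_
    ok <- !is.na(hit) & pos[sel] < bins$end[sub][pmax(hit, 1L)]
    idx[sel][ok] <- sub[hit[ok]]
  }
  idx
}

#' Correlate smoothed topology weights with recombination rate
#'
#' Each weight window is assigned to the recombination bin containing its
#' midpoint; windows landing in undefined or filtered bins are dropped
#' (counts logged). Spearman rank correlation with average-rank ties and a
#' two-sided p-value.
#'
#' @param smoothed Output of [window_average_weights()] (needs `chrom` and
#'   `midpoint`).
#' @param bins A `recombination_bins`.
#' @param column Name of the smoothed column to correlate (a topology
#'   string or an aggregated-support column added by the caller).
#' @return list of class `correlation_result`: `rho`, `p`, `n`.
#' @export
correlate_weights_with_recombination <- function(smoothed, bins, column) {
  stopifnot(column %in% names(smoothed))
  idx <- bin_of_position(bins, smoothed$chrom, smoothed$midpoint)
  rate <- bins$rate[idx]
  drop <- is.na(idx) | is.na(rate) | bins$filtered[pmax(idx, 1L)]
  n_drop <- sum(drop)
  if (n_drop) {
    ig_log("%d window(s) dropped (undefined or filtered bins)", n_drop)
  }
  w <- smoothed[[column]][!drop]
  r <- rate[!drop]
  if (length(w) < 5L) stop("fewer than 5 usable window/bin pairs")
  if (stats::sd(w) == 0 || stats::sd(r) == 0) {
    # fully tied variable: no monotone association
    return(structure(list(rho = 0, p = 1, n = length(w)),
                     class = "correlation_result"))
  }
  ct <- stats::cor.test(r, w, method = "spearman", exact = FALSE)
  structure(list(rho = unname(ct$estimate), p = ct$p.value,
                 n = length(w)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f (p = %.3g, n = %d)\n", x$rho, x$p, x$n))
  invisible(x)
}

#' Classify bins into low/high recombination regimes
#'
#' Strictly-greater partition at `threshold` (default 5 cM/Mbp), supporting
#' analyses restricted to freely recombining regions.
#'
#' @param bins A `recombination_bins`.
#' @param threshold cM/Mbp cutoff.
#' @return Character vector (`"low"`/`"high"`, `NA` for undefined or
#'   filtered bins) aligned with `bins` rows.
#' @export
classify_recombination_regime <- function(bins, threshold = 5) {
  out <- ifelse(bins$rate > threshold, "high", "low")
  out[is.na(bins$rate) | bins$filtered] <- NA_character_
  out
}
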