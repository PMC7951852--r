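#' Run the full introgression-inference pipeline on a preset scenario
#'
#' Orchestrates simulate -> topology weighting -> D / D_FOIL -> pi, dxy,
#' D2 -> recombination bins -> weight-recombination correlation, and
#' returns a machine-readable report. The same config and seed always
#' yield an identical report.
#'
#' @param config list with entries:
#'   \describe{
#'     \item{preset}{Preset name for [preset_scenario()], or a
#'       `sim_scenario` in `scenario`.}
#'     \item{seed}{Integer seed (mandatory).}
#'     \item{n_regions}{Optional override of the preset's region count.}
#'     \item{n_blocks}{Jackknife blocks (default 50).}
#'     \item{window}{Smoothing window in genes (default 5).}
#'     \item{bin_size}{Recombination bin size in bp (default 1e6).}
#'     \item{max_rate}{Bin filter in cM/Mbp (default 100).}
#'     \item{regime_threshold}{Low/high regime split (default 5 cM/Mbp).}
#'     \item{weight_threshold}{D2 class threshold (default 1).}
#'     \item{alpha}{D_FOIL sign level (default 0.01).}
#'     \item{pairwise}{Run the pairwise accession D scan (default FALSE).}
#'     \item{out_dir}{Optional directory for TSV/JSON/VCF artifacts.}
#'   }
#' @return list of class `pipeline_report` (also written as JSON when
#'   `out_dir` is given).
#' @export
run_pipeline <- function(config) {
  if (is.null(config$seed)) stop("config$seed is mandatory")
  sc <- config$scenario %||% preset_scenario(
    config$preset %||% stop("config needs a preset or scenario"),
    n_regions = config$n_regions %||% 2000L)
  roles <- attr(sc, "roles") %||% stop("scenario lacks analysis roles")
  n_blocks <- config$n_blocks %||% 50L
  window <- config$window %||% 5L
  alpha <- config$alpha %||% 0.01

  sim <- simulate_dataset(sc, config$seed, out_dir = config$out_dir)

  # --- topology weighting over all five groups -------------------------
  tm <- scenario_taxon_map(sc)
  catalog5 <- enumerate_rooted_topologies(tm$taxa)
  wt5 <- weight_table(sim$trees, tm, catalog5,
                      region_ids = sim$regions$region_id,
                      seed = config$seed)
  lewcard <- aggregate_clade_support(wt5, catalog5, roles$lewcard_clade)
  species <- aggregate_clade_support(wt5, catalog5, roles$species_clade)
  smoothed <- window_average_weights(wt5, sim$regions, window = window)
  smoothed$lewcard_support <- window_means(lewcard, sim$regions, window)
  smoothed$species_support <- window_means(species, sim$regions, window)

  # --- D statistics -----------------------------------------------------
  counts4 <- count_site_patterns(sim$gm, roles$dstat, n_blocks = n_blocks,
                                 regions = sim$regions)
  dres <- block_jackknife(counts4)
  pairwise <- if (isTRUE(config$pairwise)) {
    pairwise_d_scan(sim$gm, roles$dstat_pair_taxa[["A"]],
                    roles$dstat_pair_taxa[["B"]],
                    p1 = roles$dstat[["P1"]], outgroup = roles$dstat[["O"]],
                    n_blocks = n_blocks, regions = sim$regions)
  }
  counts5 <- count_site_patterns5(sim$gm, roles$dfoil,
                                  n_blocks = n_blocks,
                                  regions = sim$regions)
  dfoil_res <- dfoil(counts5, alpha = alpha)

  # --- D2: three-sample test (one accession per taxon) -----------------
  d2cfg <- roles$d2
  catalog3 <- enumerate_rooted_topologies(d2cfg$groups)
  tips3 <- stats::setNames(
    rep(names(d2cfg$samples), each = 2L),
    unlist(lapply(d2cfg$samples, function(s) paste0(s, c("_A", "_B")))))
  wt3 <- weight_table(sim$trees, tips3, catalog3,
                      region_ids = sim$regions$region_id,
                      seed = config$seed)
  dxy_pair <- region_dxy(sim$gm, sim$regions,
                         d2cfg$samples[[d2cfg$pair[1L]]],
                         d2cfg$samples[[d2cfg$pair[2L]]])
  d2res <- tryCatch(
    d2_test(dxy_pair, wt3, catalog3, d2cfg$species_topology,
            d2cfg$intro_topology,
            weight_threshold = config$weight_threshold %||% 1),
    error = function(e) structure(list(error = conditionMessage(e)),
                                  class = "d2_result"))

  # --- diversity summaries ---------------------------------------------
  div <- divergence_table(
    sim$gm, sim$regions,
    pi_groups = intersect(c("cardinalis", "lewisiiN", "lewisiiS"),
                          tm$taxa),
    dxy_pairs = list(d2cfg$pair))

  # --- recombination landscape -----------------------------------------
  bins <- estimate_bin_rates(sim$map, bin_size = config$bin_size %||% 1e6,
                             max_rate = config$max_rate %||% 100)
  corr <- correlate_weights_with_recombination(smoothed, bins,
                                               "lewcard_support")
  regime <- classify_recombination_regime(
    bins, threshold = config$regime_threshold %||% 5)

  report <- structure(list(
    preset = attr(sc, "preset") %||% "custom",
    seed = config$seed,
    parameters = list(n_regions = nrow(sim$regions),
                      n_blocks = n_blocks, window = window,
                      alpha = alpha,
                      weight_threshold = config$weight_threshold %||% 1,
                      bin_size = config$bin_size %||% 1e6,
                      max_rate = config$max_rate %||% 100,
                      regime_threshold = config$regime_threshold %||% 5),
    dstat = list(D = dres$D, SE = dres$SE, z = dres$z, p = dres$p,
                 n_blocks = dres$n_blocks, n_sites = dres$n_sites,
                 degenerate = dres$degenerate),
    pairwise_dstat = pairwise,
    dfoil = list(components = dfoil_res$components,
                 signature = dfoil_res$signature,
                 classification = dfoil_res$classification),
    d2 = unclass(d2res),
    weights = list(
      mean_lewcard_support = mean(lewcard),
      mean_species_support = mean(species),
      summary = summarize_weights(wt5)),
    recombination = list(rho = corr$rho, p = corr$p, n = corr$n,
                         n_bins = nrow(bins),
                         n_high = sum(regime == "high", na.rm = TRUE),
                         n_low = sum(regime == "low", na.rm = TRUE)),
    truth = list(
      n_introgressed = sum(sim$truth$introgressed),
      introgressed_fraction = mean(sim$truth$introgressed)),
    divergence = list(
      median_dxy_pair = stats::median(div[[paste0("dxy_", d2cfg$pair[1L],
                                                  "_", d2cfg$pair[2L])]],
                                      na.rm = TRUE))
  ), class = "pipeline_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(
      data.frame(region_id = rownames(wt5), as.data.frame(unclass(wt5)),
                 check.names = FALSE),
      file.path(config$out_dir, "weights.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(smoothed,
                       file.path(config$out_dir, "weights_smoothed.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(bins),
                       file.path(config$out_dir, "recombination_bins.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(div, file.path(config$out_dir, "divergence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    json <- report
    json$pairwise_dstat <- NULL
    jsonlite::write_json(prepare_report_json(json),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# strip classes so jsonlite serializes plainly
prepare_report_json <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, prepare_report_json)
  } else {
    x
  }
}

# sliding-window means of a per-region scalar, matching
# window_average_weights() windowing
window_means <- function(values, rs, window) {
  out <- numeric(0)
  for (chr in unique(rs$chrom)) {
    idx <- which(rs$chrom == chr)
    if (length(idx) < window) {
      out <- c(out, mean(values[idx]))
    } else {
      starts <- seq_len(length(idx) - window + 1L)
      out <- c(out, vapply(starts, function(s) {
        mean(values[idx[s:(s + window - 1L)]])
      }, numeric(1)))
    }
  }
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("introgressr pipeline report — preset:", x$preset, "seed:", x$seed,
      "\n")
  cat(sprintf("  D = %.4f (z = %.2f, p = %.3g)\n", x$dstat$D, x$dstat$z,
              x$dstat$p))
  cat("  D_FOIL classification:", x$dfoil$classification, "\n")
  if (is.null(x$d2$error)) {
    cat(sprintf("  D2 = %.5f (t_%.1f = %.3f, p = %.3g)\n", x$d2$D2,
                x$d2$df, x$d2$t, x$d2$p))
  } else {
    cat("  D2: ", x$d2$error, "\n")
  }
  cat(sprintf("  weight~recombination: rho = %.3f (p = %.3g)\n",
              x$recombination$rho, x$recombination$p))
  cat(sprintf("  truth: %.1f%% of loci introgressed\n",
              100 * x$truth$introgressed_fraction))
  invisible(x)
}
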