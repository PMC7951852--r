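#' Define a multispecies network coalescent scenario
#'
#' A scenario is a species tree with branch-specific population sizes,
#' optional unidirectional introgression events, and a mutation /
#' chromosome-layout model. Time runs backwards in generations from the
#' present (0). Each population (terminal taxon or ancestor) exists from
#' `t_start` (0 for tips, the latest child merge for ancestors) until it
#' joins its parent at `t_join`; the root has `t_join = Inf`.
#'
#' @param pops data.frame with columns `pop`, `parent` (NA for the root),
#'   `t_join` (generations; `Inf` for the root) and `Ne` (diploid size).
#' @param events `NULL` or data.frame with columns `donor`, `recipient`,
#'   `time`, `gamma`. Forward in time a fraction `gamma` of the recipient
#'   population descends from the donor at `time`; backward, each lineage
#'   in the recipient switches to the donor branch independently with
#'   probability `gamma`.
#' @param samples_per_taxon Named integer vector: diploid individuals
#'   sampled per terminal taxon (haploid lineages if `ploidy = 1`).
#' @param mu Mutation rate per site per generation.
#' @param sites_per_region Region length in bp (infinite-sites mutation on
#'   this many positions).
#' @param n_regions Number of regions ("genes") to simulate.
#' @param chromosome_layout List, one entry per chromosome:
#'   `list(length = <bp>, rates = <cM/Mbp per 1-Mbp bin>)`. Lengths should
#'   be whole Mbp.
#' @param coupling `NULL`, or a monotone function mapping a local
#'   recombination rate (cM/Mbp) to a multiplier in `[0, 1]` applied to
#'   every event's `gamma` for regions in that bin.
#' @param ploidy 2 (diploid samples; the default) or 1 (haploid lineages,
#'   useful for analytic gene-tree checks).
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(pops, events = NULL, samples_per_taxon,
                         mu = 1e-8, sites_per_region = 1000L,
                         n_regions = 2000L, chromosome_layout = NULL,
                         coupling = NULL, ploidy = 2L) {
  stopifnot(is.data.frame(pops),
            all(c("pop", "parent", "t_join", "Ne") %in% names(pops)))
  pops$pop <- as.character(pops$pop)
  pops$parent <- as.character(pops$parent)
  if (anyDuplicated(pops$pop)) stop("duplicate population names")
  root <- pops$pop[is.na(pops$parent)]
  if (length(root) != 1L) stop("exactly one root population required")
  if (!is.infinite(pops$t_join[pops$pop == root])) {
    stop("root population must have t_join = Inf")
  }
  if (any(pops$Ne <= 0)) stop("Ne must be positive")
  known <- pops$pop
  if (any(!is.na(pops$parent) & !pops$parent %in% known)) {
    stop("parent population not defined")
  }
  # existence interval start: 0 for childless pops, latest child join else
  t_start <- stats::setNames(rep(0, nrow(pops)), pops$pop)
  for (p in pops$pop) {
    kids <- pops$pop[!is.na(pops$parent) & pops$parent == p]
    if (length(kids)) t_start[p] <- max(pops$t_join[match(kids, pops$pop)])
  }
  if (any(t_start >= pops$t_join)) stop("population joins before it exists")
  tips <- pops$pop[!pops$pop %in% pops$parent[!is.na(pops$parent)]]
  if (!all(names(samples_per_taxon) %in% tips)) {
    stop("samples_per_taxon names must be terminal taxa")
  }
  if (!is.null(events)) {
    stopifnot(all(c("donor", "recipient", "time", "gamma") %in%
                    names(events)))
    events$donor <- as.character(events$donor)
    events$recipient <- as.character(events$recipient)
    if (any(events$gamma < 0 | events$gamma > 1)) {
      stop("gamma must lie in [0, 1]")
    }
    for (k in seq_len(nrow(events))) {
      for (side in c("donor", "recipient")) {
        p <- events[[side]][k]
        if (!p %in% pops$pop) stop("unknown population in event: ", p)
        tj <- pops$t_join[pops$pop == p]
        if (events$time[k] < t_start[p] || events$time[k] >= tj) {
          stop(sprintf(
            "event %d: time %g outside existence of %s [%g, %g)",
            k, events$time[k], p, t_start[p], tj))
        }
      }
    }
  }
  if (!is.null(chromosome_layout)) {
    for (cl in chromosome_layout) {
      stopifnot(!is.null(cl$length), !is.null(cl$rates),
                all(cl$rates >= 0),
                length(cl$rates) == ceiling(cl$length / 1e6))
    }
  }
  structure(
    list(pops = pops, t_start = t_start, root = root, tips = tips,
         events = events, samples_per_taxon = samples_per_taxon,
         mu = mu, sites_per_region = as.integer(sites_per_region),
         n_regions = as.integer(n_regions),
         chromosome_layout = chromosome_layout,
         coupling = coupling, ploidy = as.integer(ploidy)),
    class = "sim_scenario"
  )
}

# haplotype labels for all sampled lineages, grouped by taxon.
# Diploid sample ids are "<taxon>_<i>"; haplotypes "<sample>_A"/"_B".
scenario_haplotypes <- function(sc) {
  out <- list()
  for (taxon in names(sc$samples_per_taxon)) {
    n <- sc$samples_per_taxon[[taxon]]
    samples <- sprintf("%s_%d", taxon, seq_len(n))
    haps <- if (sc$ploidy == 2L) {
      as.vector(rbind(paste0(samples, "_A"), paste0(samples, "_B")))
    } else {
      samples
    }
    out[[taxon]] <- haps
  }
  out
}

# taxon_map over diploid samples
scenario_taxon_map <- function(sc) {
  taxa <- names(sc$samples_per_taxon)
  samples <- unlist(lapply(taxa, function(t) {
    sprintf("%s_%d", t, seq_len(sc$samples_per_taxon[[t]]))
  }))
  taxon <- rep(taxa, unlist(sc$samples_per_taxon[taxa]))
  taxon_map(samples, taxon)
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("sim_scenario:", length(x$tips), "taxa,",
      sum(unlist(x$samples_per_taxon)), "individuals,",
      x$n_regions, "regions of", x$sites_per_region, "bp\n")
  if (!is.null(x$events)) {
    for (k in seq_len(nrow(x$events))) {
      e <- x$events[k, ]
      cat(sprintf("  introgression: %s -> %s at t=%g (gamma=%g)\n",
                  e$donor, e$recipient, e$time, e$gamma))
    }
  }
  invisible(x)
}
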