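# Preset study scenarios. Five taxa mirroring a monkeyflower-like radiation:
# two parapatric races of a bee-pollinated species ("lewisiiN", "lewisiiS"),
# two hummingbird-pollinated species ("cardinalis", "verbenaceus") forming a
# clade, and an outgroup. Times in generations, Ne diploid.
#
# Species tree: (((lewisiiN,lewisiiS),(cardinalis,verbenaceus)),outgroup)
# lewisii races split 100k generations ago, cardinalis-verbenaceus 300k,
# ingroup root 500k, outgroup 1.2M; Ne = 1e5 everywhere. The lewisii and
# red-clade stems are then 2 and 1 coalescent units: substantial ILS, as in
# a rapid radiation, while the red-clade stem is long enough that gene
# trees conditioned on a cardinalis-lewisii cherry are dominated by
# introgressed rather than deep-coalescing histories (the regime the D2
# direction test needs). mu = 1e-8/site/gen and 1-kb regions give a
# handful to ~100 variable sites per region.

preset_pops <- function(Ne = 1e5) {
  data.frame(
    pop = c("lewisiiN", "lewisiiS", "cardinalis", "verbenaceus",
            "outgroup", "lewisii", "redclade", "ingroup", "root"),
    parent = c("lewisii", "lewisii", "redclade", "redclade", "root",
               "ingroup", "ingroup", "root", NA),
    t_join = c(100e3, 100e3, 300e3, 300e3, 1.2e6, 500e3, 500e3, 1.2e6,
               Inf),
    Ne = Ne,
    stringsAsFactors = FALSE)
}

preset_layout <- function(n_chr = 4L, len = 20e6, r_end = 8, r_mid = 0.25) {
  # U-shaped landscape: crossovers concentrated at chromosome ends, very
  # little recombination across the broad center.
  lapply(seq_len(n_chr), function(i) {
    n_bin <- len / 1e6
    x <- (seq_len(n_bin) - 0.5) / n_bin          # bin centers in (0,1)
    u <- abs(2 * x - 1)                           # 0 center -> 1 ends
    list(length = len, rates = r_mid + (r_end - r_mid) * u^3)
  })
}

#' Preset simulation scenarios
#'
#' Fully parameterized study conditions for the bundled five-taxon
#' radiation (see Details). Available presets:
#' \describe{
#'   \item{ils_only}{No introgression; discordance from ILS alone.}
#'   \item{ancestral_lew_into_card}{Gene flow from the ancestral lewisii
#'     population into cardinalis (t = 200k generations, gamma = 0.2),
#'     i.e. before the lewisii races split: the ancestral D_FOIL
#'     configuration.}
#'   \item{recent_sierran}{Recent terminal gene flow from cardinalis into
#'     the Sierran lewisii race (t = 50k, gamma = 0.2).}
#'   \item{direction_card_into_lew}{Gene flow from cardinalis into the
#'     ancestral lewisii population (t = 150k, gamma = 0.3): the direction
#'     that leaves a D2 divergence footprint.}
#'   \item{recomb_coupled}{As `ancestral_lew_into_card` but with the
#'     effective gamma per region scaled by `r / (r + 2)` where `r` is the
#'     local recombination rate (cM/Mbp), so introgressed ancestry
#'     accumulates preferentially in high-recombination regions.}
#' }
#'
#' @details The species tree is
#' `(((lewisiiN,lewisiiS),(cardinalis,verbenaceus)),outgroup)` with splits
#' at 100k / 300k / 500k / 1.2M generations, diploid Ne = 1e5 on every
#' branch, mutation rate 1e-8 per site per generation, 1-kb regions, and a
#' four-chromosome (20 Mbp each) U-shaped recombination landscape
#' (0.25 cM/Mbp centers, 8 cM/Mbp ends, 1-Mbp bins). Default sampling is
#' two diploids per ingroup taxon and one outgroup diploid.
#'
#' @param name One of `ils_only`, `ancestral_lew_into_card`,
#'   `recent_sierran`, `direction_card_into_lew`, `recomb_coupled`.
#' @param n_regions Number of regions (default 2000).
#' @param samples_per_taxon Named integer vector overriding the default
#'   sampling design.
#' @return A [sim_scenario()] with attribute `roles` giving the default
#'   role assignments for the D, D_FOIL and D2 analyses.
#' @export
preset_scenario <- function(name, n_regions = 2000L,
                            samples_per_taxon = NULL) {
  presets <- c("ils_only", "ancestral_lew_into_card", "recent_sierran",
               "direction_card_into_lew", "recomb_coupled")
  if (!name %in% presets) {
    stop("unknown preset '", name, "'; available: ",
         paste(presets, collapse = ", "))
  }
  samples_per_taxon <- samples_per_taxon %||%
    c(lewisiiN = 2L, lewisiiS = 2L, cardinalis = 2L, verbenaceus = 2L,
      outgroup = 1L)
  events <- switch(
    name,
    ils_only = NULL,
    ancestral_lew_into_card = data.frame(
      donor = "lewisii", recipient = "cardinalis", time = 200e3,
      gamma = 0.2, stringsAsFactors = FALSE),
    recent_sierran = data.frame(
      donor = "cardinalis", recipient = "lewisiiS", time = 50e3,
      gamma = 0.2, stringsAsFactors = FALSE),
    direction_card_into_lew = data.frame(
      donor = "cardinalis", recipient = "lewisii", time = 150e3,
      gamma = 0.3, stringsAsFactors = FALSE),
    recomb_coupled = data.frame(
      donor = "lewisii", recipient = "cardinalis", time = 200e3,
      gamma = 0.5, stringsAsFactors = FALSE))
  coupling <- if (name == "recomb_coupled") {
    function(r) r / (r + 2)
  } else {
    NULL
  }
  sc <- sim_scenario(preset_pops(), events, samples_per_taxon,
                     mu = 1e-8, sites_per_region = 1000L,
                     n_regions = n_regions,
                     chromosome_layout = preset_layout(),
                     coupling = coupling)
  # Default analysis roles. For Patterson's D the sign convention is
  # D > 0 <=> excess P2-P3 sharing, so the putatively introgressing pair
  # (cardinalis, lewisii) sits in the P2/P3 roles.
  attr(sc, "roles") <- list(
    dstat = c(P1 = "verbenaceus_1", P2 = "cardinalis_1", P3 = "lewisiiS_1",
              O = "outgroup_1"),
    dstat_pair_taxa = c(A = "cardinalis", B = "lewisiiS"),
    dfoil = c(P1 = "lewisiiN_1", P2 = "lewisiiS_1", P3 = "cardinalis_1",
              P4 = "verbenaceus_1", O = "outgroup_1"),
    # D2 is a three-sample test: one accession per taxon for both the
    # topology classes and the diagnostic divergence
    d2 = list(groups = c("cardinalis", "lewisiiS", "verbenaceus"),
              samples = c(cardinalis = "cardinalis_1",
                          lewisiiS = "lewisiiS_1",
                          verbenaceus = "verbenaceus_1"),
              species_topology = "((cardinalis,verbenaceus),lewisiiS)",
              intro_topology = "((cardinalis,lewisiiS),verbenaceus)",
              pair = c("lewisiiS", "verbenaceus")),
    lewcard_clade = c("cardinalis", "lewisiiN", "lewisiiS"),
    species_clade = c("cardinalis", "verbenaceus"))
  attr(sc, "preset") <- name
  sc
}
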