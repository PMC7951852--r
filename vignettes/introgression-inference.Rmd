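---
title: "Inferring introgression from gene trees, site patterns and recombination landscapes"
author: "introgressr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring introgression from gene trees, site patterns and recombination landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

In rapid radiations, individual gene trees disagree with the species tree
for two reasons that must be disentangled: incomplete lineage sorting
(ILS), the persistence of ancestral polymorphism through successive
speciations, and introgression, the movement of alleles between species
after hybridization. `introgressr` implements a set of complementary
analyses that together localize, date and orient gene flow in a small
radiation sampled with a handful of diploid accessions per taxon:

* **Topology weighting.** For a gene tree whose tips are haplotypes of
  several accessions, the weight of a species-level topology is the
  fraction of one-tip-per-group subtrees inducing that topology. Weights
  are aggregated over topologies containing a clade of interest and
  smoothed in sliding five-gene windows along chromosomes.
* **Patterson's D.** With per-role derived-allele frequencies
  $p_i \in \{0, \tfrac12, 1\}$ for a single diploid in each role,
  each site contributes $(1-p_1) p_2 p_3 (1-p_O)$ to ABBA and
  $p_1 (1-p_2) p_3 (1-p_O)$ to BABA, and
  $D = (\Sigma\mathrm{ABBA} - \Sigma\mathrm{BABA}) /
  (\Sigma\mathrm{ABBA} + \Sigma\mathrm{BABA})$. Significance comes from a
  delete-one block jackknife over contiguous genomic blocks:
  $SE^2 = \frac{g-1}{g}\sum_i (\theta_{(i)} - \bar\theta)^2$, $z = D/SE$.
* **D_FOIL.** Four D-like contrasts on the symmetric five-taxon tree
  $(((P_1,P_2),(P_3,P_4)),O)$ whose joint sign pattern distinguishes
  ancestral gene flow (involving the $P_1P_2$ ancestor; direction not
  identifiable) from terminal donor-recipient pairs.
* **D2.** A three-sample test: genes are classified by their simplified
  three-taxon topology (full topology weight for the species tree
  $((P_1,P_2),P_3)$ versus the introgression tree $((P_2,P_3),P_1)$), and
  the diagnostic divergence $d_{xy}(P_3, P_1)$ is compared between classes
  with a Welch t-test. Gene flow $P_2 \to P_3$ lowers the diagnostic
  divergence at introgression-topology genes; the reverse direction does
  not.
* **Diversity and divergence.** Per-region $\pi$ and $d_{xy}$ from allele
  counts, with denominators over accessible (variant + invariant) sites.
* **Recombination conditioning.** Per-1-Mbp recombination rates from a
  linkage map (genetic distance between the two most distal markers in
  the bin over their physical span), an extreme-rate filter
  (> 100 cM/Mbp), a low/high regime split (> 5 cM/Mbp), and a Spearman
  correlation of smoothed clade support with local recombination rate.

## The synthetic-data generator

All statistics are exercised end-to-end on a multispecies **network**
coalescent simulator (`sim_scenario()`, `simulate_dataset()`):

* Each region is one non-recombining locus; inter-locus recombination is
  implicit in the assignment of loci to recombination-rate bins. This
  matches the per-gene unit of every downstream statistic.
* Backward in time, lineages coalesce within each species-tree branch at
  rate $k(k-1)/2 \cdot (2N_e)^{-1}$; at an introgression event
  (donor, recipient, $t$, $\gamma$), every lineage currently in the
  recipient branch switches to the donor independently with probability
  $\gamma$. This yields both clean introgressed loci and mixtures when
  several lineages are sampled, and the per-locus switch events are
  recorded as ground truth (`SimTruth`).
* Mutations are infinite-sites: Poisson with rate $\mu$ per site per
  generation on the genealogy, distinct positions within the region
  (collisions redrawn), derived allele = ALT. Haplotypes are paired into
  phased diploid genotypes and can be serialized as VCF/BED/Newick/TSV.
* The linkage map integrates the per-bin cM/Mbp profile, so the
  generating landscape is recoverable from the emitted map.
* One global seed expands deterministically into per-stage child seeds;
  identical scenario + seed gives byte-identical artifacts.

### Preset study conditions

The presets emulate a monkeyflower-like radiation: two parapatric races
of a bee-pollinated species (`lewisiiN`, `lewisiiS`), a hummingbird
clade (`cardinalis`, `verbenaceus`) and an outgroup, with splits at
100k / 300k / 500k / 1.2M generations, $N_e = 10^5$ on all branches,
$\mu = 10^{-8}$, 1-kb regions, 2000 regions over four 20-Mbp chromosomes,
and a U-shaped recombination landscape (0.25 cM/Mbp centers, 8 cM/Mbp
ends) mirroring crossover concentration at chromosome ends. Two diploids
per ingroup taxon and one outgroup diploid are sampled.

Design notes on these choices:

* The lewisii and red-clade stems are 2 and 1 coalescent units, giving
  substantial ILS (tens of percent of discordant gene trees), as in a
  real rapid radiation.
* The red-clade stem must be at least about one coalescent unit for the
  D2 test to be usable at all: with a much shorter stem, genes whose
  topology places cardinalis with lewisii are dominated by deep
  coalescences rather than introgressed histories, and the direction
  signal is diluted below detectability regardless of $\gamma$. We
  verified this against the simulator's ground-truth TMRCAs.
* Introgression presets: `ancestral_lew_into_card` (ancestral lewisii
  into cardinalis, $t = 200$k, $\gamma = 0.2$), `recent_sierran`
  (cardinalis into Sierran lewisii, $t = 50$k, $\gamma = 0.2$),
  `direction_card_into_lew` (cardinalis into ancestral lewisii,
  $t = 150$k, $\gamma = 0.3$), and `recomb_coupled`, which multiplies a
  base $\gamma = 0.5$ by the saturating coupling $r / (r + 2)$ of the
  local recombination rate $r$, emulating purging of introgressed
  ancestry from low-recombination regions.

What the generator does **not** emulate: within-locus recombination,
missing data and genotyping error, variation in $N_e$ or $\mu$ across
branches and loci, selection, gene-tree estimation error (true
genealogies are handed to the weighting stage), and reference/alignment
artifacts. Passing tests therefore validate the statistical machinery
and its calibration under the model's assumptions, not robustness to
those real-data complications.

## Numerical and design choices

* **Coordinates** are 0-based half-open internally; VCF positions are
  converted on read and restored on write. Multi-allelic and non-ACGT
  records are dropped with logged counts; `./.` and half calls are
  missing. Heterozygotes are exported to FASTA as IUPAC codes, or as a
  chosen phased haplotype when phase is available.
* **Canonical topologies.** Rooted topologies are encoded as nested
  parentheses with the two children of every node ordered by smallest
  tip label (byte order); catalogs are sorted byte-wise, so the
  `(2n-3)!!` catalog order is stable across runs. The induced topology of
  a tip subset is computed from pairwise MRCA depths (repeatedly merging
  the deepest pair), a code path shared between R and the C++ kernel and
  cross-checked in the tests against an independent prune-and-compare
  oracle (ape pruning + Robinson-Foulds identity).
* **Exhaustive vs sampled weighting.** Exhaustive evaluation is used when
  the product of group sizes is at most 10,000 combinations, else 10,000
  uniform samples (both configurable). Sampled tallies are normalized by
  construction; exhaustive weights sum to 1 up to floating error (1e-9
  asserted). Polytomies are refused unless the caller opts into one-time
  random resolution. The root is taken as given; no implicit re-rooting.
* **Genome-wide subtree shares** are reported both as the
  combination-count-weighted pooled share and the unweighted mean of
  per-tree weights, since the two aggregations differ when accession
  numbers vary across trees.
* **Jackknife blocks** are contiguous runs of near-equal informative-site
  count; when the region set is available, block boundaries snap to
  region boundaries so that the tightly linked sites of one gene never
  straddle two blocks. This matters: with gene-sized linkage, site-count
  blocks that split genes underestimate the SE and inflate the type-I
  error of $z$ (we measured this on null simulations, and the acceptance
  suite asserts calibration within binomial bounds of the nominal 5%).
  The default is the unweighted delete-one jackknife over 50 blocks; a
  weighted variant (block site counts) and the chi-squared alternative
  for D_FOIL are available by flag. All p-values are two-sided normal on
  $z$; the pairwise accession scan reports raw p-values with a clearly
  secondary Benjamini-Hochberg column.
* **D_FOIL pattern sets** follow the FOIL pair logic (First $=P_1P_3$,
  Outer $=P_1P_4$, Inner $=P_2P_3$, Last $=P_2P_4$), each statistic a
  Patterson-style contrast including the within-ingroup polarization
  complements; the sign-to-configuration table was validated by
  simulating every directed gene-flow event and is frozen as a documented
  constant. Component signs are thresholded at $\alpha = 0.01$.
  Unrecognized sign vectors classify as `ambiguous`.
* **D2 is a three-sample test**: one accession per taxon for both the
  three-taxon topology classes and the diagnostic $d_{xy}$. With several
  accessions pooled into full-weight classes, deep-ILS genes dominate the
  introgression-topology class and the direction signal disappears; the
  single-accession design matches the statistic's derivation. The class
  threshold defaults to full weight (1.0) and is configurable; class
  sizes are always logged, and an empty class is an error that reports
  both sizes.
* **$\pi$ / $d_{xy}$ denominators** count accessible sites (variant +
  invariant with no missing call among the samples involved); the
  simulator annotates region lengths as accessible so invariant sites
  need not be materialized. Regions with zero accessible sites are
  undefined and excluded from medians. Per-gene (not per-site) summaries
  are reported as median and IQR; no length weighting.
* **Recombination bins** are anchored at 0 per chromosome; the final
  partial bin is kept if it has two markers. The rate uses the
  distal-marker span, not the bin width, so sparse bins can carry rates
  estimated from short spans — no correction is applied, only the
  > 100 cM/Mbp mislocalization filter. Window-to-bin assignment is by
  window midpoint; windows in undefined or filtered bins are dropped with
  logged counts. Spearman correlation uses average ranks for ties; a
  fully tied vector yields $\rho = 0$ by convention.

## Problem sizes

Defaults are sized so a full preset pipeline (simulate, weight 105-topology
catalogs over ~18-tip trees, all statistics, correlation) completes in
about a minute on one CPU: 2000 regions of 1 kb, at most ~512 subtree
combinations per gene tree. The validation suite uses 20,000 loci for the
closed-form ILS checks, 100 null replicates of 1000 regions for D
calibration, 20 replicates at the preset conditions for the D_FOIL
signature recovery, and 20 replicates of 1200 regions for each D2
direction check.

## Known limitations

* The locus-level coalescent cannot express intra-gene recombination, so
  topology weights per gene are "purer" than real capture data would be.
* Taxon-frequency mode for site patterns uses within-taxon allele
  frequencies but the bundled presets exercise single-accession roles,
  mirroring the pairwise-accession analysis design.
* The D_FOIL terminal sign table identifies donor-recipient pairs through
  structural zeros; borderline-power data sets will often classify as
  `ambiguous` rather than commit to a wrong pair.
* The recombination module estimates rates only from a supplied linkage
  map; LD-based inference and map construction are out of scope.
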