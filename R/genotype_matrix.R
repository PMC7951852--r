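#' Diploid genotype matrix
#'
#' The central substrate for all site-pattern and divergence statistics:
#' biallelic sites in rows, diploid samples in columns, genotypes coded as
#' derived(ALT)-allele dosage 0/1/2 with `NA` for missing calls. Positions
#' are stored 0-based internally (converted from the 1-based VCF convention
#' on read and restored on write).
#'
#' @param sites data.frame with columns `chrom`, `pos` (0-based), `ref`,
#'   `alt`. Invariant records carry `alt = "."`.
#' @param geno Integer matrix, `nrow(sites)` x `length(samples)`, values in
#'   \{0, 1, 2, NA\}.
#' @param samples Character vector of sample ids (column order of `geno`).
#' @param tm A [taxon_map()] covering all samples.
#' @param includes_invariant Logical; whether invariant records were kept.
#' @param hap1 Optional integer matrix of first-haplotype derived-allele
#'   indicators (0/1/NA), available when the source genotypes were phased.
#' @param phased Logical; whether `hap1` carries real phase information.
#' @param accessible Optional named numeric vector: region id -> number of
#'   accessible (callable) sites, used as denominators for pi / dxy when the
#'   matrix itself does not include invariant sites.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, geno, samples, tm,
                            includes_invariant = FALSE,
                            hap1 = NULL, phased = FALSE,
                            accessible = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
            nrow(sites) == nrow(geno),
            ncol(geno) == length(samples),
            inherits(tm, "taxon_map"))
  missing_map <- setdiff(samples, names(tm$entries))
  if (length(missing_map)) {
    stop("samples absent from taxon map: ",
         paste(missing_map, collapse = ", "))
  }
  # positions must be strictly increasing within chromosome
  by_chr <- split(sites$pos, sites$chrom)
  bad <- vapply(by_chr, function(p) any(diff(p) <= 0), logical(1))
  if (any(bad)) {
    stop("positions not strictly increasing on chromosome(s): ",
         paste(names(by_chr)[bad], collapse = ", "))
  }
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (any(geno < 0L | geno > 2L, na.rm = TRUE)) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  colnames(geno) <- samples
  structure(
    list(sites = sites, geno = geno, samples = samples, taxon_map = tm,
         includes_invariant = includes_invariant,
         hap1 = hap1, phased = phased, accessible = accessible),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$sites), "sites x", length(x$samples),
      "samples",
      if (x$includes_invariant) "(invariant sites included)" else "",
      "\n")
  invisible(x)
}

# Logical index of variant rows (ALT is a real allele and not all dosages
# are 0 or all 2).
variant_rows <- function(gm) {
  has_alt <- gm$sites$alt != "."
  n_der <- rowSums(gm$geno, na.rm = TRUE)
  n_called <- rowSums(!is.na(gm$geno))
  has_alt & n_der > 0L & n_der < 2L * n_called
}

# rows of gm falling inside region [start, end) on region's chromosome
region_site_index <- function(gm, chrom, start, end) {
  which(gm$sites$chrom == chrom & gm$sites$pos >= start &
          gm$sites$pos < end)
}
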