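#' Sample-to-taxon mapping
#'
#' A `taxon_map` assigns every sample (typically a diploid accession) to
#' exactly one taxon label. It is the grouping used by topology weighting,
#' the D-statistic roles in taxon-frequency mode, and the diversity /
#' divergence calculations.
#'
#' @param samples Character vector of sample identifiers.
#' @param taxa Character vector, same length, giving the taxon of each
#'   sample.
#' @return An object of class `taxon_map`: a list with `entries` (named
#'   character vector, sample -> taxon) and `taxa` (unique taxon labels in
#'   order of first appearance).
#' @examples
#' tm <- taxon_map(c("s1", "s2", "s3"), c("A", "A", "B"))
#' tm$taxa
#' @export
taxon_map <- function(samples, taxa) {
  samples <- as.character(samples)
  taxa <- as.character(taxa)
  if (length(samples) != length(taxa)) {
    stop("`samples` and `taxa` must have the same length")
  }
  if (anyDuplicated(samples)) {
    stop("duplicated sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  if (any(!nzchar(samples)) || any(!nzchar(taxa))) {
    stop("empty sample or taxon labels are not allowed")
  }
  structure(
    list(entries = stats::setNames(taxa, samples), taxa = unique(taxa)),
    class = "taxon_map"
  )
}

#' Read a sample-to-taxon mapping from a two-column TSV
#'
#' Expects a header line `sample<TAB>taxon`.
#'
#' @param path Path to the TSV file.
#' @return A [taxon_map()].
#' @export
read_taxon_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample", "taxon") %in% names(df))) {
    stop("taxon map must have columns 'sample' and 'taxon'")
  }
  taxon_map(df$sample, df$taxon)
}

#' @export
print.taxon_map <- function(x, ...) {
  cat("taxon_map:", length(x$entries), "samples in", length(x$taxa),
      "taxa\n")
  for (t in x$taxa) {
    cat("  ", t, ": ", paste(names(x$entries)[x$entries == t],
                             collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# samples belonging to one taxon
taxon_samples <- function(tm, taxon) {
  stopifnot(inherits(tm, "taxon_map"))
  s <- names(tm$entries)[tm$entries == taxon]
  if (length(s) == 0L) stop("no samples mapped to taxon '", taxon, "'")
  s
}
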