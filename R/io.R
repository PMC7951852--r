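#' Read diploid biallelic genotypes from a VCF
#'
#' Parses a VCF (via \pkg{vcfR}), keeps biallelic SNVs with ACGT alleles,
#' and codes genotypes as ALT-allele dosage. Multi-allelic records and
#' records with non-ACGT alleles are dropped with a logged count; half calls
#' and `./.` both become missing. When the GT separators are `|` the first
#' haplotype is retained so alignments can later be exported per haplotype.
#'
#' @param path Path to a VCF (plain text or bgzipped).
#' @param tm A [taxon_map()]; every mapped sample must appear in the VCF
#'   header.
#' @param keep_invariant Keep records whose ALT is missing/`.` (invariant
#'   sites, needed for pi / dxy denominators). Default `FALSE`.
#' @return A [genotype_matrix()].
#' @export
read_genotype_vcf <- function(path, tm, keep_invariant = FALSE) {
  stopifnot(inherits(tm, "taxon_map"))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("VCF contains no records: ", path)
  vcf_samples <- colnames(v@gt)[-1L]
  absent <- setdiff(names(tm$entries), vcf_samples)
  if (length(absent)) {
    stop("sample(s) missing from VCF header: ",
         paste(absent, collapse = ", "))
  }
  pos <- as.integer(fix$POS)
  # sortedness check before any filtering
  for (chr in unique(fix$CHROM)) {
    p <- pos[fix$CHROM == chr]
    if (is.unsorted(p, strictly = FALSE)) {
      stop("VCF not sorted by position on chromosome ", chr)
    }
  }
  alt <- fix$ALT
  alt[is.na(alt)] <- "."
  ref <- fix$REF
  is_multi <- grepl(",", alt, fixed = TRUE)
  is_inv <- !is_multi & (alt == "." | alt == "")
  acgt <- c("A", "C", "G", "T")
  ok_alleles <- ref %in% acgt & (is_inv | alt %in% acgt)
  keep <- !is_multi & ok_alleles & (keep_invariant | !is_inv)
  n_multi <- sum(is_multi)
  if (n_multi) ig_log("dropped %d multi-allelic record(s)", n_multi)
  n_bad <- sum(!ok_alleles & !is_multi)
  if (n_bad) ig_log("dropped %d record(s) with non-ACGT alleles", n_bad)
  if (!keep_invariant && sum(is_inv & ok_alleles)) {
    ig_log("dropped %d invariant record(s) (keep_invariant = FALSE)",
           sum(is_inv & ok_alleles))
  }
  if (!any(keep)) stop("no usable records in VCF: ", path)

  gt_raw <- v@gt[keep, vcf_samples, drop = FALSE]
  fmt <- v@gt[keep, 1L]
  gt_field <- function(x, fmt) {
    idx <- vapply(strsplit(fmt, ":", fixed = TRUE),
                  function(f) match("GT", f), integer(1))
    if (anyNA(idx)) stop("VCF records without GT field")
    vapply(seq_along(x), function(i) {
      strsplit(x[i], ":", fixed = TRUE)[[1L]][idx[i]]
    }, character(1))
  }
  nsite <- sum(keep)
  geno <- matrix(NA_integer_, nsite, length(vcf_samples))
  hap1 <- matrix(NA_integer_, nsite, length(vcf_samples))
  any_phased <- FALSE
  allele_dose <- c("0" = 0L, "1" = 1L)
  for (j in seq_along(vcf_samples)) {
    g <- gt_field(gt_raw[, j], fmt)
    a <- substr(g, 1L, 1L)
    sep <- substr(g, 2L, 2L)
    b <- substr(g, 3L, 3L)
    d1 <- allele_dose[a]
    d2 <- allele_dose[b]
    geno[, j] <- d1 + d2          # NA if either allele missing (half call)
    ph <- sep == "|"
    any_phased <- any_phased || any(ph)
    hap1[ph, j] <- d1[ph]
  }
  sites <- data.frame(chrom = fix$CHROM[keep],
                      pos = pos[keep] - 1L,   # to 0-based
                      ref = ref[keep],
                      alt = alt[keep],
                      stringsAsFactors = FALSE)
  sites$alt[is_inv[keep]] <- "."
  genotype_matrix(sites, geno, vcf_samples, tm,
                  includes_invariant = keep_invariant && any(is_inv[keep]),
                  hap1 = if (any_phased) hap1 else NULL,
                  phased = any_phased)
}

#' Write a genotype matrix to VCF
#'
#' Minimal VCF 4.2 writer used to serialize simulated data sets; positions
#' are converted back to the 1-based VCF convention. Genotypes are written
#' phased (`|`) when haplotype information is available.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=introgressr",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  for (chr in unique(gm$sites$chrom)) {
    writeLines(sprintf("##contig=<ID=%s>", chr), con)
  }
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$samples), collapse = "\t"), con)
  n <- nrow(gm$sites)
  if (n == 0L) return(invisible(path))
  gt <- matrix("", n, length(gm$samples))
  phased <- gm$phased && !is.null(gm$hap1)
  for (j in seq_along(gm$samples)) {
    d <- gm$geno[, j]
    if (phased) {
      a <- gm$hap1[, j]
      b <- d - a
      gt[, j] <- ifelse(is.na(d), ".|.", paste0(a, "|", b))
    } else {
      gt[, j] <- c("0/0", "0/1", "1/1")[d + 1L]
      gt[is.na(d), j] <- "./."
    }
  }
  body <- cbind(gm$sites$chrom, gm$sites$pos + 1L, ".", gm$sites$ref,
                gm$sites$alt, ".", ".", ".", "GT", gt)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Genomic region set
#'
#' Regions ("genes" / capture targets) in 0-based half-open coordinates.
#'
#' @param region_id,chrom,start,end Vectors defining the regions.
#' @return data.frame of class `region_set`, sorted by (chrom, start).
#' @export
region_set <- function(region_id, chrom, start, end) {
  df <- data.frame(region_id = as.character(region_id),
                   chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) {
    stop("region start must be < end (offending: ",
         paste(df$region_id[df$start >= df$end], collapse = ", "), ")")
  }
  if (anyDuplicated(df$region_id)) {
    stop("duplicate region id(s): ",
         paste(unique(df$region_id[duplicated(df$region_id)]),
               collapse = ", "))
  }
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("region_set", "data.frame")
  df
}

#' Read regions from a BED file
#'
#' BED3/BED4; the native 0-based half-open coordinates are preserved
#' verbatim. Overlapping intervals are allowed but logged. Without a name
#' column, ids `region_<n>` are generated.
#'
#' @param path Path to a BED file.
#' @return A [region_set()].
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    return(region_set(character(), character(), integer(), integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 3L)) {
    stop("BED line ", which(ncols < 3L)[1L], " has fewer than 3 columns")
  }
  chrom <- vapply(parts, `[`, character(1), 1L)
  start <- as.integer(vapply(parts, `[`, character(1), 2L))
  end <- as.integer(vapply(parts, `[`, character(1), 3L))
  bad <- which(start >= end)
  if (length(bad)) {
    stop("BED line ", bad[1L], ": start >= end")
  }
  ids <- if (all(ncols >= 4L)) {
    vapply(parts, `[`, character(1), 4L)
  } else {
    sprintf("region_%d", seq_along(lines))
  }
  rs <- region_set(ids, chrom, start, end)
  # log overlaps within chromosome
  n_overlap <- 0L
  for (chr in unique(rs$chrom)) {
    sub <- rs[rs$chrom == chr, ]
    if (nrow(sub) > 1L) {
      n_overlap <- n_overlap + sum(sub$start[-1L] < sub$end[-nrow(sub)])
    }
  }
  if (n_overlap) ig_log("%d overlapping region pair(s) in BED", n_overlap)
  rs
}

#' Write a region set to BED4
#' @param rs A [region_set()].
#' @param path Output path.
#' @export
write_bed <- function(rs, path) {
  utils::write.table(
    data.frame(rs$chrom, rs$start, rs$end, rs$region_id),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene trees from a Newick file (one tree per line)
#'
#' Trees are taken as rooted as written; branch lengths are optional and
#' polytomies are parsed as-is (downstream operations decide how to handle
#' them).
#'
#' @param path Path to a Newick file.
#' @return A `multiPhylo` list of trees.
#' @export
read_newick <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  open <- vapply(gregexpr("(", lines, fixed = TRUE),
                 function(m) sum(m > 0), numeric(1))
  close <- vapply(gregexpr(")", lines, fixed = TRUE),
                  function(m) sum(m > 0), numeric(1))
  bad <- which(open != close)
  if (length(bad)) {
    stop("unbalanced parentheses in Newick on line ", bad[1L])
  }
  trees <- ape::read.tree(text = paste(lines, collapse = "\n"))
  if (inherits(trees, "phylo")) trees <- c(trees)  # promote to multiPhylo
  trees
}

#' Write trees to a Newick file, one per line
#' @param trees A `phylo` or `multiPhylo`.
#' @param path Output path.
#' @export
write_newick <- function(trees, path) {
  ape::write.tree(trees, file = path)
  invisible(path)
}

#' Read a linkage map
#'
#' TSV with header columns `marker`, `chrom`, `bp`, `cM`. Markers are sorted
#' by (chrom, bp); positions where the genetic position decreases with
#' physical position are counted and reported, not altered.
#'
#' @param path Path to the TSV.
#' @return data.frame of class `linkage_map` with attribute
#'   `n_monotonicity_violations`.
#' @export
read_linkage_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("marker", "chrom", "bp", "cM")
  if (!all(need %in% names(df))) {
    stop("linkage map must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$bp < 0) || any(df$cM < 0)) {
    stop("negative bp or cM in linkage map")
  }
  linkage_map(df)
}

#' Construct a linkage map object
#' @param df data.frame with columns `marker`, `chrom`, `bp`, `cM`.
#' @return A `linkage_map`.
#' @export
linkage_map <- function(df) {
  df <- df[order(df$chrom, df$bp), c("marker", "chrom", "bp", "cM")]
  rownames(df) <- NULL
  viol <- 0L
  for (chr in unique(df$chrom)) {
    d <- diff(df$cM[df$chrom == chr])
    viol <- viol + sum(d < 0)
  }
  if (viol > 0L) {
    ig_log("linkage map: %d monotonicity violation(s) flagged", viol)
  }
  attr(df, "n_monotonicity_violations") <- viol
  class(df) <- c("linkage_map", "data.frame")
  df
}

#' Write a linkage map to TSV
#' @param lm A `linkage_map`.
#' @param path Output path.
#' @export
write_linkage_map <- function(lm, path) {
  utils::write.table(as.data.frame(lm), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# IUPAC ambiguity code for an unordered pair of bases
iupac_code <- local({
  codes <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")
  function(a, b) {
    key <- paste0(pmin(a, b), pmax(a, b))
    out <- codes[key]
    out[a == b] <- a[a == b]
    unname(out)
  }
})

#' Export per-region alignments of variable sites as FASTA
#'
#' One FASTA file per region, one sequence per sample, consisting of the
#' region's variable sites only. Heterozygous calls are written as IUPAC
#' ambiguity codes by default; with `haplotype = 1` or `2` a single phased
#' haplotype is emitted instead (requires phased input). Regions with zero
#' variable sites are skipped with a log entry.
#'
#' @param gm A [genotype_matrix()].
#' @param rs A [region_set()].
#' @param out_dir Output directory (created if needed).
#' @param haplotype `NULL` (IUPAC consensus) or 1/2 for a phased haplotype.
#' @return Invisibly, a character vector of written file paths.
#' @export
export_gene_alignments <- function(gm, rs, out_dir, haplotype = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(rs, "region_set"))
  if (!is.null(haplotype)) {
    if (!gm$phased || is.null(gm$hap1)) {
      stop("haplotype export requires phased genotypes")
    }
    if (!haplotype %in% c(1L, 2L)) stop("haplotype must be 1 or 2")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  is_var <- variant_rows(gm)
  written <- character()
  n_skipped <- 0L
  for (i in seq_len(nrow(rs))) {
    idx <- region_site_index(gm, rs$chrom[i], rs$start[i], rs$end[i])
    idx <- idx[is_var[idx]]
    if (length(idx) == 0L) {
      n_skipped <- n_skipped + 1L
      next
    }
    ref <- gm$sites$ref[idx]
    alt <- gm$sites$alt[idx]
    seqs <- vapply(seq_along(gm$samples), function(j) {
      d <- gm$geno[idx, j]
      if (is.null(haplotype)) {
        chars <- ifelse(is.na(d), "N",
                        ifelse(d == 0L, ref,
                               ifelse(d == 2L, alt, iupac_code(ref, alt))))
      } else {
        h <- gm$hap1[idx, j]
        if (haplotype == 2L) h <- d - h
        chars <- ifelse(is.na(h), "N", ifelse(h == 0L, ref, alt))
      }
      paste(chars, collapse = "")
    }, character(1))
    f <- file.path(out_dir, paste0(rs$region_id[i], ".fasta"))
    writeLines(rbind(paste0(">", gm$samples), seqs), f)
    written <- c(written, f)
  }
  if (n_skipped) {
    ig_log("skipped %d region(s) with no variable sites", n_skipped)
  }
  invisible(written)
}
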