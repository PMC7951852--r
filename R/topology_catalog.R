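# Rooted leaf-labeled topologies. Trees are held as nested lists (a leaf is
# its label, an internal node a list of two children) and identified by a
# canonical string: children of every node ordered by their smallest tip
# label in byte order, tips printed verbatim.

canonical_nested <- function(x) {
  if (is.character(x)) {
    return(list(str = x, min = x))
  }
  a <- canonical_nested(x[[1L]])
  b <- canonical_nested(x[[2L]])
  a_first <- radix_min(a$min, b$min) == a$min
  list(
    str = if (a_first) paste0("(", a$str, ",", b$str, ")")
          else paste0("(", b$str, ",", a$str, ")"),
    min = radix_min(a$min, b$min)
  )
}

# all positions to attach a new tip: above every subtree, plus a new root
insert_tip_everywhere <- function(tree, tip) {
  res <- list(list(tree, tip))
  if (!is.character(tree)) {
    for (child in 1:2) {
      other <- if (child == 1L) tree[[2L]] else tree[[1L]]
      for (sub in insert_tip_everywhere(tree[[child]], tip)) {
        res[[length(res) + 1L]] <- if (child == 1L) list(sub, other) else
          list(other, sub)
      }
    }
  }
  res
}

#' Number of rooted binary topologies for n taxa
#'
#' The closed form is the double factorial `(2n - 3)!!`; for five taxa
#' there are 105 distinct rooted trees and for seven 10,395 — the count
#' that makes exhaustive topology weighting feasible for five groups but
#' not many more.
#'
#' @param n Number of taxa (>= 2).
#' @return The number of rooted binary leaf-labeled topologies.
#' @examples
#' count_rooted_topologies(5)  # 105
#' @export
count_rooted_topologies <- function(n) {
  if (n < 2) stop("need at least 2 taxa")
  prod(seq(1, 2 * n - 3, by = 2))
}

#' Enumerate all rooted binary topologies over a taxon set
#'
#' Generates every rooted binary leaf-labeled topology by successive tip
#' insertion (each tree is produced exactly once), canonicalizes, and
#' returns them in a deterministic (byte-sorted) order.
#'
#' @param taxa Character vector of 2-8 distinct labels. Larger sets are
#'   refused (the catalog grows as `(2n-3)!!`); pass `force = TRUE` to
#'   override.
#' @param force Allow more than 8 taxa.
#' @return An object of class `topology_catalog`: list with `taxa`,
#'   `topologies` (canonical strings) and `trees` (nested-list forms).
#' @export
enumerate_rooted_topologies <- function(taxa, force = FALSE) {
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa)) stop("duplicate taxon labels")
  n <- length(taxa)
  if (n < 2) stop("need at least 2 taxa")
  if (n > 8 && !force) {
    stop("catalog for ", n, " taxa has ", count_rooted_topologies(n),
         " topologies; pass force = TRUE if you really want this")
  }
  taxa_sorted <- radix_sort(taxa)
  trees <- list(list(taxa_sorted[1L], taxa_sorted[2L]))
  if (n > 2) {
    for (i in 3:n) {
      trees <- unlist(lapply(trees, insert_tip_everywhere,
                             tip = taxa_sorted[i]),
                      recursive = FALSE)
    }
  }
  strs <- vapply(trees, function(t) canonical_nested(t)$str, character(1))
  o <- order(strs, method = "radix")
  structure(list(taxa = taxa_sorted, topologies = strs[o],
                 trees = trees[o]),
            class = "topology_catalog")
}

#' @export
print.topology_catalog <- function(x, ...) {
  cat("topology_catalog:", length(x$topologies), "rooted topologies over {",
      paste(x$taxa, collapse = ", "), "}\n")
  invisible(x)
}

# parse a canonical topology string back into a nested list
parse_topology_string <- function(s) {
  pos <- 1L
  n <- nchar(s)
  parse_node <- function() {
    if (substr(s, pos, pos) == "(") {
      pos <<- pos + 1L
      left <- parse_node()
      stopifnot(substr(s, pos, pos) == ",")
      pos <<- pos + 1L
      right <- parse_node()
      stopifnot(substr(s, pos, pos) == ")")
      pos <<- pos + 1L
      list(left, right)
    } else {
      start <- pos
      while (pos <= n && !substr(s, pos, pos) %in% c(",", ")", "(")) {
        pos <<- pos + 1L
      }
      substr(s, start, pos - 1L)
    }
  }
  parse_node()
}

# tip sets of all clades (internal nodes) in a nested-list topology
topology_clades <- function(tree) {
  clades <- list()
  walk <- function(x) {
    if (is.character(x)) return(x)
    tips <- c(walk(x[[1L]]), walk(x[[2L]]))
    clades[[length(clades) + 1L]] <<- tips
    tips
  }
  walk(tree)
  clades
}

# does topology (canonical string) contain `clade` as a monophyletic group?
topology_has_clade <- function(topology_string, clade) {
  clades <- topology_clades(parse_topology_string(topology_string))
  any(vapply(clades, function(x) setequal(x, clade), logical(1)))
}

# convert a catalog topology string to an ape phylo (used by test oracles
# and for plotting/labels)
topology_to_phylo <- function(topology_string) {
  ape::read.tree(text = paste0(topology_string, ";"))
}
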