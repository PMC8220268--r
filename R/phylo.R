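# Tree handling: Newick I/O, pruning, minimum-branch-length time-scaling,
# ultrametricization, patristic distances.
#
# Conventions used throughout: ages are in Ma before present (larger = older),
# branch lengths in Myr. A time-scaled tree is an ape `phylo` carrying a
# `root.time` element (the age of the root in Ma), so the age of any node is
# root.time minus its depth from the root.

#' Parse a Newick string into a phylogenetic tree
#'
#' Thin validated wrapper around [ape::read.tree()]. The string is checked for
#' balanced parentheses before parsing so malformed input fails with the
#' character offset of the problem rather than an opaque downstream error.
#'
#' @param text A single Newick string (terminated by `;`).
#' @param unit_lengths If `TRUE`, a tree without branch lengths is accepted
#'   and every edge is assigned length 1. Default `FALSE` (error).
#' @return An [ape::phylo] object.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' patristic_matrix(tr)
#' @export
parse_newick <- function(text, unit_lengths = FALSE) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    abort("`text` must be a single Newick string.")
  }
  check_newick_syntax(text)
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL
  )
  if (is.null(tree)) abort("Failed to parse Newick string.")
  if (is.null(tree$edge.length)) {
    if (!unit_lengths) {
      abort("Newick string has no branch lengths (set `unit_lengths = TRUE` to assign unit lengths).")
    }
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  if (anyDuplicated(tree$tip.label)) {
    abort(paste0(
      "Duplicate tip labels: ",
      paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", ")
    ))
  }
  if (any(tree$edge.length < 0)) abort("Negative branch lengths are not allowed.")
  tree
}

# Balanced-parenthesis / terminator scan; errors name the 1-based character
# offset of the first defect.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        abort(sprintf("Malformed Newick: unmatched ')' at character %d.", i))
      }
    }
  }
  if (depth > 0L) {
    abort(sprintf(
      "Malformed Newick: %d unclosed '(' (string ends at character %d).",
      depth, length(chars)
    ))
  }
  if (!grepl(";", text, fixed = TRUE)) {
    abort(sprintf("Malformed Newick: missing ';' terminator (string ends at character %d).", length(chars)))
  }
  invisible(TRUE)
}

#' Write a tree to a Newick string
#'
#' @param tree An [ape::phylo] object.
#' @param digits Significant digits for branch lengths.
#' @return A Newick string.
#' @export
write_newick <- function(tree, digits = 10) {
  ape::write.tree(tree, digits = digits)
}

#' Root age of a time-scaled tree
#'
#' Returns `tree$root.time` if present, otherwise assumes the youngest tip
#' sits at the present (0 Ma) so the root age equals the maximum root-to-tip
#' depth.
#'
#' @param tree An [ape::phylo] object with branch lengths.
#' @return Root age in Ma.
#' @export
root_time <- function(tree) {
  if (!is.null(tree$root.time)) return(tree$root.time)
  max(ape::node.depth.edgelength(tree))
}

#' Tip ages of a time-scaled tree
#'
#' @param tree An [ape::phylo] object with branch lengths (and optionally
#'   `root.time`).
#' @return Named numeric vector of tip ages in Ma before present.
#' @export
tip_ages <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  setNames(root_time(tree) - depths, tree$tip.label)
}

#' Internal node ages of a time-scaled tree
#'
#' @inheritParams tip_ages
#' @return Numeric vector of internal node ages in Ma, in node-number order.
#' @export
node_ages <- function(tree) {
  ntip <- ape::Ntip(tree)
  depths <- ape::node.depth.edgelength(tree)
  root_time(tree) - depths[(ntip + 1L):(ntip + tree$Nnode)]
}

#' Prune a tree to a set of taxa
#'
#' Keeps exactly the requested tips, suppressing degree-2 nodes by summing
#' incident branch lengths, so patristic distances among retained taxa are
#' unchanged. `root.time` is recomputed so tip ages are preserved.
#'
#' @param tree An [ape::phylo] object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return The pruned [ape::phylo].
#' @export
prune_tree <- function(tree, keep) {
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown) > 0) {
    abort(paste0("Taxa not in tree: ", paste(unknown, collapse = ", ")))
  }
  if (length(keep) < 2) abort("At least two taxa must be retained.")
  has_lengths <- !is.null(tree$edge.length)
  old_ages <- if (has_lengths) tip_ages(tree) else NULL
  pruned <- ape::keep.tip(tree, keep)
  if (has_lengths) {
    # restore the age frame of reference: any retained tip anchors root.time
    anchor <- pruned$tip.label[1]
    depth <- ape::node.depth.edgelength(pruned)[match(anchor, pruned$tip.label)]
    pruned$root.time <- old_ages[[anchor]] + depth
  }
  pruned
}

#' Time-scale a tree topology with the minimum-branch-length rule
#'
#' Dates every internal node at the minimum age consistent with (i) being at
#' least as old as each descendant plus the minimum branch length `mbl` and
#' (ii) being no younger than its oldest descendant tip. Ages propagate
#' bottom-up, so nodes are pushed older only as far as the constraints
#' require; as `mbl` approaches 0 every node is dated exactly at its oldest
#' descendant tip.
#'
#' @param tree An [ape::phylo]; only the topology is used.
#' @param ages A data frame with columns `taxon` and `fad_ma` (and optionally
#'   `lad_ma`), as returned by [read_taxon_ages()].
#' @param mbl Minimum branch length in Myr (> 0). Default 1.
#' @param age_type Which datum dates each tip: `"fad"` (default), `"lad"`, or
#'   `"mid"` (midpoint of the range).
#' @return A time-scaled [ape::phylo] with `root.time` set.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:1);")
#' ages <- tibble::tibble(taxon = c("A", "B", "C"), fad_ma = c(80, 75, 72))
#' ts <- timescale_mbl(tr, ages, mbl = 1)
#' node_ages(ts) # 82 (root), 81
#' @export
timescale_mbl <- function(tree, ages, mbl = 1, age_type = c("fad", "lad", "mid")) {
  age_type <- match.arg(age_type)
  if (!is.numeric(mbl) || length(mbl) != 1 || is.na(mbl) || mbl <= 0) {
    abort("`mbl` must be a single positive number (Myr).")
  }
  stopifnot(is.data.frame(ages), all(c("taxon", "fad_ma") %in% names(ages)))
  tip_age <- switch(age_type,
    fad = setNames(ages$fad_ma, ages$taxon),
    lad = {
      if (!"lad_ma" %in% names(ages)) abort("`ages` lacks a `lad_ma` column.")
      setNames(ages$lad_ma, ages$taxon)
    },
    mid = {
      if (!"lad_ma" %in% names(ages)) abort("`ages` lacks a `lad_ma` column.")
      setNames((ages$fad_ma + ages$lad_ma) / 2, ages$taxon)
    }
  )
  missing_taxa <- setdiff(tree$tip.label, names(tip_age)[!is.na(tip_age)])
  if (length(missing_taxa) > 0) {
    abort(paste0("Missing tip ages for: ", paste(missing_taxa, collapse = ", ")))
  }

  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  age <- numeric(ntip + nnode)
  age[seq_len(ntip)] <- tip_age[tree$tip.label]
  age[(ntip + 1L):(ntip + nnode)] <- -Inf
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1L]
    child <- po$edge[e, 2L]
    age[parent] <- max(age[parent], age[child] + mbl)
  }
  out <- tree
  out$edge.length <- age[tree$edge[, 1L]] - age[tree$edge[, 2L]]
  out$root.time <- age[ntip + 1L]
  out
}

#' Extend terminal branches so all tips are contemporaneous
#'
#' Makes a time-scaled tree ultrametric by lengthening each terminal branch
#' until its tip reaches the age of the youngest tip in the tree. Internal
#' node ages are untouched and no branch is ever shortened; an already
#' ultrametric tree is returned unchanged.
#'
#' @param tree A time-scaled [ape::phylo].
#' @return An ultrametric [ape::phylo] with the same `root.time`.
#' @export
make_ultrametric <- function(tree) {
  if (is.null(tree$edge.length)) abort("Tree has no branch lengths.")
  ages <- tip_ages(tree)
  youngest <- min(ages)
  out <- tree
  tip_edge <- match(seq_len(ape::Ntip(tree)), tree$edge[, 2L])
  out$edge.length[tip_edge] <- out$edge.length[tip_edge] +
    (ages[tree$tip.label] - youngest)
  out$root.time <- root_time(tree)
  out
}

#' Test whether a tree is ultrametric
#'
#' @param tree An [ape::phylo] with branch lengths.
#' @param tol Absolute tolerance on root-to-tip depth differences.
#' @return Logical.
#' @export
is_ultrametric <- function(tree, tol = 1e-8) {
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  diff(range(depths)) <= tol
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the path between every pair of tips, via
#' [stats::cophenetic()].
#'
#' @param tree An [ape::phylo] with branch lengths.
#' @return A symmetric labelled numeric matrix (Myr).
#' @export
patristic_matrix <- function(tree) {
  if (is.null(tree$edge.length)) abort("Tree has no branch lengths.")
  as.matrix(stats::cophenetic(tree))
}
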