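#' Parse a newick string into a validated phylogeny
#'
#' Thin wrapper around [ape::read.tree()] that first scans the string for
#' structural problems (so malformed input is reported with a character
#' offset) and then validates the resulting tree: unique tip labels, finite
#' non-negative branch lengths, a single root. Polytomies are rejected by
#' default because every downstream statistic here (contrasts, Pagel's
#' lambda, the D statistic) is defined on binary trees; set
#' `resolve_polytomies = TRUE` to resolve them arbitrarily with zero-length
#' branches.
#'
#' @param text A newick string (branch lengths in Myr).
#' @param resolve_polytomies Resolve multifurcations with zero-length
#'   branches instead of erroring.
#' @return An object of class `phylo`.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' ape::Ntip(tr)
parse_newick <- function(text, resolve_polytomies = FALSE) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    abort("`text` must be a single newick string.")
  }
  scan_newick_structure(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) abort(paste0("newick parse failed: ", conditionMessage(e)))
  )
  if (is.null(tree)) abort("newick parse failed: unreadable string.")
  validate_phylogeny(tree, resolve_polytomies = resolve_polytomies)
}

# Pre-scan for unbalanced parentheses / missing terminator, reporting the
# 1-based character offset of the first offending character.
scan_newick_structure <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        abort(sprintf("malformed newick: unmatched ')' at character offset %d", i))
      }
    }
  }
  if (depth > 0L) {
    abort(sprintf(
      "malformed newick: %d unclosed '(' (last opened before offset %d)",
      depth, length(chars)
    ))
  }
  if (!grepl(";\\s*$", text)) {
    abort(sprintf(
      "malformed newick: missing ';' terminator at character offset %d",
      length(chars)
    ))
  }
  invisible(TRUE)
}

#' Validate a phylogeny for use in the pipeline
#'
#' Checks the invariants every statistic in this package relies on:
#' unique tip labels, finite branch lengths >= 0, a binary rooted topology.
#'
#' @param tree A `phylo` object.
#' @inheritParams parse_newick
#' @return The (possibly polytomy-resolved) tree, invisibly usable.
#' @export
validate_phylogeny <- function(tree, resolve_polytomies = FALSE) {
  if (!inherits(tree, "phylo")) abort("`tree` must be a `phylo` object.")
  if (is.null(tree$edge.length)) abort("tree has no branch lengths.")
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length))) {
    abort("tree has missing or non-finite branch lengths.")
  }
  if (any(tree$edge.length < 0)) abort("tree has negative branch lengths.")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0) {
    abort(paste0("duplicate tip labels: ", paste(dup, collapse = ", ")))
  }
  if (!ape::is.rooted(tree)) abort("tree must be rooted.")
  if (!ape::is.binary(tree)) {
    if (resolve_polytomies) {
      tree <- ape::multi2di(tree, random = FALSE)
      tree$edge.length[is.na(tree$edge.length)] <- 0
    } else {
      abort("tree contains polytomies; set `resolve_polytomies = TRUE` to resolve them.")
    }
  }
  tree
}

#' Write a phylogeny to a newick string or file
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the newick string is returned.
#' @return The newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = 12)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Patristic distance matrix
#'
#' Total branch length along the path connecting each pair of tips
#' (in the tree's branch-length units, Myr for dated trees).
#'
#' @param tree A `phylo` object.
#' @return A symmetric species-by-species matrix with zero diagonal.
#' @export
patristic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  m <- ape::cophenetic.phylo(tree)
  m[tree$tip.label, tree$tip.label]
}
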