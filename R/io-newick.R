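# Newick parsing/writing, delegated to ape with validation on top: the
# pipeline consumes externally built trees (e.g. approximate-ML trees) via
# this boundary and all downstream code works on ape "phylo" objects.

#' Parse a Newick string into a phylogenetic tree
#'
#' @param text A Newick string (or a length-1 path-free character vector).
#' @return An ape `phylo` object with branch lengths.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:2):0.5,C:3);")
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop("unbalanced parentheses in Newick string", call. = FALSE)
  }
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("invalid Newick string", call. = FALSE)
  }
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup)) {
    stop("duplicate leaf name(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("negative branch length in Newick string", call. = FALSE)
  }
  tree
}

#' Serialize a phylogenetic tree to Newick
#'
#' @param tree An ape `phylo` object.
#' @return A Newick string (with trailing semicolon).
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}
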