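#' Read a rooted tree from a newick file
#'
#' Thin validating wrapper around [ape::read.tree()]: requires a single tree,
#' unique leaf labels, and (by default) a rooted topology.
#'
#' @param path path to a newick file (or a literal newick string via `text`).
#' @param text optional newick string instead of a file.
#' @param require_rooted reject unrooted trees (default TRUE; Dollo
#'   reconstruction is only meaningful on rooted trees).
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(path = NULL, text = NULL, require_rooted = TRUE) {
  tr <- tryCatch(
    suppressWarnings(
      if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)),
    error = function(e) stop("newick parse error: ", conditionMessage(e),
                             call. = FALSE))
  if (is.null(tr)) stop("newick parse error: could not parse tree", call. = FALSE)
  if (inherits(tr, "multiPhylo"))
    stop("expected a single newick tree", call. = FALSE)
  if (anyDuplicated(tr$tip.label))
    stop(sprintf("duplicate leaf label(s): %s",
                 paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                       collapse = ", ")), call. = FALSE)
  if (require_rooted && !ape::is.rooted(tr))
    stop("tree is unrooted; a rooted species tree is required", call. = FALSE)
  tr
}

#' Write a tree to a newick file
#' @param tree an [ape::phylo] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
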