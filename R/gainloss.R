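# Edges are identified by their child clade's sorted leaf set, joined with
# "|" -- stable across node renumbering and readable in reports.  The edge
# above the root (when a family's origin predates the sampled taxa) is the
# virtual root edge, id "(root)".

#' Identify the edge above a node by its descendant leaf set
#' @param tree an [ape::phylo] object.
#' @param node node number (tip or internal).
#' @return character edge identifier.
#' @export
edge_id <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  tips <- if (node <= n_tip) tree$tip.label[node] else
    tree$tip.label[tips_under(tree, node)]
  paste(sort(tips), collapse = "|")
}

# tip indices descending from a node (the node itself if a tip)
tips_under <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    tips <- kids[kids <= n_tip]
    out <- c(out, tips)
    stack <- c(stack, kids[kids > n_tip])
  }
  out
}

node_children <- function(tree, node) tree$edge[tree$edge[, 1] == node, 2]

#' Dollo-parsimony reconstruction of a gene family's gain/loss history
#'
#' Under Dollo parsimony the family is gained exactly once and thereafter
#' only lost.  The gain is placed on the edge above the MRCA of the present
#' leaves (the virtual root edge, flagged `at_root`, when that MRCA is the
#' root: origin at or before the root of the sampled taxa).  Losses are the
#' maximal wholly-absent subtrees below the gain -- the unique minimal edge
#' set explaining every absent descendant.  Polytomies are accepted; each
#' child of a polytomy is treated independently.
#'
#' @param tree rooted [ape::phylo] species tree.
#' @param presence named 0/1 (or logical) vector over the tree's leaves.
#' @param family family name carried through to the report.
#' @return a `gainloss_history`: list with `family`, `gain_edge` (edge id),
#'   `gain_node`, `at_root`, `loss_edges` (edge ids), `loss_nodes`,
#'   `n_losses`, and `implied_presence` (0/1 for every node, tips first).
#' @export
dollo_reconstruct <- function(tree, presence, family = "family") {
  if (!ape::is.rooted(tree))
    stop("dollo_reconstruct requires a rooted tree", call. = FALSE)
  if (is.logical(presence)) presence <- as.integer(presence)
  if (is.null(names(presence)))
    stop("presence vector must be named by leaf label", call. = FALSE)
  missing_sp <- setdiff(tree$tip.label, names(presence))
  if (length(missing_sp))
    stop("presence vector lacks leaves: ", paste(missing_sp, collapse = ", "),
         call. = FALSE)
  pres <- presence[tree$tip.label]
  if (!any(pres == 1L))
    stop(sprintf("family '%s' absent from every leaf: no gain/loss history exists",
                 family), call. = FALSE)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  present_tips <- which(pres == 1L)
  gain_node <- if (length(present_tips) == 1L) present_tips else
    ape::getMRCA(tree, present_tips)
  at_root <- gain_node == root

  # maximal wholly-absent subtrees strictly below the gain node
  n_node <- n_tip + tree$Nnode
  has_present <- logical(n_node)
  has_present[present_tips] <- TRUE
  # postorder accumulation of presence over internal nodes
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edges))) {
    par <- edges[k, 1]; child <- edges[k, 2]
    if (has_present[child]) has_present[par] <- TRUE
  }
  loss_nodes <- integer(0)
  stack <- node_children(tree, gain_node)
  if (gain_node <= n_tip) stack <- integer(0)
  while (length(stack)) {
    nd <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (!has_present[nd]) loss_nodes <- c(loss_nodes, nd)
    else if (nd > n_tip) stack <- c(stack, node_children(tree, nd))
  }
  loss_nodes <- sort(loss_nodes)

  implied <- integer(n_node)
  under_gain <- c(gain_node,
                  if (gain_node > n_tip) {
                    st <- node_children(tree, gain_node); acc <- integer(0)
                    while (length(st)) {
                      nd <- st[[length(st)]]; st <- st[-length(st)]
                      acc <- c(acc, nd)
                      if (nd > n_tip) st <- c(st, node_children(tree, nd))
                    }
                    acc
                  })
  implied[under_gain] <- 1L
  for (ln in loss_nodes) {
    sub <- c(ln, if (ln > n_tip) {
      st <- node_children(tree, ln); acc <- integer(0)
      while (length(st)) {
        nd <- st[[length(st)]]; st <- st[-length(st)]
        acc <- c(acc, nd)
        if (nd > n_tip) st <- c(st, node_children(tree, nd))
      }
      acc
    })
    implied[sub] <- 0L
  }
  structure(list(
    family = family,
    gain_edge = if (at_root) "(root)" else edge_id(tree, gain_node),
    gain_node = gain_node,
    at_root = at_root,
    loss_edges = vapply(loss_nodes, function(nd) edge_id(tree, nd),
                        character(1)),
    loss_nodes = loss_nodes,
    n_losses = length(loss_nodes),
    implied_presence = implied
  ), class = "gainloss_history")
}

#' Name the lost taxa/clades of a gain/loss history
#'
#' @param history a `gainloss_history`.
#' @param tree the tree it was reconstructed on.
#' @return character vector, one entry per loss, leaves joined by `+`.
#' @export
annotate_losses <- function(history, tree) {
  vapply(history$loss_nodes, function(nd) {
    n_tip <- length(tree$tip.label)
    tips <- if (nd <= n_tip) tree$tip.label[nd] else
      sort(tree$tip.label[tips_under(tree, nd)])
    paste(tips, collapse = "+")
  }, character(1))
}

#' Reconstruct gain/loss histories for every family of a matrix
#'
#' @param tree rooted [ape::phylo] species tree.
#' @param matrix presence/absence matrix, families x species.
#' @return list of `gainloss_history` objects, ranked by origin depth
#'   (deepest origin first: root-edge gains, then by decreasing clade size);
#'   attribute `table` holds a flat summary data.frame.
#' @export
gainloss_matrix <- function(tree, matrix) {
  sp_diff <- c(setdiff(colnames(matrix), tree$tip.label),
               setdiff(tree$tip.label, colnames(matrix)))
  if (length(sp_diff))
    stop("species mismatch between matrix and tree: ",
         paste(unique(sp_diff), collapse = ", "), call. = FALSE)
  fams <- rownames(matrix)[rowSums(matrix) > 0]
  histories <- lapply(fams, function(f)
    dollo_reconstruct(tree, matrix[f, ], family = f))
  names(histories) <- fams
  depth <- vapply(histories, function(h) {
    if (h$at_root) length(tree$tip.label) + 1L
    else length(tips_under(tree, h$gain_node))
  }, numeric(1))
  histories <- histories[order(-depth, fams)]
  tab <- do.call(rbind, lapply(histories, function(h)
    data.frame(family = h$family, gain_edge = h$gain_edge,
               at_root = h$at_root, n_losses = h$n_losses,
               loss_edges = paste(h$loss_edges, collapse = ";"),
               stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  attr(histories, "table") <- tab
  histories
}
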