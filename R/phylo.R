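#' Construct a multiple alignment object from aligned sequences
#'
#' @param records data.frame with `id` and `sequence` columns (equal-length
#'   gapped protein sequences, gap character `-`), e.g. from [read_fasta()]
#'   on an aligned FASTA (the reader accepts `-` via pre-stripping; use
#'   [read_alignment()]).
#' @return a `multiple_alignment`: character matrix, rows = sequences.
#' @export
multiple_alignment <- function(records) {
  if (nrow(records) < 2L) stop("alignment needs >= 2 rows", call. = FALSE)
  lens <- nchar(records$sequence)
  if (length(unique(lens)) != 1L)
    stop("aligned sequences must have equal lengths", call. = FALSE)
  m <- do.call(rbind, strsplit(toupper(records$sequence), ""))
  rownames(m) <- records$id
  class(m) <- c("multiple_alignment", class(m))
  m
}

#' Read an aligned protein FASTA
#' @param path path to aligned FASTA (gap character `-`).
#' @return a `multiple_alignment`.
#' @export
read_alignment <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ids <- character(0); seqs <- character(0); buf <- character(0); cur <- NULL
  for (line in lines) {
    line <- trimws(line)
    if (!nzchar(line)) next
    if (startsWith(line, ">")) {
      if (!is.null(cur)) { ids <- c(ids, cur); seqs <- c(seqs, paste(buf, collapse = "")) }
      cur <- sub("\\s.*$", "", sub("^>", "", line)); buf <- character(0)
    } else buf <- c(buf, toupper(line))
  }
  if (!is.null(cur)) { ids <- c(ids, cur); seqs <- c(seqs, paste(buf, collapse = "")) }
  if (anyDuplicated(ids)) stop("duplicate ids in alignment", call. = FALSE)
  multiple_alignment(data.frame(id = ids, sequence = seqs,
                                stringsAsFactors = FALSE))
}

#' Write a multiple alignment to FASTA
#' @param msa a `multiple_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(msa, path) {
  write_fasta(data.frame(id = rownames(msa),
                         description = "",
                         sequence = apply(msa, 1, paste, collapse = ""),
                         stringsAsFactors = FALSE), path)
}

#' Trim alignment columns by gap fraction
#'
#' Retains exactly the columns whose gap fraction is at or below
#' `max_gap_fraction` (an explicit, reproducible stand-in for heuristic
#' automated trimmers).
#'
#' @param msa a `multiple_alignment`.
#' @param max_gap_fraction real in \[0, 1\].
#' @return trimmed `multiple_alignment`.
#' @export
trim_alignment <- function(msa, max_gap_fraction = 0.5) {
  stopifnot(max_gap_fraction >= 0, max_gap_fraction <= 1)
  gap_frac <- colMeans(unclass(msa) == "-")
  keep <- gap_frac <= max_gap_fraction
  if (!any(keep))
    stop("all columns exceed the gap-fraction threshold; raise max_gap_fraction",
         call. = FALSE)
  out <- unclass(msa)[, keep, drop = FALSE]
  class(out) <- c("multiple_alignment", class(out))
  out
}

#' Pairwise p-distances of an alignment
#'
#' Entry (i,j) is mismatches / compared columns, where columns with a gap in
#' either row are excluded.  Pairs with zero comparable columns are `NA`
#' (flagged missing, not zero).
#'
#' @param msa a `multiple_alignment`.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
p_distance <- function(msa) {
  m <- unclass(msa)
  n <- nrow(m)
  if (n < 2L) stop("p_distance needs >= 2 rows", call. = FALSE)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    nc <- sum(ok)
    d[i, j] <- d[j, i] <- if (nc == 0L) NA_real_ else
      sum(m[i, ok] != m[j, ok]) / nc
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration on the Q criterion.  Tie-breaking is
#' deterministic: among minimal Q entries the pair earliest in label order
#' wins.  Negative branch lengths are clamped to zero with the deficit moved
#' to the sister branch, preserving the pair's summed length.
#'
#' @param d symmetric distance matrix with labels as dimnames.
#' @return unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(d) {
  if (anyNA(d)) stop("distance matrix has missing entries", call. = FALSE)
  labels <- rownames(d)
  n <- length(labels)
  if (n < 3L) stop("neighbor joining needs >= 3 taxa", call. = FALSE)
  # each active cluster is a newick fragment (without trailing length)
  frag <- labels
  D <- d
  fmt <- function(x) sprintf("%.10g", x)
  while (length(frag) > 3L) {
    m <- length(frag)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # earliest pair in current (label-derived) order among minima
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_frag <- paste0("(", frag[i], ":", fmt(li), ",", frag[j], ":",
                       fmt(lj), ")")
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- matrix(0, m - 1L, m - 1L)
    if (length(keep)) {
      D2[seq_along(keep), seq_along(keep)] <- D[keep, keep]
      D2[m - 1L, seq_along(keep)] <- D2[seq_along(keep), m - 1L] <- dk[keep]
    }
    D <- D2
    frag <- c(frag[keep], new_frag)
  }
  # final three-cluster star: three-point formulas
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  clamp <- function(x) max(x, 0)
  nwk <- paste0("(", frag[1], ":", fmt(clamp(la)), ",", frag[2], ":",
                fmt(clamp(lb)), ",", frag[3], ":", fmt(clamp(lc)), ");")
  ape::read.tree(text = nwk)
}

# Nontrivial bipartitions of an unrooted tree as canonical strings: for each
# internal edge, the leaf set on the child side; canonicalized to the side
# not containing the alphabetically first leaf, sorted and joined with "|".
tree_bipartitions <- function(tree) {
  n_tip <- length(tree$tip.label)
  all_tips <- sort(tree$tip.label)
  anchor <- all_tips[[1]]
  internal <- tree$edge[tree$edge[, 2] > n_tip, 2]
  out <- character(0)
  for (nd in internal) {
    side <- sort(tree$tip.label[tips_under(tree, nd)])
    if (anchor %in% side) side <- setdiff(all_tips, side)
    if (length(side) >= 2L && length(side) <= n_tip - 2L)
      out <- c(out, paste(side, collapse = "|"))
  }
  unique(out)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree from
#' p-distances per replicate, and reports, for every internal bipartition of
#' the original tree, the percentage of replicates containing it.  The seed
#' maps to the replicate column-index streams through R's default RNG:
#' `set.seed(seed)` then `sample(ncol, ncol, replace = TRUE)` drawn once per
#' replicate in order, so supports are reproducible bit-exactly.
#'
#' @param msa a `multiple_alignment`.
#' @param reps number of replicates (>= 1).
#' @param seed integer RNG seed.
#' @return a `supported_tree`: list with `tree` (the original-NJ
#'   [ape::phylo]), `support` (named vector, percent per bipartition), and
#'   `reps`.
#' @export
bootstrap_support <- function(msa, reps = 1000L, seed = 1L) {
  stopifnot(reps >= 1L)
  base_tree <- neighbor_joining(p_distance(msa))
  target <- tree_bipartitions(base_tree)
  counts <- setNames(numeric(length(target)), target)
  nc <- ncol(unclass(msa))
  set.seed(seed)
  for (b in seq_len(reps)) {
    idx <- sample.int(nc, nc, replace = TRUE)
    sub <- unclass(msa)[, idx, drop = FALSE]
    class(sub) <- c("multiple_alignment", class(sub))
    dm <- p_distance(sub)
    if (anyNA(dm)) next  # replicate with an incomparable pair contributes 0
    bip <- tree_bipartitions(neighbor_joining(dm))
    hit <- target %in% bip
    counts[hit] <- counts[hit] + 1
  }
  structure(list(tree = base_tree,
                 support = 100 * counts / reps,
                 reps = reps),
            class = "supported_tree")
}

#' Test monophyly of a leaf subset after rooting on an outgroup
#'
#' @param tree [ape::phylo] (rooted or unrooted).
#' @param leaf_subset character vector of leaf labels.
#' @param outgroup_leaf leaf to root on; must not be in `leaf_subset`.
#' @return `TRUE` iff `leaf_subset` is exactly the leaf set of some node of
#'   the rooted tree.
#' @export
is_monophyletic <- function(tree, leaf_subset, outgroup_leaf) {
  unknown <- setdiff(c(leaf_subset, outgroup_leaf), tree$tip.label)
  if (length(unknown))
    stop("unknown leaf label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (outgroup_leaf %in% leaf_subset)
    stop("outgroup_leaf must not be in leaf_subset", call. = FALSE)
  rooted <- ape::root(tree, outgroup = outgroup_leaf, resolve.root = TRUE)
  if (setequal(leaf_subset, setdiff(rooted$tip.label, outgroup_leaf)))
    return(TRUE)  # the full ingroup is a clade by construction
  ape::is.monophyletic(rooted, leaf_subset)
}

#' Assign subtypes to query genes by the reference clade they nest in
#'
#' Walks from each query leaf toward the root of a rooted tree; the first
#' ancestor containing at least one reference leaf decides: if its
#' references carry exactly one subtype, the query gets it, otherwise the
#' query is `"ambiguous"` (e.g. a query basal to all references).
#'
#' @param tree rooted [ape::phylo] (or a `supported_tree`, whose NJ tree is
#'   rooted on the first reference of the first subtype's sister -- pass a
#'   rooted tree to control rooting).
#' @param reference_labels named character vector: reference leaf -> subtype.
#' @return named character vector: query leaf -> subtype or `"ambiguous"`.
#' @export
assign_subtype_by_clade <- function(tree, reference_labels) {
  if (inherits(tree, "supported_tree")) tree <- tree$tree
  if (!length(reference_labels)) stop("no reference labels", call. = FALSE)
  unknown <- setdiff(names(reference_labels), tree$tip.label)
  if (length(unknown))
    stop("reference leaves missing from tree: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!ape::is.rooted(tree))
    stop("assign_subtype_by_clade requires a rooted tree", call. = FALSE)
  n_tip <- length(tree$tip.label)
  parent_of <- function(nd) {
    p <- tree$edge[tree$edge[, 2] == nd, 1]
    if (length(p)) p else NA_integer_
  }
  queries <- setdiff(tree$tip.label, names(reference_labels))
  out <- setNames(character(length(queries)), queries)
  for (q in queries) {
    nd <- which(tree$tip.label == q)
    verdict <- "ambiguous"
    repeat {
      nd <- parent_of(nd)
      if (is.na(nd)) break
      tips <- tree$tip.label[tips_under(tree, nd)]
      refs <- intersect(tips, names(reference_labels))
      if (length(refs)) {
        sub <- unique(reference_labels[refs])
        verdict <- if (length(sub) == 1L) sub else "ambiguous"
        break
      }
    }
    out[[q]] <- verdict
  }
  out
}
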