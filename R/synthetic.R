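# Synthetic-data generators with planted truth.  Every generator is a pure
# function of its arguments including the seed: the global RNG state is
# saved and restored around each call.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

AA20 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
          "T","V","W","Y")

# typical residue spans per domain type, used to lay hits along the protein
DOMAIN_SPANS <- c(EGF = 35, DSL = 45, MNLL = 30, LNR = 35, ANK = 33,
                  VWC = 60, TM = 21, Presenilin = 250, `LAG1-DNAbind` = 90,
                  bHLH = 55, Orange = 35)

#' Generate a gene with a planted domain architecture
#'
#' Emits a gene whose domain-hit table satisfies the named family signature:
#' required domains at (at least) their minimum counts, non-overlapping and
#' ordered along the protein, with E-values well below the default filter.
#' Domain instances are coordinate annotations, not sequence motifs (the
#' classifier works from hit tables, so no motif scanner is needed).  For
#' bHLH families (Hes/Hey/Helt/Cwo) the planted architecture is the shared
#' superfamily architecture; architecture-level recovery for those is at the
#' superfamily label `"HesHey"`.
#'
#' @param family_label one of the families in `signature_set`.
#' @param signature_set signatures from [notch_signatures()].
#' @param seed integer seed (same seed, same output).
#' @param species_id species to stamp on the gene.
#' @param gene_id gene identifier (default derived from family and seed).
#' @return list with `gene` (a [gene_model()]) and `truth` (planted family,
#'   expected assignment label, per-domain counts).
#' @export
generate_gene_with_architecture <- function(family_label, signature_set,
                                            seed,
                                            species_id = "synthetic_sp",
                                            gene_id = NULL) {
  sig <- signature_set[[family_label]]
  if (is.null(sig))
    stop(sprintf("unknown family label '%s'", family_label), call. = FALSE)
  if (is.null(gene_id))
    gene_id <- sprintf("%s_g%d", tolower(gsub("[^A-Za-z0-9]", "", family_label)),
                       seed)
  with_seed(seed, {
    counts <- integer(0)
    for (r in sig$requirements) {
      extra <- if (is.finite(r$max)) sample.int(r$max - r$min + 1L, 1L) - 1L
      else sample.int(3L, 1L) - 1L
      counts[[r$domain]] <- r$min + extra
    }
    # one hit instance per copy, laid out left to right in signature order
    pos <- sample(5:20, 1L)
    rows <- list()
    for (d in names(counts)) {
      for (k in seq_len(counts[[d]])) {
        span <- DOMAIN_SPANS[[d]]
        start <- pos
        end <- pos + span - 1L
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gene_id, domain_name = d, pfam_accession = "",
          env_start = start, env_end = end,
          e_value = 10^-runif(1, 8, 30), stringsAsFactors = FALSE)
        pos <- end + sample(3:15, 1L)
      }
    }
    hits <- do.call(rbind, rows)
    prot_len <- max(hits$env_end) + sample(10:30, 1L)
    protein <- paste(sample(AA20, prot_len, replace = TRUE), collapse = "")
    gene <- gene_model(gene_id, species_id, protein = protein, hits = hits)
    expected <- if (!is.na(sig$superfamily)) sig$superfamily else sig$family
    list(gene = gene,
         truth = list(kind = "architecture", family = family_label,
                      expected_assignment = expected,
                      counts = counts))
  })
}

#' Generate a clean random CDS
#'
#' ATG start, a run of sense codons drawn uniformly (so no incidental
#' in-frame stop can occur), and a terminal stop codon.
#'
#' @param n_codons total codon count including start and stop (>= 3).
#' @param seed integer seed.
#' @return character CDS of length `3 * n_codons`.
#' @export
generate_random_cds <- function(n_codons, seed) {
  stopifnot(n_codons >= 3L)
  all_codons <- apply(expand.grid(c("T","C","A","G"), c("T","C","A","G"),
                                  c("T","C","A","G")), 1, paste, collapse = "")
  sense <- setdiff(all_codons, STOP_CODONS)
  with_seed(seed, {
    body <- sample(sense, n_codons - 2L, replace = TRUE)
    paste(c("ATG", body, sample(STOP_CODONS, 1L)), collapse = "")
  })
}

#' Plant a premature-termination mutation into a reference CDS
#'
#' Applies a single-base edit of the requested mechanism at (or within) the
#' target codon and returns the mutated CDS plus the exact planted edit.
#' Indel coordinates are recorded left-normalized (the canonical
#' representative within a homopolymer run), matching what
#' [classify_mechanism()] reports.  If no single edit at the target codon
#' can realise the requested mechanism, an error advises a different target.
#'
#' @param ref_cds clean reference CDS (see [paralog_pair()] requirements).
#' @param mechanism one of `insertion_stop`, `substitution_nonsense`,
#'   `deletion_frameshift`, `insertion_frameshift`.
#' @param target_codon codon index strictly inside the open reading frame
#'   (2 .. length-1).
#' @param seed integer seed (choice among equally valid edits).
#' @return list with `cds` (mutated) and `truth` (mechanism, edit type,
#'   coordinate, base(s), resulting stop codon index).
#' @export
plant_truncation <- function(ref_cds,
                             mechanism = c("insertion_stop",
                                           "substitution_nonsense",
                                           "deletion_frameshift",
                                           "insertion_frameshift"),
                             target_codon, seed) {
  mechanism <- match.arg(mechanism)
  ref_cds <- toupper(ref_cds)
  L <- nchar(ref_cds) / 3L
  tr <- translate_cds(ref_cds)
  if (nchar(ref_cds) %% 3L != 0L || substr(ref_cds, 1, 3) != "ATG" ||
      is.na(tr$stop_codon) || tr$stop_codon != L)
    stop("ref_cds must be a clean ORF: ATG start, single terminal stop",
         call. = FALSE)
  k <- as.integer(target_codon)
  if (k < 2L || k > L - 1L)
    stop("target_codon must lie strictly inside the open reading frame",
         call. = FALSE)
  ref_chars <- strsplit(ref_cds, "")[[1]]
  bases <- c("A", "C", "G", "T")
  codon_lo <- 3L * k - 2L

  mutate_sub <- function(pos, b) {
    x <- ref_chars; x[pos] <- b; paste(x, collapse = "")
  }
  mutate_ins <- function(pos, b) {  # insert b so that alt[pos] == b
    paste(c(ref_chars[seq_len(pos - 1L)], b,
            ref_chars[seq(pos, length(ref_chars))]), collapse = "")
  }
  mutate_del <- function(pos) paste(ref_chars[-pos], collapse = "")

  options <- list()
  if (mechanism == "substitution_nonsense") {
    for (off in 0:2) for (b in bases) {
      pos <- codon_lo + off
      if (ref_chars[pos] == b) next
      alt <- mutate_sub(pos, b)
      if (!substr(alt, codon_lo, codon_lo + 2L) %in% STOP_CODONS) next
      options[[length(options) + 1L]] <-
        list(cds = alt, type = "substitution", coordinate = pos, base = b,
             stop_codon = k)
    }
  } else if (mechanism %in% c("insertion_stop", "insertion_frameshift")) {
    for (off in 0:2) for (b in bases) {
      pos <- codon_lo + off
      alt <- mutate_ins(pos, b)
      alt_chars <- strsplit(alt, "")[[1]]
      norm <- normalize_indel_pos(alt_chars, pos)
      ta <- translate_cds(alt)
      if (is.na(ta$stop_codon) || ta$stop_codon < k || ta$stop_codon >= L)
        next
      s <- ta$stop_codon
      in_stop <- norm >= 3L * s - 2L && norm <= 3L * s
      want_in_stop <- mechanism == "insertion_stop"
      if (in_stop != want_in_stop) next
      if (want_in_stop && s != k) next
      options[[length(options) + 1L]] <-
        list(cds = alt, type = "insertion", coordinate = norm, base = b,
             stop_codon = s)
    }
  } else { # deletion_frameshift
    for (off in 0:2) {
      pos <- codon_lo + off
      alt <- mutate_del(pos)
      norm <- normalize_indel_pos(ref_chars, pos)
      ta <- translate_cds(alt)
      if (is.na(ta$stop_codon) || ta$stop_codon < k || ta$stop_codon >= L)
        next
      options[[length(options) + 1L]] <-
        list(cds = alt, type = "deletion", coordinate = norm,
             base = ref_chars[pos], stop_codon = ta$stop_codon)
    }
  }
  if (!length(options))
    stop(sprintf("no single %s edit at codon %d realises the requested mechanism; try a different target codon",
                 mechanism, k), call. = FALSE)
  choice <- with_seed(seed, options[[sample.int(length(options), 1L)]])
  list(cds = choice$cds,
       truth = list(kind = "truncation", mechanism = mechanism,
                    target_codon = k, edit_type = choice$type,
                    coordinate = choice$coordinate, base = choice$base,
                    stop_codon = choice$stop_codon))
}

resolve_edge_node <- function(tree, e) {
  if (is.numeric(e)) return(as.integer(e))
  n_tip <- length(tree$tip.label)
  for (nd in seq_len(n_tip + tree$Nnode)) {
    if (identical(edge_id(tree, nd), e)) return(nd)
  }
  stop(sprintf("edge '%s' not found in tree", e), call. = FALSE)
}

#' Simulate presence/absence from a planted gain/loss history
#'
#' A leaf is present iff the path from the root passes the gain edge and no
#' loss edge.
#'
#' @param tree rooted [ape::phylo].
#' @param gain_edge edge identifier (leaf-set string from [edge_id()]) or
#'   child-node number of the gain edge.
#' @param loss_edges identifiers of loss edges; each must lie strictly below
#'   the gain edge, pairwise non-nested.
#' @param family family name.
#' @return list with `presence` (named 0/1 vector over leaves) and `truth`
#'   (gain and loss edge ids).
#' @export
simulate_gainloss <- function(tree, gain_edge, loss_edges = character(0),
                              family = "family") {
  gain_node <- resolve_edge_node(tree, gain_edge)
  loss_nodes <- vapply(loss_edges, function(e) resolve_edge_node(tree, e),
                       integer(1))
  n_tip <- length(tree$tip.label)
  gain_tips <- tips_under(tree, gain_node)
  loss_tip_sets <- lapply(loss_nodes, function(nd) tips_under(tree, nd))
  for (i in seq_along(loss_nodes)) {
    if (loss_nodes[i] == gain_node ||
        !all(loss_tip_sets[[i]] %in% gain_tips))
      stop("loss edge must lie strictly below the gain edge", call. = FALSE)
  }
  if (length(loss_nodes) > 1L) {
    for (i in seq_len(length(loss_nodes) - 1L))
      for (j in (i + 1L):length(loss_nodes))
        if (any(loss_tip_sets[[i]] %in% loss_tip_sets[[j]]) ||
            any(loss_tip_sets[[j]] %in% loss_tip_sets[[i]]))
          stop("loss edges must be pairwise non-nested", call. = FALSE)
  }
  pres <- setNames(integer(n_tip), tree$tip.label)
  pres[gain_tips] <- 1L
  for (s in loss_tip_sets) pres[s] <- 0L
  list(presence = pres,
       truth = list(kind = "gainloss", family = family,
                    gain_edge = edge_id(tree, gain_node),
                    loss_edges = unname(vapply(loss_nodes, function(nd)
                      edge_id(tree, nd), character(1)))))
}

#' Generate a pair of developmental stage profiles with a planted relation
#'
#' `similar`: the second profile is a positive affine transform of the
#' first, plus Gaussian noise; `complementary`: a negative affine transform
#' (shifted to stay nonnegative) plus noise; `unrelated`: an independent
#' draw.  Base levels are uniform on \[1, 10\] (an RPKM-like scale).
#'
#' @param n_stages number of stages (>= 4; rank correlation is degenerate
#'   below that).
#' @param relation `similar`, `complementary`, or `unrelated`.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return list with `a`, `b` (numeric profiles) and `truth`.
#' @export
generate_expression_pair <- function(n_stages,
                                     relation = c("similar", "complementary",
                                                  "unrelated"),
                                     noise_sd = 0, seed = 1L) {
  relation <- match.arg(relation)
  if (n_stages < 4L)
    stop("n_stages must be >= 4 (rank correlation degenerate below)",
         call. = FALSE)
  stopifnot(noise_sd >= 0)
  with_seed(seed, {
    a <- runif(n_stages, 1, 10)
    b <- switch(relation,
                similar = a * runif(1, 0.5, 2) + runif(1, 0, 2),
                complementary = {
                  sc <- runif(1, 0.5, 2)
                  -a * sc + sc * max(a) + runif(1, 0, 2)
                },
                unrelated = runif(n_stages, 1, 10))
    b <- pmax(b + rnorm(n_stages, 0, noise_sd), 0)
    list(a = a, b = b,
         truth = list(kind = "expression", relation = relation,
                      noise_sd = noise_sd))
  })
}

#' Generate a random rooted binary tree with branch lengths
#'
#' Topology from [ape::rtree()]; branch lengths uniform on \[0.1, 2\].
#'
#' @param n_leaves number of leaves (>= 3).
#' @param seed integer seed.
#' @return rooted binary [ape::phylo] with positive branch lengths.
#' @export
generate_random_tree <- function(n_leaves, seed) {
  if (n_leaves < 3L) stop("n_leaves must be >= 3", call. = FALSE)
  with_seed(seed, {
    tr <- ape::rtree(n_leaves)
    tr$edge.length <- runif(nrow(tr$edge), 0.1, 2)
    tr
  })
}

#' Generate an alignment with planted group structure
#'
#' Builds a protein alignment in which `n_signal` columns each assign a
#' distinct residue per group (so every signal column supports every
#' group-vs-rest bipartition) and `n_shared` columns are constant across all
#' taxa.  Used to plant clades for NJ/bootstrap/subtype tests.
#'
#' @param groups named list: group name -> character vector of taxon labels.
#' @param n_signal number of group-discriminating columns.
#' @param n_shared number of constant columns.
#' @param seed integer seed.
#' @return a `multiple_alignment`.
#' @export
generate_group_alignment <- function(groups, n_signal = 20L, n_shared = 30L,
                                     seed = 1L) {
  taxa <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(taxa)) stop("taxa must be unique across groups", call. = FALSE)
  k <- length(groups)
  if (k > length(AA20)) stop("too many groups", call. = FALSE)
  with_seed(seed, {
    cols <- matrix("", nrow = length(taxa), ncol = n_signal + n_shared,
                   dimnames = list(taxa, NULL))
    grp_of <- rep(names(groups), lengths(groups))
    for (c in seq_len(n_signal)) {
      res <- sample(AA20, k)
      cols[, c] <- res[match(grp_of, names(groups))]
    }
    for (c in seq_len(n_shared)) cols[, n_signal + c] <- sample(AA20, 1L)
    class(cols) <- c("multiple_alignment", class(cols))
    cols
  })
}

#' The packaged mollusc case-study fixture
#'
#' A synthetic, conventionalised mollusc species tree and Delta2
#' presence/absence pattern: Delta2 present in the bivalve, cephalopod and
#' two gastropod taxa, absent in the chiton-like outgroup, and lost in three
#' gastropod taxa.  The gastropod arrangement deliberately places each lost
#' taxon sister to a lineage retaining the gene, so the planted
#' three-independent-loss history is the unique Dollo optimum.  The fixture
#' also carries an all-species Delta1 row and a Helt row absent from four
#' gastropods.
#'
#' @param seed integer seed (branch lengths only; topology and pattern are
#'   fixed).
#' @return list with `tree` (rooted [ape::phylo]), `presence` (family x
#'   species 0/1 matrix), `clades` (named list of taxon groups), and `truth`
#'   (planted Delta2 gain edge and loss edges).
#' @export
mollusc_fixture <- function(seed = 1L) {
  nwk <- paste0("(Chiton_out,((BivA,(BivB,BivC)),((CephA,CephB),",
                "(GasC,(GasA,(GasD,(GasB,GasE)))))));")
  tree <- read_newick(text = nwk)
  tree <- with_seed(seed, {
    tree$edge.length <- runif(nrow(tree$edge), 0.1, 2)
    tree
  })
  species <- tree$tip.label
  clades <- list(
    outgroup = "Chiton_out",
    bivalvia = c("BivA", "BivB", "BivC"),
    cephalopoda = c("CephA", "CephB"),
    gastropoda = c("GasA", "GasB", "GasC", "GasD", "GasE")
  )
  delta2_present <- c(clades$bivalvia, clades$cephalopoda, "GasA", "GasB")
  helt_absent <- c("GasB", "GasC", "GasD", "GasE")
  fams <- c("Notch", "Delta1", "Delta2", "Jagged", "Presenilin", "SuH",
            "Hes", "Helt")
  pres <- matrix(1L, nrow = length(fams), ncol = length(species),
                 dimnames = list(fams, species))
  pres["Delta2", ] <- as.integer(species %in% delta2_present)
  pres["Helt", !species %in% helt_absent] <- 1L
  pres["Helt", species %in% helt_absent] <- 0L
  gain_node <- ape::getMRCA(tree, c(clades$bivalvia, clades$cephalopoda,
                                    clades$gastropoda))
  truth <- list(
    delta2_gain_edge = edge_id(tree, gain_node),
    delta2_loss_edges = sort(c("GasC", "GasD", "GasE")),
    # Helt absent in GasB..GasE: GasC falls singly; GasD, GasB and GasE form
    # a wholly-absent subtree of the gastropod caterpillar, one clade loss
    helt_loss_edges = sort(c("GasC", "GasB|GasD|GasE"))
  )
  list(tree = tree, presence = pres, clades = clades, truth = truth)
}
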