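# Independent oracles used to cross-check the implementation.  Each is
# deliberately written by a different route than the code it checks.

# translation oracle: Biostrings' translator, truncated at the first stop
oracle_translate <- function(cds) {
  cds <- substr(cds, 1L, 3L * (nchar(cds) %/% 3L))
  aa <- if (grepl("N", cds, fixed = TRUE))
    as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                       if.fuzzy.codon = "X"))
  else as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at == -1L) list(protein = aa, stop_codon = NA_integer_)
  else list(protein = substr(aa, 1L, stop_at - 1L),
            stop_codon = as.integer(stop_at))
}

# batch form over many N-free CDSs (one DNAStringSet call)
oracle_translate_batch <- function(cdss) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(
    substr(cdss, 1L, 3L * (nchar(cdss) %/% 3L)))))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  list(protein = ifelse(stop_at == -1L, aa, substr(aa, 1L, stop_at - 1L)),
       stop_codon = ifelse(stop_at == -1L, NA_integer_, as.integer(stop_at)))
}

# full-matrix affine-gap global alignment score (match +2, mismatch -1,
# gap of length L costs 5 + L)
oracle_align_score <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)  # ends in aligned pair
  X <- matrix(NEG, n + 1L, m + 1L)  # ends in gap in b (a consumed)
  Y <- matrix(NEG, n + 1L, m + 1L)  # ends in gap in a (b consumed)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1L, 1L] <- -5 - i
  for (j in seq_len(m)) Y[1L, j + 1L] <- -5 - j
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j]) 2 else -1
      M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - 6, X[i, j + 1L] - 1,
                               Y[i, j + 1L] - 6)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - 6, Y[i + 1L, j] - 1,
                               X[i + 1L, j] - 6)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

# Dollo oracle: enumerate every assignment of presence states to internal
# nodes; a valid single-gain history has exactly one 0->1 transition
# (counting the virtual root edge); return the minimum loss count.
oracle_dollo_min_losses <- function(tree, presence) {
  n_tip <- length(tree$tip.label)
  I <- tree$Nnode
  root <- n_tip + 1L
  states <- as.matrix(expand.grid(rep(list(0:1), I)))
  leaf <- matrix(rep(presence[tree$tip.label], each = nrow(states)),
                 nrow = nrow(states))
  Fm <- cbind(leaf, states)
  gains <- as.numeric(Fm[, root] == 1)   # gain on the virtual root edge
  losses <- numeric(nrow(states))
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    gains <- gains + (Fm[, p] == 0 & Fm[, ch] == 1)
    losses <- losses + (Fm[, p] == 1 & Fm[, ch] == 0)
  }
  ok <- gains == 1
  if (!any(ok)) return(NA_integer_)
  min(losses[ok])
}

# independent greedy overlap resolution, written recursively
oracle_resolve <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$e_value, hits$env_start, hits$domain_name)
  pick <- function(remaining, chosen) {
    if (!length(remaining)) return(chosen)
    i <- remaining[[1]]
    ok <- TRUE
    for (j in chosen) {
      ov <- min(hits$env_end[i], hits$env_end[j]) -
        max(hits$env_start[i], hits$env_start[j]) + 1L
      shorter <- min(hits$env_end[i] - hits$env_start[i] + 1L,
                     hits$env_end[j] - hits$env_start[j] + 1L)
      if (ov > 0.5 * shorter) { ok <- FALSE; break }
    }
    pick(remaining[-1], if (ok) c(chosen, i) else chosen)
  }
  hits[sort(pick(ord, integer(0))), , drop = FALSE]
}

# plant a truncation, retrying over reference seeds until the requested
# mechanism is realisable (frameshift plants need a stop in the shifted
# reading of the tail, which a given random reference may lack)
plant_with_retry <- function(mechanism, seed, n_codons = 80L,
                             target = n_codons %/% 2L) {
  for (attempt in 0:49) {
    ref <- generate_random_cds(n_codons, seed + 7919L * attempt)
    p <- tryCatch(plant_truncation(ref, mechanism, target, seed = seed),
                  error = function(e) NULL)
    if (!is.null(p)) return(list(ref = ref, plant = p))
  }
  stop("could not plant ", mechanism)
}

random_hit_table <- function(n, seed) {
  set.seed(seed)
  start <- sample.int(500L, n, replace = TRUE)
  data.frame(gene_id = paste0("g", sample.int(50L, n, replace = TRUE)),
             domain_name = sample(c("EGF", "DSL", "ANK", "bHLH"), n, TRUE),
             pfam_accession = "",
             env_start = start,
             env_end = start + sample.int(100L, n, replace = TRUE),
             e_value = 10^runif(n, -20, 0),
             stringsAsFactors = FALSE)
}
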