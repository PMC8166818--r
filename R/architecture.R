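#' Domain-architecture signatures of the nine core Notch-pathway families
#'
#' Encodes the family definitions used throughout the pipeline:
#' * **Notch**: several EGF repeats, exactly three LNR repeats, a TM segment,
#'   several ANK repeats ("several" = `several_min_count`, default 2).
#' * **Delta**: an MNLL domain, a DSL domain, and EGF repeats.
#' * **Jagged**: the Delta architecture plus a VWC domain.
#' * **Presenilin**: a Presenilin domain.
#' * **SuH**: a LAG1-DNAbind (BTD) domain.
#' * **Hes, Hey, Helt, Cwo**: a bHLH domain plus a hairy/Orange domain.
#'   These four share one architecture and belong to the `HesHey`
#'   superfamily; architecture alone cannot separate them, so
#'   [classify_gene()] assigns the superfamily label and subtype assignment
#'   is delegated to bHLH-domain phylogeny ([assign_subtype_by_clade()]).
#'
#' DSL-bearing genes that fail the full Delta signature are routed to the
#' derived label `"Dll"` (Delta-like: lost EGF repeats or other motifs) by
#' [classify_gene()]; `Dll` is a fallback verdict, not a signature.
#'
#' @param config a [run_config()] (controls the "several" floor).
#' @return list of `arch_signature` objects, one per family.
#' @export
notch_signatures <- function(config = run_config()) {
  several <- config$several_min_count
  req <- function(domain, min, max = Inf)
    list(domain = domain, min = as.integer(min),
         max = if (is.finite(max)) as.integer(max) else Inf)
  sig <- function(family, requirements, superfamily = NA_character_,
                  forbidden = character(0), order_enforced = FALSE) {
    structure(list(family = family, requirements = requirements,
                   forbidden = forbidden, order_enforced = order_enforced,
                   superfamily = superfamily),
              class = "arch_signature")
  }
  bhlh <- list(req("bHLH", 1), req("Orange", 1))
  sigs <- list(
    sig("Notch", list(req("EGF", several), req("LNR", 3, 3), req("TM", 1),
                      req("ANK", several))),
    sig("Delta", list(req("MNLL", 1), req("DSL", 1), req("EGF", 1))),
    sig("Jagged", list(req("MNLL", 1), req("DSL", 1), req("EGF", 1),
                       req("VWC", 1))),
    sig("Presenilin", list(req("Presenilin", 1))),
    sig("SuH", list(req("LAG1-DNAbind", 1))),
    sig("Hes", bhlh, superfamily = "HesHey"),
    sig("Hey", bhlh, superfamily = "HesHey"),
    sig("Helt", bhlh, superfamily = "HesHey"),
    sig("Cwo", bhlh, superfamily = "HesHey")
  )
  names(sigs) <- vapply(sigs, `[[`, character(1), "family")
  sigs
}

#' Filter domain hits by E-value
#'
#' Keeps exactly the hits with `e_value <= e_threshold`, preserving input
#' order.
#'
#' @param hits domain-hit data.frame.
#' @param e_threshold positive E-value cut-off (default 1e-5).
#' @return filtered data.frame.
#' @export
filter_hits <- function(hits, e_threshold = 1e-5) {
  stopifnot(e_threshold > 0)
  hits[hits$e_value <= e_threshold, , drop = FALSE]
}

#' Resolve overlapping domain hits within one gene
#'
#' Greedy selection: hits are ranked by E-value (ascending), ties broken by
#' leftmost start then lexicographic domain name; a hit is retained unless it
#' overlaps an already-retained hit by more than 50% of the shorter hit's
#' length.  Output preserves the original row order of the retained hits.
#'
#' @param hits domain-hit data.frame for a single gene.
#' @return data.frame of retained hits.
#' @export
resolve_overlaps <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  if (length(unique(hits$gene_id)) > 1L)
    stop("resolve_overlaps expects hits of a single gene", call. = FALSE)
  ord <- order(hits$e_value, hits$env_start, hits$domain_name)
  kept <- integer(0)
  for (i in ord) {
    conflict <- FALSE
    for (j in kept) {
      ov <- min(hits$env_end[i], hits$env_end[j]) -
        max(hits$env_start[i], hits$env_start[j]) + 1L
      shorter <- min(hits$env_end[i] - hits$env_start[i] + 1L,
                     hits$env_end[j] - hits$env_start[j] + 1L)
      if (ov > 0.5 * shorter) { conflict <- TRUE; break }
    }
    if (!conflict) kept <- c(kept, i)
  }
  hits[sort(kept), , drop = FALSE]
}

#' Construct a gene model
#'
#' @param gene_id gene identifier.
#' @param species_id species identifier.
#' @param protein one-row data.frame or character protein sequence.
#' @param cds optional character CDS sequence.
#' @param hits domain-hit data.frame for this gene.
#' @return a `gene_model` object.
#' @export
gene_model <- function(gene_id, species_id, protein = NULL, cds = NULL,
                       hits = empty_domain_hits()) {
  if (is.data.frame(protein)) protein <- protein$sequence[[1]]
  if (is.data.frame(cds)) cds <- cds$sequence[[1]]
  if (nrow(hits) && !all(hits$gene_id == gene_id))
    stop("all hits must reference gene_id ", gene_id, call. = FALSE)
  if (!is.null(protein) && nrow(hits) &&
      any(hits$env_end > nchar(protein)))
    stop("hit coordinates exceed protein length for gene ", gene_id,
         call. = FALSE)
  structure(list(gene_id = gene_id, species_id = species_id,
                 protein = protein, cds = cds, hits = hits),
            class = "gene_model")
}

signature_satisfied <- function(counts, signature) {
  unmet <- character(0)
  for (r in signature$requirements) {
    n <- counts[[r$domain]]
    if (is.null(n)) n <- 0L
    if (n < r$min)
      unmet <- c(unmet, sprintf("%s: need >= %d, have %d", r$domain, r$min, n))
    else if (is.finite(r$max) && n > r$max)
      unmet <- c(unmet, sprintf("%s: need <= %d, have %d", r$domain, r$max, n))
  }
  for (f in signature$forbidden) {
    n <- counts[[f]]
    if (!is.null(n) && n > 0L)
      unmet <- c(unmet, sprintf("%s: forbidden, have %d", f, n))
  }
  unmet
}

#' Classify a gene into a Notch-pathway family by domain architecture
#'
#' Checks the gene's (pre-filtered) domain-hit counts against every
#' signature; the most specific satisfied signature wins, specificity being
#' the number of required domain types (so Jagged outranks Delta).  Satisfied
#' signatures of equal specificity from the same superfamily collapse to the
#' superfamily label; equal-specificity conflicts across superfamilies are an
#' error, surfaced rather than silently resolved.  If no signature is
#' satisfied, a gene with a DSL hit is assigned `"Dll"` and a gene with a
#' bHLH hit is routed to `"HesHey"`; otherwise `"unassigned"`.
#'
#' @param gene a [gene_model()].
#' @param signatures list of signatures from [notch_signatures()].
#' @param config a [run_config()].
#' @return a `family_assignment`: list with `gene_id`, `family`,
#'   `matched_counts` (named integer vector of observed per-domain counts)
#'   and `failure_reasons` (data.frame of near-misses).
#' @export
classify_gene <- function(gene, signatures = notch_signatures(config),
                          config = run_config()) {
  counts <- as.list(table(gene$hits$domain_name))
  counts <- lapply(counts, as.integer)
  satisfied <- list()
  failures <- list()
  for (s in signatures) {
    unmet <- signature_satisfied(counts, s)
    if (!length(unmet)) satisfied[[length(satisfied) + 1L]] <- s
    else failures[[length(failures) + 1L]] <-
        data.frame(family = s$family, unmet = paste(unmet, collapse = "; "),
                   stringsAsFactors = FALSE)
  }
  failure_df <- if (length(failures)) do.call(rbind, failures) else
    data.frame(family = character(0), unmet = character(0))
  family <- "unassigned"
  if (length(satisfied)) {
    spec <- vapply(satisfied, function(s) length(s$requirements), integer(1))
    best <- satisfied[spec == max(spec)]
    labels <- vapply(best, function(s) {
      if (!is.na(s$superfamily)) s$superfamily else s$family
    }, character(1))
    labels <- unique(labels)
    if (length(labels) > 1L)
      stop(sprintf("gene %s satisfies conflicting equal-specificity signatures: %s",
                   gene$gene_id, paste(labels, collapse = " vs ")),
           call. = FALSE)
    family <- labels
  } else if (!is.null(counts$DSL) && counts$DSL > 0L) {
    family <- "Dll"
  } else if (!is.null(counts$bHLH) && counts$bHLH > 0L) {
    family <- "HesHey"
  }
  structure(list(gene_id = gene$gene_id, species_id = gene$species_id,
                 family = family,
                 matched_counts = unlist(counts) %||% integer(0),
                 failure_reasons = failure_df),
            class = "family_assignment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Enumerate DSL-domain instances within a gene
#'
#' Genes with more than one DSL domain get instance identifiers
#' `gene_id-k`, `k` being the 1-based rank of the hit by start coordinate;
#' a single-DSL gene yields the bare gene id.
#'
#' @param gene a [gene_model()].
#' @return character vector of instance identifiers (may be empty).
#' @export
enumerate_dsl_instances <- function(gene) {
  dsl <- gene$hits[gene$hits$domain_name == "DSL", , drop = FALSE]
  if (!nrow(dsl)) return(character(0))
  if (nrow(dsl) == 1L) return(gene$gene_id)
  ord <- order(dsl$env_start)
  paste0(gene$gene_id, "-", seq_along(ord))
}

#' Assign a DSL-family gene to one of the four DSL architecture groups
#'
#' * `dsl_only`: exactly one DSL domain, no EGF;
#' * `dsl_tandem`: two or more DSL domains (tandem repeats), no EGF;
#' * `dsl_egf`: DSL plus EGF and nothing else beyond MNLL/TM;
#' * `dsl_egf_other`: DSL plus EGF plus additional domain types (e.g. VWC).
#'
#' @param gene a [gene_model()] with at least one DSL hit.
#' @return one of the four group labels.
#' @export
dsl_group <- function(gene) {
  doms <- gene$hits$domain_name
  n_dsl <- sum(doms == "DSL")
  if (!n_dsl) stop("dsl_group requires a gene with >= 1 DSL hit", call. = FALSE)
  has_egf <- any(doms == "EGF")
  if (!has_egf) return(if (n_dsl >= 2L) "dsl_tandem" else "dsl_only")
  other <- setdiff(unique(doms), c("DSL", "EGF", "MNLL", "TM"))
  if (length(other)) "dsl_egf_other" else "dsl_egf"
}

#' Count domain instances per species
#'
#' @param genes list of [gene_model()]s carrying `species_id`.
#' @param domains_of_interest optional character vector restricting the
#'   domains counted (default: all domains seen).
#' @return data.frame with columns `species_id`, `domain_name`, `count`;
#'   attribute `grand_total` holds the per-domain totals across species.
#' @export
count_domains <- function(genes, domains_of_interest = NULL) {
  if (!length(genes))
    return(data.frame(species_id = character(0), domain_name = character(0),
                      count = integer(0)))
  all_hits <- do.call(rbind, lapply(genes, function(g) {
    if (!nrow(g$hits)) return(NULL)
    data.frame(species_id = g$species_id, domain_name = g$hits$domain_name,
               stringsAsFactors = FALSE)
  }))
  if (is.null(all_hits))
    return(data.frame(species_id = character(0), domain_name = character(0),
                      count = integer(0)))
  if (!is.null(domains_of_interest))
    all_hits <- all_hits[all_hits$domain_name %in% domains_of_interest, ,
                         drop = FALSE]
  tab <- as.data.frame(table(species_id = all_hits$species_id,
                             domain_name = all_hits$domain_name),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "count"
  tab <- tab[tab$count > 0L, , drop = FALSE]
  tab <- tab[order(tab$species_id, tab$domain_name), , drop = FALSE]
  rownames(tab) <- NULL
  tab$count <- as.integer(tab$count)
  grand <- tapply(tab$count, tab$domain_name, sum)
  attr(tab, "grand_total") <- grand
  tab
}

#' Build a family x species presence/absence matrix from assignments
#'
#' @param assignments list of `family_assignment`s (from [classify_gene()]).
#' @param species declared species order (columns).
#' @param families declared family order (rows).
#' @return integer 0/1 matrix with attribute `counts`, the per-cell gene
#'   counts (duplications show as counts > 1).
#' @export
build_presence_absence <- function(assignments, species, families) {
  counts <- matrix(0L, nrow = length(families), ncol = length(species),
                   dimnames = list(families, species))
  for (a in assignments) {
    if (a$family %in% c("unassigned")) next
    if (!a$species_id %in% species)
      stop(sprintf("species '%s' not in declared species list", a$species_id),
           call. = FALSE)
    if (!a$family %in% families)
      stop(sprintf("family '%s' not in declared family list", a$family),
           call. = FALSE)
    counts[a$family, a$species_id] <- counts[a$family, a$species_id] + 1L
  }
  pres <- (counts > 0L) * 1L
  storage.mode(pres) <- "integer"
  attr(pres, "counts") <- counts
  pres
}
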