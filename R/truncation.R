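STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Translate a CDS in frame 0 under the standard genetic code
#'
#' Translation stops at the first stop codon.  Codons containing N translate
#' to `X` and never terminate.  Trailing bases short of a full codon are
#' ignored.
#'
#' @param cds nucleotide string (A/C/G/T/N, case-insensitive).
#' @return list with `protein` (residues up to but excluding the stop) and
#'   `stop_codon` (1-based codon index of the first stop, or `NA` if the
#'   sequence ends without one).
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) < 3L) stop("CDS shorter than one codon", call. = FALSE)
  n_codon <- nchar(cds) %/% 3L
  starts <- 3L * seq_len(n_codon) - 2L
  codons <- substring(cds, starts, starts + 2L)
  code <- Biostrings::GENETIC_CODE
  aa <- character(n_codon)
  for (i in seq_len(n_codon)) {
    cd <- codons[[i]]
    if (grepl("N", cd, fixed = TRUE)) {
      aa[[i]] <- "X"
    } else {
      r <- code[[cd]]
      if (r == "*") {
        return(list(protein = paste(aa[seq_len(i - 1L)], collapse = ""),
                    stop_codon = i))
      }
      aa[[i]] <- r
    }
  }
  list(protein = paste(aa, collapse = ""), stop_codon = NA_integer_)
}

#' Construct a reference/derived paralog pair
#'
#' The reference CDS must be a clean open reading frame: length divisible by
#' three, starting ATG, ending in a stop codon with no internal stop.  The
#' derived CDS must start ATG and reach a stop in frame 0 (its length need
#' not be a codon multiple: frameshifted paralogs are the point).
#'
#' @param ref reference CDS (character), e.g. a Delta1 coding sequence.
#' @param alt derived CDS (character), e.g. a Delta2 coding sequence.
#' @param ref_id,alt_id identifiers.
#' @param anchor_residue amino-acid letter anchoring the termination window
#'   (default "R", the conserved arginine upstream of Delta2 stops).
#' @return a `paralog_pair` object.
#' @export
paralog_pair <- function(ref, alt, ref_id = "ref", alt_id = "alt",
                         anchor_residue = "R") {
  ref <- toupper(ref); alt <- toupper(alt)
  if (nchar(ref) %% 3L != 0L)
    stop("reference CDS length must be a multiple of 3", call. = FALSE)
  if (substr(ref, 1L, 3L) != "ATG" || substr(alt, 1L, 3L) != "ATG")
    stop("both CDSs must begin with ATG", call. = FALSE)
  tr <- translate_cds(ref)
  if (is.na(tr$stop_codon) || tr$stop_codon != nchar(ref) / 3L)
    stop("reference CDS must end with its only stop codon", call. = FALSE)
  ta <- translate_cds(alt)
  if (is.na(ta$stop_codon))
    stop("derived CDS reaches no stop codon in frame 0", call. = FALSE)
  structure(list(ref = ref, alt = alt, ref_id = ref_id, alt_id = alt_id,
                 anchor_residue = anchor_residue),
            class = "paralog_pair")
}

#' Globally align the two CDSs of a paralog pair
#'
#' Needleman-Wunsch global alignment via [Biostrings::pairwiseAlignment()]
#' with the fixed scheme match +2, mismatch -1, and affine gaps costing
#' 5 + L for a gap of length L (gap opening 5, gap extension 1 per
#' position).  The traceback is deterministic.
#'
#' @param pair a [paralog_pair()].
#' @return a `codon_alignment`: list with gapped `ref` and `alt` strings, the
#'   alignment `score`, and a per-column data.frame `columns` with
#'   `ref_char`, `alt_char`, `ref_pos`, `alt_pos` (0 before the first base)
#'   and `class` in match/substitution/insertion_in_alt/deletion_in_alt.
#' @export
align_paralogs <- function(pair) {
  if (!nchar(pair$ref) || !nchar(pair$alt))
    stop("cannot align empty sequences", call. = FALSE)
  m <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                                baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(pair$ref, pair$alt,
                                       substitutionMatrix = m,
                                       gapOpening = 5, gapExtension = 1,
                                       type = "global")
  r <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  a <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ref_pos <- cumsum(r != "-")
  alt_pos <- cumsum(a != "-")
  cls <- ifelse(r == "-", "insertion_in_alt",
                ifelse(a == "-", "deletion_in_alt",
                       ifelse(r == a, "match", "substitution")))
  structure(list(ref = paste(r, collapse = ""),
                 alt = paste(a, collapse = ""),
                 score = Biostrings::score(aln),
                 columns = data.frame(ref_char = r, alt_char = a,
                                      ref_pos = ref_pos, alt_pos = alt_pos,
                                      class = cls,
                                      stringsAsFactors = FALSE)),
            class = "codon_alignment")
}

# Left-normalize an indel coordinate within a homopolymer run (VCF-style):
# deleting/inserting any base of a run of equal bases yields the same
# sequence, so the leftmost position is the canonical representative.
normalize_indel_pos <- function(seq_chars, pos) {
  while (pos > 1L && seq_chars[[pos - 1L]] == seq_chars[[pos]]) pos <- pos - 1L
  pos
}

# Collapse alignment columns into edit events; consecutive gap columns of
# one kind form a single indel event.
alignment_edits <- function(alignment) {
  cols <- alignment$columns
  ref_chars <- strsplit(gsub("-", "", alignment$ref), "")[[1]]
  alt_chars <- strsplit(gsub("-", "", alignment$alt), "")[[1]]
  edits <- list()
  i <- 1L
  n <- nrow(cols)
  while (i <= n) {
    cl <- cols$class[[i]]
    if (cl == "match") { i <- i + 1L; next }
    if (cl == "substitution") {
      edits[[length(edits) + 1L]] <- list(
        type = "substitution", alt_pos = cols$alt_pos[[i]],
        ref_pos = cols$ref_pos[[i]], length = 1L,
        bases = cols$alt_char[[i]])
      i <- i + 1L
    } else {
      j <- i
      while (j < n && cols$class[[j + 1L]] == cl) j <- j + 1L
      if (cl == "insertion_in_alt") {
        pos <- normalize_indel_pos(alt_chars, cols$alt_pos[[i]])
        edits[[length(edits) + 1L]] <- list(
          type = "insertion", alt_pos = pos,
          ref_pos = cols$ref_pos[[i]], length = j - i + 1L,
          bases = paste(cols$alt_char[i:j], collapse = ""))
      } else {
        pos <- normalize_indel_pos(ref_chars, cols$ref_pos[[i]])
        # alt coordinate of the last alt base before the deleted run
        edits[[length(edits) + 1L]] <- list(
          type = "deletion", alt_pos = cols$alt_pos[[i]],
          ref_pos = pos, length = j - i + 1L,
          bases = paste(cols$ref_char[i:j], collapse = ""))
      }
      i <- j + 1L
    }
  }
  edits
}

#' Type the mechanism of premature termination in a derived paralog
#'
#' Locates the derived CDS's first in-frame stop and attributes it to the
#' nearest upstream edit in the pairwise alignment:
#' * a single-base insertion inside the stop codon -> `insertion_stop`
#'   (e.g. the inserted G creating a terminal TGA);
#' * a substitution inside the stop codon converting a sense codon to a stop
#'   -> `substitution_nonsense` (e.g. TTA corrected to TGA);
#' * an upstream deletion shifting the frame -> `deletion_frameshift`;
#' * an upstream insertion shifting the frame -> `insertion_frameshift`.
#'
#' Indel coordinates are left-normalized within homopolymer runs, so the
#' reported causal coordinate is the canonical representative of the edit.
#' The search scans edits within 30 codons upstream of the stop, widening to
#' the whole alignment if that window holds none.  When several edits
#' precede the stop, the nearest upstream one is reported as causal and the
#' rest are listed as candidates.
#'
#' Also reports the anchor offset: the distance in amino acids from the last
#' aligned anchor residue (default arginine) of the reference to the derived
#' stop, and whether that offset falls inside the configured termination
#' window.
#'
#' @param pair a [paralog_pair()].
#' @param alignment the [align_paralogs()] result for `pair` (computed if
#'   missing).
#' @param config a [run_config()].
#' @return a `truncation_report`: list with `premature`,
#'   `alt_stop_codon_index`, `ref_length_codons`, `mechanism`, `causal_edit`
#'   (type, alt/ref nucleotide coordinate, bases), `candidates`,
#'   `anchor_offset`, `within_window`, `anchor_found`.
#' @export
classify_mechanism <- function(pair, alignment = align_paralogs(pair),
                               config = run_config()) {
  tr_ref <- translate_cds(pair$ref)
  tr_alt <- translate_cds(pair$alt)
  ref_len <- nchar(pair$ref) / 3L        # codons incl. stop
  premature <- nchar(tr_alt$protein) < nchar(tr_ref$protein)
  report <- list(premature = premature,
                 alt_stop_codon_index = tr_alt$stop_codon,
                 ref_length_codons = as.integer(ref_len),
                 mechanism = "none", causal_edit = NULL,
                 candidates = list(), anchor_offset = NA_integer_,
                 within_window = NA, anchor_found = NA)
  class(report) <- "truncation_report"
  if (!premature) return(report)

  s <- tr_alt$stop_codon
  stop_lo <- 3L * s - 2L
  stop_hi <- 3L * s
  edits <- alignment_edits(alignment)
  # only edits capable of producing the stop: any upstream indel (frame
  # shift or stop creation), or a substitution inside the stop codon itself
  capable <- vapply(edits, function(e) {
    e$type != "substitution" || (e$alt_pos >= stop_lo && e$alt_pos <= stop_hi)
  }, logical(1))
  edits <- edits[capable]
  edit_pos <- vapply(edits, function(e) e$alt_pos, numeric(1))
  upstream <- edits[edit_pos <= stop_hi]
  upstream_pos <- edit_pos[edit_pos <= stop_hi]
  if (!length(upstream))
    stop("derived paralog is premature but the alignment shows no edit upstream of its stop",
         call. = FALSE)
  window_lo_nt <- stop_lo - 30L * 3L
  in_window <- upstream_pos >= window_lo_nt
  scan <- if (any(in_window)) upstream[in_window] else upstream
  scan_pos <- if (any(in_window)) upstream_pos[in_window] else upstream_pos
  ord <- order(scan_pos, decreasing = TRUE)
  causal <- scan[[ord[[1]]]]
  mech <- if (causal$type == "substitution") {
    "substitution_nonsense"
  } else if (causal$type == "insertion") {
    if (causal$alt_pos >= stop_lo && causal$alt_pos <= stop_hi)
      "insertion_stop" else "insertion_frameshift"
  } else {
    "deletion_frameshift"
  }
  coord <- if (causal$type == "deletion") causal$ref_pos else causal$alt_pos
  report$mechanism <- mech
  report$causal_edit <- list(type = causal$type, coordinate = coord,
                             ref_pos = causal$ref_pos,
                             alt_pos = causal$alt_pos, bases = causal$bases)
  report$candidates <- scan[ord][-1]

  # anchor offset: reference codon aligned to the derived stop, minus the
  # codon of the last upstream anchor residue in the reference protein
  cols <- alignment$columns
  idx <- which(cols$alt_pos >= stop_lo)
  ref_nt <- if (length(idx)) cols$ref_pos[[idx[[1]]]] else max(cols$ref_pos)
  ref_codon_at_stop <- max(1L, ceiling(ref_nt / 3))
  anchors <- which(strsplit(tr_ref$protein, "")[[1]] == pair$anchor_residue)
  anchors <- anchors[anchors <= ref_codon_at_stop]
  if (length(anchors)) {
    report$anchor_found <- TRUE
    report$anchor_offset <- as.integer(ref_codon_at_stop - max(anchors))
    report$within_window <- report$anchor_offset >= config$window_lo &
      report$anchor_offset <= config$window_hi
  } else {
    report$anchor_found <- FALSE
  }
  report
}

#' Check whether a premature stop falls in the anchored termination window
#'
#' @param report a `truncation_report` with `premature = TRUE`.
#' @param config a [run_config()] providing `window_lo`/`window_hi`.
#' @return `TRUE`/`FALSE`, or `NA` (indeterminate) when the reference holds
#'   no anchor residue upstream of the stop.
#' @export
termination_window_check <- function(report, config = run_config()) {
  if (!isTRUE(report$premature))
    stop("termination_window_check requires a premature report", call. = FALSE)
  if (identical(report$anchor_found, FALSE)) return(NA)
  report$anchor_offset >= config$window_lo &
    report$anchor_offset <= config$window_hi
}

#' Flatten a list of truncation reports into a table
#'
#' @param reports named list of `truncation_report`s.
#' @return data.frame, one row per report.
#' @export
truncation_table <- function(reports) {
  do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(pair = nm, premature = r$premature,
               alt_stop_codon = r$alt_stop_codon_index,
               ref_length_codons = r$ref_length_codons,
               mechanism = r$mechanism,
               edit_type = if (is.null(r$causal_edit)) NA_character_ else r$causal_edit$type,
               edit_coordinate = if (is.null(r$causal_edit)) NA_integer_ else r$causal_edit$coordinate,
               edit_bases = if (is.null(r$causal_edit)) NA_character_ else r$causal_edit$bases,
               n_alternate_edits = length(r$candidates),
               anchor_offset = r$anchor_offset,
               within_window = r$within_window,
               stringsAsFactors = FALSE)
  }))
}
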