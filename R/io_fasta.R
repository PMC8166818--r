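PROTEIN_CHARS <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                   "R","S","T","V","W","Y","X","*")
DNA_CHARS <- c("A","C","G","T","N")

#' Read a FASTA file into a sequence table
#'
#' A validating FASTA reader: sequences are checked against the declared
#' alphabet (DNA: ACGTN; protein: the 20 standard residues plus X and `*`),
#' ids must be unique and non-empty, and parse errors report the offending
#' line number.  Any line wrapping is accepted.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"protein"` or `"dna"`.
#' @return A data.frame with columns `id`, `description`, `sequence`, and
#'   attribute `alphabet`; record order as in the file.
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  allowed <- if (alphabet == "dna") DNA_CHARS else PROTEIN_CHARS
  lines <- readLines(path, warn = FALSE)
  ids <- character(0); descs <- character(0); seqs <- character(0)
  cur <- NULL
  buf <- character(0)
  flush_record <- function() {
    if (is.null(cur)) return(invisible(NULL))
    s <- paste(buf, collapse = "")
    if (!nzchar(s))
      stop(sprintf("FASTA parse error near line %d: record '%s' has an empty sequence",
                   cur$line, cur$id), call. = FALSE)
    ids <<- c(ids, cur$id); descs <<- c(descs, cur$desc); seqs <<- c(seqs, s)
    invisible(NULL)
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) next
    if (startsWith(line, ">")) {
      flush_record()
      hdr <- sub("^>", "", line)
      id <- sub("\\s.*$", "", hdr)
      if (!nzchar(id))
        stop(sprintf("FASTA parse error at line %d: empty header id", i),
             call. = FALSE)
      desc <- if (grepl("\\s", hdr)) sub("^\\S+\\s+", "", hdr) else ""
      cur <- list(id = id, desc = desc, line = i)
      buf <- character(0)
    } else {
      if (is.null(cur))
        stop(sprintf("FASTA parse error at line %d: sequence before first header", i),
             call. = FALSE)
      up <- toupper(line)
      bad <- setdiff(unique(strsplit(up, "")[[1]]), allowed)
      if (length(bad))
        stop(sprintf("FASTA parse error at line %d: illegal %s character(s) %s",
                     i, alphabet, paste(sQuote(bad), collapse = ", ")),
             call. = FALSE)
      buf <- c(buf, up)
    }
  }
  flush_record()
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop(sprintf("duplicate FASTA id(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  out <- data.frame(id = ids, description = descs, sequence = seqs,
                    stringsAsFactors = FALSE)
  attr(out, "alphabet") <- alphabet
  out
}

#' Write a sequence table to FASTA
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param records data.frame with columns `id`, `description`, `sequence`
#'   (as returned by [read_fasta()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    desc <- if ("description" %in% names(records) &&
                nzchar(records$description[[i]]))
      paste0(" ", records$description[[i]]) else ""
    writeLines(paste0(">", records$id[[i]], desc), con)
    s <- records$sequence[[i]]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}
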