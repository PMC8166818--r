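#' Read a domain-hit table
#'
#' Tab-separated, six fixed columns in this order: `gene_id`, `domain_name`,
#' `pfam_accession` (may be empty), `env_start`, `env_end`, `e_value`.
#' Coordinates are 1-based inclusive residue positions (HMMER envelope
#' convention).  Lines starting with `#` are comments; an optional header
#' line naming the columns is recognised and skipped.
#'
#' @param path path to the TSV file.
#' @return data.frame of validated hits in file order.
#' @export
read_domain_hits <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  lines <- lines[keep]
  idx <- which(keep)
  if (length(lines) && identical(strsplit(lines[[1]], "\t")[[1]][1], "gene_id")) {
    lines <- lines[-1]; idx <- idx[-1]
  }
  if (!length(lines)) return(empty_domain_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(parts)
  if (any(n != 6L))
    stop(sprintf("domain-hit parse error at line %d: expected 6 tab-separated fields, got %d",
                 idx[which(n != 6L)[1]], n[n != 6L][1]), call. = FALSE)
  m <- do.call(rbind, parts)
  suppressWarnings({
    env_start <- as.integer(m[, 4]); env_end <- as.integer(m[, 5])
    e_value <- as.numeric(m[, 6])
  })
  bad <- which(is.na(env_start) | is.na(env_end) | is.na(e_value))
  if (length(bad))
    stop(sprintf("domain-hit parse error at line %d: non-numeric coordinate or e_value",
                 idx[bad[1]]), call. = FALSE)
  hits <- data.frame(gene_id = m[, 1], domain_name = m[, 2],
                     pfam_accession = m[, 3],
                     env_start = env_start, env_end = env_end,
                     e_value = e_value, stringsAsFactors = FALSE)
  validate_domain_hits(hits)
  hits
}

empty_domain_hits <- function() {
  data.frame(gene_id = character(0), domain_name = character(0),
             pfam_accession = character(0), env_start = integer(0),
             env_end = integer(0), e_value = numeric(0),
             stringsAsFactors = FALSE)
}

validate_domain_hits <- function(hits) {
  bad <- which(hits$env_start < 1L | hits$env_end < hits$env_start |
                 hits$e_value < 0)
  if (length(bad))
    stop(sprintf("invalid domain hit at row %d (gene %s): need env_start >= 1, env_end >= env_start, e_value >= 0",
                 bad[1], hits$gene_id[bad[1]]), call. = FALSE)
  invisible(hits)
}

#' Write a domain-hit table
#' @param hits data.frame as returned by [read_domain_hits()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_domain_hits <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# domain-hit table: 1-based inclusive envelope coordinates", con)
  writeLines(paste(c("gene_id", "domain_name", "pfam_accession",
                     "env_start", "env_end", "e_value"), collapse = "\t"), con)
  if (nrow(hits))
    write.table(hits[, c("gene_id", "domain_name", "pfam_accession",
                         "env_start", "env_end", "e_value")],
                con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}

#' Read an expression matrix (genes x developmental stages)
#'
#' Tab-separated; first column gene ids, header row of stage labels in
#' developmental time order; values nonnegative reals (RPKM/FPKM).
#'
#' @param path path to the TSV file.
#' @param unit unit tag to attach: `"RPKM"`, `"FPKM"` or `"other"`.
#' @return numeric matrix with gene-id rownames and stage-label colnames and
#'   attribute `unit`.
#' @export
read_expression_matrix <- function(path, unit = c("RPKM", "FPKM", "other")) {
  unit <- match.arg(unit)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2L) stop("expression matrix needs >= 1 stage column", call. = FALSE)
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("expression matrix parse error: non-numeric cell", call. = FALSE)
  if (anyNA(vals)) stop("expression matrix has missing cells", call. = FALSE)
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative expression value for gene %s, stage %s",
                 ids[bad[1]], colnames(vals)[bad[2]]), call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("duplicate gene ids in expression matrix", call. = FALSE)
  rownames(vals) <- ids
  attr(vals, "unit") <- unit
  vals
}

#' Write an expression matrix
#' @param mat numeric matrix, genes x stages.
#' @param path output path.
#' @param comment optional `#` comment lines to prepend.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path, comment = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comment) writeLines(paste0("# ", cm), con)
  writeLines(paste(c("gene", colnames(mat)), collapse = "\t"), con)
  write.table(data.frame(gene = rownames(mat), mat, check.names = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a presence/absence matrix (families x species, cells 0/1)
#' @param path path to the TSV file.
#' @return integer matrix, rownames families, colnames species.
#' @export
read_presence_absence <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  fams <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!all(m %in% c(0, 1)))
    stop("presence/absence cells must be 0 or 1", call. = FALSE)
  storage.mode(m) <- "integer"
  rownames(m) <- fams
  m
}

#' Write a presence/absence matrix
#' @param mat integer 0/1 matrix, families x species.
#' @param path output path.
#' @param comment optional `#` comment lines to prepend.
#' @return `path`, invisibly.
#' @export
write_presence_absence <- function(mat, path, comment = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comment) writeLines(paste0("# ", cm), con)
  writeLines(paste(c("family", colnames(mat)), collapse = "\t"), con)
  write.table(data.frame(family = rownames(mat), mat, check.names = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
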