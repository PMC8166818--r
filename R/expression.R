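#' Normalise developmental expression profiles per gene
#'
#' Because RPKM/FPKM are only comparable as trends, profiles are normalised
#' gene-wise before comparison.  Constant rows cannot be normalised by
#' z-score or rank; they are flagged (attribute `constant_genes`) and their
#' rows set to `NA` so correlations exclude them rather than silently
#' treating them as zero.
#'
#' @param matrix numeric expression matrix, genes x stages.
#' @param method `"zscore"` (per-gene mean 0, sd 1), `"minmax"` (per-gene
#'   \[0, 1\]), or `"rank"` (per-gene ranks, mean-rank ties).
#' @return numeric matrix of the same shape with attribute `constant_genes`.
#' @export
normalize_trend <- function(matrix, method = c("zscore", "minmax", "rank")) {
  method <- match.arg(method)
  constant <- apply(matrix, 1, function(x) length(unique(x)) == 1L)
  out <- t(apply(matrix, 1, function(x) {
    if (length(unique(x)) == 1L) return(rep(NA_real_, length(x)))
    switch(method,
           zscore = (x - mean(x)) / sd(x),
           minmax = (x - min(x)) / (max(x) - min(x)),
           rank = rank(x, ties.method = "average"))
  }))
  dimnames(out) <- dimnames(matrix)
  attr(out, "constant_genes") <- rownames(matrix)[constant]
  attr(out, "method") <- method
  out
}

#' Compare two stage profiles for similarity or complementarity
#'
#' The score is the chosen correlation over the shared, ordered stages.
#' Relation: `similar` when the score is at or above
#' `similarity_threshold`, `complementary` at or below
#' `complementarity_threshold`, otherwise `unrelated`.
#'
#' @param a,b numeric stage profiles over the same stages in the same order.
#' @param method `"spearman"` (default: rank trends, robust to unit mixing)
#'   or `"pearson"`.
#' @param config a [run_config()] providing the two thresholds.
#' @return a `profile_comparison`: list with `score`, `relation`, `method`,
#'   `n_stages`.
#' @export
profile_similarity <- function(a, b, method = c("spearman", "pearson"),
                               config = run_config()) {
  method <- match.arg(method)
  if (length(a) != length(b))
    stop("profiles differ in stage count", call. = FALSE)
  if (length(a) < 4L)
    stop("need >= 4 stages for a meaningful correlation", call. = FALSE)
  score <- cor(a, b, method = method)
  relation <- if (is.na(score)) "unrelated"
  else if (score >= config$similarity_threshold) "similar"
  else if (score <= config$complementarity_threshold) "complementary"
  else "unrelated"
  structure(list(score = score, relation = relation, method = method,
                 n_stages = length(a),
                 similarity_threshold = config$similarity_threshold,
                 complementarity_threshold = config$complementarity_threshold),
            class = "profile_comparison")
}

#' Rank candidate genes by expression-profile similarity to a target
#'
#' @param target gene id of the target profile.
#' @param candidates character vector of candidate gene ids (must not
#'   include the target).
#' @param matrix numeric expression matrix containing all the genes.
#' @param method correlation method, as in [profile_similarity()].
#' @param config a [run_config()].
#' @return data.frame of candidates sorted by descending score (ties kept in
#'   gene-id order, flagged in column `tied_with_next`); constant-profile
#'   candidates are dropped and listed in attribute `excluded_constant`.
#' @export
nearest_profile <- function(target, candidates, matrix,
                            method = c("spearman", "pearson"),
                            config = run_config()) {
  method <- match.arg(method)
  if (target %in% candidates)
    stop("target must not be among the candidates", call. = FALSE)
  missing <- setdiff(c(target, candidates), rownames(matrix))
  if (length(missing))
    stop("genes missing from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  const <- vapply(candidates, function(g)
    length(unique(matrix[g, ])) == 1L, logical(1))
  if (length(unique(matrix[target, ])) == 1L)
    stop("target profile is constant; no ranking possible", call. = FALSE)
  usable <- candidates[!const]
  scores <- vapply(usable, function(g)
    profile_similarity(matrix[target, ], matrix[g, ], method = method,
                       config = config)$score, numeric(1))
  ord <- order(-scores, usable)
  out <- data.frame(candidate = usable[ord], score = scores[ord],
                    stringsAsFactors = FALSE)
  out$tied_with_next <- c(diff(out$score) == 0, FALSE)
  attr(out, "excluded_constant") <- candidates[const]
  rownames(out) <- NULL
  out
}

#' Report the peak stage of each gene's profile
#'
#' For each gene, the stage(s) of maximal expression and an enrichment
#' ratio (max + 1) / (median + 1); the pseudocount of 1 on raw values
#' avoids division by zero for mostly-silent genes.
#'
#' @param matrix numeric expression matrix, genes x stages.
#' @param gene_set genes to report (default all).
#' @return data.frame with columns `gene`, `peak_stage` (ties joined with
#'   `;`), `max_value`, `enrichment_ratio`.
#' @export
stage_peak_report <- function(matrix, gene_set = rownames(matrix)) {
  if (ncol(matrix) < 1L) stop("matrix has no stages", call. = FALSE)
  do.call(rbind, lapply(gene_set, function(g) {
    x <- matrix[g, ]
    peak <- colnames(matrix)[x == max(x)]
    data.frame(gene = g, peak_stage = paste(peak, collapse = ";"),
               max_value = max(x),
               enrichment_ratio = (max(x) + 1) / (median(x) + 1),
               stringsAsFactors = FALSE)
  }))
}

#' Flag low-expression genes
#'
#' @param matrix numeric expression matrix.
#' @param floor median raw value at or below which a gene is flagged.
#' @return character vector of flagged gene ids.
#' @export
low_expression_flags <- function(matrix, floor = 1) {
  rownames(matrix)[apply(matrix, 1, median) <= floor]
}
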