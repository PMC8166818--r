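#' Pipeline run configuration
#'
#' Bundles every tunable threshold of the pipeline.  Defaults follow the
#' analysis conventions used throughout the package: domain hits are kept at
#' E-value <= 1e-5; "several" copies of a repeat domain means at least 2;
#' premature stops are flagged as falling in the canonical termination window
#' when they occur 1-10 residues downstream of the reference anchor arginine;
#' expression profiles correlated at or above +0.5 (Spearman) are called
#' similar and at or below -0.5 complementary; alignment columns with more
#' than 50% gaps are trimmed; bootstrap uses 1000 replicates.
#'
#' @param e_value_threshold keep domain hits with E-value at or below this.
#' @param several_min_count minimum copy number read for "several" repeats
#'   (EGF, ANK) in the Notch signature.
#' @param window_lo,window_hi inclusive bounds (amino acids downstream of the
#'   anchor residue) of the expected premature-termination window.
#' @param complementarity_threshold correlation at or below this is
#'   "complementary".
#' @param similarity_threshold correlation at or above this is "similar".
#' @param gap_fraction_trim drop alignment columns whose gap fraction exceeds
#'   this.
#' @param bootstrap_reps number of bootstrap replicates.
#' @param rng_seed integer seed used for all stochastic steps.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(e_value_threshold = 1e-5,
                       several_min_count = 2L,
                       window_lo = 1L,
                       window_hi = 10L,
                       complementarity_threshold = -0.5,
                       similarity_threshold = 0.5,
                       gap_fraction_trim = 0.5,
                       bootstrap_reps = 1000L,
                       rng_seed = 1L) {
  cfg <- list(
    e_value_threshold = as.numeric(e_value_threshold),
    several_min_count = as.integer(several_min_count),
    window_lo = as.integer(window_lo),
    window_hi = as.integer(window_hi),
    complementarity_threshold = as.numeric(complementarity_threshold),
    similarity_threshold = as.numeric(similarity_threshold),
    gap_fraction_trim = as.numeric(gap_fraction_trim),
    bootstrap_reps = as.integer(bootstrap_reps),
    rng_seed = as.integer(rng_seed)
  )
  validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(cfg) {
  stopifnot(cfg$e_value_threshold > 0)
  if (cfg$several_min_count < 1L)
    stop("several_min_count must be >= 1", call. = FALSE)
  if (cfg$window_lo > cfg$window_hi)
    stop("window_lo must be <= window_hi", call. = FALSE)
  if (cfg$gap_fraction_trim < 0 || cfg$gap_fraction_trim > 1)
    stop("gap_fraction_trim must lie in [0, 1]", call. = FALSE)
  if (cfg$complementarity_threshold < -1 || cfg$complementarity_threshold > 1 ||
      cfg$similarity_threshold < -1 || cfg$similarity_threshold > 1)
    stop("correlation thresholds must lie in [-1, 1]", call. = FALSE)
  if (cfg$bootstrap_reps < 1L)
    stop("bootstrap_reps must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' Read a run configuration from a flat key:value text file
#'
#' One `key: value` pair per line; blank lines and `#` comments allowed.
#' Keys not named in [run_config()] are an error (catches typos); missing
#' keys take their defaults.
#'
#' @param path path to the config file.
#' @return A `run_config` object.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  defaults <- run_config()
  vals <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop(sprintf("config line %d is not 'key: value': %s", i, lines[[i]]),
           call. = FALSE)
    key <- trimws(parts[[1]])
    if (!key %in% names(unclass(defaults)))
      stop(sprintf("unknown config key '%s'", key), call. = FALSE)
    vals[[key]] <- as.numeric(trimws(parts[[2]]))
  }
  do.call(run_config, vals)
}

#' Write a run configuration to a flat key:value text file
#'
#' @param cfg a `run_config` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  lines <- vapply(names(unclass(cfg)), function(k) {
    sprintf("%s: %s", k, format(cfg[[k]], scientific = TRUE))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# FNV-1a 32-bit hash of the serialized config; used to stamp outputs so two
# runs can be compared for config identity without re-reading the config.
config_hash <- function(cfg) {
  txt <- paste(names(unclass(cfg)),
               vapply(unclass(cfg), function(x) format(x, digits = 15),
                      character(1)),
               sep = "=", collapse = ";")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor the byte into the low half (keeps values inside integer range)
    lo <- h %% 65536
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # 32-bit modular multiply by the FNV prime, split to keep full precision
    hi <- h %/% 65536; lo <- h %% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# info-level logging for pipeline stages: input / filtered / output counts
nt_log <- function(..., verbose = getOption("notchtrace.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[notchtrace] ", sprintf(...))
  invisible(NULL)
}
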