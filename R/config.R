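#' Analysis configuration
#'
#' Bundles every tunable parameter of the pipeline with the defaults used
#' throughout: alignment match filters (`min_match_len`, `min_mapq`), the
#' display filter for synteny plots (`display_min_len`), MinHash sketching
#' parameters (`kmer_size`, `sketch_size`), tree-search settings (`n_jumbles`,
#' `jumble_seed`), and Monte-Carlo settings for flux confidence intervals
#' (`mc_samples`, `ci_level`).
#'
#' @param min_match_len minimum reference span (bases) for a match to enter
#'   identity/coverage statistics; default 1000 (matches spanning >= 1 kbp).
#' @param display_min_len minimum span (bases) for a match to be exported for
#'   plotting; default 10000.
#' @param min_mapq minimum mapping quality kept; default 1 (quality > 0).
#' @param kmer_size k-mer size for sketching; default 21.
#' @param sketch_size number of bottom hashes retained per sketch; default 1000.
#' @param n_jumbles number of random taxon addition orders tried during tree
#'   search; default 10.
#' @param jumble_seed seed for the jumbled addition orders; default 23893.
#' @param mc_samples Monte-Carlo samples for flux confidence intervals;
#'   default 1000.
#' @param ci_level confidence level as a fraction; default 0.95.
#' @param rng_seed master seed for stochastic steps; default 1.
#' @return an object of class `kf_config` (a validated list).
#' @export
kf_config <- function(min_match_len = 1000,
                      display_min_len = 10000,
                      min_mapq = 1,
                      kmer_size = 21,
                      sketch_size = 1000,
                      n_jumbles = 10,
                      jumble_seed = 23893,
                      mc_samples = 1000,
                      ci_level = 0.95,
                      rng_seed = 1) {
  cfg <- list(
    min_match_len = as.numeric(min_match_len),
    display_min_len = as.numeric(display_min_len),
    min_mapq = as.integer(min_mapq),
    kmer_size = as.integer(kmer_size),
    sketch_size = as.integer(sketch_size),
    n_jumbles = as.integer(n_jumbles),
    jumble_seed = as.integer(jumble_seed),
    mc_samples = as.integer(mc_samples),
    ci_level = as.numeric(ci_level),
    rng_seed = as.integer(rng_seed)
  )
  stopifnot(
    cfg$min_match_len >= 0, cfg$display_min_len >= 0, cfg$min_mapq >= 0,
    cfg$kmer_size > 0, cfg$sketch_size > 0, cfg$n_jumbles > 0,
    cfg$mc_samples > 0, cfg$ci_level > 0, cfg$ci_level < 1
  )
  class(cfg) <- "kf_config"
  cfg
}

#' Read a flat key = value configuration file
#'
#' The file format is a flat TOML-style list of `key = value` assignments,
#' one per line; `#` starts a comment. Unknown keys raise an error so typos
#' do not silently fall back to defaults.
#'
#' @param path path to the configuration file.
#' @return a [kf_config()] object.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  defaults <- kf_config()
  vals <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("config line without '=': ", ln)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(unclass(defaults))) {
      stop("unknown config key: ", key)
    }
    vals[[key]] <- as.numeric(val)
  }
  do.call(kf_config, vals)
}

#' @export
print.kf_config <- function(x, ...) {
  cat("komaflux configuration\n")
  for (k in names(unclass(x))) cat(sprintf("  %-16s %s\n", k, format(x[[k]])))
  invisible(x)
}

# -- run log ------------------------------------------------------------------

# A lightweight append-only log. Filter operations record read/kept/dropped
# counts here so per-chromosome match counts can be audited after a run.
.kf_log_env <- new.env(parent = emptyenv())
.kf_log_env$messages <- list()
.kf_log_env$verbose <- FALSE

#' Enable or disable console echo of log messages
#' @param verbose logical.
#' @return previous setting, invisibly.
#' @export
kf_log_verbose <- function(verbose = TRUE) {
  old <- .kf_log_env$verbose
  .kf_log_env$verbose <- isTRUE(verbose)
  invisible(old)
}

kf_log <- function(level, msg, counts = NULL) {
  rec <- list(time = Sys.time(), level = level, message = msg, counts = counts)
  .kf_log_env$messages[[length(.kf_log_env$messages) + 1L]] <- rec
  if (.kf_log_env$verbose) {
    message(sprintf("[%s] %s: %s", format(rec$time, "%H:%M:%S"), level, msg))
  }
  invisible(rec)
}

#' Retrieve the run log
#'
#' @param clear if `TRUE`, empty the log after returning it.
#' @return a data.frame with columns time, level, message, and (where a filter
#'   was logged) n_in, n_kept, n_dropped.
#' @export
kf_run_log <- function(clear = FALSE) {
  msgs <- .kf_log_env$messages
  if (clear) .kf_log_env$messages <- list()
  if (length(msgs) == 0L) {
    return(data.frame(
      time = as.POSIXct(character()), level = character(),
      message = character(), n_in = integer(), n_kept = integer(),
      n_dropped = integer(), stringsAsFactors = FALSE
    ))
  }
  getc <- function(m, what) {
    if (is.null(m$counts)) NA_integer_ else as.integer(m$counts[[what]])
  }
  data.frame(
    time = do.call(c, lapply(msgs, `[[`, "time")),
    level = vapply(msgs, `[[`, "", "level"),
    message = vapply(msgs, `[[`, "", "message"),
    n_in = vapply(msgs, getc, 0L, "n_in"),
    n_kept = vapply(msgs, getc, 0L, "n_kept"),
    n_dropped = vapply(msgs, getc, 0L, "n_dropped"),
    stringsAsFactors = FALSE
  )
}
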