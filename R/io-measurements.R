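# GC-TOFMS measurement tables: one row per derivatized fragment with the
# metabolite, fragment ion formula, backbone carbon count, and raw
# isotopologue peak areas m0..mK with standard deviations sd0..sdK.

#' Read a GC-TOFMS isotopologue measurement table
#'
#' Expects a CSV with columns `metabolite`, `fragment_formula`,
#' `n_backbone_carbons`, optional `rt` and `adduct`, then `m0..mK` mean
#' areas and (optionally) `sd0..sdK` standard deviations. `K` must be at
#' least the backbone carbon count. Missing SD columns fall back to a
#' uniform SD (5% of the mean total area) with a warning; negative areas are
#' an error.
#'
#' @param path path to the CSV file.
#' @return an object of class `measurement_set`: a list of records, each
#'   with `frag` (a [fragment_spec()]), `raw` and `sd` vectors.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("metabolite", "fragment_formula", "n_backbone_carbons")
  if (!all(need %in% names(df))) {
    stop("measurement file must have columns: ", paste(need, collapse = ", "))
  }
  mcols <- grep("^m[0-9]+$", names(df), value = TRUE)
  sdcols <- grep("^sd[0-9]+$", names(df), value = TRUE)
  mcols <- mcols[order(as.integer(sub("m", "", mcols)))]
  sdcols <- sdcols[order(as.integer(sub("sd", "", sdcols)))]
  if (length(mcols) == 0) stop("no m0..mK area columns found")
  has_sd <- length(sdcols) == length(mcols)
  if (!has_sd) {
    warning("SD columns missing or incomplete; using uniform fallback SDs")
  }
  records <- lapply(seq_len(nrow(df)), function(i) {
    raw <- as.numeric(df[i, mcols])
    keep <- !is.na(raw)
    raw <- raw[keep]
    if (any(raw < 0)) {
      stop("negative area for ", df$metabolite[i])
    }
    n <- as.integer(df$n_backbone_carbons[i])
    if (length(raw) < n + 1) {
      stop("fewer area columns than n_backbone_carbons + 1 for ",
           df$metabolite[i])
    }
    frag <- fragment_spec(
      metabolite = df$metabolite[i],
      formula = df$fragment_formula[i],
      n_backbone_carbons = n,
      rt = if ("rt" %in% names(df)) df$rt[i] else NA_real_,
      adduct = if ("adduct" %in% names(df)) df$adduct[i] else NA_character_
    )
    sd <- if (has_sd) {
      as.numeric(df[i, sdcols])[keep]
    } else {
      rep(0.05 * mean(raw), length(raw))
    }
    list(frag = frag, raw = raw, sd = sd)
  })
  structure(records, class = "measurement_set")
}

#' Write a measurement table (generator output / round-trip partner)
#'
#' @param measurements a `measurement_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  stopifnot(inherits(measurements, "measurement_set"))
  K <- max(vapply(measurements, function(r) length(r$raw), 0L)) - 1L
  rows <- lapply(measurements, function(r) {
    m <- rep(NA_real_, K + 1); s <- rep(NA_real_, K + 1)
    m[seq_along(r$raw)] <- r$raw
    s[seq_along(r$sd)] <- r$sd
    c(list(metabolite = r$frag$metabolite,
           fragment_formula = r$frag$formula,
           n_backbone_carbons = r$frag$n_backbone_carbons,
           rt = r$frag$rt, adduct = r$frag$adduct),
      stats::setNames(as.list(m), paste0("m", 0:K)),
      stats::setNames(as.list(s), paste0("sd", 0:K)))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r,
                                                              stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf("measurement_set: %d fragments (%s)\n", length(x),
              paste(vapply(x, function(r) r$frag$metabolite, ""),
                    collapse = ", ")))
  invisible(x)
}

#' Natural-abundance-correct a whole measurement set
#'
#' Applies [correct_cid()] to every fragment and propagates the raw-area SDs
#' through the deconvolution onto the percent scale: to first order the
#' correction is the least-squares map `(M'M)^-1 M'`, which amplifies
#' measurement noise, so the corrected-CID covariance is
#' `(M'M)^-1 M' diag(sd^2) M (M'M)^-1` and the reported SDs are the square
#' roots of its diagonal rescaled to percent. A floor of `sd_floor`
#' percentage points avoids infinite weights in downstream fitting.
#'
#' @param measurements a `measurement_set`.
#' @param sd_floor minimum SD in percentage points; default 0.1.
#' @return a list of records with `metabolite`, `cid` (percent), `sd`
#'   (percent), `residual_norm`; class `cid_set`.
#' @export
correct_measurements <- function(measurements, sd_floor = 0.1) {
  stopifnot(inherits(measurements, "measurement_set"))
  out <- lapply(measurements, function(r) {
    cc <- correct_cid(r$raw, r$frag)
    M <- correction_matrix(r$frag, K = length(r$raw) - 1)
    MtM_inv <- solve(crossprod(M))
    H <- MtM_inv %*% t(M)
    cov_x <- H %*% (r$sd^2 * t(H))
    sd_pct <- 100 * sqrt(pmax(diag(cov_x), 0)) / sum(cc$areas)
    list(metabolite = r$frag$metabolite, cid = cc$ra,
         sd = pmax(sd_pct, sd_floor), residual_norm = cc$residual_norm)
  })
  structure(out, class = "cid_set")
}
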