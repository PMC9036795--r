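# Natural-abundance correction of GC-TOFMS isotopologue peak areas for
# derivatized fragments: the measured mass-shift distribution of a fragment
# ion is the carbon-backbone isotopologue distribution convolved with the
# natural isotope distributions of every other atom in the ion (H, N, O, Si,
# S, and the derivatization carbons). Deconvolution is by nonnegative least
# squares on the correction matrix.

#' Natural isotope abundance table
#'
#' Mass-shift distributions (relative to the lightest isotope) of the
#' elements occurring in ethoxime-TMS derivatized fragment ions, from the
#' IUPAC representative isotopic compositions.
#'
#' @return named list of numeric vectors; each sums to 1.
#' @export
natural_abundance_table <- function() {
  list(
    H = c(0.999885, 0.000115),
    C = c(0.9893, 0.0107),
    N = c(0.99636, 0.00364),
    O = c(0.99757, 0.00038, 0.00205),
    Si = c(0.92223, 0.04685, 0.03092),
    S = c(0.9499, 0.0075, 0.0425, 0.0001)
  )
}

#' Fragment specification
#'
#' Elemental composition of a derivatized fragment ion, with the number of
#' metabolite backbone carbons. Derivatization carbons are the total carbon
#' count minus the backbone carbons; their natural 13C is part of what the
#' correction removes, while backbone carbons are what the labeling
#' experiment measures.
#'
#' @param metabolite metabolite id.
#' @param formula elemental formula of the fragment ion, e.g.
#'   `"C11H28NO6PSi3"` (P is tolerated and ignored: phosphorus is
#'   monoisotopic).
#' @param n_backbone_carbons number of backbone carbons (>= 1).
#' @param rt retention time in minutes (metadata).
#' @param adduct adduct/fragment label (metadata).
#' @return an object of class `fragment_spec` with element counts in
#'   `$elements`.
#' @export
fragment_spec <- function(metabolite, formula, n_backbone_carbons,
                          rt = NA_real_, adduct = NA_character_) {
  counts <- parse_formula(formula)
  if (is.na(counts["C"]) || counts["C"] < 1) {
    stop("fragment formula must contain carbon: ", formula)
  }
  n <- as.integer(n_backbone_carbons)
  if (n < 1 || counts["C"] < n) {
    stop("need total C >= n_backbone_carbons >= 1 (", formula, ", n = ", n, ")")
  }
  structure(list(metabolite = metabolite, formula = formula,
                 elements = counts, n_backbone_carbons = n,
                 rt = rt, adduct = adduct),
            class = "fragment_spec")
}

#' Parse an elemental formula into element counts
#' @param formula e.g. `"C6H13O9P"`.
#' @return named integer vector.
#' @export
parse_formula <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  counts <- integer()
  for (p in parts) {
    el <- gsub("[0-9]", "", p)
    k <- gsub("[A-Za-z]", "", p)
    k <- if (nzchar(k)) as.integer(k) else 1L
    counts[el] <- (if (is.na(counts[el])) 0L else counts[el]) + k
  }
  counts
}

#' Correction matrix for a derivatized fragment
#'
#' Column `j` (j = 0..n backbone carbons) is the mass-shift distribution of a
#' fragment whose backbone carries exactly `j` heavy carbons: a delta at
#' shift `j` convolved with the natural isotope distributions of all H, N, O,
#' Si and S atoms and of the non-backbone (derivatization) carbons,
#' truncated at mass shift `K`.
#'
#' @param frag a [fragment_spec()].
#' @param table isotope table; default [natural_abundance_table()].
#' @param K truncation mass shift; default `n_backbone_carbons + 4`.
#' @return a `(K+1) x (n+1)` matrix with column sums <= 1 (equality up to
#'   the truncated tail).
#' @export
correction_matrix <- function(frag, table = natural_abundance_table(),
                              K = frag$n_backbone_carbons + 4) {
  stopifnot(inherits(frag, "fragment_spec"), K >= frag$n_backbone_carbons)
  counts <- frag$elements
  counts["C"] <- counts["C"] - frag$n_backbone_carbons
  corr <- 1
  for (el in names(counts)) {
    k <- counts[[el]]
    if (is.na(k) || k == 0) next
    if (el == "P") next # monoisotopic
    if (!el %in% names(table)) {
      stop("element missing from abundance table: ", el)
    }
    for (i in seq_len(k)) corr <- .conv(corr, table[[el]])
  }
  n <- frag$n_backbone_carbons
  M <- matrix(0, K + 1, n + 1)
  for (j in 0:n) {
    shifted <- c(rep(0, j), corr)
    M[, j + 1] <- shifted[seq_len(K + 1)][seq_len(K + 1)]
    M[is.na(M[, j + 1]), j + 1] <- 0
  }
  dimnames(M) <- list(paste0("m", 0:K), paste0("M", 0:n))
  M
}

#' Correct raw isotopologue areas for natural abundance
#'
#' Solves `M x = A_raw` for the backbone isotopologue areas `x >= 0` by
#' nonnegative least squares (matrix inversion can produce negative
#' isotopologues on noisy data), then converts to relative abundances
#' \deqn{RA_i\,[\%] = 100\, A_i / \textstyle\sum_{i=0}^{n} A_i.}
#' The NNLS residual norm is reported for quality control.
#'
#' @param raw numeric vector of raw areas over mass shifts m+0..m+K.
#' @param frag a [fragment_spec()] with `n_backbone_carbons <= K`.
#' @param table isotope table.
#' @return an object of class `corrected_cid`: list with `ra` (percent,
#'   length n+1, sums to 100), `areas` (corrected areas), `residual_norm`.
#' @export
correct_cid <- function(raw, frag, table = natural_abundance_table()) {
  stopifnot(inherits(frag, "fragment_spec"))
  if (any(raw < 0)) stop("negative raw area")
  if (sum(raw) <= 0) stop("zero total area")
  K <- length(raw) - 1
  if (K < frag$n_backbone_carbons) {
    stop("raw vector shorter than n_backbone_carbons + 1")
  }
  M <- correction_matrix(frag, table, K = K)
  fit <- pracma::lsqnonneg(M, as.numeric(raw))
  x <- fit$x
  structure(list(ra = relative_abundance(x), areas = x,
                 residual_norm = sqrt(fit$resid.norm),
                 metabolite = frag$metabolite,
                 n_backbone_carbons = frag$n_backbone_carbons),
            class = "corrected_cid")
}

#' Relative isotopologue abundances (percent)
#'
#' @param areas nonnegative numeric vector with positive sum.
#' @return percentages summing to 100.
#' @export
relative_abundance <- function(areas) {
  if (any(areas < 0)) stop("negative area")
  s <- sum(areas)
  if (s <= 0) stop("zero total area")
  100 * areas / s
}

#' Pascal's-triangle QC for 50:50 labeling controls
#'
#' A control extract grown on a 50:50 mix of unlabeled and fully labeled
#' carbon source has a carbon isotopologue distribution following the
#' binomial with p = 1/2, i.e. Pascal's-triangle row n normalized. Reports
#' the maximum absolute deviation (percentage points) from that expectation.
#'
#' @param cid corrected CID in percent (length n+1), or a `corrected_cid`.
#' @param n number of backbone carbons.
#' @param threshold pass threshold on the max deviation (percentage points).
#' @return list with `expected` (percent), `max_abs_dev`, `pass`.
#' @export
qc_pascal <- function(cid, n, threshold = 5) {
  if (inherits(cid, "corrected_cid")) cid <- cid$ra
  if (length(cid) != n + 1) stop("cid length must be n + 1")
  expected <- 100 * stats::dbinom(0:n, n, 0.5)
  dev <- max(abs(cid - expected))
  list(expected = expected, max_abs_dev = dev, pass = dev <= threshold)
}
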