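# Bulk biomass 13C accounting for EA-IRMS interpretation: natural-abundance
# baseline and the total 13C content expected after growth on a positionally
# labeled tracer, from a two-pool mixing model (pre-existing biomass carbon
# at its initial enrichment, newly fixed carbon at the tracer's mean
# per-carbon enrichment).

#' Natural 13C abundance as percent of total carbon
#'
#' The packaged natural 13C abundance (0.0107) expressed as a percentage,
#' rounded to the reporting precision. Unlabeled biomass measures at this
#' baseline.
#'
#' @param digits decimal places for reporting; `NULL` for the unrounded
#'   value.
#' @return percent 13C of total carbon.
#' @export
natural_13c_fraction <- function(digits = 1) {
  pct <- 100 * natural_abundance_table()$C[2]
  if (is.null(digits)) pct else round(pct, digits)
}

#' Expected total biomass 13C after growth on a labeled tracer
#'
#' Two-pool mixing model: a culture growing `fold_increase`-fold builds the
#' fraction `f = (fold - 1)/fold` of its final carbon from the tracer, at
#' the tracer's mean per-carbon enrichment, while the remaining `1 - f`
#' stays at the initial enrichment:
#' \deqn{100\,(f\,e_{tracer} + (1-f)\,e_{0}).}
#' Respiratory fractionation and carbon turnover are ignored.
#'
#' @param fold_increase biomass fold increase over the labeling period
#'   (>= 1).
#' @param tracer a [tracer_spec()] (mean enrichment is the average of its
#'   positional enrichments) or a single mean enrichment fraction.
#' @param initial initial biomass 13C fraction; default natural 0.0107.
#' @return expected percent 13C of total biomass carbon.
#' @export
expected_total_13c <- function(fold_increase, tracer,
                               initial = 0.0107) {
  if (fold_increase < 1) stop("fold_increase must be >= 1")
  e_tracer <- if (inherits(tracer, "tracer_spec")) {
    mean(tracer$enrichment)
  } else {
    as.numeric(tracer)
  }
  stopifnot(e_tracer >= 0, e_tracer <= 1, initial >= 0, initial <= 1)
  f <- (fold_increase - 1) / fold_increase
  100 * (f * e_tracer + (1 - f) * initial)
}
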