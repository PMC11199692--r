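#' Reported mediation rows from a published immune-cell / pancreatic-cancer
#' MR study
#'
#' A small bundled table of reported mediated effects (with 95% CIs),
#' mediated proportions, and total-effect odds ratios for four
#' immune-cell-phenotype -> plasma-metabolite -> pancreatic-cancer
#' pathways, as printed in a published two-sample MR mediation study. Used
#' as a worked example and as an internal-consistency check of the
#' mediated-proportion arithmetic: the printed proportion should equal
#' \code{100 * me / log(or_total)}.
#'
#' The cortisone row is known to be internally inconsistent as printed
#' (its proportion has the opposite sign from \code{me / log(or_total)}
#' and its CI endpoints are reversed and inconsistent in sign); it is kept
#' for illustration. See the package vignette.
#'
#' @return A data frame with columns \code{exposure, mediator, outcome,
#'   me, me_low, me_high} (reported mediated effect and CI),
#'   \code{mp_pct, mp_low_pct, mp_high_pct} (reported mediated proportion,
#'   percent), \code{or_total} (reported total-effect IVW odds ratio).
#' @examples
#' ex <- published_mediation_examples()
#' # recompute the reported proportion from the reported inputs
#' cbind(ex$mediator, reported = ex$mp_pct,
#'       recomputed = round(mediated_proportion_pct(ex$me, ex$or_total), 1))
#' @export
published_mediation_examples <- function() {
  utils::read.delim(system.file("extdata", "published_mediation_rows.tsv",
                                package = "mrmediate"),
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Mediated proportion from a mediated effect and a total-effect odds ratio
#'
#' \code{100 * me / log(or_total)}: the mediated proportion in percent,
#' with the total effect taken on the log-odds scale.
#'
#' @param me Mediated effect(s) on the log-odds scale.
#' @param or_total Total-effect odds ratio(s).
#' @return Numeric vector of percentages.
#' @export
mediated_proportion_pct <- function(me, or_total) {
  100 * me / log(or_total)
}
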