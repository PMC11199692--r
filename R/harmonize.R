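#' Harmonize exposure and outcome summary statistics to a shared effect allele
#'
#' Joins two summary-statistic tables on \code{snp_id} and aligns the outcome
#' associations to the exposure's effect allele. When the outcome's effect
#' allele equals the exposure's other allele (and vice versa) the outcome
#' beta is negated and its alleles swapped. Palindromic SNPs (A/T, C/G) are
#' unresolvable from alleles alone on two forward-reported strands and are
#' dropped under the default policy; SNPs whose allele sets cannot be
#' reconciled at all are dropped as incompatible.
#'
#' @param exposure,outcome Validated [as_sumstats()] tables. Despite the
#'   argument names this works for any trait pair (e.g. exposure/mediator).
#' @param policy Palindromic-SNP policy: \code{"drop_all"} (default) removes
#'   every A/T and C/G SNP; \code{"drop_intermediate"} removes only those
#'   with exposure EAF in [0.42, 0.58] (requires non-missing EAF);
#'   \code{"keep"} retains them untouched.
#' @return A data frame of class \code{"harmonized_pairs"} with columns
#'   \code{snp_id, gamma, se_gamma, Gamma, se_Gamma, eaf_exposure,
#'   pval_exposure, flipped} (exposure association gamma, outcome
#'   association Gamma), and attributes \code{report} (a data frame of
#'   snp_id/action/reason for every SNP in the id intersection) and
#'   \code{trait_labels}.
#' @examples
#' trip <- simulate_triple(sim_config(n_snps = 10, seed = 1))
#' h <- harmonize(trip$exposure, trip$outcome)
#' attr(h, "report")
#' @export
harmonize <- function(exposure, outcome,
                      policy = c("drop_all", "drop_intermediate", "keep")) {
  policy <- match.arg(policy)
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  if (!length(shared))
    stop("no shared SNPs between exposure and outcome tables", call. = FALSE)

  ex <- exposure[match(shared, exposure$snp_id), ]
  ou <- outcome[match(shared, outcome$snp_id), ]

  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  aligned <- ex$effect_allele == ou$effect_allele &
    ex$other_allele == ou$other_allele
  swapped <- ex$effect_allele == ou$other_allele &
    ex$other_allele == ou$effect_allele

  action <- rep("retained", length(shared))
  reason <- rep("", length(shared))

  drop_pal <- switch(policy,
    drop_all = pal,
    keep = rep(FALSE, length(shared)),
    drop_intermediate = {
      if (anyNA(ex$eaf[pal]))
        stop("policy 'drop_intermediate' requires exposure EAF for ",
             "palindromic SNPs", call. = FALSE)
      pal & ex$eaf >= 0.42 & ex$eaf <= 0.58
    })
  incompatible <- !aligned & !swapped

  action[incompatible] <- "dropped"
  reason[incompatible] <- "incompatible alleles"
  action[drop_pal & !incompatible] <- "dropped"
  reason[drop_pal & !incompatible] <- "palindromic"
  # palindromic + swapped alleles is ambiguous even under policy = keep:
  # a strand flip and an allele swap are indistinguishable
  amb <- pal & swapped & !drop_pal & !incompatible
  action[amb] <- "dropped"
  reason[amb] <- "palindromic (ambiguous swap)"

  keep <- action == "retained"
  flip <- swapped & keep

  Gamma <- ou$beta
  Gamma[flip] <- -Gamma[flip]

  res <- data.frame(
    snp_id = shared,
    gamma = ex$beta, se_gamma = ex$se,
    Gamma = Gamma, se_Gamma = ou$se,
    eaf_exposure = ex$eaf,
    pval_exposure = ex$pval,
    flipped = flip,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(res) <- NULL

  report <- data.frame(snp_id = shared, action = action, reason = reason,
                       stringsAsFactors = FALSE)
  report$reason[keep & flip] <- "allele flip"

  structure(res,
            report = report,
            trait_labels = c(exposure = attr(exposure, "trait_label") %||% "exposure",
                             outcome = attr(outcome, "trait_label") %||% "outcome"),
            class = c("harmonized_pairs", "data.frame"))
}

#' @export
print.harmonized_pairs <- function(x, ...) {
  lab <- attr(x, "trait_labels")
  rep_ <- attr(x, "report")
  cat(sprintf("Harmonized pairs: %s -> %s\n", lab[["exposure"]],
              lab[["outcome"]]))
  cat(sprintf("  %d retained (%d allele-flipped), %d dropped of %d shared SNPs\n",
              nrow(x), sum(x$flipped), sum(rep_$action == "dropped"),
              nrow(rep_)))
  dropped <- rep_[rep_$action == "dropped", ]
  if (nrow(dropped)) {
    tb <- table(dropped$reason)
    cat("  drop reasons:",
        paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
  }
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}
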