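#' IVW significance screen
#'
#' First screening stage: an exposure passes when its IVW p-value is
#' strictly below \code{alpha} (default 0.05, uncorrected — the screen is a
#' hypothesis-generating filter over many exposures, not a confirmatory
#' test; Bonferroni/FDR variants are available in [screen_exposures()]).
#'
#' @param fit An [mr_fit()] object (or its \code{estimates} data frame).
#' @param alpha Significance level.
#' @return \code{TRUE}/\code{FALSE}.
#' @export
ivw_screen <- function(fit, alpha = 0.05) {
  est <- if (inherits(fit, "mr_fit")) fit$estimates else fit
  row <- est[est$method == "IVW", ]
  if (!nrow(row) || is.na(row$pval[1]) || identical(row$status[1], "not_computable"))
    stop("IVW estimate missing; cannot screen", call. = FALSE)
  row$pval[1] < alpha
}

#' Direction consistency across MR methods
#'
#' \code{TRUE} when every computable method's estimate lies on the same
#' side of the null (all ORs above 1 or all below 1); an exactly zero beta
#' counts as inconsistent. Fewer than two computable methods is
#' indeterminate (\code{NA}).
#'
#' @param fit An [mr_fit()] object or estimates data frame.
#' @return Logical (possibly \code{NA}), with attribute \code{"n_methods"}
#'   giving the number of computable methods compared.
#' @export
direction_consistent <- function(fit) {
  est <- if (inherits(fit, "mr_fit")) fit$estimates else fit
  ok <- est[!is.na(est$beta) & est$status %in% c("ok", NA), ]
  betas <- ok$beta
  if (length(betas) < 2)
    return(structure(NA, n_methods = length(betas)))
  res <- all(betas > 0) || all(betas < 0)
  structure(res, n_methods = length(betas))
}

#' Reverse-direction MR test
#'
#' Screens for reverse causation by running MR in the opposite direction:
#' instruments are selected for the (forward) outcome trait with the same
#' rules as the forward analysis, harmonized against the exposure trait,
#' and the reverse IVW p-value is compared with \code{alpha}. A
#' significant reverse effect flags the exposure for exclusion. When no
#' instruments are selectable for the outcome the test is reported
#' not computable and the exposure is retained.
#'
#' @param outcome_stats Summary statistics of the forward-analysis outcome
#'   (the reverse-direction exposure).
#' @param exposure_stats Summary statistics of the forward-analysis
#'   exposure (the reverse-direction outcome).
#' @param ld,annotations,... Instrument-selection inputs forwarded to
#'   [select_instruments()].
#' @param alpha Reverse-significance threshold (default 0.05).
#' @param harmonize_policy Palindrome policy for the reverse harmonization.
#' @return List \code{(reverse_causal, computable, pval, beta, nsnp)}.
#' @export
reverse_mr <- function(outcome_stats, exposure_stats, ld = NULL,
                       annotations = NULL, alpha = 0.05,
                       harmonize_policy = "drop_all", ...) {
  sel <- select_instruments(outcome_stats, ld = ld,
                            annotations = annotations, ...)
  not_comp <- list(reverse_causal = FALSE, computable = FALSE,
                   pval = NA_real_, beta = NA_real_, nsnp = 0L)
  if (!nrow(sel$instruments)) return(not_comp)
  pairs <- tryCatch(
    harmonize(sel$instruments, exposure_stats, policy = harmonize_policy),
    error = function(e) NULL)
  if (is.null(pairs) || !nrow(pairs) || all(pairs$gamma == 0))
    return(not_comp)
  est <- mr_ivw(suppressWarnings(wald_ratios(pairs)))
  list(reverse_causal = est$pval < alpha, computable = TRUE,
       pval = est$pval, beta = est$beta, nsnp = est$nsnp)
}

#' Exposure-screening cascade
#'
#' Applies, per exposure and in order: (1) IVW significance at
#' \code{alpha}; (2) exclusion when the MR-Egger intercept p-value is below
#' \code{alpha} (horizontal pleiotropy); (3) direction consistency across
#' the computable methods; (4) exclusion of exposures whose reverse MR is
#' significant. The verdict is \code{"retained"} exactly when an exposure
#' passes all four stages; the first failing stage is recorded.
#'
#' @param inputs A named list, one element per exposure, each a list with
#'   components \code{fit} (an [mr_fit()] object or estimates data frame),
#'   optional \code{intercept_pval} (from [egger_intercept_test()] /
#'   [mr_sensitivity()]), and optional \code{reverse} (a [reverse_mr()]
#'   result, already thresholded at its own level). Missing diagnostics
#'   pass their stage.
#' @param alpha Stage-1 IVW significance level (default 0.05). Retention is
#'   monotone in \code{alpha}: relaxing it can only grow the retained set,
#'   since the pleiotropy threshold is separate and reverse flags are
#'   precomputed.
#' @param pleiotropy_alpha Egger-intercept exclusion threshold
#'   (default 0.05).
#' @param p_adjust Multiple-testing mode for stage 1: \code{"none"}
#'   (default, raw p-values), \code{"bonferroni"} or \code{"fdr"} — the
#'   latter two deviate from the plain cascade and are labelled in the
#'   output.
#' @return A data frame of class \code{"screen_decisions"}: one row per
#'   exposure with stage booleans (\code{ivw_significant,
#'   pleiotropy_excluded, direction_consistent, reverse_causal}),
#'   \code{verdict} and \code{excluding_stage}; per-stage counts in
#'   attribute \code{"stage_counts"}.
#' @export
screen_exposures <- function(inputs, alpha = 0.05, pleiotropy_alpha = 0.05,
                             p_adjust = c("none", "bonferroni", "fdr")) {
  p_adjust <- match.arg(p_adjust)
  if (!length(inputs))
    return(structure(data.frame(exposure = character(0)),
                     stage_counts = integer(0),
                     class = c("screen_decisions", "data.frame")))

  get_est <- function(inp)
    if (inherits(inp$fit, "mr_fit")) inp$fit$estimates else inp$fit
  ivw_p <- vapply(inputs, function(inp) {
    est <- get_est(inp)
    est$pval[est$method == "IVW"][1]
  }, numeric(1))
  ivw_p_adj <- if (p_adjust == "none") ivw_p else
    stats::p.adjust(ivw_p, method = ifelse(p_adjust == "fdr", "BH",
                                           p_adjust))

  rows <- lapply(seq_along(inputs), function(i) {
    inp <- inputs[[i]]
    label <- inp$label %||% names(inputs)[i] %||% paste0("exposure_", i)
    sig <- ivw_p_adj[i] < alpha
    pleio <- if (!is.null(inp$intercept_pval) && !is.na(inp$intercept_pval))
      inp$intercept_pval < pleiotropy_alpha else FALSE
    dircon <- direction_consistent(get_est(inp))
    dircon_pass <- !isFALSE(dircon)  # indeterminate (NA) passes, annotated
    rev_flag <- if (!is.null(inp$reverse) && isTRUE(inp$reverse$computable))
      isTRUE(inp$reverse$reverse_causal) else FALSE

    stage <- if (!sig) "ivw_significance"
      else if (pleio) "pleiotropy"
      else if (!dircon_pass) "direction"
      else if (rev_flag) "reverse_mr"
      else NA_character_
    data.frame(exposure = label,
               ivw_pval = ivw_p[i],
               ivw_significant = sig,
               pleiotropy_excluded = pleio,
               direction_consistent = dircon_pass,
               direction_indeterminate = is.na(dircon),
               reverse_causal = rev_flag,
               verdict = ifelse(is.na(stage), "retained", "excluded"),
               excluding_stage = stage,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  counts <- c(input = nrow(out),
              table(factor(out$excluding_stage,
                           levels = c("ivw_significance", "pleiotropy",
                                      "direction", "reverse_mr"))),
              retained = sum(out$verdict == "retained"))
  structure(out, stage_counts = counts, alpha = alpha, p_adjust = p_adjust,
            class = c("screen_decisions", "data.frame"))
}

#' @export
print.screen_decisions <- function(x, ...) {
  cnt <- attr(x, "stage_counts")
  cat(sprintf("Exposure screening cascade (alpha = %g, p_adjust = %s)\n",
              attr(x, "alpha"), attr(x, "p_adjust")))
  cat(sprintf("  %d exposures -> %d retained\n", cnt[["input"]],
              cnt[["retained"]]))
  cat(sprintf("  excluded: %d not IVW-significant, %d pleiotropic, %d direction-inconsistent, %d reverse-causal\n",
              cnt[["ivw_significance"]], cnt[["pleiotropy"]],
              cnt[["direction"]], cnt[["reverse_mr"]]))
  print(utils::head(as.data.frame(x)[, c("exposure", "ivw_pval", "verdict",
                                         "excluding_stage")], 10),
        row.names = FALSE)
  invisible(x)
}
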