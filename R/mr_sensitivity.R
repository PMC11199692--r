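#' Cochran's Q heterogeneity statistic
#'
#' \code{Q = sum(w_j (b_j - beta_ref)^2)} over per-SNP Wald ratios, with an
#' upper-tail chi-square p-value. With \code{beta_ref} the IVW estimate the
#' degrees of freedom are J - 1.
#'
#' @param ratios A [wald_ratios()] data frame (2+ SNPs).
#' @param beta_ref Reference effect; defaults to the IVW estimate.
#' @param df Degrees of freedom; defaults to J - 1.
#' @return A list \code{(q, df, pval)}.
#' @export
cochran_q <- function(ratios, beta_ref = NULL, df = NULL) {
  J <- nrow(ratios)
  if (J < 2)
    stop_no_instruments("Cochran's Q requires at least 2 SNPs (got ", J, ")")
  if (is.null(beta_ref)) beta_ref <- mr_ivw(ratios, effects = "fixed")$beta
  q <- sum(ratios$w * (ratios$b - beta_ref)^2)
  df <- df %||% (J - 1)
  list(q = q, df = df, pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger intercept test for horizontal pleiotropy
#'
#' The intercept of the MR-Egger regression estimates the average direct
#' (pleiotropic) effect of the instruments on the outcome; a two-sided
#' t-test with J - 2 degrees of freedom below 0.05 is taken as evidence of
#' directional horizontal pleiotropy.
#'
#' @param pairs A [harmonize()] result (3+ SNPs).
#' @param alpha Flagging threshold (default 0.05).
#' @return List \code{(intercept, se, pval, pleiotropy_flag)}.
#' @export
egger_intercept_test <- function(pairs, alpha = 0.05) {
  est <- mr_egger(pairs)
  list(intercept = est$intercept, se = est$intercept_se,
       pval = est$intercept_pval,
       pleiotropy_flag = est$intercept_pval < alpha)
}

#' Leave-one-out IVW sensitivity analysis
#'
#' Refits the IVW estimator J times, omitting each SNP in turn, to expose
#' single variants that drive the pooled estimate.
#'
#' @param pairs A [harmonize()] result (2+ SNPs).
#' @param effects IVW effects model passed to [mr_ivw()].
#' @return A data frame (class \code{"mr_loo"}) with one row per omitted
#'   SNP: \code{omitted, beta, se, pval}, plus attributes
#'   \code{full} (the all-SNP IVW estimate), \code{sign_change} and
#'   \code{crosses_alpha} (whether any omission flips the sign of beta or
#'   moves its p-value across 0.05).
#' @export
leave_one_out <- function(pairs, effects = "random") {
  ratios <- wald_ratios(pairs)
  J <- nrow(ratios)
  if (J < 2)
    stop_no_instruments("leave-one-out requires at least 2 SNPs (got ",
                        J, ")")
  full <- mr_ivw(ratios, effects = effects)
  rows <- lapply(seq_len(J), function(k) {
    est <- mr_ivw(ratios[-k, , drop = FALSE], effects = effects)
    data.frame(omitted = ratios$snp_id[k], beta = est$beta, se = est$se,
               pval = est$pval, stringsAsFactors = FALSE)
  })
  loo <- do.call(rbind, rows)
  structure(loo,
            full = full,
            sign_change = any(sign(loo$beta) != sign(full$beta)),
            crosses_alpha = any((loo$pval < 0.05) != (full$pval < 0.05)),
            class = c("mr_loo", "data.frame"))
}

#' Heterogeneity and pleiotropy diagnostics for one exposure-outcome pair
#'
#' Bundles Cochran's Q against the IVW estimate (df J - 1), the
#' Rucker-type Q' from the MR-Egger residuals (df J - 2), the Egger
#' intercept test, and the leave-one-out table. Heterogeneity is flagged
#' when the IVW Q p-value is below \code{alpha}; horizontal pleiotropy when
#' the intercept p-value is.
#'
#' @param pairs A [harmonize()] result.
#' @param alpha Flagging threshold for both tests (default 0.05).
#' @param effects IVW effects model.
#' @return An object of class \code{"mr_sensitivity"}: list with
#'   \code{q_ivw, q_egger} (each \code{(q, df, pval)}), \code{egger}
#'   (intercept test), \code{loo}, and logical flags \code{heterogeneity},
#'   \code{pleiotropy}.
#' @export
mr_sensitivity <- function(pairs, alpha = 0.05, effects = "random") {
  ratios <- wald_ratios(pairs)
  J <- nrow(ratios)
  ivw <- mr_ivw(ratios, effects = effects)
  q_ivw <- cochran_q(ratios, beta_ref = ivw$beta)
  egger <- if (J >= 3) mr_egger(pairs[pairs$gamma != 0, , drop = FALSE]) else NULL
  q_egger <- if (!is.null(egger))
    list(q = egger$q, df = egger$q_df,
         pval = stats::pchisq(egger$q, egger$q_df, lower.tail = FALSE))
  else NULL
  intercept <- if (!is.null(egger))
    list(intercept = egger$intercept, se = egger$intercept_se,
         pval = egger$intercept_pval,
         pleiotropy_flag = egger$intercept_pval < alpha)
  else NULL
  loo <- leave_one_out(pairs, effects = effects)
  structure(list(q_ivw = q_ivw, q_egger = q_egger, egger = intercept,
                 loo = loo, ivw = ivw,
                 heterogeneity = q_ivw$pval < alpha,
                 pleiotropy = if (is.null(intercept)) NA else
                   intercept$pleiotropy_flag,
                 alpha = alpha),
            class = "mr_sensitivity")
}

#' @export
print.mr_sensitivity <- function(x, ...) {
  cat("Sensitivity diagnostics\n")
  cat(sprintf("  Cochran's Q (IVW): %.3f on %d df, p = %.3g%s\n",
              x$q_ivw$q, x$q_ivw$df, x$q_ivw$pval,
              if (x$heterogeneity) "  [heterogeneity]" else ""))
  if (!is.null(x$q_egger))
    cat(sprintf("  Q' (MR-Egger):     %.3f on %d df, p = %.3g\n",
                x$q_egger$q, x$q_egger$df, x$q_egger$pval))
  if (!is.null(x$egger))
    cat(sprintf("  Egger intercept:   %.4g (se %.3g), p = %.3g%s\n",
                x$egger$intercept, x$egger$se, x$egger$pval,
                if (isTRUE(x$pleiotropy)) "  [pleiotropy]" else ""))
  cat(sprintf("  Leave-one-out: sign change %s, p crosses %.2f: %s\n",
              attr(x$loo, "sign_change"), x$alpha,
              attr(x$loo, "crosses_alpha")))
  invisible(x)
}

#' Write a sensitivity report as TSV plus JSON summary
#'
#' @param sens An [mr_sensitivity()] object.
#' @param path_tsv Path for the leave-one-out table.
#' @param path_json Optional path for the one-pair JSON summary.
#' @return \code{path_tsv}, invisibly.
#' @export
write_sensitivity <- function(sens, path_tsv, path_json = NULL) {
  utils::write.table(as.data.frame(sens$loo), path_tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(path_json)) {
    jsonlite::write_json(list(
      q_ivw = sens$q_ivw, q_egger = sens$q_egger, egger = sens$egger,
      heterogeneity = sens$heterogeneity, pleiotropy = sens$pleiotropy
    ), path_json, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path_tsv)
}
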