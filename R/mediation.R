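#' Two-step MR: exposure->mediator and mediator->outcome effects
#'
#' Step 1 estimates the causal effect of the exposure on the mediator
#' (beta1) using instruments selected for the exposure; step 2 estimates
#' the effect of the mediator on the outcome (beta2) using instruments
#' selected independently for the mediator. Both default to the IVW
#' estimator.
#'
#' By default step 2 additionally excludes mediator instruments that reach
#' the exposure's significance threshold in the exposure GWAS. Without
#' this, instruments shared with the exposure act on the outcome through
#' the exposure's direct path as well, and the step-2 estimate is pulled
#' toward the total-over-step-1 ratio instead of the mediator's own
#' effect.
#'
#' @param exposure,mediator,outcome \code{sumstats} tables for the three
#'   traits.
#' @param ld,annotations Instrument-selection inputs (see
#'   [select_instruments()]); applied to both steps.
#' @param p_threshold,r2_max,window_kb,confounder_p,f_min Selection
#'   thresholds.
#' @param method Estimator for both steps (default \code{"ivw"}).
#' @param harmonize_policy Palindromic-SNP policy.
#' @param effects IVW effects model.
#' @param exclude_exposure_snps Drop exposure-significant SNPs from the
#'   step-2 instrument set (default \code{TRUE}).
#' @return List with \code{beta1}, \code{beta2} (each an
#'   \code{mr_estimate}) and the per-step instrument counts; either step
#'   without instruments raises a no-instruments error.
#' @export
two_step_effects <- function(exposure, mediator, outcome, ld = NULL,
                             annotations = NULL, p_threshold = 5e-8,
                             r2_max = 0.001, window_kb = 10000,
                             confounder_p = 1e-5, f_min = 10,
                             method = "ivw",
                             harmonize_policy = "drop_all",
                             effects = "random",
                             exclude_exposure_snps = TRUE) {
  step <- function(from, to, step_name, drop_ids = character(0)) {
    sel <- select_instruments(from, ld = ld, annotations = annotations,
                              p_threshold = p_threshold, r2_max = r2_max,
                              window_kb = window_kb,
                              confounder_p = confounder_p, f_min = f_min)
    if (length(drop_ids)) {
      keep <- !(sel$instruments$snp_id %in% drop_ids)
      sel$instruments <- sel$instruments[keep, , drop = FALSE]
    }
    if (!nrow(sel$instruments))
      stop_no_instruments("no instruments for ", step_name,
                          "; mediation not computable")
    pairs <- harmonize(sel$instruments, to, policy = harmonize_policy)
    if (!nrow(pairs))
      stop_no_instruments("no harmonized SNPs for ", step_name)
    fit <- mr_fit(pairs, methods = method, effects = effects)
    est <- fit$fits[[method]]
    if (!identical(est$status, "ok"))
      stop_no_instruments(step_name, " estimate not computable: ",
                          est$reason)
    est$n_instruments <- nrow(sel$instruments)
    est
  }
  b1 <- step(exposure, mediator, "step 1 (exposure -> mediator)")
  exposure_hits <- if (exclude_exposure_snps)
    exposure$snp_id[exposure$pval < p_threshold] else character(0)
  b2 <- step(mediator, outcome, "step 2 (mediator -> outcome)",
             drop_ids = exposure_hits)
  list(beta1 = b1, beta2 = b2)
}

#' Decompose a total causal effect into mediated and direct parts
#'
#' Product-of-coefficients mediation on the log-odds scale: the mediated
#' (indirect) effect is \code{me = beta1 * beta2}, the direct effect
#' \code{beta3 = beta0 - me}, and the mediated proportion
#' \code{mp = 100 * me / beta0} (percent). The mediated effect's standard
#' error uses the delta method without the cross term,
#' \code{me_se = sqrt(beta1^2 se2^2 + beta2^2 se1^2)}, and its 95% CI is
#' \code{me +/- 1.96 me_se}. The proportion's CI divides the mediated
#' effect's CI endpoints by \code{beta0} and reorders them ascending;
#' uncertainty in \code{beta0} itself is not propagated.
#'
#' @param beta0 Total-effect estimate: an \code{mr_estimate} or a list
#'   with elements \code{beta} and \code{se}.
#' @param beta1,beta2 Step-1 and step-2 estimates in the same form.
#' @param labels Optional named character vector
#'   (\code{exposure, mediator, outcome}).
#' @return An object of class \code{"mr_mediation"}: list with
#'   \code{beta0, beta1, beta2, beta3} (point estimates; input SEs kept
#'   alongside), \code{me, me_se, me_ci}, \code{mp, mp_ci} (percent), and
#'   the labels. \code{beta0 = beta3 + me} holds to machine precision.
#' @examples
#' decompose(beta0 = list(beta = 0.1, se = 0.03),
#'           beta1 = list(beta = 0.2, se = 0.05),
#'           beta2 = list(beta = -0.1, se = 0.03))
#' @export
decompose <- function(beta0, beta1, beta2, labels = NULL) {
  b0 <- beta0$beta; b1 <- beta1$beta; b2 <- beta2$beta
  if (is.null(b0) || is.na(b0) || b0 == 0)
    stop("total effect beta0 is zero or missing: mediated proportion ",
         "undefined", call. = FALSE)
  me <- b1 * b2
  me_se <- sqrt(b1^2 * beta2$se^2 + b2^2 * beta1$se^2)
  me_ci <- c(me - Z95 * me_se, me + Z95 * me_se)
  mp <- 100 * me / b0
  mp_ci <- sort(100 * me_ci / b0)
  structure(list(
    labels = labels %||% c(exposure = "exposure", mediator = "mediator",
                           outcome = "outcome"),
    beta0 = b0, beta0_se = beta0$se,
    beta1 = b1, beta1_se = beta1$se,
    beta2 = b2, beta2_se = beta2$se,
    beta3 = b0 - me,
    me = me, me_se = me_se, me_ci = me_ci,
    mp = mp, mp_ci = mp_ci
  ), class = "mr_mediation")
}

#' @export
print.mr_mediation <- function(x, ...) {
  lab <- x$labels
  cat(sprintf("Two-step MR mediation: %s -> %s -> %s\n",
              lab[["exposure"]], lab[["mediator"]], lab[["outcome"]]))
  cat(sprintf("  total effect      beta0 = %.4g (se %.3g)\n", x$beta0,
              x$beta0_se))
  cat(sprintf("  step 1            beta1 = %.4g (se %.3g)\n", x$beta1,
              x$beta1_se))
  cat(sprintf("  step 2            beta2 = %.4g (se %.3g)\n", x$beta2,
              x$beta2_se))
  cat(sprintf("  mediated effect   %.4g [%.4g, %.4g]\n", x$me, x$me_ci[1],
              x$me_ci[2]))
  cat(sprintf("  direct effect     beta3 = %.4g\n", x$beta3))
  cat(sprintf("  mediated proportion %.3g%% [%.3g%%, %.3g%%]\n", x$mp,
              x$mp_ci[1], x$mp_ci[2]))
  invisible(x)
}

#' Full two-step mediation analysis on three summary-statistic tables
#'
#' Convenience wrapper: estimates the total effect (exposure -> outcome),
#' the two step effects, and decomposes. All three estimates use
#' instruments selected by the same rules.
#'
#' @inheritParams two_step_effects
#' @return An [decompose()] result.
#' @export
mr_mediation <- function(exposure, mediator, outcome, ld = NULL,
                         annotations = NULL, p_threshold = 5e-8,
                         r2_max = 0.001, window_kb = 10000,
                         confounder_p = 1e-5, f_min = 10,
                         harmonize_policy = "drop_all", effects = "random") {
  sel <- select_instruments(exposure, ld = ld, annotations = annotations,
                            p_threshold = p_threshold, r2_max = r2_max,
                            window_kb = window_kb,
                            confounder_p = confounder_p, f_min = f_min)
  if (!nrow(sel$instruments))
    stop_no_instruments("no instruments for the exposure; total effect ",
                        "not computable")
  pairs0 <- harmonize(sel$instruments, outcome, policy = harmonize_policy)
  fit0 <- mr_fit(pairs0, methods = "ivw", effects = effects)
  beta0 <- fit0$fits$ivw
  steps <- two_step_effects(exposure, mediator, outcome, ld = ld,
                            annotations = annotations,
                            p_threshold = p_threshold, r2_max = r2_max,
                            window_kb = window_kb,
                            confounder_p = confounder_p, f_min = f_min,
                            harmonize_policy = harmonize_policy,
                            effects = effects)
  decompose(beta0, steps$beta1, steps$beta2,
            labels = c(exposure = attr(exposure, "trait_label") %||% "exposure",
                       mediator = attr(mediator, "trait_label") %||% "mediator",
                       outcome = attr(outcome, "trait_label") %||% "outcome"))
}

#' Screen candidate mediators against the outcome
#'
#' Retains mediators whose five-method MR against the outcome is
#' IVW-significant and direction-consistent, reusing the screening-stage
#' operations.
#'
#' @param fits Named list of [mr_fit()] objects (or estimates data
#'   frames), one per candidate mediator vs the outcome.
#' @param alpha IVW significance level (default 0.05).
#' @return Character vector of retained mediator names.
#' @export
mediator_screen <- function(fits, alpha = 0.05) {
  if (!length(fits)) return(character(0))
  keep <- vapply(fits, function(f) {
    sig <- tryCatch(ivw_screen(f, alpha = alpha), error = function(e) FALSE)
    sig && isTRUE(direction_consistent(f))
  }, logical(1))
  names(fits)[keep]
}

#' Write a mediation table in the standard layout
#'
#' Columns: exposure, mediator, outcome, mediated effect with CI, mediated
#' proportion (%) with CI, direct effect.
#'
#' @param results A list of [decompose()] results (or a single one).
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_mediation_table <- function(results, path) {
  if (inherits(results, "mr_mediation")) results <- list(results)
  rows <- lapply(results, function(r) {
    data.frame(exposure = r$labels[["exposure"]],
               mediator = r$labels[["mediator"]],
               outcome = r$labels[["outcome"]],
               beta0 = r$beta0, beta1 = r$beta1, beta2 = r$beta2,
               beta3 = r$beta3,
               me = r$me, me_low = r$me_ci[1], me_high = r$me_ci[2],
               mp_pct = r$mp, mp_low_pct = r$mp_ci[1],
               mp_high_pct = r$mp_ci[2],
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
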