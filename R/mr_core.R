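Z95 <- 1.96  # conventional 95% normal quantile used throughout MR reporting

new_mr_estimate <- function(method, beta, se, nsnp, pval,
                            ci_low = beta - Z95 * se,
                            ci_high = beta + Z95 * se,
                            extra = list()) {
  est <- c(list(method = method, nsnp = nsnp, beta = beta, se = se,
                ci_low = ci_low, ci_high = ci_high, pval = pval,
                or = exp(beta), or_low = exp(ci_low), or_high = exp(ci_high)),
           extra)
  class(est) <- "mr_estimate"
  est
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s (%d SNPs): beta %.4g (se %.3g), OR %.3f [%.3f, %.3f], p = %.3g\n",
              x$method, x$nsnp, x$beta, x$se, x$or, x$or_low, x$or_high,
              x$pval))
  if (!is.null(x$intercept))
    cat(sprintf("  intercept %.4g (se %.3g), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_pval))
  invisible(x)
}

#' Per-SNP Wald ratios and inverse-variance weights
#'
#' For each harmonized SNP the Wald ratio \code{b_j = Gamma_j / gamma_j}
#' estimates the causal effect, with first-order standard error
#' \code{s_j = se_Gamma_j / |gamma_j|} (exposure-side uncertainty ignored,
#' the usual two-sample approximation) and weight \code{w_j = 1 / s_j^2}.
#' SNPs with exactly zero exposure effect are dropped with a warning.
#'
#' @param pairs A [harmonize()] result, or any data frame with columns
#'   \code{snp_id, gamma, se_gamma, Gamma, se_Gamma}.
#' @return A data frame of class \code{"ratio_estimates"} with columns
#'   \code{snp_id, b, s, w} plus the originating columns.
#' @export
wald_ratios <- function(pairs) {
  zero <- pairs$gamma == 0
  if (all(zero))
    stop_no_instruments("all exposure effects are zero; no usable instruments")
  if (any(zero)) {
    warning(sum(zero), " SNP(s) with zero exposure effect dropped",
            call. = FALSE)
    pairs <- pairs[!zero, , drop = FALSE]
  }
  out <- data.frame(
    snp_id = pairs$snp_id,
    gamma = pairs$gamma, se_gamma = pairs$se_gamma,
    Gamma = pairs$Gamma, se_Gamma = pairs$se_Gamma,
    b = pairs$Gamma / pairs$gamma,
    s = pairs$se_Gamma / abs(pairs$gamma),
    stringsAsFactors = FALSE
  )
  out$w <- 1 / out$s^2
  rownames(out) <- NULL
  class(out) <- c("ratio_estimates", "data.frame")
  out
}

#' Inverse-variance-weighted (IVW) estimator
#'
#' The inverse-variance-weighted mean of the per-SNP Wald ratios,
#' \code{beta = sum(w b) / sum(w)}; equivalently weighted least squares of
#' \code{Gamma} on \code{gamma} through the origin with weights
#' \code{se_Gamma^-2}. Under the default multiplicative random-effects
#' model the fixed-effect standard error \code{(sum w)^-1/2} is inflated by
#' \code{max(1, sqrt(Q / (J - 1)))}, where Q is Cochran's Q at the
#' estimate, so heterogeneity widens — never narrows — the interval.
#'
#' @param ratios A [wald_ratios()] data frame.
#' @param effects \code{"random"} (multiplicative random effects, default)
#'   or \code{"fixed"}.
#' @return An \code{mr_estimate} (beta, se, 95% CI, two-sided normal p,
#'   OR scale).
#' @export
mr_ivw <- function(ratios, effects = c("random", "fixed")) {
  effects <- match.arg(effects)
  J <- nrow(ratios)
  if (J < 1) stop_no_instruments("IVW requires at least 1 SNP")
  w <- ratios$w
  beta <- sum(w * ratios$b) / sum(w)
  se <- 1 / sqrt(sum(w))
  q <- sum(w * (ratios$b - beta)^2)
  infl <- 1
  if (effects == "random" && J >= 2)
    infl <- max(1, sqrt(q / (J - 1)))
  se <- se * infl
  pval <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate("IVW", beta, se, J, pval,
                  extra = list(q = q, q_df = J - 1, effects = effects,
                               re_inflation = infl))
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome associations on the exposure
#' associations with an unconstrained intercept: the slope is the causal
#' estimate, the intercept the average directional pleiotropy. Each SNP is
#' first oriented so its exposure effect is non-negative (both
#' \code{gamma} and \code{Gamma} negated when \code{gamma < 0}), weights
#' are \code{se_Gamma^-2}, standard errors carry the multiplicative
#' overdispersion factor \code{max(1, sqrt(Q' / (J - 2)))} and p-values use
#' the t distribution with J - 2 degrees of freedom.
#'
#' @param pairs A [harmonize()] result (or compatible data frame).
#' @return An \code{mr_estimate} with extra fields \code{intercept,
#'   intercept_se, intercept_pval, q, q_df}.
#' @export
mr_egger <- function(pairs) {
  J <- nrow(pairs)
  if (J < 3)
    stop_no_instruments("MR-Egger requires at least 3 SNPs (got ", J, ")")
  flip <- pairs$gamma < 0
  x <- ifelse(flip, -pairs$gamma, pairs$gamma)
  y <- ifelse(flip, -pairs$Gamma, pairs$Gamma)
  w <- 1 / pairs$se_Gamma^2

  # weighted normal equations, explicit to keep lm() free as a test oracle
  X <- cbind(intercept = 1, slope = x)
  XtWX <- crossprod(X, w * X)
  coefs <- solve(XtWX, crossprod(X, w * y))
  resid <- y - X %*% coefs
  qprime <- sum(w * resid^2)
  overdisp <- max(1, sqrt(qprime / (J - 2)))
  se <- sqrt(diag(solve(XtWX))) * overdisp

  slope <- unname(coefs["slope", 1])
  slope_se <- unname(se[["slope"]])
  inter <- unname(coefs["intercept", 1])
  inter_se <- unname(se[["intercept"]])
  pv <- function(est, s) 2 * stats::pt(-abs(est / s), df = J - 2)

  new_mr_estimate("MR-Egger", slope, slope_se, J, pv(slope, slope_se),
                  extra = list(intercept = inter, intercept_se = inter_se,
                               intercept_pval = pv(inter, inter_se),
                               q = qprime, q_df = J - 2))
}

# weighted-median point estimate on ratio vectors (shared with bootstrap)
weighted_median_point <- function(b, w) {
  ord <- order(b)
  b <- b[ord]; w <- w[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (s[1] >= 0.5) return(b[1])
  if (s[length(s)] <= 0.5) return(b[length(b)])
  stats::approx(s, b, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimator
#'
#' The median of the inverse-variance-weighted empirical distribution of
#' per-SNP Wald ratios: ratios are sorted, standardized cumulative weights
#' \code{s_k = (cumsum(w) - w/2) / sum(w)} computed, and the estimate is
#' the linear interpolation of the ratio across \code{s} at 0.5. Consistent
#' when at least half the weight comes from valid instruments. The standard
#' error comes from a parametric bootstrap: ratios are resampled
#' \code{b_j* ~ Normal(b_j, s_j)} with weights fixed, \code{n_boot} times.
#'
#' @param ratios A [wald_ratios()] data frame (3+ SNPs).
#' @param n_boot Bootstrap replicates for the SE (default 1000).
#' @param seed Optional seed making the bootstrap reproducible.
#' @return An \code{mr_estimate}.
#' @export
mr_weighted_median <- function(ratios, n_boot = 1000, seed = NULL) {
  J <- nrow(ratios)
  if (J < 3)
    stop_no_instruments("weighted median requires at least 3 SNPs (got ",
                        J, ")")
  beta <- weighted_median_point(ratios$b, ratios$w)
  se <- boot_se(function(b) weighted_median_point(b, ratios$w),
                ratios$b, ratios$s, n_boot, seed)
  pval <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate("Weighted median", beta, se, J, pval)
}

boot_se <- function(point_fun, b, s, n_boot, seed) {
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  reps <- vapply(seq_len(n_boot), function(i) {
    point_fun(stats::rnorm(length(b), b, s))
  }, numeric(1))
  stats::sd(reps)
}

mode_point <- function(b, w_norm, phi, grid_n = 512) {
  spread <- min(stats::sd(b), stats::IQR(b) / 1.349)
  h <- phi * 0.9 * spread * length(b)^(-1 / 5)
  if (!is.finite(h) || h <= 0) return(b[1])  # all ratios identical
  grid <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = grid_n)
  kern <- stats::dnorm(outer(grid, b, "-") / h) / h  # grid_n x J
  dens <- as.vector(kern %*% w_norm)
  grid[which.max(dens)]
}

#' Mode-based estimators (weighted and simple)
#'
#' The mode of the smoothed empirical density of per-SNP Wald ratios:
#' a Gaussian kernel with bandwidth
#' \code{h = phi * 0.9 * min(sd(b), IQR(b)/1.349) * J^(-1/5)} is placed on
#' each ratio, weighted by normalized inverse-variance weights (weighted
#' mode) or uniformly (simple mode), and the estimate is the argmax of the
#' mixture density on a 512-point grid spanning
#' \code{[min(b) - 3h, max(b) + 3h]} (the grid step bounds the resolution
#' of the estimate). Consistent when the largest group of instruments
#' sharing one ratio value is valid (plurality validity). SE by the same
#' parametric bootstrap as the weighted median.
#'
#' @param ratios A [wald_ratios()] data frame (3+ SNPs).
#' @param weighted Use inverse-variance weights (\code{TRUE}, the weighted
#'   mode) or uniform weights (the simple mode).
#' @param phi Bandwidth multiplier, > 0 (default 1).
#' @param n_boot,seed Bootstrap controls as in [mr_weighted_median()].
#' @param grid_n Density grid size (default 512).
#' @return An \code{mr_estimate}.
#' @export
mr_mode <- function(ratios, weighted = TRUE, phi = 1, n_boot = 1000,
                    seed = NULL, grid_n = 512) {
  J <- nrow(ratios)
  if (J < 3)
    stop_no_instruments("mode estimator requires at least 3 SNPs (got ",
                        J, ")")
  if (phi <= 0) stop_config("phi must be > 0 (got ", phi, ")")
  w_norm <- if (weighted) ratios$w / sum(ratios$w) else rep(1 / J, J)
  beta <- mode_point(ratios$b, w_norm, phi, grid_n)
  se <- boot_se(function(b) mode_point(b, w_norm, phi, grid_n),
                ratios$b, ratios$s, n_boot, seed)
  pval <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate(if (weighted) "Weighted mode" else "Simple mode",
                  beta, se, J, pval)
}
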