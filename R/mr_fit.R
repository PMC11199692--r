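MR_METHODS <- c("ivw", "egger", "weighted_median", "weighted_mode",
                "simple_mode")
MR_MIN_SNPS <- c(ivw = 1L, egger = 3L, weighted_median = 3L,
                 weighted_mode = 3L, simple_mode = 3L)
MR_LABELS <- c(ivw = "IVW", egger = "MR-Egger",
               weighted_median = "Weighted median",
               weighted_mode = "Weighted mode", simple_mode = "Simple mode")

#' Fit two-sample Mendelian-randomization models
#'
#' The central fitting function: computes per-SNP Wald ratios from
#' harmonized exposure/outcome associations and applies up to five
#' estimators — IVW (the primary, most efficient under valid instruments),
#' MR-Egger (allows directional pleiotropy under InSIDE), weighted median
#' (majority validity), and the weighted and simple modes (plurality
#' validity). Methods whose minimum instrument count is not met (3 for all
#' but IVW) are reported as not computable rather than errored, so
#' large screens over many exposures run unattended.
#'
#' @param pairs A [harmonize()] result (or data frame with columns
#'   \code{snp_id, gamma, se_gamma, Gamma, se_Gamma}).
#' @param methods Subset of \code{c("ivw", "egger", "weighted_median",
#'   "weighted_mode", "simple_mode")}; defaults to all five.
#' @param effects IVW effects model, \code{"random"} or \code{"fixed"}.
#' @param n_boot Parametric-bootstrap replicates for median/mode SEs.
#' @param phi Mode bandwidth multiplier.
#' @param seed Seed for the bootstrap streams; each method gets a
#'   deterministic sub-seed so results are bit-reproducible.
#' @return An object of class \code{"mr_fit"}: a list with
#'   \code{estimates} (one row per method: method, nsnp, beta, se, ci_low,
#'   ci_high, pval, or, or_low, or_high, intercept columns for MR-Egger,
#'   and \code{status}/"reason" for non-computable methods),
#'   \code{ratios}, \code{pairs}, and the call parameters. Methods:
#'   \code{print}, \code{summary}, \code{coef}, \code{confint},
#'   \code{plot}.
#' @examples
#' trip <- simulate_triple(sim_config(n_snps = 30, seed = 2))
#' fit <- mr_fit(harmonize(trip$exposure, trip$outcome), seed = 2)
#' fit
#' coef(fit)
#' @export
mr_fit <- function(pairs, methods = MR_METHODS,
                   effects = c("random", "fixed"),
                   n_boot = 1000, phi = 1, seed = NULL) {
  methods <- match.arg(methods, MR_METHODS, several.ok = TRUE)
  effects <- match.arg(effects)
  if (!nrow(pairs)) stop_no_instruments("no harmonized SNPs to fit")
  ratios <- wald_ratios(pairs)
  pairs_nz <- pairs[pairs$gamma != 0, , drop = FALSE]
  J <- nrow(ratios)

  ests <- vector("list", length(methods))
  names(ests) <- methods
  for (m in methods) {
    if (J < MR_MIN_SNPS[[m]]) {
      ests[[m]] <- list(method = MR_LABELS[[m]], nsnp = J, status = "not_computable",
                        reason = sprintf("requires >= %d SNPs, have %d",
                                         MR_MIN_SNPS[[m]], J))
      next
    }
    sub_seed <- if (is.null(seed)) NULL else derive_seed(seed, m)
    est <- switch(m,
      ivw = mr_ivw(ratios, effects = effects),
      egger = mr_egger(pairs_nz),
      weighted_median = mr_weighted_median(ratios, n_boot = n_boot,
                                           seed = sub_seed),
      weighted_mode = mr_mode(ratios, weighted = TRUE, phi = phi,
                              n_boot = n_boot, seed = sub_seed),
      simple_mode = mr_mode(ratios, weighted = FALSE, phi = phi,
                            n_boot = n_boot, seed = sub_seed))
    est$status <- "ok"
    ests[[m]] <- est
  }

  cols <- c("method", "nsnp", "beta", "se", "ci_low", "ci_high", "pval",
            "or", "or_low", "or_high", "intercept", "intercept_se",
            "intercept_pval", "status", "reason")
  rows <- lapply(ests, function(e) {
    vals <- lapply(cols, function(cn) {
      v <- e[[cn]]
      if (is.null(v)) {
        if (cn %in% c("method", "status", "reason")) NA_character_
        else NA_real_
      } else v
    })
    names(vals) <- cols
    as.data.frame(vals, stringsAsFactors = FALSE)
  })
  estimates <- do.call(rbind, rows)
  rownames(estimates) <- NULL

  structure(list(estimates = estimates, fits = ests, ratios = ratios,
                 pairs = pairs, effects = effects, n_boot = n_boot,
                 phi = phi, seed = seed,
                 trait_labels = attr(pairs, "trait_labels")),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  lab <- x$trait_labels
  if (!is.null(lab))
    cat(sprintf("Two-sample MR: %s -> %s\n", lab[["exposure"]],
                lab[["outcome"]]))
  else cat("Two-sample MR fit\n")
  cat(sprintf("  %d instruments; IVW effects model: %s\n",
              nrow(x$ratios), x$effects))
  est <- x$estimates
  show <- est[, c("method", "nsnp", "beta", "se", "or", "or_low", "or_high",
                  "pval")]
  for (cn in c("beta", "se", "or", "or_low", "or_high", "pval"))
    show[[cn]] <- signif(show[[cn]], digits)
  print(show, row.names = FALSE)
  nc <- est[est$status == "not_computable", ]
  if (nrow(nc))
    cat("  not computable:",
        paste(sprintf("%s (%s)", nc$method, nc$reason), collapse = "; "),
        "\n")
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  est <- object$estimates
  stats::setNames(est$beta, est$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  est <- object$estimates
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(low = est$beta - z * est$se, high = est$beta + z * est$se)
  rownames(out) <- est$method
  out
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object,
                 sens = tryCatch(mr_sensitivity(object$pairs),
                                 error = function(e) NULL)),
            class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$sens)) {
    cat("\n")
    print(x$sens)
  }
  invisible(x)
}

#' Scatter plot of a two-sample MR fit
#'
#' Outcome associations against exposure associations with per-SNP error
#' bars and the fitted IVW (through the origin) and MR-Egger lines.
#'
#' @param x An [mr_fit()] object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mr_fit <- function(x, ...) {
  p <- x$pairs
  flip <- p$gamma < 0
  gx <- ifelse(flip, -p$gamma, p$gamma)
  gy <- ifelse(flip, -p$Gamma, p$Gamma)
  graphics::plot(gx, gy, pch = 19, cex = 0.6,
                 xlab = "SNP effect on exposure",
                 ylab = "SNP effect on outcome", ...)
  graphics::segments(gx, gy - Z95 * p$se_Gamma, gx, gy + Z95 * p$se_Gamma,
                     col = "grey60")
  est <- x$estimates
  ivw <- est[est$method == "IVW", ]
  if (nrow(ivw) && !is.na(ivw$beta))
    graphics::abline(0, ivw$beta, col = "firebrick", lwd = 2)
  egg <- est[est$method == "MR-Egger", ]
  if (nrow(egg) && !is.na(egg$beta))
    graphics::abline(egg$intercept, egg$beta, col = "steelblue",
                     lwd = 2, lty = 2)
  graphics::legend("topleft", legend = c("IVW", "MR-Egger"),
                   col = c("firebrick", "steelblue"), lty = c(1, 2),
                   lwd = 2, bty = "n")
  invisible(x)
}

#' Forest plot of MR estimates
#'
#' One row per method, point estimate and 95% CI on the odds-ratio scale.
#'
#' @param fit An [mr_fit()] object.
#' @param ... Passed to [graphics::plot()].
#' @export
mr_forest_plot <- function(fit, ...) {
  est <- fit$estimates[fit$estimates$status == "ok", ]
  if (!nrow(est)) stop("nothing to plot", call. = FALSE)
  k <- nrow(est)
  graphics::plot(est$or, seq_len(k), xlim = range(est$or_low, est$or_high),
                 ylim = c(0.5, k + 0.5), pch = 18, yaxt = "n",
                 xlab = "Odds ratio (95% CI)", ylab = "", ...)
  graphics::segments(est$or_low, seq_len(k), est$or_high, seq_len(k))
  graphics::abline(v = 1, lty = 3, col = "grey50")
  graphics::axis(2, at = seq_len(k), labels = est$method, las = 1,
                 cex.axis = 0.8)
  invisible(fit)
}

#' Write an estimates table in the tidy TSV layout
#'
#' Columns: exposure, outcome, method, nsnp, beta, se, ci_low, ci_high,
#' pval, or, or_low, or_high — the usual forest-plot columns.
#'
#' @param fit An [mr_fit()] object.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_mr_estimates <- function(fit, path) {
  lab <- fit$trait_labels %||% c(exposure = "exposure", outcome = "outcome")
  est <- fit$estimates
  out <- cbind(data.frame(exposure = lab[["exposure"]],
                          outcome = lab[["outcome"]],
                          stringsAsFactors = FALSE),
               est[, c("method", "nsnp", "beta", "se", "ci_low", "ci_high",
                       "pval", "or", "or_low", "or_high")])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
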