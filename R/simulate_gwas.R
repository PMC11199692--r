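# Deterministic genomic layout shared by simulate_triple() and ld_matrix():
# LD blocks are contiguous runs of SNPs on chromosome 1, spaced 20,000 kb
# apart so cross-block distances always exceed the 10,000 kb clump window,
# while SNPs within a block sit 1 kb apart.
ld_layout <- function(n_snps, n_ld_blocks) {
  block <- rep(seq_len(n_ld_blocks), each = ceiling(n_snps / n_ld_blocks),
               length.out = n_snps)
  within <- stats::ave(seq_len(n_snps), block, FUN = seq_along)
  data.frame(
    snp_id = sprintf("snp_%04d", seq_len(n_snps)),
    chrom = "1",
    pos = (block - 1L) * 2e7 + (within - 1L) * 1000L + 1L,
    block = block,
    stringsAsFactors = FALSE
  )
}

#' Simulate a harmonizable exposure/mediator/outcome GWAS triple
#'
#' Generates three summary-statistic tables over a shared SNP panel under the
#' causal model of [sim_config()]. Per SNP j with exposure-instrument
#' effect \eqn{\gamma_j}{gamma_j} and mediator-specific effect
#' \eqn{\delta_j}{delta_j} (nonzero on disjoint SNP subsets): the
#' mediator's true effect is
#' \eqn{\beta_1 \gamma_j + \delta_j}{beta1*gamma_j + delta_j} and the
#' outcome's is \eqn{\beta_{direct}\gamma_j + \beta_2(\beta_1\gamma_j +
#' \delta_j) + \alpha_j}{beta_direct*gamma_j + beta2*(beta1*gamma_j +
#' delta_j) + alpha_j}, where \eqn{\alpha_j}{alpha_j} is the direct
#' (pleiotropic) effect on the outcome. Mediator-specific instruments are
#' what make the second step of two-step mediation identifiable: a SNP
#' acting on the outcome only through the mediator carries the Wald ratio
#' \eqn{\beta_2}{beta2}, whereas exposure instruments carry the total
#' effect. Estimated
#' effects are the true values plus Gaussian noise whose SD equals the
#' reported standard error \code{1/sqrt(2 n maf (1-maf))}.
#'
#' Simulation works directly on the summary level (no individual-level
#' genotypes): that is sufficient for every estimator operating on summary
#' data and orders of magnitude faster.
#'
#' @param config A [sim_config()] object.
#' @return A list of class \code{"sim_triple"} with elements
#'   \code{exposure}, \code{mediator}, \code{outcome} (each a
#'   \code{sumstats} data frame, see [read_sumstats()]) and \code{truth}, a
#'   list carrying the per-SNP true effects (\code{gamma}, \code{delta},
#'   \code{alpha}), the \code{mediator_specific} indicator, the config,
#'   and the derived true mediated (\code{true_beta1 * true_beta2}) and
#'   direct effects.
#' @examples
#' trip <- simulate_triple(sim_config(n_snps = 20, seed = 7))
#' head(trip$exposure)
#' trip$truth$beta_mediated
#' @export
simulate_triple <- function(config) {
  validate_sim_config(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  n <- config$n_snps
  lay <- ld_layout(n, config$n_ld_blocks)

  n_pal <- round(config$palindromic_frac * n)
  pal <- rep(FALSE, n)
  if (n_pal > 0) pal[sample.int(n, n_pal)] <- TRUE

  pairs_np <- matrix(c("A", "G", "C", "T", "A", "C", "G", "T"),
                     ncol = 2, byrow = TRUE)
  pairs_pal <- matrix(c("A", "T", "C", "G"), ncol = 2, byrow = TRUE)
  idx_np <- sample.int(nrow(pairs_np), n, replace = TRUE)
  idx_pal <- sample.int(nrow(pairs_pal), n, replace = TRUE)
  ea <- ifelse(pal, pairs_pal[idx_pal, 1], pairs_np[idx_np, 1])
  oa <- ifelse(pal, pairs_pal[idx_pal, 2], pairs_np[idx_np, 2])

  eaf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
  # palindromic SNPs get intermediate frequencies so drop policies matter
  eaf[pal] <- stats::runif(sum(pal), 0.45, 0.55)
  maf <- pmin(eaf, 1 - eaf)

  gamma <- stats::rnorm(n, 0, config$gamma_scale)
  # mediator-specific instruments: zero exposure effect, own mediator effect
  n_med <- round(config$mediator_snp_frac * n)
  med_specific <- rep(FALSE, n)
  if (n_med > 0) med_specific[sample.int(n, n_med)] <- TRUE
  gamma[med_specific] <- 0
  delta <- rep(0, n)
  delta[med_specific] <- stats::rnorm(n_med, 0, config$delta_scale)
  alpha <- switch(config$pleiotropy_mode,
                  none = rep(0, n),
                  balanced = stats::rnorm(n, 0, config$pleiotropy_sd),
                  directional = stats::rnorm(n, config$pleiotropy_mean,
                                             config$pleiotropy_sd))

  beta_mediated <- config$true_beta1 * config$true_beta2
  beta_direct <- config$true_beta_total - beta_mediated
  true_exp <- gamma
  true_med <- config$true_beta1 * gamma + delta
  # directional pleiotropy acts on the exposure-increasing allele: that is
  # the orientation in which the Egger intercept measures average direct
  # effects, so alpha is aligned with sign(gamma) (symmetric modes are
  # unaffected)
  alpha_oriented <- ifelse(gamma < 0, -alpha, alpha)
  true_out <- beta_direct * gamma + config$true_beta2 * true_med +
    alpha_oriented

  mk <- function(true_beta, n_gwas, label) {
    se <- 1 / sqrt(2 * n_gwas * maf * (1 - maf))
    beta <- true_beta + stats::rnorm(n, 0, se)
    pval <- pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin)
    as_sumstats(data.frame(
      snp_id = lay$snp_id, chrom = lay$chrom, pos = lay$pos,
      effect_allele = ea, other_allele = oa, eaf = eaf,
      beta = beta, se = se, pval = pval, n = n_gwas,
      stringsAsFactors = FALSE
    ), trait_label = label)
  }

  out <- list(
    exposure = mk(true_exp, config$n_exposure, "exposure"),
    mediator = mk(true_med, config$n_mediator, "mediator"),
    outcome = mk(true_out, config$n_outcome, "outcome"),
    truth = list(
      snp_id = lay$snp_id, gamma = gamma, delta = delta, alpha = alpha,
      mediator_specific = med_specific,
      block = lay$block, palindromic = pal,
      config = config,
      beta_mediated = beta_mediated,
      beta_direct = beta_direct
    )
  )
  class(out) <- "sim_triple"
  out
}

#' Pairwise LD r-squared matrix for a simulated SNP panel
#'
#' Block-diagonal LD: SNPs in the same block share
#' \code{within_block_r2}; SNPs in different blocks have r-squared 0. The
#' layout is deterministic given \code{n_snps} and \code{n_ld_blocks} and
#' matches [simulate_triple()] positions, with same-block SNPs < 10,000 kb
#' apart and different blocks >= 10,000 kb apart.
#'
#' @param config A [sim_config()] object.
#' @return A symmetric numeric matrix with unit diagonal and SNP ids as
#'   dimnames; SNP chromosome/position metadata attached as attribute
#'   \code{"layout"}.
#' @export
ld_matrix <- function(config) {
  validate_sim_config(config)
  lay <- ld_layout(config$n_snps, config$n_ld_blocks)
  same_block <- outer(lay$block, lay$block, "==")
  r2 <- ifelse(same_block, config$within_block_r2, 0)
  diag(r2) <- 1
  dimnames(r2) <- list(lay$snp_id, lay$snp_id)
  attr(r2, "layout") <- lay[, c("snp_id", "chrom", "pos")]
  r2
}

#' @export
print.sim_triple <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("Simulated GWAS triple: %d SNPs (seed %d)\n",
              cfg$n_snps, cfg$seed))
  cat(sprintf("  true total effect %g (direct %g, mediated %g)\n",
              cfg$true_beta_total, x$truth$beta_direct, x$truth$beta_mediated))
  cat(sprintf("  pleiotropy: %s; %d palindromic SNP(s)\n",
              cfg$pleiotropy_mode, sum(x$truth$palindromic)))
  invisible(x)
}

# save/restore the global RNG state so simulation calls are self-contained
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
}
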