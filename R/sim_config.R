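#' Simulation configuration for summary-level GWAS triples
#'
#' Defines the causal scenario under which [simulate_triple()] generates
#' exposure, mediator and outcome GWAS summary statistics. The causal graph is
#' exposure -> mediator -> outcome plus a direct exposure -> outcome path:
#' the total effect \code{true_beta_total} decomposes as
#' \code{true_beta_total = beta_direct + true_beta1 * true_beta2}.
#'
#' Instrument effects on the exposure are drawn Normal(0, \code{gamma_scale}^2)
#' on a per-allele standardized-trait scale. Reported standard errors follow
#' the standard summary-statistic approximation
#' \code{1 / sqrt(2 * n * maf * (1 - maf))}, so instrument strength
#' (F-statistics) is controlled through the GWAS sample sizes.
#'
#' @param n_snps Number of candidate instrument SNPs (>= 1).
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes (>= 2). The
#'   outcome default (6000) is the effective sample size typical of a
#'   case-control disease GWAS with a few thousand cases, so the outcome
#'   trait — like a rare cancer — has essentially no genome-wide
#'   significant hits of its own and reverse-direction instrument
#'   selection behaves as it does on real disease outcomes.
#' @param true_beta_total Total causal effect of exposure on outcome
#'   (log-odds per exposure unit).
#' @param true_beta1 Exposure -> mediator causal effect.
#' @param true_beta2 Mediator -> outcome causal effect.
#' @param gamma_scale SD of the true per-SNP instrument-exposure effects.
#' @param mediator_snp_frac Fraction of the panel that are
#'   mediator-specific instruments: these SNPs have zero exposure effect
#'   and a direct mediator effect drawn Normal(0, \code{delta_scale}^2),
#'   mimicking the trait-specific loci (e.g. cis enzyme variants) that
#'   dominate metabolite GWAS. Set to 0 for a panel of pure exposure
#'   instruments.
#' @param delta_scale SD of the mediator-specific effects; defaults larger
#'   than \code{gamma_scale} because mediator-specific loci typically
#'   carry bigger per-allele effects than trans effects routed through an
#'   upstream exposure.
#' @param pleiotropy_mode One of \code{"none"}, \code{"balanced"},
#'   \code{"directional"}: distribution of direct SNP -> outcome effects.
#' @param pleiotropy_sd,pleiotropy_mean Parameters of the direct-effect
#'   distribution; both must be 0 when \code{pleiotropy_mode = "none"};
#'   \code{pleiotropy_mean} must be 0 when balanced.
#' @param maf_range Interval in (0, 0.5] from which effect-allele
#'   frequencies are drawn uniformly.
#' @param palindromic_frac Fraction of SNPs assigned A/T or C/G allele
#'   pairs (these get EAF near 0.5 so harmonization drop policies are
#'   exercised).
#' @param n_ld_blocks,within_block_r2 LD structure: SNPs within a block
#'   share pairwise r-squared \code{within_block_r2}; cross-block r-squared
#'   is 0. Blocks are placed >= 10,000 kb apart.
#' @param seed RNG seed for reproducibility.
#'
#' @return An object of class \code{"sim_config"} (a validated list).
#' @seealso [simulate_triple()], [ld_matrix()]
#' @export
sim_config <- function(n_snps = 100,
                       n_exposure = 1e5, n_mediator = 1e5, n_outcome = 6000,
                       true_beta_total = 0.1,
                       true_beta1 = 0.2, true_beta2 = -0.1,
                       gamma_scale = 0.3,
                       mediator_snp_frac = 0.3, delta_scale = 0.7,
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleiotropy_sd = 0, pleiotropy_mean = 0,
                       maf_range = c(0.05, 0.5),
                       palindromic_frac = 0.1,
                       n_ld_blocks = 1, within_block_r2 = 0,
                       seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  cfg <- list(n_snps = as.integer(n_snps),
              n_exposure = n_exposure, n_mediator = n_mediator,
              n_outcome = n_outcome,
              true_beta_total = true_beta_total,
              true_beta1 = true_beta1, true_beta2 = true_beta2,
              gamma_scale = gamma_scale,
              mediator_snp_frac = mediator_snp_frac,
              delta_scale = delta_scale,
              pleiotropy_mode = pleiotropy_mode,
              pleiotropy_sd = pleiotropy_sd,
              pleiotropy_mean = pleiotropy_mean,
              maf_range = maf_range,
              palindromic_frac = palindromic_frac,
              n_ld_blocks = as.integer(n_ld_blocks),
              within_block_r2 = within_block_r2,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_snps < 1L)
    stop_config("n_snps must be >= 1 (got ", cfg$n_snps, ")")
  for (f in c("n_exposure", "n_mediator", "n_outcome"))
    if (cfg[[f]] < 2)
      stop_config(f, " must be >= 2 (got ", cfg[[f]], ")")
  mr <- cfg$maf_range
  if (length(mr) != 2 || mr[1] <= 0 || mr[2] > 0.5 || mr[1] > mr[2])
    stop_config("maf_range must be an interval within (0, 0.5] (got [",
                mr[1], ", ", mr[2], "])")
  if (cfg$palindromic_frac < 0 || cfg$palindromic_frac > 1)
    stop_config("palindromic_frac must be in [0, 1] (got ",
                cfg$palindromic_frac, ")")
  if (cfg$within_block_r2 < 0 || cfg$within_block_r2 > 1)
    stop_config("within_block_r2 must be in [0, 1] (got ",
                cfg$within_block_r2, ")")
  if (cfg$gamma_scale < 0)
    stop_config("gamma_scale must be >= 0 (got ", cfg$gamma_scale, ")")
  if (cfg$mediator_snp_frac < 0 || cfg$mediator_snp_frac > 1)
    stop_config("mediator_snp_frac must be in [0, 1] (got ",
                cfg$mediator_snp_frac, ")")
  if (cfg$delta_scale < 0)
    stop_config("delta_scale must be >= 0 (got ", cfg$delta_scale, ")")
  if (cfg$n_ld_blocks < 1L)
    stop_config("n_ld_blocks must be >= 1 (got ", cfg$n_ld_blocks, ")")
  if (cfg$pleiotropy_mode == "none" &&
      (cfg$pleiotropy_sd != 0 || cfg$pleiotropy_mean != 0))
    stop_config("pleiotropy_mode = 'none' requires pleiotropy_sd = ",
                "pleiotropy_mean = 0")
  if (cfg$pleiotropy_mode == "balanced" && cfg$pleiotropy_mean != 0)
    stop_config("pleiotropy_mode = 'balanced' requires pleiotropy_mean = 0")
  if (cfg$pleiotropy_sd < 0)
    stop_config("pleiotropy_sd must be >= 0 (got ", cfg$pleiotropy_sd, ")")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("GWAS triple simulation config\n")
  cat(sprintf("  %d SNPs in %d LD block(s) (within-block r2 = %g)\n",
              x$n_snps, x$n_ld_blocks, x$within_block_r2))
  cat(sprintf("  n: exposure %g, mediator %g, outcome %g\n",
              x$n_exposure, x$n_mediator, x$n_outcome))
  cat(sprintf("  truth: total %g = direct %g + (%g x %g) mediated\n",
              x$true_beta_total,
              x$true_beta_total - x$true_beta1 * x$true_beta2,
              x$true_beta1, x$true_beta2))
  cat(sprintf("  pleiotropy: %s (mean %g, sd %g); palindromic_frac %g; seed %d\n",
              x$pleiotropy_mode, x$pleiotropy_mean, x$pleiotropy_sd,
              x$palindromic_frac, x$seed))
  invisible(x)
}
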