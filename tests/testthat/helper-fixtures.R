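# Build a harmonized-pairs-like data frame whose Wald ratios and ratio SEs
# are exactly the supplied b and s: Gamma = b * gamma, se_Gamma = s * |gamma|
# reproduces (b, s) for any nonzero gamma. Default gammas vary so
# regression-based methods (Egger) have a nondegenerate design.
pairs_from_ratios <- function(b, s,
                              gamma = seq(0.5, 1.5,
                                          length.out = length(b)),
                              se_gamma = rep(1e-6, length(b))) {
  data.frame(snp_id = sprintf("snp_%02d", seq_along(b)),
             gamma = gamma, se_gamma = se_gamma,
             Gamma = b * gamma, se_Gamma = s * abs(gamma),
             stringsAsFactors = FALSE)
}

# Random harmonized pairs around a true slope, for oracle comparisons.
random_pairs <- function(J, seed, slope = 0.3, intercept = 0,
                         noise = 0.02) {
  set.seed(seed)
  gamma <- runif(J, 0.05, 0.4)
  se_Gamma <- runif(J, 0.01, 0.05)
  data.frame(snp_id = sprintf("snp_%02d", seq_len(J)),
             gamma = gamma, se_gamma = runif(J, 0.005, 0.02),
             Gamma = intercept + slope * gamma + rnorm(J, 0, noise),
             se_Gamma = se_Gamma,
             stringsAsFactors = FALSE)
}

# Minimal sumstats table builder for IO / filter tests.
toy_sumstats <- function(snp_id, pval = NULL, beta = 0.1, se = 0.01,
                         chrom = "1", pos = NULL,
                         ea = "A", oa = "G", eaf = 0.3, n = 1000,
                         label = "toy") {
  k <- length(snp_id)
  rec <- function(x) rep_len(x, k)
  if (is.null(pos)) pos <- seq_len(k) * 1000L
  if (is.null(pval)) pval <- rec(1e-10)
  as_sumstats(data.frame(
    snp_id = snp_id, chrom = rec(chrom), pos = pos,
    effect_allele = rec(ea), other_allele = rec(oa), eaf = rec(eaf),
    beta = rec(beta), se = rec(se), pval = pval, n = rec(n),
    stringsAsFactors = FALSE), trait_label = label)
}

# estimates data frame shaped like mr_fit()$estimates, for screening tests
fake_estimates <- function(betas, ivw_pval = 0.01,
                           methods = c("IVW", "MR-Egger", "Weighted median",
                                       "Weighted mode", "Simple mode")) {
  k <- length(betas)
  data.frame(method = methods[seq_len(k)], nsnp = 10L, beta = betas,
             se = 0.05, ci_low = betas - 0.1, ci_high = betas + 0.1,
             pval = c(ivw_pval, rep(0.2, k - 1)),
             or = exp(betas), or_low = exp(betas - 0.1),
             or_high = exp(betas + 0.1),
             intercept = NA_real_, intercept_se = NA_real_,
             intercept_pval = NA_real_,
             status = "ok", reason = NA_character_,
             stringsAsFactors = FALSE)
}
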