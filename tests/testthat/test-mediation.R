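test_that("decompose matches the hand-computed delta-method example", {
  res <- decompose(beta0 = list(beta = 0.1, se = 0.03),
                   beta1 = list(beta = 0.2, se = 0.05),
                   beta2 = list(beta = -0.1, se = 0.03))
  expect_equal(res$me, -0.02, tolerance = 1e-12)
  expect_equal(res$me_se, sqrt(0.2^2 * 0.03^2 + 0.1^2 * 0.05^2),
               tolerance = 1e-12)
  expect_equal(res$me_se, 0.007810, tolerance = 1e-4)
  expect_equal(res$me_ci, c(-0.03531, -0.004693), tolerance = 1e-3)
  expect_equal(res$mp, -20, tolerance = 1e-12)
  expect_equal(res$mp_ci, c(-35.31, -4.693), tolerance = 1e-3)
  expect_equal(res$beta3, 0.12, tolerance = 1e-12)
})

test_that("a zero mediated effect leaves the whole total effect direct", {
  res <- decompose(beta0 = list(beta = 0.1, se = 0.03),
                   beta1 = list(beta = 0, se = 0.05),
                   beta2 = list(beta = -0.1, se = 0.03))
  expect_equal(res$mp, 0)
  expect_equal(res$beta3, 0.1)
  expect_error(decompose(beta0 = list(beta = 0, se = 0.01),
                         beta1 = list(beta = 0.1, se = 0.01),
                         beta2 = list(beta = 0.1, se = 0.01)),
               "undefined")
})

test_that("decomposition identities hold exactly and are scale-equivariant", {
  set.seed(12)
  for (i in 1:20) {
    b0 <- list(beta = runif(1, -0.5, 0.5), se = runif(1, 0.01, 0.1))
    if (b0$beta == 0) next
    b1 <- list(beta = runif(1, -0.5, 0.5), se = runif(1, 0.01, 0.1))
    b2 <- list(beta = runif(1, -0.5, 0.5), se = runif(1, 0.01, 0.1))
    res <- decompose(b0, b1, b2)
    expect_equal(res$beta3 + res$me, b0$beta, tolerance = 1e-14)
    expect_equal(res$mp, 100 * res$me / b0$beta, tolerance = 1e-14)
    expect_true(res$me_ci[1] <= res$me && res$me <= res$me_ci[2])
    expect_equal(sort(100 * res$me_ci / b0$beta), res$mp_ci)

    # rescaling beta1 by c and beta2 by 1/c leaves the decomposition fixed
    cc <- 3.7
    res2 <- decompose(b0,
                      list(beta = b1$beta * cc, se = b1$se * cc),
                      list(beta = b2$beta / cc, se = b2$se / cc))
    expect_equal(res2$me, res$me, tolerance = 1e-12)
    expect_equal(res2$mp, res$mp, tolerance = 1e-12)
    expect_equal(res2$beta3, res$beta3, tolerance = 1e-12)
  }
})

test_that("reported mediated proportions are reproduced from reported inputs", {
  # ME = -0.00655 against a total-effect OR of 1.058 gives -11.6%
  expect_equal(mediated_proportion_pct(-0.00655, 1.058), -11.6,
               tolerance = 2e-3)
  res <- decompose(beta0 = list(beta = log(1.058), se = 0.03),
                   beta1 = list(beta = 0.0655, se = 0.02),
                   beta2 = list(beta = -0.1, se = 0.05))
  expect_equal(res$mp, -11.6, tolerance = 0.1)
})

test_that("a negative total effect flips and reorders the proportion CI", {
  res <- decompose(beta0 = list(beta = -0.1, se = 0.03),
                   beta1 = list(beta = 0.2, se = 0.05),
                   beta2 = list(beta = -0.1, se = 0.03))
  expect_equal(res$mp, 20, tolerance = 1e-12)
  expect_true(res$mp_ci[1] <= res$mp_ci[2])
  expect_equal(res$mp_ci, sort(100 * res$me_ci / -0.1))
})

test_that("two-step effects recover the truth in a near-noiseless simulation", {
  trip <- simulate_triple(sim_config(
    n_snps = 40, n_exposure = 1e12, n_mediator = 1e12, n_outcome = 1e12,
    true_beta_total = 0.1, true_beta1 = 0.2, true_beta2 = -0.1,
    palindromic_frac = 0, seed = 23))
  # near-noiseless: step 2 uses only mediator-specific instruments
  steps <- two_step_effects(trip$exposure, trip$mediator, trip$outcome)
  expect_equal(steps$beta1$beta, 0.2, tolerance = 1e-3)
  expect_equal(steps$beta2$beta, -0.1, tolerance = 1e-3)
})

test_that("two-step effects land within three SEs of the simulation truth", {
  trip <- simulate_triple(sim_config(seed = 7))
  steps <- two_step_effects(trip$exposure, trip$mediator, trip$outcome)
  expect_lt(abs(steps$beta1$beta - 0.2), 3 * steps$beta1$se)
  expect_lt(abs(steps$beta2$beta - (-0.1)), 3 * steps$beta2$se)
})

test_that("a mediator without exposure effect yields a near-zero step-1 estimate", {
  trip <- simulate_triple(sim_config(true_beta1 = 0, true_beta2 = 0,
                                     true_beta_total = 0.1,
                                     palindromic_frac = 0,
                                     mediator_snp_frac = 0, seed = 29))
  sel <- select_instruments(trip$exposure)
  pairs <- harmonize(sel$instruments, trip$mediator)
  b1 <- mr_ivw(wald_ratios(pairs))
  expect_lt(abs(b1$beta), 3 * b1$se)
  # and the mediator itself has no instruments, so step 2 is not computable
  expect_error(two_step_effects(trip$exposure, trip$mediator,
                                trip$outcome),
               class = "mrmediate_no_instruments_error")
})

test_that("full mediation wrapper reproduces the configured causal truth", {
  # average over replicates: the single-replicate mediated proportion has
  # Monte-Carlo sd ~2pp at the default sample sizes, dominated by the
  # total-effect denominator
  mps <- vapply(41:48, function(s) {
    trip <- simulate_triple(sim_config(seed = s))
    res <- mr_mediation(trip$exposure, trip$mediator, trip$outcome)
    expect_equal(res$beta3 + res$me, res$beta0, tolerance = 1e-14)
    res$mp
  }, numeric(1))
  expect_lt(abs(mean(mps) - (-20)), 2.5)
})

test_that("mediator screening keeps significant direction-consistent metabolites", {
  fits <- list(
    good = fake_estimates(rep(0.1, 5), ivw_pval = 0.001),
    inconsistent = fake_estimates(c(0.1, -0.1, 0.2, 0.1, 0.1),
                                  ivw_pval = 0.001),
    not_sig = fake_estimates(rep(0.1, 5), ivw_pval = 0.3)
  )
  expect_equal(mediator_screen(fits), "good")
  expect_equal(mediator_screen(list()), character(0))
})

test_that("the bundled reported rows are self-consistent except the known bad row", {
  ex <- published_mediation_examples()
  expect_equal(nrow(ex), 4)
  recomputed <- mediated_proportion_pct(ex$me, ex$or_total)
  consistent <- abs(recomputed - ex$mp_pct) < 0.2
  # the cortisone row has the sign of its printed proportion flipped
  expect_equal(unname(consistent), c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(recomputed[2], -ex$mp_pct[2], tolerance = 0.01)
})
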