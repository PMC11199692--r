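test_that("Wald ratios follow the first-order formulas", {
  p <- pairs_from_ratios(b = 0.5, s = 0.2, gamma = 0.1,
                         se_gamma = 0.01)
  # gamma = 0.1, Gamma = 0.05, se_Gamma = 0.02
  r <- wald_ratios(p)
  expect_equal(r$b, 0.5)
  expect_equal(r$s, 0.2)
  expect_equal(r$w, 25)

  p2 <- data.frame(snp_id = "x", gamma = 0.1, se_gamma = 0.01,
                   Gamma = 0, se_Gamma = 0.02)
  r2 <- wald_ratios(p2)
  expect_equal(r2$b, 0)
  expect_equal(r2$s, 0.2)

  # joint sign flip of (gamma, Gamma) leaves the ratio unchanged
  p3 <- p; p3$gamma <- -p3$gamma; p3$Gamma <- -p3$Gamma
  expect_equal(wald_ratios(p3)$b, r$b)

  pz <- data.frame(snp_id = c("a", "b"), gamma = c(0, 0.1),
                   se_gamma = 0.01, Gamma = 0.05, se_Gamma = 0.02)
  expect_warning(rz <- wald_ratios(pz), "zero exposure effect")
  expect_equal(nrow(rz), 1)
  pz0 <- pz; pz0$gamma <- 0
  expect_error(wald_ratios(pz0), "no usable instruments")
})

test_that("IVW reproduces the hand-computed weighted mean, SE and Q", {
  r <- wald_ratios(pairs_from_ratios(b = c(0.2, 0.4, 0.3),
                                     s = c(0.1, 0.2, 0.1)))
  est <- mr_ivw(r)
  expect_equal(est$beta, 4 / 15, tolerance = 1e-12)
  expect_equal(est$q, 1.0, tolerance = 1e-12)
  # Q/(J-1) = 0.5 < 1: no random-effects inflation, se stays fixed-effect
  expect_equal(est$se, 1 / 15, tolerance = 1e-12)
  expect_equal(mr_ivw(r, effects = "fixed")$se, 1 / 15, tolerance = 1e-12)
  expect_equal(est$or, exp(est$beta))
  expect_true(est$ci_low <= est$beta && est$beta <= est$ci_high)
})

test_that("single-SNP IVW degenerates to the Wald ratio", {
  r <- wald_ratios(pairs_from_ratios(b = 0.37, s = 0.12))
  est <- mr_ivw(r)
  expect_equal(est$beta, 0.37)
  expect_equal(est$se, 0.12)
  expect_equal(est$nsnp, 1)
})

test_that("IVW equals origin-constrained WLS and Egger equals WLS with intercept (lm oracle)", {
  p <- random_pairs(20, seed = 101, slope = 0.3, intercept = 0.02)
  r <- wald_ratios(p)
  w <- 1 / p$se_Gamma^2

  wls0 <- lm(Gamma ~ 0 + gamma, data = p, weights = w)
  expect_equal(mr_ivw(r)$beta, unname(coef(wls0)), tolerance = 1e-10)

  egger <- mr_egger(p)  # gammas all positive here, orientation is a no-op
  wls1 <- lm(Gamma ~ gamma, data = p, weights = w)
  expect_equal(egger$beta, unname(coef(wls1)["gamma"]), tolerance = 1e-10)
  expect_equal(egger$intercept, unname(coef(wls1)["(Intercept)"]),
               tolerance = 1e-10)
  # lm's SEs scale by sigma; ours floor sigma at 1 — equal when sigma > 1
  sig <- summary(wls1)$sigma
  if (sig > 1) {
    se_lm <- summary(wls1)$coefficients[, "Std. Error"]
    expect_equal(egger$se, unname(se_lm["gamma"]), tolerance = 1e-10)
    expect_equal(egger$intercept_se, unname(se_lm["(Intercept)"]),
                 tolerance = 1e-10)
  }
  # residual heterogeneity matches the weighted RSS
  expect_equal(egger$q, sum(w * resid(wls1)^2), tolerance = 1e-10)
})

test_that("Egger recovers an exact line and a zero intercept through the origin", {
  gam <- c(0.1, 0.2, 0.3)
  p <- data.frame(snp_id = c("a", "b", "c"), gamma = gam,
                  se_gamma = 0.01, Gamma = 0.05 + 0.5 * gam,
                  se_Gamma = 0.02)
  est <- mr_egger(p)
  expect_equal(est$beta, 0.5, tolerance = 1e-10)
  expect_equal(est$intercept, 0.05, tolerance = 1e-10)
  expect_equal(est$q, 0, tolerance = 1e-10)

  p0 <- p; p0$Gamma <- 0.5 * gam
  expect_equal(mr_egger(p0)$intercept, 0, tolerance = 1e-10)
  expect_error(mr_egger(p[1:2, ]), "at least 3")
})

test_that("Egger orientation makes the fit invariant to per-SNP sign conventions", {
  p <- random_pairs(15, seed = 7, slope = 0.4, intercept = 0.03)
  est1 <- mr_egger(p)
  p2 <- p
  flip <- c(2, 5, 9)
  p2$gamma[flip] <- -p2$gamma[flip]
  p2$Gamma[flip] <- -p2$Gamma[flip]
  est2 <- mr_egger(p2)
  expect_equal(est2$beta, est1$beta, tolerance = 1e-12)
  expect_equal(est2$intercept, est1$intercept, tolerance = 1e-12)
})

test_that("weighted median interpolates the weighted ratio distribution at 0.5", {
  r <- wald_ratios(pairs_from_ratios(b = c(0.1, 0.3, 0.6),
                                     s = 1 / sqrt(c(1, 1, 2))))
  expect_equal(r$w, c(1, 1, 2))
  est <- mr_weighted_median(r, n_boot = 50, seed = 1)
  expect_equal(est$beta, 0.4, tolerance = 1e-12)

  # equal weights, odd J, asymmetric values: the middle order statistic
  r2 <- wald_ratios(pairs_from_ratios(b = c(0.9, 0.1, 0.5), s = rep(1, 3)))
  expect_equal(mr_weighted_median(r2, n_boot = 50, seed = 1)$beta, 0.5)

  # degenerate: identical ratios; bootstrap SE on the scale of the ratio SEs
  r3 <- wald_ratios(pairs_from_ratios(b = rep(0.25, 4), s = rep(0.1, 4)))
  est3 <- mr_weighted_median(r3, n_boot = 500, seed = 2)
  expect_equal(est3$beta, 0.25)
  expect_gt(est3$se, 0.01)
  expect_lt(est3$se, 0.2)
})

test_that("mode estimators find the dominant ratio cluster", {
  r <- wald_ratios(pairs_from_ratios(b = c(0.5, 0.5, 0.5, 2.0),
                                     s = rep(0.1, 4)))
  est <- mr_mode(r, weighted = FALSE, n_boot = 50, seed = 3)
  h <- 0.9 * min(sd(r$b), IQR(r$b) / 1.349) * 4^(-1 / 5)
  grid_step <- (diff(range(r$b)) + 6 * h) / 511
  expect_lt(abs(est$beta - 0.5), max(3 * grid_step, 0.05))

  # one SNP carrying ~99% of the weight dominates the weighted mode
  r2 <- wald_ratios(pairs_from_ratios(b = c(0.8, 0.2, 0.3),
                                      s = c(0.01, 0.5, 0.5)))
  est2 <- mr_mode(r2, weighted = TRUE, n_boot = 50, seed = 3)
  expect_lt(abs(est2$beta - 0.8), 0.05)

  expect_error(mr_mode(r, phi = 0), "phi")
  expect_error(mr_mode(r[1:2, ]), "at least 3")

  # all ratios identical: zero bandwidth, the common value is returned
  r3 <- wald_ratios(pairs_from_ratios(b = rep(0.4, 3), s = rep(0.1, 3)))
  expect_equal(mr_mode(r3, n_boot = 50, seed = 4)$beta, 0.4)
})

test_that("512-point mode agrees with a dense-grid brute-force maximization", {
  set.seed(42)
  b <- c(rnorm(12, 0.3, 0.05), rnorm(4, 0.9, 0.05))
  s <- runif(16, 0.05, 0.2)
  r <- wald_ratios(pairs_from_ratios(b = b, s = s))
  est <- mr_mode(r, weighted = TRUE, n_boot = 10, seed = 5)

  w_norm <- r$w / sum(r$w)
  h <- 0.9 * min(sd(b), IQR(b) / 1.349) * length(b)^(-1 / 5)
  dense <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = 1e5)
  dens <- vapply(dense, function(x) sum(w_norm * dnorm(x, b, h)),
                 numeric(1))
  brute <- dense[which.max(dens)]
  coarse_step <- (diff(range(b)) + 6 * h) / 511
  expect_lt(abs(est$beta - brute), coarse_step)
})

test_that("mr_fit returns five estimates, degrading gracefully at small J", {
  trip <- simulate_triple(sim_config(n_snps = 20, seed = 16))
  pairs <- harmonize(trip$exposure, trip$outcome)
  fit <- mr_fit(pairs, seed = 1)
  expect_equal(nrow(fit$estimates), 5)
  expect_true(all(fit$estimates$status == "ok"))
  expect_equal(unname(coef(fit)), fit$estimates$beta)

  fit2 <- mr_fit(pairs[1:2, ], seed = 1)
  est2 <- fit2$estimates
  expect_equal(est2$status[est2$method == "IVW"], "ok")
  expect_true(all(est2$status[est2$method != "IVW"] == "not_computable"))
  expect_match(est2$reason[est2$method == "MR-Egger"], ">= 3")
})

test_that("all five methods recover an exact proportional relationship", {
  gam <- seq(0.05, 0.4, length.out = 8)
  p <- data.frame(snp_id = sprintf("s%d", 1:8), gamma = gam,
                  se_gamma = 0.01, Gamma = 0.3 * gam, se_Gamma = 0.02)
  fit <- mr_fit(p, seed = 9)
  est <- fit$estimates
  grid_tol <- 0.02
  expect_equal(est$beta[est$method == "IVW"], 0.3, tolerance = 1e-10)
  expect_equal(est$beta[est$method == "MR-Egger"], 0.3, tolerance = 1e-10)
  expect_equal(est$beta[est$method == "Weighted median"], 0.3,
               tolerance = 1e-10)
  expect_lt(abs(est$beta[est$method == "Weighted mode"] - 0.3), grid_tol)
  expect_lt(abs(est$beta[est$method == "Simple mode"] - 0.3), grid_tol)
})

test_that("estimators are equivariant under a joint sign flip and stay in ratio range", {
  p <- random_pairs(25, seed = 33, slope = 0.25, intercept = 0.01)
  fit1 <- mr_fit(p, seed = 5)
  pneg <- p; pneg$Gamma <- -pneg$Gamma  # flips every ratio's sign
  fit2 <- mr_fit(pneg, seed = 5)
  expect_equal(fit2$estimates$beta, -fit1$estimates$beta, tolerance = 1e-6)
  # analytic SEs (IVW, Egger) are exactly invariant; bootstrap SEs only in
  # distribution, so compare those loosely
  analytic <- fit1$estimates$method %in% c("IVW", "MR-Egger")
  expect_equal(fit2$estimates$se[analytic], fit1$estimates$se[analytic],
               tolerance = 1e-10)
  expect_equal(fit2$estimates$se[!analytic], fit1$estimates$se[!analytic],
               tolerance = 0.3)

  r <- fit1$ratios
  for (m in c("IVW", "Weighted median")) {
    bet <- fit1$estimates$beta[fit1$estimates$method == m]
    expect_gte(bet, min(r$b))
    expect_lte(bet, max(r$b))
  }
})

test_that("estimates bracket the simulation truth at three sigma in most replicates", {
  ok <- vapply(1:60, function(s) {
    trip <- simulate_triple(sim_config(
      n_snps = 40, palindromic_frac = 0, true_beta_total = 0.1,
      mediator_snp_frac = 0, n_outcome = 1e5, seed = 5000 + s))
    pairs <- harmonize(trip$exposure, trip$outcome)
    fit <- mr_fit(pairs, n_boot = 200, seed = s)
    est <- fit$estimates
    all(abs(est$beta - 0.1) < 3 * est$se)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
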