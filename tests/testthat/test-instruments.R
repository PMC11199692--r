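test_that("significance filter keeps strictly sub-threshold p-values, preserving order", {
  st <- toy_sumstats(c("rs1", "rs2"), pval = c(1e-9, 1e-7))
  kept <- significance_filter(st, 5e-8)
  expect_equal(kept$snp_id, "rs1")
  expect_warning(significance_filter(toy_sumstats("rs1", pval = 1e-3)),
                 "no SNP passes")
  st3 <- toy_sumstats(c("b", "a", "c"), pval = c(0.2, 0.01, 0.5))
  expect_equal(significance_filter(st3, 1)$snp_id, c("b", "a", "c"))
  # idempotence
  expect_equal(significance_filter(kept, 5e-8), kept)
})

test_that("greedy clumping follows the p-value-ordered trace", {
  st <- toy_sumstats(c("A", "B", "C"), pval = c(1e-10, 1e-9, 1e-8),
                     pos = c(1e6, 1e6 + 5e4, 5e6))
  ld <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  diag(ld) <- 1
  ld["A", "B"] <- ld["B", "A"] <- 0.5
  ld["A", "C"] <- ld["C", "A"] <- 0.0005
  out <- clump(st, ld, r2_max = 0.001, window_kb = 10000)
  expect_equal(sort(out$snp_id), c("A", "C"))
  expect_equal(attr(out, "removed")$snp_id, "B")
  expect_equal(attr(out, "removed")$index_snp, "A")
})

test_that("independent SNPs all survive; distant correlated SNPs survive", {
  st <- toy_sumstats(c("A", "B"), pval = c(1e-10, 1e-9),
                     pos = c(1e6, 1e6 + 2e7))
  ld <- matrix(c(1, 0.9, 0.9, 1), 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(nrow(clump(st, ld, 0.001, 10000)), 2)

  st2 <- toy_sumstats(letters[1:4], pval = c(1e-9, 1e-10, 1e-8, 1e-7))
  ld0 <- diag(4); dimnames(ld0) <- list(letters[1:4], letters[1:4])
  expect_equal(nrow(clump(st2, ld0, 0.001, 10000)), 4)
})

test_that("clumping is invariant to input row order and matches a brute-force oracle", {
  brute_clump <- function(st, ldm, r2_max, window_kb) {
    ids <- st$snp_id[order(st$pval, st$snp_id)]
    st <- st[match(ids, st$snp_id), ]
    kept <- character(0)
    avail <- ids
    while (length(avail)) {
      top <- avail[1]
      kept <- c(kept, top)
      i <- match(top, st$snp_id)
      keep_rest <- vapply(avail[-1], function(s) {
        j <- match(s, st$snp_id)
        st$chrom[j] != st$chrom[i] ||
          abs(st$pos[j] - st$pos[i]) > window_kb * 1000 ||
          ldm[top, s] <= r2_max
      }, logical(1))
      avail <- avail[-1][keep_rest]
    }
    sort(kept)
  }
  for (seed in 1:5) {
    set.seed(seed)
    k <- 12
    ids <- sprintf("s%02d", 1:k)
    st <- toy_sumstats(ids, pval = runif(k, 1e-12, 1e-8),
                       pos = sample.int(3e7, k),
                       chrom = sample(c("1", "2"), k, replace = TRUE))
    ldm <- matrix(0, k, k, dimnames = list(ids, ids))
    for (i in 1:(k - 1)) for (j in (i + 1):k)
      ldm[i, j] <- ldm[j, i] <- sample(c(0, 0.002, 0.3, 0.9), 1)
    diag(ldm) <- 1
    out <- clump(st, ldm, 0.001, 10000)
    expect_equal(sort(out$snp_id), brute_clump(st, ldm, 0.001, 10000))
    # retained pairs never violate (r2 <= max OR outside window)
    if (nrow(out) > 1) {
      for (i in 1:(nrow(out) - 1)) for (j in (i + 1):nrow(out)) {
        ok <- out$chrom[i] != out$chrom[j] ||
          abs(out$pos[i] - out$pos[j]) > 1e7 ||
          ldm[out$snp_id[i], out$snp_id[j]] <= 0.001
        expect_true(ok)
      }
    }
    shuf <- st[sample.int(k), ]
    class(shuf) <- class(st)
    expect_equal(sort(clump(shuf, ldm, 0.001, 10000)$snp_id),
                 sort(out$snp_id))
  }
})

test_that("long-format LD tables work and missing pairs count as zero", {
  st <- toy_sumstats(c("A", "B", "C"), pval = c(1e-10, 1e-9, 1e-8))
  ld <- data.frame(snp_a = "A", snp_b = "B", r2 = 0.9,
                   stringsAsFactors = FALSE)
  out <- clump(st, ld, 0.001, 10000)
  expect_equal(sort(out$snp_id), c("A", "C"))
})

test_that("F statistics follow (beta/se)^2 with the mean-F weak rule", {
  st <- toy_sumstats(c("rs1", "rs2"), beta = c(0.1, 0.03),
                     se = c(0.02, 0.01))
  f <- f_statistics(st)
  expect_equal(f$per_snp$f, c(25, 9))
  expect_equal(f$mean_f, 17)
  expect_false(f$weak_flag)
  expect_equal(f$weak_snps, "rs2")
  f2 <- f_statistics(toy_sumstats("rs2", beta = 0.03, se = 0.01))
  expect_equal(f2$mean_f, 9)
  expect_true(f2$weak_flag)
})

test_that("confounder filter removes only sub-threshold confounder hits", {
  st <- toy_sumstats(c("rs1", "rs2", "rs3"))
  ann <- data.frame(snp_id = c("rs1", "rs2"),
                    trait = c("BMI", "BMI"),
                    pval = c(1e-8, 1e-3), stringsAsFactors = FALSE)
  out <- confounder_filter(st, ann, p_threshold = 1e-5,
                           confounder_traits = "BMI")
  expect_equal(out$snp_id, c("rs2", "rs3"))
  expect_equal(attr(out, "removed")$snp_id, "rs1")
  # unlisted trait ignored
  ann2 <- data.frame(snp_id = "rs3", trait = "height", pval = 1e-20)
  out2 <- confounder_filter(st, ann2, confounder_traits = "BMI")
  expect_equal(nrow(out2), 3)
  # empty annotation table is the identity
  out3 <- confounder_filter(st, ann[0, ])
  expect_equal(out3$snp_id, st$snp_id)
  expect_equal(nrow(attr(out3, "removed")), 0)
})

test_that("select_instruments audit counts are conserved at every stage", {
  trip <- simulate_triple(sim_config(n_snps = 60, n_ld_blocks = 3,
                                     within_block_r2 = 0.5, seed = 31))
  ann <- data.frame(snp_id = trip$exposure$snp_id[1:3],
                    trait = "BMI", pval = 1e-9, stringsAsFactors = FALSE)
  sel <- select_instruments(trip$exposure, ld = ld_matrix(trip$truth$config),
                            annotations = ann,
                            confounder_traits = "BMI")
  aud <- sel$audit
  expect_true(all(aud$candidates == aud$removed + aud$retained))
  expect_equal(aud$retained[nrow(aud)], nrow(sel$instruments))
  # every retained SNP passes the significance threshold
  expect_true(all(sel$instruments$pval < 5e-8))
  # clumped result keeps one SNP per LD block among significant ones
  expect_true(nrow(sel$instruments) <= 3)
})
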