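mk_ct <- function(sample, gene, plate, ct) {
  data.frame(sample = sample, gene = gene, plate = plate,
             ct1 = ct[, 1], ct2 = ct[, 2], ct3 = ct[, 3],
             stringsAsFactors = FALSE)
}

test_that("triplicate QC applies the Ct, SD and plate rules in order", {
  base <- withr::with_seed(1, matrix(rnorm(3 * 20, 30, 0.05), 20, 3))
  tab <- mk_ct(sprintf("s%02d", 1:20), "GENE", "plate1", base)
  tab$ct1[1] <- 36            # high_ct (any replicate > 35)
  tab[2, c("ct1", "ct2", "ct3")] <- c(30.0, 30.4, 31.1)  # SD 0.557 > 0.5
  tab[3, c("ct1", "ct2", "ct3")] <- c(34, 34, 34)        # plate outlier
  qc <- triplicate_qc(tab)
  expect_equal(qc$exclusion_reason[1:3],
               c("high_ct", "high_sd", "plate_outlier"))
  expect_true(all(qc$qc_pass[4:20]))
  expect_identical(qc$qc_pass, qc$exclusion_reason == "none")
  # mean/sd computed from the triplicate only
  expect_equal(qc$mean_ct[2], mean(c(30.0, 30.4, 31.1)))
  expect_equal(qc$sd_ct[2], sd(c(30.0, 30.4, 31.1)))
  # high_ct takes precedence over high_sd
  both <- mk_ct("s1", "G", "p", matrix(c(36, 30, 30), 1))
  expect_equal(triplicate_qc(both)$exclusion_reason, "high_ct")
  # order-stable: QC of a QC'd table gives identical flags
  qc2 <- triplicate_qc(qc[, names(tab)])
  expect_identical(qc2$exclusion_reason, qc$exclusion_reason)
  # a plate with < 3 passing records skips the plate filter
  tiny <- mk_ct(c("s1", "s2"), "G", "p", matrix(c(20, 34, 20, 34, 20, 34), 2))
  expect_message(qt <- triplicate_qc(tiny), "skipped")
  expect_true(all(qt$qc_pass))
})

test_that("delta-Ct subtracts the reference and removes dct outliers", {
  samples <- sprintf("s%02d", 1:50)
  # evenly spaced deviations: max |dev| is ~1.7 SD on a uniform grid, so the
  # +/-2SD outlier rule removes nothing from the clean table
  gene_ct <- matrix(rep(30 + seq(-0.05, 0.05, length.out = 50), 3), 50, 3)
  ref_ct <- matrix(20, 50, 3)
  tab <- rbind(mk_ct(samples, "GENE", "p1", gene_ct),
               mk_ct(samples, "GAPDH", "p1", ref_ct))
  qc <- triplicate_qc(tab)
  d <- delta_ct(qc, "GAPDH")
  expect_equal(nrow(d), 50)
  expect_equal(mean(d$dct), 10, tolerance = 0.01)

  # one extreme dct among 50 near-constant values is flagged, and only it
  tab2 <- tab
  tab2[1, c("ct1", "ct2", "ct3")] <- 33
  d2 <- delta_ct(triplicate_qc(tab2), "GAPDH")
  expect_false("s01" %in% d2$sample)
  expect_equal(nrow(d2), 49)

  # all-equal dct: SD = 0 excludes nothing
  tab3 <- rbind(mk_ct(samples, "GENE", "p1", matrix(30, 50, 3)),
                mk_ct(samples, "GAPDH", "p1", ref_ct))
  expect_equal(nrow(delta_ct(triplicate_qc(tab3), "GAPDH")), 50)
  expect_true(all(delta_ct(triplicate_qc(tab3), "GAPDH")$dct == 10))

  # samples without a passing reference are dropped
  tab4 <- rbind(mk_ct(samples, "GENE", "p1", gene_ct),
                mk_ct(samples[-1], "GAPDH", "p1", ref_ct[-1, ]))
  expect_message(d4 <- delta_ct(triplicate_qc(tab4), "GAPDH"), "dropping")
  expect_false("s01" %in% d4$sample)
})

test_that("fold change is 2^-ddCt with the reciprocal property", {
  expect_equal(fold_change(rep(11, 5), rep(10, 5)), 0.5)
  expect_equal(fold_change(rep(10, 5), rep(10, 5)), 1.0)
  expect_equal(fold_change(rep(10.2176, 5), rep(10, 5)), 0.860,
               tolerance = 1e-3)
  x <- withr::with_seed(3, rnorm(10)); y <- withr::with_seed(4, rnorm(8))
  expect_equal(fold_change(x, y) * fold_change(y, x), 1, tolerance = 1e-12)
  expect_error(fold_change(numeric(0), y), "nonempty")
})

test_that("rank-sum comparison: exact, tied and large-sample behavior", {
  same <- group_compare(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$p, 1)
  sep <- group_compare(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(sep$p, 0.1)  # 2/20: both extreme assignments of ranks
  tied <- group_compare(rep(5, 10), rep(c("a", "b"), each = 5))
  expect_equal(tied$p, 1)
  expect_equal(tied$W, 12.5)

  # large-sample approximation against a permutation oracle
  vals <- withr::with_seed(5, c(rnorm(30), rnorm(30, 0.4)))
  status <- rep(c("control", "case"), each = 30)
  gc <- group_compare(vals, status)
  u_of <- function(v) {
    r <- rank(v)
    sum(r[1:30]) - 30 * 31 / 2
  }
  u_obs <- u_of(vals)
  perm <- withr::with_seed(6, replicate(1e4, {
    u <- u_of(sample(vals))
    abs(u - 450) >= abs(u_obs - 450)
  }))
  p_mc <- mean(perm)
  se <- sqrt(p_mc * (1 - p_mc) / 1e4)
  expect_lt(abs(gc$p - p_mc), 3 * se + 1e-6)
})

test_that("platform concordance is Spearman with average-rank ties", {
  expect_equal(platform_concordance(1:10, 10:1)$rho, -1)
  a <- withr::with_seed(7, rnorm(25))
  b <- withr::with_seed(8, rnorm(25))
  r <- platform_concordance(a, b)
  expect_equal(r$rho, cor(rank(a), rank(b)), tolerance = 1e-12)
  # ties handled by average ranks
  at <- c(1, 1, 2, 3); bt <- c(2, 1, 1, 3)
  expect_equal(platform_concordance(at, bt)$rho,
               cor(rank(at), rank(bt)), tolerance = 1e-12)
  expect_error(platform_concordance(rep(1, 5), 1:5), "constant")
  expect_error(platform_concordance(1:2, 2:1), "3 paired")
})

test_that("array and qPCR residuals of one planted signal are concordant", {
  set.seed(9)
  n <- 60
  status <- rep(c("control", "case"), each = n / 2)
  cv <- data.frame(age = rnorm(n, 40, 8),
                   sex = factor(sample(c("F", "M"), n, TRUE)))
  expr <- 8 - 0.5 * (status == "case") + rnorm(n, 0, 0.6)
  names(expr) <- sprintf("s%02d", 1:n)
  ct <- simulate_qpcr_plates(cbind(GENE = expr), reference_gene = "GAPDH",
                             seed = 10)
  d <- delta_ct(triplicate_qc(ct), "GAPDH")
  d <- d[d$gene == "GENE", ]
  common <- d$sample
  plate <- ct$plate[match(common, ct$sample)]
  qpcr_res <- residualize(d$dct, data.frame(plate = plate,
                                            cv[match(common, names(expr)), ]))
  array_res <- residualize(expr[common],
                           cv[match(common, names(expr)), , drop = FALSE])
  conc <- platform_concordance(array_res, qpcr_res)
  expect_lt(conc$rho, -0.5)  # high Ct = low expression
  expect_lt(conc$p, 1e-4)
})
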