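test_that("generate_truth is deterministic and respects its constraints", {
  t1 <- generate_truth(n_genes = 1000, n_modules = 5,
                       module_size_range = c(50, 150), seed = 1)
  t2 <- generate_truth(n_genes = 1000, n_modules = 5,
                       module_size_range = c(50, 150), seed = 1)
  expect_identical(t1, t2)
  expect_false(identical(t1, generate_truth(seed = 2)))

  sizes <- as.integer(table(t1$module_membership[t1$module_membership > 0]))
  expect_length(sizes, 5)
  expect_true(all(sizes >= 50 & sizes <= 150))
  # modules are disjoint by construction; background has zero driver corr
  expect_true(all(t1$module_corr[t1$module_membership == 0] == 0))
  expect_true(all(t1$module_corr[t1$module_membership > 0] > 0))

  t0 <- generate_truth(n_genes = 100, n_modules = 0)
  expect_true(all(t0$module_membership == 0))

  expect_error(generate_truth(n_genes = 100, n_modules = 5,
                              module_size_range = c(30, 40)), "infeasible")
  expect_error(generate_truth(corr_range = c(0, 0.9)), "corr_range")
})

test_that("pairwise gene correlations follow the driver-factor model", {
  truth <- generate_truth(n_genes = 60, n_modules = 1,
                          module_size_range = c(30, 30),
                          corr_range = c(0.8, 0.8), disease_effect = 0, seed = 3)
  coh <- simulate_cohort(truth, cohort_spec(1000, 1000, label = "big"), seed = 7)
  x <- coh$gene_values
  mod_genes <- names(truth$module_membership)[truth$module_membership == 1]
  r <- cor(t(x[mod_genes, ]))
  # same-module genes with rho_i = rho_j = 0.8 correlate at rho^2 = 0.64
  off <- r[upper.tri(r)]
  expect_lt(max(abs(off - 0.64)), 0.05)
  # background pairwise correlations are noise-level
  bg <- names(truth$module_membership)[truth$module_membership == 0]
  rb <- cor(t(x[bg, ]))
  frac_small <- mean(abs(rb[upper.tri(rb)]) < 4 / sqrt(2000))
  expect_gte(frac_small, 0.95)
})

test_that("noise-free probe configuration reproduces the gene signal exactly", {
  truth <- generate_truth(n_genes = 40, n_modules = 1,
                          module_size_range = c(20, 20),
                          corr_range = c(0.95, 0.95), seed = 2)
  spec <- cohort_spec(10, 10, probe_multiplicity = c(1, 0, 0), noise_sd = 0,
                      probe_offset_sd = 0, batch_sd = 0, dead_probe_frac = 0,
                      n_batches = 1, label = "clean")
  coh <- simulate_cohort(truth, spec, seed = 5)
  probes <- coh$values
  rownames(probes) <- sub("_p1$", "", rownames(probes))
  expect_equal(probes[rownames(coh$gene_values), ], coh$gene_values)
  # a near-unit-rho module gene tracks its driver
  g <- names(truth$module_membership)[truth$module_membership == 1][1]
  expect_gt(cor(coh$gene_values[g, ], coh$drivers[1, ]), 0.9)
})

test_that("planted disease effects shift the driver; null effects do not", {
  # null: no disease effect => driver uncorrelated with status across seeds
  z <- sapply(1:100, function(s) {
    truth <- generate_truth(n_genes = 20, n_modules = 1,
                            module_size_range = c(10, 10),
                            disease_effect = 0, seed = s)
    coh <- simulate_cohort(truth, cohort_spec(
      50, 50, probe_multiplicity = c(1, 0, 0), label = "null"), seed = 100 + s)
    cor(coh$drivers[1, ], as.numeric(coh$covariates$status == "case"))
  })
  expect_lt(abs(mean(z)), 0.04)  # ~4 MC standard errors at 100 seeds

  # planted effect 1.0 at n = 100: two-sample t on the driver exceeds the
  # nominal 5% critical value in the vast majority of seeds
  hits <- sapply(1:100, function(s) {
    truth <- generate_truth(n_genes = 20, n_modules = 1,
                            module_size_range = c(10, 10),
                            disease_effect = 1.0, seed = s)
    coh <- simulate_cohort(truth, cohort_spec(
      50, 50, probe_multiplicity = c(1, 0, 0), label = "alt"), seed = 200 + s)
    case <- coh$covariates$status == "case"
    abs(t.test(coh$drivers[1, case], coh$drivers[1, !case])$statistic) > 1.96
  })
  expect_gt(mean(hits), 0.9)
})

test_that("dead probes get uniform detection p-values, live probes small ones", {
  truth <- generate_truth(n_genes = 200, n_modules = 1,
                          module_size_range = c(50, 50), seed = 4)
  coh <- simulate_cohort(truth, cohort_spec(20, 20, dead_probe_frac = 0.5,
                                            label = "dp"), seed = 9)
  mins <- apply(coh$detection_p, 1, min)
  # live probes: every detection p < 0.01; dead: Uniform(0,1) rarely all small
  expect_gt(mean(apply(coh$detection_p, 1, max) < 0.01), 0.4)
  expect_gt(mean(mins > 0.01), 0.05)
})

test_that("marker lists have the requested sizes, purity and alignment", {
  truth <- generate_truth(n_genes = 1000, n_modules = 5,
                          module_size_range = c(100, 150), seed = 11)
  ml <- simulate_marker_and_brain_lists(truth, seed = 1)
  expect_identical(lengths(ml$marker_lists),
                   c(neutrophil = 51L, lymphocyte = 56L, red_cell_size = 56L,
                     blood_draw = 30L))
  expect_true(all(unlist(ml$marker_lists) %in% names(truth$module_membership)))
  expect_length(ml$brain_flag, 1000)

  pure <- simulate_marker_and_brain_lists(
    truth, list_sizes = c(test = 20), alignment = 2, purity = 1, seed = 2)
  expect_true(all(truth$module_membership[pure$marker_lists$test] == 2))

  expect_error(simulate_marker_and_brain_lists(
    truth, list_sizes = c(test = 20), alignment = 9), "nonexistent")
})

test_that("brain-flag enrichment is null-calibrated when probabilities match", {
  truth <- generate_truth(n_genes = 400, n_modules = 2,
                          module_size_range = c(60, 100), seed = 21)
  target <- names(truth$module_membership)[truth$module_membership == 1]
  other <- setdiff(names(truth$module_membership), target)
  rej <- sapply(1:500, function(s) {
    fl <- simulate_marker_and_brain_lists(
      truth, list_sizes = c(x = 10), alignment = 2, purity = 1,
      p_brain_in_target = 0.5, p_brain_background = 0.5, seed = s)$brain_flag
    brain_enrichment_fisher(target, other, names(fl)[fl])$p < 0.05
  })
  # Fisher is exact and slightly conservative under discreteness
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
})

test_that("GWAS tables are uniform under the null and enriched when planted", {
  truth <- generate_truth(n_genes = 300, n_modules = 2,
                          module_size_range = c(50, 80), seed = 31)
  null_tab <- simulate_gwas_table(truth, snps_per_gene_mean = 30,
                                  enriched_fraction = 0, seed = 1)
  expect_lt(abs(mean(null_tab$snps$p < 0.05) - 0.05), 0.01)
  # coordinates: every SNP lies within 10 kb of its generating gene span
  map <- snp_gene_map(null_tab$snps, null_tab$coords, window = 10000)
  expect_equal(sort(unique(map$snp)), sort(null_tab$snps$snp))

  empty <- simulate_gwas_table(truth, snps_per_gene_mean = 0, seed = 1)
  expect_equal(nrow(empty$snps), 0)

  # planted enrichment: fraction of target-module SNP p < 0.05 exceeds 5%
  hits <- sapply(1:100, function(s) {
    tab <- simulate_gwas_table(truth, snps_per_gene_mean = 10,
                               enriched_fraction = 0.3, beta_shape = 0.2,
                               seed = s)
    map <- snp_gene_map(tab$snps, tab$coords)
    tgt <- names(truth$module_membership)[truth$module_membership == 1]
    mean(map$p[map$gene %in% tgt] < 0.05) > 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("qPCR plate simulation is exact in the noiseless limit", {
  expr <- matrix(c(8, 9, 10, 7.5), ncol = 1,
                 dimnames = list(sprintf("s%d", 1:4), "GENE1"))
  ct <- simulate_qpcr_plates(expr, reference_gene = "REF", n_plates = 1,
                             plate_effect_sd = 0, triplicate_sd = 0,
                             slope = 1, intercept = 30, seed = 1)
  qc <- triplicate_qc(ct)
  expect_true(all(qc$sd_ct == 0))
  g <- qc[qc$gene == "GENE1", ]
  # slope 1, no noise: Ct differences equal minus the expression differences
  expect_equal(diff(g$mean_ct[order(g$sample)]),
               unname(-diff(expr[order(rownames(expr)), 1])))
})
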