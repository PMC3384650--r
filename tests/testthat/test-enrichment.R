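test_that("hypergeometric enrichment matches exact enumeration", {
  bg <- sprintf("g%02d", 1:20)
  module <- bg[1:5]
  lst <- bg[c(1, 2, 3, 4)]
  r <- hypergeom_list_enrichment(module, lst, bg)
  expect_equal(r$overlap, 4)
  expect_equal(r$p, 5 / 4845, tolerance = 1e-12)
  expect_equal(r$p, hyper_tail_oracle(4, 20, 4, 5), tolerance = 1e-12)

  # zero overlap: the upper tail from 0 carries all mass
  r0 <- hypergeom_list_enrichment(bg[1:3], bg[18:20], bg)
  expect_equal(r0$p, 1)

  # counts are taken after intersection with the background
  r2 <- hypergeom_list_enrichment(c(module, "alien"), c(lst, "alien2"), bg)
  expect_equal(r2$module_size, 5)
  expect_equal(r2$list_in_background, 4)

  # Bonferroni
  r3 <- hypergeom_list_enrichment(module, lst, bg, n_tests = 56)
  expect_equal(r3$p_adjusted, min(1, r3$p * 56))
  expect_error(hypergeom_list_enrichment(module, lst, character(0)), "empty")
})

test_that("hypergeometric tail agrees with a permutation oracle", {
  # fixed small case: N = 20, 4 list genes, module of 5, overlap >= 2
  p_exact <- hyper_tail_oracle(2, 20, 4, 5)
  draws <- withr::with_seed(42, replicate(1e5, {
    sum(sample(rep(c(TRUE, FALSE), c(4, 16)), 5)) >= 2
  }))
  p_mc <- mean(draws)
  se <- sqrt(p_exact * (1 - p_exact) / 1e5)
  expect_lt(abs(p_mc - p_exact), 3 * se)
  bg <- sprintf("g%02d", 1:20)
  expect_equal(hypergeom_list_enrichment(bg[1:5], bg[c(1, 2, 19, 20)], bg)$p,
               p_exact, tolerance = 1e-12)
})

test_that("a strongly aligned list reaches an extreme enrichment p", {
  # scenario shaped like a cell-type module: background 5000, module 399,
  # list 29 in background, overlap 22
  bg <- sprintf("g%04d", 1:5000)
  module <- bg[1:399]
  lst <- c(bg[1:22], bg[4994:5000])
  r <- hypergeom_list_enrichment(module, lst, bg)
  expect_equal(r$overlap, 22)
  expect_lt(r$p, 1e-10)
  expect_equal(r$p, hyper_tail_oracle(22, 5000, 29, 399), tolerance = 1e-10)
})

test_that("family-wise enrichment corrects across modules x lists", {
  labels <- setNames(rep(c("turquoise", "blue", "grey"), c(40, 35, 25)),
                     sprintf("g%03d", 1:100))
  lists <- list(a = sprintf("g%03d", 1:10), b = sprintf("g%03d", 50:64))
  out <- module_list_enrichment(labels, lists)
  expect_equal(nrow(out), 4)  # 2 modules x 2 lists; grey skipped
  expect_equal(out$p_adjusted, pmin(1, out$p * 4))
  expect_equal(out$background_size, rep(100, 4))
})

test_that("brain-expressed calling uses a strict mean threshold", {
  m <- rbind(high = rep(5, 4), boundary = rep(4, 4), low = rep(2, 4),
             mixed = c(3, 4, 5, 6))
  expect_identical(brain_expressed_set(m, 4), c("high", "mixed"))
  means <- rowMeans(m)
  expect_identical(brain_expressed_set(m, 4), names(means)[means > 4])
})

test_that("brain enrichment Fisher test matches table enumeration", {
  tab <- matrix(c(8, 2, 10, 40), 2, 2, byrow = TRUE)
  target <- sprintf("t%02d", 1:10)
  other <- sprintf("o%02d", 1:50)
  brain <- c(target[1:8], other[1:10])
  r <- brain_enrichment_fisher(target, other, brain)
  expect_equal(unname(r$table), tab)
  expect_equal(r$p, fisher_greater_oracle(tab), tolerance = 1e-12)

  # equal brain fractions: no enrichment
  r_null <- brain_enrichment_fisher(target, other,
                                    c(target[1:5], other[1:25]))
  expect_gte(r_null$p, 0.5)

  # 61% in a 129-gene module vs 45% elsewhere is detectable
  target2 <- sprintf("t%03d", 1:129)
  other2 <- sprintf("o%04d", 1:4871)
  brain2 <- c(target2[1:79], other2[1:2192])
  expect_lt(brain_enrichment_fisher(target2, other2, brain2)$p, 0.05)

  expect_error(brain_enrichment_fisher(target, target, brain), "disjoint")
})

test_that("SNP-to-gene mapping respects the 10 kb window boundaries", {
  coords <- data.frame(gene = c("gA", "gB"), chrom = c("chr1", "chr1"),
                       start = c(1000, 11000), end = c(2000, 13000))
  snps <- data.frame(snp = paste0("rs", 1:5), chrom = "chr1",
                     pos = c(500L, 12000L, 12001L, 2500L, 30000L),
                     p = runif(5))
  map <- snp_gene_map(snps, coords, window = 10000)
  gets <- function(g) sort(map$snp[map$gene == g])
  # rs1 at 500: within 10 kb upstream of gA (and of gB: 11000 - 10000 = 1000 > 500)
  expect_true("rs1" %in% gets("gA"))
  expect_false("rs1" %in% gets("gB"))
  # boundary: gA window ends at 2000 + 10000 = 12000 inclusive
  expect_true("rs2" %in% gets("gA"))
  expect_false("rs3" %in% gets("gA"))
  # overlap: rs4 falls in both windows
  expect_true(all(c("gA", "gB") %in% map$gene[map$snp == "rs4"]))
  # rs5 at 30000 > 13000 + 10000: unmapped
  expect_false("rs5" %in% map$snp)

  # monotone in window
  map_small <- snp_gene_map(snps, coords, window = 100)
  expect_true(all(paste(map_small$gene, map_small$snp) %in%
                    paste(map$gene, map$snp)))

  bad <- snps; bad$pos[2] <- -5L
  expect_error(snp_gene_map(bad, coords), "rows: 2")
})

test_that("GWAS enrichment computes exact binomial tails per mode", {
  mk_map <- function(p) data.frame(gene = paste0("g", seq_along(p)),
                                   snp = paste0("rs", seq_along(p)), p = p)
  # no nominal SNPs
  expect_equal(gwas_enrichment(mk_map(c(0.5, 0.9)))$p_enrichment, 1)
  # exact small tails
  expect_equal(gwas_enrichment(mk_map(0.01))$p_enrichment, 0.05,
               tolerance = 1e-12)
  expect_equal(gwas_enrichment(mk_map(c(0.01, 0.02)))$p_enrichment, 0.0025,
               tolerance = 1e-12)
  # enumeration oracle on a larger case
  p20 <- withr::with_seed(1, runif(20, 0, 0.2))
  g <- gwas_enrichment(mk_map(p20))
  expect_equal(g$p_enrichment,
               binom_tail_oracle(g$n_nominal, 20, 0.05), tolerance = 1e-12)
  # with one SNP per gene the two modes coincide
  b <- gwas_enrichment(mk_map(p20), mode = "best_snp_per_gene")
  expect_equal(b$n_nominal, g$n_nominal)
  expect_equal(b$p_enrichment, g$p_enrichment)
  expect_true(b$anti_conservative)
  expect_false(g$anti_conservative)
  # a SNP mapped to two genes counts once in all_snps mode
  dup <- rbind(mk_map(c(0.01, 0.5)),
               data.frame(gene = "g3", snp = "rs1", p = 0.01))
  expect_equal(gwas_enrichment(dup)$n_tested, 2)
  # qq points: expected quantiles are uniform order statistics
  expect_equal(g$qq_points$expected, -log10((1:20) / 21), tolerance = 1e-12)
  expect_equal(g$qq_points$observed, -log10(sort(p20)), tolerance = 1e-12)
})
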