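#!/usr/bin/env Rscript
# Enrichment layers over the discovery modules: blood-cell marker lists
# (hypergeometric, Bonferroni across modules x lists), brain-expressed
# genes (one-sided Fisher for the disease module), and GWAS SNPs within
# 10 kb of module genes (exact binomial against the 5% nominal rate, in
# all-SNP and best-SNP-per-gene modes).

library(coexmod)

mods <- utils::read.delim("results/discovery/modules.tsv")
labels <- setNames(mods$module, mods$gene)
background <- mods$gene

## blood-cell marker lists -----------------------------------------------
files <- list.files("results/synthetic", pattern = "^markers_",
                    full.names = TRUE)
lists <- lapply(files, readLines)
names(lists) <- sub("^markers_(.*)\\.txt$", "\\1", basename(files))
enr <- module_list_enrichment(labels, lists, background = background)
hits <- enr[enr$p_adjusted < 0.05, ]
message("marker-list enrichment (Bonferroni < 0.05):")
for (i in seq_len(nrow(hits)))
  message(sprintf("  %s ~ %s: %d/%d genes overlap, p = %.2g",
                  hits$module[i], hits$list[i], hits$overlap[i],
                  hits$list_in_background[i], hits$p[i]))
utils::write.table(format(enr, digits = 3), "results/marker_enrichment.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

## brain-expressed genes --------------------------------------------------
bdf <- utils::read.delim("results/synthetic/brain_expression.tsv",
                         check.names = FALSE)
brain <- as.matrix(bdf[, -1]); rownames(brain) <- bdf[[1]]
brain_set <- brain_expressed_set(brain, threshold = 4)

# the disease module: the one holding most planted module-1 genes
truth <- utils::read.delim("results/synthetic/truth_membership.tsv")
m1 <- truth$gene[truth$module == 1]
disease_module <- names(which.max(table(labels[intersect(m1, names(labels))])))
tan <- names(labels)[labels == disease_module]
other <- names(labels)[labels != disease_module & labels != "grey"]
bf <- brain_enrichment_fisher(tan, other, brain_set)
message(sprintf(
  "disease module '%s': %.0f%% brain-expressed vs %.0f%% elsewhere, Fisher p = %.2g",
  disease_module, 100 * mean(tan %in% brain_set),
  100 * mean(other %in% brain_set), bf$p))

## GWAS SNP enrichment ----------------------------------------------------
snps <- utils::read.delim("results/synthetic/gwas_snps.tsv")
coords <- utils::read.delim("results/synthetic/gene_coords.tsv")
map <- snp_gene_map(snps, coords[coords$gene %in% tan, ], window = 10000)
g_all <- gwas_enrichment(map, mode = "all_snps")
g_best <- gwas_enrichment(map, mode = "best_snp_per_gene")
message(sprintf(
  "GWAS: %d genes of '%s' covered by %d SNPs; %d with p < 0.05 (%.0f%%), binomial p = %.2g",
  g_all$n_genes, disease_module, g_all$n_tested, g_all$n_nominal,
  100 * g_all$n_nominal / g_all$n_tested, g_all$p_enrichment))
message(sprintf(
  "best SNP per gene: %d of %d genes nominal, p = %.2g (anti-conservative under the 5%% null)",
  g_best$n_nominal, g_best$n_tested, g_best$p_enrichment))
utils::write.table(g_all$qq_points, "results/gwas_qq_points.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

summary_df <- data.frame(
  analysis = c("brain_fisher", "gwas_all_snps", "gwas_best_snp"),
  statistic = c(bf$odds_ratio, g_all$n_nominal / g_all$n_tested,
                g_best$n_nominal / g_best$n_tested),
  p = c(bf$p, g_all$p_enrichment, g_best$p_enrichment))
utils::write.table(format(summary_df, digits = 3),
                   "results/disease_module_enrichment.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote results/marker_enrichment.tsv, gwas_qq_points.tsv, disease_module_enrichment.tsv")
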