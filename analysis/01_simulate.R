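#!/usr/bin/env Rscript
# Simulate the synthetic two-cohort study: a planted truth (5 co-expression
# modules, one pure disease module under-expressed in cases, four
# medication-confounded modules), a medicated discovery cohort (92 cases /
# 78 controls) and an antipsychotic-free replication cohort (29 / 40),
# plus all side inputs: blood-cell marker lists, brain expression, a GWAS
# SNP table and gene coordinates.

library(coexmod)

seed <- 20120627 %% 100000  # study seed for the whole workflow
out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

truth <- generate_truth(seed = seed)
message("planted truth: ", truth$n_modules, " modules of sizes ",
        paste(sort(truth$module_sizes, decreasing = TRUE), collapse = ", "),
        "; disease effect on module 1 = ", truth$disease_effect[1], " SD")

disc <- simulate_cohort(truth, discovery_cohort(), seed = seed + 1)
repl <- simulate_cohort(truth, replication_cohort(), seed = seed + 2)
write_cohort(disc, file.path(out, "discovery"))
write_cohort(repl, file.path(out, "replication"))
message("discovery: ", nrow(disc$values), " probes x ", ncol(disc$values),
        " samples; replication: ", nrow(repl$values), " probes x ",
        ncol(repl$values), " samples")

side <- simulate_marker_and_brain_lists(truth, seed = seed + 3)
for (nm in names(side$marker_lists))
  writeLines(side$marker_lists[[nm]],
             file.path(out, paste0("markers_", nm, ".txt")))
message("marker lists: ",
        paste(sprintf("%s (%d)", names(side$marker_lists),
                      lengths(side$marker_lists)), collapse = ", "))

brain <- simulate_brain_matrix(side$brain_flag, n_samples = 50,
                               seed = seed + 4)
utils::write.table(data.frame(gene = rownames(brain), brain,
                              check.names = FALSE),
                   file.path(out, "brain_expression.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

gw <- simulate_gwas_table(truth, seed = seed + 5)
utils::write.table(gw$snps, file.path(out, "gwas_snps.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(gw$coords, file.path(out, "gene_coords.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("GWAS: ", nrow(gw$snps), " SNPs over ", nrow(gw$coords), " genes")

# truth for later scoring
truth_df <- data.frame(gene = names(truth$module_membership),
                       module = truth$module_membership,
                       rho = truth$module_corr)
utils::write.table(truth_df, file.path(out, "truth_membership.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote ", out)
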