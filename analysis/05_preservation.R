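#!/usr/bin/env Rscript
# Is the discovery module structure preserved in the replication cohort?
# Permutation Z statistics for density and connectivity; Z > 2 preserved,
# Z > 8 strongly preserved. A label-shuffled negative control should not
# be called preserved.

library(coexmod)

seed <- 20120627 %% 100000
read_expr <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1]); rownames(m) <- df[[1]]; m
}
x_ref <- read_expr("results/discovery/expression.tsv")
x_test <- read_expr("results/replication/expression.tsv")
mods <- utils::read.delim("results/discovery/modules.tsv")
labels <- setNames(mods$module, mods$gene)

matched <- module_overlap_map(rownames(x_ref), rownames(x_test))
message(length(matched), " of ", nrow(x_ref),
        " discovery genes present in the replication set (",
        round(100 * length(matched) / nrow(x_ref)), "%)")

pres <- preservation_summary(x_ref, x_test, labels,
                             n_permutations = 200, seed = seed)
message("preservation z_summary by module:")
for (i in seq_len(nrow(pres)))
  message(sprintf("  %-12s z = %6.1f  (%s)", pres$module[i],
                  pres$z_summary[i],
                  if (pres$z_summary[i] > 8) "strongly preserved"
                  else if (pres$z_summary[i] > 2) "preserved"
                  else "not preserved"))

set.seed(seed)
shuffled <- setNames(sample(labels), names(labels))
pres0 <- preservation_summary(x_ref, x_test, shuffled,
                              n_permutations = 200, seed = seed + 1)
message("shuffled-label control: max |z_summary| = ",
        round(max(abs(pres0$z_summary)), 2))

pres$control_max_abs_z <- max(abs(pres0$z_summary))
utils::write.table(format(pres, digits = 4), "results/preservation.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote results/preservation.tsv")
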