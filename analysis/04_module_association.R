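#!/usr/bin/env Rscript
# Summarize modules by eigengenes and regress each eigengene on disease
# status (age and sex as covariates) in the discovery cohort, then repeat
# in the antipsychotic-free replication cohort using the discovery module
# assignment. Also compute intramodular connectivity and hub genes.

library(coexmod)

read_expr <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1]); rownames(m) <- df[[1]]; m
}
mods <- utils::read.delim("results/discovery/modules.tsv")
labels <- setNames(mods$module, mods$gene)

for (cohort in c("discovery", "replication")) {
  x <- read_expr(file.path("results", cohort, "expression.tsv"))
  cv <- utils::read.delim(file.path("results", cohort, "covariates.tsv"))
  cv$status <- factor(cv$status, levels = c("control", "case"))
  me <- module_eigengenes(x, labels)
  assoc <- associate_modules(me, cv)
  assoc$size <- as.integer(table(labels[labels != "grey"])[assoc$module])
  sig <- assoc$module[assoc$q < 0.05]
  message(cohort, ": ", sum(assoc$q < 0.05), " of ", nrow(assoc),
          " modules associated with disease at FDR 5%",
          if (length(sig)) paste0(" (", paste(sig, collapse = ", "), ")"))
  utils::write.table(format(assoc, digits = 4),
                     file.path("results", cohort, "association.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  eg <- data.frame(sample = rownames(me$eigengenes), me$eigengenes,
                   check.names = FALSE)
  utils::write.table(eg, file.path("results", cohort, "eigengenes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

# hub genes from the discovery network
x <- read_expr("results/discovery/expression.tsv")
adj <- soft_adjacency(x, beta = 6)
kwi <- intramodular_connectivity(adj, labels)
hubs <- kwi[kwi$is_hub, c("gene", "module", "k_within_raw")]
message("hub genes: ",
        paste(sprintf("%s (%s)", hubs$gene, hubs$module), collapse = ", "))
utils::write.table(kwi, "results/discovery/connectivity.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
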