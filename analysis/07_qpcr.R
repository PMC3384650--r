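#!/usr/bin/env Rscript
# qPCR validation of the disease-module hub gene: simulate triplicate Ct
# plates from the hub's array expression, run triplicate QC, delta-Ct
# against the reference gene, residualize (plate + age + sex), and test
# case/control differences (Wilcoxon) plus array/qPCR concordance
# (Spearman; negative because high Ct means low expression).

library(coexmod)

seed <- 20120627 %% 100000
read_expr <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1]); rownames(m) <- df[[1]]; m
}
x <- read_expr("results/discovery/expression.tsv")
cv <- utils::read.delim("results/discovery/covariates.tsv")
cv$status <- factor(cv$status, levels = c("control", "case"))
kwi <- utils::read.delim("results/discovery/connectivity.tsv")
mods <- utils::read.delim("results/discovery/modules.tsv")
truth <- utils::read.delim("results/synthetic/truth_membership.tsv")
labels <- setNames(mods$module, mods$gene)
m1 <- truth$gene[truth$module == 1]
disease_module <- names(which.max(table(labels[intersect(m1, names(labels))])))
hub <- kwi$gene[kwi$module == disease_module & kwi$is_hub]
message("validating hub gene ", hub, " of module '", disease_module, "'")

ct <- simulate_qpcr_plates(cbind(HUB = x[hub, ]), reference_gene = "GAPDH",
                           seed = seed)
qc <- triplicate_qc(ct)
message(sum(!qc$qc_pass), " of ", nrow(qc), " measurements excluded by QC (",
        paste(names(table(qc$exclusion_reason[!qc$qc_pass])),
              table(qc$exclusion_reason[!qc$qc_pass]), collapse = ", "), ")")
dct <- delta_ct(qc, "GAPDH")
dct <- dct[dct$gene == "HUB", ]
cvm <- cv[match(dct$sample, cv$sample), ]
message(nrow(dct), " samples retained (",
        sum(cvm$status == "case"), " cases, ",
        sum(cvm$status == "control"), " controls)")

plate <- ct$plate[match(dct$sample, ct$sample)]
qpcr_res <- residualize(dct$dct, data.frame(plate = plate, age = cvm$age,
                                            sex = cvm$sex))
array_res <- residualize(x[hub, dct$sample],
                         data.frame(age = cvm$age, sex = cvm$sex))
conc <- platform_concordance(array_res, qpcr_res)
message(sprintf("array/qPCR concordance: Spearman rho = %.2f, p = %.2g",
                conc$rho, conc$p))

gc <- group_compare(qpcr_res, cvm$status)
case <- cvm$status == "case"
fc <- fold_change(dct$dct[case], dct$dct[!case])
message(sprintf("case vs control: W = %.0f, p = %.2g, fold change = %.2f (%s)",
                gc$W, gc$p, fc,
                if (fc < 1) "under-expressed in cases" else "over-expressed"))

out <- data.frame(gene = hub, module = disease_module, n = nrow(dct),
                  n_cases = sum(case), W = gc$W, p_wilcoxon = gc$p,
                  fold_change = fc, spearman_rho = conc$rho,
                  spearman_p = conc$p)
utils::write.table(format(out, digits = 4), "results/qpcr_validation.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote results/qpcr_validation.tsv")
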