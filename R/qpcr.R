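# qPCR validation arithmetic: triplicate QC, delta-Ct against a reference
# gene, group comparison, fold change and array/qPCR concordance.

#' Triplicate quality control for Ct measurements
#'
#' A record is excluded when any raw Ct exceeds `max_ct` (high_ct), when the
#' triplicate SD exceeds `max_sd` (high_sd), or — among records passing the
#' first two filters — when its mean Ct lies outside the per-gene per-plate
#' mean +/- `plate_sd_mult` x SD (plate_outlier). Plates with fewer than 3
#' passing records for a gene skip the plate filter (logged). Applying the
#' QC twice yields identical flags.
#'
#' @param ct_table data.frame with columns sample, gene, plate, ct1, ct2,
#'   ct3.
#' @param max_ct Maximum acceptable raw Ct (default 35).
#' @param max_sd Maximum triplicate SD (default 0.5).
#' @param plate_sd_mult Plate outlier multiple (default 2).
#' @return The table with added columns mean_ct, sd_ct, qc_pass,
#'   exclusion_reason.
#' @export
triplicate_qc <- function(ct_table, max_ct = 35, max_sd = 0.5,
                          plate_sd_mult = 2) {
  stopifnot(all(c("sample", "gene", "plate", "ct1", "ct2", "ct3") %in%
                  names(ct_table)))
  ct <- as.matrix(ct_table[, c("ct1", "ct2", "ct3")])
  out <- ct_table
  out$mean_ct <- rowMeans(ct)
  out$sd_ct <- apply(ct, 1, sd)
  reason <- rep("none", nrow(out))
  reason[out$sd_ct > max_sd] <- "high_sd"
  reason[apply(ct > max_ct, 1, any)] <- "high_ct"  # high_ct takes precedence

  pass12 <- reason == "none"
  for (key in split(seq_len(nrow(out)),
                    list(out$gene, out$plate), drop = TRUE)) {
    idx <- key[pass12[key]]
    if (length(idx) < 3) {
      if (length(key) > 0)
        message("plate filter skipped for gene '", out$gene[key[1]],
                "' on plate '", out$plate[key[1]], "' (<3 passing records)")
      next
    }
    mu <- mean(out$mean_ct[idx])
    s <- sd(out$mean_ct[idx])
    outlier <- idx[abs(out$mean_ct[idx] - mu) > plate_sd_mult * s]
    reason[outlier] <- "plate_outlier"
  }
  out$exclusion_reason <- reason
  out$qc_pass <- reason == "none"
  out
}

#' Delta-Ct normalization against a reference gene
#'
#' For each sample and target gene passing QC, dct = mean Ct(gene) - mean
#' Ct(reference). Per gene, samples with dct outside mean +/- 2 SD are then
#' flagged `dct_outlier` and removed (SD = 0 excludes nothing). Samples
#' lacking a passing reference measurement are dropped with a message.
#'
#' @param records QC'd Ct table from [triplicate_qc()].
#' @param reference_gene Reference gene id (e.g. "GAPDH").
#' @param sd_mult Outlier multiple on the per-gene dct distribution.
#' @return data.frame sample/gene/dct for retained measurements.
#' @export
delta_ct <- function(records, reference_gene, sd_mult = 2) {
  stopifnot("qc_pass" %in% names(records))
  ok <- records[records$qc_pass, , drop = FALSE]
  ref <- ok[ok$gene == reference_gene, , drop = FALSE]
  if (nrow(ref) == 0) stop("no passing measurements for the reference gene")
  targets <- ok[ok$gene != reference_gene, , drop = FALSE]
  ref_ct <- setNames(ref$mean_ct, ref$sample)
  missing <- !(targets$sample %in% names(ref_ct))
  if (any(missing)) {
    message("dropping ", sum(missing),
            " measurement(s) without a passing reference")
    targets <- targets[!missing, , drop = FALSE]
  }
  out <- data.frame(sample = targets$sample, gene = targets$gene,
                    dct = targets$mean_ct - ref_ct[targets$sample],
                    stringsAsFactors = FALSE, row.names = NULL)
  keep <- unlist(lapply(split(seq_len(nrow(out)), out$gene), function(idx) {
    mu <- mean(out$dct[idx])
    s <- sd(out$dct[idx])
    if (is.na(s) || s == 0) return(idx)
    idx[abs(out$dct[idx] - mu) <= sd_mult * s]
  }), use.names = FALSE)
  out[sort(keep), , drop = FALSE]
}

#' Fold change from delta-Ct values (2^-ddCt)
#'
#' ddCt = mean(dct cases) - mean(dct controls); since high Ct means low
#' expression, a fold change below 1 indicates under-expression in cases.
#' `fold_change(x, y) * fold_change(y, x) == 1`.
#'
#' @param dct_cases,dct_controls Numeric vectors of per-sample dct values.
#' @return Fold change 2^-ddCt.
#' @export
fold_change <- function(dct_cases, dct_controls) {
  if (length(dct_cases) == 0 || length(dct_controls) == 0)
    stop("both groups must be nonempty")
  2^-(mean(dct_cases) - mean(dct_controls))
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Exact test for small samples (both groups <= 20, no ties), normal
#' approximation with tie correction otherwise. W is the Mann-Whitney
#' statistic of the smaller group (ties in group size: the first level of
#' `status`); all-tied data returns p = 1.
#'
#' @param values Numeric vector (e.g. residualized dct).
#' @param status Two-level grouping of the same length (levels ordered
#'   control, case where applicable).
#' @return List with `W`, `p` and the group sizes.
#' @export
group_compare <- function(values, status) {
  status <- as.factor(status)
  if (nlevels(status) != 2) stop("status must have exactly two levels")
  g1 <- values[status == levels(status)[1]]
  g2 <- values[status == levels(status)[2]]
  if (length(g1) == 0 || length(g2) == 0) stop("both groups must be nonempty")
  n <- c(length(g1), length(g2))
  if (length(unique(c(g1, g2))) == 1)
    return(list(W = n[1] * n[2] / 2, p = 1, n = n))
  # smaller-group convention: W is the Mann-Whitney U of the smaller group
  if (n[2] < n[1]) { tmp <- g1; g1 <- g2; g2 <- tmp; n <- rev(n) }
  wt <- suppressWarnings(wilcox.test(g1, g2, exact = max(n) <= 20,
                                     correct = TRUE))
  list(W = unname(wt$statistic), p = wt$p.value, n = n)
}

#' Spearman concordance between array and qPCR measurements
#'
#' Spearman rank correlation with average ranks for ties. Expression and Ct
#' encode opposite directions, so concordant platforms give a negative rho.
#'
#' @param array_residuals,qpcr_residuals Paired per-sample residuals
#'   (>= 3 pairs).
#' @return List with `rho` and `p` (t-approximation for tied data,
#'   exact/AS89 otherwise via [stats::cor.test()]).
#' @export
platform_concordance <- function(array_residuals, qpcr_residuals) {
  if (length(array_residuals) != length(qpcr_residuals))
    stop("inputs must be paired")
  if (length(array_residuals) < 3) stop("at least 3 paired samples required")
  if (sd(array_residuals) == 0 || sd(qpcr_residuals) == 0)
    stop("constant input")
  ct <- suppressWarnings(cor.test(array_residuals, qpcr_residuals,
                                  method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
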