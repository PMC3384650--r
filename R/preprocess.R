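# Probe-level filtering, normalization, batch adjustment, probe-to-gene
# collapsing and variable-gene selection.

#' Filter probes on detection p-values
#'
#' Retains exactly the probes whose detection p-value is strictly below
#' `alpha` in at least one sample; probe order is preserved.
#'
#' @param probes A list with `values` and `detection_p` (probes x samples
#'   matrices of identical shape) and optionally `annotation`
#'   (data.frame probe/gene); [simulate_cohort()] output works directly.
#' @param alpha Detection threshold in (0, 1).
#' @return The input list with non-detected probes removed.
#' @export
detection_filter <- function(probes, alpha = 0.01) {
  stopifnot(is.list(probes), alpha > 0, alpha < 1)
  v <- probes$values
  d <- probes$detection_p
  if (!identical(dim(v), dim(d)))
    stop("`values` and `detection_p` must have identical dimensions")
  keep <- apply(d, 1, min) < alpha
  if (!any(keep)) warning("detection filter removed every probe")
  probes$values <- v[keep, , drop = FALSE]
  probes$detection_p <- d[keep, , drop = FALSE]
  if (!is.null(probes$annotation))
    probes$annotation <-
      probes$annotation[probes$annotation$probe %in% rownames(probes$values), ,
                        drop = FALSE]
  probes
}

#' Normalize expression values across samples
#'
#' Variance stabilization plus cross-sample distribution equalization:
#' raw-scale input is log2(x + 1) transformed, then all samples are quantile
#' normalized to the common reference (the row mean of the sorted columns),
#' so that after normalization every sample has the identical sorted value
#' vector. The map is monotone within each sample and idempotent on its own
#' output.
#'
#' @param x Probes/genes x samples numeric matrix.
#' @param log2_input `TRUE` (default) if `x` is already on a log-like scale;
#'   `FALSE` applies log2(x + 1) first (requires non-negative values).
#' @return Normalized matrix of the same shape.
#' @export
normalize_expression <- function(x, log2_input = TRUE) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite values in expression matrix")
  if (!log2_input) {
    if (any(x < 0)) stop("raw-scale input must be non-negative")
    x <- log2(x + 1)
  }
  limma::normalizeQuantiles(x, ties = TRUE)
}

#' Remove batch offsets by per-gene mean centering
#'
#' For each gene, shifts every batch so its mean equals the gene's grand
#' mean; within-batch deviations are unchanged. This removes additive
#' array-generation offsets.
#'
#' @param x Genes x samples matrix.
#' @param batch Batch label per sample (length `ncol(x)`).
#' @return Adjusted matrix.
#' @export
adjust_batch <- function(x, batch) {
  x <- as.matrix(x)
  batch <- as.factor(batch)
  if (length(batch) != ncol(x)) stop("one batch label per sample required")
  sizes <- table(batch)
  if (any(sizes < 2)) stop("singleton batch: every batch needs >= 2 samples")
  grand <- rowMeans(x)
  for (b in levels(batch)) {
    idx <- which(batch == b)
    x[, idx] <- x[, idx] - rowMeans(x[, idx, drop = FALSE]) + grand
  }
  x
}

#' Collapse probes to genes
#'
#' One probe is selected per gene: a single probe passes through; of two
#' probes the one with the highest maximum expression over samples wins; of
#' three or more probes the one with the highest soft-threshold connectivity
#' wins. Connectivity of a candidate probe is the sum of |cor|^beta to the
#' gene's other probes and to a seeded random background panel of probes
#' from other genes (the probe most coherent with real co-expression
#' structure wins over a noise probe). Ties break towards the
#' lexicographically first probe id.
#'
#' @param probes List with `values` (probes x samples) and `annotation`
#'   (data.frame probe/gene).
#' @param beta Soft-threshold power for the connectivity rule.
#' @param background_n Size of the random background panel.
#' @param seed Seed for the background panel draw.
#' @return List with `values` (genes x samples, rows ordered by gene id) and
#'   `selected` (data.frame gene/probe/n_probes/rule).
#' @export
collapse_probes <- function(probes, beta = 6, background_n = 500, seed = 1) {
  v <- probes$values
  ann <- probes$annotation
  if (is.null(ann)) stop("probe annotation required for collapsing")
  ann <- ann[match(rownames(v), ann$probe), , drop = FALSE]
  if (any(is.na(ann$gene))) stop("every probe needs a gene annotation")

  split_probes <- split(ann$probe, ann$gene)
  multi3 <- names(split_probes)[lengths(split_probes) >= 3]

  # connectivity universe for the >=3-probe rule: candidate probes + panel
  k_of <- NULL
  if (length(multi3) > 0) {
    cand <- unlist(split_probes[multi3], use.names = FALSE)
    pool <- setdiff(rownames(v), cand)
    panel <- with_salted_seed(seed, 7, sample(pool, min(background_n, length(pool))))
    universe <- unique(c(cand, panel))
    # correlations of candidates against the whole universe
    cc <- suppressWarnings(cor(t(v[cand, , drop = FALSE]),
                               t(v[universe, , drop = FALSE])))
    cc[!is.finite(cc)] <- 0
    a <- abs(cc)^beta
    k_all <- rowSums(a)
    # subtract self-correlation term (|cor(p,p)|^beta = 1)
    k_of <- k_all - 1
    names(k_of) <- cand
  }

  pick <- character(length(split_probes))
  rule <- character(length(split_probes))
  for (i in seq_along(split_probes)) {
    ps <- sort(split_probes[[i]])
    if (length(ps) == 1) {
      pick[i] <- ps
      rule[i] <- "single"
    } else if (length(ps) == 2) {
      mx <- apply(v[ps, , drop = FALSE], 1, max)
      pick[i] <- ps[which.max(mx)]  # ties -> first (lexicographic)
      rule[i] <- "max_expression"
    } else {
      k <- k_of[ps]
      pick[i] <- ps[which.max(k)]
      rule[i] <- "max_connectivity"
    }
  }
  genes <- names(split_probes)
  out <- v[pick, , drop = FALSE]
  rownames(out) <- genes
  list(values = out,
       selected = data.frame(gene = genes, probe = pick,
                             n_probes = lengths(split_probes),
                             rule = rule, row.names = NULL,
                             stringsAsFactors = FALSE))
}

#' Select the most variable genes
#'
#' Ranks genes by sample variance and keeps the top `n_top`; ties break by
#' lexicographic gene id for determinism. If fewer genes are present than
#' requested, all are kept (genome-wide mode) with a message.
#'
#' @param x Genes x samples matrix.
#' @param n_top Number of genes to keep (default 5000).
#' @return The matrix restricted to the selected genes, original row order.
#' @export
select_variable_genes <- function(x, n_top = 5000) {
  x <- as.matrix(x)
  if (n_top >= nrow(x)) {
    if (n_top > nrow(x))
      message("fewer genes than n_top; keeping all ", nrow(x), " genes")
    return(x)
  }
  v <- apply(x, 1, var)
  ord <- order(-v, rownames(x))
  keep <- sort(ord[seq_len(n_top)])
  x[keep, , drop = FALSE]
}

#' Ordinary least-squares residualization
#'
#' Removes covariate effects by OLS: the returned residuals are orthogonal
#' to every design column. Used for the array/qPCR concordance analysis
#' (expression residualized on cohort, age and sex; delta-Ct residualized on
#' plate, age and sex).
#'
#' @param values Numeric vector (per-sample) or matrix (features x samples).
#' @param covariates data.frame of covariates (an intercept is added) or a
#'   numeric design matrix used as-is.
#' @return Residuals with the shape of `values`.
#' @export
residualize <- function(values, covariates) {
  design <- if (is.matrix(covariates)) covariates
            else model.matrix(~ ., data = as.data.frame(covariates))
  n <- if (is.matrix(values)) ncol(values) else length(values)
  if (nrow(design) != n) stop("covariate rows must match samples")
  if (n <= ncol(design)) stop("more design columns than samples")
  if (qr(design)$rank < ncol(design)) stop("rank-deficient design")
  if (is.matrix(values)) {
    fit <- lm.fit(design, t(values))
    t(fit$residuals)
  } else {
    lm.fit(design, values)$residuals
  }
}
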