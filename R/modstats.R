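# Module eigengenes, covariate-adjusted disease association, intramodular
# connectivity and hub genes.

#' Module eigengenes (first principal components)
#'
#' Each proper module is summarized by the leading left-singular direction
#' over samples of its standardized expression submatrix (genes scaled to
#' mean 0, variance 1 across samples). Scores have unit Euclidean norm and
#' the sign is anchored so the eigengene correlates positively with the
#' module's mean expression profile, making "under-expressed in cases"
#' equivalent to a negative status coefficient downstream.
#'
#' @param x Genes x samples matrix.
#' @param modules A `module_assignment` or named label vector; "grey" is
#'   ignored.
#' @return List with `eigengenes` (samples x modules matrix, columns in
#'   decreasing module size order) and `var_explained` (named vector, share
#'   of variance captured by the first component).
#' @export
module_eigengenes <- function(x, modules) {
  labels <- module_labels(modules)
  x <- as.matrix(x)
  labels <- labels[names(labels) %in% rownames(x)]
  mods <- names(sort(table(labels[labels != "grey"]), decreasing = TRUE))
  if (length(mods) == 0) stop("no proper modules")
  scores <- matrix(NA_real_, nrow = ncol(x), ncol = length(mods),
                   dimnames = list(colnames(x), mods))
  ve <- setNames(numeric(length(mods)), mods)
  for (m in mods) {
    genes <- names(labels)[labels == m]
    if (length(genes) < 2) stop("module '", m, "' has fewer than 2 genes")
    sub <- x[genes, , drop = FALSE]
    sub <- t(scale(t(sub)))  # standardize each gene across samples
    if (any(!is.finite(sub))) stop("constant gene in module '", m, "'")
    sv <- svd(sub, nu = 0, nv = 1)
    e <- sv$v[, 1]
    anchor <- cor(e, colMeans(sub))
    if (!is.na(anchor) && anchor < 0) e <- -e
    scores[, m] <- e
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = scores, var_explained = ve)
}

#' Associate module eigengenes with disease status
#'
#' Ordinary least-squares regression of each eigengene on disease status
#' with age and sex as covariates; reports the status coefficient
#' t-statistic, its two-sided p-value and the Benjamini-Hochberg q-value
#' across all modules tested here (the FDR family is the set of modules
#' tested in the dataset). Status is coded control = 0, case = 1, so t < 0
#' means the module's genes are predominantly under-expressed in cases
#' (via the eigengene sign convention).
#'
#' @param eigengenes Samples x modules matrix (or [module_eigengenes()]
#'   output).
#' @param covariates data.frame with columns `status` (factor with levels
#'   control, case — or 0/1 numeric), `age`, `sex`.
#' @return data.frame with module, t, p, q (sorted by increasing p).
#' @export
associate_modules <- function(eigengenes, covariates) {
  if (is.list(eigengenes) && !is.null(eigengenes$eigengenes))
    eigengenes <- eigengenes$eigengenes
  eigengenes <- as.matrix(eigengenes)
  cv <- as.data.frame(covariates)
  if (!all(c("status", "age", "sex") %in% names(cv)))
    stop("covariates must contain status, age and sex")
  status <- if (is.numeric(cv$status)) cv$status
            else as.numeric(factor(cv$status, levels = c("control", "case"))) - 1
  design <- cbind(intercept = 1, status = status, age = cv$age,
                  sex = as.numeric(as.factor(cv$sex)) - 1)
  if (nrow(design) != nrow(eigengenes)) stop("sample mismatch")
  if (qr(design)$rank < ncol(design)) stop("rank-deficient design")

  res <- lapply(colnames(eigengenes), function(m) {
    fit <- lm(eigengenes[, m] ~ design - 1)
    s <- summary(fit)$coefficients
    data.frame(module = m, t = s["designstatus", "t value"],
               p = s["designstatus", "Pr(>|t|)"], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}

#' Intramodular connectivity and hub genes
#'
#' For each gene of a proper module: k_within_raw is the sum of adjacency to
#' the other genes of its own module; k_within divides by the module
#' maximum (so the hub has k_within = 1). Exactly one hub per module; ties
#' break to the lexicographically first gene. Grey genes get no report.
#'
#' @param adj A `coex_adjacency` or adjacency matrix.
#' @param modules A `module_assignment` or named label vector.
#' @return data.frame gene/module/k_within_raw/k_within/is_hub.
#' @export
intramodular_connectivity <- function(adj, modules) {
  labels <- module_labels(modules)
  a <- as_adjacency_matrix(adj)
  labels <- labels[names(labels) %in% rownames(a)]
  mods <- names(sort(table(labels[labels != "grey"]), decreasing = TRUE))
  out <- lapply(mods, function(m) {
    genes <- sort(names(labels)[labels == m])
    k <- connectivity(a, genes)
    hub <- genes[which.max(k)]  # which.max -> first max; genes sorted
    data.frame(gene = genes, module = m, k_within_raw = unname(k),
               k_within = unname(k) / max(k), is_hub = genes == hub,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
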