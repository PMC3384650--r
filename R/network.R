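# Weighted co-expression network construction and module detection.

# Size-ranked module color palette (largest proper module first); names are
# labels only.
module_color_palette <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue")

#' Soft-thresholded co-expression adjacency
#'
#' Computes the weighted adjacency a_ij = |cor(x_i, x_j)|^beta between all
#' gene pairs (unsigned network; a signed variant uses
#' ((1 + cor)/2)^beta). The diagonal is fixed at 1 by convention and is
#' excluded from the connectivity k. Genes with zero variance are dropped
#' with a warning (their correlation is undefined).
#'
#' @param x Genes x samples matrix (>= 3 samples).
#' @param beta Soft-threshold power (>= 1), default 6.
#' @param signed Use the signed adjacency variant.
#' @return A `coex_adjacency` list: `adjacency` (symmetric matrix in
#'   \[0,1\]), `k` (named connectivity vector, diagonal excluded), `beta`,
#'   `signed`.
#' @export
soft_adjacency <- function(x, beta = 6, signed = FALSE) {
  x <- as.matrix(x)
  if (ncol(x) < 3) stop("at least 3 samples required")
  if (beta < 1) stop("beta must be >= 1")
  v <- apply(x, 1, var)
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0), " zero-variance gene(s)")
    x <- x[v > 0, , drop = FALSE]
  }
  r <- cor(t(x))
  a <- if (signed) ((1 + r) / 2)^beta else abs(r)^beta
  a <- pmin(pmax(a, 0), 1)
  diag(a) <- 1
  k <- rowSums(a) - 1
  structure(list(adjacency = a, k = k, beta = beta, signed = signed),
            class = "coex_adjacency")
}

as_adjacency_matrix <- function(adj) {
  if (inherits(adj, "coex_adjacency")) adj$adjacency else as.matrix(adj)
}

#' Topological overlap matrix
#'
#' TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' l_ij = sum_{u != i,j} a_iu a_uj; TOM measures shared network
#' neighborhoods in addition to the direct connection. The diagonal is 1 and
#' `diss = 1 - tom` is the clustering dissimilarity.
#'
#' @param adj A `coex_adjacency` or plain adjacency matrix (diagonal 1).
#' @return List with `tom` and `diss` matrices.
#' @export
topological_overlap <- function(adj) {
  a <- as_adjacency_matrix(adj)
  a0 <- a
  diag(a0) <- 0
  l <- a0 %*% a0            # l_ij = sum_u a_iu a_uj, u != i, j (diag zeroed)
  k <- rowSums(a0)
  denom <- outer(k, k, pmin) + 1 - a0
  tom <- (l + a0) / denom
  tom <- pmin(pmax(tom, 0), 1)
  diag(tom) <- 1
  list(tom = tom, diss = 1 - tom)
}

#' Connectivity (sum of connection strengths)
#'
#' Row sums of the adjacency with the diagonal excluded, optionally
#' restricted to a gene subset (intramodular semantics: for genes in
#' `subset`, sum of adjacency to the other `subset` genes).
#'
#' @param adj A `coex_adjacency` or adjacency matrix.
#' @param subset Optional character vector of gene ids.
#' @return Named numeric vector of connectivities.
#' @export
connectivity <- function(adj, subset = NULL) {
  a <- as_adjacency_matrix(adj)
  if (is.null(subset)) {
    rowSums(a) - diag(a)
  } else {
    if (length(subset) == 0) stop("empty gene subset")
    if (!all(subset %in% rownames(a))) stop("subset genes absent from adjacency")
    sub <- a[subset, subset, drop = FALSE]
    rowSums(sub) - diag(sub)
  }
}

#' Detect modules as branches of an average-linkage tree
#'
#' Average-linkage hierarchical clustering on the TOM dissimilarity; the
#' tree is cut at a static height (`"auto"` = 0.99 x the maximum merge
#' height) and branches smaller than `min_module_size` are assigned to the
#' improper "grey" module. Proper modules are named from a fixed palette by
#' decreasing size (largest = "turquoise").
#'
#' @param diss Symmetric dissimilarity matrix (1 - TOM), or the list
#'   returned by [topological_overlap()].
#' @param min_module_size Minimum branch size for a proper module.
#' @param cut_height Static cut height in (0, 1\], or `"auto"`.
#' @return A `module_assignment` list: `labels` (named character; "grey"
#'   for unassigned), `dendrogram` (the hclust object, its merge record),
#'   `cut_height` (numeric height used), `sizes` (named sizes of proper
#'   modules, decreasing).
#' @export
detect_modules <- function(diss, min_module_size = 30, cut_height = "auto") {
  if (is.list(diss) && !is.null(diss$diss)) diss <- diss$diss
  diss <- as.matrix(diss)
  if (any(!is.finite(diss))) stop("non-finite dissimilarities")
  hc <- hclust(as.dist(diss), method = "average")
  h <- if (identical(cut_height, "auto")) 0.99 * max(hc$height)
       else as.numeric(cut_height)
  cl <- cutree(hc, h = h)
  sizes <- table(cl)
  proper <- names(sizes)[sizes >= min_module_size]
  labels <- setNames(rep("grey", length(cl)), names(cl))
  if (length(proper) > 0) {
    # order proper branches by decreasing size; ties by branch id
    ord <- proper[order(-sizes[proper], as.integer(proper))]
    palette <- c(module_color_palette,
                 sprintf("module%d", seq_len(max(0, length(ord) -
                                                    length(module_color_palette)))))
    for (i in seq_along(ord))
      labels[cl == as.integer(ord[i])] <- palette[i]
  }
  mod_sizes <- sort(table(labels[labels != "grey"]), decreasing = TRUE)
  structure(list(labels = labels, dendrogram = hc, cut_height = h,
                 sizes = mod_sizes),
            class = "module_assignment")
}

module_labels <- function(modules) {
  if (inherits(modules, "module_assignment")) modules$labels else modules
}

#' Export a thresholded TOM edge list
#'
#' Upper-triangle gene pairs with TOM above `threshold`, for import into
#' graph viewers.
#'
#' @param tom TOM matrix or [topological_overlap()] output.
#' @param threshold Minimum TOM to keep an edge.
#' @param genes Optional subset of genes (e.g. one module).
#' @return data.frame gene1/gene2/tom, decreasing by weight.
#' @export
tom_edge_list <- function(tom, threshold = 0.1, genes = NULL) {
  if (is.list(tom) && !is.null(tom$tom)) tom <- tom$tom
  if (!is.null(genes)) tom <- tom[genes, genes, drop = FALSE]
  idx <- which(upper.tri(tom) & tom > threshold, arr.ind = TRUE)
  out <- data.frame(gene1 = rownames(tom)[idx[, 1]],
                    gene2 = colnames(tom)[idx[, 2]],
                    tom = tom[idx], stringsAsFactors = FALSE)
  out[order(-out$tom), , drop = FALSE]
}
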