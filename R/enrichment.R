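# Gene-set, brain-expression and GWAS SNP enrichment of modules.

#' Hypergeometric enrichment of a module for a candidate gene list
#'
#' All counts are taken after intersection with the background universe
#' (e.g. the genes that entered the network). The p-value is the upper
#' hypergeometric tail P(X >= overlap) with population `background`,
#' successes = list genes in background, draws = module size; Bonferroni
#' adjustment multiplies by the size of the test family.
#'
#' @param module_genes,candidate_list Character vectors of gene ids.
#' @param background Character vector: the gene universe.
#' @param n_tests Size of the test family for Bonferroni (default 1).
#' @return One-row data.frame: overlap, list_in_background, module_size,
#'   background_size, p, p_adjusted.
#' @export
hypergeom_list_enrichment <- function(module_genes, candidate_list,
                                      background, n_tests = 1) {
  if (length(background) == 0) stop("empty background universe")
  background <- unique(background)
  module_genes <- intersect(unique(module_genes), background)
  list_bg <- intersect(unique(candidate_list), background)
  overlap <- length(intersect(module_genes, list_bg))
  N <- length(background)
  K <- length(list_bg)
  m <- length(module_genes)
  p <- phyper(overlap - 1, K, N - K, m, lower.tail = FALSE)
  data.frame(overlap = overlap, list_in_background = K, module_size = m,
             background_size = N, p = p,
             p_adjusted = min(1, p * n_tests))
}

#' Enrichment of every module for every candidate list
#'
#' Bonferroni correction is applied across the full modules x lists family.
#'
#' @param modules A `module_assignment` or named label vector ("grey"
#'   skipped).
#' @param lists Named list of candidate gene id vectors.
#' @param background Gene universe (default: the labeled genes).
#' @return data.frame with one row per module x list.
#' @export
module_list_enrichment <- function(modules, lists, background = NULL) {
  labels <- module_labels(modules)
  if (is.null(background)) background <- names(labels)
  mods <- names(sort(table(labels[labels != "grey"]), decreasing = TRUE))
  n_tests <- length(mods) * length(lists)
  out <- lapply(mods, function(m) {
    genes <- names(labels)[labels == m]
    rows <- lapply(names(lists), function(l) {
      r <- hypergeom_list_enrichment(genes, lists[[l]], background, n_tests)
      cbind(data.frame(module = m, list = l, stringsAsFactors = FALSE), r)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  out[order(out$p), , drop = FALSE]
}

#' Brain-expressed gene set from a brain expression matrix
#'
#' @param brain_matrix Genes x samples matrix on the log2 scale.
#' @param threshold Genes whose mean across samples strictly exceeds this
#'   are called brain-expressed (default 4).
#' @return Character vector of gene ids.
#' @export
brain_expressed_set <- function(brain_matrix, threshold = 4) {
  m <- rowMeans(as.matrix(brain_matrix))
  names(m)[m > threshold]
}

#' Fisher test for brain-expression enrichment of a target module
#'
#' One-sided (greater) Fisher's exact test of the 2x2 table with rows
#' {target module, other genes} and columns {brain-expressed, not}.
#'
#' @param target_module_genes,other_modules_genes Disjoint gene id vectors.
#' @param brain_set Brain-expressed gene ids.
#' @return List with `p`, `odds_ratio` and the 2x2 `table`.
#' @export
brain_enrichment_fisher <- function(target_module_genes, other_modules_genes,
                                    brain_set) {
  if (length(intersect(target_module_genes, other_modules_genes)) > 0)
    stop("gene groups must be disjoint")
  tab <- matrix(c(sum(target_module_genes %in% brain_set),
                  sum(!target_module_genes %in% brain_set),
                  sum(other_modules_genes %in% brain_set),
                  sum(!other_modules_genes %in% brain_set)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("target", "other"),
                                c("brain", "not_brain")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("empty margin in 2x2 table")
  ft <- fisher.test(tab, alternative = "greater")
  list(p = ft$p.value, odds_ratio = unname(ft$estimate), table = tab)
}

#' Map SNPs to genes within a window
#'
#' A SNP maps to a gene iff it lies on the same chromosome within
#' \[start - window, end + window\] (1-based inclusive coordinates, window
#' boundaries inclusive). A SNP inside several gene windows maps to all of
#' them.
#'
#' @param snps data.frame with columns snp, chrom, pos, p.
#' @param coords data.frame with columns gene, chrom, start, end.
#' @param window Flank size in base pairs (default 10000).
#' @return data.frame gene/snp/p (long format), one row per mapping.
#' @export
snp_gene_map <- function(snps, coords, window = 10000) {
  stopifnot(all(c("snp", "chrom", "pos", "p") %in% names(snps)),
            all(c("gene", "chrom", "start", "end") %in% names(coords)))
  bad <- which(!is.finite(snps$pos) | snps$pos < 1 | snps$pos != round(snps$pos))
  if (length(bad) > 0)
    stop("malformed SNP positions at rows: ", paste(bad, collapse = ", "))
  bad <- which(!is.finite(coords$start) | !is.finite(coords$end) |
                 coords$start < 1 | coords$end < coords$start)
  if (length(bad) > 0)
    stop("malformed gene coordinates at rows: ", paste(bad, collapse = ", "))
  out <- lapply(seq_len(nrow(coords)), function(i) {
    hit <- snps$chrom == coords$chrom[i] &
      snps$pos >= coords$start[i] - window &
      snps$pos <= coords$end[i] + window
    if (!any(hit)) return(NULL)
    data.frame(gene = coords$gene[i], snp = snps$snp[hit], p = snps$p[hit],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene = character(0), snp = character(0),
                      p = numeric(0), stringsAsFactors = FALSE)
  out
}

#' GWAS enrichment of a mapped SNP set for nominal association
#'
#' Counts SNPs with p < `alpha` among those mapped to the module's genes
#' and tests the count against the expected proportion `alpha` with the
#' exact binomial upper tail. `all_snps` counts every mapped SNP once;
#' `best_snp_per_gene` first reduces to the minimum p per gene (note: this
#' is anti-conservative under the nominal 5% null, since a minimum of
#' several uniform p-values falls below alpha more often than alpha; the
#' flag `anti_conservative` marks it). QQ points (expected vs observed
#' -log10 p) are returned for plotting; expected quantiles are i/(n+1).
#'
#' @param map data.frame gene/snp/p from [snp_gene_map()].
#' @param mode "all_snps" or "best_snp_per_gene".
#' @param alpha Nominal significance threshold (default 0.05).
#' @return List: mode, n_tested, n_nominal, alpha, p_enrichment, qq_points,
#'   n_genes, anti_conservative.
#' @export
gwas_enrichment <- function(map, mode = c("all_snps", "best_snp_per_gene"),
                            alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha < 1, all(is.finite(map$p)))
  if (mode == "all_snps") {
    keep <- !duplicated(map$snp)
    pv <- map$p[keep]
  } else {
    pv <- vapply(split(map$p, map$gene), min, numeric(1))
  }
  n <- length(pv)
  n_nominal <- sum(pv < alpha)
  p_enr <- if (n == 0) 1 else pbinom(n_nominal - 1, n, alpha, lower.tail = FALSE)
  pv_sorted <- sort(pv)
  qq <- data.frame(expected = -log10(seq_len(n) / (n + 1)),
                   observed = -log10(pv_sorted))
  list(mode = mode, n_tested = n, n_nominal = n_nominal, alpha = alpha,
       p_enrichment = p_enr, qq_points = qq,
       n_genes = length(unique(map$gene)),
       anti_conservative = mode == "best_snp_per_gene")
}
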