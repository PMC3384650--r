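# Permutation-based module preservation between a reference and a test
# cohort: is a module, defined in one dataset, denser and similarly wired
# in an independent dataset than random gene sets of the same size?

#' Match reference genes into a test gene universe
#'
#' @param genes_ref,genes_test Character vectors of gene ids.
#' @return The intersection, preserving reference order.
#' @export
module_overlap_map <- function(genes_ref, genes_test) {
  matched <- genes_ref[genes_ref %in% genes_test]
  if (length(matched) == 0) stop("no genes shared between the two datasets")
  matched
}

#' Module preservation Z statistics
#'
#' For each proper reference module with matched gene set M, two observed
#' statistics are computed: density D(M), the mean off-diagonal
#' test-adjacency within M, and connectivity C(M), the correlation over M
#' between intramodular connectivity in the reference and in the test
#' network. A permutation null replaces M by random gene sets of the same
#' size drawn from the matched universe; each statistic is standardized to
#' Z = (observed - null mean) / null SD, and z_summary is the mean of the
#' two (a two-statistic composite of the published Z-summary family, used
#' against the conventional thresholds: Z > 2 preserved, > 8 strongly
#' preserved). A zero permutation SD yields +/-Inf with a message.
#'
#' @param x_ref,x_test Genes x samples matrices (preprocessed comparably).
#' @param modules_ref A `module_assignment` or named label vector on the
#'   reference genes.
#' @param beta Soft-threshold power for both networks.
#' @param n_permutations Number of random gene sets (default 200).
#' @param seed Integer RNG seed for the permutation draw.
#' @return data.frame module/n_genes_matched/z_density/z_connectivity/
#'   z_summary/n_permutations/seed.
#' @export
preservation_summary <- function(x_ref, x_test, modules_ref, beta = 6,
                                 n_permutations = 200, seed = 1) {
  labels <- module_labels(modules_ref)
  x_ref <- as.matrix(x_ref)
  x_test <- as.matrix(x_test)
  matched <- module_overlap_map(rownames(x_ref), rownames(x_test))
  a_ref <- soft_adjacency(x_ref[matched, , drop = FALSE], beta = beta)$adjacency
  a_test <- soft_adjacency(x_test[matched, , drop = FALSE], beta = beta)$adjacency

  labels <- labels[intersect(names(labels), matched)]
  mods <- names(sort(table(labels[labels != "grey"]), decreasing = TRUE))
  if (length(mods) == 0) stop("no proper modules among matched genes")

  density_stat <- function(a, set) {
    sub <- a[set, set, drop = FALSE]
    m <- length(set)
    (sum(sub) - m) / (m * (m - 1))
  }
  conn_stat <- function(set) {
    kr <- connectivity(a_ref, set)
    kt <- connectivity(a_test, set)
    if (sd(kr) == 0 || sd(kt) == 0) return(0)
    cor(kr, kt)
  }

  universe <- sort(matched)  # canonical order: z invariant to input gene order
  with_salted_seed(seed, 8, {
    out <- lapply(mods, function(m) {
      set <- names(labels)[labels == m]
      if (length(set) < 2) stop("module '", m, "' has < 2 matched genes")
      obs_d <- density_stat(a_test, set)
      obs_c <- conn_stat(set)
      perm_d <- numeric(n_permutations)
      perm_c <- numeric(n_permutations)
      for (i in seq_len(n_permutations)) {
        rand <- sample(universe, length(set))
        perm_d[i] <- density_stat(a_test, rand)
        perm_c[i] <- conn_stat(rand)
      }
      z_of <- function(obs, perm, stat) {
        s <- sd(perm)
        if (s == 0) {
          message("degenerate permutation null for ", stat, " of module '",
                  m, "'; Z set to +/-Inf")
          return(if (obs > mean(perm)) Inf else if (obs < mean(perm)) -Inf else NaN)
        }
        (obs - mean(perm)) / s
      }
      zd <- z_of(obs_d, perm_d, "density")
      zc <- z_of(obs_c, perm_c, "connectivity")
      data.frame(module = m, n_genes_matched = length(set),
                 z_density = zd, z_connectivity = zc,
                 z_summary = (zd + zc) / 2,
                 n_permutations = n_permutations, seed = seed,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}
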