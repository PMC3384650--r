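# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so simulation functions are pure in their `seed` argument.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Decorrelate RNG streams across functions: without this, a workflow that
# reuses one seed (e.g. generate_truth(seed = 1) followed by
# preservation_summary(..., seed = 1)) would replay the same stream prefix,
# and permutation draws could echo the planted assignment. Each simulation
# or permutation function passes its own salt.
with_salted_seed <- function(seed, salt, code) {
  with_seed((as.numeric(seed) + salt * 1e6) %% 2147483647, code)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items.
#' Used to score recovered module assignments against a planted truth;
#' label names are irrelevant, only the induced partitions matter.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return A single number in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sum_ij <- sum_comb(tab)
  sum_a <- sum_comb(rowSums(tab))
  sum_b <- sum_comb(colSums(tab))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Score recovered modules against a planted truth
#'
#' @param labels Named character vector of module labels (e.g. from
#'   [detect_modules()]); "grey" is treated as one background group.
#' @param truth A `synthetic_truth` object from [generate_truth()].
#' @return Adjusted Rand index between the recovered partition and the
#'   planted membership, over the genes present in `labels`.
#' @export
score_module_recovery <- function(labels, truth) {
  genes <- names(labels)
  if (is.null(genes)) stop("`labels` must be named by gene id")
  missing <- setdiff(genes, names(truth$module_membership))
  if (length(missing) > 0) stop("labels contain genes absent from truth")
  adjusted_rand_index(unname(labels), unname(truth$module_membership[genes]))
}
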