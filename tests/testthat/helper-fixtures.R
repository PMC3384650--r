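# Small fixture builders used across test files.

# Named module labels ("m1".."mK" / "grey") from a synthetic truth.
truth_labels <- function(truth) {
  setNames(ifelse(truth$module_membership > 0,
                  paste0("m", truth$module_membership), "grey"),
           names(truth$module_membership))
}

# Two planted blocks with exact within-block population correlation `rho`
# and independent blocks, as a genes x samples matrix.
block_matrix <- function(block_sizes, n_samples, rho = 0.9, seed = 1) {
  withr::with_seed(seed, {
    rows <- lapply(seq_along(block_sizes), function(b) {
      driver <- rnorm(n_samples)
      t(sapply(seq_len(block_sizes[b]), function(i)
        sqrt(rho) * driver + sqrt(1 - rho) * rnorm(n_samples)))
    })
    x <- do.call(rbind, rows)
    dimnames(x) <- list(sprintf("g%03d", seq_len(nrow(x))),
                        sprintf("s%03d", seq_len(n_samples)))
    x
  })
}

# A data vector pair with an exact empirical correlation r.
exact_cor_pair <- function(r, n = 20, seed = 1) {
  withr::with_seed(seed, {
    x <- scale(rnorm(n))[, 1]
    z <- rnorm(n)
    z <- scale(lm.fit(cbind(1, x), z)$residuals)[, 1]
    y <- r * x + sqrt(1 - r^2) * z
    rbind(x = x, y = y)
  })
}

# Minimal probe bundle for preprocess tests.
probe_bundle <- function(values, detection_p = NULL, annotation = NULL) {
  if (is.null(detection_p))
    detection_p <- matrix(0.001, nrow(values), ncol(values),
                          dimnames = dimnames(values))
  list(values = values, detection_p = detection_p, annotation = annotation)
}
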