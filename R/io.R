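# Plain-text (TSV) readers and writers for the pipeline's inputs/outputs.

write_tsv_matrix <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a simulated cohort to a directory of TSV files
#'
#' Emits `probes.tsv` (probes x samples), `detection.tsv` (same shape),
#' `annotation.tsv` (probe, gene) and `covariates.tsv`.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_matrix(cohort$values, file.path(dir, "probes.tsv"), "probe")
  write_tsv_matrix(cohort$detection_p, file.path(dir, "detection.tsv"), "probe")
  utils::write.table(cohort$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing the TSV files.
#' @return A list with `values`, `detection_p`, `annotation`, `covariates`,
#'   shaped like [simulate_cohort()] output.
#' @export
read_cohort <- function(dir) {
  cov <- utils::read.delim(file.path(dir, "covariates.tsv"),
                           stringsAsFactors = FALSE)
  cov$status <- factor(cov$status, levels = c("control", "case"))
  cov$sex <- factor(cov$sex, levels = c("F", "M"))
  cov$batch <- factor(cov$batch)
  list(values = read_tsv_matrix(file.path(dir, "probes.tsv")),
       detection_p = read_tsv_matrix(file.path(dir, "detection.tsv")),
       annotation = utils::read.delim(file.path(dir, "annotation.tsv"),
                                      stringsAsFactors = FALSE),
       covariates = cov)
}
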