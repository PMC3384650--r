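# Synthetic two-cohort expression data with planted co-expression modules.
#
# Generative model: each module q has a latent per-sample driver
#   e_q = N(0,1) + disease_effect[q] * I(case) + medication_effect[q] * I(medicated case)
# and each member gene i follows x_i = rho_i * e_q + sqrt(1 - rho_i^2) * eps_i,
# so rho_i is the gene-to-driver correlation and two members with rho_i, rho_j
# correlate at rho_i * rho_j in the population. Background genes are pure noise.
# Probes replicate the gene signal plus a per-probe offset and measurement
# noise; batches add per-gene offsets; a configurable fraction of probes is
# "dead" (no signal, uniform detection p-values).

#' Generate a planted module truth
#'
#' Draws module memberships, per-gene driver correlations, per-gene baseline
#' expression levels and per-module disease/medication effects. The returned
#' object is the ground truth against which cohort simulations and the
#' downstream pipeline are scored.
#'
#' @param n_genes Number of genes.
#' @param n_modules Number of planted modules (0 gives pure background).
#' @param module_size_range Length-2 integer vector; each module size is drawn
#'   uniformly from this range. `n_modules * max(size)` must not exceed
#'   `n_genes`.
#' @param corr_range Range (within (0,1)) for per-gene driver correlations.
#' @param disease_effect Per-module standardized shift of the driver with case
#'   status (recycled to `n_modules`). The default plants one pure disease
#'   module (module 1) with a -1.5 SD shift (negative: the disease module's
#'   genes are under-expressed in cases), sized so the smaller
#'   (replication-style, 29 cases / 40 controls) cohort has >99% power to
#'   detect the eigengene association at an FDR-adjusted threshold.
#' @param medication_effect Per-module shift applied to cases only in
#'   medicated cohorts (recycled). The default makes modules 2..n_modules
#'   medication-confounded (same 1.5 SD magnitude): associated with status
#'   in a medicated cohort, null in an antipsychotic-free one.
#' @param gwas_enriched_module Module index carrying planted GWAS signal
#'   (used by [simulate_gwas_table()]), or `NA` for none.
#' @param seed Integer RNG seed; output is deterministic in it.
#' @return A `synthetic_truth` list with fields `module_membership` (named
#'   integer, 0 = background), `module_corr` (named numeric, 0 for
#'   background), `baseline` (named numeric, log2-scale gene means),
#'   `disease_effect`, `medication_effect`, `module_sizes`,
#'   `gwas_enriched_module`, `n_genes`, `n_modules`, `seed`.
#' @export
generate_truth <- function(n_genes = 1000, n_modules = 5,
                           module_size_range = c(50, 150),
                           corr_range = c(0.5, 0.9),
                           disease_effect = c(-1.5, rep(0, max(0, n_modules - 1))),
                           medication_effect = c(0, rep(1.5, max(0, n_modules - 1))),
                           gwas_enriched_module = if (n_modules > 0) 1L else NA_integer_,
                           seed = 1) {
  stopifnot(n_genes >= 1, n_modules >= 0, length(module_size_range) == 2,
            length(corr_range) == 2)
  if (corr_range[1] <= 0 || corr_range[2] >= 1 || corr_range[1] > corr_range[2])
    stop("`corr_range` must lie strictly inside (0, 1)")
  if (n_modules > 0 && n_modules * module_size_range[2] > n_genes)
    stop("infeasible module size request: n_modules * max size exceeds n_genes")
  if (n_modules > 0) {
    disease_effect <- rep_len(disease_effect, n_modules)
    medication_effect <- rep_len(medication_effect, n_modules)
    if (!is.na(gwas_enriched_module) &&
        (gwas_enriched_module < 1 || gwas_enriched_module > n_modules))
      stop("`gwas_enriched_module` is not a planted module index")
  } else {
    disease_effect <- numeric(0)
    medication_effect <- numeric(0)
    gwas_enriched_module <- NA_integer_
  }

  genes <- sprintf("g%05d", seq_len(n_genes))
  with_salted_seed(seed, 1, {
    sizes <- if (n_modules > 0)
      sample(seq(module_size_range[1], module_size_range[2]), n_modules,
             replace = TRUE)
    else integer(0)
    membership <- setNames(integer(n_genes), genes)
    shuffled <- sample(genes)
    at <- 1L
    for (q in seq_len(n_modules)) {
      membership[shuffled[at:(at + sizes[q] - 1L)]] <- q
      at <- at + sizes[q]
    }
    corr <- setNames(numeric(n_genes), genes)
    in_mod <- membership > 0
    corr[in_mod] <- runif(sum(in_mod), corr_range[1], corr_range[2])
    baseline <- setNames(runif(n_genes, 6, 12), genes)

    structure(list(
      module_membership = membership,
      module_corr = corr,
      baseline = baseline,
      disease_effect = disease_effect,
      medication_effect = medication_effect,
      module_sizes = sizes,
      gwas_enriched_module = gwas_enriched_module,
      n_genes = n_genes,
      n_modules = n_modules,
      seed = seed
    ), class = "synthetic_truth")
  })
}

#' Cohort simulation settings
#'
#' @param n_cases,n_controls Sample counts (both > 0).
#' @param medicated Logical; when `TRUE`, per-module medication effects are
#'   added to cases (emulating a cohort of medicated patients).
#' @param n_batches Number of array batches; samples are assigned cyclically
#'   so every batch has at least two samples.
#' @param probe_multiplicity Probabilities of a gene being measured by 1, 2
#'   or 3 probes; must sum to 1.
#' @param noise_sd Per-measurement probe noise SD (log2 units).
#' @param probe_offset_sd SD of the fixed per-probe intensity offset.
#' @param batch_sd SD of per-gene per-batch offsets.
#' @param dead_probe_frac Fraction of probes carrying no signal, with
#'   Uniform(0,1) detection p-values.
#' @param age_mean,age_sd,age_range Age distribution: normal truncated to
#'   `age_range`.
#' @param p_male Probability a sample is male.
#' @param label Cohort label used in sample ids and covariates.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_cases, n_controls, medicated = FALSE, n_batches = 2,
                        probe_multiplicity = c(0.3, 0.5, 0.2),
                        noise_sd = 0.2, probe_offset_sd = 0.25, batch_sd = 0.3,
                        dead_probe_frac = 0.1,
                        age_mean = 40, age_sd = 10, age_range = c(18, 70),
                        p_male = 0.5, label = "cohort") {
  stopifnot(n_cases > 0, n_controls > 0, n_batches >= 1,
            length(probe_multiplicity) == 3,
            noise_sd >= 0, probe_offset_sd >= 0, batch_sd >= 0,
            dead_probe_frac >= 0, dead_probe_frac <= 1)
  if (abs(sum(probe_multiplicity) - 1) > 1e-8)
    stop("`probe_multiplicity` probabilities must sum to 1")
  if (n_cases + n_controls < 2 * n_batches)
    stop("each batch needs at least two samples")
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 medicated = medicated, n_batches = n_batches,
                 probe_multiplicity = probe_multiplicity,
                 noise_sd = noise_sd, probe_offset_sd = probe_offset_sd,
                 batch_sd = batch_sd, dead_probe_frac = dead_probe_frac,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 p_male = p_male, label = label),
            class = "cohort_spec")
}

#' Preset cohorts: medicated discovery and antipsychotic-free replication
#'
#' Sample sizes follow the study design the generator emulates: a discovery
#' cohort of 92 medicated cases and 78 controls, and a replication cohort of
#' 29 antipsychotic-free cases and 40 controls.
#'
#' @param ... Overrides passed on to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
discovery_cohort <- function(...) {
  args <- list(n_cases = 92, n_controls = 78, medicated = TRUE,
               label = "discovery")
  do.call(cohort_spec, utils::modifyList(args, list(...)))
}

#' @rdname discovery_cohort
#' @export
replication_cohort <- function(...) {
  args <- list(n_cases = 29, n_controls = 40, medicated = FALSE,
               label = "replication")
  do.call(cohort_spec, utils::modifyList(args, list(...)))
}

#' Simulate a probe-level expression cohort from a planted truth
#'
#' @param truth A `synthetic_truth` from [generate_truth()].
#' @param spec A `cohort_spec`.
#' @param seed Integer RNG seed.
#' @return A list with `values` (probes x samples, log2-like scale),
#'   `detection_p` (same shape; < 0.01 for expressed probes, Uniform(0,1)
#'   for dead ones), `annotation` (data.frame probe/gene), `covariates`
#'   (data.frame sample/status/medicated/age/sex/batch/cohort), plus
#'   ground-truth extras for testing: `drivers` (modules x samples latent
#'   drivers) and `gene_values` (noise-free gene x sample signal, baseline
#'   plus latent component).
#' @export
simulate_cohort <- function(truth, spec, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(spec, "cohort_spec"))
  n <- spec$n_cases + spec$n_controls
  genes <- names(truth$module_membership)

  with_salted_seed(seed, 2, {
    samples <- sprintf("%s_s%03d", spec$label, seq_len(n))
    status <- factor(rep(c("case", "control"), c(spec$n_cases, spec$n_controls)),
                     levels = c("control", "case"))
    case <- as.numeric(status == "case")
    age <- rnorm(n, spec$age_mean, spec$age_sd)
    while (any(bad <- age < spec$age_range[1] | age > spec$age_range[2]))
      age[bad] <- rnorm(sum(bad), spec$age_mean, spec$age_sd)
    sex <- factor(ifelse(runif(n) < spec$p_male, "M", "F"), levels = c("F", "M"))
    batch <- factor(sprintf("b%d", rep_len(seq_len(spec$n_batches), n)))

    # latent drivers, shifted in cases
    nm <- truth$n_modules
    drivers <- matrix(rnorm(nm * n), nrow = nm,
                      dimnames = list(NULL, samples))
    if (nm > 0) {
      shift <- truth$disease_effect +
        if (spec$medicated) truth$medication_effect else 0
      drivers <- drivers + outer(shift, case)
    }

    # gene-level signal
    eps <- matrix(rnorm(length(genes) * n), nrow = length(genes),
                  dimnames = list(genes, samples))
    rho <- truth$module_corr
    x <- eps
    in_mod <- truth$module_membership > 0
    if (any(in_mod)) {
      q <- truth$module_membership[in_mod]
      x[in_mod, ] <- rho[in_mod] * drivers[q, , drop = FALSE] +
        sqrt(1 - rho[in_mod]^2) * eps[in_mod, , drop = FALSE]
    }
    gene_values <- truth$baseline + x  # baseline recycles down columns

    # probes
    mult <- sample(1:3, length(genes), replace = TRUE,
                   prob = spec$probe_multiplicity)
    probe_gene <- rep(genes, mult)
    probe_id <- sprintf("%s_p%d", probe_gene,
                        unlist(lapply(mult, seq_len), use.names = FALSE))
    np <- length(probe_id)
    dead <- runif(np) < spec$dead_probe_frac
    offset <- rnorm(np, 0, spec$probe_offset_sd)

    values <- matrix(rnorm(np * n, 0, spec$noise_sd), nrow = np,
                     dimnames = list(probe_id, samples))
    values <- values + offset
    values <- values + truth$baseline[probe_gene]
    live <- !dead
    values[live, ] <- values[live, ] + x[probe_gene[live], , drop = FALSE]

    # per-gene per-batch offsets, applied to all probes of the gene
    if (spec$n_batches > 1 && spec$batch_sd > 0) {
      boff <- matrix(rnorm(length(genes) * spec$n_batches, 0, spec$batch_sd),
                     nrow = length(genes),
                     dimnames = list(genes, levels(batch)))
      values <- values + boff[probe_gene, as.character(batch), drop = FALSE]
    }

    detection_p <- matrix(runif(np * n, 0, 0.01), nrow = np,
                          dimnames = list(probe_id, samples))
    if (any(dead))
      detection_p[dead, ] <- runif(sum(dead) * n)

    list(values = values,
         detection_p = detection_p,
         annotation = data.frame(probe = probe_id, gene = probe_gene,
                                 stringsAsFactors = FALSE),
         covariates = data.frame(sample = samples, status = status,
                                 medicated = spec$medicated & status == "case",
                                 age = age, sex = sex, batch = batch,
                                 cohort = spec$label,
                                 stringsAsFactors = FALSE),
         drivers = drivers,
         gene_values = gene_values)
  })
}

#' Simulate blood-cell marker gene lists and brain-expression flags
#'
#' Marker lists emulate published blood cell-type signatures (defaults:
#' neutrophil count 51 genes, lymphocyte count 56, red blood cell size 56,
#' time of blood draw 30); each list is drawn mostly from one aligned module.
#' Brain-expression flags are Bernoulli with one probability inside the
#' target (disease) module and another elsewhere (defaults 0.61 / 0.45).
#'
#' @param truth A `synthetic_truth`.
#' @param list_sizes Named integer vector of list sizes.
#' @param alignment Module index per list. `NULL` aligns lists to the largest
#'   modules excluding `truth$gwas_enriched_module` (disease modules are not
#'   cell-type modules), in decreasing size order.
#' @param purity Fraction of each list drawn from its aligned module; the
#'   remainder comes from background genes.
#' @param p_brain_in_target,p_brain_background Brain-flag probabilities
#'   inside/outside the target module.
#' @param brain_target_module Module whose genes use `p_brain_in_target`;
#'   defaults to the GWAS-enriched (disease) module.
#' @param seed Integer RNG seed.
#' @return A list with `marker_lists` (named list of gene id vectors) and
#'   `brain_flag` (named logical over all genes).
#' @export
simulate_marker_and_brain_lists <- function(truth,
                                            list_sizes = c(neutrophil = 51,
                                                           lymphocyte = 56,
                                                           red_cell_size = 56,
                                                           blood_draw = 30),
                                            alignment = NULL, purity = 0.9,
                                            p_brain_in_target = 0.61,
                                            p_brain_background = 0.45,
                                            brain_target_module = truth$gwas_enriched_module,
                                            seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"),
            purity >= 0, purity <= 1,
            p_brain_in_target >= 0, p_brain_in_target <= 1,
            p_brain_background >= 0, p_brain_background <= 1)
  genes <- names(truth$module_membership)
  membership <- truth$module_membership
  if (is.null(alignment)) {
    candidates <- setdiff(order(truth$module_sizes, decreasing = TRUE),
                          truth$gwas_enriched_module)
    if (length(candidates) < length(list_sizes))
      stop("not enough modules to align the requested lists")
    alignment <- candidates[seq_along(list_sizes)]
  }
  if (length(alignment) != length(list_sizes))
    stop("`alignment` must give one module per list")
  if (any(alignment < 1 | alignment > truth$n_modules))
    stop("alignment to nonexistent module")

  with_salted_seed(seed, 3, {
    background <- genes[membership == 0]
    marker_lists <- vector("list", length(list_sizes))
    names(marker_lists) <- names(list_sizes)
    for (i in seq_along(list_sizes)) {
      size <- list_sizes[i]
      mod_genes <- genes[membership == alignment[i]]
      n_in <- round(purity * size)
      if (n_in > length(mod_genes))
        stop(sprintf("list '%s' (size %d, purity %.2f) exceeds module %d size %d",
                     names(list_sizes)[i], size, purity, alignment[i],
                     length(mod_genes)))
      n_out <- size - n_in
      if (n_out > length(background))
        stop("not enough background genes to fill the list")
      marker_lists[[i]] <- c(sample(mod_genes, n_in),
                             if (n_out > 0) sample(background, n_out))
    }
    p <- rep(p_brain_background, length(genes))
    if (!is.na(brain_target_module))
      p[membership == brain_target_module] <- p_brain_in_target
    brain_flag <- setNames(runif(length(genes)) < p, genes)
    list(marker_lists = marker_lists, brain_flag = brain_flag)
  })
}

#' Simulate a brain expression matrix consistent with brain flags
#'
#' Convenience generator for exercising [brain_expressed_set()]: flagged
#' genes get mean log2 expression above the detection threshold (default 4),
#' unflagged genes below it.
#'
#' @param brain_flag Named logical vector (from
#'   [simulate_marker_and_brain_lists()]).
#' @param n_samples Number of brain samples.
#' @param threshold Expression threshold the flags should reproduce.
#' @param seed Integer RNG seed.
#' @return Gene x sample matrix of log2 expression values.
#' @export
simulate_brain_matrix <- function(brain_flag, n_samples = 50, threshold = 4,
                                  seed = 1) {
  genes <- names(brain_flag)
  with_salted_seed(seed, 4, {
    mu <- ifelse(brain_flag, runif(length(genes), threshold + 1, threshold + 5),
                 runif(length(genes), threshold - 3, threshold - 0.5))
    m <- matrix(rnorm(length(genes) * n_samples, mean = mu, sd = 0.3),
                nrow = length(genes),
                dimnames = list(genes, sprintf("brain_s%03d", seq_len(n_samples))))
    m
  })
}

#' Simulate a GWAS SNP table and gene coordinates
#'
#' Genes are laid out on 22 chromosomes with non-overlapping windows; each
#' gene receives a Poisson number of SNPs placed uniformly within its span
#' plus/minus 10 kb. SNP p-values are Uniform(0,1), except that inside the
#' GWAS-enriched module a fraction of SNPs is drawn from Beta(`beta_shape`,
#' 1), a decreasing density on (0,1) concentrating mass near 0.
#'
#' @param truth A `synthetic_truth`.
#' @param snps_per_gene_mean Mean SNPs per gene (Poisson).
#' @param enriched_fraction Fraction of SNPs in the target module's genes
#'   drawn from the enriched density.
#' @param beta_shape Shape parameter (< 1 gives enrichment of small p).
#' @param gene_span Gene length in base pairs.
#' @param seed Integer RNG seed.
#' @return A list with `snps` (data.frame snp/chrom/pos/p) and `coords`
#'   (data.frame gene/chrom/start/end, 1-based inclusive).
#' @export
simulate_gwas_table <- function(truth, snps_per_gene_mean = 15,
                                enriched_fraction = 0.3, beta_shape = 0.2,
                                gene_span = 20000, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"),
            enriched_fraction >= 0, enriched_fraction <= 1,
            snps_per_gene_mean >= 0, beta_shape > 0, gene_span >= 1)
  genes <- names(truth$module_membership)
  n_genes <- length(genes)
  chrom <- sprintf("chr%d", rep_len(1:22, n_genes))
  idx_on_chrom <- stats::ave(seq_len(n_genes), chrom, FUN = seq_along)
  gap <- 30000  # > 2 * 10 kb window, so windows never overlap
  # offset keeps SNP positions positive within the 10 kb upstream window
  start <- 10001 + (idx_on_chrom - 1) * (gene_span + gap)
  coords <- data.frame(gene = genes, chrom = chrom, start = start,
                       end = start + gene_span - 1, stringsAsFactors = FALSE)

  with_salted_seed(seed, 5, {
    n_snps <- rpois(n_genes, snps_per_gene_mean)
    total <- sum(n_snps)
    if (total == 0) {
      snps <- data.frame(snp = character(0), chrom = character(0),
                         pos = integer(0), p = numeric(0),
                         stringsAsFactors = FALSE)
      return(list(snps = snps, coords = coords))
    }
    g_idx <- rep(seq_len(n_genes), n_snps)
    pos <- floor(runif(total, coords$start[g_idx] - 10000,
                       coords$end[g_idx] + 10000 + 1))
    p <- runif(total)
    target <- truth$gwas_enriched_module
    if (!is.na(target) && enriched_fraction > 0) {
      in_target <- truth$module_membership[g_idx] == target
      enrich <- in_target & runif(total) < enriched_fraction
      if (any(enrich)) p[enrich] <- rbeta(sum(enrich), beta_shape, 1)
    }
    snps <- data.frame(snp = sprintf("rs%07d", seq_len(total)),
                       chrom = coords$chrom[g_idx], pos = as.integer(pos),
                       p = p, stringsAsFactors = FALSE)
    list(snps = snps, coords = coords)
  })
}

#' Simulate qPCR plates with triplicate Ct measurements
#'
#' Ct values follow `intercept - slope * expression + plate effect +
#' triplicate noise`, so higher expression gives lower Ct. The reference
#' gene, if absent from `expression`, is generated with no disease effect.
#'
#' @param expression Samples x genes matrix of expression values (log2-like
#'   scale), rownames = sample ids.
#' @param reference_gene Reference gene id (e.g. "GAPDH").
#' @param n_plates Number of plates; samples assigned cyclically.
#' @param plate_effect_sd SD of per-plate per-gene Ct offsets.
#' @param triplicate_sd SD of technical replicate noise.
#' @param slope,intercept Linear map from expression to Ct.
#' @param seed Integer RNG seed.
#' @return data.frame with columns sample, gene, plate, ct1, ct2, ct3.
#' @export
simulate_qpcr_plates <- function(expression, reference_gene = "GAPDH",
                                 n_plates = 2, plate_effect_sd = 0.15,
                                 triplicate_sd = 0.15, slope = 1,
                                 intercept = 30, seed = 1) {
  expression <- as.matrix(expression)
  if (is.null(rownames(expression)))
    stop("`expression` must have sample ids as rownames")
  samples <- rownames(expression)
  with_salted_seed(seed, 6, {
    if (!reference_gene %in% colnames(expression)) {
      ref <- rnorm(length(samples), mean = mean(expression), sd = 0.1)
      expression <- cbind(expression, ref)
      colnames(expression)[ncol(expression)] <- reference_gene
    }
    genes <- colnames(expression)
    plate <- sprintf("plate%d", rep_len(seq_len(n_plates), length(samples)))
    peff <- matrix(rnorm(n_plates * length(genes), 0, plate_effect_sd),
                   nrow = n_plates,
                   dimnames = list(sprintf("plate%d", seq_len(n_plates)), genes))
    grid <- expand.grid(sample = samples, gene = genes,
                        stringsAsFactors = FALSE)
    grid$plate <- plate[match(grid$sample, samples)]
    true_ct <- intercept - slope * expression[cbind(grid$sample, grid$gene)] +
      peff[cbind(grid$plate, grid$gene)]
    reps <- matrix(rnorm(3 * nrow(grid), 0, triplicate_sd), ncol = 3) + true_ct
    grid$ct1 <- reps[, 1]; grid$ct2 <- reps[, 2]; grid$ct3 <- reps[, 3]
    grid
  })
}
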