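#' Configuration for a synthetic two-group cohort
#'
#' Defines the statistical structure the downstream analysis assumes: two
#' response groups (R/NR), a set of planted miRNA-target pairs in which the
#' miRNA is up-regulated in non-responders and its validated target gene is
#' down-regulated by the same log2 amount (reciprocal structure), decoy
#' interactions among non-perturbed features, i.i.d. Gaussian noise on the
#' log2 scale, exponential survival with a proportional-hazards group effect,
#' and uniform censoring.
#'
#' Defaults emulate the design of a small retrospective treatment-response
#' cohort: 5 responders vs 9 non-responders on the arrays, a baseline
#' (responder) median overall survival of 134 months with a non-responder
#' hazard ratio of 4.8 (median ratio 134/28 under an exponential model), and
#' 30% censoring.
#'
#' @param n_responders,n_nonresponders samples per group.
#' @param n_mirnas,n_genes numbers of miRNA and gene features.
#' @param n_true_pairs planted reciprocal miRNA-target pairs (one miRNA paired
#'   with one gene, one-to-one).
#' @param n_decoy_pairs validated-interaction decoys drawn among non-planted
#'   features, so the planted set is the unique reciprocal solution.
#' @param effect_log2 mean log2 shift of planted features in NR (miRNAs +,
#'   their target genes -).
#' @param noise_sd per-observation Gaussian sd on the log2 scale.
#' @param hazard_ratio NR-vs-R hazard multiplier for survival times.
#' @param censor_rate expected fraction of censored records, in \[0, 1\].
#' @param seed integer seed; the whole cohort is reproducible given the seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_responders = 5, n_nonresponders = 9,
                          n_mirnas = 150, n_genes = 300,
                          n_true_pairs = 20, n_decoy_pairs = 40,
                          effect_log2 = 1.5, noise_sd = 0.5,
                          hazard_ratio = 4.8, censor_rate = 0.3,
                          seed = 1) {
  for (nm in c("n_responders", "n_nonresponders", "n_mirnas", "n_genes",
               "n_true_pairs", "n_decoy_pairs")) {
    stop_if_not_count(get(nm), nm)
  }
  if (n_responders < 2 || n_nonresponders < 2) {
    stop("at least 2 samples per group are required", call. = FALSE)
  }
  if (n_true_pairs > min(n_mirnas, n_genes)) {
    stop("n_true_pairs cannot exceed min(n_mirnas, n_genes) (one-to-one planting)",
         call. = FALSE)
  }
  if (n_true_pairs > n_mirnas * n_genes) {
    stop("n_true_pairs cannot exceed n_mirnas * n_genes", call. = FALSE)
  }
  if (!is.numeric(effect_log2) || effect_log2 < 0) {
    stop("'effect_log2' must be a non-negative real", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("'noise_sd' must be non-negative", call. = FALSE)
  }
  if (!is.numeric(hazard_ratio) || hazard_ratio <= 0) {
    stop("'hazard_ratio' must be positive", call. = FALSE)
  }
  if (!is.numeric(censor_rate) || censor_rate < 0 || censor_rate > 1) {
    stop("'censor_rate' must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_responders = as.integer(n_responders),
         n_nonresponders = as.integer(n_nonresponders),
         n_mirnas = as.integer(n_mirnas), n_genes = as.integer(n_genes),
         n_true_pairs = as.integer(n_true_pairs),
         n_decoy_pairs = as.integer(n_decoy_pairs),
         effect_log2 = effect_log2, noise_sd = noise_sd,
         hazard_ratio = hazard_ratio, censor_rate = censor_rate,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# baseline responder median OS, months; lambda = log(2) / 134
.BASELINE_MEDIAN_OS <- 134

#' Generate a synthetic cohort
#'
#' Draws a full cohort under the configured model: miRNA and gene log2
#' expression matrices with planted reciprocal effects, a validated-interaction
#' table containing the planted pairs plus decoys among non-planted features,
#' survival records with group-dependent exponential hazards and uniform
#' censoring, and a triplicate qPCR Ct table for a handful of planted markers
#' (lower Ct = higher expression, so planted miRNAs get a negative Ct shift in
#' NR samples).
#'
#' @param config a [cohort_config()].
#' @return a `synthetic_cohort` list with elements `mirna_matrix`,
#'   `gene_matrix` (both [expression_matrix()]), `interactions`
#'   (an `interaction_set`), `truth_pairs` (data frame `mirna`, `gene`),
#'   `survival` (data frame `sample`, `group`, `time_months`, `event`),
#'   `ct_table` (long Ct data frame), `ct_reference` and `config`.
#' @examples
#' co <- generate_cohort(cohort_config(seed = 7))
#' co$truth_pairs[1:3, ]
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)

  n_r <- config$n_responders
  n_nr <- config$n_nonresponders
  samples <- c(sprintf("R%02d", seq_len(n_r)), sprintf("NR%02d", seq_len(n_nr)))
  labels <- stats::setNames(rep(c("R", "NR"), c(n_r, n_nr)), samples)
  is_nr <- labels == "NR"

  mirna_ids <- sprintf("hsa-mir-9%04d-5p", seq_len(config$n_mirnas))
  gene_ids <- sprintf("SYNG%04d", seq_len(config$n_genes))

  planted_m <- sample(mirna_ids, config$n_true_pairs)
  planted_g <- sample(gene_ids, config$n_true_pairs)
  truth <- data.frame(mirna = planted_m, gene = planted_g,
                      stringsAsFactors = FALSE)

  draw_matrix <- function(ids, planted, effect_sign) {
    base <- stats::rnorm(length(ids), mean = 8, sd = 1.5)
    m <- matrix(base, nrow = length(ids), ncol = length(samples)) +
      matrix(stats::rnorm(length(ids) * length(samples), 0, config$noise_sd),
             nrow = length(ids), ncol = length(samples))
    dimnames(m) <- list(ids, samples)
    m[planted, is_nr] <- m[planted, is_nr] + effect_sign * config$effect_log2
    m
  }
  mirna_m <- draw_matrix(mirna_ids, planted_m, +1)
  gene_m <- draw_matrix(gene_ids, planted_g, -1)

  # decoy interactions connect only non-planted features, so the planted set
  # is exactly the reciprocal solution recoverable downstream
  free_m <- setdiff(mirna_ids, planted_m)
  free_g <- setdiff(gene_ids, planted_g)
  n_decoy <- min(config$n_decoy_pairs, length(free_m) * length(free_g))
  decoys <- if (n_decoy > 0) {
    idx <- sample(length(free_m) * length(free_g), n_decoy)
    data.frame(mirna = free_m[(idx - 1L) %% length(free_m) + 1L],
               gene = free_g[(idx - 1L) %/% length(free_m) + 1L],
               stringsAsFactors = FALSE)
  } else {
    data.frame(mirna = character(), gene = character())
  }
  inter <- rbind(truth, decoys)
  inter <- inter[!duplicated(inter), , drop = FALSE]
  inter$evidence <- rep("synthetic", nrow(inter))
  interactions <- interaction_set(inter, alias_map = NULL)

  # exponential survival with a PH group effect; censoring is independent
  # uniform U(0, m) with the window m solved per group so the expected
  # censored fraction equals censor_rate (keeps the KM estimator unbiased)
  lambda <- log(2) / .BASELINE_MEDIAN_OS *
    ifelse(is_nr, config$hazard_ratio, 1)
  t_event <- stats::rexp(length(samples), rate = lambda)
  if (config$censor_rate > 0) {
    censor_window <- function(rate) {
      # P(C < T) = (1 - exp(-rate * m)) / (rate * m) = censor_rate
      stats::uniroot(function(m) {
        (1 - exp(-rate * m)) / (rate * m) - config$censor_rate
      }, lower = 1e-8, upper = 1e8, tol = 1e-10)$root
    }
    m <- vapply(unique(lambda), censor_window, 0)[match(lambda,
                                                        unique(lambda))]
    t_censor <- stats::runif(length(samples), 0, m)
  } else {
    t_censor <- rep(Inf, length(samples))
  }
  event <- as.integer(t_event <= t_censor)
  survival <- data.frame(sample = samples, group = unname(labels),
                         time_months = pmax(pmin(t_event, t_censor), 1e-3),
                         event = event,
                         stringsAsFactors = FALSE)

  ct_targets <- planted_m[seq_len(min(4L, length(planted_m)))]
  ct_table <- if (length(ct_targets) > 0) {
    generate_ct_table(n_per_group = NULL, targets = ct_targets,
                      reference_gene = "RNU48",
                      group_shift_ct = config$effect_log2,
                      seed = NULL, samples = samples, groups = unname(labels))
  } else {
    NULL
  }

  structure(
    list(mirna_matrix = expression_matrix(mirna_m, labels),
         gene_matrix = expression_matrix(gene_m, labels),
         interactions = interactions,
         truth_pairs = truth,
         survival = survival,
         ct_table = ct_table,
         ct_reference = "RNU48",
         config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic_cohort: %d miRNAs x %d genes, %d samples, ",
                     "%d planted pairs, %d interactions\n"),
              nrow(x$mirna_matrix$values), nrow(x$gene_matrix$values),
              ncol(x$mirna_matrix$values), nrow(x$truth_pairs),
              nrow(x$interactions$records)))
  invisible(x)
}

#' Generate a replicate qPCR Ct table
#'
#' Simulates triplicate Ct measurements per sample and target plus a reference
#' gene. Non-responder samples are shifted by `-group_shift_ct` cycles on the
#' targets (a lower Ct means higher expression, so a positive shift encodes
#' up-regulation in NR).
#'
#' @param n_per_group samples per group (ignored when `samples` is given).
#' @param targets marker ids to measure.
#' @param reference_gene reference (housekeeping) assay id; must not be among
#'   `targets`.
#' @param group_shift_ct Ct cycles subtracted from NR target measurements.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param replicate_sd technical replicate sd in cycles.
#' @param sample_sd biological between-sample sd in cycles, applied once per
#'   sample x assay and shared by its replicates. Set both sds to 0 for
#'   noiseless, closed-form-checkable tables.
#' @param n_replicates replicates per sample x target (design = 3).
#' @param samples,groups optional explicit sample ids and `"R"`/`"NR"` labels,
#'   used to keep the Ct table consistent with a cohort's samples.
#' @return long-format data frame with columns `sample`, `group`, `target`,
#'   `replicate`, `ct`.
#' @export
generate_ct_table <- function(n_per_group, targets, reference_gene = "RNU48",
                              group_shift_ct = 1, seed = 1,
                              replicate_sd = 0.15, sample_sd = 0.5,
                              n_replicates = 3,
                              samples = NULL, groups = NULL) {
  if (length(targets) == 0) stop("'targets' must be non-empty", call. = FALSE)
  if (reference_gene %in% targets) {
    stop("'reference_gene' must not be among 'targets'", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(samples)) {
    stop_if_not_count(n_per_group, "n_per_group", min = 1)
    samples <- c(sprintf("R%02d", seq_len(n_per_group)),
                 sprintf("NR%02d", seq_len(n_per_group)))
    groups <- rep(c("R", "NR"), each = n_per_group)
  }
  assays <- c(targets, reference_gene)
  base_ct <- stats::setNames(c(rep(28, length(targets)), 22), assays)

  grid <- expand.grid(replicate = seq_len(n_replicates), target = assays,
                      sample = samples, stringsAsFactors = FALSE)
  grid$group <- groups[match(grid$sample, samples)]
  shift <- ifelse(grid$group == "NR" & grid$target != reference_gene,
                  -group_shift_ct, 0)
  # biological variability: one offset per sample x assay, shared by replicates
  bio_key <- paste(grid$sample, grid$target)
  bio_levels <- unique(bio_key)
  bio <- if (sample_sd > 0) {
    stats::setNames(stats::rnorm(length(bio_levels), 0, sample_sd),
                    bio_levels)[bio_key]
  } else {
    0
  }
  noise <- if (replicate_sd > 0) {
    stats::rnorm(nrow(grid), 0, replicate_sd)
  } else {
    0
  }
  grid$ct <- base_ct[grid$target] + shift + bio + noise
  grid[, c("sample", "group", "target", "replicate", "ct")]
}

#' Write all cohort components to a directory of TSV files
#'
#' Expression matrices, sample labels, interactions (miRTarBase-like dialect),
#' planted truth pairs, survival records and the Ct table are written as plain
#' TSV so any stage can be re-run from files.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(
    mirna = file.path(dir, "mirna_matrix.tsv"),
    gene = file.path(dir, "gene_matrix.tsv"),
    samples = file.path(dir, "samples.tsv"),
    interactions = file.path(dir, "interactions.tsv"),
    truth = file.path(dir, "truth_pairs.tsv"),
    survival = file.path(dir, "survival.tsv"),
    ct = file.path(dir, "ct_table.tsv")
  )
  write_expression_tsv(cohort$mirna_matrix, p["mirna"])
  write_expression_tsv(cohort$gene_matrix, p["gene"])
  write_tsv(data.frame(sample = cohort$mirna_matrix$sample_ids,
                       group = cohort$mirna_matrix$labels), p["samples"])
  write_interaction_table(cohort$interactions, p["interactions"])
  write_tsv(cohort$truth_pairs, p["truth"])
  write_tsv(cohort$survival, p["survival"])
  if (!is.null(cohort$ct_table)) write_tsv(cohort$ct_table, p["ct"])
  invisible(p)
}
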