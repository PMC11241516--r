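#' Run the integrated analysis pipeline end to end
#'
#' Orchestrates differential expression -> reciprocal-network integration ->
#' gene-set enrichment, and — when the corresponding inputs exist — qPCR
#' relative quantification, marker-panel ROC evaluation and survival
#' comparison. All stage outputs are written as TSV (plus SIF/GraphML for the
#' network) under `out_dir`, together with a JSON run manifest recording the
#' package version, seed, thresholds and md5 checksums of every written file.
#' Outputs are deterministic: re-running with the same cohort/seed reproduces
#' every file byte-identically.
#'
#' @param cohort a [generate_cohort()] result, or `NULL` to generate one from
#'   `config`.
#' @param config a [cohort_config()], used when `cohort` is `NULL`.
#' @param interactions an `interaction_set`; defaults to the cohort's own.
#' @param collection optional [gene_set_collection()] (or GMT path) for
#'   enrichment of the network's gene nodes.
#' @param fc_threshold,p_threshold differential-expression gates.
#' @param max_ct qPCR reliability cut-off in cycles.
#' @param kappa_threshold term-grouping kappa threshold.
#' @param panels optional list of marker-id vectors for
#'   [evaluate_panels()]; defaults to all single markers plus all pairs of the
#'   qPCR targets.
#' @param out_dir output directory.
#' @return invisibly, a list with every stage result (`de_mirnas`, `de_genes`,
#'   `network`, `summary`, `enrichment`, `groups`, `relexp`, `qpcr_report`,
#'   `panel_aucs`, `survival_test`, `manifest`).
#' @export
run_pipeline <- function(cohort = NULL, config = cohort_config(),
                         interactions = NULL, collection = NULL,
                         fc_threshold = 1.5, p_threshold = 0.05,
                         max_ct = 35, kappa_threshold = 0.4,
                         panels = NULL, out_dir = "results") {
  if (is.null(cohort)) cohort <- generate_cohort(config)
  stopifnot(inherits(cohort, "synthetic_cohort") ||
              (is.list(cohort) && !is.null(cohort$mirna_matrix)))
  interactions <- interactions %||% cohort$interactions
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  put <- function(writer, obj, file) {
    path <- file.path(out_dir, file)
    writer(obj, path)
    written <<- c(written, path)
    path
  }

  de_mi <- differential_expression(cohort$mirna_matrix, fc_threshold,
                                   p_threshold)
  de_ge <- differential_expression(cohort$gene_matrix, fc_threshold,
                                   p_threshold)
  put(write_de_table, de_mi, "de_mirnas.tsv")
  put(write_de_table, de_ge, "de_genes.tsv")

  network <- reciprocal_filter(de_mi, de_ge, interactions)
  summ <- network_summary(network)
  if (summ$n_edges == 0L) {
    warning("reciprocal network is empty under the current thresholds")
  }
  export_network(network, "sif", file.path(out_dir, "network.sif"))
  export_network(network, "graphml", file.path(out_dir, "network.graphml"))
  written <- c(written, file.path(out_dir, c("network.sif", "network.graphml")))
  put(write_network_summary, network, "network_summary.tsv")

  enrichment <- NULL
  groups <- NULL
  if (!is.null(collection) && summ$n_genes > 0L) {
    if (is.character(collection)) collection <- read_gmt(collection)
    enrichment <- tryCatch(
      suppressWarnings(hypergeometric_enrichment(network$gene_nodes,
                                                 collection)),
      error = function(e) {
        warning("enrichment skipped: ", conditionMessage(e))
        NULL
      }
    )
    if (!is.null(enrichment)) {
      put(write_enrichment_report, enrichment, "enrichment.tsv")
      groups <- group_terms(enrichment, kappa_threshold)
      put(write_tsv, groups$groups, "term_groups.tsv")
    }
  }

  relexp <- NULL
  report <- NULL
  panel_aucs <- NULL
  if (!is.null(cohort$ct_table)) {
    relexp <- suppressMessages(
      relative_quantification(cohort$ct_table, cohort$ct_reference,
                              max_ct = max_ct)
    )
    put(write_tsv, relexp, "qpcr_relative_expression.tsv")
    report <- qpcr_group_report(relexp)
    put(write_tsv, report, "qpcr_group_report.tsv")

    mm <- marker_matrix_from_relexp(relexp)
    if (is.null(panels)) {
      singles <- as.list(colnames(mm$markers))
      pairs <- if (ncol(mm$markers) >= 2) {
        utils::combn(colnames(mm$markers), 2, simplify = FALSE)
      } else {
        list()
      }
      panels <- c(singles, pairs)
    }
    panel_aucs <- evaluate_panels(mm$markers, mm$labels, panels)
    put(write_tsv, panel_aucs, "panel_aucs.tsv")
  }

  survival_test <- NULL
  if (!is.null(cohort$survival)) {
    sv <- cohort$survival
    survival_test <- logrank_test(sv$time_months, sv$event, sv$group)
    st <- data.frame(chi2 = survival_test$chi2, df = survival_test$df,
                     p = survival_test$p,
                     median_NR = survival_test$medians[["NR"]],
                     median_R = survival_test$medians[["R"]])
    put(write_tsv, st, "survival_logrank.tsv")
    for (g in c("R", "NR")) {
      km <- km_estimate(sv$time_months[sv$group == g], sv$event[sv$group == g])
      put(write_km_table, km, sprintf("km_%s.tsv", g))
    }
  }

  manifest <- list(
    package = "mirtarnet",
    version = as.character(utils::packageVersion("mirtarnet")),
    seed = if (!is.null(cohort$config)) cohort$config$seed else NA,
    thresholds = list(fc = fc_threshold, p = p_threshold, ct_max = max_ct,
                      kappa = kappa_threshold),
    network = list(n_mirnas = summ$n_mirnas, n_genes = summ$n_genes,
                   n_edges = summ$n_edges),
    checksums = as.list(tools::md5sum(sort(written)))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(de_mirnas = de_mi, de_genes = de_ge, network = network,
                 summary = summ, enrichment = enrichment, groups = groups,
                 relexp = relexp, qpcr_report = report,
                 panel_aucs = panel_aucs, survival_test = survival_test,
                 manifest = manifest))
}
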