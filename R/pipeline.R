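#' End-to-end analysis pipeline
#'
#' Runs the full two-stage analysis on a synthetic cohort (or one read from
#' files): call-rate QC, exclusion of high-missing subjects, gene-vector
#' assembly, diversity summary, clinical outcome labeling, the response-gene
#' screen, and the constrained neural-net stage with random-walk restarts
#' and stratified k-fold cross-validation.  Everything is deterministic
#' under the seed embedded in the configuration.
#'
#' @param cohort A [generate_cohort()] result, or a list with elements
#'   `genotypes` ([genotype_table()]) and `trajectories` (trajectory
#'   tibble).
#' @param train A [train_config()]; its seed defaults to the cohort seed.
#' @param screen_params List overriding the screen defaults (`rarity`,
#'   `min_characteristic`, `min_count`).
#' @param select Run greedy classifier-gene selection on the screened pool;
#'   default `TRUE`.
#' @param missing_cutoff Subject missing-rate exclusion threshold;
#'   default 0.05.
#' @param max_pairs Gene pairs used in the diversity association summary.
#' @param out Optional path; when given, the summary is also written there
#'   as JSON.
#' @return A list of class `pipeline_result`: `diversity`
#'   ([diversity_summary()]), `labels`, `screen`, `selection` (or `NULL`),
#'   `search` ([random_walk_search()] result or `NULL` when no gene was
#'   flagged), `summary` (plain list mirrored to JSON), `qc_report`.
#' @export
run_pipeline <- function(cohort, train = train_config(restarts = 3),
                         screen_params = list(), select = TRUE,
                         missing_cutoff = 0.05, max_pairs = 100,
                         out = NULL) {
  sp <- utils::modifyList(
    list(rarity = 0.10, min_characteristic = 0.20, min_count = 5),
    screen_params
  )
  seed <- train$seed %||% (if (!is.null(cohort$config)) cohort$config$seed else 1L)
  set.seed(seed)

  qc <- qc_filter(cohort$genotypes)
  keep <- exclude_high_missing(qc$table, cutoff = missing_cutoff)
  table <- subset_subjects(qc$table, keep)

  gvm <- build_gene_vector_matrix(table)
  diversity <- diversity_summary(gvm, max_pairs = max_pairs)

  labels <- label_outcomes(cohort$trajectories)
  labels <- labels[labels$subject_id %in% gvm$subjects & labels$included, ]

  screen <- screen_cohort(gvm, labels,
    rarity = sp$rarity, min_characteristic = sp$min_characteristic,
    min_count = sp$min_count
  )
  pool <- response_genes(screen)

  analysis_ids <- labels$subject_id
  gvm_lab <- subset_gvm(gvm, analysis_ids)
  y <- labels$responder

  selection <- NULL
  search <- NULL
  if (length(pool)) {
    genes_used <- pool
    cfg <- train
    cfg$seed <- seed + 1
    if (select && length(pool) > 1) {
      selection <- select_classifier_genes(gvm_lab, pool, y, cfg,
                                           min_count = sp$min_count)
      if (any(selection$selected)) genes_used <- selection$gene[selection$selected]
    }
    features <- one_hot_encode(gvm_lab, genes_used, min_count = sp$min_count)
    cfg$seed <- seed + 2
    search <- random_walk_search(features, y, cfg)
  }

  summary <- list(
    seed = seed,
    n_subjects_input = length(cohort$genotypes$subjects),
    n_subjects_analysis = length(analysis_ids),
    n_snps = ncol(table$geno),
    n_genes = nrow(gvm$genes),
    qc_removed = nrow(qc$report),
    diversity = list(
      mean_d = diversity$mean_d,
      range_d = diversity$range_d,
      observed_total = diversity$observed_total,
      expected_total = diversity$expected_total,
      dependence_ratio = diversity$dependence_ratio,
      association_mean = diversity$association_mean,
      association_sd = diversity$association_sd
    ),
    labels = list(
      n_included = sum(labels$included),
      n_responders = sum(labels$responder),
      n_early_improvers = sum(labels$early_improver),
      n_non_improvers = sum(labels$non_improver),
      severity = as.list(table(labels$severity))
    ),
    screen = list(
      params = sp,
      n_response_genes = length(pool),
      response_genes = pool
    ),
    selection = if (!is.null(selection)) {
      list(selected = selection$gene[selection$selected],
           stability = setNames(selection$stability, selection$gene))
    },
    classifier = if (!is.null(search)) {
      p <- search$cv$pooled
      list(
        restart = search$restart, threshold = search$threshold,
        pooled = list(
          tp = p$tp, fn = p$fn, fp = p$fp, tn = p$tn,
          sensitivity = p$sensitivity, specificity = p$specificity,
          fp_rate = p$fp_rate, correct = p$correct,
          constraint_accuracy = p$constraint_accuracy
        )
      )
    },
    config = if (!is.null(cohort$config)) unclass_config(cohort$config)
  )
  if (!is.null(out)) {
    jsonlite::write_json(summary, out, auto_unbox = TRUE, digits = NA, na = "null")
  }
  structure(
    list(
      diversity = diversity, labels = labels, screen = screen,
      selection = selection, search = search, summary = summary,
      qc_report = qc$report
    ),
    class = "pipeline_result"
  )
}

unclass_config <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$cross_gene_link <- as.data.frame(cfg$cross_gene_link)
  cfg$response_genes <- as.data.frame(cfg$response_genes)
  cfg
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0(
      "<pipeline_result> %d analysis subjects, %d genes\n",
      "  diversity: mean d %.1f, dependence ratio %.3f\n",
      "  labels: %d responders / %d included\n",
      "  screen: %d response genes\n"
    ),
    s$n_subjects_analysis, s$n_genes, s$diversity$mean_d,
    s$diversity$dependence_ratio, s$labels$n_responders, s$labels$n_included,
    s$screen$n_response_genes
  ))
  if (!is.null(s$classifier)) {
    cat(sprintf("  classifier: pooled CV sensitivity %.3f, FP %d\n",
                s$classifier$pooled$sensitivity, s$classifier$pooled$fp))
  }
  invisible(x)
}
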