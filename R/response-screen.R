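#' Class-wise genotypic-pattern frequencies for one gene
#'
#' Frequencies of each observed pattern within a target and a contrast
#' class, computed over subjects with a complete gene vector.  Frequencies
#' sum to 1 within each class.
#'
#' @param matrix A [build_gene_vector_matrix()] result.
#' @param gene Gene id.
#' @param target_ids,contrast_ids Disjoint subject-id sets (e.g. responders
#'   and non-responders).
#' @return A tibble: `pattern`, `n_target`, `n_contrast`, `f_target`,
#'   `f_contrast`.
#' @export
pattern_class_frequencies <- function(matrix, gene, target_ids, contrast_ids) {
  if (length(intersect(target_ids, contrast_ids))) {
    abort("target and contrast classes must be disjoint")
  }
  cat_tab <- pattern_catalog(matrix, gene,
    subgroups = list(target = target_ids, contrast = contrast_ids)
  )
  n_t <- sum(cat_tab$target)
  n_c <- sum(cat_tab$contrast)
  if (n_t == 0 || n_c == 0) {
    abort("a class has no subjects with complete gene vectors",
          class = "genevec_empty_class")
  }
  tibble::tibble(
    pattern = cat_tab$pattern,
    n_target = cat_tab$target,
    n_contrast = cat_tab$contrast,
    f_target = cat_tab$target / n_t,
    f_contrast = cat_tab$contrast / n_c
  )
}

qualify_patterns <- function(freqs, rarity, min_characteristic, min_count) {
  fwd <- dplyr::filter(
    freqs,
    .data$f_contrast < rarity,
    .data$f_target >= min_characteristic,
    .data$n_target >= min_count
  ) |> dplyr::mutate(direction = "target")
  rev <- dplyr::filter(
    freqs,
    .data$f_target < rarity,
    .data$f_contrast >= min_characteristic,
    .data$n_contrast >= min_count
  ) |> dplyr::mutate(direction = "contrast")
  dplyr::bind_rows(fwd, rev)
}

#' Screen one gene for class-characteristic patterns
#'
#' A pattern qualifies when it is rare in one class (frequency below
#' `rarity`) while being characteristic of the other (frequency at least
#' `min_characteristic`, with at least `min_count` carriers there); both
#' directions are tested.  A gene carrying any qualifying pattern is a
#' "response gene".
#'
#' @inheritParams pattern_class_frequencies
#' @param rarity Maximum frequency in the rare class (exclusive);
#'   default 0.10.
#' @param min_characteristic Minimum frequency in the characteristic class;
#'   default 0.20.
#' @param min_count Minimum carrier count in the characteristic class;
#'   default 5.
#' @return A tibble of qualifying patterns (possibly empty) with a
#'   `direction` column; attribute `response_gene` flags the gene.
#' @export
screen_gene <- function(matrix, gene, target_ids, contrast_ids,
                        rarity = 0.10, min_characteristic = 0.20, min_count = 5) {
  freqs <- pattern_class_frequencies(matrix, gene, target_ids, contrast_ids)
  qual <- qualify_patterns(freqs, rarity, min_characteristic, min_count)
  structure(qual, response_gene = nrow(qual) > 0, gene = gene)
}

#' Screen a cohort for response genes
#'
#' Stage-1 screen of the two-stage analysis: every candidate gene is tested
#' for genotypic patterns characteristic of one outcome class and rare in
#' the other; flagged genes form the candidate pool for the neural-net
#' stage.  Screening runs on the full labeled sample, which mirrors the
#' two-stage design it implements; the fold-honest alternative used for
#' leakage control lives in [cv_with_screen()].
#'
#' @param matrix A [build_gene_vector_matrix()] result.
#' @param labels Tibble with `subject_id` and a logical outcome column.
#' @param outcome Name of the logical outcome column; default `"responder"`.
#' @inheritParams screen_gene
#' @return An object of class `screen_result`: tibble with one row per gene
#'   (`gene`, `n_qualifying`, `response_gene`), attributes `patterns`
#'   (qualifying-pattern tibble) and `params`.
#' @export
screen_cohort <- function(matrix, labels, outcome = "responder",
                          rarity = 0.10, min_characteristic = 0.20, min_count = 5) {
  if (!outcome %in% names(labels)) abort(paste0("labels lack column '", outcome, "'"))
  lab <- labels[labels$subject_id %in% matrix$subjects, ]
  target_ids <- lab$subject_id[lab[[outcome]] %in% TRUE]
  contrast_ids <- lab$subject_id[lab[[outcome]] %in% FALSE]
  rows <- vector("list", nrow(matrix$genes))
  pats <- vector("list", nrow(matrix$genes))
  for (g in seq_len(nrow(matrix$genes))) {
    gene <- matrix$genes$gene[g]
    qual <- tryCatch(
      screen_gene(matrix, gene, target_ids, contrast_ids,
                  rarity, min_characteristic, min_count),
      genevec_empty_class = function(e) NULL
    )
    nq <- if (is.null(qual)) 0L else nrow(qual)
    rows[[g]] <- tibble::tibble(gene = gene, n_qualifying = nq, response_gene = nq > 0)
    if (nq > 0) pats[[g]] <- dplyr::mutate(tibble::as_tibble(qual), gene = gene, .before = 1)
  }
  out <- dplyr::bind_rows(rows)
  structure(out,
    class = c("screen_result", class(out)),
    patterns = dplyr::bind_rows(pats),
    params = list(
      outcome = outcome, rarity = rarity,
      min_characteristic = min_characteristic, min_count = min_count
    )
  )
}

#' Response-gene ids from a screen result
#'
#' @param screen A [screen_cohort()] result.
#' @return Character vector of flagged genes.
#' @export
response_genes <- function(screen) {
  screen$gene[screen$response_gene]
}

#' @export
tidy.screen_result <- function(x, ...) attr(x, "patterns")

#' @export
glance.screen_result <- function(x, ...) {
  p <- attr(x, "params")
  tibble::tibble(
    n_genes = nrow(x),
    n_response_genes = sum(x$response_gene),
    rarity = p$rarity,
    min_characteristic = p$min_characteristic,
    min_count = p$min_count
  )
}
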