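#' Genotype table
#'
#' A subjects-by-SNPs matrix of additive genotype calls together with the
#' per-SNP metadata (gene membership, chromosome, 1-based position) needed to
#' assemble gene vectors.  Genotypes are coded 0/1/2 as the number of copies
#' of the alphabetically later allele; `NA` marks a missing call.
#'
#' @param geno Integer matrix, subjects in rows, SNPs in columns, values in
#'   `{0, 1, 2, NA}`.  Row names are subject ids; column names SNP ids.
#' @param snp_info Data frame with one row per SNP: `snp_id`, `gene`
#'   (`NA` allowed for intergenic SNPs), `chrom`, `pos` (1-based bp).
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(geno, snp_info) {
  snp_info <- tibble::as_tibble(snp_info)
  need <- c("snp_id", "gene", "chrom", "pos")
  if (!all(need %in% names(snp_info))) {
    abort(paste0("snp_info must have columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(snp_info$snp_id)) abort("duplicate snp_id in snp_info")
  if (any(snp_info$pos < 1, na.rm = TRUE)) abort("SNP positions must be >= 1")
  geno <- as.matrix(geno)
  if (ncol(geno) != nrow(snp_info)) {
    abort("ncol(geno) must equal nrow(snp_info)")
  }
  if (is.null(colnames(geno))) colnames(geno) <- snp_info$snp_id
  if (!identical(colnames(geno), as.character(snp_info$snp_id))) {
    geno <- geno[, as.character(snp_info$snp_id), drop = FALSE]
  }
  if (is.null(rownames(geno))) {
    rownames(geno) <- if (nrow(geno)) sprintf("S%04d", seq_len(nrow(geno))) else character()
  }
  bad <- !(geno %in% c(0L, 1L, 2L, NA))
  if (any(bad)) abort("genotype values must be 0, 1, 2 or NA")
  storage.mode(geno) <- "integer"
  structure(
    list(subjects = rownames(geno), snps = snp_info, geno = geno),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  miss <- mean(is.na(x$geno))
  cat(sprintf(
    "<genotype_table> %d subjects x %d SNPs (%d genes), %.2f%% missing\n",
    nrow(x$geno), ncol(x$geno),
    dplyr::n_distinct(x$snps$gene[!is.na(x$snps$gene)]), 100 * miss
  ))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$geno)

#' Long-format view of a genotype table
#'
#' @param x A [genotype_table()].
#' @param ... Unused.
#' @return A tibble with columns `subject_id`, `snp_id`, `genotype`.
#' @export
as_tibble.genotype_table <- function(x, ...) {
  tibble::tibble(
    subject_id = rep(x$subjects, times = ncol(x$geno)),
    snp_id = rep(colnames(x$geno), each = nrow(x$geno)),
    genotype = as.integer(x$geno)
  )
}

#' Gene definitions from SNP metadata
#'
#' Groups the SNPs of a genotype table by gene and orders them by physical
#' position; the position order defines the base-3 digit order of the gene
#' vector (digit k = k-th SNP by ascending position).
#'
#' @param x A [genotype_table()] or a `snp_info` data frame.
#' @return A tibble with one row per gene: `gene`, `chrom`, `start`, `end`,
#'   `m` (number of member SNPs) and `snp_ids` (list column, ascending
#'   position).
#' @export
gene_definitions <- function(x) {
  snps <- if (inherits(x, "genotype_table")) x$snps else tibble::as_tibble(x)
  snps |>
    dplyr::filter(!is.na(.data$gene)) |>
    dplyr::arrange(.data$gene, .data$pos) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      chrom = dplyr::first(.data$chrom),
      start = min(.data$pos),
      end = max(.data$pos),
      m = dplyr::n(),
      snp_ids = list(as.character(.data$snp_id)),
      .groups = "drop"
    )
}

#' Call-rate quality filter
#'
#' Drops SNPs whose call rate falls below `snp_call_rate`, then subjects whose
#' call rate (over the retained SNPs) falls below `sample_call_rate`.
#'
#' @param table A [genotype_table()].
#' @param snp_call_rate,sample_call_rate Minimum acceptable call rates in
#'   `(0, 1]`; defaults 0.95 and 0.80.
#' @return A list with elements `table` (filtered) and `report` (tibble of
#'   removed items with their call rates).
#' @export
qc_filter <- function(table, snp_call_rate = 0.95, sample_call_rate = 0.80) {
  stopifnot(inherits(table, "genotype_table"))
  if (snp_call_rate <= 0 || snp_call_rate > 1 || sample_call_rate <= 0 || sample_call_rate > 1) {
    abort("call-rate thresholds must lie in (0, 1]")
  }
  snp_cr <- colMeans(!is.na(table$geno))
  keep_snp <- snp_cr >= snp_call_rate
  geno <- table$geno[, keep_snp, drop = FALSE]
  subj_cr <- if (ncol(geno)) rowMeans(!is.na(geno)) else rep(1, nrow(geno))
  keep_subj <- subj_cr >= sample_call_rate
  report <- dplyr::bind_rows(
    tibble::tibble(
      item = colnames(table$geno)[!keep_snp], kind = "snp",
      call_rate = unname(snp_cr[!keep_snp])
    ),
    tibble::tibble(
      item = table$subjects[!keep_subj], kind = "subject",
      call_rate = unname(subj_cr[!keep_subj])
    )
  )
  out <- genotype_table(
    geno[keep_subj, , drop = FALSE],
    table$snps[keep_snp, , drop = FALSE]
  )
  list(table = out, report = report)
}

#' Exclude subjects with a high missing-genotype rate
#'
#' Multivariate pattern analyses degrade quickly with missing genotypes, so
#' subjects whose missing rate exceeds the cutoff (default 5%) are removed
#' before classifier training.
#'
#' @param table A [genotype_table()].
#' @param cutoff Maximum tolerated missing fraction; default 0.05.
#' @return Character vector of retained subject ids.
#' @export
exclude_high_missing <- function(table, cutoff = 0.05) {
  stopifnot(inherits(table, "genotype_table"))
  miss <- rowMeans(is.na(table$geno))
  table$subjects[miss <= cutoff]
}

#' Subset a genotype table by subjects
#'
#' @param table A [genotype_table()].
#' @param subjects Character vector of subject ids to keep (order preserved).
#' @return A [genotype_table()].
#' @export
subset_subjects <- function(table, subjects) {
  stopifnot(inherits(table, "genotype_table"))
  missing_ids <- setdiff(subjects, table$subjects)
  if (length(missing_ids)) {
    abort(paste0("unknown subject ids: ", paste(head(missing_ids, 5), collapse = ", ")))
  }
  genotype_table(table$geno[subjects, , drop = FALSE], table$snps)
}
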