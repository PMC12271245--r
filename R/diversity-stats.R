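#' Observed per-SNP genotype-state frequencies for a gene
#'
#' Marginal frequencies of the three genotype states among subjects with a
#' complete (non-missing) gene vector, recovered by decoding the observed
#' pattern codes.
#'
#' @param matrix A [build_gene_vector_matrix()] result.
#' @param gene Gene id.
#' @return An `m x 3` matrix of state frequencies (rows sum to 1).
#' @export
snp_marginals <- function(matrix, gene) {
  codes <- gvm_gene_codes(matrix, gene)
  codes <- codes[!is.na(codes)]
  m <- matrix$genes$m[match(gene, matrix$genes$gene)]
  out <- matrix(0, nrow = m, ncol = 3, dimnames = list(NULL, c("0", "1", "2")))
  if (!length(codes)) return(out)
  tab <- table(codes)
  for (i in seq_along(tab)) {
    digits <- decode_gene_vector(as.numeric(names(tab)[i]), m)
    for (k in seq_len(m)) out[k, digits[k] + 1] <- out[k, digits[k] + 1] + tab[i]
  }
  out / length(codes)
}

#' Expected number of distinct patterns under SNP independence
#'
#' For a gene with `m` SNPs and per-SNP marginal state frequencies, the
#' expected number of distinct patterns in a sample of size `n` when the
#' SNPs are independent is `sum_c [1 - (1 - p_c)^n]` over all `3^m`
#' patterns, `p_c` the product of per-SNP state probabilities.  Comparing
#' this to the observed diversity index quantifies within-gene SNP
#' dependence.
#'
#' @param marginals An `m x 3` matrix of per-SNP state frequencies (rows sum
#'   to 1), e.g. from [snp_marginals()].
#' @param n Sample size.
#' @return Expected distinct-pattern count.
#' @export
expected_distinct_independent <- function(marginals, n) {
  marginals <- as.matrix(marginals)
  m <- nrow(marginals)
  3^m * expected_pattern_coverage(m, n, probs = marginals)
}

#' Ratio of observed to independence-expected pattern counts
#'
#' Sums the observed diversity indices over all genes and divides by the sum
#' of the per-gene independence expectations (each computed from the gene's
#' own observed marginals at its own complete-sample size).  Positive
#' within-gene SNP dependence drives the ratio below 1; the study population
#' showed roughly one third of the independence expectation.
#'
#' @param matrix A [build_gene_vector_matrix()] result.
#' @return A one-row tibble: `observed`, `expected`, `ratio`; the per-gene
#'   breakdown is attached as attribute `per_gene`.
#' @export
dependence_ratio <- function(matrix) {
  di <- diversity_indices(matrix)
  if (!nrow(di)) abort("at least one gene required")
  expected <- vapply(seq_len(nrow(di)), function(i) {
    if (di$n_complete[i] == 0) return(0)
    expected_distinct_independent(snp_marginals(matrix, di$gene[i]), di$n_complete[i])
  }, numeric(1))
  per_gene <- dplyr::mutate(di, expected = expected)
  out <- tibble::tibble(
    observed = sum(di$d),
    expected = sum(expected),
    ratio = sum(di$d) / sum(expected)
  )
  attr(out, "per_gene") <- per_gene
  out
}

#' Between-gene pattern association
#'
#' Association between the genotypic-pattern categories of two genes,
#' measured as Cramér's V on their contingency table after pooling patterns
#' rarer than `min_count` (within the pairwise-complete subjects) into one
#' "rare" category per gene.  By default the Bergsma small-sample bias
#' correction is applied, which keeps independent genes near 0 even with
#' many categories.
#'
#' @param matrix A [build_gene_vector_matrix()] result.
#' @param geneA,geneB Gene ids.
#' @param min_count Patterns with pairwise-complete count below this are
#'   pooled; default 5.
#' @param correct `"bergsma"` (default) for the bias-corrected V, `"none"`
#'   for the classical statistic.
#' @return Association coefficient in `[0, 1]`.
#' @export
between_gene_association <- function(matrix, geneA, geneB, min_count = 5,
                                     correct = c("bergsma", "none")) {
  correct <- match.arg(correct)
  a <- gvm_gene_codes(matrix, geneA)
  b <- gvm_gene_codes(matrix, geneB)
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]
  b <- b[ok]
  fa <- pool_rare(a, min_count)
  fb <- pool_rare(b, min_count)
  if (nlevels(fa) < 2 || nlevels(fb) < 2) {
    abort("fewer than 2 pattern categories after pooling: association undefined",
          class = "genevec_undefined_association")
  }
  tab <- table(fa, fb)
  cramers_v(tab, correct = correct)
}

pool_rare <- function(codes, min_count) {
  cnt <- table(codes)
  common <- names(cnt)[cnt >= min_count]
  lab <- ifelse(as.character(codes) %in% common, as.character(codes), "rare")
  lvl <- c(sort(as.numeric(common)), if (any(lab == "rare")) "rare")
  factor(lab, levels = as.character(lvl))
}

cramers_v <- function(tab, correct = "bergsma") {
  n <- sum(tab)
  chi2 <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
  r <- nrow(tab)
  c <- ncol(tab)
  phi2 <- as.numeric(chi2) / n
  if (correct == "bergsma") {
    phi2 <- max(0, phi2 - (r - 1) * (c - 1) / (n - 1))
    r <- r - (r - 1)^2 / (n - 1)
    c <- c - (c - 1)^2 / (n - 1)
  }
  denom <- min(r - 1, c - 1)
  if (denom <= 0) return(0)
  sqrt(phi2 / denom)
}

#' Prominent genotypic patterns
#'
#' The smallest set of patterns, taken in descending-count order (ties broken
#' by ascending code), whose cumulative share of the complete-vector subjects
#' reaches the coverage target.  In the study about two thirds of genes were
#' dominated by 8-12 prominent patterns covering more than 80% of patients.
#'
#' @param catalog A [pattern_catalog()].
#' @param coverage Target cumulative share in `(0, 1]`; default 0.80.
#' @return A list: `patterns` (codes in selection order) and `n_prominent`.
#' @export
prominent_patterns <- function(catalog, coverage = 0.80) {
  if (!nrow(catalog)) abort("catalog is empty")
  if (coverage <= 0 || coverage > 1) abort("coverage must lie in (0, 1]")
  ord <- order(-catalog$count, catalog$pattern)
  cum <- cumsum(catalog$count[ord]) / sum(catalog$count)
  k <- which(cum >= coverage - 1e-12)[1]
  list(patterns = catalog$pattern[ord][seq_len(k)], n_prominent = k)
}

#' Cohort-level diversity report
#'
#' Aggregates the per-gene diversity indices, the dependence ratio against
#' the SNP-independence expectation, and the distribution of between-gene
#' pattern associations.
#'
#' @param matrix A [build_gene_vector_matrix()] result.
#' @param max_pairs Upper bound on the number of gene pairs used for the
#'   association summary (pairs are chosen deterministically); default 200.
#' @param min_count Rare-pattern pooling threshold for associations.
#' @return An object of class `diversity_report`: a list with `per_gene`
#'   (tibble), `mean_d`, `range_d`, `observed_total`, `expected_total`,
#'   `dependence_ratio`, `association_mean`, `association_sd`, `n_pairs`.
#' @export
diversity_summary <- function(matrix, max_pairs = 200, min_count = 5) {
  dr <- dependence_ratio(matrix)
  per_gene <- attr(dr, "per_gene")
  genes <- matrix$genes$gene
  assoc <- numeric(0)
  if (length(genes) >= 2) {
    pairs <- utils::combn(genes, 2)
    if (ncol(pairs) > max_pairs) {
      idx <- round(seq(1, ncol(pairs), length.out = max_pairs))
      pairs <- pairs[, idx, drop = FALSE]
    }
    assoc <- vapply(seq_len(ncol(pairs)), function(j) {
      tryCatch(
        between_gene_association(matrix, pairs[1, j], pairs[2, j], min_count = min_count),
        genevec_undefined_association = function(e) NA_real_
      )
    }, numeric(1))
    assoc <- assoc[!is.na(assoc)]
  }
  structure(
    list(
      per_gene = per_gene,
      mean_d = mean(per_gene$d),
      range_d = range(per_gene$d),
      observed_total = dr$observed,
      expected_total = dr$expected,
      dependence_ratio = dr$ratio,
      association_mean = if (length(assoc)) mean(assoc) else NA_real_,
      association_sd = if (length(assoc) > 1) stats::sd(assoc) else NA_real_,
      n_pairs = length(assoc)
    ),
    class = "diversity_report"
  )
}

#' @export
print.diversity_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<diversity_report> %d genes\n",
      "  diversity index d: mean %.1f (range %d-%d)\n",
      "  distinct patterns: %d observed vs %.1f expected under independence (ratio %.3f)\n",
      "  between-gene association: %.3f +/- %.3f over %d pairs\n"
    ),
    nrow(x$per_gene), x$mean_d, x$range_d[1], x$range_d[2],
    x$observed_total, x$expected_total, x$dependence_ratio,
    x$association_mean, x$association_sd, x$n_pairs
  ))
  invisible(x)
}

#' @export
glance.diversity_report <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$per_gene),
    mean_d = x$mean_d,
    min_d = x$range_d[1],
    max_d = x$range_d[2],
    observed_total = x$observed_total,
    expected_total = x$expected_total,
    dependence_ratio = x$dependence_ratio,
    association_mean = x$association_mean,
    association_sd = x$association_sd
  )
}

#' @export
tidy.diversity_report <- function(x, ...) x$per_gene

#' Serialize / restore a diversity report
#'
#' @param x A [diversity_summary()] result.
#' @param path File path for the JSON document.
#' @return `write_diversity_report()` returns `path` invisibly;
#'   `read_diversity_report()` returns a `diversity_report`.
#' @export
write_diversity_report <- function(x, path) {
  payload <- list(
    per_gene = x$per_gene,
    mean_d = x$mean_d, range_d = x$range_d,
    observed_total = x$observed_total, expected_total = x$expected_total,
    dependence_ratio = x$dependence_ratio,
    association_mean = x$association_mean, association_sd = x$association_sd,
    n_pairs = x$n_pairs
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_diversity_report
#' @export
read_diversity_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$per_gene <- tibble::as_tibble(raw$per_gene)
  raw$range_d <- as.numeric(raw$range_d)
  structure(raw, class = "diversity_report")
}
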