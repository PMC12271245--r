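#' Encode a gene vector
#'
#' Collapses the ordered genotypes of a gene's member SNPs into a single
#' base-3 integer, the "gene vector": `v = sum_k s_k * 3^(k-1)` with
#' `s_k` the additive genotype (0/1/2) of the k-th SNP in ascending physical
#' position.  With `m` SNPs there are `3^m` possible codes, so each code is
#' one multi-SNP genotypic pattern.
#'
#' @param genotypes Integer vector of genotypes in `{0, 1, 2}`, length
#'   1 to 15, ordered by ascending SNP position.
#' @return The pattern code, a number in `[0, 3^m - 1]`.
#' @examples
#' encode_gene_vector(c(1, 2, 0)) # 1*1 + 2*3 + 0*9 = 7
#' @export
encode_gene_vector <- function(genotypes) {
  m <- length(genotypes)
  if (m < 1 || m > 15) abort("gene vectors support 1 to 15 SNPs")
  if (anyNA(genotypes)) abort("missing genotype: gene vector undefined", class = "genevec_missing_genotype")
  if (!all(genotypes %in% c(0, 1, 2))) abort("genotypes must be 0, 1 or 2")
  sum(genotypes * 3^(seq_len(m) - 1))
}

#' Decode a gene vector
#'
#' Inverse of [encode_gene_vector()]: recovers the ordered genotypes from a
#' pattern code.
#'
#' @param code Pattern code in `[0, 3^m - 1]`.
#' @param m Number of SNPs in the gene (1 to 15).
#' @return Integer vector of length `m` with values in `{0, 1, 2}`.
#' @export
decode_gene_vector <- function(code, m) {
  if (m < 1 || m > 15) abort("gene vectors support 1 to 15 SNPs")
  if (length(code) != 1 || is.na(code) || code < 0 || code >= 3^m || code != floor(code)) {
    abort("code must be an integer in [0, 3^m)")
  }
  out <- integer(m)
  for (k in seq_len(m)) {
    out[k] <- code %% 3
    code <- code %/% 3
  }
  out
}

#' Gene-vector matrix
#'
#' Encodes every (subject, gene) combination of a genotype table as a base-3
#' pattern code.  A subject's code for a gene is missing whenever any of the
#' gene's member genotypes is missing: a base-3 number with an unknown digit
#' is undefined, so no partial patterns are formed.
#'
#' @param table A [genotype_table()].
#' @param genes Gene definitions as returned by [gene_definitions()];
#'   defaults to the genes annotated in `table`.
#' @return An object of class `gene_vector_matrix`: subject ids, a gene
#'   tibble (`gene`, `m`), and a numeric `codes` matrix (subjects x genes,
#'   `NA` = missing).
#' @export
build_gene_vector_matrix <- function(table, genes = gene_definitions(table)) {
  stopifnot(inherits(table, "genotype_table"))
  absent <- setdiff(unlist(genes$snp_ids), colnames(table$geno))
  if (length(absent)) {
    abort(paste0("gene definitions reference SNPs absent from the table: ",
                 paste(head(absent, 5), collapse = ", ")))
  }
  codes <- matrix(
    NA_real_, nrow = nrow(table$geno), ncol = nrow(genes),
    dimnames = list(table$subjects, genes$gene)
  )
  for (g in seq_len(nrow(genes))) {
    ids <- genes$snp_ids[[g]]
    sub <- table$geno[, ids, drop = FALSE]
    w <- 3^(seq_along(ids) - 1)
    v <- as.numeric(sub %*% w) # NA propagates through any missing digit
    codes[, g] <- v
  }
  structure(
    list(
      subjects = table$subjects,
      genes = tibble::tibble(gene = genes$gene, m = genes$m),
      codes = codes
    ),
    class = "gene_vector_matrix"
  )
}

#' @export
print.gene_vector_matrix <- function(x, ...) {
  cat(sprintf(
    "<gene_vector_matrix> %d subjects x %d genes, %.2f%% missing vectors\n",
    length(x$subjects), nrow(x$genes), 100 * mean(is.na(x$codes))
  ))
  invisible(x)
}

#' @rdname build_gene_vector_matrix
#' @param x A `gene_vector_matrix`.
#' @param ... Unused.
#' @export
as_tibble.gene_vector_matrix <- function(x, ...) {
  tibble::tibble(
    subject_id = rep(x$subjects, times = nrow(x$genes)),
    gene = rep(x$genes$gene, each = length(x$subjects)),
    m = rep(x$genes$m, each = length(x$subjects)),
    code = as.numeric(x$codes)
  )
}

gvm_gene_codes <- function(matrix, gene) {
  g <- match(gene, matrix$genes$gene)
  if (is.na(g)) abort(paste0("unknown gene: ", gene))
  matrix$codes[, g]
}

#' Diversity index of a gene
#'
#' The diversity index `d` is the number of distinct genotypic patterns
#' (gene-vector codes) observed for a gene in the sample; it measures the
#' gene's resolution of between-subject differences.
#'
#' @param matrix A [build_gene_vector_matrix()] result.
#' @param gene Gene id.
#' @return Integer count of distinct non-missing codes.
#' @export
diversity_index <- function(matrix, gene) {
  codes <- gvm_gene_codes(matrix, gene)
  dplyr::n_distinct(codes[!is.na(codes)])
}

#' Diversity indices for all genes
#'
#' @param matrix A [build_gene_vector_matrix()] result.
#' @return A tibble with `gene`, `m`, `n_complete`, `d`.
#' @export
diversity_indices <- function(matrix) {
  tibble::tibble(
    gene = matrix$genes$gene,
    m = matrix$genes$m,
    n_complete = unname(colSums(!is.na(matrix$codes))),
    d = unname(apply(matrix$codes, 2, function(v) dplyr::n_distinct(v[!is.na(v)])))
  )
}

#' Pattern catalog for a gene
#'
#' Tabulates the distinct genotypic patterns of one gene with overall counts
#' and, optionally, counts within named subject subgroups (responders,
#' severity bands, IgM strata, ...).  Rows are sorted by ascending pattern
#' code; the number of rows is the gene's diversity index.
#'
#' @param matrix A [build_gene_vector_matrix()] result.
#' @param gene Gene id.
#' @param subgroups Named list of subject-id vectors; each becomes a count
#'   column.
#' @return A tibble (class `pattern_catalog`) with columns `pattern`, `count`
#'   and one column per subgroup; attributes `gene`, `m`, `n_complete`.
#' @export
pattern_catalog <- function(matrix, gene, subgroups = NULL) {
  codes <- gvm_gene_codes(matrix, gene)
  names(codes) <- matrix$subjects
  ok <- !is.na(codes)
  tab <- tibble::tibble(pattern = unname(codes[ok])) |>
    dplyr::count(.data$pattern, name = "count") |>
    dplyr::arrange(.data$pattern)
  if (!is.null(subgroups)) {
    if (is.null(names(subgroups)) || any(names(subgroups) == "")) {
      abort("subgroups must be a named list")
    }
    for (nm in names(subgroups)) {
      ids <- subgroups[[nm]]
      unknown <- setdiff(ids, matrix$subjects)
      if (length(unknown)) {
        abort(paste0("subgroup '", nm, "' contains unknown subjects: ",
                     paste(head(unknown, 5), collapse = ", ")))
      }
      sub_codes <- codes[intersect(ids, names(codes)[ok])]
      cnt <- table(factor(sub_codes, levels = tab$pattern))
      tab[[nm]] <- as.integer(cnt)
    }
  }
  structure(tab,
    class = c("pattern_catalog", class(tab)),
    gene = gene,
    m = matrix$genes$m[match(gene, matrix$genes$gene)],
    n_complete = sum(ok)
  )
}

#' Expected fraction of possible patterns observed under SNP independence
#'
#' Closed-form coupon-collector expectation: with independent SNPs the
#' probability of pattern `c` is the product of its per-SNP state
#' probabilities, and the expected observed fraction in a sample of size `n`
#' is `mean_c [1 - (1 - p_c)^n]` over all `3^m` patterns.  With equally
#' distributed SNPs a sample of `4 * 3^m` subjects is expected to show about
#' 95% of the possible patterns.
#'
#' @param m Number of SNPs (1 to 15).
#' @param n Sample size.
#' @param probs Per-SNP genotype-state probabilities: either a length-3
#'   vector shared by all SNPs or an `m x 3` matrix (rows sum to 1).
#'   Default: uniform (1/3, 1/3, 1/3).
#' @return Expected fraction of the `3^m` patterns observed, in `[0, 1]`.
#' @examples
#' expected_pattern_coverage(1, 3) # 1 - (2/3)^3 = 19/27
#' @export
expected_pattern_coverage <- function(m, n, probs = NULL) {
  p <- pattern_probabilities(m, probs)
  if (n < 0) abort("n must be non-negative")
  mean(1 - (1 - p)^n)
}

pattern_probabilities <- function(m, probs = NULL) {
  if (m < 1 || m > 15) abort("m must be between 1 and 15 (3^m enumeration bound)")
  if (is.null(probs)) probs <- rep(1 / 3, 3)
  if (is.matrix(probs)) {
    if (nrow(probs) != m || ncol(probs) != 3) abort("probs matrix must be m x 3")
    rows <- lapply(seq_len(m), function(k) probs[k, ])
  } else {
    if (length(probs) != 3) abort("probs must have 3 states per SNP")
    rows <- rep(list(as.numeric(probs)), m)
  }
  for (r in rows) {
    if (abs(sum(r) - 1) > 1e-8 || any(r < 0)) abort("probabilities must be non-negative and sum to 1 per SNP")
  }
  # digit k has weight 3^(k-1): kronecker in reverse keeps index = code + 1
  p <- 1
  for (k in rev(seq_len(m))) p <- kronecker(rows[[k]], p)
  p
}

#' Monte-Carlo check of the pattern-coverage expectation
#'
#' Draws `reps` independent samples of `n` subjects with `m` independent SNPs
#' and returns the mean fraction of the `3^m` patterns observed, for
#' comparison against [expected_pattern_coverage()].
#'
#' @inheritParams expected_pattern_coverage
#' @param reps Number of Monte-Carlo replicates.
#' @param seed Optional integer seed.
#' @return Mean observed pattern fraction over replicates.
#' @export
simulate_pattern_coverage <- function(m, n, reps = 100, probs = NULL, seed = NULL) {
  if (reps < 1) abort("reps must be >= 1")
  p <- pattern_probabilities(m, probs)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(0)
  total <- 3^m
  mean(vapply(seq_len(reps), function(r) {
    codes <- sample.int(total, size = n, replace = TRUE, prob = p)
    length(unique(codes)) / total
  }, numeric(1)))
}
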