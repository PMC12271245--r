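# Small cohort configurations shared across tests.

tiny_config <- function(seed = 1, ...) {
  cohort_config(
    n_f2 = 20, n_f3 = 60, n_genes = 8, seed = seed,
    response_genes = tibble::tibble(
      gene = sprintf("G%03d", 1:2),
      freq_responders = 0.30, freq_nonresponders = 0.05
    ),
    ...
  )
}

# A gene_vector_matrix built directly from a code matrix, bypassing the
# genotype layer; m gives each gene's SNP count.
make_gvm <- function(codes, m = rep(4L, ncol(codes)),
                     genes = sprintf("G%03d", seq_len(ncol(codes))),
                     subjects = sprintf("S%04d", seq_len(nrow(codes)))) {
  codes <- as.matrix(codes)
  dimnames(codes) <- list(subjects, genes)
  structure(
    list(subjects = subjects, genes = tibble::tibble(gene = genes, m = m),
         codes = codes),
    class = "gene_vector_matrix"
  )
}

# One-subject trajectory tibble.
make_traj <- function(days, scores, diagnosis = "F3",
                      scale = if (diagnosis == "F3") "HAM-D17" else "PANSS-P",
                      subject = "S0001") {
  tibble::tibble(
    subject_id = subject, diagnosis = diagnosis, scale = scale,
    day = days, score = scores
  )
}
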