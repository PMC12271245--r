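test_that("configuration invariants are enforced", {
  expect_error(cohort_config(missing_rate = 1.2), class = "genevec_config_error")
  expect_error(cohort_config(snps_per_gene = c(1, 8)), class = "genevec_config_error")
  expect_error(cohort_config(snps_per_gene = c(4, 16)), class = "genevec_config_error")
  expect_error(cohort_config(allele_freq_range = c(0, 0.5)), class = "genevec_config_error")
  expect_error(
    cohort_config(trajectory = list(horizon_days = 10)),
    class = "genevec_config_error"
  )
  expect_error(
    cohort_config(n_genes = 5, response_genes = tibble::tibble(
      gene = "G099", freq_responders = 0.3, freq_nonresponders = 0.05
    )),
    class = "genevec_config_error"
  )
})

test_that("independent SNPs follow Hardy-Weinberg marginals", {
  cfg <- cohort_config(
    n_f2 = 0, n_f3 = 6000, n_genes = 2, within_gene_ld = 0,
    allele_freq_range = c(0.5, 0.5), missing_rate = 0,
    high_missing_subject_fraction = 0,
    cross_gene_link = tibble::tibble(geneA = character(), geneB = character(),
                                     strength = numeric()),
    response_genes = tibble::tibble(gene = character(), freq_responders = numeric(),
                                    freq_nonresponders = numeric()),
    seed = 17
  )
  tab <- simulate_genotypes(cfg, seed = 17)
  expected <- c(0.25, 0.5, 0.25)
  for (j in seq_len(ncol(tab$geno))) {
    freq <- tabulate(tab$geno[, j] + 1, nbins = 3) / nrow(tab$geno)
    se <- sqrt(expected * (1 - expected) / nrow(tab$geno))
    expect_true(all(abs(freq - expected) < 3.5 * se))
  }
})

test_that("with no within-gene LD the distinct-pattern fraction matches independence", {
  cfg <- cohort_config(
    n_f2 = 0, n_f3 = 324, n_genes = 6, snps_per_gene = c(4, 4),
    within_gene_ld = 0, missing_rate = 0, high_missing_subject_fraction = 0,
    cross_gene_link = tibble::tibble(geneA = character(), geneB = character(),
                                     strength = numeric()),
    response_genes = tibble::tibble(gene = character(), freq_responders = numeric(),
                                    freq_nonresponders = numeric()),
    seed = 23
  )
  tab <- simulate_genotypes(cfg, seed = 23)
  gvm <- build_gene_vector_matrix(tab)
  for (g in gvm$genes$gene) {
    marg <- snp_marginals(gvm, g)
    expected <- expected_distinct_independent(marg, 324)
    observed <- diversity_index(gvm, g)
    # binomial-style dispersion of the distinct count around its expectation
    expect_lt(abs(observed - expected), 3 * sqrt(expected))
  }
})

test_that("an empty cohort still carries full SNP metadata", {
  cfg <- cohort_config(n_f2 = 0, n_f3 = 0, n_genes = 5, seed = 2,
                       response_genes = tibble::tibble(gene = character(),
                                                       freq_responders = numeric(),
                                                       freq_nonresponders = numeric()))
  tab <- simulate_genotypes(cfg, seed = 2)
  expect_equal(nrow(tab$geno), 0)
  expect_gt(nrow(tab$snps), 0)
  expect_equal(dplyr::n_distinct(tab$snps$gene), 5)
})

test_that("response-pattern planting hits the configured class frequencies", {
  cfg <- cohort_config(
    n_f2 = 0, n_f3 = 600, n_genes = 6, missing_rate = 0,
    high_missing_subject_fraction = 0, seed = 31,
    response_genes = tibble::tibble(gene = "G001", freq_responders = 0.30,
                                    freq_nonresponders = 0.05)
  )
  tab <- simulate_genotypes(cfg, seed = 31)
  labels <- tibble::tibble(
    subject_id = tab$subjects,
    responder = rep(c(TRUE, FALSE), c(200, 400))
  )
  planted <- plant_response_patterns(tab, cfg, labels, seed = 32)
  gvm <- build_gene_vector_matrix(planted$table)
  codes <- gvm$codes[, "G001"]
  hit <- codes == planted$truth$pattern[1]
  n_resp <- sum(hit[labels$responder])
  n_non <- sum(hit[!labels$responder])
  expect_lt(abs(n_resp - 60), 3 * sqrt(200 * 0.3 * 0.7) + 3) # + background carriers
  expect_lt(abs(n_non - 20), 3 * sqrt(400 * 0.05 * 0.95) + 3)

  # deterministic planting: freq 1 / 0
  cfg2 <- cfg
  cfg2$response_genes$freq_responders <- 1
  cfg2$response_genes$freq_nonresponders <- 0
  planted2 <- plant_response_patterns(tab, cfg2, labels, seed = 33)
  codes2 <- build_gene_vector_matrix(planted2$table)$codes[, "G001"]
  expect_true(all(codes2[labels$responder] == planted2$truth$pattern[1]))

  # null planting leaves the table untouched
  cfg3 <- cfg
  cfg3$response_genes$freq_responders <- 0
  cfg3$response_genes$freq_nonresponders <- 0
  planted3 <- plant_response_patterns(tab, cfg3, labels, seed = 34)
  expect_identical(planted3$table$geno, tab$geno)

  cfg4 <- cfg
  cfg4$response_genes$gene <- "G999"
  expect_error(plant_response_patterns(tab, cfg4, labels, seed = 35))
})

test_that("trajectories recover the configured responder fraction", {
  cfg <- cohort_config(
    n_f2 = 0, n_f3 = 500, responder_fraction = 0.4,
    trajectory = list(noise_sd = 0.3, responder_reduction = c(0.60, 0.85)),
    seed = 41
  )
  co <- generate_cohort(cfg)
  labels <- label_outcomes(co$trajectories)
  expect_lt(abs(mean(labels$responder) - 0.4), 0.05)
  # generative classes agree with the rule-derived labels for most subjects
  agree <- mean(labels$responder == co$true_labels$responder)
  expect_gt(agree, 0.9)
})

test_that("without triggers nobody meets the response criterion", {
  cfg <- cohort_config(n_f2 = 10, n_f3 = 40, responder_fraction = 0,
                       stuck_fraction = 0, seed = 43)
  co <- generate_cohort(cfg)
  labels <- label_outcomes(co$trajectories)
  expect_equal(sum(labels$responder), 0)
})

test_that("a noiseless decline from 24 to 10 is a response by the 50% rule", {
  traj <- make_traj(c(0, 3, 7, 10, 14, 21, 28, 42),
                    c(24, 24, 22, 19, 16, 12, 10, 10))
  expect_true(classify_response(traj))
})

test_that("missingness masking matches its configured rates", {
  cfg <- cohort_config(n_f2 = 0, n_f3 = 100, n_genes = 90, missing_rate = 0.02,
                       high_missing_subject_fraction = 0.1, seed = 51,
                       response_genes = tibble::tibble(gene = character(),
                                                       freq_responders = numeric(),
                                                       freq_nonresponders = numeric()))
  tab <- simulate_genotypes(cfg, seed = 51)
  expect_gt(ncol(tab$geno), 400)

  cfg0 <- cfg
  cfg0$missing_rate <- 0
  cfg0$high_missing_subject_fraction <- 0
  expect_identical(apply_missingness(tab, cfg0, seed = 52)$geno, tab$geno)

  masked <- apply_missingness(tab, cfg, seed = 53)
  overall <- mean(is.na(masked$geno))
  p <- ncol(tab$geno)
  # base rate check on the non-elevated subjects
  subj_rate <- rowMeans(is.na(masked$geno))
  base_subjects <- subj_rate <= 0.05
  base_rate <- mean(is.na(masked$geno[base_subjects, ]))
  expect_lt(abs(base_rate - 0.02), 3 * sqrt(0.02 * 0.98 / (sum(base_subjects) * p)))
  # roughly 10 subjects exceed the 5% analysis cutoff
  expect_gte(sum(subj_rate > 0.05), 7)
  expect_lte(sum(subj_rate > 0.05), 13)
  expect_equal(length(exclude_high_missing(masked)), sum(subj_rate <= 0.05))
})

test_that("IgM flags hit the configured prevalence and respect independence at zero strength", {
  cfg <- cohort_config(n_f2 = 0, n_f3 = 900, n_genes = 10, seed = 61)
  co_tab <- simulate_genotypes(cfg, seed = 61)

  cfg0 <- cfg
  cfg0$igm$prevalence <- 0
  flags0 <- simulate_igm(co_tab, cfg0, seed = 62)
  expect_false(any(flags0$igm_elevated))

  flags <- simulate_igm(co_tab, cfg, seed = 63)
  expect_lt(abs(sum(flags$igm_elevated) - 234), 3 * sqrt(900 * 0.26 * 0.74))

  # zero association strength: flag independent of carrier status
  cfg_null <- cfg
  cfg_null$igm$strength <- 0
  pvals <- vapply(1:20, function(s) {
    tab <- simulate_genotypes(cohort_config(n_f2 = 0, n_f3 = 400, n_genes = 4,
                                            seed = 70 + s), seed = 70 + s)
    fl <- simulate_igm(tab, cfg_null, seed = 170 + s)
    gvm <- build_gene_vector_matrix(tab)
    codes <- gvm$codes[, cfg$igm$genes[1]]
    modal <- as.numeric(names(which.max(table(codes))))
    carrier <- !is.na(codes) & codes == modal
    suppressWarnings(stats::chisq.test(table(carrier, fl$igm_elevated))$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.9)
})

test_that("cohort generation is deterministic and seed-sensitive", {
  cfg <- tiny_config(seed = 77)
  t0 <- Sys.time()
  a <- generate_cohort(cfg)
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  b <- generate_cohort(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c_ <- generate_cohort(tiny_config(seed = 78))
  expect_false(identical(a$genotypes$geno, c_$genotypes$geno))
  # study-sized generation stays well under a minute (tiny config is ~1/10)
  expect_lt(elapsed, 30)
  expect_true(all(a$truth$gene %in% a$genes$gene))
  expect_true(all(table(a$trajectories$subject_id) >= 1))
})

test_that("cross-gene linkage induces association and LD suppresses diversity", {
  base <- list(
    n_f2 = 0, n_f3 = 500, n_genes = 6, missing_rate = 0,
    high_missing_subject_fraction = 0,
    response_genes = tibble::tibble(gene = character(), freq_responders = numeric(),
                                    freq_nonresponders = numeric())
  )
  cfg_link <- do.call(cohort_config, c(base, list(
    seed = 81,
    cross_gene_link = tibble::tibble(geneA = "G001", geneB = "G002", strength = 0.5)
  )))
  gvm <- build_gene_vector_matrix(simulate_genotypes(cfg_link, seed = 81))
  v_linked <- between_gene_association(gvm, "G001", "G002")
  v_free <- between_gene_association(gvm, "G003", "G004")
  expect_gt(v_linked, 0.3)
  expect_lt(v_free, 0.15)

  mean_d <- vapply(c(0, 0.45, 0.9), function(ld) {
    cfg <- do.call(cohort_config, c(base, list(
      seed = 83, within_gene_ld = ld,
      cross_gene_link = tibble::tibble(geneA = character(), geneB = character(),
                                       strength = numeric())
    )))
    mean(diversity_indices(build_gene_vector_matrix(simulate_genotypes(cfg, seed = 83)))$d)
  }, numeric(1))
  expect_true(all(diff(mean_d) < 0))
})
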