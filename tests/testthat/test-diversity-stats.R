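test_that("independence-expected distinct counts match closed forms and simulation", {
  expect_equal(expected_distinct_independent(matrix(c(1, 0, 0), 1), 50), 1)
  expect_equal(
    expected_distinct_independent(matrix(1 / 3, 2, 3), 36),
    9 * (1 - (8 / 9)^36)
  )
  # Monte-Carlo oracle: m = 3 independent SNPs, n = 50
  set.seed(7)
  marg <- matrix(c(0.5, 0.3, 0.2), 3, 3, byrow = TRUE)
  reps <- 400
  distinct <- vapply(1:reps, function(r) {
    g <- vapply(1:3, function(k) sample(0:2, 50, replace = TRUE, prob = marg[k, ]), numeric(50))
    length(unique(g %*% 3^(0:2)))
  }, numeric(1))
  se <- stats::sd(distinct) / sqrt(reps)
  expect_lt(abs(mean(distinct) - expected_distinct_independent(marg, 50)), 3 * se)
})

test_that("dependence ratio is near 1 for independent SNPs and drops with LD", {
  ratios <- vapply(1:5, function(s) {
    cfg <- cohort_config(
      n_f2 = 0, n_f3 = 400, n_genes = 15, within_gene_ld = 0,
      missing_rate = 0, high_missing_subject_fraction = 0, seed = s,
      cross_gene_link = tibble::tibble(geneA = character(), geneB = character(),
                                       strength = numeric()),
      response_genes = tibble::tibble(gene = character(), freq_responders = numeric(),
                                      freq_nonresponders = numeric())
    )
    gvm <- build_gene_vector_matrix(simulate_genotypes(cfg, seed = s))
    dependence_ratio(gvm)$ratio
  }, numeric(1))
  expect_gt(mean(ratios), 0.95)
  expect_lt(mean(ratios), 1.05)

  cfg_ld <- cohort_config(
    n_f2 = 0, n_f3 = 400, n_genes = 15, within_gene_ld = 0.9,
    missing_rate = 0, high_missing_subject_fraction = 0, seed = 1,
    cross_gene_link = tibble::tibble(geneA = character(), geneB = character(),
                                     strength = numeric()),
    response_genes = tibble::tibble(gene = character(), freq_responders = numeric(),
                                    freq_nonresponders = numeric())
  )
  gvm_ld <- build_gene_vector_matrix(simulate_genotypes(cfg_ld, seed = 1))
  expect_lt(dependence_ratio(gvm_ld)$ratio, 0.6)
})

test_that("dependence ratio decreases monotonically in within-gene LD", {
  lds <- c(0, 0.225, 0.45, 0.675, 0.9)
  means <- vapply(lds, function(ld) {
    mean(vapply(1:3, function(s) {
      cfg <- cohort_config(
        n_f2 = 0, n_f3 = 300, n_genes = 10, within_gene_ld = ld,
        missing_rate = 0, high_missing_subject_fraction = 0, seed = s,
        cross_gene_link = tibble::tibble(geneA = character(), geneB = character(),
                                         strength = numeric()),
        response_genes = tibble::tibble(gene = character(), freq_responders = numeric(),
                                        freq_nonresponders = numeric())
      )
      gvm <- build_gene_vector_matrix(simulate_genotypes(cfg, seed = 100 + s))
      dependence_ratio(gvm)$ratio
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("between-gene association matches the hand-computed 2x2 value", {
  # contingency [[40,10],[10,40]]: chi2 = 36, V = sqrt(36/100) = 0.6
  codes_a <- rep(c(0, 0, 1, 1), c(40, 10, 10, 40))
  codes_b <- rep(c(0, 1, 0, 1), c(40, 10, 10, 40))
  gvm <- make_gvm(cbind(codes_a, codes_b), m = c(4L, 4L))
  expect_equal(between_gene_association(gvm, "G001", "G002", correct = "none"), 0.6)
  # default Bergsma correction shrinks the same table slightly
  v_corr <- between_gene_association(gvm, "G001", "G002")
  expect_lt(v_corr, 0.6)
  expect_gt(v_corr, 0.55)
})

test_that("association is symmetric, maximal for relabelings, near zero for independence", {
  set.seed(11)
  a <- sample(0:3, 300, replace = TRUE)
  gvm <- make_gvm(cbind(a, 10 - a, sample(0:3, 300, replace = TRUE)), m = rep(4L, 3))
  expect_equal(between_gene_association(gvm, "G001", "G002", correct = "none"), 1.0)
  expect_equal(
    between_gene_association(gvm, "G001", "G003"),
    between_gene_association(gvm, "G003", "G001")
  )
  # constant gene after pooling errors rather than returning NaN
  gvm_const <- make_gvm(cbind(rep(1, 50), sample(0:3, 50, replace = TRUE)), m = c(4L, 4L))
  expect_error(between_gene_association(gvm_const, "G001", "G002"),
               class = "genevec_undefined_association")

  null_vs <- vapply(1:30, function(i) {
    g <- make_gvm(cbind(sample(0:8, 500, TRUE), sample(0:8, 500, TRUE)), m = c(4L, 4L))
    between_gene_association(g, "G001", "G002")
  }, numeric(1))
  expect_lt(mean(null_vs), 0.1)
})

test_that("prominent patterns take the smallest descending-count prefix", {
  shares <- c(50, 20, 15, 10, 5)
  cat_tab <- structure(
    tibble::tibble(pattern = 0:4, count = shares),
    class = c("pattern_catalog", class(tibble::tibble())),
    gene = "G", m = 4, n_complete = 100
  )
  pp <- prominent_patterns(cat_tab, coverage = 0.80)
  expect_equal(pp$n_prominent, 3)
  expect_equal(pp$patterns, c(0, 1, 2))

  single <- structure(tibble::tibble(pattern = 7, count = 10),
                      class = class(cat_tab), gene = "G", m = 4, n_complete = 10)
  expect_equal(prominent_patterns(single, 0.8)$n_prominent, 1)

  unif <- structure(tibble::tibble(pattern = 0:99, count = rep(1, 100)),
                    class = class(cat_tab), gene = "G", m = 5, n_complete = 100)
  expect_equal(prominent_patterns(unif, 0.8)$n_prominent, 80)
  expect_error(prominent_patterns(unif, 0))
  # prefix length is non-decreasing in the coverage target
  lens <- vapply(c(0.2, 0.5, 0.8, 0.95), function(cv) {
    prominent_patterns(cat_tab, cv)$n_prominent
  }, numeric(1))
  expect_true(all(diff(lens) >= 0))
})

test_that("the diversity report aggregates and round-trips through JSON", {
  gvm <- make_gvm(matrix(c(1, 1, 2), ncol = 1), m = 4L)
  rep1 <- diversity_summary(gvm)
  expect_equal(rep1$mean_d, 2)
  expect_equal(rep1$range_d, c(2, 2))

  co <- generate_cohort(tiny_config(seed = 8))
  rep2 <- diversity_summary(build_gene_vector_matrix(co$genotypes), max_pairs = 10)
  path <- withr::local_tempfile(fileext = ".json")
  write_diversity_report(rep2, path)
  rep3 <- read_diversity_report(path)
  expect_equal(rep3$per_gene$d, rep2$per_gene$d)
  expect_equal(rep3$dependence_ratio, rep2$dependence_ratio)
  expect_equal(rep3$association_mean, rep2$association_mean)
})
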