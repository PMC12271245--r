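test_that("one-hot encoding gives rare patterns to OTHER and zeroes missing blocks", {
  codes <- c(rep(5, 50), rep(9, 3), NA)
  gvm <- make_gvm(matrix(codes, ncol = 1))
  f <- one_hot_encode(gvm, "G001", min_count = 5)
  expect_setequal(colnames(f$X), c("G001:5", "G001:OTHER"))
  expect_equal(unname(f$X[1, "G001:5"]), 1)
  expect_equal(unname(f$X[51, "G001:OTHER"]), 1) # code 9, count 3 < 5
  expect_equal(sum(f$X[54, ]), 0) # missing vector
  expect_true(all(rowSums(f$X) %in% c(0, 1)))
  expect_error(one_hot_encode(gvm, character(0)))
  expect_error(one_hot_encode(gvm, "G999"))

  # a vocabulary aligns new data, mapping unseen codes to OTHER
  gvm2 <- make_gvm(matrix(c(5, 7, NA), ncol = 1))
  f2 <- one_hot_encode(gvm2, "G001", vocab = f$vocab)
  expect_identical(colnames(f2$X), colnames(f$X))
  expect_equal(unname(f2$X[2, "G001:OTHER"]), 1)
})

test_that("high-missing subjects are excluded at the 5% cutoff", {
  snp_info <- tibble::tibble(snp_id = sprintf("s%02d", 1:100), gene = "G",
                             chrom = 1, pos = 1:100 * 10)
  geno <- matrix(1L, 3, 100, dimnames = list(c("a", "b", "c"), snp_info$snp_id))
  geno["b", 1:6] <- NA # 6% missing
  tab <- genotype_table(geno, snp_info)
  expect_equal(exclude_high_missing(tab), c("a", "c"))
})

test_that("the forward pass follows the sigmoid equations", {
  set.seed(2)
  m <- nn_model(3, 2)
  m$W1[] <- 0
  m$w2[] <- 0
  expect_equal(forward(m, c(1, 0, 1))$output, 0.5)
  expect_equal(forward(m, c(1, 0, 1))$hidden, c(0.5, 0.5))
  expect_error(forward(m, c(1, 0)))

  # independent scalar re-implementation
  m2 <- nn_model(4, 3, init_sd = 1)
  x <- runif(4)
  sig <- function(z) 1 / (1 + exp(-z))
  hid <- numeric(3)
  for (j in 1:3) {
    z <- 0
    for (k in 1:4) z <- z + m2$W1[j, k] * x[k]
    z <- z + m2$W1[j, 5] # bias unit
    hid[j] <- sig(z)
  }
  out <- sig(sum(m2$w2[1:3] * hid) + m2$w2[4])
  act <- forward(m2, x)
  expect_equal(act$output, out, tolerance = 1e-12)
  expect_equal(act$hidden, hid, tolerance = 1e-12)
})

test_that("the backprop update reproduces the printed per-probe formulas", {
  m <- nn_model(1, 1, alpha = 1)
  m$W1[] <- 0
  m$w2[] <- 0
  m2 <- backprop_update(m, 1, 1, alpha = 1)
  # output-side: alpha * eps * s_j * s_i(1 - s_i) = 1 * 0.5 * 0.5 * 0.25
  expect_equal(m2$w2[1], 0.0625)
  expect_equal(m2$w2[2], 0.125) # bias unit carries s_j = 1
  # hidden-side delta carries the pre-update w_ij = 0
  expect_equal(m2$W1, m$W1)
})

test_that("the update equals steepest descent on half the squared error", {
  set.seed(31)
  worst <- 0
  for (rep in 1:25) {
    n_in <- sample(2:6, 1)
    n_h <- sample(2:5, 1)
    m <- nn_model(n_in, n_h, init_sd = 1)
    x <- runif(n_in, -1, 1)
    y <- sample(0:1, 1)
    m2 <- backprop_update(m, x, y, alpha = 1)
    E <- function(mm) 0.5 * (y - forward(mm, x)$output)^2
    h <- 1e-5
    for (i in seq_along(m$W1)) {
      mp <- m; mp$W1[i] <- mp$W1[i] + h
      mn <- m; mn$W1[i] <- mn$W1[i] - h
      g <- (E(mp) - E(mn)) / (2 * h)
      worst <- max(worst, abs((m2$W1[i] - m$W1[i]) + g) / max(abs(g), 1e-6))
    }
    for (i in seq_along(m$w2)) {
      mp <- m; mp$w2[i] <- mp$w2[i] + h
      mn <- m; mn$w2[i] <- mn$w2[i] - h
      g <- (E(mp) - E(mn)) / (2 * h)
      worst <- max(worst, abs((m2$w2[i] - m$w2[i]) + g) / max(abs(g), 1e-6))
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("the compiled trainer matches the R reference update over an epoch", {
  set.seed(7)
  X <- matrix(rbinom(40 * 5, 1, 0.4), 40, 5)
  y <- rbinom(40, 1, 0.5)
  cfg <- train_config(iterations = 1, shuffle = FALSE, n_hidden = 3,
                      alpha = 0.7, init_sd = 0.4)
  set.seed(11)
  fit <- nn_train(X, y, cfg)
  set.seed(11)
  m <- nn_model(5, 3, alpha = 0.7, init_sd = 0.4)
  for (i in seq_len(nrow(X))) m <- backprop_update(m, X[i, ], y[i])
  expect_equal(fit$model$W1, m$W1, tolerance = 1e-12)
  expect_equal(fit$model$w2, m$w2, tolerance = 1e-12)
})

test_that("training refuses single-class labels and alpha = 0 leaves weights fixed", {
  X <- matrix(rbinom(20 * 3, 1, 0.5), 20, 3)
  expect_error(nn_train(X, rep(1, 20), train_config()), class = "genevec_single_class")

  y <- rep(c(0, 1), 10)
  cfg <- train_config(iterations = 5, alpha = 0, n_hidden = 2, seed = 3)
  fit <- nn_train(X, y, cfg)
  set.seed(3)
  m0 <- nn_model(3, 2, alpha = 0, init_sd = cfg$init_sd)
  expect_equal(fit$model$W1, m0$W1)
  expect_equal(fit$model$w2, m0$w2)
})

test_that("a separable pattern is learned to full sensitivity and specificity", {
  set.seed(13)
  n <- 150
  x1 <- rbinom(n, 1, 0.3)
  X <- cbind(x1, matrix(rbinom(n * 3, 1, 0.3), n, 3))
  fit <- nn_train(X, x1, train_config(iterations = 2000, n_hidden = 4, seed = 17))
  res <- criterion_evaluate(fit$model, X, x1)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)
  expect_equal(res$constraint_accuracy, 1)
  expect_lte(fit$epochs, 2000)
})

test_that("criterion evaluation places the threshold just above the constraint class", {
  # a 1-1-1 net with identity-ish weights maps chosen inputs to chosen outputs
  m <- nn_model(1, 1)
  m$W1 <- matrix(c(1, 0), 1, 2)   # h = sig(x)
  m$w2 <- c(4, -2)                # out = sig(4 h - 2), range (0.12, 0.88)
  logit <- function(p) log(p / (1 - p))
  x_for <- function(out) logit(pmin(pmax((logit(out) + 2) / 4, 1e-6), 1 - 1e-6))
  outs <- c(0.2, 0.4, 0.3, 0.9) # negatives: 0.2, 0.4; positives: 0.3, 0.9
  X <- matrix(x_for(outs), ncol = 1)
  y <- c(0, 0, 1, 1)
  res <- criterion_evaluate(m, X, y)
  expect_equal(res$threshold, 0.4 + 1e-9, tolerance = 1e-6)
  expect_equal(res$sensitivity, 0.5)
  expect_equal(res$specificity, 1)
  expect_equal(res$fp, 0)
  expect_equal(res$constraint_accuracy, 1)

  # all outputs equal: nobody clears the threshold
  res2 <- criterion_evaluate(m, matrix(rep(0, 4), ncol = 1), y)
  expect_equal(res2$sensitivity, 0)
  expect_equal(res2$specificity, 1)

  # reverse constraint: every positive must be recognized
  res3 <- criterion_evaluate(m, X, y, constraint = "positive")
  expect_equal(res3$constraint_accuracy, 1)
  expect_equal(res3$sensitivity, 1)
  expect_equal(res3$fp, 1) # the 0.4 negative clears the permissive threshold
})

test_that("stratified folds partition the sample with near-equal sizes", {
  set.seed(19)
  y <- rep(c(0, 1), 10)
  fold <- genevec:::stratified_folds(y, 10)
  expect_equal(sort(unique(fold)), 1:10)
  expect_true(all(table(fold) == 2))
  expect_true(all(table(fold, y) == 1))
  expect_error(genevec:::stratified_folds(c(0, rep(1, 19)), 10),
               class = "genevec_stratification_error")
})

test_that("cross-validation pools fold counts and stays deterministic", {
  set.seed(23)
  n <- 120
  x1 <- rbinom(n, 1, 0.35)
  X <- cbind(x1, matrix(rbinom(n * 2, 1, 0.3), n, 2))
  y <- as.numeric(runif(n) < 0.15 + 0.7 * x1)
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  cfg <- train_config(iterations = 150, n_hidden = 3, k = 5, seed = 29)
  cv <- kfold_cv(X, y, cfg)
  expect_equal(sum(cv$folds$n_test), n)
  expect_equal(cv$pooled$tp, sum(cv$folds$tp))
  expect_equal(cv$pooled$fp, sum(cv$folds$fp))
  expect_equal(cv$pooled$tp + cv$pooled$fn, sum(y == 1))
  expect_equal(cv$pooled$constraint_accuracy, 1)
  cv2 <- kfold_cv(X, y, cfg)
  expect_equal(cv$pooled, cv2$pooled)
  expect_s3_class(glance(cv), "tbl_df")
  expect_equal(nrow(tidy(cv)), 5)
})

test_that("random-walk restarts pick the best criterion and stay reproducible", {
  set.seed(37)
  n <- 100
  x1 <- rbinom(n, 1, 0.3)
  X <- cbind(x1, matrix(rbinom(n * 2, 1, 0.3), n, 2))
  colnames(X) <- c("a", "b", "c")
  cfg <- train_config(iterations = 300, n_hidden = 3, k = 5, restarts = 3, seed = 41)
  s1 <- random_walk_search(X, x1, cfg)
  s2 <- random_walk_search(X, x1, cfg)
  expect_equal(s1$cv$pooled, s2$cv$pooled)
  expect_equal(s1$restart, s2$restart)
  expect_equal(nrow(s1$keys), 3)
  # separable toy: every restart reaches the same (perfect) criterion
  expect_true(all(abs(s1$keys[, "sensitivity"] - 1) < 1e-9))

  one <- random_walk_search(X, x1, utils::modifyList(cfg, list(restarts = 1L)))
  expect_equal(one$restart, 1)
})

test_that("cross-cohort overlap scores another cohort at the trained threshold", {
  co <- generate_cohort(tiny_config(seed = 43))
  gvm <- build_gene_vector_matrix(co$genotypes)
  y <- co$true_labels$responder[match(gvm$subjects, co$true_labels$subject_id)]
  feats <- one_hot_encode(gvm, gvm$genes$gene[1:3])
  cfg <- train_config(iterations = 100, k = 5, restarts = 1, seed = 47)
  search <- random_walk_search(feats, y, cfg)
  ov <- cross_cohort_overlap(search, gvm)
  expect_gte(ov, 0)
  expect_lte(ov, 1)
  # scoring only the training positives recovers 1 - training FN rate
  pos <- gvm$subjects[y == 1]
  gvm_pos <- genevec:::subset_gvm(gvm, pos)
  full_eval <- criterion_evaluate(search$model, feats, y)
  expect_equal(cross_cohort_overlap(search, gvm_pos), full_eval$sensitivity)
  expect_error(cross_cohort_overlap(search, make_gvm(matrix(1, 4, 1), genes = "ZZZ")))
})

test_that("split-half stability is near zero for a separable toy and deterministic", {
  set.seed(53)
  n <- 120
  x1 <- rbinom(n, 1, 0.4)
  X <- cbind(x1, matrix(rbinom(n, 1, 0.3), n, 1))
  cfg <- train_config(iterations = 400, n_hidden = 3, k = 5, seed = 59)
  st <- split_half_stability(X, x1, cfg, repeats = 4)
  expect_lt(abs(st$mean_drop), 0.1)
  st2 <- split_half_stability(X, x1, cfg, repeats = 4)
  expect_equal(st$per_repeat, st2$per_repeat)
  expect_error(split_half_stability(X[1:20, ], x1[1:20], cfg))
})

test_that("fold-honest screening keeps test folds untouched by gene discovery", {
  cfg <- cohort_config(
    n_f2 = 0, n_f3 = 240, n_genes = 12, seed = 61,
    response_genes = tibble::tibble(gene = sprintf("G%03d", 1:3),
                                    freq_responders = 0.5, freq_nonresponders = 0.03)
  )
  co <- generate_cohort(cfg)
  keep <- exclude_high_missing(co$genotypes)
  gvm <- build_gene_vector_matrix(subset_subjects(co$genotypes, keep))
  lab <- co$true_labels[co$true_labels$subject_id %in% keep, ]
  cv <- cv_with_screen(gvm, lab, config = train_config(iterations = 100, k = 5, seed = 67),
                       select = FALSE)
  expect_equal(length(cv$pool_sizes), 5)
  expect_equal(cv$pooled$tp + cv$pooled$fn, sum(lab$responder))
  expect_equal(cv$pooled$constraint_accuracy, 1)
})
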