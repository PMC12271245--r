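stratified_folds <- function(y, k) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < k) abort("n must be at least k")
  if (any(table(y) < 2)) {
    abort("a class would be absent from some training fold", class = "genevec_stratification_error")
  }
  fold <- integer(n)
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of the constrained network
#'
#' Splits the subjects into `k` stratified folds of near-equal size; each
#' fold serves once as the test partition while the network is trained on
#' the remaining `k - 1`.  The decision threshold is calibrated on the
#' training fold only (100% constraint-class accuracy there, by
#' construction) and test-fold predictions are pooled across folds.
#'
#' @inheritParams nn_train
#' @return An object of class `nn_cv`: `folds` (per-fold metric tibble),
#'   `pooled` (one-row tibble of pooled counts and rates), `config`.
#' @export
kfold_cv <- function(features, labels, config = train_config()) {
  X <- feature_X(features)
  y <- as.numeric(labels)
  if (!is.null(config$seed)) set.seed(config$seed)
  fold <- stratified_folds(y, config$k)
  inner <- config
  inner$seed <- NULL # folds share the ambient RNG stream
  n_restart <- max(1L, config$fold_restarts %||% 1L)
  rows <- vector("list", config$k)
  for (f in seq_len(config$k)) {
    tr <- fold != f
    Xtr <- X[tr, , drop = FALSE]
    ytr <- y[tr]
    # random-walk restarts within the fold, judged purely on the training
    # fold's own criterion (no test-fold information)
    best <- NULL
    for (r in seq_len(n_restart)) {
      fit <- nn_train(Xtr, ytr, inner)
      res_tr <- criterion_evaluate(fit$model, Xtr, ytr, constraint = config$constraint)
      key <- c(res_tr$constraint_accuracy, -res_tr$fp, res_tr$sensitivity)
      if (is.null(best) || key_better(key, best$key)) best <- list(fit = fit, key = key)
    }
    res <- criterion_evaluate(
      best$fit$model, X[!tr, , drop = FALSE], y[!tr],
      constraint = config$constraint,
      calibration = list(features = Xtr, labels = ytr)
    )
    rows[[f]] <- dplyr::mutate(tibble::as_tibble(res), fold = f, n_test = sum(!tr), .before = 1)
  }
  folds <- dplyr::bind_rows(rows)
  pooled <- tibble::tibble(
    tp = sum(folds$tp), fn = sum(folds$fn),
    fp = sum(folds$fp), tn = sum(folds$tn)
  ) |>
    dplyr::mutate(
      sensitivity = ifelse(.data$tp + .data$fn > 0, .data$tp / (.data$tp + .data$fn), NA_real_),
      specificity = ifelse(.data$fp + .data$tn > 0, .data$tn / (.data$fp + .data$tn), NA_real_),
      fp_rate = ifelse(.data$fp + .data$tn > 0, .data$fp / (.data$fp + .data$tn), NA_real_),
      correct = (.data$tp + .data$tn) / length(y),
      constraint_accuracy = min(folds$constraint_accuracy)
    )
  structure(list(folds = folds, pooled = pooled, config = config), class = "nn_cv")
}

#' @export
print.nn_cv <- function(x, ...) {
  p <- x$pooled
  cat(sprintf(
    "<nn_cv> %d-fold CV: pooled sensitivity %.3f, specificity %.3f, FP %d, training constraint accuracy %.3f\n",
    nrow(x$folds), p$sensitivity, p$specificity, p$fp, p$constraint_accuracy
  ))
  invisible(x)
}

#' @export
tidy.nn_cv <- function(x, ...) x$folds

#' @export
glance.nn_cv <- function(x, ...) x$pooled

# Lexicographic criterion key: higher is better.
criterion_key <- function(cv) {
  p <- cv$pooled
  c(p$constraint_accuracy, -p$fp, p$sensitivity)
}

key_better <- function(a, b, tol = 1e-12) {
  for (i in seq_along(a)) {
    if (a[i] > b[i] + tol) return(TRUE)
    if (a[i] < b[i] - tol) return(FALSE)
  }
  FALSE
}

#' Random-walk restarts
#'
#' Repeats cross-validated training from independent random initializations
#' and keeps the restart with the best lexicographic criterion value
#' (constraint-class accuracy, then fewest pooled false positives, then
#' highest sensitivity); ties go to the earliest restart.  A full-sample
#' model is then trained under the winning restart's stream and its
#' threshold calibrated on the full sample.
#'
#' @inheritParams nn_train
#' @return An object of class `nn_search`: `cv` (best restart's [kfold_cv()]
#'   result), `model`, `threshold`, `restart`, `keys` (matrix of restart
#'   criterion keys), `vocab` (when `features` is a [one_hot_encode()]
#'   result).
#' @export
random_walk_search <- function(features, labels, config = train_config()) {
  base_seed <- config$seed %||% sample.int(1e6, 1)
  best <- NULL
  keys <- matrix(NA_real_, nrow = config$restarts, ncol = 3,
                 dimnames = list(NULL, c("constraint", "neg_fp", "sensitivity")))
  for (r in seq_len(config$restarts)) {
    cfg <- config
    cfg$seed <- (base_seed + 7919 * r) %% .Machine$integer.max
    cv <- kfold_cv(features, labels, cfg)
    keys[r, ] <- criterion_key(cv)
    if (is.null(best) || key_better(keys[r, ], best$key)) {
      best <- list(cv = cv, key = keys[r, ], restart = r, seed = cfg$seed)
    }
  }
  cfg <- config
  cfg$seed <- best$seed + 1
  fit <- nn_train(features, labels, cfg)
  eval_full <- criterion_evaluate(fit$model, features, labels, constraint = config$constraint)
  structure(
    list(
      cv = best$cv, model = fit$model, threshold = eval_full$threshold,
      restart = best$restart, keys = keys,
      vocab = if (inherits(features, "feature_matrix")) features$vocab else NULL,
      config = config
    ),
    class = "nn_search"
  )
}

#' @export
print.nn_search <- function(x, ...) {
  cat(sprintf("<nn_search> best of %d restarts (restart %d)\n",
              nrow(x$keys), x$restart))
  print(x$cv)
  invisible(x)
}

#' Greedy classifier-gene selection with a stability rule
#'
#' Forward selection over the response-gene pool: starting from the empty
#' set, the gene whose addition most improves the pooled cross-validated
#' lexicographic criterion is added until no gene improves it.  The greedy
#' search is repeated from `restarts` independent initializations and a gene
#' is retained only when it is selected in at least `stability` of the
#' restarts, operationalizing construction under the constraint of
#' reproducibility.
#'
#' @param matrix A [build_gene_vector_matrix()] result.
#' @param pool Character vector of candidate (response) genes.
#' @param labels Logical outcome vector aligned with `matrix$subjects`.
#' @param config A [train_config()]; `config$restarts` greedy repetitions
#'   are run.
#' @param stability Minimum selection fraction across restarts; default 0.7.
#' @param min_count Passed to [one_hot_encode()].
#' @param max_genes Upper bound on the greedy subset size; default 6,
#'   matching the small classifier-gene sets the criterion favours.
#' @return A tibble of class `gene_selection`: `gene`, `times_selected`,
#'   `stability`, `selected`; attribute `runs` holds the per-restart sets.
#' @export
select_classifier_genes <- function(matrix, pool, labels,
                                    config = train_config(),
                                    stability = 0.7, min_count = 5,
                                    max_genes = 6) {
  if (!length(pool)) abort("gene pool is empty")
  features <- one_hot_encode(matrix, pool, min_count = min_count)
  base_seed <- config$seed %||% sample.int(1e6, 1)
  runs <- vector("list", config$restarts)
  for (r in seq_len(config$restarts)) {
    cfg <- config
    cfg$restarts <- 1L
    cfg$seed <- (base_seed + 104729 * r) %% .Machine$integer.max
    runs[[r]] <- greedy_select(features, labels, pool, cfg, max_genes = max_genes)
  }
  times <- vapply(pool, function(g) sum(vapply(runs, function(s) g %in% s, logical(1))), numeric(1))
  frac <- times / config$restarts
  is_stable <- frac >= stability
  out <- tibble::tibble(
    gene = pool,
    times_selected = as.integer(times),
    stability = frac,
    selected = is_stable
  )
  structure(out, class = c("gene_selection", class(out)), runs = runs)
}

# Subset-growth key: training constraint accuracy, then the pooled-CV
# sensitivity *excess* over the false-positive rate, then fewest false
# positives.  Under the max-over-constraint-class threshold a noise feature
# set classifies test subjects essentially at random, giving sensitivity
# close to its false-positive rate, while an informative set yields
# sensitivity well above it; the excess is therefore the signal the greedy
# growth can see, whereas raw sensitivity (or raw FP count) cannot
# distinguish signal from overfitting noise.  random_walk_search() keeps
# the plain (constraint, FP, sensitivity) order for restart selection.
selection_key <- function(cv) {
  p <- cv$pooled
  c(p$constraint_accuracy, p$sensitivity - p$fp_rate, -p$fp)
}

# A candidate gene must improve the incumbent key beyond these margins;
# differences inside the margins are treated as ties, which is what stops
# the greedy search from absorbing noise genes on cross-validation jitter.
key_improves <- function(a, b, margins = c(0.005, 0.02, 1.5)) {
  for (i in seq_along(a)) {
    if (a[i] > b[i] + margins[i]) return(TRUE)
    if (a[i] < b[i] - margins[i]) return(FALSE)
  }
  FALSE
}

# Per-gene stage-1 evidence: the largest absolute class-frequency contrast
# over the gene's one-hot pattern indicators.  Used to seed the greedy
# subset, because under the hard-constraint threshold no *single* gene can
# produce test sensitivity (its characteristic pattern also occurs among
# constraint-class subjects), leaving forward selection from the empty set
# without a gradient to follow.
screen_strength <- function(features, labels) {
  y <- as.numeric(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  contrast <- abs(colSums(features$X[y == 1, , drop = FALSE]) / n1 -
                    colSums(features$X[y == 0, , drop = FALSE]) / n0)
  tibble::tibble(gene = features$vocab$gene, contrast = contrast) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(strength = max(.data$contrast), .groups = "drop")
}

greedy_select <- function(features, labels, pool, config, max_genes = 6,
                          seed_size = 3) {
  # Seed the subset with the strongest stage-1 contrasts, computed on a
  # restart-specific 70% subsample: genuinely informative genes top the
  # ranking under any resampling, while under pure noise each restart seeds
  # differently and the cross-restart stability rule then discards them.
  set.seed(config$seed)
  y <- as.numeric(labels)
  sub <- sort(sample(length(y), round(0.7 * length(y))))
  fsub <- features
  fsub$X <- fsub$X[sub, , drop = FALSE]
  strength <- screen_strength(fsub, y[sub])
  strength <- strength[match(pool, strength$gene), ]
  selected <- pool[order(-strength$strength)][seq_len(min(seed_size, length(pool)))]
  eval_set <- function(genes, seed) {
    cols <- features$vocab$gene %in% genes
    cfg <- config
    cfg$seed <- seed
    cfg$fold_restarts <- 1L # candidate comparison is relative; one fit per fold
    selection_key(kfold_cv(features$X[, cols, drop = FALSE], labels, cfg))
  }
  step <- 0
  best_key <- eval_set(selected, (config$seed + 613 * step) %% .Machine$integer.max)
  repeat {
    remaining <- setdiff(pool, selected)
    if (!length(remaining) || length(selected) >= max_genes) break
    step <- step + 1
    # one shared seed per step: candidates are compared on identical folds
    # and initializations, so key differences reflect the features alone
    step_seed <- (config$seed + 613 * step) %% .Machine$integer.max
    cand_best <- NULL
    for (g in remaining) {
      key <- eval_set(c(selected, g), step_seed)
      if (is.null(cand_best) || key_better(key, cand_best$key)) {
        cand_best <- list(gene = g, key = key)
      }
    }
    if (!key_improves(cand_best$key, best_key)) break
    selected <- c(selected, cand_best$gene)
    best_key <- cand_best$key
  }
  # Honest final check: the greedy loop's key is an argmax-inflated
  # estimate, so the final subset is re-evaluated on fresh folds; a subset
  # whose mean sensitivity excess over the false-positive rate does not
  # clear chance level is no classifier and is discarded.
  honest <- vapply(1:3, function(r) {
    eval_set(selected, (config$seed + 7717 * r) %% .Machine$integer.max)
  }, numeric(3))
  if (min(honest[1, ]) < 1 - 1e-9 || mean(honest[2, ]) <= 0.035) return(character())
  selected
}

#' Cross-cohort classification overlap
#'
#' Applies a trained classifier (model, threshold and feature vocabulary) to
#' another cohort and reports the fraction classified positive — the overlap
#' of the other diagnosis group with the trained response profile.  Patterns
#' unseen during training map to the per-gene `OTHER` indicator.
#'
#' @param search An [random_walk_search()] result trained on
#'   [one_hot_encode()] features.
#' @param other_matrix The other cohort's [build_gene_vector_matrix()].
#' @return Fraction in `[0, 1]`.
#' @export
cross_cohort_overlap <- function(search, other_matrix) {
  if (is.null(search$vocab)) {
    abort("search carries no feature vocabulary; train on one_hot_encode() features")
  }
  genes <- unique(search$vocab$gene)
  absent <- setdiff(genes, other_matrix$genes$gene)
  if (length(absent)) {
    abort(paste0("other cohort lacks classifier genes: ", paste(absent, collapse = ", ")))
  }
  feats <- one_hot_encode(other_matrix, genes, vocab = search$vocab)
  out <- forward_outputs(search$model, feats$X)
  mean(out >= search$threshold)
}

#' Split-half stability of the classification rate
#'
#' Repeatedly splits the sample into stratified halves, trains and
#' calibrates on one half and evaluates the correctly-classified fraction on
#' the other, reporting the mean drop relative to the full-sample pooled
#' cross-validation rate.
#'
#' @inheritParams nn_train
#' @param repeats Number of random half-splits; default 20.
#' @return A list: `reference` (full-sample pooled CV correct fraction),
#'   `mean_drop`, `per_repeat` tibble.
#' @export
split_half_stability <- function(features, labels, config = train_config(),
                                 repeats = 20) {
  X <- feature_X(features)
  y <- as.numeric(labels)
  if (length(y) < 40) abort("split-half stability needs at least 40 subjects")
  if (!is.null(config$seed)) set.seed(config$seed)
  reference <- kfold_cv(X, y, utils::modifyList(config, list(seed = NULL)))$pooled$correct
  rows <- purrr::map_dfr(seq_len(repeats), function(r) {
    half <- stratified_folds(y, 2) == 1
    cfg <- utils::modifyList(config, list(seed = NULL))
    fit <- nn_train(X[half, , drop = FALSE], y[half], cfg)
    res <- criterion_evaluate(
      fit$model, X[!half, , drop = FALSE], y[!half],
      constraint = config$constraint,
      calibration = list(features = X[half, , drop = FALSE], labels = y[half])
    )
    tibble::tibble(repeat_id = r, correct = res$correct,
                   sensitivity = res$sensitivity, specificity = res$specificity)
  })
  list(
    reference = reference,
    mean_drop = reference - mean(rows$correct),
    per_repeat = rows
  )
}

#' Fold-honest screen + selection + cross-validation
#'
#' Leakage-controlled variant of the two-stage analysis: within each
#' cross-validation fold the response-gene screen (and optionally the greedy
#' gene selection) runs on the training subjects only, and the test fold is
#' scored with the fold's own vocabulary and threshold.  Folds whose screen
#' flags no gene predict nobody positive.  This is the pipeline the null
#' control runs on permuted labels.
#'
#' @param matrix A [build_gene_vector_matrix()] result.
#' @param labels Tibble with `subject_id` and a logical outcome column.
#' @param outcome Outcome column name; default `"responder"`.
#' @param config A [train_config()].
#' @param select Run greedy gene selection inside each fold (restarts = 1);
#'   default `TRUE`.
#' @param rarity,min_characteristic,min_count Screen parameters, as in
#'   [screen_cohort()].
#' @return An `nn_cv`-like list: `folds`, `pooled`, plus `pool_sizes`.
#' @export
cv_with_screen <- function(matrix, labels, outcome = "responder",
                           config = train_config(), select = TRUE,
                           rarity = 0.10, min_characteristic = 0.20,
                           min_count = 5) {
  lab <- labels[match(matrix$subjects, labels$subject_id), ]
  y <- as.numeric(lab[[outcome]])
  if (!is.null(config$seed)) set.seed(config$seed)
  fold <- stratified_folds(y, config$k)
  inner <- utils::modifyList(config, list(seed = NULL))
  rows <- vector("list", config$k)
  pool_sizes <- integer(config$k)
  subjects <- matrix$subjects
  for (f in seq_len(config$k)) {
    tr <- fold != f
    tr_matrix <- subset_gvm(matrix, subjects[tr])
    scr <- screen_cohort(tr_matrix, lab[tr, ], outcome = outcome,
                         rarity = rarity, min_characteristic = min_characteristic,
                         min_count = min_count)
    pool <- response_genes(scr)
    pool_sizes[f] <- length(pool)
    if (!length(pool)) {
      rows[[f]] <- tibble::tibble(
        fold = f, n_test = sum(!tr), threshold = NA_real_,
        tp = 0L, fn = sum(!tr & y == 1), fp = 0L, tn = sum(!tr & y == 0),
        sensitivity = 0, specificity = 1, fp_rate = 0,
        correct = mean(y[!tr] == 0), constraint_accuracy = 1
      )
      next
    }
    if (select && length(pool) > 1) {
      sel_cfg <- utils::modifyList(inner, list(restarts = 1L, seed = NULL))
      sel_cfg$seed <- sample.int(.Machine$integer.max - 1, 1)
      sel <- select_classifier_genes(tr_matrix, pool, y[tr], sel_cfg,
                                     stability = 0, min_count = min_count)
      chosen <- attr(sel, "runs")[[1]]
      if (length(chosen)) pool <- chosen
    }
    tr_feats <- one_hot_encode(tr_matrix, pool, min_count = min_count)
    te_feats <- one_hot_encode(subset_gvm(matrix, subjects[!tr]), pool,
                               vocab = tr_feats$vocab)
    fit <- nn_train(tr_feats, y[tr], inner)
    res <- criterion_evaluate(
      fit$model, te_feats, y[!tr], constraint = config$constraint,
      calibration = list(features = tr_feats, labels = y[tr])
    )
    rows[[f]] <- dplyr::mutate(tibble::as_tibble(res), fold = f, n_test = sum(!tr), .before = 1)
  }
  folds <- dplyr::bind_rows(rows)
  pooled <- tibble::tibble(
    tp = sum(folds$tp), fn = sum(folds$fn), fp = sum(folds$fp), tn = sum(folds$tn)
  ) |>
    dplyr::mutate(
      sensitivity = ifelse(.data$tp + .data$fn > 0, .data$tp / (.data$tp + .data$fn), NA_real_),
      specificity = ifelse(.data$fp + .data$tn > 0, .data$tn / (.data$fp + .data$tn), NA_real_),
      fp_rate = ifelse(.data$fp + .data$tn > 0, .data$fp / (.data$fp + .data$tn), NA_real_),
      correct = (.data$tp + .data$tn) / length(y),
      constraint_accuracy = min(folds$constraint_accuracy)
    )
  structure(list(folds = folds, pooled = pooled, config = config,
                 pool_sizes = pool_sizes),
            class = "nn_cv")
}

subset_gvm <- function(matrix, subjects) {
  idx <- match(subjects, matrix$subjects)
  if (anyNA(idx)) abort("unknown subjects in subset")
  structure(
    list(subjects = subjects, genes = matrix$genes,
         codes = matrix$codes[idx, , drop = FALSE]),
    class = "gene_vector_matrix"
  )
}
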