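#' One-hot pattern features for the network
#'
#' Expands gene-vector codes into binary pattern indicators: per gene, one
#' indicator for every pattern with at least `min_count` carriers plus one
#' `OTHER` indicator collecting the rarer patterns.  A missing gene vector
#' leaves the gene's whole block at zero, so per gene the block row sum is 1
#' for complete vectors and 0 for missing ones.
#'
#' @param matrix A [build_gene_vector_matrix()] result.
#' @param genes Character vector of genes to encode (e.g. the screened
#'   response genes).
#' @param min_count Minimum carrier count for a dedicated indicator.
#' @param vocab Optional feature vocabulary from a previous encoding (tibble
#'   `feature`, `gene`, `pattern`); codes absent from the vocabulary fall
#'   into the gene's `OTHER` indicator.  Used to align test folds and other
#'   cohorts with a trained model.
#' @return An object of class `feature_matrix`: binary matrix `X`
#'   (subjects x features), `vocab`, `subjects`.
#' @export
one_hot_encode <- function(matrix, genes, min_count = 5, vocab = NULL) {
  if (!length(genes)) abort("empty gene list")
  missing_genes <- setdiff(genes, matrix$genes$gene)
  if (length(missing_genes)) {
    abort(paste0("genes absent from matrix: ", paste(missing_genes, collapse = ", ")))
  }
  if (is.null(vocab)) {
    vocab <- purrr::map_dfr(genes, function(g) {
      codes <- gvm_gene_codes(matrix, g)
      cnt <- table(codes[!is.na(codes)])
      keep <- sort(as.numeric(names(cnt)[cnt >= min_count]))
      tibble::tibble(
        gene = g,
        pattern = c(keep, NA_real_) # NA = OTHER
      )
    })
    vocab$feature <- ifelse(
      is.na(vocab$pattern),
      paste0(vocab$gene, ":OTHER"),
      paste0(vocab$gene, ":", vocab$pattern)
    )
  } else {
    vocab <- tibble::as_tibble(vocab)
    bad <- setdiff(genes, unique(vocab$gene))
    if (length(bad)) abort(paste0("vocabulary lacks genes: ", paste(bad, collapse = ", ")))
    vocab <- vocab[vocab$gene %in% genes, ]
  }
  n <- length(matrix$subjects)
  X <- matrix(0, nrow = n, ncol = nrow(vocab),
              dimnames = list(matrix$subjects, vocab$feature))
  for (g in unique(vocab$gene)) {
    codes <- gvm_gene_codes(matrix, g)
    rows <- which(vocab$gene == g)
    listed <- vocab$pattern[rows]
    for (r in rows) {
      p <- vocab$pattern[r]
      if (is.na(p)) {
        X[, r] <- as.numeric(!is.na(codes) & !(codes %in% listed[!is.na(listed)]))
      } else {
        X[, r] <- as.numeric(!is.na(codes) & codes == p)
      }
    }
  }
  structure(list(X = X, vocab = vocab, subjects = matrix$subjects),
            class = "feature_matrix")
}

feature_X <- function(features) {
  if (inherits(features, "feature_matrix")) features$X else as.matrix(features)
}

#' Create an untrained network
#'
#' One hidden layer of logistic units and a single logistic output; weights
#' drawn from `N(0, init_sd)` using the current RNG stream.  Bias terms are
#' realized as weights to constant-1 units appended to the input and hidden
#' layers.
#'
#' @param n_in Number of input features.
#' @param n_hidden Number of hidden units.
#' @param alpha Learning rate (> 0).
#' @param init_sd Initial weight scale.
#' @return An object of class `nn_model` with weight matrices `W1`
#'   (`n_hidden x (n_in + 1)`) and `w2` (length `n_hidden + 1`).
#' @export
nn_model <- function(n_in, n_hidden, alpha = 0.5, init_sd = 0.5) {
  if (alpha < 0) abort("alpha must be non-negative")
  structure(
    list(
      W1 = matrix(rnorm(n_hidden * (n_in + 1), 0, init_sd), n_hidden, n_in + 1),
      w2 = rnorm(n_hidden + 1, 0, init_sd),
      n_in = as.integer(n_in), n_hidden = as.integer(n_hidden),
      alpha = alpha
    ),
    class = "nn_model"
  )
}

#' @export
print.nn_model <- function(x, ...) {
  cat(sprintf("<nn_model> %d-%d-1 logistic network (alpha = %g)\n",
              x$n_in, x$n_hidden, x$alpha))
  invisible(x)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Forward pass
#'
#' Computes the network activations for a single feature row: each hidden
#' unit is the logistic function of the weighted input sum, the output the
#' logistic function of the weighted hidden sum.
#'
#' @param model An [nn_model()].
#' @param x Numeric feature vector of length `n_in`.
#' @return A list: `output` (scalar in (0,1)) and `hidden` (length
#'   `n_hidden`).
#' @export
forward <- function(model, x) {
  if (length(x) != model$n_in) abort("feature length does not match the network input size")
  s_j <- sigmoid(as.numeric(model$W1 %*% c(x, 1)))
  s_i <- sigmoid(sum(model$w2 * c(s_j, 1)))
  list(output = s_i, hidden = s_j)
}

forward_outputs <- function(model, X) {
  H <- sigmoid(cbind(X, 1) %*% t(model$W1))
  as.numeric(sigmoid(cbind(H, 1) %*% model$w2))
}

#' Single-probe backpropagation update
#'
#' Applies the online gradient-descent update for one probe: the
#' output-side weights move by `alpha * eps * s_j * s_i (1 - s_i)` and the
#' hidden-side weights by
#' `alpha * eps * s_k * s_i (1 - s_i) * w_ij * s_j (1 - s_j)`, with
#' `eps = y - s_i` and both deltas evaluated at the pre-update weights.
#' This is steepest descent on half the squared error of the probe.  The
#' compiled trainer used by [nn_train()] performs exactly this update; this
#' R version is the reference implementation.
#'
#' @param model An [nn_model()].
#' @param x Feature vector of length `n_in`.
#' @param y Observed response in `{0, 1}`.
#' @param alpha Learning rate; defaults to the model's.
#' @return The updated `nn_model`.
#' @export
backprop_update <- function(model, x, y, alpha = model$alpha) {
  act <- forward(model, x)
  s_i <- act$output
  s_j <- act$hidden
  eps <- y - s_i
  d <- alpha * eps * s_i * (1 - s_i)
  x_aug <- c(x, 1)
  # hidden-layer delta uses the pre-update output weights
  w2_hidden <- model$w2[seq_len(model$n_hidden)]
  dW1 <- (d * w2_hidden * s_j * (1 - s_j)) %o% x_aug
  model$W1 <- model$W1 + dW1
  model$w2 <- model$w2 + d * c(s_j, 1)
  model
}

#' Training configuration
#'
#' @param iterations Epoch budget: one iteration is one full pass over all
#'   probes in shuffled order.
#' @param alpha Learning rate.
#' @param n_hidden Hidden-layer size; `NULL` sizes it from the feature set
#'   at training time (`min(2 * n_genes, 32)`).
#' @param window,tol Oscillation stop rule: training stops once the mean
#'   squared error over the trailing `window` epochs varies by less than
#'   `tol` (relative) without improving.
#' @param init_sd Initial weight scale.
#' @param shuffle Reshuffle probe order every epoch (the per-probe update
#'   rule implies online training); `FALSE` processes probes in storage
#'   order, used for reference comparisons.
#' @param k Cross-validation folds.
#' @param restarts Random-walk restarts (whole cross-validations) in
#'   [random_walk_search()].
#' @param fold_restarts Random-walk restarts *within* each training fold of
#'   [kfold_cv()]: the restart with the best training-fold criterion
#'   (constraint accuracy, fewest false positives, highest sensitivity,
#'   all in-sample) is kept before the test fold is scored.  Guards
#'   against poor local minima of the online training; default 3.
#' @param constraint `"negative"` (all constraint-class subjects, e.g.
#'   non-responders, must be classified correctly) or `"positive"` for the
#'   reverse direction.
#' @param seed Optional integer seed for fold assignment, weight
#'   initialization and shuffling.
#' @return A list of class `train_config`.
#' @export
train_config <- function(iterations = 300, alpha = 0.5, n_hidden = NULL,
                         window = 25, tol = 1e-4, init_sd = 0.5,
                         shuffle = TRUE, k = 10, restarts = 5,
                         fold_restarts = 3,
                         constraint = c("negative", "positive"),
                         seed = NULL) {
  if (iterations < 1) abort("iteration budget must be >= 1")
  if (k < 2) abort("k must be >= 2")
  structure(
    list(
      iterations = as.integer(iterations), alpha = alpha, n_hidden = n_hidden,
      window = as.integer(window), tol = tol, init_sd = init_sd,
      shuffle = shuffle, k = as.integer(k), restarts = as.integer(restarts),
      fold_restarts = as.integer(fold_restarts),
      constraint = match.arg(constraint), seed = seed
    ),
    class = "train_config"
  )
}

default_hidden <- function(features) {
  n_genes <- if (inherits(features, "feature_matrix")) {
    dplyr::n_distinct(features$vocab$gene)
  } else {
    max(1, ncol(feature_X(features)) %/% 4)
  }
  min(2 * n_genes, 32)
}

#' Train the network
#'
#' Online backpropagation over shuffled probes, stopping at the epoch budget
#' or when the error begins to oscillate without further improvement (the
#' steady-state rule).  Deterministic under a fixed seed.
#'
#' @param features A [one_hot_encode()] result or binary feature matrix.
#' @param labels Logical (or 0/1) outcome vector aligned with the feature
#'   rows.
#' @param config A [train_config()].
#' @return A list of class `nn_fit`: `model` (trained [nn_model()]),
#'   `history` (per-epoch mean squared error), `epochs`.
#' @export
nn_train <- function(features, labels, config = train_config()) {
  X <- feature_X(features)
  y <- as.numeric(labels)
  if (length(y) != nrow(X)) abort("labels length must match feature rows")
  if (dplyr::n_distinct(y) < 2) abort("training requires both classes", class = "genevec_single_class")
  if (!is.null(config$seed)) set.seed(config$seed)
  n_hidden <- config$n_hidden %||% default_hidden(features)
  model <- nn_model(ncol(X), n_hidden, alpha = config$alpha, init_sd = config$init_sd)
  fit <- nn_train_cpp(
    cbind(X, 1), y, model$W1, model$w2,
    alpha = config$alpha, max_epochs = config$iterations,
    window = config$window, tol = config$tol, shuffle = config$shuffle
  )
  model$W1 <- fit$W1
  model$w2 <- as.numeric(fit$w2)
  structure(list(model = model, history = as.numeric(fit$mse), epochs = fit$epochs),
            class = "nn_fit")
}

#' Constraint-based evaluation
#'
#' Operationalizes the training criterion: the decision threshold is placed
#' just beyond the most extreme output of the constraint class on the
#' calibration set (by default the evaluation set itself), guaranteeing 100%
#' constraint-class accuracy there; sensitivity and false-positive counts
#' are then reported on the evaluation data.
#'
#' @param model A trained [nn_model()] (or `nn_fit`).
#' @param features Evaluation features ([one_hot_encode()] result or
#'   matrix).
#' @param labels Evaluation outcomes (logical or 0/1).
#' @param constraint `"negative"` (default): all class-0 calibration
#'   subjects fall below the threshold; `"positive"`: all class-1 subjects
#'   fall above it.
#' @param calibration Optional list `(features, labels)` used for threshold
#'   calibration (e.g. the training fold); defaults to the evaluation data.
#' @return A one-row tibble of class `criterion_result`: `threshold`,
#'   `tp`, `fn`, `fp`, `tn`, `sensitivity`, `specificity`, `fp_rate`,
#'   `correct`, `constraint_accuracy` (on the calibration set).
#' @export
criterion_evaluate <- function(model, features, labels,
                               constraint = c("negative", "positive"),
                               calibration = NULL) {
  constraint <- match.arg(constraint)
  if (inherits(model, "nn_fit")) model <- model$model
  X <- feature_X(features)
  y <- as.numeric(labels)
  if (is.null(calibration)) calibration <- list(features = features, labels = labels)
  y_cal <- as.numeric(calibration$labels)
  out_cal <- forward_outputs(model, feature_X(calibration$features))
  delta <- 1e-9
  if (constraint == "negative") {
    if (!any(y_cal == 0)) abort("constraint class (negatives) empty in calibration data")
    threshold <- max(out_cal[y_cal == 0]) + delta
  } else {
    if (!any(y_cal == 1)) abort("constraint class (positives) empty in calibration data")
    threshold <- min(out_cal[y_cal == 1]) - delta
  }
  pred_cal <- out_cal >= threshold
  constraint_accuracy <- if (constraint == "negative") {
    mean(!pred_cal[y_cal == 0])
  } else {
    mean(pred_cal[y_cal == 1])
  }
  out <- forward_outputs(model, X)
  pred <- out >= threshold
  tp <- sum(pred & y == 1)
  fn <- sum(!pred & y == 1)
  fp <- sum(pred & y == 0)
  tn <- sum(!pred & y == 0)
  res <- tibble::tibble(
    threshold = threshold, tp = tp, fn = fn, fp = fp, tn = tn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (fp + tn > 0) tn / (fp + tn) else NA_real_,
    fp_rate = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
    correct = (tp + tn) / length(y),
    constraint_accuracy = constraint_accuracy
  )
  class(res) <- c("criterion_result", class(res))
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
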