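#' Synthetic-cohort configuration
#'
#' Parameters of the synthetic genotype-phenotype cohort generator.  The
#' defaults emulate the structure of the two-diagnosis inpatient study the
#' package's analysis pipeline targets: 264 schizophrenic (F2) and 638
#' depressive (F3) subjects, 100 candidate genes of 4-8 SNPs each,
#' within-gene SNP dependence that suppresses pattern diversity to roughly a
#' third of the independence expectation, cross-gene pattern co-occurrence,
#' planted response genes whose characteristic patterns are rare (5%) among
#' non-responders, trigger-model score trajectories over 42 days with 8
#' scheduled assessments, ~2% missing genotypes with a tail of high-missing
#' subjects, and ~26% elevated-IgM prevalence.
#'
#' @param n_f2,n_f3 Subjects per diagnosis group.
#' @param n_genes Number of candidate genes.
#' @param snps_per_gene Integer range (length 2) of SNPs per gene, within
#'   `[2, 15]`.
#' @param allele_freq_range Range the per-SNP minor-ish allele frequency is
#'   drawn from, inside `(0, 1)`.
#' @param within_gene_ld Equicorrelation of the latent Gaussian copula that
#'   couples a gene's SNPs before discretization to genotypes; 0 gives
#'   independent Hardy-Weinberg SNPs.
#' @param cross_gene_link Tibble (`geneA`, `geneB`, `strength`) of linked
#'   gene pairs: with probability `strength` a subject's pattern of `geneB`
#'   is deterministically derived from its `geneA` pattern.  `NULL` (default)
#'   links 16 disjoint pairs among the non-response genes at strength 0.3.
#' @param response_genes Tibble (`gene`, `freq_responders`,
#'   `freq_nonresponders`) of planted response genes.  Default: 10 genes with
#'   a characteristic pattern at frequency 0.30 in responders and 0.05 in
#'   non-responders.
#' @param responder_fraction Fraction of responders per diagnosis.
#' @param stuck_fraction Fraction, among non-responders, that improves
#'   partially and then plateaus ("stuck").
#' @param early_improver_fraction Fraction of improving subjects whose
#'   improvement is triggered within the first days (yielding onset within
#'   two weeks).
#' @param missing_rate Baseline genotype missingness.
#' @param high_missing_subject_fraction Fraction of subjects given an extra,
#'   elevated missing rate (beyond the 5% analysis cutoff).
#' @param trajectory List of trajectory-model parameters: `n_visits`,
#'   `horizon_days`, `early_trigger_days` / `late_trigger_days` (ranges the
#'   trigger day is drawn from), `decline_days` (range of the post-trigger
#'   decline duration), `responder_reduction` (range of the final fractional
#'   reduction for responders), `stuck_shed` (range of the fraction of
#'   baseline shed before a stuck subject plateaus), `noise_sd` (visit noise,
#'   scale points), `nonimprover_drift` (points/day drift for non-improvers).
#' @param igm List: `prevalence` (marginal elevated-IgM fraction), `genes`
#'   (associated gene ids), `strength` (relative-risk increment for carriers
#'   of the associated patterns; 0 = no association).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration including the seed.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_f2 = 264, n_f3 = 638, n_genes = 100,
                          snps_per_gene = c(4L, 8L),
                          allele_freq_range = c(0.10, 0.50),
                          within_gene_ld = 0.86,
                          cross_gene_link = NULL,
                          response_genes = NULL,
                          responder_fraction = 0.30,
                          stuck_fraction = 0.45,
                          early_improver_fraction = 0.60,
                          missing_rate = 0.02,
                          high_missing_subject_fraction = 0.15,
                          trajectory = list(),
                          igm = list(),
                          seed = 1L) {
  gene_ids <- sprintf("G%03d", seq_len(n_genes))
  if (is.null(response_genes)) {
    k <- min(10L, n_genes)
    response_genes <- tibble::tibble(
      gene = gene_ids[seq_len(k)],
      freq_responders = 0.30,
      freq_nonresponders = 0.05
    )
  } else {
    response_genes <- tibble::as_tibble(response_genes)
  }
  if (is.null(cross_gene_link)) {
    pool <- setdiff(gene_ids, response_genes$gene)
    n_pairs <- min(16L, length(pool) %/% 2)
    cross_gene_link <- tibble::tibble(
      geneA = pool[2 * seq_len(n_pairs) - 1],
      geneB = pool[2 * seq_len(n_pairs)],
      strength = 0.3
    )
  } else {
    cross_gene_link <- tibble::as_tibble(cross_gene_link)
  }
  traj_defaults <- list(
    n_visits = 8L, horizon_days = 42L,
    early_trigger_days = c(1L, 8L), late_trigger_days = c(15L, 28L),
    decline_days = c(10, 25), responder_reduction = c(0.55, 0.85),
    stuck_shed = c(0.20, 0.50), noise_sd = 1.0, nonimprover_drift = 0
  )
  trajectory <- utils::modifyList(traj_defaults, trajectory)
  igm_defaults <- list(
    prevalence = 0.26,
    genes = head(response_genes$gene, 3),
    strength = 2
  )
  igm <- utils::modifyList(igm_defaults, igm)

  cfg <- list(
    n_f2 = as.integer(n_f2), n_f3 = as.integer(n_f3),
    n_genes = as.integer(n_genes), gene_ids = gene_ids,
    snps_per_gene = as.integer(snps_per_gene),
    allele_freq_range = allele_freq_range,
    within_gene_ld = within_gene_ld,
    cross_gene_link = cross_gene_link,
    response_genes = response_genes,
    responder_fraction = responder_fraction,
    stuck_fraction = stuck_fraction,
    early_improver_fraction = early_improver_fraction,
    missing_rate = missing_rate,
    high_missing_subject_fraction = high_missing_subject_fraction,
    trajectory = trajectory,
    igm = igm,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  fr <- c(
    cfg$responder_fraction, cfg$stuck_fraction, cfg$early_improver_fraction,
    cfg$missing_rate, cfg$high_missing_subject_fraction, cfg$igm$prevalence,
    cfg$response_genes$freq_responders, cfg$response_genes$freq_nonresponders,
    cfg$cross_gene_link$strength
  )
  if (any(fr < 0 | fr > 1)) abort("all fractions must lie in [0, 1]", class = "genevec_config_error")
  if (cfg$n_f2 < 0 || cfg$n_f3 < 0 || cfg$n_genes < 1) abort("invalid cohort sizes", class = "genevec_config_error")
  if (length(cfg$snps_per_gene) != 2 || any(cfg$snps_per_gene < 2) || any(cfg$snps_per_gene > 15) ||
      cfg$snps_per_gene[1] > cfg$snps_per_gene[2]) {
    abort("snps_per_gene must be an increasing range within [2, 15]", class = "genevec_config_error")
  }
  if (any(cfg$allele_freq_range <= 0) || any(cfg$allele_freq_range >= 1) ||
      cfg$allele_freq_range[1] > cfg$allele_freq_range[2]) {
    abort("allele_freq_range must lie strictly inside (0, 1)", class = "genevec_config_error")
  }
  if (cfg$within_gene_ld < 0 || cfg$within_gene_ld > 1) {
    abort("within_gene_ld must lie in [0, 1]", class = "genevec_config_error")
  }
  if (cfg$trajectory$n_visits < 3) abort("at least 3 visits required", class = "genevec_config_error")
  if (cfg$trajectory$horizon_days < 14) {
    abort("horizon below 14 days leaves the early-improvement window undefined",
          class = "genevec_config_error")
  }
  bad <- setdiff(c(cfg$response_genes$gene, cfg$cross_gene_link$geneA,
                   cfg$cross_gene_link$geneB, cfg$igm$genes), cfg$gene_ids)
  if (length(bad)) {
    abort(paste0("unknown gene ids in config: ", paste(bad, collapse = ", ")),
          class = "genevec_config_error")
  }
  invisible(cfg)
}

subject_ids <- function(cfg) {
  n <- cfg$n_f2 + cfg$n_f3
  if (n == 0) character() else sprintf("S%04d", seq_len(n))
}

subject_diagnoses <- function(cfg) {
  c(rep("F2", cfg$n_f2), rep("F3", cfg$n_f3))
}

#' Simulate a genotype table
#'
#' Draws per-SNP genotypes from Hardy-Weinberg proportions at a sampled
#' allele frequency.  Within-gene dependence is induced by an equicorrelated
#' latent Gaussian copula (`within_gene_ld`) thresholded at the HWE genotype
#' quantiles; cross-gene linkage copies a deterministic transform of the
#' source gene's pattern into the linked gene with the configured
#' probability.
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A [genotype_table()].
#' @export
simulate_genotypes <- function(config, seed = NULL) {
  validate_cohort_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_f2 + config$n_f3
  rng <- config$snps_per_gene
  m_per_gene <- sample(seq(rng[1], rng[2]), config$n_genes, replace = TRUE)
  chrom <- sample(1:22, config$n_genes, replace = TRUE)
  snp_info <- purrr::map_dfr(seq_len(config$n_genes), function(g) {
    start <- sample.int(2e8, 1)
    tibble::tibble(
      snp_id = sprintf("%s_snp%02d", config$gene_ids[g], seq_len(m_per_gene[g])),
      gene = config$gene_ids[g],
      chrom = chrom[g],
      pos = start + cumsum(sample(500:5000, m_per_gene[g], replace = TRUE))
    )
  })
  geno <- matrix(NA_integer_, nrow = n, ncol = nrow(snp_info))
  colnames(geno) <- snp_info$snp_id
  rho <- config$within_gene_ld
  col0 <- 0L
  for (g in seq_len(config$n_genes)) {
    m <- m_per_gene[g]
    q <- runif(m, config$allele_freq_range[1], config$allele_freq_range[2])
    p0 <- (1 - q)^2
    p1 <- 2 * q * (1 - q)
    if (n > 0) {
      u_common <- rnorm(n)
      z <- sqrt(rho) * matrix(u_common, n, m) + sqrt(1 - rho) * matrix(rnorm(n * m), n, m)
      u <- pnorm(z)
      gg <- (u > matrix(p0, n, m, byrow = TRUE)) + (u > matrix(p0 + p1, n, m, byrow = TRUE))
      geno[, col0 + seq_len(m)] <- gg
    }
    col0 <- col0 + m
  }
  tab <- genotype_table(geno, snp_info)
  if (n > 0) rownames(tab$geno) <- tab$subjects <- subject_ids(config)
  apply_cross_gene_links(tab, config)
}

apply_cross_gene_links <- function(tab, config) {
  links <- config$cross_gene_link
  if (is.null(links) || !nrow(links) || !length(tab$subjects)) return(tab)
  defs <- gene_definitions(tab)
  for (i in seq_len(nrow(links))) {
    a <- defs[defs$gene == links$geneA[i], ]
    b <- defs[defs$gene == links$geneB[i], ]
    sel <- which(runif(length(tab$subjects)) < links$strength[i])
    if (!length(sel)) next
    ga <- tab$geno[sel, a$snp_ids[[1]], drop = FALSE]
    codes <- as.numeric(ga %*% 3^(seq_len(a$m) - 1))
    for (j in seq_along(sel)) {
      if (is.na(codes[j])) next
      tab$geno[sel[j], b$snp_ids[[1]]] <-
        decode_gene_vector(codes[j] %% 3^b$m, b$m)
    }
  }
  tab
}

#' Plant response-characteristic patterns
#'
#' For each configured response gene, one designated multi-SNP pattern is
#' written into a random subset of responders and non-responders at the
#' configured frequencies (all other genotypes untouched), creating genes
#' whose patterns are characteristic of one outcome class and rare in the
#' other.
#'
#' @param table A [genotype_table()].
#' @param config A [cohort_config()].
#' @param labels Tibble with `subject_id` and logical `responder`.
#' @param seed Optional integer seed.
#' @return A list: `table` (modified genotypes) and `truth` (tibble `gene`,
#'   `pattern`, `freq_responders`, `freq_nonresponders`).
#' @export
plant_response_patterns <- function(table, config, labels, seed = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  if (!is.null(seed)) set.seed(seed)
  rg <- config$response_genes
  defs <- gene_definitions(table)
  bad <- setdiff(rg$gene, defs$gene)
  if (length(bad)) abort(paste0("unknown response gene: ", paste(bad, collapse = ", ")))
  resp_ids <- labels$subject_id[labels$responder]
  nonresp_ids <- labels$subject_id[!labels$responder]
  truth <- tibble::tibble(
    gene = character(), pattern = numeric(),
    freq_responders = numeric(), freq_nonresponders = numeric()
  )
  for (i in seq_len(nrow(rg))) {
    def <- defs[defs$gene == rg$gene[i], ]
    # the designated pattern must be naturally rare, otherwise background
    # carriers dilute the configured responder/non-responder contrast
    codes_now <- as.numeric(table$geno[, def$snp_ids[[1]], drop = FALSE] %*%
                              3^(seq_len(def$m) - 1))
    digits <- sample(0:2, def$m, replace = TRUE)
    for (try in seq_len(50)) {
      cand <- sample(0:2, def$m, replace = TRUE)
      f_nat <- mean(codes_now == encode_gene_vector(cand), na.rm = TRUE)
      if (is.nan(f_nat) || f_nat <= 0.02) {
        digits <- cand
        break
      }
    }
    code <- encode_gene_vector(digits)
    sel_r <- resp_ids[runif(length(resp_ids)) < rg$freq_responders[i]]
    sel_n <- nonresp_ids[runif(length(nonresp_ids)) < rg$freq_nonresponders[i]]
    sel <- c(sel_r, sel_n)
    if (length(sel)) {
      table$geno[sel, def$snp_ids[[1]]] <-
        matrix(digits, nrow = length(sel), ncol = def$m, byrow = TRUE)
    }
    truth <- dplyr::bind_rows(truth, tibble::tibble(
      gene = rg$gene[i], pattern = code,
      freq_responders = rg$freq_responders[i],
      freq_nonresponders = rg$freq_nonresponders[i]
    ))
  }
  list(table = table, truth = truth)
}

rtrunc_norm <- function(n, mean, sd, lower) {
  u <- runif(n, pnorm((lower - mean) / sd), 1)
  mean + sd * qnorm(u)
}

baseline_params <- function(diagnosis, scale) {
  # calibrated so mild/moderate/severe proportions match the study text
  if (scale == "HAM-D17") list(mean = 22.7, sd = 3.9, lower = 15)
  else if (scale == "PANSS-G") list(mean = 42.9, sd = 8.7, lower = 21)
  else list(mean = 22, sd = 5, lower = 10) # PANSS-P
}

#' Simulate clinical score trajectories
#'
#' Trigger-model trajectories over the 8-visit/42-day schedule: the baseline
#' is drawn from a diagnosis-calibrated truncated normal above the inclusion
#' threshold; improving subjects receive a trigger day (early or late) after
#' which the score declines linearly to a class-specific plateau (responders
#' shed 55-85% of baseline, "stuck" subjects 20-50%); non-improvers never
#' trigger and drift at the configured rate.  I.i.d. Gaussian visit noise is
#' added after baseline and scores are rounded to integer scale points.
#'
#' @param labels Tibble with `subject_id`, `diagnosis`, `class`
#'   (`"responder"`, `"stuck"` or `"non_improver"`) and logical `early`.
#' @param config A [cohort_config()].
#' @param seed Optional integer seed.
#' @return A trajectory tibble (`subject_id`, `diagnosis`, `scale`, `day`,
#'   `score`); F2 subjects carry PANSS-G and PANSS-P records, F3 subjects
#'   HAM-D17.
#' @export
simulate_trajectories <- function(labels, config, seed = NULL) {
  validate_cohort_config(config)
  if (!is.null(seed)) set.seed(seed)
  tp <- config$trajectory
  days <- visit_schedule()
  days <- head(days[days <= tp$horizon_days], tp$n_visits)
  out <- vector("list", nrow(labels) * 2)
  k <- 0
  for (i in seq_len(nrow(labels))) {
    diagnosis <- labels$diagnosis[i]
    cls <- labels$class[i]
    early <- labels$early[i]
    rs <- response_scale(diagnosis)
    bp <- baseline_params(diagnosis, rs)
    baseline <- round(rtrunc_norm(1, bp$mean, bp$sd, bp$lower))
    if (cls == "non_improver") {
      mu <- baseline + tp$nonimprover_drift * days
    } else {
      trig <- if (early) {
        sample(seq(tp$early_trigger_days[1], tp$early_trigger_days[2]), 1)
      } else {
        sample(seq(tp$late_trigger_days[1], tp$late_trigger_days[2]), 1)
      }
      r_target <- if (cls == "responder") {
        runif(1, tp$responder_reduction[1], tp$responder_reduction[2])
      } else {
        runif(1, tp$stuck_shed[1], tp$stuck_shed[2])
      }
      dur <- runif(1, tp$decline_days[1], tp$decline_days[2])
      slope <- baseline * r_target / dur
      mu <- pmax(baseline * (1 - r_target), baseline - pmax(0, days - trig) * slope)
    }
    score <- round(mu + c(0, rnorm(length(days) - 1, 0, tp$noise_sd)))
    score <- pmax(score, 0)
    score[1] <- baseline
    k <- k + 1
    out[[k]] <- tibble::tibble(
      subject_id = labels$subject_id[i], diagnosis = diagnosis,
      scale = rs, day = days, score = score
    )
    if (diagnosis == "F2") {
      bpg <- baseline_params(diagnosis, "PANSS-G")
      bg <- round(rtrunc_norm(1, bpg$mean, bpg$sd, bpg$lower))
      sg <- round(bg + c(0, rnorm(length(days) - 1, 0, tp$noise_sd)))
      k <- k + 1
      out[[k]] <- tibble::tibble(
        subject_id = labels$subject_id[i], diagnosis = diagnosis,
        scale = "PANSS-G", day = days, score = pmax(sg, 0)
      )
    }
  }
  dplyr::bind_rows(out[seq_len(k)])
}

#' Mask genotypes at random
#'
#' Applies uniform missingness at `missing_rate` and gives a designated
#' fraction of subjects an additional, elevated missing rate so that they
#' exceed the 5% analysis cutoff.
#'
#' @param table A [genotype_table()].
#' @param config A [cohort_config()].
#' @param seed Optional integer seed.
#' @return The masked [genotype_table()].
#' @export
apply_missingness <- function(table, config, seed = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(table$geno)
  p <- ncol(table$geno)
  if (n == 0 || config$missing_rate < 0) return(table)
  if (config$missing_rate > 0) {
    mask <- matrix(runif(n * p) < config$missing_rate, n, p)
    table$geno[mask] <- NA_integer_
  }
  n_high <- round(config$high_missing_subject_fraction * n)
  if (n_high > 0) {
    rows <- sample.int(n, n_high)
    extra <- runif(n_high, 0.06, 0.15)
    for (j in seq_along(rows)) {
      mask <- runif(p) < extra[j]
      table$geno[rows[j], mask] <- NA_integer_
    }
  }
  table
}

#' Simulate elevated-IgM flags
#'
#' Carriers of the designated patterns in the IgM-associated genes receive a
#' relative risk of `1 + strength` for chronically elevated IgM, with the
#' non-carrier probability solved so that the marginal prevalence matches
#' the configured value.
#'
#' @param table A [genotype_table()].
#' @param config A [cohort_config()].
#' @param truth Optional planted-pattern tibble from
#'   [plant_response_patterns()]; associated genes not listed there use their
#'   modal observed pattern as the designated one.
#' @param seed Optional integer seed.
#' @return Tibble with `subject_id` and logical `igm_elevated`.
#' @export
simulate_igm <- function(table, config, truth = NULL, seed = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(table$subjects)
  prev <- config$igm$prevalence
  if (n == 0 || prev == 0) {
    return(tibble::tibble(subject_id = table$subjects, igm_elevated = logical(n)))
  }
  defs <- gene_definitions(table)
  bad <- setdiff(config$igm$genes, defs$gene)
  if (length(bad)) abort(paste0("IgM-associated gene absent: ", paste(bad, collapse = ", ")))
  gvm <- build_gene_vector_matrix(table, defs[defs$gene %in% config$igm$genes, ])
  carrier <- rep(FALSE, n)
  for (g in gvm$genes$gene) {
    codes <- gvm_gene_codes(gvm, g)
    designated <- if (!is.null(truth) && g %in% truth$gene) {
      truth$pattern[truth$gene == g][1]
    } else {
      tab <- table(codes)
      as.numeric(names(tab)[which.max(tab)])
    }
    carrier <- carrier | (!is.na(codes) & codes == designated)
  }
  f_c <- mean(carrier)
  rr <- 1 + config$igm$strength
  p_nc <- min(1, prev / (1 + f_c * (rr - 1)))
  p_c <- min(1, rr * p_nc)
  prob <- ifelse(carrier, p_c, p_nc)
  tibble::tibble(
    subject_id = table$subjects,
    igm_elevated = runif(n) < prob
  )
}

#' Generate a complete synthetic cohort
#'
#' Composes genotype simulation, response-pattern planting, trajectory
#' simulation, missingness and IgM flags into one deterministic cohort:
#' identical configurations (including the seed) give identical cohorts.
#'
#' @param config A [cohort_config()].
#' @return An object of class `synthetic_cohort`: `genotypes`
#'   ([genotype_table()]), `genes` ([gene_definitions()] tibble),
#'   `trajectories` (tibble), `true_labels` (tibble with the generative
#'   class, responder/early flags and IgM flag), `truth` (planted response
#'   patterns) and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  ids <- subject_ids(config)
  diagnosis <- subject_diagnoses(config)
  n <- length(ids)
  is_resp <- runif(n) < config$responder_fraction
  is_stuck <- !is_resp & runif(n) < config$stuck_fraction
  cls <- ifelse(is_resp, "responder", ifelse(is_stuck, "stuck", "non_improver"))
  early <- cls != "non_improver" & runif(n) < config$early_improver_fraction
  true_labels <- tibble::tibble(
    subject_id = ids, diagnosis = diagnosis, class = cls,
    responder = is_resp, early = early
  )
  tab <- simulate_genotypes(config)
  planted <- plant_response_patterns(tab, config, true_labels)
  traj <- simulate_trajectories(true_labels, config)
  tab <- apply_missingness(planted$table, config)
  igm <- simulate_igm(tab, config, planted$truth)
  true_labels <- dplyr::left_join(true_labels, igm, by = "subject_id")
  structure(
    list(
      genotypes = tab,
      genes = gene_definitions(tab),
      trajectories = traj,
      true_labels = true_labels,
      truth = planted$truth,
      config = config
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d subjects (%d F2, %d F3), %d genes, %d SNPs, %d planted response genes\n",
    length(x$genotypes$subjects), x$config$n_f2, x$config$n_f3,
    nrow(x$genes), ncol(x$genotypes$geno), nrow(x$truth)
  ))
  invisible(x)
}
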