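# Synthetic cohorts with planted brain-behavior structure.
#
# The behavioral score is right-skewed on the clinical range (scaled Beta via
# a Gaussian copula); planted edges couple to the score's latent Gaussian so
# the target rank correlation is hit exactly in expectation:
# Spearman rho_s of a bivariate normal with Pearson r is (6/pi)*asin(r/2),
# hence r = 2*sin(pi*rho_s/6) and beta = noise_sd * r / sqrt(1 - r^2).

.spearman_to_pearson <- function(rho) 2 * sin(pi * rho / 6)

#' Simulation configuration for synthetic cohorts
#'
#' Holds every knob of the synthetic cohort generator. Defaults emulate a
#' drug-naive Parkinson's training cohort: 47 subjects, a 268-node
#' parcellation,
#' 57 positive and 58 negative severity-coupled connections, a right-skewed
#' severity score on 4-68, and covariates whose rank correlations with the
#' score are about .40 (age) and .53 (disease duration).
#'
#' @param n_subjects Number of subjects.
#' @param n_nodes Number of atlas nodes.
#' @param n_planted_positive,n_planted_negative Numbers of edges whose
#'   strength increases / decreases with the score.
#' @param effect_size Target rank-correlation magnitude between each planted
#'   edge's strength and the score, in `[0, 1)`.
#' @param noise_sd Edge noise standard deviation on the Fisher-z scale (> 0).
#' @param score_range Two numbers, the score's attainable range.
#' @param score_shape Beta shape parameters of the score distribution;
#'   the default `c(2, 5)` is right-skewed.
#' @param covariate_effects Named numeric vector of target rank correlations
#'   between covariates and the score; names `age` and `duration` get
#'   realistic units, other names are kept as standardized columns.
#' @param seed Integer seed; identical seeds reproduce identical cohorts.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 47L, n_nodes = 268L,
                       n_planted_positive = 57L, n_planted_negative = 58L,
                       effect_size = 0.6, noise_sd = 0.1,
                       score_range = c(4, 68), score_shape = c(2, 5),
                       covariate_effects = c(age = 0.404, duration = 0.527),
                       seed = 1L) {
  cfg <- list(n_subjects = n_subjects, n_nodes = n_nodes,
              n_planted_positive = n_planted_positive,
              n_planted_negative = n_planted_negative,
              effect_size = effect_size, noise_sd = noise_sd,
              score_range = as.numeric(score_range),
              score_shape = as.numeric(score_shape),
              covariate_effects = covariate_effects, seed = seed)
  .validate_sim_config(cfg)
}

.validate_sim_config <- function(cfg) {
  cfg$n_subjects <- .check_count(cfg$n_subjects, "n_subjects", min = 4L)
  cfg$n_nodes <- .check_count(cfg$n_nodes, "n_nodes", min = 2L)
  cfg$n_planted_positive <- .check_count(cfg$n_planted_positive,
                                         "n_planted_positive")
  cfg$n_planted_negative <- .check_count(cfg$n_planted_negative,
                                         "n_planted_negative")
  if (cfg$n_planted_positive + cfg$n_planted_negative > count_edges(cfg$n_nodes))
    stop_input("'n_planted_positive' + 'n_planted_negative' exceeds the number of edges")
  if (!is.numeric(cfg$effect_size) || length(cfg$effect_size) != 1L ||
      is.na(cfg$effect_size) || cfg$effect_size < 0 || cfg$effect_size >= 1)
    stop_input("'effect_size' must be a single value in [0, 1)")
  if (!is.numeric(cfg$noise_sd) || length(cfg$noise_sd) != 1L ||
      is.na(cfg$noise_sd) || cfg$noise_sd <= 0)
    stop_input("'noise_sd' must be a single positive value")
  if (length(cfg$score_range) != 2L || anyNA(cfg$score_range) ||
      diff(cfg$score_range) <= 0)
    stop_input("'score_range' must be two increasing values")
  if (length(cfg$score_shape) != 2L || anyNA(cfg$score_shape) ||
      any(cfg$score_shape <= 0))
    stop_input("'score_shape' must be two positive Beta shape parameters")
  ce <- cfg$covariate_effects
  if (length(ce)) {
    if (!is.numeric(ce) || is.null(names(ce)) || any(names(ce) == "") ||
        anyNA(ce) || any(abs(ce) >= 1))
      stop_input("'covariate_effects' must be a named numeric vector with values in (-1, 1)")
    cfg$covariate_effects <- ce
  } else {
    cfg$covariate_effects <- stats::setNames(numeric(0), character(0))
  }
  cfg$seed <- .check_count(cfg$seed, "seed")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  subjects: %d, nodes: %d (%d edges)\n", x$n_subjects,
              x$n_nodes, count_edges(x$n_nodes)))
  cat(sprintf("  planted: %d positive + %d negative, effect %.3g, noise sd %.3g\n",
              x$n_planted_positive, x$n_planted_negative, x$effect_size,
              x$noise_sd))
  cat(sprintf("  score: Beta(%.3g, %.3g) on [%.3g, %.3g]\n",
              x$score_shape[1], x$score_shape[2], x$score_range[1],
              x$score_range[2]))
  if (length(x$covariate_effects))
    cat("  covariates:", paste(sprintf("%s=%.3g", names(x$covariate_effects),
                                       x$covariate_effects), collapse = ", "),
        "\n")
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# phenotypes shared by matrix and time-series cohorts; z is the score's
# latent Gaussian (one value per subject)
.generate_phenotypes <- function(cfg, z) {
  n <- cfg$n_subjects
  score <- cfg$score_range[1] + diff(cfg$score_range) *
    stats::qbeta(stats::pnorm(z), cfg$score_shape[1], cfg$score_shape[2])
  ph <- data.frame(subject_id = sprintf("S%03d", seq_len(n)), score = score,
                   stringsAsFactors = FALSE)
  for (nm in names(cfg$covariate_effects)) {
    r <- .spearman_to_pearson(cfg$covariate_effects[[nm]])
    lat <- r * z + sqrt(1 - r^2) * stats::rnorm(n)
    ph[[nm]] <- switch(nm,
      age = 58 + 10 * lat,
      duration = stats::qlnorm(stats::pnorm(lat), meanlog = log(1.8),
                               sdlog = 0.8),
      lat)
  }
  ph$gender <- stats::rbinom(n, 1L, 0.5)
  stage_lat <- 0.8 * z + 0.6 * stats::rnorm(n)
  ph$hy_stage <- as.integer(cut(stage_lat,
                                breaks = c(-Inf,
                                           stats::quantile(stage_lat,
                                                           c(0.25, 0.8))[1:2],
                                           Inf),
                                labels = FALSE))
  ph$mmse <- pmax(19, pmin(30, round(stats::rnorm(n, 27.5, 1.8))))
  ph$mean_fd <- stats::rlnorm(n, meanlog = log(0.1), sdlog = 0.4)
  ph
}

#' Generate a synthetic cohort of connectivity matrices
#'
#' Draws a cohort of symmetric Fisher-z connectivity matrices and a phenotype
#' table with known planted structure: a right-skewed severity score, planted
#' positive/negative edges whose strength couples monotonically to the score
#' at the configured rank correlation, covariates (age, duration) rank-
#' correlated with the score, an independent binary gender, and per-subject
#' mean head motion independent of the score. All other edges are independent
#' noise around per-edge baselines.
#'
#' @param config A [sim_config()].
#' @param truth Optional: either another `synthetic_cohort` or its `truth`
#'   list (`positive` and `negative` [edge_mask()]s over the same nodes).
#'   The new cohort plants its effects on exactly those edges — and, when a
#'   whole cohort is given, shares its per-edge baseline strengths — so
#'   held-out validation cohorts come from the same population as training.
#'   Overrides `n_planted_positive` / `n_planted_negative`.
#' @return An object of class `synthetic_cohort`: list with `matrices` (list
#'   of square matrices), `phenotypes` (data frame), `truth` (planted
#'   positive/negative [edge_mask()]s) and `config`.
#' @export
#' @examples
#' coh <- generate_cohort(sim_config(n_subjects = 12, n_nodes = 10,
#'                                   n_planted_positive = 2,
#'                                   n_planted_negative = 2, seed = 7))
#' coh
generate_cohort <- function(config, truth = NULL) {
  cfg <- .validate_sim_config(config)
  baseline <- NULL
  if (inherits(truth, "synthetic_cohort")) {
    baseline <- truth$edge_baseline
    truth <- truth$truth
  }
  if (!is.null(truth)) {
    for (pol in c("positive", "negative")) {
      if (!inherits(truth[[pol]], "edge_mask") ||
          attr(truth[[pol]], "n_nodes") != cfg$n_nodes)
        stop_input("'truth' must carry edge_mask objects over n_nodes nodes")
    }
    if (length(intersect(mask_indices(truth$positive),
                         mask_indices(truth$negative))))
      stop_input("'truth' positive and negative sets overlap")
    cfg$n_planted_positive <- mask_size(truth$positive)
    cfg$n_planted_negative <- mask_size(truth$negative)
  }
  set.seed(cfg$seed)
  n <- cfg$n_subjects
  E <- count_edges(cfg$n_nodes)
  z <- stats::rnorm(n)
  ph <- .generate_phenotypes(cfg, z)

  if (is.null(truth)) {
    n_pl <- cfg$n_planted_positive + cfg$n_planted_negative
    planted <- if (n_pl) sample.int(E, n_pl) else integer(0)
    pos_idx <- sort(planted[seq_len(cfg$n_planted_positive)])
    neg_idx <- sort(planted[seq_len(cfg$n_planted_negative) +
                              cfg$n_planted_positive])
  } else {
    pos_idx <- mask_indices(truth$positive)
    neg_idx <- mask_indices(truth$negative)
  }

  r <- .spearman_to_pearson(cfg$effect_size)
  beta <- cfg$noise_sd * r / sqrt(1 - r^2)
  edge_mu <- if (!is.null(baseline)) baseline
             else stats::rnorm(E, mean = 0.25, sd = 0.15)
  if (length(edge_mu) != E)
    stop_input("baseline cohort has a different node count")
  X <- matrix(stats::rnorm(n * E, sd = cfg$noise_sd), n, E)
  X <- sweep(X, 2L, edge_mu, "+")
  if (length(pos_idx))
    X[, pos_idx] <- X[, pos_idx] + beta * z
  if (length(neg_idx))
    X[, neg_idx] <- X[, neg_idx] - beta * z

  pairs <- edge_pairs(cfg$n_nodes)
  mats <- vector("list", n)
  for (s in seq_len(n)) {
    m <- matrix(0, cfg$n_nodes, cfg$n_nodes)
    m[pairs] <- X[s, ]
    mats[[s]] <- m + t(m)
  }
  names(mats) <- ph$subject_id

  truth <- list(
    positive = edge_mask(pairs[pos_idx, , drop = FALSE], cfg$n_nodes,
                         "positive"),
    negative = edge_mask(pairs[neg_idx, , drop = FALSE], cfg$n_nodes,
                         "negative"))
  structure(list(matrices = mats, phenotypes = ph, truth = truth,
                 config = cfg, edge_baseline = edge_mu),
            class = "synthetic_cohort")
}

#' Generate a null cohort (no planted brain-behavior coupling)
#'
#' As [generate_cohort()] with the effect size forced to zero and empty truth
#' sets: every edge is independent of the score. Used to calibrate the
#' permutation test and selection type-I error.
#'
#' @param config A [sim_config()]; its `effect_size` is ignored.
#' @return A `synthetic_cohort` with empty `truth` masks.
#' @export
generate_null_cohort <- function(config) {
  cfg <- .validate_sim_config(config)
  cfg$effect_size <- 0
  coh <- generate_cohort(cfg)
  coh$truth <- list(
    positive = edge_mask(NULL, cfg$n_nodes, "positive"),
    negative = edge_mask(NULL, cfg$n_nodes, "negative"))
  coh
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d nodes\n",
              length(x$matrices), x$config$n_nodes))
  cat(sprintf("  planted: %d positive, %d negative (effect %.3g)\n",
              mask_size(x$truth$positive), mask_size(x$truth$negative),
              x$config$effect_size))
  cat(sprintf("  score: median %.1f, range %.1f-%.1f\n",
              stats::median(x$phenotypes$score), min(x$phenotypes$score),
              max(x$phenotypes$score)))
  invisible(x)
}

#' Generate a cohort of parcellated node time series
#'
#' Draws per-subject node time series from a latent-factor model in which
#' designated node pairs (nodes 1-2, 3-4, ... for `n_planted_positive`
#' pairs) share a common factor with the given loading, so their expected
#' sample correlation is `loading^2`. A nonnegative framewise-displacement
#' trace is attached with motion spikes at or above the 0.2 mm scrub
#' threshold occurring at the configured per-volume rate.
#'
#' @param config A [sim_config()]; `n_planted_positive` sets the number of
#'   coupled node pairs and `seed` the randomness.
#' @param n_volumes Number of time points per subject (>= 1).
#' @param fd_spike_rate Per-volume probability of a motion spike, in `[0, 1]`.
#' @param loading Factor loading of each coupled pair in `[0, 1]`; defaults
#'   to `sqrt(effect_size)` so the pair correlation equals the configured
#'   effect size. A loading of 1 gives noiseless, perfectly correlated pairs.
#' @return List with `timeseries` (list of [parcel_timeseries()]),
#'   `phenotypes`, and `pairs` (the coupled node pairs).
#' @export
generate_timeseries_cohort <- function(config, n_volumes = 200L,
                                       fd_spike_rate = 0.05,
                                       loading = NULL) {
  cfg <- .validate_sim_config(config)
  n_volumes <- .check_count(n_volumes, "n_volumes", min = 1L)
  if (!is.numeric(fd_spike_rate) || length(fd_spike_rate) != 1L ||
      is.na(fd_spike_rate) || fd_spike_rate < 0 || fd_spike_rate > 1)
    stop_input("'fd_spike_rate' must be a probability in [0, 1]")
  if (is.null(loading)) loading <- sqrt(cfg$effect_size)
  if (!is.numeric(loading) || length(loading) != 1L || is.na(loading) ||
      loading < 0 || loading > 1)
    stop_input("'loading' must be a single value in [0, 1]")
  n_pairs <- cfg$n_planted_positive
  if (2L * n_pairs > cfg$n_nodes)
    stop_input("'n_planted_positive' coupled pairs need 2 nodes each")

  set.seed(cfg$seed)
  z <- stats::rnorm(cfg$n_subjects)
  ph <- .generate_phenotypes(cfg, z)

  pairs <- if (n_pairs)
    cbind(i = 2L * seq_len(n_pairs) - 1L, j = 2L * seq_len(n_pairs))
  else matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j")))
  node_labels <- sprintf("node%03d", seq_len(cfg$n_nodes))

  ts_list <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    sig <- matrix(stats::rnorm(n_volumes * cfg$n_nodes), n_volumes,
                  cfg$n_nodes, dimnames = list(NULL, node_labels))
    if (n_pairs) {
      f <- matrix(stats::rnorm(n_volumes * n_pairs), n_volumes, n_pairs)
      for (p in seq_len(n_pairs)) {
        for (nd in c(pairs[p, 1L], pairs[p, 2L]))
          sig[, nd] <- loading * f[, p] +
            sqrt(1 - loading^2) * stats::rnorm(n_volumes)
      }
    }
    fd <- stats::runif(n_volumes, 0.02, 0.15)
    spike <- stats::runif(n_volumes) < fd_spike_rate
    fd[spike] <- 0.2 + stats::rexp(sum(spike), rate = 10)
    ts_list[[s]] <- parcel_timeseries(sig, fd,
                                      subject_id = ph$subject_id[s])
  }
  names(ts_list) <- ph$subject_id
  list(timeseries = ts_list, phenotypes = ph, pairs = pairs)
}
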