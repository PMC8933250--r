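# Connectome-based predictive modeling: candidate selection, LOOCV
# consensus, the two-feature linear model, evaluation, permutation
# inference and threshold optimization.

#' Select candidate connections on one training set
#'
#' For every whole-brain edge, correlates the connection strength across
#' subjects with the severity score by partial Spearman correlation
#' (controlling the nuisance covariates) and assigns the edge to the
#' positive candidate set when `p < p_threshold` with `rho > 0`, or to the
#' negative set when `p < p_threshold` with `rho < 0`.
#'
#' @param matrices List of square symmetric connectivity matrices (or a
#'   3-d array, or a `synthetic_cohort`), one per subject.
#' @param scores Per-subject severity scores.
#' @param covariates Optional numeric matrix/data frame of nuisance
#'   variables (e.g. age, duration, 0/1 gender, mean FD).
#' @param p_threshold Selection significance cutoff in `(0, 0.05]`.
#' @return List with `positive` and `negative` [edge_mask()]s and the
#'   per-edge `rho` and `p` vectors (in [edge_pairs()] order).
#' @export
select_candidates <- function(matrices, scores, covariates = NULL,
                              p_threshold = 0.009) {
  ed <- .as_edge_data(matrices)
  y <- .check_scores(scores, ed$n)
  C <- .check_covariates(covariates, ed$n)
  .check_threshold(p_threshold)
  k <- if (is.null(C)) 0L else ncol(C)
  if (ed$n < k + 4L)
    stop_input(sprintf("need at least %d subjects for %d covariate(s)",
                       k + 4L, k))

  R <- .rank_cols(ed$X)
  D <- cbind(rep(1, ed$n), if (k) .rank_cols(C))
  qd <- qr(D)
  Ex <- qr.resid(qd, R)
  ey <- qr.resid(qd, rank(y))
  sy <- sqrt(sum(ey^2))
  if (sy < 1e-10)
    stop_input("scores have no residual rank variance after covariate removal")
  ss <- sqrt(.colSums(Ex^2, ed$n, ed$E))
  degenerate <- ss < 1e-10
  if (any(degenerate)) {
    warning(sprintf("%d edge(s) with no rank variance (e.g. edges %s): correlation set to 0",
                    sum(degenerate),
                    paste(utils::head(which(degenerate), 3L), collapse = ", ")),
            call. = FALSE)
    ss[degenerate] <- Inf
  }
  rho <- as.vector(crossprod(Ex / rep(ss, each = ed$n), ey / sy))
  df <- ed$n - 2L - k
  tval <- rho * sqrt(df / pmax(1 - rho^2, 1e-12))
  p <- 2 * stats::pt(-abs(tval), df)
  pairs <- edge_pairs(ed$n_nodes)
  sel_pos <- which(p < p_threshold & rho > 0)
  sel_neg <- which(p < p_threshold & rho < 0)
  list(positive = edge_mask(pairs[sel_pos, , drop = FALSE], ed$n_nodes,
                            "positive"),
       negative = edge_mask(pairs[sel_neg, , drop = FALSE], ed$n_nodes,
                            "negative"),
       rho = rho, p = p)
}

#' Leave-one-out consensus connections
#'
#' Runs candidate selection once per leave-one-out fold (each subject
#' omitted in turn) and intersects the per-fold candidate sets: the
#' consensus connections are those selected in every iteration, separately
#' for the positive and negative polarity.
#'
#' @inheritParams select_candidates
#' @return List with consensus `positive` and `negative` [edge_mask()]s and
#'   `folds`, the per-fold candidate sets (edge indices in [edge_pairs()]
#'   order) for audit.
#' @export
loocv_consensus <- function(matrices, scores, covariates = NULL,
                            p_threshold = 0.009) {
  ed <- .as_edge_data(matrices)
  y <- .check_scores(scores, ed$n)
  C <- .check_covariates(covariates, ed$n)
  .check_threshold(p_threshold)
  engine <- .build_engine(ed$X, C)
  folds <- .fold_candidates(engine, y, p_threshold)
  pos <- Reduce(intersect, lapply(folds, `[[`, "positive"))
  neg <- Reduce(intersect, lapply(folds, `[[`, "negative"))
  pairs <- edge_pairs(ed$n_nodes)
  list(positive = edge_mask(pairs[pos, , drop = FALSE], ed$n_nodes,
                            "positive"),
       negative = edge_mask(pairs[neg, , drop = FALSE], ed$n_nodes,
                            "negative"),
       folds = folds)
}

#' Fit the two-feature CPM linear model for given masks
#'
#' Computes each subject's summed strength over the positive and negative
#' connection sets and fits the severity score on them by ordinary least
#' squares: `predicted = a1 * x1 + a2 * x2 + b`. An empty or constant
#' feature is dropped (with a warning) and its coefficient reported as 0.
#'
#' @inheritParams select_candidates
#' @param positive_mask,negative_mask [edge_mask()]s over the same nodes.
#' @param p_threshold Selection threshold recorded in the model (metadata
#'   only at this level).
#' @param covariate_names Names of the nuisance covariates used during
#'   selection, recorded in the model.
#' @return An object of class `cpm`; see [cpm()].
#' @export
cpm_fit <- function(matrices, scores, positive_mask, negative_mask,
                    p_threshold = NA_real_, covariate_names = character(0)) {
  ed <- .as_edge_data(matrices)
  y <- .check_scores(scores, ed$n)
  if (ed$n < 4L) stop_input("need at least 4 subjects to fit")
  for (m in list(positive_mask, negative_mask)) {
    if (!inherits(m, "edge_mask")) stop_input("masks must be edge_mask objects")
    if (attr(m, "n_nodes") != ed$n_nodes)
      stop_input("mask node count does not match the matrices")
  }
  ip <- mask_indices(positive_mask); inn <- mask_indices(negative_mask)
  if (length(intersect(ip, inn)))
    stop_input("positive and negative masks must be disjoint")
  if (!length(ip) && !length(inn))
    stop_input("both masks are empty; nothing to fit")
  x1 <- if (length(ip)) .rowSums(ed$X[, ip, drop = FALSE], ed$n, length(ip))
        else numeric(ed$n)
  x2 <- if (length(inn)) .rowSums(ed$X[, inn, drop = FALSE], ed$n, length(inn))
        else numeric(ed$n)
  fit <- .fit_sums(x1, x2, y, length(ip) > 0L, length(inn) > 0L)
  evaluation <- cpm_evaluate(fit$fitted, y)
  structure(list(positive_mask = positive_mask,
                 negative_mask = negative_mask,
                 coefficients = c(a1 = fit$a1, a2 = fit$a2, b = fit$b),
                 p_threshold = p_threshold,
                 covariates = covariate_names,
                 n_train = ed$n, n_nodes = ed$n_nodes,
                 features = cbind(pos_sum = x1, neg_sum = x2),
                 fitted = fit$fitted, observed = y,
                 evaluation = evaluation,
                 call = match.call()),
            class = "cpm")
}

#' Fit a connectome-based predictive model
#'
#' The full training pipeline on one cohort: leave-one-out consensus
#' selection of positive and negative connections at `p_threshold`
#' (partial Spearman correlation with the nuisance covariates), then an
#' ordinary least-squares fit of the score on the two summed-strength
#' features, `predicted = a1 * x1 + a2 * x2 + b`.
#'
#' The reported training evaluation is in-sample: the consensus masks come
#' from cross-validation, but the final coefficients are fit on all training
#' subjects and evaluated on those same subjects. The honest out-of-sample
#' counterpart is the per-fold variant of [cpm_variant()].
#'
#' @inheritParams select_candidates
#' @param keep_fold_sets Keep the per-fold candidate sets in the fitted
#'   object for audit (default `TRUE`).
#' @return An object of class `cpm` with components `positive_mask`,
#'   `negative_mask`, `coefficients` (`a1`, `a2`, `b`), `p_threshold`,
#'   `covariates`, `n_train`, `n_nodes`, `features`, `fitted`, `observed`,
#'   `evaluation` (in-sample `r_true`, `p`, `mse`) and `fold_sets`.
#'   Supported methods: `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals`, `plot`.
#' @export
#' @examples
#' coh <- generate_cohort(sim_config(n_subjects = 25, n_nodes = 12,
#'                                   n_planted_positive = 3,
#'                                   n_planted_negative = 3,
#'                                   effect_size = 0.8, seed = 2))
#' fit <- cpm(coh$matrices, coh$phenotypes$score,
#'            covariates = coh$phenotypes[c("age", "duration", "gender")],
#'            p_threshold = 0.01)
#' fit
cpm <- function(matrices, scores, covariates = NULL, p_threshold = 0.009,
                keep_fold_sets = TRUE) {
  ed <- .as_edge_data(matrices)
  y <- .check_scores(scores, ed$n)
  C <- .check_covariates(covariates, ed$n)
  .check_threshold(p_threshold)
  engine <- .build_engine(ed$X, C)
  folds <- .fold_candidates(engine, y, p_threshold)
  pos <- Reduce(intersect, lapply(folds, `[[`, "positive"))
  neg <- Reduce(intersect, lapply(folds, `[[`, "negative"))
  if (!length(pos) && !length(neg))
    stop_input(sprintf("no consensus connections at p < %.3g; consider optimizing the threshold",
                       p_threshold))
  pairs <- edge_pairs(ed$n_nodes)
  x1 <- if (length(pos)) .rowSums(ed$X[, pos, drop = FALSE], ed$n, length(pos))
        else numeric(ed$n)
  x2 <- if (length(neg)) .rowSums(ed$X[, neg, drop = FALSE], ed$n, length(neg))
        else numeric(ed$n)
  fit <- .fit_sums(x1, x2, y, length(pos) > 0L, length(neg) > 0L)
  evaluation <- cpm_evaluate(fit$fitted, y)
  structure(list(positive_mask = edge_mask(pairs[pos, , drop = FALSE],
                                           ed$n_nodes, "positive"),
                 negative_mask = edge_mask(pairs[neg, , drop = FALSE],
                                           ed$n_nodes, "negative"),
                 coefficients = c(a1 = fit$a1, a2 = fit$a2, b = fit$b),
                 p_threshold = p_threshold,
                 covariates = if (is.null(C)) character(0) else colnames(C),
                 n_train = ed$n, n_nodes = ed$n_nodes,
                 features = cbind(pos_sum = x1, neg_sum = x2),
                 fitted = fit$fitted, observed = y,
                 evaluation = evaluation,
                 fold_sets = if (keep_fold_sets) folds,
                 call = match.call()),
            class = "cpm")
}

#' @export
print.cpm <- function(x, ...) {
  cat("Connectome-based predictive model\n")
  cat(sprintf("  %d positive + %d negative consensus connections over %d nodes (p < %.3g)\n",
              mask_size(x$positive_mask), mask_size(x$negative_mask),
              x$n_nodes, x$p_threshold))
  cat(sprintf("  predicted = %.4g * x1 + %.4g * x2 + %.4g\n",
              x$coefficients[["a1"]], x$coefficients[["a2"]],
              x$coefficients[["b"]]))
  if (!is.null(x$evaluation) && !is.na(x$evaluation$r_true))
    cat(sprintf("  training (in-sample): r_true = %.3f, MSE = %.2f (n = %d)\n",
                x$evaluation$r_true, x$evaluation$mse, x$n_train))
  invisible(x)
}

#' @export
summary.cpm <- function(object, ...) {
  structure(list(model = object), class = "summary.cpm")
}

#' @export
print.summary.cpm <- function(x, ...) {
  m <- x$model
  print(m)
  if (length(m$covariates))
    cat("  selection covariates:", paste(m$covariates, collapse = ", "), "\n")
  ev <- m$evaluation
  if (!is.null(ev))
    cat(sprintf("  in-sample evaluation: r_true = %.3f (p = %.3g), MSE = %.2f\n",
                ev$r_true, ev$p, ev$mse))
  if (!is.null(m$fold_sets)) {
    sizes <- vapply(m$fold_sets,
                    function(f) length(f$positive) + length(f$negative),
                    numeric(1L))
    cat(sprintf("  per-fold candidates: median %d (range %d-%d) across %d folds\n",
                as.integer(stats::median(sizes)), min(sizes), max(sizes),
                length(sizes)))
  }
  invisible(x)
}

#' @export
coef.cpm <- function(object, ...) object$coefficients

#' @export
fitted.cpm <- function(object, ...) object$fitted

#' @export
residuals.cpm <- function(object, ...) object$observed - object$fitted

#' Predict severity scores from connectivity matrices
#'
#' Applies the frozen linear model to each subject's matrix:
#' `a1 * summed_strength(positive) + a2 * summed_strength(negative) + b`.
#' No re-selection or re-fitting takes place.
#'
#' @param object A fitted [cpm()] model.
#' @param matrices Connectivity matrices of new subjects (same node count);
#'   omitted returns the training fitted values.
#' @param ... Unused.
#' @return Numeric vector of predicted scores.
#' @export
predict.cpm <- function(object, matrices = NULL, ...) {
  if (is.null(matrices)) return(object$fitted)
  ed <- .as_edge_data(matrices)
  if (ed$n_nodes != object$n_nodes)
    stop_input(sprintf("matrices have %d nodes; the model expects %d",
                       ed$n_nodes, object$n_nodes))
  ip <- mask_indices(object$positive_mask)
  inn <- mask_indices(object$negative_mask)
  x1 <- if (length(ip)) .rowSums(ed$X[, ip, drop = FALSE], ed$n, length(ip))
        else numeric(ed$n)
  x2 <- if (length(inn)) .rowSums(ed$X[, inn, drop = FALSE], ed$n, length(inn))
        else numeric(ed$n)
  co <- object$coefficients
  out <- as.vector(co[["a1"]] * x1 + co[["a2"]] * x2 + co[["b"]])
  if (!is.null(ed$ids)) names(out) <- ed$ids
  out
}

#' @export
plot.cpm <- function(x, ...) {
  graphics::plot(x$fitted, x$observed,
                 xlab = "Predicted score", ylab = "Observed score",
                 main = sprintf("CPM training fit (r_true = %.3f)",
                                x$evaluation$r_true), ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Evaluate predicted against observed scores
#'
#' `r_true` is the Spearman correlation between predicted and observed
#' scores, with a two-sided parametric p value; the MSE is the mean squared
#' difference on the score scale. When either vector is constant, the
#' correlation is undefined: a warning is issued and `r_true` is `NA` while
#' the MSE is still returned.
#'
#' @param predicted,observed Numeric vectors of equal length >= 4.
#' @return Object of class `cpm_evaluation`: list with `r_true`, `p`,
#'   `mse`, `n`.
#' @export
cpm_evaluate <- function(predicted, observed) {
  predicted <- as.numeric(predicted); observed <- as.numeric(observed)
  n <- length(predicted)
  if (length(observed) != n)
    stop_input("'predicted' and 'observed' must have the same length")
  if (n < 4L) stop_input("need at least 4 subjects to evaluate")
  if (anyNA(predicted) || anyNA(observed))
    stop_input("missing values in 'predicted' or 'observed'")
  mse <- mean((predicted - observed)^2)
  if (stats::var(predicted) == 0 || stats::var(observed) == 0) {
    warning("correlation undefined for a constant vector; r_true is NA (MSE still computed)",
            call. = FALSE)
    return(structure(list(r_true = NA_real_, p = NA_real_, mse = mse, n = n),
                     class = "cpm_evaluation"))
  }
  ct <- partial_rank_cor(predicted, observed)
  structure(list(r_true = ct$rho, p = ct$p, mse = mse, n = n),
            class = "cpm_evaluation")
}

#' @export
print.cpm_evaluation <- function(x, ...) {
  cat(sprintf("<cpm_evaluation> r_true = %.3f (p = %.3g), MSE = %.2f, n = %d\n",
              x$r_true, x$p, x$mse, x$n))
  invisible(x)
}

#' Validate a frozen model on an external cohort
#'
#' Applies [predict.cpm()] per subject and evaluates the predictions with
#' Spearman correlation (standard parametric significance) and MSE. The
#' model is used as-is: no re-selection or re-fitting on the validation
#' cohort.
#'
#' @param model A fitted [cpm()] model.
#' @param matrices Validation cohort connectivity matrices.
#' @param scores Observed validation scores.
#' @return List with `evaluation` (a [cpm_evaluate()] result) and
#'   `predictions`.
#' @export
cpm_validate <- function(model, matrices, scores) {
  predictions <- predict(model, matrices)
  scores <- as.numeric(scores)
  if (length(scores) != length(predictions))
    stop_input("validation scores do not match the number of matrices")
  list(evaluation = cpm_evaluate(predictions, scores),
       predictions = predictions)
}

#' Covariate-adjusted evaluation of predictions
#'
#' Partial Spearman correlation between predicted and observed scores,
#' controlling clinical characteristics; used to confirm that a model's
#' predictions are not carried by the covariates alone.
#'
#' @inheritParams partial_rank_cor
#' @param predicted,observed Numeric score vectors.
#' @return As [partial_rank_cor()].
#' @export
cpm_partial_evaluation <- function(predicted, observed, covariates = NULL) {
  partial_rank_cor(predicted, observed, covariates)
}

#' Permutation test of a CPM's predictive significance
#'
#' Computes the in-sample `r_true` of the full consensus-selection-and-fit
#' pipeline, then repeats the entire pipeline on score vectors shuffled
#' across subjects (covariate and matrix rows stay aligned with their
#' subjects). The permutation p value is the strict fraction of permuted
#' pipelines whose r meets or exceeds `r_true` — a plain
#' `count / n_perm` with no +1 smoothing, so 0 and 1 are attainable.
#' Permutation iterations whose consensus is empty contribute a correlation
#' of -1 by convention so the denominator stays fixed; their count is
#' reported.
#'
#' @inheritParams select_candidates
#' @param n_perm Number of permutations (default 1000).
#' @param seed Mandatory integer seed for the shuffles.
#' @return Object of class `cpm_permutation`: list with `p_permu`,
#'   `r_true`, `perm_r`, `n_perm`, `n_empty`, `seed`.
#' @export
cpm_permutation <- function(matrices, scores, covariates = NULL,
                            p_threshold = 0.009, n_perm = 1000L, seed) {
  if (missing(seed)) stop_input("'seed' is required for reproducible permutations")
  seed <- .check_count(seed, "seed")
  n_perm <- .check_count(n_perm, "n_perm", min = 1L)
  ed <- .as_edge_data(matrices)
  y <- .check_scores(scores, ed$n)
  C <- .check_covariates(covariates, ed$n)
  .check_threshold(p_threshold)
  engine <- .build_engine(ed$X, C)
  r_true <- .pipeline_r(engine, ed$X, y, p_threshold)
  if (r_true == -1)
    message("observed pipeline yielded an empty consensus; r_true recorded as -1")
  set.seed(seed)
  perm_r <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm_r[b] <- .pipeline_r(engine, ed$X, sample(y), p_threshold)
  }
  structure(list(p_permu = mean(perm_r >= r_true), r_true = r_true,
                 perm_r = perm_r, n_perm = n_perm,
                 n_empty = sum(perm_r == -1), seed = seed),
            class = "cpm_permutation")
}

#' @export
print.cpm_permutation <- function(x, ...) {
  cat(sprintf("<cpm_permutation> r_true = %.3f, p_permu = %.4g (%d permutations, %d empty-consensus)\n",
              x$r_true, x$p_permu, x$n_perm, x$n_empty))
  invisible(x)
}

#' Optimize the candidate-selection threshold
#'
#' Re-runs the consensus + fit + evaluate pipeline over a grid of selection
#' p-value cutoffs (default `.001` to `.050` in steps of `.001`, 50 values)
#' and returns the threshold affording the highest in-sample `r_true`. Ties
#' resolve to the smaller (more stringent) threshold. Thresholds whose
#' consensus is empty get `NA` performance and cannot win.
#'
#' @inheritParams select_candidates
#' @param grid Numeric vector of thresholds in `(0, 1)`.
#' @return List with `best_threshold` and `table`, a data frame of
#'   threshold, consensus sizes, `r_true` and `mse`.
#' @export
cpm_optimize_threshold <- function(matrices, scores, covariates = NULL,
                                   grid = seq(0.001, 0.05, by = 0.001)) {
  if (!is.numeric(grid) || !length(grid) || anyNA(grid) ||
      any(grid <= 0 | grid >= 1))
    stop_input("'grid' must be thresholds strictly inside (0, 1)")
  grid <- sort(unique(grid))
  ed <- .as_edge_data(matrices)
  y <- .check_scores(scores, ed$n)
  C <- .check_covariates(covariates, ed$n)
  engine <- .build_engine(ed$X, C)
  rho <- .fold_rho_matrix(engine, y)
  tab <- data.frame(threshold = grid, n_positive = NA_integer_,
                    n_negative = NA_integer_, r_true = NA_real_,
                    mse = NA_real_)
  for (g in seq_along(grid)) {
    rc <- .rho_crit(grid[g], engine$df)
    pos <- which(.colSums(rho > rc, engine$n, engine$E) == engine$n)
    neg <- which(.colSums(rho < -rc, engine$n, engine$E) == engine$n)
    tab$n_positive[g] <- length(pos)
    tab$n_negative[g] <- length(neg)
    if (!length(pos) && !length(neg)) next
    x1 <- if (length(pos)) .rowSums(ed$X[, pos, drop = FALSE], ed$n,
                                    length(pos)) else numeric(ed$n)
    x2 <- if (length(neg)) .rowSums(ed$X[, neg, drop = FALSE], ed$n,
                                    length(neg)) else numeric(ed$n)
    fit <- tryCatch(.fit_sums(x1, x2, y, length(pos) > 0L, length(neg) > 0L,
                              quiet = TRUE),
                    error = function(e) NULL)
    if (is.null(fit)) next
    r <- suppressWarnings(stats::cor(fit$fitted, y, method = "spearman"))
    tab$r_true[g] <- r
    tab$mse[g] <- mean((fit$fitted - y)^2)
  }
  if (all(is.na(tab$r_true)))
    stop_input("no threshold in the grid yields a non-empty consensus")
  best <- tab$threshold[which.max(tab$r_true)]
  list(best_threshold = best, table = tab)
}
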