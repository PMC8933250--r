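# Model variants (single-polarity, per-fold), the clinical hybrid model and
# dependent-correlation model comparison.

#' Build a CPM variant
#'
#' Three alternatives to the full two-feature consensus model:
#' `positive_only` (M1-style) and `negative_only` (M2-style) fit a
#' single-feature linear model on the respective consensus sum; `per_fold`
#' (M3-style) selects candidates within each leave-one-out fold, fits on
#' that fold's training subjects, and predicts the held-out subject, so its
#' predictions are genuinely out-of-sample. At a shared threshold the
#' single-polarity masks equal the corresponding masks of the full model.
#'
#' @inheritParams select_candidates
#' @param variant One of `"positive_only"`, `"negative_only"`, `"per_fold"`.
#' @return List of class `cpm_variant` with `variant`, `predictions`,
#'   `evaluation` and, for the single-polarity variants, the fitted `model`
#'   (a `cpm` object with the unused polarity empty).
#' @export
cpm_variant <- function(matrices, scores, covariates = NULL,
                        p_threshold = 0.009,
                        variant = c("positive_only", "negative_only",
                                    "per_fold")) {
  variant <- match.arg(variant)
  ed <- .as_edge_data(matrices)
  y <- .check_scores(scores, ed$n)
  C <- .check_covariates(covariates, ed$n)
  .check_threshold(p_threshold)
  engine <- .build_engine(ed$X, C)
  folds <- .fold_candidates(engine, y, p_threshold)
  pairs <- edge_pairs(ed$n_nodes)

  if (variant %in% c("positive_only", "negative_only")) {
    pol <- if (variant == "positive_only") "positive" else "negative"
    idx <- Reduce(intersect, lapply(folds, `[[`, pol))
    if (!length(idx))
      stop_input(sprintf("empty consensus for the %s polarity at p < %.3g",
                         pol, p_threshold))
    xs <- .rowSums(ed$X[, idx, drop = FALSE], ed$n, length(idx))
    zero <- numeric(ed$n)
    fit <- if (pol == "positive")
      .fit_sums(xs, zero, y, TRUE, FALSE, quiet = TRUE)
    else
      .fit_sums(zero, xs, y, FALSE, TRUE, quiet = TRUE)
    evaluation <- cpm_evaluate(fit$fitted, y)
    model <- structure(
      list(positive_mask = edge_mask(if (pol == "positive")
             pairs[idx, , drop = FALSE] else NULL, ed$n_nodes, "positive"),
           negative_mask = edge_mask(if (pol == "negative")
             pairs[idx, , drop = FALSE] else NULL, ed$n_nodes, "negative"),
           coefficients = c(a1 = fit$a1, a2 = fit$a2, b = fit$b),
           p_threshold = p_threshold,
           covariates = if (is.null(C)) character(0) else colnames(C),
           n_train = ed$n, n_nodes = ed$n_nodes,
           features = cbind(pos_sum = if (pol == "positive") xs else zero,
                            neg_sum = if (pol == "negative") xs else zero),
           fitted = fit$fitted, observed = y,
           evaluation = evaluation, fold_sets = folds,
           call = match.call()),
      class = "cpm")
    return(structure(list(variant = variant, predictions = fit$fitted,
                          evaluation = evaluation, model = model),
                     class = "cpm_variant"))
  }

  # per_fold: out-of-sample prediction assembled across LOOCV iterations
  predictions <- numeric(ed$n)
  for (f in seq_len(ed$n)) {
    train <- seq_len(ed$n)[-f]
    pos <- folds[[f]]$positive
    neg <- folds[[f]]$negative
    if (!length(pos) && !length(neg)) {
      predictions[f] <- mean(y[train])  # no candidates: fall back to the mean
      next
    }
    x1 <- if (length(pos))
      .rowSums(ed$X[train, pos, drop = FALSE], length(train), length(pos))
    else numeric(length(train))
    x2 <- if (length(neg))
      .rowSums(ed$X[train, neg, drop = FALSE], length(train), length(neg))
    else numeric(length(train))
    fit <- tryCatch(.fit_sums(x1, x2, y[train], length(pos) > 0L,
                              length(neg) > 0L, quiet = TRUE),
                    error = function(e) NULL)
    if (is.null(fit)) {
      predictions[f] <- mean(y[train])
      next
    }
    predictions[f] <- fit$b +
      fit$a1 * sum(ed$X[f, pos]) + fit$a2 * sum(ed$X[f, neg])
  }
  structure(list(variant = "per_fold", predictions = predictions,
                 evaluation = cpm_evaluate(predictions, y), model = NULL),
            class = "cpm_variant")
}

#' @export
print.cpm_variant <- function(x, ...) {
  cat(sprintf("<cpm_variant> %s: r_true = %.3f, MSE = %.2f (n = %d)\n",
              x$variant, x$evaluation$r_true, x$evaluation$mse,
              x$evaluation$n))
  invisible(x)
}

#' Compare two dependent model predictions with Steiger's Z
#'
#' Both models predict the same observed scores, so their correlations with
#' the observed scores are dependent; [steiger_z()] accounts for that
#' dependence through the correlation between the two prediction vectors.
#' All three correlations are Spearman, matching the package's evaluation
#' metric. Identical prediction vectors are reported as `z = 0`, `p = 1`.
#'
#' @param pred_a,pred_b Predicted-score vectors from the two models.
#' @param observed Observed scores (same length).
#' @return Object of class `cpm_comparison`: list with `model_a_r`,
#'   `model_b_r`, `r_ab`, `n`, `z`, `p`.
#' @export
cpm_compare <- function(pred_a, pred_b, observed) {
  pred_a <- as.numeric(pred_a); pred_b <- as.numeric(pred_b)
  observed <- as.numeric(observed)
  n <- length(observed)
  if (length(pred_a) != n || length(pred_b) != n)
    stop_input("prediction vectors and 'observed' must have the same length")
  if (n < 4L) stop_input("need at least 4 subjects")
  r_a <- stats::cor(pred_a, observed, method = "spearman")
  r_b <- stats::cor(pred_b, observed, method = "spearman")
  r_ab <- stats::cor(pred_a, pred_b, method = "spearman")
  if (isTRUE(all.equal(pred_a, pred_b)) ||
      (r_a == r_b && abs(r_ab) >= 1)) {
    st <- list(z = 0, p = 1)
  } else {
    st <- steiger_z(r_a, r_b, r_ab, n)
  }
  structure(list(model_a_r = r_a, model_b_r = r_b, r_ab = r_ab, n = n,
                 z = st$z, p = st$p),
            class = "cpm_comparison")
}

#' @export
print.cpm_comparison <- function(x, ...) {
  cat(sprintf("<cpm_comparison> r_a = %.3f vs r_b = %.3f (r_ab = %.3f, n = %d): Steiger z = %.3f, p = %.3g\n",
              x$model_a_r, x$model_b_r, x$r_ab, x$n, x$z, x$p))
  invisible(x)
}

#' Hybrid model combining connectome features with clinical factors
#'
#' Ordinary least-squares fit of the score on the positive and negative
#' summed strengths plus clinical covariates (typically age, gender, disease
#' duration and clinical stage). An empty mask's sum feature is dropped with
#' a warning; a rank-deficient design is an error.
#'
#' @inheritParams cpm_fit
#' @param clinical Data frame or matrix of complete numeric clinical
#'   covariates, one row per subject.
#' @return Object of class `cpm_hybrid` with `coefficients`, masks,
#'   `clinical_names`, `fitted`, `observed` and `evaluation`. `predict` on
#'   new matrices requires the matching `clinical` table.
#' @export
cpm_hybrid <- function(matrices, scores, positive_mask, negative_mask,
                       clinical) {
  ed <- .as_edge_data(matrices)
  y <- .check_scores(scores, ed$n)
  Cl <- .check_covariates(clinical, ed$n)
  if (is.null(Cl)) stop_input("'clinical' covariates are required")
  for (m in list(positive_mask, negative_mask)) {
    if (!inherits(m, "edge_mask")) stop_input("masks must be edge_mask objects")
    if (attr(m, "n_nodes") != ed$n_nodes)
      stop_input("mask node count does not match the matrices")
  }
  ip <- mask_indices(positive_mask); inn <- mask_indices(negative_mask)
  x1 <- if (length(ip)) .rowSums(ed$X[, ip, drop = FALSE], ed$n, length(ip))
        else numeric(ed$n)
  x2 <- if (length(inn)) .rowSums(ed$X[, inn, drop = FALSE], ed$n, length(inn))
        else numeric(ed$n)
  cols <- list(`(Intercept)` = rep(1, ed$n))
  if (length(ip)) cols$pos_sum <- x1
  else warning("positive mask is empty; its sum feature is dropped",
               call. = FALSE)
  if (length(inn)) cols$neg_sum <- x2
  else warning("negative mask is empty; its sum feature is dropped",
               call. = FALSE)
  D <- cbind(do.call(cbind, cols), Cl)
  colnames(D) <- c(names(cols), colnames(Cl))
  qd <- qr(D)
  if (qd$rank < ncol(D))
    stop_input("singular fit: hybrid design matrix is rank-deficient")
  beta <- qr.coef(qd, y)
  fitted <- as.vector(D %*% beta)
  structure(list(coefficients = beta,
                 positive_mask = positive_mask, negative_mask = negative_mask,
                 clinical_names = colnames(Cl), n_train = ed$n,
                 n_nodes = ed$n_nodes, fitted = fitted, observed = y,
                 evaluation = cpm_evaluate(fitted, y), call = match.call()),
            class = "cpm_hybrid")
}

#' @export
print.cpm_hybrid <- function(x, ...) {
  cat("Hybrid connectome + clinical model\n")
  cat(sprintf("  %d positive + %d negative connections, clinical: %s\n",
              mask_size(x$positive_mask), mask_size(x$negative_mask),
              paste(x$clinical_names, collapse = ", ")))
  cat(sprintf("  training (in-sample): r_true = %.3f, MSE = %.2f (n = %d)\n",
              x$evaluation$r_true, x$evaluation$mse, x$n_train))
  invisible(x)
}

#' @export
coef.cpm_hybrid <- function(object, ...) object$coefficients

#' @export
fitted.cpm_hybrid <- function(object, ...) object$fitted

#' @rdname cpm_hybrid
#' @param object A fitted `cpm_hybrid` model.
#' @param ... Unused.
#' @export
predict.cpm_hybrid <- function(object, matrices = NULL, clinical = NULL,
                               ...) {
  if (is.null(matrices)) return(object$fitted)
  ed <- .as_edge_data(matrices)
  if (ed$n_nodes != object$n_nodes)
    stop_input(sprintf("matrices have %d nodes; the model expects %d",
                       ed$n_nodes, object$n_nodes))
  Cl <- .check_covariates(clinical, ed$n)
  if (is.null(Cl) || !all(object$clinical_names %in% colnames(Cl)))
    stop_input("'clinical' must supply columns: ",
               paste(object$clinical_names, collapse = ", "))
  ip <- mask_indices(object$positive_mask)
  inn <- mask_indices(object$negative_mask)
  cols <- list(`(Intercept)` = rep(1, ed$n))
  if (length(ip))
    cols$pos_sum <- .rowSums(ed$X[, ip, drop = FALSE], ed$n, length(ip))
  if (length(inn))
    cols$neg_sum <- .rowSums(ed$X[, inn, drop = FALSE], ed$n, length(inn))
  D <- cbind(do.call(cbind, cols),
             Cl[, object$clinical_names, drop = FALSE])
  as.vector(D %*% object$coefficients[c(names(cols), object$clinical_names)])
}
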