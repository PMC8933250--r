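# Internal LOOCV selection engine.
#
# All per-fold quantities that do not depend on the score vector — edge ranks
# on the retained subjects, the QR of the rank-covariate design, and the
# column-normalized edge residuals — are precomputed once. Re-running
# selection for a new (e.g. permuted) score vector then costs one rank
# vector, one QR residual and one matrix-vector product per fold. The
# "p < threshold" test is applied as an equivalent critical value on the
# partial correlation (|rho| > r_crit with r_crit = t_crit/sqrt(df+t_crit^2)),
# avoiding per-edge p-value evaluation in hot loops.
#
# When no edge column (or the score) carries ties, leave-one-out ranks are
# derived from the full-sample ranks by the shift identity
# rank_{-f}(x_s) = rank(x_s) - [rank(x_s) > rank(x_f)], avoiding re-sorting.

.rank_cols <- function(M) {
  if (!ncol(M)) return(M)
  apply(M, 2L, rank)
}

.as_edge_data <- function(matrices, check_symmetry = TRUE) {
  if (inherits(matrices, "synthetic_cohort")) matrices <- matrices$matrices
  if (is.array(matrices) && length(dim(matrices)) == 3L) {
    matrices <- lapply(seq_len(dim(matrices)[3L]),
                       function(s) matrices[, , s])
  }
  if (!is.list(matrices) || !length(matrices))
    stop_input("'matrices' must be a non-empty list of square matrices (or a 3-d array)")
  n_nodes <- nrow(matrices[[1L]])
  for (s in seq_along(matrices)) {
    m <- matrices[[s]]
    if (!is.matrix(m) || nrow(m) != ncol(m))
      stop_input(sprintf("matrix %d is not square", s))
    if (nrow(m) != n_nodes)
      stop_input(sprintf("matrix %d has %d nodes, expected %d", s, nrow(m),
                         n_nodes))
    if (!all(is.finite(m)))
      stop_input(sprintf("matrix %d has non-finite entries", s))
    if (check_symmetry && max(abs(m - t(m))) > 1e-8)
      stop_input(sprintf("matrix %d is asymmetric beyond 1e-8", s))
  }
  E <- count_edges(n_nodes)
  X <- t(vapply(matrices, .upper_vec, numeric(E)))
  list(X = X, n_nodes = n_nodes, n = nrow(X), E = E,
       ids = names(matrices))
}

.check_scores <- function(scores, n) {
  scores <- as.numeric(scores)
  if (length(scores) != n)
    stop_input(sprintf("%d scores supplied for %d subjects", length(scores), n))
  if (anyNA(scores)) stop_input("missing values in 'scores'")
  if (stats::var(scores) == 0) stop_input("'scores' is constant")
  scores
}

.check_threshold <- function(p_threshold) {
  if (!is.numeric(p_threshold) || length(p_threshold) != 1L ||
      is.na(p_threshold) || p_threshold <= 0 || p_threshold > 0.05)
    stop_input("'p_threshold' must lie in (0, 0.05]")
  p_threshold
}

.build_engine <- function(X, C = NULL) {
  n <- nrow(X); E <- ncol(X)
  k <- if (is.null(C)) 0L else ncol(C)
  if (n < k + 5L)
    stop_input(sprintf("LOOCV selection needs at least %d subjects for %d covariate(s)",
                       k + 5L, k))
  Rfull <- .rank_cols(X)
  has_ties <- any(vapply(seq_len(E),
                         function(e) anyDuplicated(X[, e]) > 0L, logical(1L)))
  folds <- vector("list", n)
  for (f in seq_len(n)) {
    idx <- seq_len(n)[-f]
    if (!has_ties) {
      Rf <- Rfull[idx, , drop = FALSE]
      Rf <- Rf - (Rf > rep(Rfull[f, ], each = n - 1L))
    } else {
      Rf <- .rank_cols(X[idx, , drop = FALSE])
    }
    Df <- cbind(rep(1, n - 1L),
                if (k) .rank_cols(C[idx, , drop = FALSE]))
    qf <- qr(Df)
    Ex <- qr.resid(qf, Rf)
    ss <- sqrt(.colSums(Ex^2, n - 1L, E))
    ss[ss < 1e-10] <- Inf  # degenerate edges correlate 0, never selected
    Ex <- Ex / rep(ss, each = n - 1L)
    folds[[f]] <- list(f = f, idx = idx, qr = qf, X = Ex)
  }
  structure(list(folds = folds, n = n, E = E, k = k,
                 df = (n - 1L) - 2L - k),
            class = "cpm_engine")
}

# normalized rank residual of the score within one fold, or NULL if the
# score is (residually) constant there
.score_resid <- function(fold, y, ry_full, ties) {
  if (ties) {
    ry <- rank(y[fold$idx])
  } else {
    ry <- ry_full[fold$idx]
    ry <- ry - (ry > ry_full[fold$f])
  }
  ey <- qr.resid(fold$qr, ry)
  s <- sqrt(sum(ey^2))
  if (s < 1e-10) return(NULL)
  ey / s
}

.rho_crit <- function(thr, df) {
  tc <- stats::qt(1 - thr / 2, df)
  tc / sqrt(df + tc^2)
}

# consensus edge indices at a threshold; early exit once both polarities die
.consensus <- function(engine, y, thr) {
  rc <- .rho_crit(thr, engine$df)
  ties <- anyDuplicated(y) > 0L
  ryf <- if (!ties) rank(y) else NULL
  pos <- neg <- rep(TRUE, engine$E)
  for (fold in engine$folds) {
    ey <- .score_resid(fold, y, ryf, ties)
    if (is.null(ey)) {
      pos[] <- FALSE; neg[] <- FALSE; break
    }
    rho <- as.vector(crossprod(fold$X, ey))
    pos <- pos & (rho > rc)
    neg <- neg & (rho < -rc)
    if (!any(pos) && !any(neg)) break
  }
  list(positive = which(pos), negative = which(neg))
}

# per-fold candidate sets (no early exit; audit path)
.fold_candidates <- function(engine, y, thr) {
  rc <- .rho_crit(thr, engine$df)
  ties <- anyDuplicated(y) > 0L
  ryf <- if (!ties) rank(y) else NULL
  lapply(engine$folds, function(fold) {
    ey <- .score_resid(fold, y, ryf, ties)
    if (is.null(ey))
      return(list(positive = integer(0), negative = integer(0)))
    rho <- as.vector(crossprod(fold$X, ey))
    list(positive = which(rho > rc), negative = which(rho < -rc))
  })
}

# folds x edges matrix of per-fold partial rank correlations
.fold_rho_matrix <- function(engine, y) {
  ties <- anyDuplicated(y) > 0L
  ryf <- if (!ties) rank(y) else NULL
  out <- matrix(0, engine$n, engine$E)
  for (fold in engine$folds) {
    ey <- .score_resid(fold, y, ryf, ties)
    if (!is.null(ey)) out[fold$f, ] <- as.vector(crossprod(fold$X, ey))
  }
  out
}

# OLS of y on the available sum features; dropped/degenerate features get a
# zero coefficient
.fit_sums <- function(x1, x2, y, has_pos, has_neg, quiet = FALSE) {
  use1 <- has_pos && stats::var(x1) > 0
  use2 <- has_neg && stats::var(x2) > 0
  if (!quiet) {
    if (has_pos && !use1)
      warning("positive sum feature is constant; dropped from the fit",
              call. = FALSE)
    if (has_neg && !use2)
      warning("negative sum feature is constant; dropped from the fit",
              call. = FALSE)
  }
  D <- cbind(`(Intercept)` = rep(1, length(y)),
             if (use1) x1, if (use2) x2)
  qd <- qr(D)
  if (qd$rank < ncol(D))
    stop_input("singular fit: summed-strength features are collinear")
  beta <- qr.coef(qd, y)
  a1 <- if (use1) beta[2L] else 0
  a2 <- if (use2) beta[length(beta)] else 0
  b <- beta[1L]
  list(a1 = unname(a1), a2 = unname(a2), b = unname(b),
       fitted = as.vector(b + a1 * x1 + a2 * x2))
}

# in-sample r of the full selection + fit pipeline; -1 when the consensus is
# empty or the fit/evaluation degenerates (permutation convention)
.pipeline_r <- function(engine, X, y, thr) {
  cons <- .consensus(engine, y, thr)
  np <- length(cons$positive); nn <- length(cons$negative)
  if (!np && !nn) return(-1)
  x1 <- if (np) .rowSums(X[, cons$positive, drop = FALSE], nrow(X), np)
        else numeric(nrow(X))
  x2 <- if (nn) .rowSums(X[, cons$negative, drop = FALSE], nrow(X), nn)
        else numeric(nrow(X))
  fit <- tryCatch(.fit_sums(x1, x2, y, np > 0L, nn > 0L, quiet = TRUE),
                  error = function(e) NULL)
  if (is.null(fit)) return(-1)
  r <- suppressWarnings(stats::cor(fit$fitted, y, method = "spearman"))
  if (is.na(r)) -1 else r
}
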