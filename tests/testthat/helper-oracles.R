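# Independent brute-force reimplementations used as oracles: explicit ranks,
# explicit normal equations, exhaustive per-edge loops. Deliberately naive
# and kept free of the package's vectorized selection engine.

oracle_partial_rank <- function(x, y, C = NULL) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  D <- matrix(1, n, 1)
  if (!is.null(C)) {
    C <- as.matrix(C)
    for (j in seq_len(ncol(C))) D <- cbind(D, rank(C[, j]))
  }
  beta_x <- solve(t(D) %*% D) %*% t(D) %*% rx
  beta_y <- solve(t(D) %*% D) %*% t(D) %*% ry
  ex <- rx - as.vector(D %*% beta_x)
  ey <- ry - as.vector(D %*% beta_y)
  rho <- sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
  k <- ncol(D) - 1L
  df <- n - 2L - k
  tval <- rho * sqrt(df / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tval), df), df = df)
}

# exhaustive edge loop over a list of square matrices
oracle_select <- function(mats, y, C, thr) {
  n_nodes <- nrow(mats[[1L]])
  pos <- integer(0); neg <- integer(0)
  e <- 0L
  for (i in seq_len(n_nodes - 1L)) {
    for (j in (i + 1L):n_nodes) {
      e <- e + 1L
      strength <- vapply(mats, function(m) m[i, j], numeric(1L))
      res <- oracle_partial_rank(strength, y, C)
      if (res$p < thr && res$rho > 0) pos <- c(pos, e)
      if (res$p < thr && res$rho < 0) neg <- c(neg, e)
    }
  }
  list(positive = pos, negative = neg)
}

oracle_loocv <- function(mats, y, C, thr) {
  n <- length(mats)
  sets <- vector("list", n)
  for (f in seq_len(n)) {
    Cf <- if (is.null(C)) NULL else as.matrix(C)[-f, , drop = FALSE]
    sets[[f]] <- oracle_select(mats[-f], y[-f], Cf, thr)
  }
  list(positive = Reduce(intersect, lapply(sets, `[[`, "positive")),
       negative = Reduce(intersect, lapply(sets, `[[`, "negative")),
       folds = sets)
}

# published Z1* formula, written out step by step
oracle_steiger <- function(r_jk, r_jh, r_kh, n) {
  fisher <- function(r) 0.5 * log((1 + r) / (1 - r))
  rbar <- (r_jk + r_jh) / 2
  psi <- r_kh * (1 - rbar^2 - rbar^2) -
    0.5 * (rbar * rbar) * (1 - rbar^2 - rbar^2 - r_kh^2)
  sbar <- psi / ((1 - rbar^2) * (1 - rbar^2))
  z <- (fisher(r_jk) - fisher(r_jh)) * sqrt((n - 3) / (2 - 2 * sbar))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

oracle_summed <- function(m, mask) {
  total <- 0
  if (nrow(mask)) {
    for (e in seq_len(nrow(mask))) total <- total + m[mask[e, 1L], mask[e, 2L]]
  }
  total
}

# ordinary least squares by explicit normal equations
oracle_ols <- function(D, y) as.vector(solve(t(D) %*% D) %*% t(D) %*% y)
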