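# Statistical primitives: partial Spearman correlation and Steiger's Z.

#' Partial Spearman rank correlation
#'
#' Rank-transforms all variables (average ranks for ties), residualizes `x`
#' and `y` on the rank-transformed covariates by least squares (with
#' intercept), and Pearson-correlates the residuals. With no covariates this
#' is the plain Spearman correlation. The two-sided p value comes from
#' `t = rho * sqrt(df / (1 - rho^2))` on `df = n - 2 - k` degrees of freedom,
#' where `k` is the number of covariates.
#'
#' Degenerate inputs where a variable has no residual rank variance after
#' covariate removal (for example, `x` identical to a covariate) return
#' `rho = 0` with a warning rather than an error.
#'
#' @param x,y Numeric vectors of equal length `n >= k + 4`; neither constant.
#' @param covariates Optional numeric matrix or data frame of nuisance
#'   variables (columns), e.g. age, disease duration and 0/1 gender.
#' @return List with `rho`, `p`, `df`, `n`.
#' @export
#' @examples
#' set.seed(1)
#' z <- rnorm(30); x <- z + rnorm(30); y <- z + rnorm(30)
#' partial_rank_cor(x, y, covariates = cbind(z = z))
partial_rank_cor <- function(x, y, covariates = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop_input("'x' and 'y' must have the same length")
  if (anyNA(x) || anyNA(y)) stop_input("missing values in 'x' or 'y'")
  C <- .check_covariates(covariates, n)
  k <- if (is.null(C)) 0L else ncol(C)
  if (n < k + 4L)
    stop_input(sprintf("need at least %d observations for %d covariate(s)",
                       k + 4L, k))
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop_input("correlation undefined: 'x' or 'y' is constant")

  rx <- rank(x); ry <- rank(y)
  D <- cbind(rep(1, n), if (k) apply(C, 2L, rank))
  qd <- qr(D)
  ex <- qr.resid(qd, rx)
  ey <- qr.resid(qd, ry)
  sx <- sqrt(sum(ex^2)); sy <- sqrt(sum(ey^2))
  df <- n - 2L - k
  if (sx < 1e-10 || sy < 1e-10) {
    warning("degenerate partial correlation: no residual rank variance after covariate removal; returning 0",
            call. = FALSE)
    return(list(rho = 0, p = NA_real_, df = df, n = n))
  }
  rho <- sum(ex * ey) / (sx * sy)
  rho <- max(-1, min(1, rho))
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt(df / (1 - rho^2))
    2 * stats::pt(-abs(tval), df)
  }
  list(rho = rho, p = p, df = df, n = n)
}

.check_covariates <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  C <- as.matrix(as.data.frame(covariates))
  if (!is.numeric(C))
    stop_input("covariates must be numeric (encode gender as 0/1)")
  if (nrow(C) != n)
    stop_input(sprintf("covariates have %d rows for %d subjects", nrow(C), n))
  if (anyNA(C)) stop_input("missing values in covariates")
  if (is.null(colnames(C))) colnames(C) <- sprintf("cov%d", seq_len(ncol(C)))
  C
}

#' Steiger's Z for two dependent correlations sharing one variable
#'
#' Compares `r_jk` and `r_jh` — two correlations that share the variable `j`
#' (for a CPM comparison, `j` is the observed score and `k`, `h` are two
#' models' predicted scores) — given `r_kh`, the correlation between the two
#' non-shared variables. Implements Steiger's Z1*: both correlations are
#' Fisher-z transformed and their difference scaled by an asymptotic standard
#' error whose covariance term uses the mean of the two compared
#' correlations:
#' \deqn{\bar r = (r_{jk} + r_{jh})/2}
#' \deqn{\psi = r_{kh}(1 - 2\bar r^2) - \tfrac12 \bar r^2 (1 - 2\bar r^2 - r_{kh}^2)}
#' \deqn{Z = (z_{jk} - z_{jh}) \sqrt{\frac{n - 3}{2 - 2\,\psi/(1-\bar r^2)^2}}}
#' with a two-sided p from the standard normal.
#'
#' @param r_jk,r_jh The two correlations being compared, each in `(-1, 1)`.
#' @param r_kh Correlation between the non-shared variables, in `(-1, 1)`.
#'   The three correlations must form a positive semi-definite correlation
#'   matrix (any triple computed from real data does).
#' @param n Number of subjects (>= 4).
#' @return List with `z` and `p`.
#' @export
steiger_z <- function(r_jk, r_jh, r_kh, n) {
  for (r in list(r_jk = r_jk, r_jh = r_jh, r_kh = r_kh)) {
    if (!is.numeric(r) || length(r) != 1L || is.na(r))
      stop_input("correlations must be single non-missing numbers")
  }
  if (abs(r_jk) >= 1 || abs(r_jh) >= 1 || abs(r_kh) >= 1)
    stop_input("correlations must lie strictly inside (-1, 1)")
  if (1 - r_jk^2 - r_jh^2 - r_kh^2 + 2 * r_jk * r_jh * r_kh < 0)
    stop_input("the three correlations do not form a positive semi-definite correlation matrix")
  n <- .check_count(n, "n", min = 4L)
  z1 <- atanh(r_jk); z2 <- atanh(r_jh)
  if (z1 == z2) return(list(z = 0, p = 1))
  rbar <- (r_jk + r_jh) / 2
  psi <- r_kh * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_kh^2)
  sbar <- min(psi / (1 - rbar^2)^2, 1)
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * sbar))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
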