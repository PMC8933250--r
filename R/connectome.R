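# From parcellated node time series to scrubbed Fisher-z connectivity.
# Inputs are assumed already preprocessed and node-level: voxel-to-node
# averaging, nuisance regression, filtering and dummy-volume removal all
# happen upstream of this package.

#' Parcellated node time series with framewise displacement
#'
#' @param signal Numeric matrix, rows = time points (volumes), columns =
#'   nodes; column names are node labels (generated when absent).
#' @param fd Nonnegative per-volume framewise displacement in mm, one value
#'   per row of `signal`.
#' @param subject_id Subject identifier.
#' @return An object of class `parcel_ts`.
#' @export
parcel_timeseries <- function(signal, fd, subject_id = "subject") {
  signal <- as.matrix(signal)
  if (!is.numeric(signal) || !nrow(signal) || !ncol(signal))
    stop_input("'signal' must be a non-empty numeric matrix (volumes x nodes)")
  fd <- as.numeric(fd)
  if (length(fd) != nrow(signal))
    stop_input(sprintf("'fd' has %d values for %d volumes", length(fd),
                       nrow(signal)))
  if (anyNA(fd) || any(fd < 0))
    stop_input("'fd' must be nonnegative with no missing values")
  if (is.null(colnames(signal)))
    colnames(signal) <- sprintf("node%03d", seq_len(ncol(signal)))
  structure(list(subject_id = as.character(subject_id)[1L], signal = signal,
                 fd = fd),
            class = "parcel_ts")
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat(sprintf("<parcel_ts> subject %s: %d volumes x %d nodes, mean FD %.3f mm\n",
              x$subject_id, nrow(x$signal), ncol(x$signal), mean(x$fd)))
  invisible(x)
}

#' Motion-scrub a time series
#'
#' Removes volumes whose framewise displacement is at or above the threshold
#' (the censoring rule is `FD >= fd_threshold`), preserving temporal order,
#' and flags the subject for exclusion when fewer than `min_volumes` volumes
#' survive (the default, 120 volumes, is 4 minutes at a 2 s repetition time).
#' The reported mean FD is computed over all input volumes, before scrubbing.
#'
#' @param ts A [parcel_timeseries()].
#' @param fd_threshold Censoring threshold in mm (> 0); volumes with
#'   `FD >= fd_threshold` are removed.
#' @param min_volumes Minimum retained volumes below which the subject is
#'   flagged excluded.
#' @return List with `ts` (the scrubbed `parcel_ts`) and `report` (class
#'   `scrub_report`: subject id, input/removed/retained counts, mean FD,
#'   exclusion flag).
#' @export
scrub <- function(ts, fd_threshold = 0.2, min_volumes = 120L) {
  if (!inherits(ts, "parcel_ts")) stop_input("'ts' must be a parcel_ts")
  if (!nrow(ts$signal)) stop_input("empty time series")
  if (!is.numeric(fd_threshold) || length(fd_threshold) != 1L ||
      is.na(fd_threshold) || fd_threshold <= 0)
    stop_input("'fd_threshold' must be a single positive value (mm)")
  min_volumes <- .check_count(min_volumes, "min_volumes")
  keep <- ts$fd < fd_threshold
  out <- parcel_timeseries(ts$signal[keep, , drop = FALSE], ts$fd[keep],
                           subject_id = ts$subject_id)
  report <- structure(list(subject_id = ts$subject_id,
                           n_input_volumes = length(keep),
                           n_removed = sum(!keep),
                           n_retained = sum(keep),
                           mean_fd = mean(ts$fd),
                           excluded = sum(keep) < min_volumes),
                      class = "scrub_report")
  list(ts = out, report = report)
}

#' @export
print.scrub_report <- function(x, ...) {
  cat(sprintf("<scrub_report> subject %s: %d/%d volumes retained (%d removed), mean FD %.3f mm%s\n",
              x$subject_id, x$n_retained, x$n_input_volumes, x$n_removed,
              x$mean_fd, if (x$excluded) " -- EXCLUDED" else ""))
  invisible(x)
}

#' Build a Fisher-z connectivity matrix
#'
#' Pearson-correlates every pair of node time series and applies the Fisher
#' r-to-z transform `z = atanh(r)`. Both positive and negative correlations
#' are retained; the diagonal is set to zero and never enumerated as an
#' edge. Correlations of magnitude 1 (up to numerical saturation) are
#' clamped to `+/-(1 - 1e-7)` before the transform, with a warning.
#'
#' @param ts A [parcel_timeseries()] with at least 3 retained volumes and no
#'   zero-variance node.
#' @return Square symmetric numeric matrix of Fisher-z strengths with node
#'   labels as dimnames and the subject id as attribute `subject_id`.
#' @export
build_connectivity <- function(ts) {
  if (!inherits(ts, "parcel_ts")) stop_input("'ts' must be a parcel_ts")
  if (nrow(ts$signal) < 3L)
    stop_input("need at least 3 retained volumes to correlate")
  sds <- apply(ts$signal, 2L, stats::sd)
  if (any(sds == 0))
    stop_input("zero-variance node(s): ",
               paste(colnames(ts$signal)[sds == 0], collapse = ", "))
  r <- stats::cor(ts$signal)
  off <- r[upper.tri(r)]
  if (any(abs(off) >= 1 - 1e-7))
    warning("saturated correlation(s) |r| ~ 1 clamped to +/-(1 - 1e-7) before atanh",
            call. = FALSE)
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- 0
  attr(z, "subject_id") <- ts$subject_id
  z
}

#' Association between head motion and a score
#'
#' Spearman rank correlation between per-subject mean framewise displacement
#' and a score vector, with a two-sided parametric p value. Used to verify
#' that neither observed nor predicted severity is driven by motion.
#'
#' @param mean_fd Per-subject mean FD values (mm).
#' @param scores Per-subject scores, same length, >= 4 subjects.
#' @return List with `rho` and `p` (plus `df`, `n`).
#' @export
motion_association <- function(mean_fd, scores) {
  if (length(mean_fd) != length(scores))
    stop_input("'mean_fd' and 'scores' must have the same length")
  if (length(scores) < 4L) stop_input("need at least 4 subjects")
  partial_rank_cor(mean_fd, scores)
}
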