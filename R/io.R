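# File formats. All external files are UTF-8 delimited text with mandatory
# headers and 1-based node indices; matrices carry node labels on both the
# header row and first column; edge lists in model files follow the
# row-major (i < j) convention of edge_pairs().

#' Read / write a connectivity matrix
#'
#' Square tab-delimited numeric text with node labels as header row and
#' first column. Reading validates squareness, finiteness and symmetry
#' (tolerance 1e-8), naming the offending cell on failure.
#'
#' @param path File path.
#' @return `read_connectivity_matrix`: a square symmetric numeric matrix.
#' @export
read_connectivity_matrix <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop_input("matrix file has non-numeric entries: ", path)
  if (nrow(m) != ncol(m))
    stop_input(sprintf("matrix file is not square (%d x %d): %s", nrow(m),
                       ncol(m), path))
  if (!all(is.finite(m))) stop_input("matrix file has non-finite entries: ", path)
  d <- abs(m - t(m))
  if (max(d) > 1e-8) {
    w <- which(d == max(d), arr.ind = TRUE)[1L, ]
    stop_input(sprintf("asymmetric matrix: |z[%d,%d] - z[%d,%d]| = %.3g > 1e-8",
                       w[1L], w[2L], w[2L], w[1L], max(d)))
  }
  m
}

#' @rdname read_connectivity_matrix
#' @param matrix Square symmetric numeric matrix (node labels taken from
#'   dimnames, generated when absent).
#' @export
write_connectivity_matrix <- function(matrix, path) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stop_input("'matrix' must be square")
  if (is.null(rownames(matrix))) {
    labels <- sprintf("node%03d", seq_len(nrow(matrix)))
    dimnames(matrix) <- list(labels, labels)
  }
  utils::write.table(matrix, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Read / write a parcellated time series
#'
#' Tab-delimited text, header row of node labels, one row per volume. The
#' framewise-displacement trace is either a column headed `FD` inside the
#' file or a companion one-column file given as `fd_path`.
#'
#' @param path File path.
#' @param fd_path Optional companion FD file (one header line, one value
#'   per volume); required when the file has no `FD` column.
#' @param subject_id Subject identifier for the returned object.
#' @return `read_timeseries`: a [parcel_timeseries()].
#' @export
read_timeseries <- function(path, fd_path = NULL, subject_id = "subject") {
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  if ("FD" %in% names(df)) {
    fd <- df[["FD"]]
    df[["FD"]] <- NULL
  } else if (!is.null(fd_path)) {
    if (!file.exists(fd_path)) stop_input("FD file not found: ", fd_path)
    fd <- utils::read.table(fd_path, header = TRUE, sep = "\t")[[1L]]
  } else {
    stop_input("no 'FD' column in ", path, " and no 'fd_path' supplied")
  }
  parcel_timeseries(as.matrix(df), fd, subject_id = subject_id)
}

#' @rdname read_timeseries
#' @param ts A [parcel_timeseries()].
#' @export
write_timeseries <- function(ts, path) {
  if (!inherits(ts, "parcel_ts")) stop_input("'ts' must be a parcel_ts")
  out <- cbind(as.data.frame(ts$signal), FD = ts$fd)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a phenotype table
#'
#' Comma-separated, one row per subject. `subject_id` and `score` are
#' mandatory; optional clinical columns (age, gender, duration, hy_stage,
#' mmse, ledd, treat_duration, mean_fd) may be absent or NA-coded, but a
#' column named as a covariate downstream must be complete there.
#' Duplicate subject ids are rejected.
#'
#' @param path File path.
#' @return `read_phenotypes`: a data frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("subject_id", "score")) {
    if (!col %in% names(df))
      stop_input(sprintf("phenotype file lacks mandatory column '%s': %s",
                         col, path))
  }
  dup <- duplicated(df$subject_id)
  if (any(dup))
    stop_input("duplicate subject_id in phenotype file (line ",
               which(dup)[1L] + 1L, "): ", df$subject_id[which(dup)[1L]])
  if (anyNA(df$score))
    stop_input("missing score (line ", which(is.na(df$score))[1L] + 1L,
               "): every subject needs a score")
  df
}

#' @rdname read_phenotypes
#' @param phenotypes Data frame with at least `subject_id` and `score`.
#' @export
write_phenotypes <- function(phenotypes, path) {
  for (col in c("subject_id", "score")) {
    if (!col %in% names(phenotypes))
      stop_input(sprintf("'phenotypes' lacks mandatory column '%s'", col))
  }
  utils::write.csv(phenotypes, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a node-to-network partition
#'
#' Two-column tab-delimited text: 1-based node index and network label,
#' with a header row. Every node from 1 to the maximum index must appear
#' exactly once.
#'
#' @param path File path.
#' @return `read_partition`: a [network_partition()].
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop_input("partition file needs two columns (node, network): ", path)
  node <- as.integer(df[[1L]])
  if (anyNA(node)) stop_input("non-integer node index in partition file: ", path)
  n <- max(node)
  if (anyDuplicated(node) || !setequal(node, seq_len(n)))
    stop_input("partition file must list every node from 1 to ", n,
               " exactly once")
  labels <- character(n)
  labels[node] <- as.character(df[[2L]])
  network_partition(labels)
}

#' @rdname read_partition
#' @param partition A [network_partition()].
#' @export
write_partition <- function(partition, path) {
  if (!inherits(partition, "network_partition"))
    stop_input("'partition' must be a network_partition")
  utils::write.table(data.frame(node = seq_len(partition$n_nodes),
                                network = partition$labels),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a fitted CPM model
#'
#' JSON with a format version, node count, 1-based edge lists per polarity,
#' the linear coefficients, selection threshold, covariate names and
#' training size. Round-trips reproduce the masks exactly and the
#' coefficients to full written precision.
#'
#' @param path File path.
#' @return `read_cpm_model`: a `cpm` object (without training data; all
#'   prediction methods work).
#' @export
read_cpm_model <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (fld in c("format_version", "n_nodes", "coefficients", "p_threshold"))
    if (is.null(obj[[fld]]))
      stop_input("model file lacks field '", fld, "': ", path)
  as_pairs <- function(x) {
    if (is.null(x) || !length(x)) return(NULL)
    matrix(as.integer(unlist(x)), ncol = 2L, byrow = is.list(x))
  }
  structure(list(
    positive_mask = edge_mask(as_pairs(obj$positive_edges), obj$n_nodes,
                              "positive"),
    negative_mask = edge_mask(as_pairs(obj$negative_edges), obj$n_nodes,
                              "negative"),
    coefficients = c(a1 = obj$coefficients$a1, a2 = obj$coefficients$a2,
                     b = obj$coefficients$b),
    p_threshold = obj$p_threshold,
    covariates = as.character(obj$covariates %||% character(0)),
    n_train = obj$n_train %||% NA_integer_,
    n_nodes = obj$n_nodes,
    features = NULL, fitted = NULL, observed = NULL, evaluation = NULL,
    fold_sets = NULL, call = NULL),
    class = "cpm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_cpm_model
#' @param model A fitted [cpm()] model.
#' @export
write_cpm_model <- function(model, path) {
  if (!inherits(model, "cpm")) stop_input("'model' must be a cpm object")
  pm <- unclass(model$positive_mask); nm <- unclass(model$negative_mask)
  payload <- list(
    format_version = 1L,
    n_nodes = model$n_nodes,
    p_threshold = model$p_threshold,
    coefficients = as.list(model$coefficients),
    covariates = model$covariates,
    n_train = model$n_train,
    positive_edges = if (nrow(pm)) unname(pm[, 1:2, drop = FALSE]),
    negative_edges = if (nrow(nm)) unname(nm[, 1:2, drop = FALSE]))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read / write a simulation configuration
#'
#' YAML-style key-value text holding every [sim_config()] field including
#' the seed, so a cohort can be regenerated identically from its file.
#'
#' @param path File path.
#' @return `read_sim_config`: a validated [sim_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  obj <- yaml::read_yaml(path)
  ce <- obj$covariate_effects
  do.call(sim_config, c(
    obj[setdiff(names(obj), "covariate_effects")],
    list(covariate_effects = if (length(ce)) unlist(ce)
         else stats::setNames(numeric(0), character(0)))))
}

#' @rdname read_sim_config
#' @param config A [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  cfg <- .validate_sim_config(config)
  yaml::write_yaml(list(
    n_subjects = cfg$n_subjects, n_nodes = cfg$n_nodes,
    n_planted_positive = cfg$n_planted_positive,
    n_planted_negative = cfg$n_planted_negative,
    effect_size = cfg$effect_size, noise_sd = cfg$noise_sd,
    score_range = cfg$score_range, score_shape = cfg$score_shape,
    covariate_effects = as.list(cfg$covariate_effects),
    seed = cfg$seed), path)
  invisible(path)
}

#' Read / write a run configuration
#'
#' YAML key-value text tying a pipeline run together: input paths,
#' covariate list, scrub parameters, threshold grid, permutation count and
#' the seed. A seed is required whenever `n_perm` is set.
#'
#' @param path File path.
#' @return `read_run_config`: a named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$n_perm) && is.null(cfg$seed))
    stop_input("run config enables permutations but sets no seed")
  cfg
}

#' @rdname read_run_config
#' @param config Named list of run settings.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
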