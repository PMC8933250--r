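# Network anatomy of a connectome model: mapping consensus edges onto a
# seven-network node partition, size-normalized connection proportions, and
# computational lesion analysis.

#' Node-to-network partition
#'
#' @param labels Character vector assigning each node (by position) to a
#'   named functional network.
#' @return Object of class `network_partition` with `n_nodes`, `labels`,
#'   `networks` (label levels in order of first appearance) and `sizes`.
#' @export
network_partition <- function(labels) {
  labels <- as.character(labels)
  if (!length(labels) || anyNA(labels) || any(labels == ""))
    stop_input("'labels' must assign every node a non-empty network name")
  networks <- unique(labels)
  sizes <- vapply(networks, function(nw) sum(labels == nw), integer(1L))
  structure(list(n_nodes = length(labels), labels = labels,
                 networks = networks, sizes = sizes),
            class = "network_partition")
}

#' @export
print.network_partition <- function(x, ...) {
  cat(sprintf("<network_partition> %d nodes in %d networks\n", x$n_nodes,
              length(x$networks)))
  cat(paste(sprintf("  %s: %d", x$networks, x$sizes), collapse = "\n"), "\n")
  invisible(x)
}

#' Seven-network partition of a 268-node parcellation
#'
#' A synthetic block assignment of 268 nodes to the seven canonical
#' functional networks with the canonical sizes: frontoparietal (63),
#' default mode (20), motor (50), visual (45), limbic (30), basal ganglia
#' (29) and cerebellum (31). Only the network sizes are meaningful; the
#' node-to-network assignment is contiguous by construction and carries no
#' real anatomy. Supply your own partition file for real analyses.
#'
#' @return A [network_partition()] over 268 nodes.
#' @export
#' @examples
#' seven_network_partition()
seven_network_partition <- function() {
  sizes <- c(frontoparietal = 63L, default_mode = 20L, motor = 50L,
             visual = 45L, limbic = 30L, basal_ganglia = 29L,
             cerebellum = 31L)
  network_partition(rep(names(sizes), sizes))
}

#' Within- and between-network connection counts
#'
#' Counts the mask's edges for every unordered network pair. Within-network
#' counts sit on the diagonal of the returned matrices; the number of
#' possible connections is `n_A * (n_A - 1) / 2` within a network and
#' `n_A * n_B` between two networks.
#'
#' @param mask An [edge_mask()].
#' @param partition A [network_partition()] over the same nodes.
#' @return Object of class `anatomy_report`: list with symmetric `counts`
#'   and `possible` matrices (networks x networks), `n_edges`, `networks`,
#'   `sizes`.
#' @export
pair_counts <- function(mask, partition) {
  if (!inherits(mask, "edge_mask")) stop_input("'mask' must be an edge_mask")
  if (!inherits(partition, "network_partition"))
    stop_input("'partition' must be a network_partition")
  if (attr(mask, "n_nodes") != partition$n_nodes)
    stop_input(sprintf("mask is over %d nodes but the partition assigns %d",
                       attr(mask, "n_nodes"), partition$n_nodes))
  K <- length(partition$networks)
  counts <- matrix(0L, K, K,
                   dimnames = list(partition$networks, partition$networks))
  if (nrow(mask)) {
    ai <- match(partition$labels[mask[, 1L]], partition$networks)
    aj <- match(partition$labels[mask[, 2L]], partition$networks)
    a <- pmin(ai, aj); b <- pmax(ai, aj)
    for (e in seq_along(a)) {
      counts[a[e], b[e]] <- counts[a[e], b[e]] + 1L
    }
    counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
  }
  nsz <- partition$sizes
  possible <- outer(nsz, nsz)
  diag(possible) <- nsz * (nsz - 1L) / 2L
  dimnames(possible) <- dimnames(counts)
  structure(list(counts = counts, possible = possible,
                 n_edges = nrow(mask), networks = partition$networks,
                 sizes = nsz),
            class = "anatomy_report")
}

#' @export
print.anatomy_report <- function(x, ...) {
  cat(sprintf("<anatomy_report> %d connections over %d networks\n",
              x$n_edges, length(x$networks)))
  print(x$counts)
  invisible(x)
}

#' Size-normalized connection proportions, per mille
#'
#' Divides each network pair's connection count by its number of possible
#' connections, scaled to parts per thousand, and aggregates within-network
#' and between-network proportions. The default aggregation pools counts
#' over pooled possibles before dividing; `"average"` instead averages the
#' per-pair ratios.
#'
#' @param report An [pair_counts()] result.
#' @param aggregate `"pooled"` (default) or `"average"`.
#' @return List with `per_pair` (per-mille matrix), `within`, `between`,
#'   `aggregate`.
#' @export
per_mille <- function(report, aggregate = c("pooled", "average")) {
  aggregate <- match.arg(aggregate)
  if (!inherits(report, "anatomy_report"))
    stop_input("'report' must come from pair_counts()")
  if (any(report$possible == 0))
    stop_input("a network pair has no possible connections (singleton network)")
  per_pair <- 1000 * report$counts / report$possible
  dg <- diag(report$counts); dgp <- diag(report$possible)
  up <- upper.tri(report$counts)
  if (aggregate == "pooled") {
    within <- 1000 * sum(dg) / sum(dgp)
    between <- 1000 * sum(report$counts[up]) / sum(report$possible[up])
  } else {
    within <- mean(1000 * dg / dgp)
    between <- mean(1000 * report$counts[up] / report$possible[up])
  }
  list(per_pair = per_pair, within = within, between = between,
       aggregate = aggregate)
}

#' Per-network contribution of a connectome model
#'
#' A network's raw contribution is the number of model connections (positive
#' and negative combined) incident to it — a between-network edge credits
#' both its networks. The size-normalized weight divides by the number of
#' possible edges incident to the network,
#' `n_k (n_k - 1)/2 + n_k (N - n_k)`.
#'
#' @param positive_mask,negative_mask The model's [edge_mask()]s.
#' @param partition A [network_partition()] over the same nodes.
#' @return Data frame with `network`, `raw`, `possible`, `normalized`,
#'   sorted as the partition's networks.
#' @export
network_contribution <- function(positive_mask, negative_mask, partition) {
  if (!inherits(partition, "network_partition"))
    stop_input("'partition' must be a network_partition")
  edges <- rbind(unclass(positive_mask)[, 1:2, drop = FALSE],
                 unclass(negative_mask)[, 1:2, drop = FALSE])
  for (m in list(positive_mask, negative_mask)) {
    if (attr(m, "n_nodes") != partition$n_nodes)
      stop_input("mask node count does not match the partition")
  }
  N <- partition$n_nodes
  raw <- vapply(partition$networks, function(nw) {
    inw <- partition$labels[edges[, 1L]] == nw
    jnw <- partition$labels[edges[, 2L]] == nw
    sum(inw | jnw)
  }, integer(1L))
  nsz <- partition$sizes
  possible <- nsz * (nsz - 1L) / 2L + nsz * (N - nsz)
  data.frame(network = partition$networks, raw = raw, possible = possible,
             normalized = raw / possible, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Lesion a functional network out of the model
#'
#' Deletes every node of one functional network (and all incident
#' connections) from each subject's matrix, reindexes, and re-runs the full
#' consensus-selection-and-fit pipeline on the reduced matrices at the
#' supplied fixed threshold (the original model's optimum; no
#' re-optimization). Lesioning the 63-node frontoparietal network of a
#' 268-node parcellation, for example, submits 205 x 205 matrices.
#'
#' @inheritParams select_candidates
#' @param partition A [network_partition()] over the matrices' nodes.
#' @param remove Name of the network to lesion.
#' @param validation_matrices,validation_scores Optional frozen validation
#'   cohort, lesioned with the same nodes and evaluated with the lesioned
#'   model.
#' @return List of class `cpm_lesion` with `model` (the lesioned `cpm`),
#'   `removed_network`, `kept_nodes`, `n_nodes` (reduced dimension),
#'   `train_evaluation` and optional `validation_evaluation` /
#'   `validation_predictions`.
#' @export
lesion_model <- function(matrices, scores, covariates = NULL, partition,
                         remove, p_threshold = 0.009,
                         validation_matrices = NULL,
                         validation_scores = NULL) {
  if (!inherits(partition, "network_partition"))
    stop_input("'partition' must be a network_partition")
  if (!remove %in% partition$networks)
    stop_input(sprintf("network '%s' is not in the partition", remove))
  keep <- which(partition$labels != remove)
  if (length(keep) < 2L)
    stop_input("lesioning this network leaves fewer than 2 nodes")
  if (inherits(matrices, "synthetic_cohort")) matrices <- matrices$matrices
  lesioned <- lapply(matrices, function(m) m[keep, keep, drop = FALSE])
  model <- cpm(lesioned, scores, covariates = covariates,
               p_threshold = p_threshold)
  out <- list(model = model, removed_network = remove, kept_nodes = keep,
              n_nodes = length(keep), train_evaluation = model$evaluation,
              validation_evaluation = NULL, validation_predictions = NULL)
  if (!is.null(validation_matrices)) {
    if (is.null(validation_scores))
      stop_input("'validation_scores' required with 'validation_matrices'")
    vles <- lapply(validation_matrices,
                   function(m) m[keep, keep, drop = FALSE])
    val <- cpm_validate(model, vles, validation_scores)
    out$validation_evaluation <- val$evaluation
    out$validation_predictions <- val$predictions
  }
  structure(out, class = "cpm_lesion")
}

#' @export
print.cpm_lesion <- function(x, ...) {
  cat(sprintf("<cpm_lesion> removed '%s': %d nodes remain\n",
              x$removed_network, x$n_nodes))
  cat(sprintf("  train r_true = %.3f", x$train_evaluation$r_true))
  if (!is.null(x$validation_evaluation))
    cat(sprintf(", validation r = %.3f", x$validation_evaluation$r_true))
  cat("\n")
  invisible(x)
}

#' Compare a lesioned model against the full model
#'
#' Steiger's Z on the two dependent prediction-observation correlations
#' (the correlation between the two prediction vectors supplies the
#' covariance term), with a Bonferroni adjustment over the family of
#' lesion comparisons (default 14: seven lesions evaluated in two cohorts).
#'
#' @param full_predictions,lesioned_predictions Aligned predicted-score
#'   vectors from the full and lesioned models.
#' @param observed Observed scores.
#' @param n_comparisons Bonferroni family size (default 14).
#' @return List with `z`, `p`, `p_bonferroni`, `n_comparisons`.
#' @export
compare_lesioned <- function(full_predictions, lesioned_predictions,
                             observed, n_comparisons = 14L) {
  n_comparisons <- .check_count(n_comparisons, "n_comparisons", min = 1L)
  cmp <- cpm_compare(full_predictions, lesioned_predictions, observed)
  list(z = cmp$z, p = cmp$p,
       p_bonferroni = min(1, cmp$p * n_comparisons),
       n_comparisons = n_comparisons)
}
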