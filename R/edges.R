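# Edge enumeration convention used throughout the package:
# unordered node pairs (i < j), 1-based, enumerated row-major over the upper
# triangle: (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n).

stop_input <- function(...) stop(..., call. = FALSE)

#' Enumerate whole-brain edges
#'
#' All unordered node pairs `(i, j)` with `i < j`, in the package's canonical
#' row-major upper-triangle order. This is the order in which per-edge
#' statistics and mask indices are stored everywhere in the package.
#'
#' @param n_nodes Number of atlas nodes (>= 2).
#' @return Integer matrix with columns `i` and `j`, one row per edge.
#' @export
#' @examples
#' edge_pairs(4)
edge_pairs <- function(n_nodes) {
  n_nodes <- .check_count(n_nodes, "n_nodes", min = 2L)
  i <- rep.int(seq_len(n_nodes - 1L), times = (n_nodes - 1L):1L)
  j <- sequence((n_nodes - 1L):1L) + i
  cbind(i = i, j = j)
}

#' Count whole-brain edges
#'
#' Number of unordered node pairs for an atlas of `n_nodes` nodes,
#' `n_nodes * (n_nodes - 1) / 2`. For the 268-node parcellation this is the
#' familiar 35,778 whole-brain connections.
#'
#' @param n_nodes Number of atlas nodes (>= 2).
#' @return Integer count of edges.
#' @export
#' @examples
#' count_edges(268)
count_edges <- function(n_nodes) {
  n_nodes <- .check_count(n_nodes, "n_nodes", min = 2L)
  as.integer(n_nodes * (n_nodes - 1L) / 2L)
}

# linear index of edge (i, j) in the row-major upper-triangle order
edge_index <- function(i, j, n_nodes) {
  (i - 1L) * (2L * n_nodes - i) / 2L + (j - i)
}

# vectorize the upper triangle of a square matrix in row-major (i < j) order
.upper_vec <- function(m) t(m)[lower.tri(m)]

.check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min)
    stop_input(sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(x)
}

#' Construct an edge mask
#'
#' An edge mask is the set of connections carried by one polarity of a CPM
#' model: node pairs whose strength indexes higher (positive) or lower
#' (negative) severity scores.
#'
#' @param edges Two-column integer matrix of node pairs (any order within a
#'   row; stored with `i < j`), or `NULL`/zero-row matrix for an empty mask.
#' @param n_nodes Number of atlas nodes the mask refers to.
#' @param polarity `"positive"` or `"negative"`.
#' @return An object of class `edge_mask`: the pair matrix with attributes
#'   `n_nodes` and `polarity`.
#' @export
edge_mask <- function(edges, n_nodes, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  n_nodes <- .check_count(n_nodes, "n_nodes", min = 2L)
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop_input("'edges' must have two columns (i, j)")
    storage.mode(edges) <- "integer"
    if (anyNA(edges) || any(edges < 1L) || any(edges > n_nodes))
      stop_input("edge indices must lie in [1, n_nodes]")
    if (any(edges[, 1L] == edges[, 2L]))
      stop_input("self-connections (i == j) are not edges")
    swap <- edges[, 1L] > edges[, 2L]
    if (any(swap)) edges[swap, ] <- edges[swap, 2:1]
    idx <- edge_index(edges[, 1L], edges[, 2L], n_nodes)
    if (anyDuplicated(idx)) stop_input("duplicate edges in mask")
    edges <- edges[order(idx), , drop = FALSE]
  }
  dimnames(edges) <- list(NULL, c("i", "j"))
  structure(edges, n_nodes = n_nodes, polarity = polarity,
            class = c("edge_mask", class(edges)))
}

#' @export
print.edge_mask <- function(x, ...) {
  cat(sprintf("<edge_mask> %d %s connection(s) over %d nodes\n",
              nrow(x), attr(x, "polarity"), attr(x, "n_nodes")))
  if (nrow(x)) {
    show <- utils::head(x, 10L)
    cat(paste(sprintf("  %d -- %d", show[, 1L], show[, 2L]), collapse = "\n"),
        "\n")
    if (nrow(x) > 10L) cat(sprintf("  ... and %d more\n", nrow(x) - 10L))
  }
  invisible(x)
}

#' Number of connections in an edge mask
#' @param mask An [edge_mask()].
#' @return Integer count.
#' @export
mask_size <- function(mask) nrow(mask)

# row-major upper-triangle indices of a mask's edges
mask_indices <- function(mask) {
  n <- attr(mask, "n_nodes")
  if (!nrow(mask)) return(integer(0))
  as.integer(edge_index(mask[, 1L], mask[, 2L], n))
}

#' Summed strength of a connection set
#'
#' Sum of Fisher-z edge strengths over the connections of a mask, each
#' unordered edge counted once. These sums are the two features
#' (`x1` positive, `x2` negative) of the CPM linear model.
#'
#' @param matrix Square symmetric connectivity matrix.
#' @param mask An [edge_mask()] with matching `n_nodes`.
#' @return A single number; 0 for an empty mask.
#' @export
summed_strength <- function(matrix, mask) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stop_input("'matrix' must be square")
  if (nrow(matrix) != attr(mask, "n_nodes"))
    stop_input(sprintf("dimension mismatch: matrix has %d nodes, mask expects %d",
                       nrow(matrix), attr(mask, "n_nodes")))
  if (!nrow(mask)) return(0)
  sum(matrix[unclass(mask)[, 1:2, drop = FALSE]])
}

#' Percentage overlap between two edge masks
#'
#' Overlap of mask `b` with reference mask `a`, reported as a percentage of
#' the reference mask's size (the convention used when checking how much of a
#' model's network survives adding a nuisance variable). A symmetric Jaccard
#' variant is also available.
#'
#' @param a Reference [edge_mask()].
#' @param b Comparison [edge_mask()] over the same nodes.
#' @param denominator `"reference"` (default): `100 * |a n b| / |a|`;
#'   `"jaccard"`: `100 * |a n b| / |a u b|`.
#' @return Percentage in `[0, 100]`.
#' @export
edge_overlap <- function(a, b, denominator = c("reference", "jaccard")) {
  denominator <- match.arg(denominator)
  if (attr(a, "n_nodes") != attr(b, "n_nodes"))
    stop_input("masks refer to different node counts")
  ia <- mask_indices(a); ib <- mask_indices(b)
  if (!length(ia)) stop_input("overlap undefined: reference mask is empty")
  inter <- length(intersect(ia, ib))
  denom <- switch(denominator,
                  reference = length(ia),
                  jaccard = length(union(ia, ib)))
  100 * inter / denom
}
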