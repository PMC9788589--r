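#' PCA of state-level profiles
#'
#' Principal components of an observations (states) x features matrix.
#' Features are always centered; unit scaling is conventional for gene
#' matrices (shared-unit flux matrices are left unscaled). Component signs
#' are fixed so the largest-magnitude loading of each component is
#' positive, making outputs byte-reproducible.
#'
#' @param mat observations x features numeric matrix with dimnames.
#' @param n_components number of components to retain (default all).
#' @param scale. unit-scale features (drop zero-variance features first).
#' @return list: `coordinates` (observations x components), `loadings`,
#'   `variance_explained` (fraction per retained component).
#' @export
pca_states <- function(mat, n_components = NULL, scale. = FALSE) {
  mat <- as.matrix(mat)
  if (scale.) {
    keep <- apply(mat, 2, stats::sd) > 0
    mat <- mat[, keep, drop = FALSE]
  }
  if (ncol(mat) == 0L || all(apply(mat, 2, stats::sd) == 0)) {
    stop("matrix has no variance; PCA undefined", call. = FALSE)
  }
  if (is.null(n_components)) n_components <- min(dim(mat)) - 1L
  n_components <- min(n_components, min(nrow(mat) - 1L, ncol(mat)))
  pc <- stats::prcomp(mat, center = TRUE, scale. = scale.)
  k <- min(n_components, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  coords <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) { rot[, j] <- -rot[, j]; coords[, j] <- -coords[, j] }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(coordinates = coords, loadings = rot,
       variance_explained = ve[seq_len(k)])
}

#' Minimum spanning tree over points or a distance matrix
#'
#' Kruskal's algorithm with edges ordered by (weight, then lexicographic
#' edge label), making the returned tree deterministic even under ties.
#'
#' @param x either an observations x features coordinate matrix (rows are
#'   named points; Euclidean distances are used) or a symmetric
#'   non-negative distance matrix with zero diagonal.
#' @return data.frame of the n-1 tree edges: `from`, `to` (with
#'   `from < to` lexicographically), `weight`.
#' @export
minimum_spanning_tree <- function(x) {
  x <- as.matrix(x)
  is_dist <- nrow(x) == ncol(x) && !is.null(rownames(x)) &&
    identical(rownames(x), colnames(x)) && all(abs(diag(x)) < 1e-12)
  if (is_dist) {
    if (max(abs(x - t(x))) > 1e-8) stop("distance matrix is not symmetric",
                                        call. = FALSE)
    if (any(x < 0)) stop("distances must be non-negative", call. = FALSE)
    D <- x
  } else {
    D <- as.matrix(stats::dist(x))
  }
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(D)))
  n <- nrow(D)
  edges <- data.frame(from = character(0), to = character(0), weight = numeric(0),
                      stringsAsFactors = FALSE)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a < b) {
      lab <- sort(c(labels[a], labels[b]), method = "radix")
      edges <- rbind(edges, data.frame(from = lab[1], to = lab[2],
                                       weight = D[a, b], stringsAsFactors = FALSE))
    }
  }
  edges <- edges[order(edges$weight, edges$from, edges$to, method = "radix"), ]
  parent <- stats::setNames(labels, labels)
  find_root <- function(v) { while (parent[[v]] != v) v <- parent[[v]]; v }
  out <- list()
  for (i in seq_len(nrow(edges))) {
    ra <- find_root(edges$from[i]); rb <- find_root(edges$to[i])
    if (ra != rb) {
      parent[[ra]] <- rb
      out[[length(out) + 1L]] <- edges[i, ]
      if (length(out) == n - 1L) break
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pseudo-temporal ordering from a minimum spanning tree
#'
#' Depth-first traversal of the tree from a chosen root (children visited
#' in lexicographic order), reporting the visit order and any branch
#' points (tree degree >= 3). A path-graph tree yields a total order.
#'
#' @param mst_edges edge data.frame from [minimum_spanning_tree()].
#' @param root state label to start from (must be in the tree).
#' @return list: `root`, `ordering` (character), `branch_points`
#'   (character, possibly empty).
#' @export
extract_trajectory <- function(mst_edges, root) {
  nodes <- sort(unique(c(mst_edges$from, mst_edges$to)), method = "radix")
  if (!(root %in% nodes)) stop("root not in tree: ", root, call. = FALSE)
  adj <- stats::setNames(lapply(nodes, function(v) {
    sort(c(mst_edges$to[mst_edges$from == v], mst_edges$from[mst_edges$to == v]),
         method = "radix")
  }), nodes)
  degree <- vapply(adj, length, integer(1))
  ordering <- character(0)
  visited <- character(0)
  stack <- root
  while (length(stack) > 0L) {
    v <- stack[1]; stack <- stack[-1]
    if (v %in% visited) next
    visited <- c(visited, v)
    ordering <- c(ordering, v)
    kids <- setdiff(adj[[v]], visited)
    stack <- c(kids, stack)
  }
  list(root = root, ordering = ordering,
       branch_points = nodes[degree >= 3L])
}

#' Check whether a sequence of states forms a path in an MST
#'
#' True when every consecutive pair of the sequence is an edge of the
#' tree — the planted-trajectory recovery criterion.
#'
#' @param mst_edges edge data.frame from [minimum_spanning_tree()].
#' @param sequence character vector of state labels.
#' @return logical scalar.
#' @export
is_mst_path <- function(mst_edges, sequence) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  edge_keys <- key(mst_edges$from, mst_edges$to)
  if (length(sequence) < 2L) return(TRUE)
  pairs <- key(sequence[-length(sequence)], sequence[-1])
  all(pairs %in% edge_keys)
}
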