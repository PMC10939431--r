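#' Hypergraphs over incidence matrices
#'
#' A hypergraph is stored as its m x n binary incidence matrix `A`
#' (rows = nodes, columns = hyperedges) together with the node degree
#' vector `d_v` (row sums) and hyperedge degree vector `d_e` (column
#' sums). In the herb channel the nodes are chemical components and the
#' hyperedges are herbs; in the disease channel the nodes are protein
#' targets and the hyperedges are diseases.
#'
#' @param A Binary matrix with node ids as rownames and hyperedge ids as
#'   colnames.
#' @return A list of class `"hypergraph"` with fields `node_ids`,
#'   `edge_ids`, `A`, `d_v`, `d_e`.
#' @export
hypergraph_from_incidence <- function(A) {
  if (!is.matrix(A)) stop("A must be a matrix")
  if (is.null(rownames(A)) || is.null(colnames(A))) {
    stop("incidence matrix needs node rownames and hyperedge colnames")
  }
  if (!all(A %in% c(0, 1))) stop("incidence entries must be 0 or 1")
  storage.mode(A) <- "double"
  out <- list(node_ids = rownames(A), edge_ids = colnames(A), A = A,
              d_v = rowSums(A), d_e = colSums(A))
  class(out) <- "hypergraph"
  out
}

#' Build a hypergraph from an association table
#'
#' With `nodes_are = "target"` (the default for herb-component tables read
#' as herb -> component) the table's target ids become the nodes and the
#' source ids the hyperedges; `"source"` swaps the roles. Row/column order
#' follows the table's sorted vocabularies, so the construction is
#' deterministic.
#'
#' @param assoc An [association_table()].
#' @param nodes_are Which side of the table supplies the nodes.
#' @return A [hypergraph_from_incidence()] object.
#' @export
build_hypergraph <- function(assoc, nodes_are = c("target", "source")) {
  stopifnot(inherits(assoc, "association_table"))
  nodes_are <- match.arg(nodes_are)
  if (nrow(assoc$edges) == 0L) stop("association table is empty")
  if (nodes_are == "target") {
    nodes <- assoc$target_vocab
    edges <- assoc$source_vocab
    ni <- match(assoc$edges$target_id, nodes)
    ei <- match(assoc$edges$source_id, edges)
  } else {
    nodes <- assoc$source_vocab
    edges <- assoc$target_vocab
    ni <- match(assoc$edges$source_id, nodes)
    ei <- match(assoc$edges$target_id, edges)
  }
  A <- matrix(0, length(nodes), length(edges), dimnames = list(nodes, edges))
  A[cbind(ni, ei)] <- 1
  hypergraph_from_incidence(A)
}

# diagonal pseudo-inverse scaling: zero degrees stay zero, keeping the
# aggregation operators total on graphs with isolated nodes/hyperedges
.inv_scale_rows <- function(M, deg) {
  inv <- ifelse(deg > 0, 1 / deg, 0)
  M * inv
}

#' Hyperedge aggregation
#'
#' `M = D_e^{-1} A^T E`: each hyperedge embedding is the arithmetic mean
#' of its member nodes' embeddings. Hyperedges with zero degree yield
#' zero rows.
#'
#' @param H A [hypergraph_from_incidence()] object.
#' @param E m x d node embedding matrix.
#' @return n x d hyperedge embedding matrix.
#' @export
hyperedge_aggregate <- function(H, E) {
  stopifnot(inherits(H, "hypergraph"))
  E <- as.matrix(E)
  if (nrow(E) != length(H$node_ids)) {
    stop("node embedding rows (", nrow(E), ") do not match node count (",
         length(H$node_ids), ")")
  }
  M <- .inv_scale_rows(crossprod(H$A, E), H$d_e)
  rownames(M) <- H$edge_ids
  M
}

#' Node aggregation
#'
#' `N = D_v^{-1} A M`: each node embedding is the mean of the embeddings
#' of the hyperedges containing it. Isolated nodes yield zero rows.
#'
#' @param H A [hypergraph_from_incidence()] object.
#' @param M n x d hyperedge embedding matrix.
#' @return m x d node embedding matrix.
#' @export
node_aggregate <- function(H, M) {
  stopifnot(inherits(H, "hypergraph"))
  M <- as.matrix(M)
  if (nrow(M) != length(H$edge_ids)) {
    stop("hyperedge embedding rows (", nrow(M),
         ") do not match hyperedge count (", length(H$edge_ids), ")")
  }
  N <- .inv_scale_rows(H$A %*% M, H$d_v)
  rownames(N) <- H$node_ids
  N
}

# the fixed propagation operator P = D_v^{-1} A D_e^{-1} A^T of a channel
.propagation_matrix <- function(H) {
  B <- .inv_scale_rows(t(H$A), H$d_e)       # D_e^{-1} A^T
  .inv_scale_rows(H$A %*% B, H$d_v)         # D_v^{-1} A (.)
}

#' One residual hypergraph convolution layer
#'
#' `E' = sigma(D_v^{-1} A D_e^{-1} A^T E Theta + E)`: node embeddings are
#' smoothed through their hyperedges, linearly transformed, and added back
#' to themselves (residual skip) before the nonlinearity, which protects
#' the original features from dilution across layers.
#'
#' @param H A [hypergraph_from_incidence()] object.
#' @param E m x d node embedding matrix.
#' @param theta Square d x d transform matrix.
#' @param activation `"relu"` or `"identity"`.
#' @return Updated m x d node embedding matrix.
#' @export
conv_layer <- function(H, E, theta, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  E <- as.matrix(E)
  theta <- as.matrix(theta)
  if (nrow(theta) != ncol(theta)) stop("theta must be square (d x d)")
  if (ncol(E) != nrow(theta)) stop("embedding width does not match theta")
  pre <- .propagation_matrix(H) %*% E %*% theta + E
  if (activation == "relu") pmax(pre, 0) else pre
}

#' Run one convolution channel
#'
#' Iterates [conv_layer()] `l` times from `E0` and records, after each
#' layer update, the hyperedge readout `M^k = D_e^{-1} A^T E^k`. The list
#' of per-layer hyperedge matrices is what the model pools into its final
#' herb/disease embeddings.
#'
#' @param H A [hypergraph_from_incidence()] object.
#' @param E0 Initial m x d node embeddings.
#' @param thetas List of `l` square d x d matrices.
#' @param activation `"relu"` or `"identity"`.
#' @return A list with `M_list` (length-`l` list of n x d hyperedge
#'   matrices) and `E_final` (node embeddings after the last layer).
#' @export
run_channel <- function(H, E0, thetas, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  if (length(thetas) < 1L) stop("need at least one layer (l >= 1)")
  E <- as.matrix(E0)
  M_list <- vector("list", length(thetas))
  for (k in seq_along(thetas)) {
    E <- conv_layer(H, E, thetas[[k]], activation)
    M_list[[k]] <- hyperedge_aggregate(H, E)
  }
  list(M_list = M_list, E_final = E)
}
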