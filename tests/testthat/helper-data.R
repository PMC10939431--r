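# shared fixture builders; everything is generated in code under fixed seeds

# a small random hypergraph with no empty nodes/edges guaranteed only
# when ensure_degree = TRUE
random_hypergraph <- function(m, n, p = 0.4, seed = 1, ensure_degree = TRUE) {
  set.seed(seed)
  A <- matrix(rbinom(m * n, 1, p), m, n)
  if (ensure_degree) {
    for (i in which(rowSums(A) == 0)) A[i, sample(n, 1)] <- 1
    for (j in which(colSums(A) == 0)) A[sample(m, 1), j] <- 1
  }
  dimnames(A) <- list(sprintf("v%02d", seq_len(m)), sprintf("e%02d", seq_len(n)))
  hypergraph_from_incidence(A)
}

random_fingerprint <- function(n_bits = 128, density = 0.2, seed = 1) {
  set.seed(seed)
  k <- max(1, rbinom(1, n_bits, density))
  fingerprint(sample(0:(n_bits - 1), k), n_bits)
}

# tiny planted dataset + pair frame for model-level tests
tiny_model_fixture <- function(seed = 11, d = 4, n_layers = 2) {
  ds <- generate_planted_dataset(n_herbs = 6, n_components = 10,
                                 n_targets = 8, n_diseases = 5,
                                 n_groups = 2, noise_rate = 0, seed = seed)
  Hh <- hypergraph_from_incidence(ds$A_ch)
  Hd <- hypergraph_from_incidence(ds$A_td)
  set.seed(seed + 1)
  E0c <- matrix(runif(nrow(ds$A_ch) * d, 0.1, 1), nrow(ds$A_ch), d,
                dimnames = list(rownames(ds$A_ch), NULL))
  E0t <- matrix(runif(nrow(ds$A_td) * d, 0.1, 1), nrow(ds$A_td), d,
                dimnames = list(rownames(ds$A_td), NULL))
  pairs <- data.frame(
    herb_id = rep(rownames(ds$A_hd), ncol(ds$A_hd)),
    disease_id = rep(colnames(ds$A_hd), each = nrow(ds$A_hd)),
    label = as.integer(ds$A_hd), stringsAsFactors = FALSE)
  list(dataset = ds,
       data = list(herb_hypergraph = Hh, disease_hypergraph = Hd,
                   E0_components = E0c, E0_targets = E0t, pairs = pairs),
       d = d, n_layers = n_layers)
}

# brute-force per-entity implementations used as independent oracles
loop_hyperedge_aggregate <- function(H, E) {
  n <- length(H$edge_ids)
  d <- ncol(E)
  M <- matrix(0, n, d)
  for (j in seq_len(n)) {
    members <- which(H$A[, j] == 1)
    if (length(members) > 0) {
      M[j, ] <- colSums(E[members, , drop = FALSE]) / length(members)
    }
  }
  M
}

loop_node_aggregate <- function(H, M) {
  m <- length(H$node_ids)
  d <- ncol(M)
  N <- matrix(0, m, d)
  for (i in seq_len(m)) {
    touching <- which(H$A[i, ] == 1)
    if (length(touching) > 0) {
      N[i, ] <- colSums(M[touching, , drop = FALSE]) / length(touching)
    }
  }
  N
}

loop_conv_layer <- function(H, E, theta, relu = TRUE) {
  pre <- loop_node_aggregate(H, loop_hyperedge_aggregate(H, E)) %*% theta + E
  if (relu) pmax(pre, 0) else pre
}

# all-pairs Mann-Whitney AUROC
loop_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + (p > q) + 0.5 * (p == q)
  }
  wins / (length(pos) * length(neg))
}

# trapezoidal integration of the ROC curve over unique thresholds
trapezoid_auroc <- function(scores, labels) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / P, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / N, 0)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}
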