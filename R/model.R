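#' Pool per-layer hyperedge embeddings into final representations
#'
#' The herb (or disease) representation is the elementwise sum of the
#' per-layer hyperedge embeddings; the `"mean"` mode (the degraded
#' average-pooling ablation) divides by the number of layers.
#'
#' @param layer_Ms Non-empty list of equal-shape n x d matrices.
#' @param mode `"sum"` or `"mean"`.
#' @return n x d matrix.
#' @export
readout_embeddings <- function(layer_Ms, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  if (length(layer_Ms) == 0L) stop("empty layer list")
  dims <- lapply(layer_Ms, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("layer matrices must share a common shape")
  }
  out <- Reduce(`+`, layer_Ms)
  if (mode == "mean") out <- out / length(layer_Ms)
  out
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.clamp_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Score herb-disease pairs by sigmoid inner product
#'
#' @param E_H Herb embedding matrix (rownames = herb ids).
#' @param E_D Disease embedding matrix (rownames = disease ids).
#' @param pairs Data frame with columns `herb_id`, `disease_id` and
#'   optionally `label`.
#' @return A data frame of class `"pair_scores"` with columns `herb_id`,
#'   `disease_id`, `label` (NA when unknown) and `prob`, probabilities
#'   clamped strictly inside (0, 1).
#' @export
score_pairs <- function(E_H, E_D, pairs) {
  hi <- match(as.character(pairs$herb_id), rownames(E_H))
  di <- match(as.character(pairs$disease_id), rownames(E_D))
  if (anyNA(hi)) stop("unknown herb id: ", pairs$herb_id[which(is.na(hi))[1]])
  if (anyNA(di)) {
    stop("unknown disease id: ", pairs$disease_id[which(is.na(di))[1]])
  }
  s <- rowSums(E_H[hi, , drop = FALSE] * E_D[di, , drop = FALSE])
  out <- data.frame(herb_id = as.character(pairs$herb_id),
                    disease_id = as.character(pairs$disease_id),
                    label = if ("label" %in% names(pairs)) {
                      as.integer(pairs$label)
                    } else NA_integer_,
                    prob = .clamp_prob(.sigmoid(s)),
                    stringsAsFactors = FALSE)
  class(out) <- c("pair_scores", class(out))
  out
}

#' Cross-entropy loss with L2 penalty on the transform matrices
#'
#' `sum_ij -[y log p + (1-y) log(1-p)] + lambda * sum_l ||Theta^l||_F^2`.
#' Probabilities are clamped to `[1e-7, 1 - 1e-7]` so the logs stay
#' finite; at `lambda = 0` the loss reduces to plain cross-entropy.
#'
#' @param scores A `pair_scores` data frame with binary `label`.
#' @param theta_set List of trainable matrices entering the penalty.
#' @param lambda Nonnegative regularisation weight.
#' @return Nonnegative scalar.
#' @export
bce_l2_loss <- function(scores, theta_set = list(), lambda = 0) {
  y <- scores$label
  if (anyNA(y) || !all(y %in% c(0L, 1L))) stop("labels must be binary")
  p <- .clamp_prob(scores$prob)
  ce <- -sum(y * log(p) + (1 - y) * log(1 - p))
  reg <- if (length(theta_set) > 0L) {
    lambda * sum(vapply(theta_set, function(m) sum(m^2), numeric(1)))
  } else 0
  ce + reg
}

# full forward pass of one channel keeping every intermediate needed by
# the backward pass
.channel_forward <- function(P, B, E0, thetas, readout) {
  l <- length(thetas)
  E_list <- vector("list", l + 1L)
  pre_list <- vector("list", l)
  PE_list <- vector("list", l)
  E_list[[1]] <- E0
  for (k in seq_len(l)) {
    PE <- P %*% E_list[[k]]
    pre <- PE %*% thetas[[k]] + E_list[[k]]
    E_list[[k + 1L]] <- pmax(pre, 0)
    PE_list[[k]] <- PE
    pre_list[[k]] <- pre
  }
  M_list <- lapply(E_list[-1L], function(E) B %*% E)
  w <- if (readout == "mean") 1 / l else 1
  R <- Reduce(`+`, M_list) * w
  list(E_list = E_list, pre_list = pre_list, PE_list = PE_list,
       M_list = M_list, readout = R, w = w)
}

# backward pass through one channel: dR is the gradient at the pooled
# readout; returns gradients for each theta
.channel_backward <- function(P, B, thetas, fw, dR, lambda) {
  l <- length(thetas)
  tP <- t(P)
  tB <- t(B)
  dE <- matrix(0, nrow(fw$E_list[[1]]), ncol(fw$E_list[[1]]))
  grads <- vector("list", l)
  for (k in rev(seq_len(l))) {
    dE <- dE + tB %*% dR * fw$w           # readout contribution to E^k
    dpre <- dE * (fw$pre_list[[k]] > 0)   # through ReLU
    grads[[k]] <- crossprod(fw$PE_list[[k]], dpre) + 2 * lambda * thetas[[k]]
    dE <- tP %*% (dpre %*% t(thetas[[k]])) + dpre
  }
  grads
}

# sum rows of `contrib` into `n` buckets given by `idx`
.scatter_rows <- function(contrib, idx, n) {
  out <- matrix(0, n, ncol(contrib))
  rs <- rowsum(contrib, idx)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

#' Train the dual-channel association model
#'
#' Jointly optimises the per-layer transform matrices of both channels
#' (the node features `E0` stay fixed) by full-batch Adam on the
#' cross-entropy + L2 objective over the supplied training pairs. The run
#' is seeded and returns a per-epoch loss trace.
#'
#' @param dataset A list with `herb_hypergraph` and `disease_hypergraph`
#'   ([hypergraph_from_incidence()] objects whose hyperedges are herbs and
#'   diseases respectively), `E0_components` and `E0_targets` (node
#'   feature matrices), and `pairs` (data frame `herb_id`, `disease_id`,
#'   `label` with both classes present).
#' @param config An [hda_config()].
#' @return A list of class `"hda_model"` carrying the trained transforms,
#'   cached herb/disease embeddings `E_H`, `E_D`, and `loss_trace`.
#' @export
train_model <- function(dataset, config = hda_config()) {
  Hh <- dataset$herb_hypergraph
  Hd <- dataset$disease_hypergraph
  stopifnot(inherits(Hh, "hypergraph"), inherits(Hd, "hypergraph"))
  pairs <- dataset$pairs
  y <- as.integer(pairs$label)
  if (length(y) == 0L || length(unique(y)) < 2L) {
    stop("training pairs must contain both positive and negative labels")
  }
  E0c <- as.matrix(dataset$E0_components)
  E0t <- as.matrix(dataset$E0_targets)
  if (ncol(E0c) != ncol(E0t)) stop("channel embedding dims differ")
  d <- ncol(E0c)
  l <- config$n_layers
  set.seed(config$seed)
  lim <- sqrt(6 / (d + d))
  thetas_h <- replicate(l, matrix(stats::runif(d * d, -lim, lim), d, d),
                        simplify = FALSE)
  thetas_d <- replicate(l, matrix(stats::runif(d * d, -lim, lim), d, d),
                        simplify = FALSE)

  Ph <- .propagation_matrix(Hh)
  Bh <- .inv_scale_rows(t(Hh$A), Hh$d_e)
  Pd <- .propagation_matrix(Hd)
  Bd <- .inv_scale_rows(t(Hd$A), Hd$d_e)

  hi <- match(as.character(pairs$herb_id), Hh$edge_ids)
  di <- match(as.character(pairs$disease_id), Hd$edge_ids)
  if (anyNA(hi) || anyNA(di)) stop("pair ids missing from hypergraphs")
  n_h <- length(Hh$edge_ids)
  n_d <- length(Hd$edge_ids)

  st_h <- lapply(thetas_h, .adam_init)
  st_d <- lapply(thetas_d, .adam_init)
  lr <- config$learning_rate
  lam <- config$lambda
  trace <- numeric(config$epochs + 1L)

  loss_of <- function(fh, fd) {
    s <- rowSums(fh$readout[hi, , drop = FALSE] *
                   fd$readout[di, , drop = FALSE])
    p <- .clamp_prob(.sigmoid(s))
    ce <- -sum(y * log(p) + (1 - y) * log(1 - p))
    reg <- lam * (sum(vapply(thetas_h, function(m) sum(m^2), numeric(1))) +
                    sum(vapply(thetas_d, function(m) sum(m^2), numeric(1))))
    list(loss = ce + reg, p = p)
  }

  fh <- .channel_forward(Ph, Bh, E0c, thetas_h, config$layer_readout)
  fd <- .channel_forward(Pd, Bd, E0t, thetas_d, config$layer_readout)
  cur <- loss_of(fh, fd)
  trace[1L] <- cur$loss

  for (epoch in seq_len(config$epochs)) {
    resid <- .sigmoid(rowSums(fh$readout[hi, , drop = FALSE] *
                                fd$readout[di, , drop = FALSE])) - y
    # gradient at the two readouts via the pair list
    dRh <- .scatter_rows(resid * fd$readout[di, , drop = FALSE], hi, n_h)
    dRd <- .scatter_rows(resid * fh$readout[hi, , drop = FALSE], di, n_d)
    g_h <- .channel_backward(Ph, Bh, thetas_h, fh, dRh, lam)
    g_d <- .channel_backward(Pd, Bd, thetas_d, fd, dRd, lam)
    for (k in seq_len(l)) {
      upd <- .adam_step(thetas_h[[k]], g_h[[k]], st_h[[k]], lr)
      thetas_h[[k]] <- upd$value
      st_h[[k]] <- upd$state
      upd <- .adam_step(thetas_d[[k]], g_d[[k]], st_d[[k]], lr)
      thetas_d[[k]] <- upd$value
      st_d[[k]] <- upd$state
    }
    fh <- .channel_forward(Ph, Bh, E0c, thetas_h, config$layer_readout)
    fd <- .channel_forward(Pd, Bd, E0t, thetas_d, config$layer_readout)
    cur <- loss_of(fh, fd)
    if (!is.finite(cur$loss)) {
      stop("model training diverged (non-finite loss); ",
           "try a smaller learning_rate")
    }
    trace[epoch + 1L] <- cur$loss
  }

  E_H <- fh$readout
  rownames(E_H) <- Hh$edge_ids
  E_D <- fd$readout
  rownames(E_D) <- Hd$edge_ids
  model <- list(thetas_herb = thetas_h, thetas_disease = thetas_d,
                herb_hypergraph = Hh, disease_hypergraph = Hd,
                E0_components = E0c, E0_targets = E0t,
                E_H = E_H, E_D = E_D,
                config = config, loss_trace = trace)
  class(model) <- "hda_model"
  model
}

#' Analytic gradient of the training objective
#'
#' Exposes the backward pass used by [train_model()] so it can be checked
#' against finite differences: returns the loss and the gradients with
#' respect to every transform matrix of both channels.
#'
#' @inheritParams train_model
#' @param thetas_herb,thetas_disease Lists of d x d transform matrices.
#' @return A list with `loss`, `grads_herb`, `grads_disease`.
#' @export
model_loss_gradient <- function(dataset, thetas_herb, thetas_disease,
                                config = hda_config()) {
  Hh <- dataset$herb_hypergraph
  Hd <- dataset$disease_hypergraph
  pairs <- dataset$pairs
  y <- as.integer(pairs$label)
  E0c <- as.matrix(dataset$E0_components)
  E0t <- as.matrix(dataset$E0_targets)
  d <- ncol(E0c)
  Ph <- .propagation_matrix(Hh)
  Bh <- .inv_scale_rows(t(Hh$A), Hh$d_e)
  Pd <- .propagation_matrix(Hd)
  Bd <- .inv_scale_rows(t(Hd$A), Hd$d_e)
  hi <- match(as.character(pairs$herb_id), Hh$edge_ids)
  di <- match(as.character(pairs$disease_id), Hd$edge_ids)
  fh <- .channel_forward(Ph, Bh, E0c, thetas_herb, config$layer_readout)
  fd <- .channel_forward(Pd, Bd, E0t, thetas_disease, config$layer_readout)
  s <- rowSums(fh$readout[hi, , drop = FALSE] * fd$readout[di, , drop = FALSE])
  p <- .clamp_prob(.sigmoid(s))
  lam <- config$lambda
  loss <- -sum(y * log(p) + (1 - y) * log(1 - p)) +
    lam * (sum(vapply(thetas_herb, function(m) sum(m^2), numeric(1))) +
             sum(vapply(thetas_disease, function(m) sum(m^2), numeric(1))))
  resid <- .sigmoid(s) - y
  n_h <- length(Hh$edge_ids)
  n_d <- length(Hd$edge_ids)
  dRh <- .scatter_rows(resid * fd$readout[di, , drop = FALSE], hi, n_h)
  dRd <- .scatter_rows(resid * fh$readout[hi, , drop = FALSE], di, n_d)
  list(loss = loss,
       grads_herb = .channel_backward(Ph, Bh, thetas_herb, fh, dRh, lam),
       grads_disease = .channel_backward(Pd, Bd, thetas_disease, fd, dRd, lam))
}

#' Score every herb-disease pair
#'
#' @param model A trained `hda_model`.
#' @return A herbs x diseases matrix of probabilities
#'   `sigmoid(E_H E_D^T)`, entries strictly inside (0, 1).
#' @export
predict_all <- function(model) {
  stopifnot(inherits(model, "hda_model"))
  .clamp_prob(.sigmoid(model$E_H %*% t(model$E_D)))
}

#' Top-ranked diseases for one herb
#'
#' Sorts one row of [predict_all()] by descending score with
#' lexicographic tie-breaking on disease id.
#'
#' @param model A trained `hda_model`.
#' @param herb_id Herb identifier.
#' @param k Number of diseases to return.
#' @return Data frame `disease_id`, `score` in rank order.
#' @export
top_predictions <- function(model, herb_id, k = 10L) {
  P <- predict_all(model)
  if (!herb_id %in% rownames(P)) stop("unknown herb id: ", herb_id)
  row <- P[herb_id, ]
  ord <- order(-row, names(row))
  data.frame(disease_id = names(row)[ord][seq_len(min(k, length(row)))],
             score = unname(row[ord][seq_len(min(k, length(row)))]),
             stringsAsFactors = FALSE)
}
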