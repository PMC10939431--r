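#' Balanced fold construction with negative sampling
#'
#' Positives are partitioned across `k` folds; an equal number of
#' negatives (within 1 on remainders) is drawn uniformly without
#' replacement from the unknown pairs, disjointly across folds, so no
#' sampled negative is reused.
#'
#' @param positives Data frame `herb_id`, `disease_id` of known
#'   associations.
#' @param all_pairs Data frame `herb_id`, `disease_id` enumerating the
#'   candidate universe (typically every herb x disease combination).
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return A list of class `"fold_split"`: `folds` (length-`k` list of
#'   data frames `herb_id`, `disease_id`, `label`) and `seed`.
#' @export
make_folds <- function(positives, all_pairs, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  pos_key <- paste(positives$herb_id, positives$disease_id, sep = "\r")
  all_key <- paste(all_pairs$herb_id, all_pairs$disease_id, sep = "\r")
  unknown <- all_pairs[!(all_key %in% pos_key), , drop = FALSE]
  n_pos <- nrow(positives)
  if (n_pos < k) stop("fewer positives than folds")
  if (nrow(unknown) < n_pos) {
    stop("insufficient unknown pairs to sample ", n_pos, " negatives (",
         nrow(unknown), " available)")
  }
  set.seed(seed)
  pos_fold <- sample(rep(seq_len(k), length.out = n_pos))
  neg_idx <- sample(nrow(unknown), n_pos)
  neg_fold <- pos_fold  # negative counts mirror positive counts per fold
  folds <- lapply(seq_len(k), function(f) {
    pos <- positives[pos_fold == f, c("herb_id", "disease_id"), drop = FALSE]
    neg <- unknown[neg_idx[neg_fold == f],
                   c("herb_id", "disease_id"), drop = FALSE]
    out <- rbind(cbind(pos, label = 1L), cbind(neg, label = 0L))
    rownames(out) <- NULL
    out
  })
  structure(list(folds = folds, seed = seed), class = "fold_split")
}

#' Confusion counts at a probability threshold
#'
#' Pairs with `prob >= threshold` are predicted positive (ties go to the
#' positive class).
#'
#' @param scores A `pair_scores` data frame with binary labels.
#' @param threshold Cut-off strictly inside (0, 1).
#' @return A list `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(scores, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  y <- as.integer(scores$label)
  pred <- as.integer(scores$prob >= threshold)
  list(TP = sum(pred == 1L & y == 1L), FP = sum(pred == 1L & y == 0L),
       FN = sum(pred == 0L & y == 1L), TN = sum(pred == 0L & y == 0L))
}

#' Recall, precision and F1 from confusion counts
#'
#' Zero-denominator cases return 0 with a warning.
#'
#' @param counts A list with `TP`, `FP`, `FN` (and optionally `TN`).
#' @return Named numeric vector `recall`, `precision`, `f1`.
#' @export
precision_recall_f1 <- function(counts) {
  tp <- counts$TP
  fp <- counts$FP
  fn <- counts$FN
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("no positive labels; recall defined as 0")
    0
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    warning("no positive predictions; precision defined as 0")
    0
  }
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  c(recall = recall, precision = precision, f1 = f1)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the fraction of positive-negative pairs in
#' which the positive scores higher, counting ties as one half. Computed
#' via midranks, so tied scores are handled exactly.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (one of each class required).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  y <- as.integer(labels)
  P <- sum(y == 1L)
  N <- sum(y == 0L)
  if (P == 0L || N == 0L) stop("need at least one positive and one negative")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - P * (P + 1) / 2) / (P * N)
}

#' Area under the precision-recall curve
#'
#' Average-precision step integration over descending unique score
#' thresholds: `sum_k (R_k - R_{k-1}) P_k`.
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  y <- as.integer(labels)
  P <- sum(y == 1L)
  if (P == 0L) stop("need at least one positive")
  thresholds <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  prev_recall <- 0
  tp <- 0
  n_pred <- 0
  for (t in thresholds) {
    sel <- scores >= t
    tp <- sum(y[sel] == 1L)
    n_pred <- sum(sel)
    recall <- tp / P
    precision <- tp / n_pred
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# evaluate one scored fold with all five metrics
.fold_metrics <- function(scores, threshold) {
  cm <- confusion_counts(scores, threshold)
  prf <- precision_recall_f1(cm)
  c(prf,
    auroc = auroc(scores$prob, scores$label),
    auprc = auprc(scores$prob, scores$label))
}

.enumerate_pairs <- function(herb_ids, disease_ids) {
  expand.grid(herb_id = herb_ids, disease_id = disease_ids,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

.positives_from_matrix <- function(A_hd) {
  idx <- which(A_hd == 1, arr.ind = TRUE)
  data.frame(herb_id = rownames(A_hd)[idx[, 1]],
             disease_id = colnames(A_hd)[idx[, 2]],
             stringsAsFactors = FALSE)
}

# node features for both channels under the configured init_mode
.initial_embeddings <- function(dataset, config) {
  d <- config$embed_dim
  if (config$init_mode == "random") {
    set.seed(config$seed + 211L)
    nc <- nrow(dataset$S_C)
    nt <- nrow(dataset$S_T)
    E0c <- matrix(stats::runif(nc * d), nc, d,
                  dimnames = list(rownames(dataset$S_C), NULL))
    E0t <- matrix(stats::runif(nt * d), nt, d,
                  dimnames = list(rownames(dataset$S_T), NULL))
  } else {
    cfg_c <- config
    cfg_c$seed <- config$seed + 101L
    cfg_t <- config
    cfg_t$seed <- config$seed + 103L
    E0c <- train_autoencoder(dataset$S_C, d, cfg_c)$embeddings
    E0t <- train_autoencoder(dataset$S_T, d, cfg_t)$embeddings
  }
  list(E0c = E0c, E0t = E0t)
}

#' Balanced k-fold cross-validation of the full pipeline
#'
#' For every repeat, folds are drawn afresh ([make_folds()] with a
#' repeat-shifted seed), the model is trained on k-1 folds and scored on
#' the held-out fold, and recall, precision, F1, AUROC and AUPRC are
#' recorded per fold. Node features are computed once per call from the
#' dataset's similarity matrices under the configured `init_mode`.
#'
#' @param dataset A list with `S_C`, `S_T` (similarity matrices), `A_ch`
#'   (components x herbs incidence), `A_td` (targets x diseases
#'   incidence) and `A_hd` (herbs x diseases 0/1 label matrix), as
#'   produced by [generate_planted_dataset()].
#' @param config An [hda_config()].
#' @param k Number of folds.
#' @param repeats Number of independent repetitions of the whole CV.
#' @param report `"mean"` (mean with sd) or `"best"` (best repeat).
#' @return A list of class `"metrics_report"`: `per_fold` data frame
#'   (repeat, fold, five metrics), `mean`, `sd`, `best`, and
#'   `fold_scores` (per-fold scored pairs for audit).
#' @export
cross_validate <- function(dataset, config = hda_config(), k = 5L,
                           repeats = 1L, report = c("mean", "best")) {
  report <- match.arg(report)
  emb <- .initial_embeddings(dataset, config)
  Hh <- hypergraph_from_incidence(dataset$A_ch)
  Hd <- hypergraph_from_incidence(dataset$A_td)
  positives <- .positives_from_matrix(dataset$A_hd)
  universe <- .enumerate_pairs(rownames(dataset$A_hd),
                               colnames(dataset$A_hd))
  rows <- list()
  fold_scores <- list()
  for (r in seq_len(repeats)) {
    fs <- make_folds(positives, universe, k, seed = config$seed + 1000L * r)
    for (f in seq_len(k)) {
      train_pairs <- do.call(rbind, fs$folds[-f])
      cfg <- config
      cfg$seed <- config$seed + 1000L * r + f
      model <- train_model(list(
        herb_hypergraph = Hh, disease_hypergraph = Hd,
        E0_components = emb$E0c, E0_targets = emb$E0t,
        pairs = train_pairs), cfg)
      sc <- score_pairs(model$E_H, model$E_D, fs$folds[[f]])
      rows[[length(rows) + 1L]] <- c(repeat_ = r, fold = f,
                                     .fold_metrics(sc,
                                                   config$classification_threshold))
      fold_scores[[length(fold_scores) + 1L]] <- sc
    }
  }
  per_fold <- as.data.frame(do.call(rbind, rows))
  metric_cols <- c("recall", "precision", "f1", "auroc", "auprc")
  by_rep <- vapply(split(per_fold, per_fold$repeat_),
                   function(df) colMeans(df[metric_cols]),
                   numeric(length(metric_cols)))
  best_rep <- which.max(by_rep["auroc", ])
  out <- list(per_fold = per_fold,
              mean = colMeans(per_fold[metric_cols]),
              sd = apply(per_fold[metric_cols], 2, stats::sd),
              best = by_rep[, best_rep],
              report = report,
              fold_scores = fold_scores)
  class(out) <- "metrics_report"
  out
}

#' Randomly flip a fraction of a binary matrix
#'
#' Exactly `round(fraction * m * n)` distinct, uniformly chosen cells are
#' flipped (0 <-> 1); deterministic under the seed.
#'
#' @param A Binary matrix.
#' @param fraction Fraction of cells to flip, in \[0, 1\].
#' @param seed Integer seed.
#' @return The perturbed matrix.
#' @export
shuffle_matrix <- function(A, fraction, seed = 1L) {
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  n_flip <- round(fraction * length(A))
  if (n_flip == 0L) return(A)
  set.seed(seed)
  idx <- sample(length(A), n_flip)
  A[idx] <- 1 - A[idx]
  A
}

#' Robustness to random structural shuffling
#'
#' At each requested level, the same fraction of cells of `A_ch`, `A_td`
#' and `A_hd` is randomly flipped and the full balanced CV is re-run on
#' the perturbed dataset, recording mean AUROC and AUPRC. When flipping
#' makes positives outnumber the remaining unknown pairs, positives are
#' uniformly downsampled to the number of available negatives so folds
#' stay balanced.
#'
#' @inheritParams cross_validate
#' @param fractions Numeric vector of flip fractions in \[0, 1\].
#' @return Data frame `fraction`, `auroc`, `auprc`.
#' @export
shuffle_experiment <- function(dataset, config = hda_config(),
                               fractions = c(0, 0.3, 0.6, 0.9), k = 5L) {
  res <- lapply(fractions, function(fr) {
    ds <- dataset
    if (fr > 0) {
      ds$A_ch <- shuffle_matrix(dataset$A_ch, fr, seed = config$seed + 11L)
      ds$A_td <- shuffle_matrix(dataset$A_td, fr, seed = config$seed + 13L)
      ds$A_hd <- shuffle_matrix(dataset$A_hd, fr, seed = config$seed + 17L)
      ds$A_hd <- .balance_labels(ds$A_hd, seed = config$seed + 19L)
    }
    rep <- cross_validate(ds, config, k = k, repeats = 1L)
    c(fraction = fr, auroc = unname(rep$mean["auroc"]),
      auprc = unname(rep$mean["auprc"]))
  })
  as.data.frame(do.call(rbind, res))
}

# downsample positives when they exceed the unknown pairs available as
# negatives, keeping balanced fold construction feasible
.balance_labels <- function(A_hd, seed) {
  n_pos <- sum(A_hd == 1)
  n_unk <- length(A_hd) - n_pos
  if (n_pos <= n_unk) return(A_hd)
  set.seed(seed)
  drop_n <- n_pos - n_unk
  pos_idx <- which(A_hd == 1)
  A_hd[sample(pos_idx, drop_n)] <- 0
  A_hd
}

#' Cold-start split for one held-out herb
#'
#' All positives of the chosen herb plus an equal number of sampled
#' negatives among that herb's unknown pairs form the test set; training
#' keeps every other herb's positives (plus sampled negatives). The
#' held-out herb stays in the herb-component hypergraph, so its embedding
#' is still computed structurally.
#'
#' @param dataset As in [cross_validate()].
#' @param herb_id The herb whose associations are withheld.
#' @param seed Integer seed for negative sampling.
#' @return A list with `train` and `test` data frames (`herb_id`,
#'   `disease_id`, `label`).
#' @export
cold_start_split <- function(dataset, herb_id, seed = 1L) {
  A_hd <- dataset$A_hd
  if (!herb_id %in% rownames(A_hd)) stop("unknown herb id: ", herb_id)
  pos_dis <- colnames(A_hd)[A_hd[herb_id, ] == 1]
  if (length(pos_dis) == 0L) stop("herb '", herb_id, "' has no known HDAs")
  unk_dis <- colnames(A_hd)[A_hd[herb_id, ] == 0]
  if (length(unk_dis) < length(pos_dis)) {
    stop("not enough unknown pairs for herb '", herb_id, "'")
  }
  set.seed(seed)
  neg_dis <- sample(unk_dis, length(pos_dis))
  test <- data.frame(
    herb_id = herb_id,
    disease_id = c(pos_dis, neg_dis),
    label = rep(c(1L, 0L), c(length(pos_dis), length(neg_dis))),
    stringsAsFactors = FALSE)

  rest <- A_hd[setdiff(rownames(A_hd), herb_id), , drop = FALSE]
  train_pos <- .positives_from_matrix(rest)
  universe <- .enumerate_pairs(rownames(rest), colnames(rest))
  key <- paste(universe$herb_id, universe$disease_id, sep = "\r")
  pos_key <- paste(train_pos$herb_id, train_pos$disease_id, sep = "\r")
  unknown <- universe[!(key %in% pos_key), , drop = FALSE]
  neg_idx <- sample(nrow(unknown), min(nrow(train_pos), nrow(unknown)))
  train <- rbind(cbind(train_pos, label = 1L),
                 cbind(unknown[neg_idx, ], label = 0L))
  rownames(train) <- NULL
  list(train = train, test = test)
}

#' Cold-start evaluation over several held-out herbs
#'
#' @inheritParams cross_validate
#' @param n_herbs Number of herbs (with at least one association) to hold
#'   out, each evaluated independently.
#' @return Data frame `herb_id`, `auroc`, `auprc`.
#' @export
cold_start_experiment <- function(dataset, config = hda_config(),
                                  n_herbs = 5L) {
  emb <- .initial_embeddings(dataset, config)
  Hh <- hypergraph_from_incidence(dataset$A_ch)
  Hd <- hypergraph_from_incidence(dataset$A_td)
  eligible <- rownames(dataset$A_hd)[rowSums(dataset$A_hd) >= 1]
  set.seed(config$seed + 31L)
  held <- sample(eligible, min(n_herbs, length(eligible)))
  res <- lapply(seq_along(held), function(i) {
    split <- cold_start_split(dataset, held[i], seed = config$seed + 41L + i)
    cfg <- config
    cfg$seed <- config$seed + 51L + i
    model <- train_model(list(
      herb_hypergraph = Hh, disease_hypergraph = Hd,
      E0_components = emb$E0c, E0_targets = emb$E0t,
      pairs = split$train), cfg)
    sc <- score_pairs(model$E_H, model$E_D, split$test)
    c(auroc = auroc(sc$prob, sc$label), auprc = auprc(sc$prob, sc$label))
  })
  data.frame(herb_id = held, do.call(rbind, res), stringsAsFactors = FALSE)
}

#' Run one ablation variant
#'
#' Each variant flips exactly one switch relative to the supplied
#' configuration: `"m"` mean readout, `"s"` random node features, `"t"`
#' Tanimoto component similarity, `"b"` BLOSUM62 sequence similarity,
#' `"c"` the cold-start protocol. Variants `"t"` and `"b"` recompute the
#' relevant similarity matrix and therefore need `fingerprints` (a list
#' of [fingerprint()]s) or `sequences` (named character vector) attached
#' to the dataset.
#'
#' @param variant One of `"m"`, `"s"`, `"t"`, `"b"`, `"c"`.
#' @inheritParams cross_validate
#' @return A `metrics_report` (or the [cold_start_experiment()] data
#'   frame for `"c"`), with the variant configuration attached as
#'   attribute `"config"`.
#' @export
run_ablation <- function(variant = c("m", "s", "t", "b", "c"), dataset,
                         config = hda_config(), k = 5L, repeats = 1L) {
  variant <- match.arg(variant)
  cfg <- config
  ds <- dataset
  if (variant == "m") {
    cfg$layer_readout <- "mean"
  } else if (variant == "s") {
    cfg$init_mode <- "random"
  } else if (variant == "t") {
    if (is.null(dataset$fingerprints)) {
      stop("variant 't' needs fingerprints attached to the dataset")
    }
    cfg$component_similarity <- "tanimoto"
    ds$S_C <- .similarity_from_fingerprints(dataset$fingerprints,
                                            tanimoto_similarity)
  } else if (variant == "b") {
    if (is.null(dataset$sequences)) {
      stop("variant 'b' needs sequences attached to the dataset")
    }
    cfg$sequence_scheme <- "blosum62"
    ds$S_T <- target_similarity_matrix(dataset$sequences, cfg)
  }
  out <- if (variant == "c") {
    cold_start_experiment(ds, cfg)
  } else {
    cross_validate(ds, cfg, k = k, repeats = repeats)
  }
  attr(out, "config") <- cfg
  out
}

.similarity_from_fingerprints <- function(fps, simfun) {
  ids <- names(fps)
  n <- length(ids)
  m <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        m[i, j] <- m[j, i] <- simfun(fps[[i]], fps[[j]])
      }
    }
  }
  dimnames(m) <- list(ids, ids)
  m
}
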