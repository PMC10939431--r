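toy_positives <- function(n_herbs = 8, n_dis = 6, n_pos = 10, seed = 1) {
  set.seed(seed)
  universe <- expand.grid(herb_id = sprintf("h%d", 1:n_herbs),
                          disease_id = sprintf("d%d", 1:n_dis),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  list(universe = universe,
       positives = universe[sample(nrow(universe), n_pos), ])
}

test_that("balanced folds partition positives and sample disjoint negatives", {
  tp <- toy_positives()
  fs <- make_folds(tp$positives, tp$universe, k = 5, seed = 2)
  expect_length(fs$folds, 5L)
  pos_keys <- unlist(lapply(fs$folds, function(f) {
    with(f[f$label == 1, ], paste(herb_id, disease_id))
  }))
  expect_setequal(pos_keys, with(tp$positives, paste(herb_id, disease_id)))
  expect_false(anyDuplicated(pos_keys) > 0)
  for (f in fs$folds) expect_equal(sum(f$label == 1), sum(f$label == 0))
  # 10 positives over 5 folds -> 2 + 2 per fold
  expect_true(all(vapply(fs$folds, nrow, 0L) == 4L))

  expect_identical(make_folds(tp$positives, tp$universe, 5, seed = 2), fs)
})

test_that("fold invariants hold across many seeds", {
  tp <- toy_positives(n_herbs = 10, n_dis = 8, n_pos = 23, seed = 3)
  pos_key <- with(tp$positives, paste(herb_id, disease_id))
  for (s in 1:50) {
    fs <- make_folds(tp$positives, tp$universe, k = 5, seed = s)
    neg_keys <- unlist(lapply(fs$folds, function(f) {
      with(f[f$label == 0, ], paste(herb_id, disease_id))
    }))
    expect_false(any(neg_keys %in% pos_key))       # negatives are unknowns
    expect_false(anyDuplicated(neg_keys) > 0)      # disjoint across folds
    for (f in fs$folds) {
      expect_lte(abs(sum(f$label == 1) - sum(f$label == 0)), 1L)
    }
  }
})

test_that("infeasible negative sampling errors out", {
  uni <- expand.grid(herb_id = c("h1", "h2"), disease_id = c("d1", "d2"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  expect_error(make_folds(uni[1:3, ], uni, k = 2, seed = 1), "insufficient")
})

test_that("confusion counts respect the tie-goes-positive rule", {
  sc <- data.frame(prob = c(0.9, 0.4), label = c(1L, 1L))
  cm <- confusion_counts(sc, 0.5)
  expect_equal(cm[c("TP", "FN")], list(TP = 1L, FN = 1L))

  tie <- data.frame(prob = 0.5, label = 0L)
  expect_equal(confusion_counts(tie, 0.5)$FP, 1L)

  perfect <- data.frame(prob = c(0.9, 0.1), label = c(1L, 0L))
  cm2 <- confusion_counts(perfect, 0.5)
  expect_equal(cm2$FP + cm2$FN, 0L)
})

test_that("precision/recall/F1 match direct arithmetic and conventions", {
  m <- precision_recall_f1(list(TP = 2, FP = 1, FN = 1))
  expect_equal(unname(m), rep(2 / 3, 3))
  expect_equal(unname(precision_recall_f1(list(TP = 3, FP = 0, FN = 0))),
               c(1, 1, 1))
  suppressWarnings(
    expect_equal(unname(precision_recall_f1(list(TP = 0, FP = 2, FN = 1))["f1"]),
                 0))
})

test_that("auroc equals all-pairs counting and trapezoidal integration", {
  expect_equal(auroc(c(0.9, 0.3, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "negative")

  set.seed(17)
  for (i in 1:200) {
    n <- sample(6:30, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), sample(1:3, 1))  # coarse grid induces ties
    a <- auroc(scores, labels)
    expect_lt(abs(a - loop_auroc(scores, labels)), 1e-10)
    expect_lt(abs(a - trapezoid_auroc(scores, labels)), 1e-10)
  }
})

test_that("auroc and auprc agree with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  labels <- rbinom(60, 1, 0.4)
  labels[1:2] <- c(0, 1)
  scores <- runif(60)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auroc(scores, labels), ref, tolerance = 1e-10)
})

test_that("auprc matches a hand-enumerated step sum", {
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auprc(0.7, 1), 1)
  # both positives ranked last among 4: steps (R=1/2, P=1/3), (R=1, P=1/2)
  expect_equal(auprc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)),
               0.5 * (1 / 3) + 0.5 * (1 / 2))
  expect_error(auprc(c(0.5, 0.6), c(0, 0)), "positive")
})

test_that("shuffle_matrix flips the exact number of uniformly chosen cells", {
  A <- matrix(rbinom(100, 1, 0.3), 10, 10)
  expect_identical(shuffle_matrix(A, 0, seed = 1), A)
  B <- shuffle_matrix(A, 0.1, seed = 4)
  expect_equal(sum(B != A), 10L)
  expect_identical(shuffle_matrix(A, 0.1, seed = 4), B)
  expect_equal(shuffle_matrix(A, 1, seed = 2), 1 - A)
  expect_error(shuffle_matrix(A, 1.2), "fraction")
})

test_that("cold-start split is balanced and disjoint from training", {
  ds <- generate_planted_dataset(n_herbs = 12, n_components = 24,
                                 n_targets = 16, n_diseases = 10,
                                 n_groups = 3, noise_rate = 0, seed = 19)
  herb <- rownames(ds$A_hd)[which(rowSums(ds$A_hd) >= 2)[1]]
  split <- cold_start_split(ds, herb, seed = 3)
  expect_equal(sum(split$test$label == 1), sum(split$test$label == 0))
  expect_true(all(split$test$herb_id == herb))
  expect_false(herb %in% split$train$herb_id)
  test_key <- with(split$test, paste(herb_id, disease_id))
  train_key <- with(split$train, paste(herb_id, disease_id))
  expect_length(intersect(test_key, train_key), 0L)
  expect_error(cold_start_split(ds, "nonexistent"), "unknown herb")
})

test_that("cross-validation reports are reproducible and self-consistent", {
  ds <- generate_planted_dataset(n_herbs = 14, n_components = 24,
                                 n_targets = 16, n_diseases = 12,
                                 n_groups = 2, noise_rate = 0, seed = 23)
  cfg <- hda_config(embed_dim = 8, n_layers = 2, epochs = 60,
                    ae_epochs = 60, seed = 2)
  r1 <- cross_validate(ds, cfg, k = 3, repeats = 2)
  r2 <- cross_validate(ds, cfg, k = 3, repeats = 2)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_equal(nrow(r1$per_fold), 6L)
  # metrics recomputed offline from the saved per-fold scores must match
  for (i in seq_len(nrow(r1$per_fold))) {
    sc <- r1$fold_scores[[i]]
    expect_equal(r1$per_fold$auroc[i], auroc(sc$prob, sc$label))
    expect_equal(r1$per_fold$auprc[i], auprc(sc$prob, sc$label))
  }
  expect_true(all(unlist(r1$per_fold[, 3:7]) >= 0 &
                    unlist(r1$per_fold[, 3:7]) <= 1))
})

test_that("ablation variants flip exactly one configured switch", {
  ds <- generate_planted_dataset(n_herbs = 14, n_components = 24,
                                 n_targets = 16, n_diseases = 12,
                                 n_groups = 3, noise_rate = 0, seed = 29,
                                 with_molecules = TRUE)
  cfg <- hda_config(embed_dim = 8, n_layers = 2, epochs = 40,
                    ae_epochs = 40, seed = 3)
  rm_ <- run_ablation("m", ds, cfg, k = 2)
  expect_equal(attr(rm_, "config")$layer_readout, "mean")
  rs <- run_ablation("s", ds, cfg, k = 2)
  expect_equal(attr(rs, "config")$init_mode, "random")
  rs2 <- run_ablation("s", ds, cfg, k = 2)
  expect_identical(rs$per_fold, rs2$per_fold)

  rt <- run_ablation("t", ds, cfg, k = 2)
  expect_equal(attr(rt, "config")$component_similarity, "tanimoto")
  rb <- run_ablation("b", ds, cfg, k = 2)
  expect_equal(attr(rb, "config")$sequence_scheme, "blosum62")

  ds2 <- ds
  ds2$fingerprints <- NULL
  expect_error(run_ablation("t", ds2, cfg), "fingerprints")
})
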