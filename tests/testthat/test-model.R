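test_that("readout pooling sums or averages layer matrices", {
  a <- matrix(1, 1, 1)
  b <- matrix(3, 1, 1)
  expect_equal(readout_embeddings(list(a, b), "sum"), matrix(4, 1, 1))
  expect_equal(readout_embeddings(list(a, b), "mean"), matrix(2, 1, 1))
  expect_equal(readout_embeddings(list(b), "sum"), b)
  expect_equal(readout_embeddings(list(b), "mean"), b)
  X <- matrix(rnorm(6), 2, 3)
  expect_equal(readout_embeddings(rep(list(X), 4), "mean"), X)
  expect_error(readout_embeddings(list()), "empty")
  expect_error(readout_embeddings(list(a, matrix(0, 2, 2))), "shape")
})

test_that("pair scores follow the sigmoid inner product closed form", {
  E_H <- rbind(h1 = c(0, 0), h2 = c(log(3), 0), h3 = c(-log(3), 0))
  E_D <- rbind(d1 = c(1, 0))
  sc <- score_pairs(E_H, E_D, data.frame(herb_id = c("h1", "h2", "h3"),
                                         disease_id = "d1"))
  expect_equal(sc$prob, c(0.5, 0.75, 0.25))
  expect_error(score_pairs(E_H, E_D, data.frame(herb_id = "zz",
                                                disease_id = "d1")),
               "unknown herb")
})

test_that("cross-entropy loss reproduces closed forms and the L2 term", {
  sc <- data.frame(herb_id = "h", disease_id = "d", label = 1L, prob = 0.5)
  expect_equal(bce_l2_loss(sc), log(2), tolerance = 1e-12)

  ideal <- data.frame(herb_id = c("h", "h"), disease_id = c("d1", "d2"),
                      label = c(1L, 0L), prob = c(1 - 1e-9, 1e-9))
  expect_lt(bce_l2_loss(ideal), 1e-6)
  expect_equal(bce_l2_loss(ideal, theta_set = list(matrix(2, 1, 1)),
                           lambda = 1), 4, tolerance = 1e-6)

  # loss is non-decreasing in lambda for fixed parameters
  losses <- vapply(c(0, 0.1, 1, 10), function(l) {
    bce_l2_loss(sc, theta_set = list(diag(2)), lambda = l)
  }, numeric(1))
  expect_true(all(diff(losses) >= 0))
})

test_that("analytic gradients match central finite differences", {
  fx <- tiny_model_fixture()
  cfg <- hda_config(embed_dim = fx$d, n_layers = fx$n_layers,
                    lambda = 0.01, seed = 5)
  set.seed(21)
  th <- replicate(fx$n_layers, matrix(rnorm(fx$d^2, sd = 0.3), fx$d, fx$d),
                  simplify = FALSE)
  td <- replicate(fx$n_layers, matrix(rnorm(fx$d^2, sd = 0.3), fx$d, fx$d),
                  simplify = FALSE)
  g <- model_loss_gradient(fx$data, th, td, cfg)
  eps <- 1e-6
  set.seed(22)
  probe <- cbind(sample(fx$n_layers, 8, TRUE), sample(fx$d, 8, TRUE),
                 sample(fx$d, 8, TRUE), sample(2, 8, TRUE))
  for (row in seq_len(nrow(probe))) {
    k <- probe[row, 1]; i <- probe[row, 2]; j <- probe[row, 3]
    herb_side <- probe[row, 4] == 1
    thp <- th; tdp <- td; thm <- th; tdm <- td
    if (herb_side) {
      thp[[k]][i, j] <- thp[[k]][i, j] + eps
      thm[[k]][i, j] <- thm[[k]][i, j] - eps
    } else {
      tdp[[k]][i, j] <- tdp[[k]][i, j] + eps
      tdm[[k]][i, j] <- tdm[[k]][i, j] - eps
    }
    fd <- (model_loss_gradient(fx$data, thp, tdp, cfg)$loss -
             model_loss_gradient(fx$data, thm, tdm, cfg)$loss) / (2 * eps)
    an <- if (herb_side) g$grads_herb[[k]][i, j] else g$grads_disease[[k]][i, j]
    expect_lt(abs(fd - an), 1e-4)
  }
})

test_that("swapping the two channels transposes the objective", {
  fx <- tiny_model_fixture()
  cfg <- hda_config(embed_dim = fx$d, n_layers = 2, lambda = 0, seed = 5)
  set.seed(31)
  th <- replicate(2, matrix(rnorm(16, sd = 0.3), 4, 4), simplify = FALSE)
  td <- replicate(2, matrix(rnorm(16, sd = 0.3), 4, 4), simplify = FALSE)
  swapped <- list(
    herb_hypergraph = fx$data$disease_hypergraph,
    disease_hypergraph = fx$data$herb_hypergraph,
    E0_components = fx$data$E0_targets,
    E0_targets = fx$data$E0_components,
    pairs = data.frame(herb_id = fx$data$pairs$disease_id,
                       disease_id = fx$data$pairs$herb_id,
                       label = fx$data$pairs$label))
  l1 <- model_loss_gradient(fx$data, th, td, cfg)$loss
  l2 <- model_loss_gradient(swapped, td, th, cfg)$loss
  expect_equal(l1, l2, tolerance = 1e-10)
})

test_that("training reduces the loss, is seeded, and needs both classes", {
  fx <- tiny_model_fixture()
  cfg <- hda_config(embed_dim = fx$d, n_layers = 2, epochs = 200, seed = 9)
  m1 <- train_model(fx$data, cfg)
  expect_lt(tail(m1$loss_trace, 1), 0.5 * m1$loss_trace[1])
  m2 <- train_model(fx$data, cfg)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$E_H, m2$E_H)

  all_pos <- fx$data
  all_pos$pairs$label <- 1L
  expect_error(train_model(all_pos, cfg), "both positive and negative")
})

test_that("predict_all is consistent with score_pairs and ranked output", {
  fx <- tiny_model_fixture()
  cfg <- hda_config(embed_dim = fx$d, n_layers = 2, epochs = 50, seed = 9)
  model <- train_model(fx$data, cfg)
  P <- predict_all(model)
  expect_true(all(P > 0 & P < 1))
  h <- rownames(P)[2]
  d <- colnames(P)[3]
  sc <- score_pairs(model$E_H, model$E_D,
                    data.frame(herb_id = h, disease_id = d))
  expect_equal(unname(P[h, d]), sc$prob)

  top <- top_predictions(model, h, k = 3)
  row <- P[h, ]
  ord <- order(-row, names(row))
  expect_equal(top$disease_id, names(row)[ord][1:3])
})
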