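# independent oracle: herb -> component -> group link -> target -> disease
transitive_labels <- function(ds) {
  n_h <- ncol(ds$A_ch)
  n_d <- ncol(ds$A_td)
  out <- matrix(0L, n_h, n_d,
                dimnames = list(colnames(ds$A_ch), colnames(ds$A_td)))
  for (h in seq_len(n_h)) {
    for (dd in seq_len(n_d)) {
      hit <- FALSE
      for (ci in which(ds$A_ch[, h] == 1)) {
        for (ti in which(ds$A_td[, dd] == 1)) {
          if (ds$group_link[ds$groups_c[ci], ds$groups_t[ti]] == 1) hit <- TRUE
        }
      }
      out[h, dd] <- as.integer(hit)
    }
  }
  out
}

test_that("noise-free labels equal the brute-force transitive computation", {
  ds <- generate_planted_dataset(n_herbs = 10, n_components = 20,
                                 n_targets = 14, n_diseases = 8,
                                 n_groups = 3, noise_rate = 0, seed = 37)
  expect_identical(ds$A_hd, transitive_labels(ds))
})

test_that("generation is deterministic under the seed", {
  d1 <- generate_planted_dataset(n_herbs = 10, n_components = 20,
                                 n_targets = 14, n_diseases = 8,
                                 n_groups = 3, noise_rate = 0.1, seed = 5)
  d2 <- generate_planted_dataset(n_herbs = 10, n_components = 20,
                                 n_targets = 14, n_diseases = 8,
                                 n_groups = 3, noise_rate = 0.1, seed = 5)
  expect_identical(d1, d2)
})

test_that("a single group makes every herb-disease pair positive", {
  ds <- generate_planted_dataset(n_herbs = 6, n_components = 12,
                                 n_targets = 10, n_diseases = 5,
                                 n_groups = 1, noise_rate = 0, seed = 4)
  expect_true(all(ds$A_hd == 1L))
})

test_that("noise flips the declared fraction of label cells", {
  base <- generate_planted_dataset(n_herbs = 10, n_components = 20,
                                   n_targets = 14, n_diseases = 8,
                                   n_groups = 3, noise_rate = 0, seed = 41)
  clean <- transitive_labels(base)
  noisy <- generate_planted_dataset(n_herbs = 10, n_components = 20,
                                    n_targets = 14, n_diseases = 8,
                                    n_groups = 3, noise_rate = 0.1, seed = 41)
  # same structural draw, so differences are exactly the flipped cells
  expect_identical(noisy$A_ch, base$A_ch)
  expect_equal(sum(noisy$A_hd != clean), round(0.1 * length(clean)))
})

test_that("similarity blocks separate within- from between-group entries", {
  ds <- generate_planted_dataset(seed = 7)
  expect_silent(validate_similarity_matrix(ds$S_C))
  expect_silent(validate_similarity_matrix(ds$S_T))
  same <- outer(ds$groups_c, ds$groups_c, "==")
  off <- !diag(TRUE, nrow(ds$S_C))
  expect_gt(mean(ds$S_C[same & off]), mean(ds$S_C[!same]))
})

test_that("toy fingerprints share group cores with bounded Dice", {
  groups <- rep(1:2, each = 4)
  fps <- generate_toy_fingerprints(8, 256, groups, seed = 13,
                                   core_bits = 24, private_bits = 8)
  expect_length(fps, 8L)
  expect_identical(fps,
                   generate_toy_fingerprints(8, 256, groups, seed = 13,
                                             core_bits = 24, private_bits = 8))
  # members of one group share >= the 24 core bits out of <= 32 each
  d <- dice_similarity(fps[[1]], fps[[2]])
  expect_gte(d, 2 * 24 / (32 + 32))
  expect_equal(generate_toy_fingerprints(0, 256, integer(0), seed = 1), list())
})

test_that("toy sequences track the requested mutation rate", {
  groups <- rep(1:2, each = 5)
  s0 <- generate_toy_sequences(10, 40, groups, mutation_rate = 0, seed = 3)
  expect_equal(sequence_similarity(s0[1], s0[2]), 1)

  rate <- 0.2
  s <- generate_toy_sequences(60, 50, rep(1, 60), mutation_rate = rate,
                              seed = 11)
  # observed within-group identity vs binomial expectation (3 sd band);
  # two mutated copies agree per site w.p. at least (1-rate)^2
  id12 <- mean(strsplit(s[1], "")[[1]] == strsplit(s[2], "")[[1]])
  p <- (1 - rate)^2
  expect_gt(id12, p - 3 * sqrt(p * (1 - p) / 50))
  expect_identical(s, generate_toy_sequences(60, 50, rep(1, 60),
                                             mutation_rate = rate, seed = 11))
})

test_that("written synthetic datasets are a drop-in for the IO layer", {
  ds <- generate_planted_dataset(n_herbs = 8, n_components = 16,
                                 n_targets = 12, n_diseases = 6,
                                 n_groups = 2, noise_rate = 0, seed = 31)
  dir <- withr::local_tempdir()
  write_synthetic_dataset(ds, dir)
  hc <- read_association_table(file.path(dir, "herb_component.tsv"))
  H <- build_hypergraph(hc, nodes_are = "target")
  # unused components drop out of the edge list; incidences must agree
  expect_equal(H$A,
               ds$A_ch[rownames(ds$A_ch) %in% rownames(H$A),
                       colnames(ds$A_ch) %in% colnames(H$A)])
  S_C <- read_matrix_tsv(file.path(dir, "similarity_components.tsv"))
  expect_equal(S_C, ds$S_C, tolerance = 1e-12)
})
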