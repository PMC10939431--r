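#' Planted-structure synthetic dataset
#'
#' Generates a fully self-contained benchmark with the structure the
#' model assumes. Components and protein targets are partitioned into
#' latent groups; each component group is linked to one or more target
#' groups (latent bioactivity). Every herb draws 2-8 components from its
#' primary component group and every disease draws 2-8 targets from its
#' primary target group, mirroring the multi-component / multi-target
#' premise while keeping the herb-disease label matrix balanced enough to
#' sample negatives from. Similarity matrices are block-structured:
#' within-group entries ~ Beta(8, 2), between-group ~ Beta(2, 8),
#' symmetrised with unit diagonal. The ground-truth label
#' `A_hd[i, j] = 1` iff some component group of herb i is linked to some
#' target group of disease j; a fraction `noise_rate` of label cells is
#' then flipped.
#'
#' @param n_herbs,n_components,n_targets,n_diseases Entity counts.
#' @param n_groups Number of latent groups on each side.
#' @param noise_rate Fraction of label cells flipped, in \[0, 0.5).
#' @param seed Integer seed; every draw is derived from it.
#' @param with_molecules If `TRUE`, also attach toy fingerprints (for the
#'   Tanimoto ablation) and toy protein sequences (for the BLOSUM62
#'   ablation) consistent with the group assignments.
#' @return A list of class `"synthetic_dataset"` with `S_C`, `S_T`,
#'   `A_ch` (components x herbs), `A_td` (targets x diseases), `A_hd`
#'   (herbs x diseases), group assignments `groups_c`, `groups_t`, herb
#'   and disease primary groups, the group link matrix, the generation
#'   parameters, and optionally `fingerprints` and `sequences`.
#' @export
generate_planted_dataset <- function(n_herbs = 60L, n_components = 120L,
                                     n_targets = 80L, n_diseases = 50L,
                                     n_groups = 4L, noise_rate = 0.05,
                                     seed = 7L, with_molecules = FALSE) {
  if (n_components < n_groups || n_targets < n_groups) {
    stop("need at least one component and target per group")
  }
  if (n_herbs < 1L || n_diseases < 1L) stop("need at least one herb/disease")
  if (noise_rate < 0 || noise_rate >= 0.5) {
    stop("noise_rate must lie in [0, 0.5)")
  }
  set.seed(seed)

  comp_ids <- sprintf("c%03d", seq_len(n_components))
  targ_ids <- sprintf("t%03d", seq_len(n_targets))
  herb_ids <- sprintf("h%03d", seq_len(n_herbs))
  dis_ids <- sprintf("d%03d", seq_len(n_diseases))

  groups_c <- stats::setNames(rep(seq_len(n_groups),
                                  length.out = n_components), comp_ids)
  groups_t <- stats::setNames(rep(seq_len(n_groups),
                                  length.out = n_targets), targ_ids)

  # latent bioactivity: every component group acts on its own target
  # group and, with probability 0.3, on one additional group
  link <- diag(1, n_groups)
  for (g in seq_len(n_groups)) {
    if (n_groups > 1L && stats::runif(1) < 0.3) {
      extra <- sample(setdiff(seq_len(n_groups), g), 1L)
      link[g, extra] <- 1
    }
  }

  S_C <- .block_similarity(groups_c)
  S_T <- .block_similarity(groups_t)

  herb_group <- sample(seq_len(n_groups), n_herbs, replace = TRUE)
  dis_group <- sample(seq_len(n_groups), n_diseases, replace = TRUE)

  A_ch <- matrix(0, n_components, n_herbs,
                 dimnames = list(comp_ids, herb_ids))
  for (h in seq_len(n_herbs)) {
    pool <- which(groups_c == herb_group[h])
    size <- sample(2:8, 1L)
    A_ch[sample(pool, min(size, length(pool))), h] <- 1
  }
  A_td <- matrix(0, n_targets, n_diseases,
                 dimnames = list(targ_ids, dis_ids))
  for (dd in seq_len(n_diseases)) {
    pool <- which(groups_t == dis_group[dd])
    size <- sample(2:8, 1L)
    A_td[sample(pool, min(size, length(pool))), dd] <- 1
  }

  # transitive ground truth herb -> component group -> target group ->
  # disease, then label noise
  A_hd <- matrix(0L, n_herbs, n_diseases, dimnames = list(herb_ids, dis_ids))
  for (h in seq_len(n_herbs)) {
    cg <- unique(groups_c[A_ch[, h] == 1])
    if (length(cg) == 0L) next
    reach <- which(colSums(link[cg, , drop = FALSE]) > 0)
    for (dd in seq_len(n_diseases)) {
      tg <- unique(groups_t[A_td[, dd] == 1])
      if (length(intersect(reach, tg)) > 0L) A_hd[h, dd] <- 1L
    }
  }
  n_flip <- round(noise_rate * length(A_hd))
  if (n_flip > 0L) {
    idx <- sample(length(A_hd), n_flip)
    A_hd[idx] <- 1L - A_hd[idx]
  }

  out <- list(S_C = S_C, S_T = S_T, A_ch = A_ch, A_td = A_td, A_hd = A_hd,
              groups_c = groups_c, groups_t = groups_t,
              herb_group = herb_group, disease_group = dis_group,
              group_link = link,
              params = list(n_herbs = n_herbs, n_components = n_components,
                            n_targets = n_targets, n_diseases = n_diseases,
                            n_groups = n_groups, noise_rate = noise_rate,
                            seed = seed))
  if (with_molecules) {
    out$fingerprints <- generate_toy_fingerprints(
      n_components, 256L, groups_c, seed = seed + 1L)
    names(out$fingerprints) <- comp_ids
    out$sequences <- generate_toy_sequences(
      n_targets, 40L, groups_t, mutation_rate = 0.1, seed = seed + 2L)
    names(out$sequences) <- targ_ids
  }
  class(out) <- "synthetic_dataset"
  out
}

# block similarity: within-group ~ Beta(8, 2), between ~ Beta(2, 8),
# symmetric, unit diagonal
.block_similarity <- function(groups) {
  n <- length(groups)
  same <- outer(groups, groups, "==")
  m <- matrix(0, n, n)
  ut <- upper.tri(m)
  n_ut <- sum(ut)
  vals <- numeric(n_ut)
  within <- same[ut]
  vals[within] <- stats::rbeta(sum(within), 8, 2)
  vals[!within] <- stats::rbeta(sum(!within), 2, 8)
  m[ut] <- vals
  m <- m + t(m)
  diag(m) <- 1
  dimnames(m) <- list(names(groups), names(groups))
  m
}

#' Toy fingerprints with group structure
#'
#' Members of a group share a common core of on-bits and add private
#' random bits, so within-group Dice similarity exceeds between-group
#' similarity in expectation.
#'
#' @param n Number of fingerprints.
#' @param n_bits Bit-vector length (>= 64).
#' @param group_assignments Integer group label per fingerprint.
#' @param seed Integer seed.
#' @param core_bits,private_bits Number of shared and private on-bits.
#' @return List of [fingerprint()]s.
#' @export
generate_toy_fingerprints <- function(n, n_bits = 256L, group_assignments,
                                      seed = 1L, core_bits = 24L,
                                      private_bits = 8L) {
  if (n == 0L) return(list())
  if (n_bits < 64L) stop("n_bits must be >= 64")
  stopifnot(length(group_assignments) == n)
  set.seed(seed)
  groups <- sort(unique(group_assignments))
  cores <- lapply(groups, function(g) sample(0:(n_bits - 1L), core_bits))
  names(cores) <- as.character(groups)
  lapply(seq_len(n), function(i) {
    core <- cores[[as.character(group_assignments[i])]]
    priv <- sample(setdiff(0:(n_bits - 1L), core), private_bits)
    fingerprint(c(core, priv), n_bits)
  })
}

#' Toy protein sequences with group structure
#'
#' Each group has a random ancestor sequence; members are point-mutated
#' copies, so expected within-group identity is `1 - mutation_rate`.
#'
#' @param n Number of sequences.
#' @param length Sequence length (>= 10).
#' @param group_assignments Integer group label per sequence.
#' @param mutation_rate Per-position substitution probability in \[0, 1).
#' @param seed Integer seed.
#' @return Character vector of sequences.
#' @export
generate_toy_sequences <- function(n, length = 40L, group_assignments,
                                   mutation_rate = 0.1, seed = 1L) {
  if (n == 0L) return(character(0))
  if (length < 10L) stop("sequence length must be >= 10")
  if (mutation_rate < 0 || mutation_rate >= 1) {
    stop("mutation_rate must lie in [0, 1)")
  }
  stopifnot(base::length(group_assignments) == n)
  set.seed(seed)
  aa <- setdiff(.aa_alphabet, "X")
  groups <- sort(unique(group_assignments))
  ancestors <- lapply(groups, function(g) sample(aa, length, replace = TRUE))
  names(ancestors) <- as.character(groups)
  vapply(seq_len(n), function(i) {
    s <- ancestors[[as.character(group_assignments[i])]]
    mut <- stats::runif(length) < mutation_rate
    if (any(mut)) s[mut] <- sample(aa, sum(mut), replace = TRUE)
    paste(s, collapse = "")
  }, character(1))
}

#' Write a synthetic dataset in the package's on-disk formats
#'
#' Emits the herb-component, target-disease and herb-disease association
#' tables plus the two similarity matrices, making a synthetic run a
#' drop-in replacement for a real one.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  .write_edges <- function(M, path, rows_are_source = FALSE) {
    idx <- which(M == 1, arr.ind = TRUE)
    src <- if (rows_are_source) rownames(M)[idx[, 1]] else
      colnames(M)[idx[, 2]]
    tgt <- if (rows_are_source) colnames(M)[idx[, 2]] else
      rownames(M)[idx[, 1]]
    write_association_table(
      association_table(data.frame(source_id = src, target_id = tgt)), path)
  }
  .write_edges(dataset$A_ch, file.path(dir, "herb_component.tsv"))
  .write_edges(dataset$A_td, file.path(dir, "target_disease.tsv"),
               rows_are_source = TRUE)
  .write_edges(dataset$A_hd, file.path(dir, "herb_disease.tsv"),
               rows_are_source = TRUE)
  write_matrix_tsv(dataset$S_C, file.path(dir, "similarity_components.tsv"))
  write_matrix_tsv(dataset$S_T, file.path(dir, "similarity_targets.tsv"))
  invisible(dir)
}
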