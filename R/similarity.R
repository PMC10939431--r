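#' Validate a similarity matrix
#'
#' Similarity matrices are plain numeric matrices with entity ids as
#' dimnames, symmetric, unit diagonal, entries in \[0, 1\].
#'
#' @param m Numeric matrix.
#' @param tol Numerical tolerance for the symmetry/diagonal checks.
#' @return The matrix, invisibly, or an error.
#' @export
validate_similarity_matrix <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("not a square matrix")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m))) {
    stop("similarity matrix needs matching row/column ids")
  }
  if (any(!is.finite(m))) stop("non-finite similarity entries")
  if (any(m < -tol) || any(m > 1 + tol)) stop("entries outside [0, 1]")
  if (max(abs(m - t(m))) > tol) stop("matrix is not symmetric")
  if (max(abs(diag(m) - 1)) > tol) stop("diagonal entries must equal 1")
  invisible(m)
}

#' Component similarity matrix from SMILES
#'
#' Converts every component SMILES to a Morgan fingerprint and fills the
#' pairwise similarity matrix with the configured coefficient (Dice by
#' default, Tanimoto under the ablation switch). The diagonal is forced
#' to 1.
#'
#' @param smiles_map Named character vector, component id -> SMILES.
#' @param config An [hda_config()]; `component_similarity` selects the
#'   coefficient.
#' @param n_bits,radius Fingerprint parameters.
#' @return A symmetric similarity matrix with component ids as dimnames,
#'   ordered by id.
#' @export
component_similarity_matrix <- function(smiles_map, config = hda_config(),
                                        n_bits = 2048L, radius = 2L) {
  if (length(smiles_map) == 0L) stop("need at least one component")
  ids <- sort(names(smiles_map))
  fps <- lapply(ids, function(id) {
    tryCatch(morgan_fingerprint(smiles_map[[id]], n_bits, radius),
             error = function(e) {
               stop("component '", id, "': ", conditionMessage(e),
                    call. = FALSE)
             })
  })
  simfun <- switch(config$component_similarity,
                   dice = dice_similarity,
                   tanimoto = tanimoto_similarity)
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
  validate_similarity_matrix(m)
  m
}

.aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                  "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

# identity scoring matrix over the amino-acid alphabet: match 1, mismatch 0
.identity_submat <- function() {
  n <- length(.aa_alphabet)
  m <- diag(1, n)
  dimnames(m) <- list(.aa_alphabet, .aa_alphabet)
  m
}

.check_sequence <- function(s, name = "sequence") {
  if (!is.character(s) || length(s) != 1L || !nzchar(s)) {
    stop(name, " must be a non-empty string")
  }
  letters <- strsplit(s, "")[[1]]
  bad <- setdiff(letters, .aa_alphabet)
  if (length(bad) > 0L) {
    stop("illegal amino-acid character '", bad[1], "' in ", name)
  }
  invisible(s)
}

.alignment_score <- function(seq_i, seq_j, scheme) {
  if (scheme == "default") {
    Biostrings::pairwiseAlignment(
      seq_i, seq_j, type = "global",
      substitutionMatrix = .identity_submat(),
      gapOpening = 0, gapExtension = 0, scoreOnly = TRUE)
  } else {
    Biostrings::pairwiseAlignment(
      Biostrings::AAString(seq_i), Biostrings::AAString(seq_j),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5, scoreOnly = TRUE)
  }
}

#' Normalised global-alignment similarity between two protein sequences
#'
#' Aligns the two sequences globally and normalises the raw score by the
#' geometric mean of the self-alignment scores,
#' `s(i, j) / sqrt(s(i, i) s(j, j))`, so self-similarity is exactly 1 and
#' all values fall in \[0, 1\] (negative substitution-matrix scores are
#' clamped to 0 first). The `"default"` scheme scores match 1, mismatch 0
#' with free gaps; `"blosum62"` uses BLOSUM62 with affine gaps
#' (open 10, extend 0.5).
#'
#' @param seq_i,seq_j Amino-acid sequences (20-letter alphabet plus X).
#' @param scheme `"default"` or `"blosum62"`.
#' @param normalize If `FALSE`, return the raw alignment score instead.
#' @return Similarity in \[0, 1\] (or a raw score when `normalize = FALSE`).
#' @export
sequence_similarity <- function(seq_i, seq_j,
                                scheme = c("default", "blosum62"),
                                normalize = TRUE) {
  scheme <- match.arg(scheme)
  seq_i <- toupper(seq_i)
  seq_j <- toupper(seq_j)
  .check_sequence(seq_i, "seq_i")
  .check_sequence(seq_j, "seq_j")
  s_ij <- .alignment_score(seq_i, seq_j, scheme)
  if (!normalize) return(s_ij)
  s_ii <- .alignment_score(seq_i, seq_i, scheme)
  s_jj <- .alignment_score(seq_j, seq_j, scheme)
  s_ij <- max(s_ij, 0)
  if (s_ii <= 0 || s_jj <= 0) return(0)
  min(1, s_ij / sqrt(s_ii * s_jj))
}

#' Target-protein similarity matrix from sequences
#'
#' @param seq_map Named character vector, target id -> amino-acid sequence.
#' @param config An [hda_config()]; `sequence_scheme` selects the scoring
#'   scheme.
#' @return A symmetric similarity matrix with target ids as dimnames,
#'   ordered by id.
#' @export
target_similarity_matrix <- function(seq_map, config = hda_config()) {
  if (length(seq_map) == 0L) stop("need at least one target sequence")
  ids <- sort(names(seq_map))
  n <- length(ids)
  m <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        m[i, j] <- m[j, i] <- sequence_similarity(
          seq_map[[ids[i]]], seq_map[[ids[j]]],
          scheme = config$sequence_scheme)
      }
    }
  }
  dimnames(m) <- list(ids, ids)
  validate_similarity_matrix(m)
  m
}
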