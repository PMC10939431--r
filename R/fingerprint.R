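#' Molecular fingerprints as bit sets
#'
#' A fingerprint is the set of on-bit indices of a fixed-length binary
#' vector (default 2048 bits, the conventional folded length for circular
#' fingerprints). Set semantics: indices are unique, sorted, 0-based.
#'
#' @param on_bits Integer vector of 0-based bit indices.
#' @param n_bits Total bit-vector length.
#' @return A list of class `"fingerprint"` with fields `n_bits`, `on_bits`.
#' @export
fingerprint <- function(on_bits, n_bits = 2048L) {
  n_bits <- as.integer(n_bits)
  on_bits <- sort(unique(as.integer(on_bits)))
  if (n_bits < 1L) stop("n_bits must be positive")
  if (length(on_bits) > 0L && (min(on_bits) < 0L || max(on_bits) >= n_bits)) {
    stop("on_bits indices must lie in [0, n_bits)")
  }
  structure(list(n_bits = n_bits, on_bits = on_bits), class = "fingerprint")
}

# atomic numbers and default valences used to infer implicit hydrogens;
# formal charges are not modelled (neutral organic subset)
.element_info <- list(
  H = c(1, 1), B = c(5, 3), C = c(6, 4), N = c(7, 3), O = c(8, 2),
  F = c(9, 1), Si = c(14, 4), P = c(15, 3), S = c(16, 2), Cl = c(17, 1),
  Br = c(35, 1), I = c(53, 1)
)

# deterministic integer hash of an integer vector (callers pre-sort any
# order-free parts); exact double arithmetic below 2^31
.hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + (x %% 2147483647)) %% 2147483647
  h
}

#' Morgan (circular) fingerprint from SMILES
#'
#' Computes an ECFP-style circular fingerprint: atoms start from local
#' invariants (atomic number, heavy-atom degree, implicit hydrogen count,
#' ring membership) and are iteratively hashed together with their
#' neighbours' identifiers and bond orders up to the requested radius.
#' Environments are deduplicated by their bond set, and environments that
#' stop growing contribute no further bits, matching the usual
#' extended-connectivity convention. SMILES parsing is delegated to
#' ChemmineR/OpenBabel, so aromatic rings are processed in their
#' kekulized form.
#'
#' @param smiles A single SMILES string.
#' @param n_bits Folded fingerprint length (default 2048).
#' @param radius Neighbourhood radius (default 2, the ECFP4 convention).
#' @return A [fingerprint()].
#' @export
morgan_fingerprint <- function(smiles, n_bits = 2048L, radius = 2L) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  n_bits <- as.integer(n_bits)
  radius <- as.integer(radius)
  if (radius < 0L) stop("radius must be nonnegative")
  mol <- .parse_smiles(smiles)
  n_atoms <- length(mol$element)
  if (n_atoms == 0L) {
    stop("invalid molecular structure (no atoms): '", smiles, "'")
  }

  info <- .element_info[mol$element]
  if (any(vapply(info, is.null, logical(1)))) {
    bad <- mol$element[vapply(info, is.null, logical(1))][1]
    stop("unsupported element '", bad, "' in SMILES '", smiles, "'")
  }
  atomic_num <- vapply(info, `[[`, numeric(1), 1L)
  valence <- vapply(info, `[[`, numeric(1), 2L)

  bonds <- mol$bonds  # matrix: a1, a2, order
  n_bonds <- nrow(bonds)
  incident <- vector("list", n_atoms)
  for (i in seq_len(n_atoms)) incident[[i]] <- integer(0)
  if (n_bonds > 0L) {
    for (b in seq_len(n_bonds)) {
      incident[[bonds[b, 1]]] <- c(incident[[bonds[b, 1]]], b)
      incident[[bonds[b, 2]]] <- c(incident[[bonds[b, 2]]], b)
    }
  }
  degree <- lengths(incident)
  bond_order_sum <- vapply(seq_len(n_atoms), function(i) {
    if (degree[i] == 0L) 0 else sum(bonds[incident[[i]], 3])
  }, numeric(1))
  h_count <- pmax(0, valence - bond_order_sum)
  in_ring <- .ring_atoms(n_atoms, bonds)

  # radius-0 identifiers from local invariants
  code <- vapply(seq_len(n_atoms), function(i) {
    .hash_ints(c(atomic_num[i], degree[i], h_count[i], as.integer(in_ring[i])))
  }, numeric(1))
  bits <- unique(code %% n_bits)

  env_bonds <- rep(list(integer(0)), n_atoms)
  seen_sets <- character(0)
  alive <- rep(TRUE, n_atoms)

  r <- 1L
  while (r <= radius && any(alive) && n_bonds > 0L) {
    new_code <- code
    new_env <- env_bonds
    for (a in seq_len(n_atoms)) {
      if (!alive[a] || degree[a] == 0L) next
      nb_bonds <- incident[[a]]
      nb_atoms <- ifelse(bonds[nb_bonds, 1] == a,
                         bonds[nb_bonds, 2], bonds[nb_bonds, 1])
      ord <- order(bonds[nb_bonds, 3], code[nb_atoms])
      pieces <- as.vector(rbind(bonds[nb_bonds, 3][ord], code[nb_atoms][ord]))
      new_code[a] <- .hash_ints(c(r, code[a], pieces))
      env <- env_bonds[[a]]
      for (k in seq_along(nb_bonds)) {
        env <- c(env, nb_bonds[k], env_bonds[[nb_atoms[k]]])
      }
      new_env[[a]] <- sort(unique(env))
    }
    for (a in seq_len(n_atoms)) {
      if (!alive[a] || degree[a] == 0L) {
        alive[a] <- FALSE
        next
      }
      if (length(new_env[[a]]) == length(env_bonds[[a]])) {
        alive[a] <- FALSE  # environment stopped growing
        next
      }
      key <- paste(new_env[[a]], collapse = ",")
      if (!(key %in% seen_sets)) {
        seen_sets <- c(seen_sets, key)
        bits <- c(bits, new_code[a] %% n_bits)
      }
    }
    code <- new_code
    env_bonds <- new_env
    r <- r + 1L
  }

  fingerprint(sort(unique(as.integer(bits))), n_bits)
}

# lexical sanity checks; the toolkit parser is permissive and silently
# truncates some malformed strings, so reject those up front
.validate_smiles_syntax <- function(smiles) {
  bad <- function(why) {
    stop("invalid molecular structure: '", smiles, "' (", why, ")",
         call. = FALSE)
  }
  if (!nzchar(smiles)) bad("empty string")
  if (grepl("[^A-Za-z0-9()\\[\\]=#+%./\\\\@:*-]", smiles, perl = TRUE)) {
    bad("illegal character")
  }
  chars <- strsplit(smiles, "")[[1]]
  if (cumsum(chars == "(")[length(chars)] != sum(chars == ")") ||
      any(cumsum(chars == "(") < cumsum(chars == ")"))) {
    bad("unbalanced parentheses")
  }
  if (sum(chars == "[") != sum(chars == "]") ||
      any(cumsum(chars == "[") < cumsum(chars == "]"))) {
    bad("unbalanced brackets")
  }
  if (grepl("[=#(/\\\\.-]$", smiles)) bad("dangling bond or branch")
  invisible(smiles)
}

# SMILES -> list(element, bonds) via ChemmineR; explicit hydrogens are
# folded into their heavy neighbour's hydrogen count
.parse_smiles <- function(smiles) {
  .validate_smiles_syntax(smiles)
  parsed <- tryCatch({
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
    if (length(sdf) == 0L) stop("parser returned no molecule")
    list(ab = ChemmineR::atomblock(sdf[[1]]),
         bb = ChemmineR::bondblock(sdf[[1]]))
  }, error = function(e) {
    stop("invalid molecular structure: '", smiles, "' (",
         conditionMessage(e), ")", call. = FALSE)
  })
  ab <- parsed$ab
  bb <- parsed$bb
  element <- sub("_.*$", "", rownames(ab))
  if (length(element) == 0L) {
    stop("invalid molecular structure (no atoms): '", smiles, "'",
         call. = FALSE)
  }
  if (!all(grepl("^[A-Za-z]{1,2}$", element))) {
    # bond-free molecules come back garbled from the SDF round trip;
    # recover the atom symbols from the raw V2000 text instead
    return(.parse_smiles_bondfree(smiles))
  }
  bonds <- if (is.null(bb) || nrow(bb) == 0L || ncol(bb) < 3L) {
    matrix(numeric(0), ncol = 3)
  } else {
    cbind(as.numeric(bb[, 1]), as.numeric(bb[, 2]), as.numeric(bb[, 3]))
  }
  # drop explicit hydrogens, keeping heavy-atom indices contiguous
  heavy <- which(element != "H")
  if (length(heavy) < length(element)) {
    remap <- match(seq_along(element), heavy)
    keep <- bonds[, 1] %in% heavy & bonds[, 2] %in% heavy
    bonds <- bonds[keep, , drop = FALSE]
    bonds[, 1] <- remap[bonds[, 1]]
    bonds[, 2] <- remap[bonds[, 2]]
    element <- element[heavy]
  }
  list(element = element, bonds = bonds)
}

# atoms of a molecule with no bonds, read off the V2000 atom lines
.parse_smiles_bondfree <- function(smiles) {
  txt <- ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n"))
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  counts <- strsplit(trimws(lines[4]), "\\s+")[[1]]
  n_atoms <- as.integer(counts[1])
  if (is.na(n_atoms) || n_atoms < 1L) {
    stop("invalid molecular structure (no atoms): '", smiles, "'",
         call. = FALSE)
  }
  element <- vapply(lines[4L + seq_len(n_atoms)], function(ln) {
    strsplit(trimws(ln), "\\s+")[[1]][4]
  }, character(1), USE.NAMES = FALSE)
  el <- element[element != "H"]
  if (length(el) == 0L) el <- element  # molecular hydrogen etc.
  list(element = el, bonds = matrix(numeric(0), ncol = 3))
}

# ring membership: an atom is in a ring iff it touches a non-bridge edge
.ring_atoms <- function(n_atoms, bonds) {
  if (nrow(bonds) == 0L) return(rep(FALSE, n_atoms))
  g <- igraph::graph_from_edgelist(cbind(bonds[, 1], bonds[, 2]),
                                   directed = FALSE)
  if (igraph::vcount(g) < n_atoms) {
    g <- igraph::add_vertices(g, n_atoms - igraph::vcount(g))
  }
  bridge_idx <- igraph::bridges(g)
  cyc <- setdiff(seq_len(nrow(bonds)), as.integer(bridge_idx))
  out <- rep(FALSE, n_atoms)
  out[unique(c(bonds[cyc, 1], bonds[cyc, 2]))] <- TRUE
  out
}

.check_fp_pair <- function(fp_i, fp_j) {
  stopifnot(inherits(fp_i, "fingerprint"), inherits(fp_j, "fingerprint"))
  if (fp_i$n_bits != fp_j$n_bits) {
    stop("fingerprint bit-length mismatch: ", fp_i$n_bits, " vs ", fp_j$n_bits)
  }
}

#' Dice similarity between two fingerprints
#'
#' `2 |A intersect B| / (|A| + |B|)`. A pair of empty fingerprints has no
#' defined overlap; by convention the similarity is 0 (with a warning).
#'
#' @param fp_i,fp_j [fingerprint()] objects with equal `n_bits`.
#' @return Similarity in \[0, 1\].
#' @export
dice_similarity <- function(fp_i, fp_j) {
  .check_fp_pair(fp_i, fp_j)
  a <- length(fp_i$on_bits)
  b <- length(fp_j$on_bits)
  if (a + b == 0L) {
    warning("both fingerprints are empty; similarity defined as 0")
    return(0)
  }
  i <- length(intersect(fp_i$on_bits, fp_j$on_bits))
  i / ((a + b) / 2)
}

#' Tanimoto similarity between two fingerprints
#'
#' `|A intersect B| / |A union B|`; the coefficient behind the
#' tanimoto ablation switch.
#'
#' @inheritParams dice_similarity
#' @return Similarity in \[0, 1\].
#' @export
tanimoto_similarity <- function(fp_i, fp_j) {
  .check_fp_pair(fp_i, fp_j)
  a <- length(fp_i$on_bits)
  b <- length(fp_j$on_bits)
  if (a + b == 0L) {
    warning("both fingerprints are empty; similarity defined as 0")
    return(0)
  }
  i <- length(intersect(fp_i$on_bits, fp_j$on_bits))
  i / (a + b - i)
}
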