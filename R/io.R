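#' Association tables
#'
#' An association table is the package's exchange format for bipartite
#' edge lists: herb-component, target-disease and herb-disease links.
#' Vocabularies are sorted lexicographically so that incidence matrices
#' built from a table have a deterministic row/column order regardless of
#' the order of the input rows.
#'
#' @param edges A two-column data frame (source_id, target_id) of character
#'   ids. Duplicate rows are collapsed.
#' @return A list of class `"association_table"` with fields `edges`
#'   (deduplicated data frame), `source_vocab` and `target_vocab`.
#' @export
association_table <- function(edges) {
  edges <- data.frame(source_id = as.character(edges[[1]]),
                      target_id = as.character(edges[[2]]),
                      stringsAsFactors = FALSE)
  edges <- unique(edges)
  edges <- edges[order(edges$source_id, edges$target_id), , drop = FALSE]
  rownames(edges) <- NULL
  out <- list(
    edges = edges,
    source_vocab = sort(unique(edges$source_id)),
    target_vocab = sort(unique(edges$target_id))
  )
  class(out) <- "association_table"
  out
}

#' Read an association table from delimited text
#'
#' @param path Path to a headerless delimited file with at least two
#'   columns; only the first two are used.
#' @param delimiter Field delimiter, tab by default.
#' @return An [association_table()].
#' @export
read_association_table <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("association file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(association_table(data.frame(source_id = character(0),
                                        target_id = character(0))))
  }
  parts <- strsplit(lines, delimiter, fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 2L)
  if (length(bad) > 0L) {
    stop("malformed row (need >= 2 columns) at line ", bad[1],
         ": '", lines[bad[1]], "'")
  }
  association_table(data.frame(
    source_id = trimws(vapply(parts, `[[`, character(1), 1L)),
    target_id = trimws(vapply(parts, `[[`, character(1), 2L)),
    stringsAsFactors = FALSE
  ))
}

#' Write an association table
#'
#' @param table An [association_table()].
#' @param path Output path.
#' @param delimiter Field delimiter.
#' @export
write_association_table <- function(table, path, delimiter = "\t") {
  stopifnot(inherits(table, "association_table"))
  utils::write.table(table$edges, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a component id to SMILES mapping
#'
#' Two-column delimited text: component id, SMILES. Each id must occur once
#' and every SMILES field must be non-empty.
#'
#' @inheritParams read_association_table
#' @return A named character vector of SMILES keyed by component id.
#' @export
read_component_smiles <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("SMILES file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(stats::setNames(character(0), character(0)))
  parts <- strsplit(lines, delimiter, fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 2L)
  if (length(bad) > 0L) {
    stop("malformed SMILES row at line ", bad[1])
  }
  ids <- trimws(vapply(parts, `[[`, character(1), 1L))
  smi <- trimws(vapply(parts, `[[`, character(1), 2L))
  if (anyDuplicated(ids)) {
    stop("duplicate component id: ", ids[duplicated(ids)][1])
  }
  if (any(!nzchar(smi))) {
    stop("empty SMILES field for component: ", ids[!nzchar(smi)][1])
  }
  stats::setNames(smi, ids)
}

#' Read protein sequences from FASTA
#'
#' The id of each record is the header token up to the first whitespace;
#' multi-line sequences are concatenated and uppercased.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of amino-acid sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id: ", ids[duplicated(ids)][1])
  }
  empty <- which(Biostrings::width(seqs) == 0L)
  if (length(empty) > 0L) {
    stop("empty sequence for record: ", ids[empty[1]])
  }
  stats::setNames(toupper(as.character(seqs)), ids)
}

#' Write ranked association predictions
#'
#' Rows are ordered by descending score; ties are broken lexicographically
#' by (herb_id, disease_id) so top-k lists are reproducible across runs.
#'
#' @param scores Data frame with columns `herb_id`, `disease_id`, `score`
#'   (scores in \[0, 1\]).
#' @param path Output path.
#' @param delimiter Field delimiter.
#' @export
write_predictions <- function(scores, path, delimiter = "\t") {
  scores <- data.frame(herb_id = as.character(scores$herb_id),
                       disease_id = as.character(scores$disease_id),
                       score = as.numeric(scores$score),
                       stringsAsFactors = FALSE)
  if (nrow(scores) > 0L &&
      (any(!is.finite(scores$score)) || any(scores$score < 0) ||
       any(scores$score > 1))) {
    stop("prediction scores must lie in [0, 1]")
  }
  ord <- order(-scores$score, scores$herb_id, scores$disease_id)
  utils::write.table(scores[ord, , drop = FALSE], path, sep = delimiter,
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read or write a similarity/embedding matrix as delimited text
#'
#' Matrices are stored with an id header row and an id first column.
#'
#' @param m Numeric matrix with dimnames.
#' @param path File path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
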