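#' Run configuration
#'
#' Bundles every tunable knob of the pipeline into one validated object.
#' The defaults reflect the recommended operating point: five convolution
#' layers, sum readout over per-layer hyperedge embeddings, Dice similarity
#' on Morgan fingerprints for components, default pairwise alignment scoring
#' for protein targets, and autoencoder-compressed node features.
#'
#' @param embed_dim Latent dimensionality `d` of the autoencoder embeddings
#'   and all convolution layers (positive integer).
#' @param n_layers Number of hypergraph convolution layers `l` (>= 1).
#' @param lambda Nonnegative L2 penalty on the per-layer transform matrices.
#' @param learning_rate Adam step size for model training.
#' @param epochs Full-batch training epochs for the association model.
#' @param ae_learning_rate Adam step size for autoencoder pre-training.
#' @param ae_epochs Training epochs for the autoencoder.
#' @param seed Integer seed controlling every random draw downstream.
#' @param layer_readout How per-layer hyperedge embeddings are pooled into
#'   the final herb/disease representations: `"sum"` (default) or `"mean"`.
#' @param component_similarity Fingerprint similarity coefficient,
#'   `"dice"` (default) or `"tanimoto"`.
#' @param sequence_scheme Protein alignment scoring, `"default"`
#'   (match 1 / mismatch 0 / free gaps) or `"blosum62"` (affine gaps,
#'   open 10, extend 0.5).
#' @param init_mode Node feature initialisation, `"autoencoder"` (default)
#'   or `"random"`.
#' @param classification_threshold Probability cut-off used when hard
#'   labels are needed, strictly inside (0, 1).
#' @return A list of class `"hda_config"`.
#' @export
hda_config <- function(embed_dim = 64L,
                       n_layers = 5L,
                       lambda = 1e-4,
                       learning_rate = 0.01,
                       epochs = 200L,
                       ae_learning_rate = 5e-3,
                       ae_epochs = 200L,
                       seed = 1L,
                       layer_readout = c("sum", "mean"),
                       component_similarity = c("dice", "tanimoto"),
                       sequence_scheme = c("default", "blosum62"),
                       init_mode = c("autoencoder", "random"),
                       classification_threshold = 0.5) {
  cfg <- list(
    embed_dim = as.integer(embed_dim),
    n_layers = as.integer(n_layers),
    lambda = as.numeric(lambda),
    learning_rate = as.numeric(learning_rate),
    epochs = as.integer(epochs),
    ae_learning_rate = as.numeric(ae_learning_rate),
    ae_epochs = as.integer(ae_epochs),
    seed = as.integer(seed),
    layer_readout = match.arg(layer_readout),
    component_similarity = match.arg(component_similarity),
    sequence_scheme = match.arg(sequence_scheme),
    init_mode = match.arg(init_mode),
    classification_threshold = as.numeric(classification_threshold)
  )
  class(cfg) <- "hda_config"
  validate_hda_config(cfg)
}

#' @rdname hda_config
#' @param x Object to validate.
#' @export
validate_hda_config <- function(x) {
  stopifnot(inherits(x, "hda_config"))
  if (x$embed_dim < 1L) stop("embed_dim must be a positive integer")
  if (x$n_layers < 1L) stop("n_layers must be >= 1")
  if (x$lambda < 0) stop("lambda must be nonnegative")
  if (x$learning_rate <= 0 || x$ae_learning_rate <= 0) {
    stop("learning rates must be positive")
  }
  if (x$epochs < 1L || x$ae_epochs < 1L) stop("epochs must be >= 1")
  if (x$classification_threshold <= 0 || x$classification_threshold >= 1) {
    stop("classification_threshold must lie strictly inside (0, 1)")
  }
  invisible(x)
}

#' Read or write a run configuration as JSON
#'
#' @param path File path.
#' @return `read_hda_config` returns a validated `hda_config`.
#' @export
read_hda_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(hda_config, raw)
}

#' @rdname read_hda_config
#' @param config An `hda_config`.
#' @export
write_hda_config <- function(config, path) {
  validate_hda_config(config)
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
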