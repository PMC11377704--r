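# Embedding providers: the contract between sequence and per-residue vectors.

#' Prepare a sequence for embedding
#'
#' Removes gap characters and maps rare or non-standard residues to `X`,
#' the same preprocessing applied to MSA rows before they are embedded.
#'
#' @param seq A possibly gapped amino-acid string.
#' @return Ungapped uppercase string over the 20 standard residues and `X`.
#' @export
#' @examples
#' preprocess_for_embedding("AC-DE")  # "ACDE"
preprocess_for_embedding <- function(seq) {
  stopifnot(is_string(seq))
  out <- gsub("[-.]", "", toupper(seq))
  out <- suppressWarnings(normalize_residues(out))
  if (nchar(out) == 0L) stop("sequence is empty after preprocessing")
  out
}

#' Construct an embedding provider
#'
#' A provider bundles a name, an output width `D` and a deterministic
#' `embed` function mapping a [protein_record()] to an `L x D` matrix.
#'
#' @param name Provider name.
#' @param D Embedding width.
#' @param embed Function `protein_record -> L x D matrix`.
#' @return Object of class `embedding_provider`.
#' @export
embedding_provider <- function(name, D, embed) {
  stopifnot(is_string(name), D >= 1, is.function(embed))
  structure(list(name = name, D = as.integer(D), embed = embed),
            class = "embedding_provider")
}

#' @export
print.embedding_provider <- function(x, ...) {
  cat("<embedding_provider> ", x$name, " (D = ", x$D, ")\n", sep = "")
  invisible(x)
}

#' Embed a record with a provider
#'
#' @param provider An [embedding_provider()].
#' @param record A [protein_record()].
#' @return `L x D` numeric matrix.
#' @export
embed_record <- function(provider, record) {
  stopifnot(inherits(provider, "embedding_provider"),
            inherits(record, "protein_record"))
  m <- provider$embed(record)
  if (!is.matrix(m) || nrow(m) != record$length || ncol(m) != provider$D)
    stop("provider '", provider$name, "' returned a ", nrow(m), "x", ncol(m),
         " matrix for '", record$id, "' (expected ", record$length, "x",
         provider$D, ")")
  m
}

#' Label-driven synthetic embedding provider
#'
#' Emulates a pLM on synthetic records: residue `i` of a record with
#' per-residue labels is embedded as `mu[label_i] + N(0, sigma^2)` noise per
#' coordinate. The noise is deterministic given the provider seed and the
#' record id, so repeated calls agree. Averaging such embeddings over a
#' family whose labels are conserved provably reduces the noise variance —
#' the property the MSA-embedding workflow exploits.
#'
#' @param mu Named list or matrix of class signal vectors: one `D`-vector per
#'   label (see [signal_table()]).
#' @param sigma Noise standard deviation per coordinate (`>= 0`).
#' @param seed Integer root seed.
#' @param name Provider name.
#' @return An [embedding_provider()].
#' @export
synthetic_provider <- function(mu, sigma, seed = 1L, name = "synthetic") {
  if (is.matrix(mu)) mu <- lapply(setNames(seq_len(nrow(mu)), rownames(mu)),
                                  function(i) mu[i, ])
  stopifnot(is.list(mu), !is.null(names(mu)), sigma >= 0)
  D <- length(mu[[1]])
  stopifnot(all(vapply(mu, length, 1L) == D))
  mu_mat <- do.call(rbind, mu)
  embed <- function(record) {
    labels <- record$labels
    if (is.null(labels))
      stop("record '", record$id, "' carries no label oracle; ",
           "synthetic embeddings are label-driven")
    if (!all(labels %in% names(mu)))
      stop("labels outside the signal table for '", record$id, "'")
    base <- mu_mat[match(labels, names(mu)), , drop = FALSE]
    if (sigma > 0) {
      noise <- with_seed(mix_seed(seed, hash_string(record$id)),
                         matrix(stats::rnorm(length(base), 0, sigma),
                                nrow(base), ncol(base)))
      base <- base + noise
    }
    unname(base)
  }
  embedding_provider(name, D, embed)
}

#' Provider backed by a precomputed embedding container
#'
#' Adapter for real pLM embeddings (SeqVec/ProtBert/ProtT5 style): the model
#' itself runs elsewhere and writes its `L x D` matrices to the on-disk
#' container; this provider simply looks records up by id.
#'
#' @param path Container written by [write_embeddings()].
#' @param name Provider name.
#' @return An [embedding_provider()].
#' @export
stored_provider <- function(path, name = "stored") {
  store <- read_embeddings(path)
  D <- attr(store, "D")
  embed <- function(record) {
    m <- store[[record$id]]
    if (is.null(m)) stop("no stored embedding for id '", record$id, "'")
    m
  }
  embedding_provider(name, D, embed)
}

#' Class signal table for synthetic embeddings
#'
#' Places the `K` class means on a scaled orthonormal simplex in `D`
#' dimensions so that every pair of means is exactly `separation` apart.
#'
#' @param classes Character vector of class labels (e.g. `c("H","E","O")`).
#' @param D Embedding width (`>= length(classes)`).
#' @param separation Pairwise Euclidean distance between class means.
#' @return Named list of `D`-vectors.
#' @export
signal_table <- function(classes = c("H", "E", "O"), D = 16L, separation = 1) {
  K <- length(classes)
  stopifnot(K >= 2, D >= K, separation > 0)
  mu <- lapply(seq_len(K), function(k) {
    v <- numeric(D)
    v[k] <- separation / sqrt(2)
    v
  })
  names(mu) <- classes
  mu
}
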