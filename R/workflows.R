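# The five end-to-end prediction strategies, generic over any provider and
# fitted predictor. All return an L x K per-residue track for the query.

#' @noRd
as_track <- function(m, workflow, classes = NULL) {
  attr(m, "workflow") <- workflow
  if (!is.null(classes)) colnames(m) <- classes
  m
}

#' Workflow: predict from raw embeddings
#'
#' The query sequence is embedded with the provider and the embedding is fed
#' to a base-variant model.
#'
#' @param record A [protein_record()].
#' @param provider An [embedding_provider()].
#' @param model A fitted base-variant [residue_cnn()].
#' @return `L x K` per-residue probability (or score) matrix.
#' @export
predict_raw <- function(record, provider, model) {
  stopifnot(inherits(model, "residue_cnn"))
  if (model$config$variant != "base")
    stop("predict_raw needs a base-variant model")
  feats <- setNames(list(embed_record(provider, record)), record$id)
  type <- if (model$config$continuous) "score" else "prob"
  out <- predict(model, feats, type = type)[[1]]
  if (model$config$continuous) out <- matrix(out, ncol = 1)
  as_track(out, "raw", model$config$classes)
}

#' Workflow: predict from MSA-averaged embeddings
#'
#' Embeds every alignment row, averages embeddings column-wise over the MSA
#' ([msa_average_embeddings()]) and feeds the averaged embedding to a
#' base-variant model. With a single-row alignment this is identical to
#' [predict_raw()].
#'
#' @inheritParams predict_raw
#' @param msa An [msa()] whose query is `record`.
#' @param records Optional per-row records passed through to
#'   [msa_average_embeddings()].
#' @return `L x K` per-residue track.
#' @export
predict_msa_embedding <- function(record, msa, provider, model, records = NULL) {
  stopifnot(inherits(model, "residue_cnn"))
  if (model$config$variant != "base")
    stop("predict_msa_embedding needs a base-variant model")
  q <- msa_query(msa)
  if (q$seq != record$seq)
    stop("MSA query does not match record '", record$id, "'")
  avg <- msa_average_embeddings(msa, provider, records = records)
  feats <- setNames(list(avg), record$id)
  type <- if (model$config$continuous) "score" else "prob"
  out <- predict(model, feats, type = type)[[1]]
  if (model$config$continuous) out <- matrix(out, ncol = 1)
  as_track(out, "msa-emb", model$config$classes)
}

#' Workflow: MSA-consensus prediction (MSACons)
#'
#' Predicts each alignment row independently on its own ungapped sequence and
#' averages the per-residue prediction channels column-wise over the MSA
#' (query included): probability vectors for categorical predictors, scores
#' for continuous ones. The argmax, if wanted, is taken after averaging.
#' Rows that cannot be predicted are skipped with a warning.
#'
#' @param record A [protein_record()].
#' @param msa An [msa()] whose query is `record`.
#' @param predictor Function `protein_record -> L x K matrix` (see
#'   [cnn_predictor()] to wrap a fitted model and provider). This makes the
#'   consensus generic over any per-residue method, including external ones.
#' @param records Optional named per-row records (label-carrying synthetic
#'   records); defaults to records built from the ungapped rows.
#' @return `L x K` per-residue track for the query.
#' @export
predict_msacons <- function(record, msa, predictor, records = NULL) {
  stopifnot(is.function(predictor))
  q <- msa_query(msa)
  if (q$seq != record$seq)
    stop("MSA query does not match record '", record$id, "'")
  ids <- names(msa$rows)
  L <- length(msa$column_map)
  inv <- integer(msa$ncol)
  inv[msa$column_map] <- seq_len(L)
  total <- NULL
  count <- numeric(L)
  for (i in seq_along(ids)) {
    chars <- strsplit(msa$rows[[i]], "")[[1]]
    res_cols <- which(chars != "-")
    rec <- if (!is.null(records) && !is.null(records[[ids[i]]])) records[[ids[i]]]
           else protein_record(ids[i], preprocess_for_embedding(msa$rows[[i]]))
    track <- tryCatch(predictor(rec), error = function(e) {
      warning("skipping row '", ids[i], "': ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(track)) {
      if (i == msa$query_row) stop("query row could not be predicted")
      next
    }
    if (is.null(total)) total <- matrix(0, L, ncol(track))
    qpos <- inv[res_cols]
    keep <- qpos > 0L
    total[qpos[keep], ] <- total[qpos[keep], , drop = FALSE] +
      track[which(keep), , drop = FALSE]
    count[qpos[keep]] <- count[qpos[keep]] + 1
  }
  as_track(total / count, "msacons")
}

#' Wrap a fitted model and provider as a per-record predictor
#'
#' @param model A fitted base-variant [residue_cnn()].
#' @param provider An [embedding_provider()].
#' @return Function `protein_record -> L x K matrix`, suitable for
#'   [predict_msacons()].
#' @export
cnn_predictor <- function(model, provider) {
  stopifnot(inherits(model, "residue_cnn"),
            inherits(provider, "embedding_provider"))
  function(record) {
    feats <- setNames(list(embed_record(provider, record)), record$id)
    if (model$config$continuous)
      matrix(predict(model, feats, type = "score")[[1]], ncol = 1)
    else predict(model, feats, type = "prob")[[1]]
  }
}

#' Workflow: embedding + PSSM concatenation
#'
#' The raw query embedding and the per-residue PSSM profile are concatenated
#' row-wise into a single `L x (D+20)` feature matrix for a concat-variant
#' model.
#'
#' @inheritParams predict_msa_embedding
#' @param model A fitted concat-variant [residue_cnn()].
#' @param alpha Pseudocount passed to [compute_pssm()].
#' @return `L x K` per-residue track.
#' @export
predict_pssm_concat <- function(record, msa, provider, model, alpha = 1) {
  stopifnot(inherits(model, "residue_cnn"))
  if (model$config$variant != "concat")
    stop("predict_pssm_concat needs a concat-variant model")
  emb <- embed_record(provider, record)
  pssm <- pssm_features(compute_pssm(msa, alpha = alpha))
  feats <- setNames(list(cbind(emb, pssm)), record$id)
  type <- if (model$config$continuous) "score" else "prob"
  out <- predict(model, feats, type = type)[[1]]
  if (model$config$continuous) out <- matrix(out, ncol = 1)
  as_track(out, "pssm-concat", model$config$classes)
}

#' Workflow: split-branch embedding + PSSM fusion
#'
#' Embedding and PSSM are fed as separate inputs to the two convolutional
#' branches of a split-variant model; their learned per-residue features are
#' concatenated inside the model before the final block.
#'
#' @inheritParams predict_pssm_concat
#' @param model A fitted split-variant [residue_cnn()].
#' @return `L x K` per-residue track.
#' @export
predict_pssm_split <- function(record, msa, provider, model, alpha = 1) {
  stopifnot(inherits(model, "residue_cnn"))
  if (model$config$variant != "split")
    stop("predict_pssm_split needs a split-variant model")
  emb <- embed_record(provider, record)
  pssm <- pssm_features(compute_pssm(msa, alpha = alpha))
  feats <- setNames(list(list(emb = emb, pssm = pssm)), record$id)
  type <- if (model$config$continuous) "score" else "prob"
  out <- predict(model, feats, type = type)[[1]]
  if (model$config$continuous) out <- matrix(out, ncol = 1)
  as_track(out, "pssm-split", model$config$classes)
}

#' Hard labels from a per-residue track
#'
#' @param track `L x K` matrix with class columns.
#' @param classes Class labels; default the track's column names.
#' @return Character vector of argmax labels, ties to the earliest class.
#' @export
track_labels <- function(track, classes = colnames(track)) {
  stopifnot(!is.null(classes))
  classes[max.col(track, ties.method = "first")]
}
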