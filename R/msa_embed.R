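#' Column-wise MSA average of per-residue embeddings
#'
#' Each alignment row is embedded independently on its own ungapped sequence;
#' for every query residue position the embedding vectors of all rows with a
#' residue in that column (the query included) are averaged. With noisy
#' embeddings and conserved structure this denoises the query representation;
#' for a single-row alignment it reduces exactly to the raw embedding.
#'
#' @param msa An [msa()] object.
#' @param provider An [embedding_provider()].
#' @param records Optional named list of [protein_record()]s for the rows
#'   (needed when the provider requires more than the sequence, e.g. the
#'   label oracle of [synthetic_provider()]); defaults to records built from
#'   the ungapped rows.
#' @return `L x D` matrix, `L` the query length.
#' @export
msa_average_embeddings <- function(msa, provider, records = NULL) {
  stopifnot(inherits(msa, "msa"), inherits(provider, "embedding_provider"))
  ids <- names(msa$rows)
  L <- length(msa$column_map)
  D <- provider$D
  total <- matrix(0, L, D)
  count <- numeric(L)
  # column index -> query position (0 where the query has a gap)
  inv <- integer(msa$ncol)
  inv[msa$column_map] <- seq_len(L)
  for (i in seq_along(ids)) {
    chars <- strsplit(msa$rows[[i]], "")[[1]]
    res_cols <- which(chars != "-")
    rec <- if (!is.null(records) && !is.null(records[[ids[i]]])) {
      records[[ids[i]]]
    } else {
      protein_record(ids[i], preprocess_for_embedding(msa$rows[[i]]))
    }
    emb <- tryCatch(embed_record(provider, rec), error = function(e) {
      warning("skipping row '", ids[i], "': ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(emb)) {
      if (i == msa$query_row) stop("query row could not be embedded")
      next
    }
    qpos <- inv[res_cols]            # 0 where the query is gapped
    keep <- qpos > 0L
    total[qpos[keep], ] <- total[qpos[keep], , drop = FALSE] +
      emb[which(keep), , drop = FALSE]
    count[qpos[keep]] <- count[qpos[keep]] + 1
  }
  if (any(count == 0)) stop("alignment column with no contributor (no query residue?)")
  total / count
}
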