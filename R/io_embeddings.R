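#' Embedding container on disk
#'
#' Per-residue embeddings are stored keyed by record id in a single
#' tab-separated text container: a header comment records the embedding
#' width `D`, then one row per residue (`id`, `pos`, `v1..vD`) at full
#' floating-point precision, so a write/read round-trip reproduces the
#' matrices bitwise. Records of different lengths may share a container;
#' the width `D` is fixed per container.
#'
#' @param embeddings Named list of numeric `L x D` matrices.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(embeddings, path) {
  stopifnot(is.list(embeddings), !is.null(names(embeddings)), length(embeddings) > 0)
  D <- ncol(embeddings[[1]])
  for (id in names(embeddings)) {
    if (ncol(embeddings[[id]]) != D)
      stop("embedding width mismatch for '", id, "': ", ncol(embeddings[[id]]),
           " != declared D = ", D)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#D=", D), con)
  writeLines(paste(c("id", "pos", paste0("v", seq_len(D))), collapse = "\t"), con)
  for (id in names(embeddings)) {
    m <- embeddings[[id]]
    body <- apply(m, 1, function(r) paste(format_full(r), collapse = "\t"))
    writeLines(paste(id, seq_len(nrow(m)), body, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_embeddings
#' @param ids Optional ids to extract; an absent requested id is an error.
#' @return `read_embeddings`: named list of `L x D` matrices with attribute
#'   `D`.
#' @export
read_embeddings <- function(path, ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (!grepl("^#D=", first)) stop("not an embedding container: ", path)
  D <- as.integer(sub("^#D=", "", first))
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          colClasses = c("character", "integer",
                                         rep("numeric", D)))
  if (!is.null(ids)) {
    missing <- setdiff(ids, unique(df$id))
    if (length(missing))
      stop("id(s) not in container: ", paste(missing, collapse = ", "))
    df <- df[df$id %in% ids, ]
  }
  out <- lapply(split(df, df$id), function(d) {
    d <- d[order(d$pos), ]
    unname(as.matrix(d[, -(1:2), drop = FALSE]))
  })
  keep <- unique(df$id)
  out <- out[keep]
  attr(out, "D") <- D
  out
}
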