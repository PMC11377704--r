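# Label tracks and PSSMs on disk as plain TSV.

#' Write per-residue label tracks
#'
#' One row per residue: `id`, `pos` (1-based), `label`. Continuous tracks
#' store scores at full precision.
#'
#' @param tracks Named list; each element a character vector (categorical) or
#'   numeric vector (continuous) of per-residue values.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_tracks <- function(tracks, path) {
  stopifnot(is.list(tracks), !is.null(names(tracks)))
  rows <- lapply(names(tracks), function(id) {
    v <- tracks[[id]]
    val <- if (is.numeric(v)) format_full(v) else as.character(v)
    data.frame(id = id, pos = seq_along(v), label = val)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-residue label tracks
#'
#' @param path TSV written by [write_label_tracks()].
#' @param continuous If `TRUE`, parse values as numeric scores.
#' @return Named list of per-residue vectors.
#' @export
read_label_tracks <- function(path, continuous = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer", "character"))
  out <- lapply(split(df, df$id), function(d) {
    d <- d[order(d$pos), ]
    if (!all(d$pos == seq_len(nrow(d))))
      stop("non-contiguous positions for id '", d$id[1], "'")
    if (continuous) as.numeric(d$label) else d$label
  })
  out[unique(df$id)]
}

#' Write a PSSM as TSV
#'
#' Header is the fixed 20-residue column order `ARNDCQEGHILKMFPSTWYV`;
#' one row per residue position.
#'
#' @param pssm A [compute_pssm()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(pssm, path) {
  stopifnot(inherits(pssm, "pssm"))
  m <- pssm$values
  df <- as.data.frame(matrix(format_full(m), nrow = nrow(m), ncol = ncol(m)))
  colnames(df) <- pssm$alphabet
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PSSM from TSV
#'
#' @param path TSV written by [write_pssm()].
#' @param scheme Scheme tag to attach (`"frequency"` or `"log-odds"`).
#' @return A `pssm` object.
#' @export
read_pssm <- function(path, scheme = "frequency") {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (!identical(colnames(df), AA20))
    stop("PSSM columns must be ", paste(AA20, collapse = ""))
  new_pssm(as.matrix(df), scheme = scheme, alpha = NA_real_)
}
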