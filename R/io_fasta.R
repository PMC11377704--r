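#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased; characters outside the 20 standard amino acids
#' and `X` are mapped to `X` with a warning (the same preprocessing applied
#' before computing embeddings).
#'
#' @param path Path to a FASTA file.
#' @return A named list of [protein_record()] objects, one per entry.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  recs <- lapply(seq_along(set), function(i) protein_record(ids[i], as.character(set[[i]])))
  names(recs) <- ids
  recs
}

#' Write protein records to a FASTA file
#'
#' @param records A list of [protein_record()] objects.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "protein_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(paste0(">", r$id), con)
    starts <- seq(1L, r$length, by = width)
    writeLines(substring(r$seq, starts, pmin(starts + width - 1L, r$length)), con)
  }
  invisible(path)
}
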