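#' Protein sequence record
#'
#' The unit of prediction: an identifier plus an ungapped, uppercase amino-acid
#' sequence over the 20 standard residues and `X` (any non-standard residue).
#'
#' @param id Single string identifier.
#' @param seq Single string amino-acid sequence; lower case is accepted and
#'   uppercased, characters outside the 20-letter alphabet are mapped to `X`.
#' @param labels Optional per-residue label vector of length `nchar(seq)`;
#'   carried along for synthetic records whose embeddings are label-driven.
#'
#' @return An object of class `protein_record` with elements `id`, `seq`,
#'   `length` and optionally `labels`.
#' @export
#' @examples
#' protein_record("q", "ACDE")
protein_record <- function(id, seq, labels = NULL) {
  stopifnot(is_string(id), is_string(seq))
  seq <- normalize_residues(toupper(seq), context = id)
  if (nchar(seq) < 1L) stop("sequence for '", id, "' is empty")
  if (grepl("[-.]", seq)) stop("sequence for '", id, "' contains gap characters")
  if (!is.null(labels) && length(labels) != nchar(seq))
    stop("labels length (", length(labels), ") != sequence length (", nchar(seq), ")")
  structure(list(id = id, seq = seq, length = nchar(seq), labels = labels),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$id, " (", x$length, " aa)\n", sep = "")
  s <- if (x$length > 60) paste0(substr(x$seq, 1, 57), "...") else x$seq
  cat("  ", s, "\n", sep = "")
  invisible(x)
}

# Map any character outside {20 standard AAs, X} to X, warning once per call.
#' @noRd
normalize_residues <- function(seq, context = "") {
  chars <- strsplit(seq, "")[[1]]
  bad <- !(chars %in% c(AA20, "X", "-", "."))
  if (any(bad)) {
    warning("mapped ", sum(bad), " non-standard residue(s) (",
            paste(unique(chars[bad]), collapse = ","), ") to X",
            if (nzchar(context)) paste0(" in '", context, "'"),
            call. = FALSE)
    chars[bad] <- "X"
  }
  paste(chars, collapse = "")
}
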