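#' Multiple sequence alignment keyed to a query
#'
#' An `msa` holds gapped rows over a common column space together with the
#' mapping from query residue positions to alignment columns. It is the
#' carrier of evolutionary information for MSA-averaged embeddings, consensus
#' prediction and PSSM construction.
#'
#' @param rows Named character vector of gapped rows, all the same width;
#'   gaps are `-` (`.` is normalized to `-`).
#' @param query_id Name of the query row; must ungap to the query sequence.
#' @return An object of class `msa` with elements `rows`, `query_row`
#'   (index into `rows`), `column_map` (for query residue `i`, the alignment
#'   column holding it) and `ncol`.
#' @export
#' @examples
#' m <- msa(c(q = "AC-E", h = "ACDE"), "q")
#' m$column_map  # 1 2 4
msa <- function(rows, query_id) {
  stopifnot(is.character(rows), !is.null(names(rows)), is_string(query_id))
  rows <- toupper(rows)
  rows <- gsub(".", "-", rows, fixed = TRUE)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L)
    stop("MSA rows have unequal widths: ", paste(unique(widths), collapse = ", "))
  qi <- match(query_id, names(rows))
  if (is.na(qi)) stop("query id '", query_id, "' not found in MSA")
  rows <- vapply(rows, normalize_residues, "", USE.NAMES = TRUE)
  qchars <- strsplit(rows[[qi]], "")[[1]]
  column_map <- which(qchars != "-")
  if (length(column_map) == 0L) stop("query row is all gaps")
  structure(list(rows = rows, query_row = qi, column_map = column_map,
                 ncol = widths[[1]]),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("<msa> ", length(x$rows), " rows x ", x$ncol, " columns; query: ",
      names(x$rows)[x$query_row], " (", length(x$column_map), " residues)\n",
      sep = "")
  invisible(x)
}

#' Query record of an alignment
#'
#' @param x An [msa()] object.
#' @return The ungapped query as a [protein_record()].
#' @export
msa_query <- function(x) {
  stopifnot(inherits(x, "msa"))
  protein_record(names(x$rows)[x$query_row], ungap(x$rows[[x$query_row]]))
}

#' @noRd
ungap <- function(s) gsub("-", "", s, fixed = TRUE)

#' Read a multiple sequence alignment
#'
#' Two dialects are supported. `aligned-fasta` requires all rows to have equal
#' width and keeps every column. `a3m` treats lowercase characters as
#' insertions relative to the query; insertion positions are dropped row-wise
#' before the common column space is formed, per the A3M convention.
#'
#' @param path Path to the alignment file.
#' @param query_id Identifier of the query row.
#' @param dialect `"aligned-fasta"` or `"a3m"`.
#' @return An [msa()] object.
#' @export
read_msa <- function(path, query_id, dialect = c("aligned-fasta", "a3m")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no FASTA headers in ", path)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    paste(lines[seq(hdr[i] + 1L, ends[i])], collapse = "")
  }, "")
  names(seqs) <- ids
  if (dialect == "a3m") {
    # lowercase = insertion relative to the query -> removed before alignment
    seqs <- vapply(seqs, function(s) {
      chars <- strsplit(s, "")[[1]]
      paste(chars[chars == toupper(chars)], collapse = "")
    }, "", USE.NAMES = TRUE)
  }
  msa(seqs, query_id)
}

#' Write an alignment as aligned FASTA
#'
#' @param x An [msa()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(x, path) {
  stopifnot(inherits(x, "msa"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x$rows)) {
    writeLines(c(paste0(">", names(x$rows)[i]), x$rows[[i]]), con)
  }
  invisible(path)
}
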