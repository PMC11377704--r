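#' Reduce 8-state DSSP secondary structure to 3 states
#'
#' The standard reduction: DSSP classes H, G and I become helix (`H`),
#' E and B become strand (`E`), and everything else (T, S, `-`, blank)
#' becomes other (`O`).
#'
#' @param dssp A single string of per-residue DSSP symbols over
#'   `H G I E B T S - ' '`.
#' @return A character vector of per-residue 3-state labels (`H`/`E`/`O`);
#'   length 0 for empty input.
#' @export
#' @examples
#' reduce_dssp8_to_3("HGIEB")  # H H H E E
reduce_dssp8_to_3 <- function(dssp) {
  stopifnot(is.character(dssp), length(dssp) == 1L)
  if (nchar(dssp) == 0L) return(character(0))
  chars <- strsplit(dssp, "")[[1]]
  known <- c("H", "G", "I", "E", "B", "T", "S", "-", " ")
  bad <- which(!(chars %in% known))
  if (length(bad))
    stop("unknown DSSP symbol '", chars[bad[1]], "' at position ", bad[1])
  out <- rep("O", length(chars))
  out[chars %in% c("H", "G", "I")] <- "H"
  out[chars %in% c("E", "B")] <- "E"
  out
}
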