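# Per-segment evaluation: segment extraction, the endpoint/overlap matching
# rule, and the per-protein Q_ok score used for transmembrane segments.

#' Extract maximal segments of one label type
#'
#' @param labels Character vector of per-residue labels.
#' @param type The label whose runs are extracted.
#' @return Data frame with 1-based inclusive `start` and `end` columns, one
#'   row per maximal run of `type`, in order; zero rows if absent.
#' @export
#' @examples
#' extract_segments(strsplit("OOHHHOO", "")[[1]], "H")  # start 3, end 5
extract_segments <- function(labels, type) {
  stopifnot(is.character(labels))
  if (length(labels) == 0L) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(labels == type)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = stops[keep])
}

#' Segment matching rule
#'
#' A predicted segment matches an observed segment of the same type iff
#' both endpoints differ by at most five residues and the intersection of
#' the two intervals covers at least half of their union.
#'
#' @param pred,obs Lists or one-row data frames with `start` and `end`
#'   (1-based inclusive).
#' @param max_shift Maximum allowed endpoint difference (default 5).
#' @return `TRUE` or `FALSE`.
#' @export
segment_match <- function(pred, obs, max_shift = 5L) {
  ps <- pred$start; pe <- pred$end
  os <- obs$start; oe <- obs$end
  stopifnot(ps <= pe, os <= oe)
  if (abs(ps - os) > max_shift || abs(pe - oe) > max_shift) return(FALSE)
  inter <- max(0L, min(pe, oe) - max(ps, os) + 1L)
  uni <- max(pe, oe) - min(ps, os) + 1L
  inter >= uni / 2
}

#' Per-protein segment accuracy (Q_ok)
#'
#' A protein counts as correct iff it has the same number of predicted and
#' observed segments of type `T` and, pairing them in order, every pair
#' satisfies [segment_match()]. The denominator counts only proteins with at
#' least one observed segment of type `T`.
#'
#' @param pred_tracks,obs_tracks Named lists of per-residue label vectors.
#' @param type Segment type `T` (a label).
#' @param max_shift Endpoint tolerance, passed to [segment_match()].
#' @return Percentage in `[0, 100]`; `NA` if no protein has an observed
#'   segment of the type.
#' @export
q_ok <- function(pred_tracks, obs_tracks, type, max_shift = 5L) {
  stopifnot(identical(names(pred_tracks), names(obs_tracks)))
  eligible <- 0L
  correct <- 0L
  for (id in names(obs_tracks)) {
    oseg <- extract_segments(obs_tracks[[id]], type)
    if (nrow(oseg) == 0L) next
    eligible <- eligible + 1L
    pseg <- extract_segments(pred_tracks[[id]], type)
    if (nrow(pseg) != nrow(oseg)) next
    ok <- all(vapply(seq_len(nrow(oseg)), function(k)
      segment_match(pseg[k, ], oseg[k, ], max_shift = max_shift), TRUE))
    if (ok) correct <- correct + 1L
  }
  if (eligible == 0L) {
    warning("no protein with observed segments of type '", type, "'",
            call. = FALSE)
    return(NA_real_)
  }
  100 * correct / eligible
}
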