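# Pairwise similarity measures (PIDE, HVAL) and PSSM construction.

#' Percentage pairwise sequence identity
#'
#' `PIDE = 100 * n_ident / L`, where `L` counts alignment match states
#' (columns where both sequences have a residue) and `n_ident` the identical
#' aligned residue pairs.
#'
#' @param n_ident Number of identical aligned residue pairs.
#' @param L Number of match states; must be at least 1.
#' @return Identity percentage in `[0, 100]`.
#' @export
#' @examples
#' compute_pide(50, 100)  # 50
compute_pide <- function(n_ident, L) {
  stopifnot(length(n_ident) == length(L))
  if (any(L < 1)) stop("L must be >= 1 (no aligned match states)")
  if (any(n_ident < 0 | n_ident > L)) stop("n_ident must lie in [0, L]")
  n_ident * 100 / L
}

#' HSSP-value: identity above the length-dependent similarity threshold
#'
#' The HSSP curve gives, for an alignment of `L` match states, the percentage
#' identity above which two proteins are expected to share structure. The
#' HVAL is the observed identity minus that threshold:
#' \deqn{HVAL = PIDE - \begin{cases}
#'   100 & L \le 11 \\
#'   480\, L^{-0.32\,[1 + \exp(-L/1000)]} & 11 < L \le 450 \\
#'   19.5 & L > 450.\end{cases}}
#' Pairs with `HVAL <= 0` are considered safe to separate across data-set
#' splits.
#'
#' @param pide Percentage identity in `[0, 100]` (vectorized).
#' @param L Match-state count, `>= 1` (vectorized).
#' @return HVAL (percentage points above the threshold curve).
#' @export
#' @examples
#' compute_hval(100, 10)  # 0: at L <= 11 only 100% identity is significant
#' compute_hval(30, 500)  # 10.5
compute_hval <- function(pide, L) {
  stopifnot(length(pide) == length(L) || length(pide) == 1L || length(L) == 1L)
  if (any(pide < 0 | pide > 100)) stop("pide must lie in [0, 100]")
  if (any(L < 1)) stop("L must be >= 1")
  threshold <- ifelse(L <= 11, 100,
               ifelse(L <= 450, 480 * L^(-0.32 * (1 + exp(-L / 1000))), 19.5))
  pide - threshold
}

#' Match-state statistics of an aligned sequence pair
#'
#' Counts the columns where both gapped rows carry a residue (`L`, match
#' states) and how many of those are identical (`n_ident`) — the inputs of
#' [compute_pide()].
#'
#' @param row1,row2 Gapped strings of equal width.
#' @return List with `n_ident` and `L`.
#' @export
pairwise_stats <- function(row1, row2) {
  stopifnot(nchar(row1) == nchar(row2))
  a <- strsplit(toupper(row1), "")[[1]]
  b <- strsplit(toupper(row2), "")[[1]]
  both <- a != "-" & a != "." & b != "-" & b != "."
  list(n_ident = sum(both & a == b), L = sum(both))
}

#' @noRd
new_pssm <- function(values, scheme, alpha) {
  structure(list(values = values, alphabet = AA20, scheme = scheme,
                 alpha = alpha),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat("<pssm> ", nrow(x$values), " positions x 20 residues; scheme: ",
      x$scheme, if (!is.na(x$alpha)) paste0(", alpha = ", x$alpha), "\n",
      sep = "")
  invisible(x)
}

#' Position-specific scoring matrix from an alignment
#'
#' For each query residue position, residues observed in the corresponding
#' alignment column (over rows with a residue there) are counted and turned
#' into pseudocount-smoothed frequencies
#' `f(i, a) = (c(i, a) + alpha * q_a) / (n_i + alpha)` with uniform background
#' `q_a = 1/20`, so every row sums to 1. The optional log-odds scheme reports
#' `log2(f / q_a)`. Residues outside the 20-letter alphabet (`X`) contribute
#' to neither counts nor depth.
#'
#' @param msa An [msa()] object.
#' @param alpha Pseudocount weight (default 1; 0 gives raw frequencies).
#' @param scheme `"frequency"` or `"log-odds"`.
#' @return A `pssm` object: `L x 20` matrix (`L` = query residues) plus
#'   alphabet, scheme and pseudocount.
#' @export
compute_pssm <- function(msa, alpha = 1, scheme = c("frequency", "log-odds")) {
  stopifnot(inherits(msa, "msa"), alpha >= 0)
  scheme <- match.arg(scheme)
  chars <- do.call(rbind, strsplit(unname(msa$rows), ""))
  q <- 1 / 20
  L <- length(msa$column_map)
  values <- matrix(0, L, 20, dimnames = list(NULL, AA20))
  for (i in seq_len(L)) {
    col <- chars[, msa$column_map[i]]
    col <- col[col %in% AA20]
    n <- length(col)
    counts <- tabulate(match(col, AA20), nbins = 20)
    if (n + alpha == 0) {
      values[i, ] <- q  # no countable residue, no pseudocount: background
    } else {
      values[i, ] <- (counts + alpha * q) / (n + alpha)
    }
  }
  if (scheme == "log-odds") values <- log2(values / q)
  new_pssm(values, scheme = scheme, alpha = alpha)
}

#' Numeric model input from a PSSM
#'
#' Frequency profiles are already in `[0, 1]` and pass through unchanged;
#' log-odds scores are clipped to `[-5, 5]` and divided by 5 so both schemes
#' occupy a comparable numeric range as model features.
#'
#' @param pssm A `pssm` object.
#' @return An `L x 20` numeric matrix.
#' @export
pssm_features <- function(pssm) {
  stopifnot(inherits(pssm, "pssm"))
  v <- pssm$values
  if (identical(pssm$scheme, "log-odds")) v <- pmin(pmax(v, -5), 5) / 5
  unname(v)
}
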