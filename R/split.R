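# Redundancy-reduction splitting with leakage verification.
#
# Mirrors the sequential construction of the secondary-structure data sets:
# sample a test set whose members are pairwise below the HSSP curve
# (HVAL <= 0), then a validation set below the curve against test and within
# itself, then keep the remaining chains for training if they are below the
# curve against test and validation and mutually at most 70% identical.

#' @noRd
stats_lookup <- function(stats) {
  stopifnot(all(c("id1", "id2", "n_ident", "L") %in% names(stats)))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  pide <- compute_pide(stats$n_ident, stats$L)
  hval <- compute_hval(pide, stats$L)
  env <- new.env(parent = emptyenv(), size = max(1L, nrow(stats)))
  k <- key(stats$id1, stats$id2)
  for (i in seq_along(k)) assign(k[i], c(pide[i], hval[i]), envir = env)
  function(a, b) {
    v <- get0(key(a, b), envir = env)
    # a pair without an alignment record produced no detectable similarity
    if (is.null(v)) c(0, -Inf) else v
  }
}

#' Redundancy-reducing train/validation/test split
#'
#' Greedy, seeded assignment honouring the HSSP-curve criteria: every pair
#' that spans or lies inside test/validation must have `HVAL <= test_hval_max`
#' (default 0), and any two training chains must share at most
#' `train_pide_max` percent identity (default 70); violators are dropped.
#' Pairs absent from `stats` are treated as having no detectable similarity.
#'
#' @param ids Character vector of record identifiers.
#' @param stats Data frame of pairwise alignment statistics with columns
#'   `id1`, `id2`, `n_ident`, `L` (one row per aligned pair; unordered).
#' @param n_test,n_val Requested test and validation sizes.
#' @param test_hval_max Maximum HVAL allowed for any pair touching test or
#'   validation.
#' @param train_pide_max Maximum PIDE allowed between two training chains.
#' @param eligible Optional named logical vector of per-record metadata
#'   filters (e.g. resolution or deposition-date criteria); ineligible
#'   records can only be assigned to train or dropped.
#' @param seed Integer seed for the random draws.
#' @return An object of class `split_assignment`: data frame with columns
#'   `id` and `partition` (`test`, `val`, `train`, `dropped`) plus the
#'   criteria used, stored as attribute `criteria`.
#' @export
redundancy_split <- function(ids, stats, n_test, n_val,
                             test_hval_max = 0, train_pide_max = 70,
                             eligible = NULL, seed = 1L) {
  stopifnot(length(ids) >= 1, !anyDuplicated(ids), n_test >= 0, n_val >= 0)
  look <- stats_lookup(stats)
  hval <- function(a, b) look(a, b)[2]
  pide <- function(a, b) look(a, b)[1]
  elig <- rep(TRUE, length(ids))
  names(elig) <- ids
  if (!is.null(eligible)) elig[names(eligible)] <- eligible

  pick_set <- function(candidates, n, against, label) {
    chosen <- character(0)
    for (id in candidates) {
      if (length(chosen) == n) break
      ok <- all(vapply(c(against, chosen), function(o) hval(id, o) <= test_hval_max,
                       TRUE))
      if (ok) chosen <- c(chosen, id)
    }
    if (length(chosen) < n)
      stop("requested ", label, " size ", n, " unattainable; at most ",
           length(chosen), " compatible records available")
    chosen
  }

  order1 <- with_seed(seed, sample(ids))
  test <- pick_set(order1[elig[order1]], n_test, character(0), "test")
  rest1 <- setdiff(order1, test)
  val <- pick_set(rest1[elig[rest1]], n_val, test, "val")

  rest2 <- setdiff(order1, c(test, val))
  dropped <- character(0)
  # cross-set criterion first, then the mutual-identity filter inside train
  ok_cross <- vapply(rest2, function(id)
    all(vapply(c(test, val), function(o) hval(id, o) <= test_hval_max, TRUE)),
    TRUE)
  dropped <- c(dropped, rest2[!ok_cross])
  train <- character(0)
  for (id in rest2[ok_cross]) {
    if (all(vapply(train, function(o) pide(id, o) <= train_pide_max, TRUE)))
      train <- c(train, id)
    else dropped <- c(dropped, id)
  }

  partition <- setNames(rep("dropped", length(ids)), ids)
  partition[test] <- "test"
  partition[val] <- "val"
  partition[train] <- "train"
  out <- data.frame(id = ids, partition = unname(partition[ids]))
  attr(out, "criteria") <- list(test_hval_max = test_hval_max,
                                train_pide_max = train_pide_max,
                                n_test = n_test, n_val = n_val, seed = seed)
  class(out) <- c("split_assignment", "data.frame")
  out
}

#' @export
print.split_assignment <- function(x, ...) {
  tab <- table(factor(x$partition, levels = c("train", "val", "test", "dropped")))
  cat("<split_assignment> ", nrow(x), " records: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Verify that no sequence similarity leaks across partitions
#'
#' Lists every pair spanning two different partitions (train/val/test) whose
#' fractional identity `PIDE/100` is at or above `threshold` (default 0.3,
#' the conventional limit below which unrelated structures are expected).
#' An empty report means the split is leakage-free at that threshold.
#'
#' @param assignment A [redundancy_split()] result (or any data frame with
#'   `id` and `partition` columns).
#' @param stats Pairwise statistics as in [redundancy_split()].
#' @param threshold Fractional identity limit in `[0, 1]`.
#' @return Data frame with columns `id1`, `id2`, `partition1`, `partition2`,
#'   `pide`; zero rows on pass. Attribute `pass` is `TRUE`/`FALSE`.
#' @export
verify_no_leakage <- function(assignment, stats, threshold = 0.3) {
  part <- setNames(assignment$partition, assignment$id)
  keep <- stats$id1 %in% names(part) & stats$id2 %in% names(part)
  s <- stats[keep, , drop = FALSE]
  p1 <- unname(part[s$id1])
  p2 <- unname(part[s$id2])
  active <- p1 != "dropped" & p2 != "dropped" & p1 != p2
  pide <- compute_pide(s$n_ident, s$L)
  bad <- active & pide / 100 >= threshold
  report <- data.frame(id1 = s$id1[bad], id2 = s$id2[bad],
                       partition1 = p1[bad], partition2 = p2[bad],
                       pide = pide[bad])
  attr(report, "pass") <- nrow(report) == 0L
  report
}
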