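# Random baselines that calibrate the accuracy scales.

#' Shuffle-label baseline
#'
#' Draws both labels and predictions i.i.d. from the class distribution `p`
#' and reports the simulated accuracy next to its closed form
#' `100 * sum(p^2)`. With three equally likely states the expectation is
#' 33.3% (Q3); with ten, 10% (Q10).
#'
#' @param p Class probabilities (summing to 1).
#' @param n Number of draws (residues or proteins).
#' @param seed Integer seed.
#' @return List with `simulated` and `expected` (both percent).
#' @export
baseline_shuffle_labels <- function(p, n, seed = 1L) {
  stopifnot(abs(sum(p) - 1) < 1e-9, all(p >= 0), n >= 1)
  k <- length(p)
  sim <- with_seed(seed, {
    obs <- sample.int(k, n, replace = TRUE, prob = p)
    pred <- sample.int(k, n, replace = TRUE, prob = p)
    100 * mean(obs == pred)
  })
  list(simulated = sim, expected = 100 * sum(p^2))
}

#' Majority-class baseline
#'
#' Predicts the globally most frequent observed class for every residue
#' (ties resolved to the earliest class in `classes`).
#'
#' @param obs Character vector of observed per-residue labels.
#' @param classes Class order used for tie-breaking; defaults to the sorted
#'   unique observed labels.
#' @return List with `prediction` (constant label track) and `accuracy`
#'   (percent).
#' @export
baseline_majority <- function(obs, classes = sort(unique(obs))) {
  stopifnot(length(obs) >= 1)
  counts <- vapply(classes, function(cl) sum(obs == cl), 1L)
  winner <- classes[which.max(counts)]  # which.max takes the earliest tie
  pred <- rep(winner, length(obs))
  list(prediction = pred, accuracy = q3(pred, obs), class = winner)
}
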