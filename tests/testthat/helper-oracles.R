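# Independent brute-force oracles used to cross-check every metric.
# They deliberately share no code with the package implementations.

oracle_accuracy <- function(pred, obs) {
  hits <- 0
  for (i in seq_along(pred)) if (pred[i] == obs[i]) hits <- hits + 1
  100 * hits / length(pred)
}

oracle_spearman <- function(u, v) {
  suppressWarnings(stats::cor(u, v, method = "spearman"))
}

oracle_f1 <- function(pred, obs, positive) {
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == positive && obs[i] == positive) tp <- tp + 1
    if (pred[i] == positive && obs[i] != positive) fp <- fp + 1
    if (pred[i] != positive && obs[i] == positive) fn <- fn + 1
  }
  p <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA
  r <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA
  p0 <- if (is.na(p)) 0 else p
  r0 <- if (is.na(r)) 0 else r
  if (p0 + r0 == 0) 0 else 2 * p0 * r0 / (p0 + r0)
}

oracle_mcc <- function(pred_bin, obs_bin) {
  tab <- table(factor(pred_bin, c(FALSE, TRUE)), factor(obs_bin, c(FALSE, TRUE)))
  tp <- tab[2, 2]; tn <- tab[1, 1]; fp <- tab[2, 1]; fn <- tab[1, 2]
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(NA_real_)
  (tp * tn - fp * fn) / den
}

# Enumerates segments and applies the matching rule literally.
oracle_qok <- function(pred_tracks, obs_tracks, type) {
  segs <- function(x) {
    out <- list()
    i <- 1
    while (i <= length(x)) {
      if (x[i] == type) {
        j <- i
        while (j < length(x) && x[j + 1] == type) j <- j + 1
        out[[length(out) + 1]] <- c(i, j)
        i <- j + 1
      } else i <- i + 1
    }
    out
  }
  ok_pair <- function(p, o) {
    if (abs(p[1] - o[1]) > 5 || abs(p[2] - o[2]) > 5) return(FALSE)
    inter <- min(p[2], o[2]) - max(p[1], o[1]) + 1
    uni <- max(p[2], o[2]) - min(p[1], o[1]) + 1
    inter >= uni / 2
  }
  n_ok <- 0; n_el <- 0
  for (id in names(obs_tracks)) {
    os <- segs(obs_tracks[[id]])
    if (length(os) == 0) next
    n_el <- n_el + 1
    ps <- segs(pred_tracks[[id]])
    if (length(ps) != length(os)) next
    if (all(mapply(ok_pair, ps, os))) n_ok <- n_ok + 1
  }
  if (n_el == 0) NA_real_ else 100 * n_ok / n_el
}
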