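# Per-residue, per-protein and per-chain evaluation measures.

#' Three-state per-residue accuracy (Q3)
#'
#' `100 * correct / total` over aligned per-residue label tracks.
#'
#' @param pred,obs Equal-length character vectors of per-residue labels.
#' @return Percentage in `[0, 100]`.
#' @export
q3 <- function(pred, obs) {
  if (length(pred) != length(obs))
    stop("length mismatch: ", length(pred), " vs ", length(obs))
  if (length(pred) == 0L) stop("empty tracks")
  100 * mean(pred == obs)
}

#' Ten-state per-protein accuracy (Q10)
#'
#' `100 * correct / total` over per-protein class assignments.
#'
#' @param pred,obs Equal-length vectors of per-protein classes.
#' @return Percentage in `[0, 100]`.
#' @export
q10 <- function(pred, obs) {
  if (length(pred) != length(obs))
    stop("length mismatch: ", length(pred), " vs ", length(obs))
  if (length(pred) == 0L) stop("no proteins")
  100 * mean(pred == obs)
}

#' Per-chain aggregation of a performance measure
#'
#' Metrics are estimated per chain; the chain distribution gives the mean,
#' the population standard deviation, and the standard error
#' `SE = SD / sqrt(n - 1)`. The 95% confidence half-width is `1.96 * SE`.
#'
#' @param values Numeric per-chain metric values.
#' @return List of class `metric_report`: `values`, `n`, `mean`, `sd`, `se`,
#'   `ci95`. For `n = 1`, `sd`/`se`/`ci95` are `NA` (flagged undefined).
#' @export
aggregate_per_chain <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1)
  n <- length(values)
  m <- mean(values)
  if (n == 1L) {
    out <- list(values = values, n = n, mean = m, sd = NA_real_,
                se = NA_real_, ci95 = NA_real_)
  } else {
    sd_pop <- sqrt(mean((values - m)^2))
    se <- sd_pop / sqrt(n - 1)
    out <- list(values = values, n = n, mean = m, sd = sd_pop, se = se,
                ci95 = 1.96 * se)
  }
  structure(out, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report> n = ", x$n, ": mean ", signif(x$mean, 5), sep = "")
  if (!is.na(x$sd))
    cat(" (SD ", signif(x$sd, 5), ", SE ", signif(x$se, 5),
        ", 95% CI +/- ", signif(x$ci95, 5), ")", sep = "")
  else cat(" (SD/SE undefined for a single chain)")
  cat("\n")
  invisible(x)
}

#' Spearman rank correlation
#'
#' The product-moment correlation applied to average ranks (ties receive
#' their mean rank), the standard form for comparing predicted and observed
#' continuous per-residue scores.
#'
#' @param u,v Equal-length numeric vectors, length `>= 2`.
#' @return Correlation in `[-1, 1]`; `NA` (flagged undefined) if either
#'   vector is constant after ranking.
#' @export
spearman <- function(u, v) {
  if (length(u) != length(v)) stop("length mismatch")
  if (length(u) < 2L) stop("need at least 2 observations")
  ru <- rank(u, ties.method = "average")
  rv <- rank(v, ties.method = "average")
  du <- ru - mean(ru)
  dv <- rv - mean(rv)
  den <- sqrt(sum(du^2) * sum(dv^2))
  if (den == 0) {
    warning("constant vector: Spearman correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  sum(du * dv) / den
}

#' Precision, recall and F1 for a binary per-residue task
#'
#' `Recall = TP/(TP+FN)`, `Precision = TP/(TP+FP)` (both in percent) and
#' `F1 = 2 * R * P / (R + P)`. When no residue is predicted positive,
#' precision is undefined (`NA`); when additionally `R + P = 0`, F1 is 0 by
#' the usual convention.
#'
#' @param pred,obs Equal-length label vectors.
#' @param positive The positive-class label (e.g. `"binding"`).
#' @return List with `tp`, `fp`, `fn`, `tn`, `precision`, `recall`, `f1`
#'   (percent).
#' @export
f1_binary <- function(pred, obs, positive) {
  if (length(pred) != length(obs)) stop("length mismatch")
  tp <- sum(pred == positive & obs == positive)
  fp <- sum(pred == positive & obs != positive)
  fn <- sum(pred != positive & obs == positive)
  tn <- sum(pred != positive & obs != positive)
  recall <- if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn)
  precision <- if (tp + fp == 0) NA_real_ else 100 * tp / (tp + fp)
  r0 <- if (is.na(recall)) 0 else recall
  p0 <- if (is.na(precision)) 0 else precision
  f1 <- if (r0 + p0 == 0) 0 else 2 * r0 * p0 / (r0 + p0)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       precision = precision, recall = recall, f1 = f1)
}

#' Matthews correlation for conservation classes
#'
#' Per-residue conservation is annotated in nine classes (1 most variable,
#' 9 most conserved). Both tracks are binarized into conserved (class 6 and
#' above) versus not conserved, and the Matthews correlation coefficient of
#' the resulting 2x2 table is returned.
#'
#' @param pred,obs Equal-length integer vectors with classes in 1..9.
#' @return MCC in `[-1, 1]`; `NA` (flagged) for a degenerate table.
#' @export
mcc_conservation <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("length mismatch")
  stopifnot(all(pred %in% 1:9), all(obs %in% 1:9))
  mcc_binary(pred >= 6, obs >= 6)
}

#' @noRd
mcc_binary <- function(pred, obs) {
  tp <- sum(pred & obs); tn <- sum(!pred & !obs)
  fp <- sum(pred & !obs); fn <- sum(!pred & obs)
  den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  if (den == 0) {
    warning("degenerate 2x2 table: MCC undefined", call. = FALSE)
    return(NA_real_)
  }
  (tp * tn - fp * fn) / den
}
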