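#' Configuration for the per-residue convolutional predictor
#'
#' All variants share the same residue-level convolutional architecture with
#' channel widths `input -> 32 -> 16 -> 8 -> K` and leaky-relu activations,
#' so performance differences between workflows can be attributed to their
#' inputs rather than model capacity. `concat` widens the input by the 20
#' PSSM columns; `split` processes embedding and PSSM in separate branches
#' whose learned features are concatenated (after each branch's second layer)
#' before a final convolutional block.
#'
#' @param variant `"base"`, `"concat"` or `"split"`.
#' @param input_width Embedding width `D` fed to the embedding input.
#' @param pssm_width Width of the PSSM input (20; used by concat/split).
#' @param hidden_widths Channel widths of the hidden layers.
#' @param n_classes Number of output channels `K` (`>= 2` categorical;
#'   use `continuous = TRUE` for a single-score regression head).
#' @param classes Class labels in fixed order; ties in argmax go to the
#'   earliest label.
#' @param kernel_size Odd convolution window over the residue axis.
#' @param continuous If `TRUE`, a linear single-channel head trained with
#'   squared error (disorder-score style) replaces the softmax head.
#' @param lr Adam learning rate.
#' @param max_epochs Maximum training epochs (full-batch).
#' @param patience Early-stopping patience: training stops once the epochs
#'   elapsed since the best validation metric reach `patience` (0 trains
#'   exactly one epoch).
#' @param seed Integer seed controlling initialization (training is
#'   deterministic given data and seed).
#' @return A list of class `cnn_config`.
#' @export
cnn_config <- function(variant = c("base", "concat", "split"),
                       input_width = 1024L, pssm_width = 20L,
                       hidden_widths = c(32L, 16L, 8L),
                       n_classes = 3L, classes = c("H", "E", "O"),
                       kernel_size = 7L, continuous = FALSE,
                       lr = 1e-3, max_epochs = 200L, patience = 10L,
                       seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(length(hidden_widths) >= 1, kernel_size %% 2 == 1,
            input_width >= 1, pssm_width >= 1)
  if (continuous) {
    n_classes <- 1L
    classes <- NULL
  } else {
    stopifnot(n_classes >= 2, length(classes) == n_classes)
  }
  if (variant == "split" && length(hidden_widths) < 3)
    stop("split variant needs at least 3 hidden widths (two per-branch, one merged)")
  structure(list(variant = variant, input_width = as.integer(input_width),
                 pssm_width = as.integer(pssm_width),
                 hidden_widths = as.integer(hidden_widths),
                 n_classes = as.integer(n_classes), classes = classes,
                 kernel_size = as.integer(kernel_size),
                 continuous = continuous, lr = lr,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "cnn_config")
}

# Layer plan per variant. Widths follow the 1024/32/16/8 scheme scaled to
# the configured input width.
#' @noRd
build_params <- function(config) {
  k <- config$kernel_size
  with_seed(config$seed, {
    if (config$variant == "split") {
      h <- config$hidden_widths
      be <- list(conv_init(k, config$input_width, h[1]), conv_init(k, h[1], h[2]))
      bp <- list(conv_init(k, config$pssm_width, h[1]), conv_init(k, h[1], h[2]))
      rest_w <- c(2L * h[2], h[-(1:2)], config$n_classes)
      merged <- lapply(seq_len(length(rest_w) - 1L), function(l)
        conv_init(k, rest_w[l], rest_w[l + 1L]))
      list(branch_emb = be, branch_pssm = bp, merged = merged)
    } else {
      d0 <- config$input_width +
        if (config$variant == "concat") config$pssm_width else 0L
      w <- c(d0, config$hidden_widths, config$n_classes)
      list(main = lapply(seq_len(length(w) - 1L), function(l)
        conv_init(k, w[l], w[l + 1L])))
    }
  })
}

#' @noRd
n_params <- function(params) {
  sum(rapply(params, length, how = "unlist"))
}

# Stacks a named list of per-chain matrices into one matrix + chain ids.
#' @noRd
stack_chains <- function(xs) {
  lens <- vapply(xs, nrow, 1L)
  list(X = do.call(rbind, lapply(xs, unname)),
       chain = rep(seq_along(xs), lens), lens = lens, ids = names(xs))
}

# Forward pass for any variant; returns output scores and caches.
#' @noRd
net_forward <- function(params, config, X, Xp, shifts) {
  if (config$variant == "split") {
    fe <- stack_forward(X, params$branch_emb, shifts, act_last = TRUE)
    fp <- stack_forward(Xp, params$branch_pssm, shifts, act_last = TRUE)
    merged_in <- cbind(fe$acts[[length(fe$acts)]], fp$acts[[length(fp$acts)]])
    fm <- stack_forward(merged_in, params$merged, shifts, act_last = FALSE)
    list(out = fm$acts[[length(fm$acts)]], fe = fe, fp = fp, fm = fm)
  } else {
    f <- stack_forward(X, params$main, shifts, act_last = FALSE)
    list(out = f$acts[[length(f$acts)]], f = f)
  }
}

#' @noRd
net_backward <- function(params, config, fw, dOut, shifts) {
  if (config$variant == "split") {
    bm <- stack_backward(fw$fm, params$merged, shifts, dOut, act_last = FALSE)
    h2 <- ncol(fw$fe$acts[[length(fw$fe$acts)]])
    dMerged <- bm$dX
    be <- stack_backward(fw$fe, params$branch_emb, shifts,
                         dMerged[, seq_len(h2), drop = FALSE], act_last = TRUE)
    bp <- stack_backward(fw$fp, params$branch_pssm, shifts,
                         dMerged[, h2 + seq_len(h2), drop = FALSE],
                         act_last = TRUE)
    list(branch_emb = be$grads, branch_pssm = bp$grads, merged = bm$grads)
  } else {
    b <- stack_backward(fw$f, params$main, shifts, dOut, act_last = FALSE)
    list(main = b$grads)
  }
}

# Split features (if any) out of the per-chain feature list. Accepted forms:
# a plain matrix per chain (base/concat), or list(emb =, pssm =) per chain.
#' @noRd
prepare_features <- function(x, config) {
  stopifnot(is.list(x), length(x) >= 1, !is.null(names(x)))
  if (config$variant == "split") {
    emb <- lapply(x, function(e) {
      if (!is.list(e) || is.null(e$emb) || is.null(e$pssm))
        stop("split variant needs per-chain list(emb =, pssm =) features")
      e$emb
    })
    pssm <- lapply(x, `[[`, "pssm")
    for (id in names(x)) {
      if (ncol(emb[[id]]) != config$input_width)
        stop("embedding width ", ncol(emb[[id]]), " != configured ",
             config$input_width, " for '", id, "'")
      if (ncol(pssm[[id]]) != config$pssm_width)
        stop("PSSM width mismatch for '", id, "'")
      if (nrow(emb[[id]]) != nrow(pssm[[id]]))
        stop("embedding/PSSM length mismatch for '", id, "'")
    }
    se <- stack_chains(emb)
    sp <- stack_chains(pssm)
    list(X = se$X, Xp = sp$X, chain = se$chain, lens = se$lens, ids = se$ids)
  } else {
    want <- config$input_width +
      if (config$variant == "concat") config$pssm_width else 0L
    for (id in names(x)) {
      if (!is.matrix(x[[id]]))
        stop("features for '", id, "' must be a matrix for variant ",
             config$variant)
      if (ncol(x[[id]]) != want)
        stop("feature width ", ncol(x[[id]]), " != expected ", want,
             " for '", id, "'")
    }
    s <- stack_chains(x)
    list(X = s$X, Xp = NULL, chain = s$chain, lens = s$lens, ids = s$ids)
  }
}

#' @noRd
encode_labels <- function(y, config, lens, ids) {
  stopifnot(identical(sort(names(y)), sort(ids)))
  y <- y[ids]
  bad <- which(vapply(y, length, 1L) != lens)
  if (length(bad))
    stop("label length mismatch for '", ids[bad[1]], "'")
  v <- unlist(y, use.names = FALSE)
  if (config$continuous) return(as.numeric(v))
  idx <- match(v, config$classes)
  if (anyNA(idx))
    stop("labels outside declared classes: ",
         paste(unique(v[is.na(idx)]), collapse = ", "))
  idx
}

#' Fit the per-residue convolutional predictor
#'
#' Trains a small 1-D CNN over the residue axis on fixed per-residue input
#' features (pLM embeddings, optionally fused with PSSMs) by full-batch Adam
#' on per-residue cross-entropy (categorical) or squared error (continuous),
#' with early stopping on the validation metric (Q3-style accuracy, or
#' Spearman correlation for continuous targets). Training is deterministic
#' given the data and `config$seed`; the returned model carries the weights
#' of the best validation epoch.
#'
#' @param x Named list of per-chain feature matrices (`L x D` for
#'   `base`, `L x (D+20)` for `concat`) or, for `split`, per-chain
#'   `list(emb =, pssm =)` pairs.
#' @param y Named list of per-chain label vectors (character over
#'   `config$classes`, or numeric when `config$continuous`).
#' @param val_x,val_y Optional validation chains in the same format; ids must
#'   be disjoint from the training ids. Without a validation set the
#'   training loss drives early stopping.
#' @param config A [cnn_config()].
#' @return An object of class `residue_cnn` with `config`, fitted `params`,
#'   per-epoch `history` (loss and validation metric) and `best_epoch`.
#' @seealso [predict.residue_cnn()]
#' @export
residue_cnn <- function(x, y, val_x = NULL, val_y = NULL,
                        config = cnn_config()) {
  stopifnot(inherits(config, "cnn_config"))
  if (length(x) == 0) stop("empty training set")
  if (!is.null(val_x) && length(intersect(names(x), names(val_x))))
    stop("train and validation ids overlap")
  tr <- prepare_features(x, config)
  ty <- encode_labels(y, config, tr$lens, tr$ids)
  shifts <- make_shifts(tr$chain, config$kernel_size)
  va <- NULL
  if (!is.null(val_x)) {
    va <- prepare_features(val_x, config)
    va$y <- encode_labels(val_y, config, va$lens, va$ids)
    va$shifts <- make_shifts(va$chain, config$kernel_size)
  }

  params <- build_params(config)
  opt <- adam_new(params)
  n <- nrow(tr$X)
  onehot <- NULL
  if (!config$continuous) {
    onehot <- matrix(0, n, config$n_classes)
    onehot[cbind(seq_len(n), ty)] <- 1
  }

  val_metric <- function(p) {
    if (is.null(va)) return(NA_real_)
    out <- net_forward(p, config, va$X, va$Xp, va$shifts)$out
    if (config$continuous) {
      spearman(as.numeric(out), va$y)
    } else {
      100 * mean(max.col(out, ties.method = "first") == va$y)
    }
  }

  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_metric = numeric(0))
  best <- list(metric = -Inf, params = params, epoch = 0L)
  for (epoch in seq_len(config$max_epochs)) {
    fw <- net_forward(params, config, tr$X, tr$Xp, shifts)
    if (config$continuous) {
      pred <- as.numeric(fw$out)
      loss <- mean((pred - ty)^2)
      dOut <- matrix(2 * (pred - ty) / n, ncol = 1)
    } else {
      P <- softmax_rows(fw$out)
      loss <- -mean(log(pmax(P[cbind(seq_len(n), ty)], 1e-12)))
      dOut <- (P - onehot) / n
    }
    if (!is.finite(loss)) stop("non-finite loss at epoch ", epoch)
    grads <- net_backward(params, config, fw, dOut, shifts)
    st <- adam_step(params, grads, opt, lr = config$lr)
    params <- st$params
    opt <- st$state

    metric <- if (is.null(va)) -loss else val_metric(params)
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = loss,
                                val_metric = if (is.null(va)) NA_real_ else metric))
    if (metric > best$metric) {
      best <- list(metric = metric, params = params, epoch = epoch)
    }
    if (epoch - best$epoch >= config$patience) break
  }

  structure(list(config = config, params = best$params, history = history,
                 best_epoch = best$epoch,
                 best_val_metric = if (is.null(va)) NA_real_ else best$metric,
                 n_params = n_params(best$params)),
            class = "residue_cnn")
}

#' Predict per-residue tracks with a fitted model
#'
#' @param object A fitted [residue_cnn()].
#' @param newdata Named list of per-chain features in the training format.
#' @param type `"prob"` for `L x K` per-residue class probabilities (rows sum
#'   to 1), `"class"` for argmax labels (ties resolved to the earliest
#'   configured class), `"score"` for the raw continuous head.
#' @param ... Unused.
#' @return Named list of per-chain prediction tracks.
#' @export
predict.residue_cnn <- function(object, newdata,
                                type = c("prob", "class", "score"), ...) {
  type <- match.arg(type)
  config <- object$config
  if (config$continuous && type != "score") type <- "score"
  pf <- prepare_features(newdata, config)
  shifts <- make_shifts(pf$chain, config$kernel_size)
  out <- net_forward(object$params, config, pf$X, pf$Xp, shifts)$out
  if (!config$continuous && type != "score") {
    out <- softmax_rows(out)
    colnames(out) <- config$classes
  }
  split_rows <- function(m) {
    stops <- cumsum(pf$lens)
    starts <- stops - pf$lens + 1L
    setNames(lapply(seq_along(pf$lens), function(i)
      m[starts[i]:stops[i], , drop = FALSE]), pf$ids)
  }
  tracks <- split_rows(out)
  if (type == "class") {
    tracks <- lapply(tracks, function(m)
      config$classes[max.col(m, ties.method = "first")])
  } else if (type == "score" && config$continuous) {
    tracks <- lapply(tracks, as.numeric)
  }
  tracks
}

#' @export
print.residue_cnn <- function(x, ...) {
  cat("<residue_cnn> variant: ", x$config$variant,
      if (x$config$continuous) " (continuous head)", "\n", sep = "")
  cat("  input width: ", x$config$input_width,
      if (x$config$variant != "base") paste0(" + ", x$config$pssm_width, " PSSM"),
      "; hidden: ", paste(x$config$hidden_widths, collapse = "/"),
      "; K = ", x$config$n_classes, "; kernel = ", x$config$kernel_size,
      "\n", sep = "")
  cat("  ", x$n_params, " parameters; trained ", nrow(x$history),
      " epochs (best epoch ", x$best_epoch, ")\n", sep = "")
  invisible(x)
}

#' @export
summary.residue_cnn <- function(object, ...) {
  print(object)
  h <- object$history
  cat("  final loss: ", signif(h$loss[nrow(h)], 5), sep = "")
  if (!is.na(object$best_val_metric))
    cat("; best validation metric: ", signif(object$best_val_metric, 5), sep = "")
  cat("\n")
  invisible(object)
}

#' @export
coef.residue_cnn <- function(object, ...) object$params

#' @export
plot.residue_cnn <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch", ylab = "loss",
                 main = "training history", ...)
  if (!all(is.na(h$val_metric))) {
    graphics::par(new = TRUE)
    graphics::plot(h$epoch, h$val_metric, type = "l", lty = 2, col = 2,
                   axes = FALSE, xlab = "", ylab = "")
    graphics::axis(4, col.axis = 2)
    graphics::mtext("validation metric", side = 4, line = 2, col = 2)
  }
  invisible(x)
}

#' @export
residuals.residue_cnn <- function(object, x, y, ...) {
  if (missing(x) || missing(y))
    stop("supply the features and labels to compute residuals against")
  if (object$config$continuous) {
    pred <- predict(object, x, type = "score")
    Map(function(p, o) p - o, pred, y[names(pred)])
  } else {
    prob <- predict(object, x, type = "prob")
    Map(function(p, o) 1 - p[cbind(seq_along(o), match(o, object$config$classes))],
        prob, y[names(prob)])
  }
}

#' @export
simulate.residue_cnn <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (object$config$continuous)
    stop("simulate() is defined for categorical models only")
  prob <- predict(object, newdata, type = "prob")
  do_draw <- function() lapply(prob, function(m)
    object$config$classes[apply(m, 1, function(p) sample.int(length(p), 1, prob = p))])
  if (!is.null(seed)) with_seed(seed, replicate(nsim, do_draw(), simplify = FALSE))
  else replicate(nsim, do_draw(), simplify = FALSE)
}
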