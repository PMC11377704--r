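# 1-D convolution primitives over the residue axis.
#
# Chains are stacked row-wise into one big (sum L) x width matrix together
# with a chain-id vector; convolution is computed as a sum of shifted
# matrix products, with shifts that never cross a chain boundary (positions
# beyond a chain contribute zeros, i.e. zero padding per chain).

# Precompute, for kernel size k, the row-index vectors into rbind(0, X):
# index 1 is the all-zero row, index i+1 is residue i.
#' @noRd
make_shifts <- function(chain, k) {
  n <- length(chain)
  h <- (k - 1L) %/% 2L
  lapply(seq.int(-h, h), function(t) {
    j <- seq_len(n) + t
    ok <- j >= 1L & j <= n
    ok[ok] <- chain[j[ok]] == chain[ok]
    idx <- rep(1L, n)
    idx[ok] <- j[ok] + 1L
    idx
  })
}

#' @noRd
conv_init <- function(k, d_in, d_out) {
  sd <- sqrt(2 / (k * d_in))
  list(W = lapply(seq_len(k), function(j)
         matrix(stats::rnorm(d_in * d_out, 0, sd), d_in, d_out)),
       b = numeric(d_out))
}

#' @noRd
conv_forward <- function(X, layer, shifts) {
  n <- nrow(X)
  Xz <- rbind(0, X)
  H <- matrix(layer$b, n, length(layer$b), byrow = TRUE)
  for (j in seq_along(shifts))
    H <- H + Xz[shifts[[j]], , drop = FALSE] %*% layer$W[[j]]
  H
}

# Returns gradients (dW, db) and the gradient w.r.t. the layer input.
#' @noRd
conv_backward <- function(X, layer, shifts, dH) {
  n <- nrow(X)
  Xz <- rbind(0, X)
  dW <- vector("list", length(shifts))
  dX <- matrix(0, n, ncol(X))
  for (j in seq_along(shifts)) {
    idx <- shifts[[j]]
    dW[[j]] <- crossprod(Xz[idx, , drop = FALSE], dH)
    M <- dH %*% t(layer$W[[j]])
    valid <- idx > 1L
    rows <- idx[valid] - 1L   # injective for a fixed shift
    dX[rows, ] <- dX[rows, , drop = FALSE] + M[valid, , drop = FALSE]
  }
  list(dW = dW, db = colSums(dH), dX = dX)
}

#' @noRd
lrelu <- function(x, slope = 0.01) {
  neg <- x < 0
  x[neg] <- slope * x[neg]
  x
}

#' @noRd
lrelu_grad <- function(x, slope = 0.01) ifelse(x < 0, slope, 1)

#' @noRd
softmax_rows <- function(H) {
  m <- H - apply(H, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

# A stack of convolutional layers with leaky-relu between them; the final
# layer is linear (probability/score transform applied by the caller).
#' @noRd
stack_forward <- function(X, layers, shifts, act_last = FALSE) {
  acts <- vector("list", length(layers) + 1L)
  pre <- vector("list", length(layers))
  acts[[1]] <- X
  for (l in seq_along(layers)) {
    Z <- conv_forward(acts[[l]], layers[[l]], shifts)
    pre[[l]] <- Z
    acts[[l + 1L]] <- if (l < length(layers) || act_last) lrelu(Z) else Z
  }
  list(acts = acts, pre = pre)
}

# dOut is the gradient w.r.t. the stack output (post-activation if act_last).
#' @noRd
stack_backward <- function(fw, layers, shifts, dOut, act_last = FALSE) {
  grads <- vector("list", length(layers))
  d <- dOut
  for (l in rev(seq_along(layers))) {
    if (l < length(layers) || act_last) d <- d * lrelu_grad(fw$pre[[l]])
    g <- conv_backward(fw$acts[[l]], layers[[l]], shifts, d)
    grads[[l]] <- list(dW = g$dW, db = g$db)
    d <- g$dX
  }
  list(grads = grads, dX = d)
}

# Adam over a nested parameter list (layers of W-lists and b vectors).
#' @noRd
adam_new <- function(params) {
  zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

#' @noRd
adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- vector("list", length(p))
      names(out) <- names(p)
      for (i in seq_along(p)) {
        r <- walk(p[[i]], g[[i]], m[[i]], v[[i]])
        out[[i]] <- r
      }
      return(out)
    }
    m2 <- beta1 * m + (1 - beta1) * g
    v2 <- beta2 * v + (1 - beta2) * g * g
    mh <- m2 / (1 - beta1^state$t)
    vh <- v2 / (1 - beta2^state$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m2, v = v2, leaf = TRUE)
  }
  # walk returns interleaved structure; unzip it
  unzip <- function(r, field) {
    if (!is.null(r$leaf)) return(r[[field]])
    lapply(r, unzip, field = field)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = unzip(r, "p"),
       state = list(m = unzip(r, "m"), v = unzip(r, "v"), t = state$t))
}
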