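# Minimal reverse-mode automatic differentiation on matrices.
#
# The action-value network needs gradients through embeddings, an LSTM,
# convolutions (as shifted-stack matmuls), multi-head attention, layer
# normalisation and linear maps.  Rather than emulate a full tensor library,
# each of these is a fused tape op with a hand-derived backward pass.  A tape
# is recorded per forward pass; backward() walks it in reverse.  Correctness
# is pinned down by a finite-difference gradient check in the test suite.

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL
.ag$n <- 0L
.ag$recording <- FALSE

ag_recording <- function() isTRUE(.ag$recording)

# start recording a fresh tape
ag_begin <- function() {
  .ag$tape <- vector("list", 256L)
  .ag$n <- 0L
  .ag$recording <- TRUE
  invisible(NULL)
}

ag_stop <- function() {
  .ag$recording <- FALSE
  .ag$tape <- NULL
  .ag$n <- 0L
  invisible(NULL)
}

ag_push <- function(node) {
  n <- .ag$n + 1L
  if (n > length(.ag$tape)) {
    .ag$tape <- c(.ag$tape, vector("list", length(.ag$tape)))
  }
  .ag$tape[[n]] <- node
  .ag$n <- n
  node
}

# a node wraps a numeric matrix; leaves are parameters whose gradient is read
# back after backward()
ag_node <- function(val, backfn = NULL, leaf = FALSE) {
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$grad <- NULL
  e$backfn <- backfn
  e$leaf <- leaf
  class(e) <- "ag_node"
  if (ag_recording() && (!is.null(backfn) || leaf)) ag_push(e)
  e
}

ag_leaf <- function(val) ag_node(val, leaf = TRUE)
ag_const <- function(val) ag_node(val)

ag_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# run the tape backwards from a scalar loss node
ag_backward <- function(loss) {
  stopifnot(ag_recording())
  loss$grad <- 1
  for (k in seq(.ag$n, 1L)) {
    node <- .ag$tape[[k]]
    if (!is.null(node$grad) && !is.null(node$backfn)) node$backfn(node$grad)
  }
  invisible(NULL)
}

## ---- primitive ops -------------------------------------------------------

ag_mm <- function(a, b) {
  v <- a$val %*% b$val
  ag_node(v, backfn = function(g) {
    ag_accum(a, g %*% t(b$val))
    ag_accum(b, t(a$val) %*% g)
  })
}

ag_add <- function(a, b) {
  ag_node(a$val + b$val, backfn = function(g) {
    ag_accum(a, g)
    ag_accum(b, g)
  })
}

# add a 1 x d bias row to every row of a
ag_add_bias <- function(a, bias) {
  v <- a$val + matrix(bias$val, nrow(a$val), length(bias$val), byrow = TRUE)
  ag_node(v, backfn = function(g) {
    ag_accum(a, g)
    ag_accum(bias, matrix(colSums(g), 1L))
  })
}

ag_scale <- function(a, s) {
  ag_node(a$val * s, backfn = function(g) ag_accum(a, g * s))
}

ag_tanh <- function(a) {
  v <- tanh(a$val)
  ag_node(v, backfn = function(g) ag_accum(a, g * (1 - v * v)))
}

ag_relu <- function(a) {
  v <- pmax(a$val, 0)
  ag_node(v, backfn = function(g) ag_accum(a, g * (a$val > 0)))
}

# embedding lookup: rows of table W at 1-based indices idx
ag_embed <- function(W, idx) {
  v <- W$val[idx, , drop = FALSE]
  ag_node(v, backfn = function(g) {
    gw <- matrix(0, nrow(W$val), ncol(W$val))
    acc <- rowsum(g, group = idx)
    gw[as.integer(rownames(acc)), ] <- acc
    ag_accum(W, gw)
  })
}

ag_slice_cols <- function(a, cols) {
  v <- a$val[, cols, drop = FALSE]
  ag_node(v, backfn = function(g) {
    ga <- matrix(0, nrow(a$val), ncol(a$val))
    ga[, cols] <- g
    ag_accum(a, ga)
  })
}

ag_cbind <- function(parts) {
  widths <- vapply(parts, function(p) ncol(p$val), integer(1))
  v <- do.call(cbind, lapply(parts, function(p) p$val))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ag_node(v, backfn = function(g) {
    for (m in seq_along(parts)) {
      ag_accum(parts[[m]], g[, starts[m]:ends[m], drop = FALSE])
    }
  })
}

# stack shifted copies of x column-blockwise: block m holds x shifted down by
# -offsets[m] rows (offset -1 = previous position), zero-padded.  Convolution
# with kernel k is then a single matmul with a (k*d) x d_out weight.
ag_shift_stack <- function(x, offsets) {
  n <- nrow(x$val); d <- ncol(x$val)
  v <- matrix(0, n, d * length(offsets))
  for (m in seq_along(offsets)) {
    o <- offsets[m]
    rows <- seq_len(n) + o
    ok <- rows >= 1L & rows <= n
    v[ok, (m - 1L) * d + seq_len(d)] <- x$val[rows[ok], , drop = FALSE]
  }
  ag_node(v, backfn = function(g) {
    gx <- matrix(0, n, d)
    for (m in seq_along(offsets)) {
      o <- offsets[m]
      rows <- seq_len(n) + o
      ok <- rows >= 1L & rows <= n
      gx[rows[ok], ] <- gx[rows[ok], , drop = FALSE] +
        g[ok, (m - 1L) * d + seq_len(d), drop = FALSE]
    }
    ag_accum(x, gx)
  })
}

# scaled dot-product attention for one head.  mask: additive matrix
# (0 / -Inf), or NULL.  q: n x dh, k/v: m x dh.
ag_attention <- function(q, k, v, mask = NULL) {
  dh <- ncol(q$val)
  scores <- q$val %*% t(k$val) / sqrt(dh)
  if (!is.null(mask)) scores <- scores + mask
  smax <- apply(scores, 1L, max)
  ex <- exp(scores - smax)
  S <- ex / rowSums(ex)
  out <- S %*% v$val
  ag_node(out, backfn = function(g) {
    gV <- t(S) %*% g
    gS <- g %*% t(v$val)
    gZ <- S * (gS - rowSums(gS * S))
    ag_accum(q, gZ %*% k$val / sqrt(dh))
    ag_accum(k, t(gZ) %*% q$val / sqrt(dh))
    ag_accum(v, gV)
  })
}

# per-row layer normalisation with learned gain/bias (1 x d each)
ag_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  d <- ncol(x$val)
  mu <- rowMeans(x$val)
  xc <- x$val - mu
  varr <- rowMeans(xc * xc)
  inv <- 1 / sqrt(varr + eps)
  xhat <- xc * inv
  gv <- as.numeric(gamma$val)
  v <- xhat * matrix(gv, nrow(x$val), d, byrow = TRUE) +
    matrix(as.numeric(beta$val), nrow(x$val), d, byrow = TRUE)
  ag_node(v, backfn = function(g) {
    ag_accum(beta, matrix(colSums(g), 1L))
    ag_accum(gamma, matrix(colSums(g * xhat), 1L))
    gxhat <- g * matrix(gv, nrow(g), d, byrow = TRUE)
    gx <- inv * (gxhat - rowMeans(gxhat) - xhat * rowMeans(gxhat * xhat))
    ag_accum(x, gx)
  })
}

# unidirectional LSTM over the rows of x (n x d_in), hidden size dh.
# Wx: d_in x 4dh, Wh: dh x 4dh, b: 1 x 4dh; gate order [input forget cell
# output].  Returns the hidden-state sequence (n x dh).
ag_lstm <- function(x, Wx, Wh, b) {
  n <- nrow(x$val)
  dh <- ncol(Wh$val) / 4L
  XW <- x$val %*% Wx$val
  H <- matrix(0, n, dh); C <- matrix(0, n, dh)
  Iv <- matrix(0, n, dh); Fv <- matrix(0, n, dh)
  Gv <- matrix(0, n, dh); Ov <- matrix(0, n, dh); Tc <- matrix(0, n, dh)
  h <- numeric(dh); cc <- numeric(dh)
  bv <- as.numeric(b$val)
  ix <- seq_len(dh); fx <- dh + ix; gx_ <- 2L * dh + ix; ox <- 3L * dh + ix
  for (t in seq_len(n)) {
    z <- XW[t, ] + as.numeric(h %*% Wh$val) + bv
    i <- 1 / (1 + exp(-z[ix]))
    f <- 1 / (1 + exp(-z[fx]))
    g_ <- tanh(z[gx_])
    o <- 1 / (1 + exp(-z[ox]))
    cc <- f * cc + i * g_
    tc <- tanh(cc)
    h <- o * tc
    Iv[t, ] <- i; Fv[t, ] <- f; Gv[t, ] <- g_; Ov[t, ] <- o
    C[t, ] <- cc; Tc[t, ] <- tc; H[t, ] <- h
  }
  ag_node(H, backfn = function(g) {
    gWx <- matrix(0, nrow(Wx$val), ncol(Wx$val))
    gWh <- matrix(0, nrow(Wh$val), ncol(Wh$val))
    gb <- numeric(4L * dh)
    gX <- matrix(0, n, nrow(Wx$val))
    dh_next <- numeric(dh); dc_next <- numeric(dh)
    for (t in seq(n, 1L)) {
      dht <- g[t, ] + dh_next
      dct <- dht * Ov[t, ] * (1 - Tc[t, ]^2) + dc_next
      c_prev <- if (t > 1L) C[t - 1L, ] else numeric(dh)
      di <- dct * Gv[t, ] * Iv[t, ] * (1 - Iv[t, ])
      df <- dct * c_prev * Fv[t, ] * (1 - Fv[t, ])
      dg <- dct * Iv[t, ] * (1 - Gv[t, ]^2)
      do_ <- dht * Tc[t, ] * Ov[t, ] * (1 - Ov[t, ])
      dz <- c(di, df, dg, do_)
      h_prev <- if (t > 1L) H[t - 1L, ] else numeric(dh)
      gWx <- gWx + outer(x$val[t, ], dz)
      gWh <- gWh + outer(h_prev, dz)
      gb <- gb + dz
      gX[t, ] <- as.numeric(Wx$val %*% dz)
      dh_next <- as.numeric(Wh$val %*% dz)
      dc_next <- dct * Fv[t, ]
    }
    ag_accum(x, gX)
    ag_accum(Wx, gWx)
    ag_accum(Wh, gWh)
    ag_accum(b, matrix(gb, 1L))
  })
}

# mean squared error between grid entries at idx (2-col 1-based index matrix)
# and a constant target vector; the scalar loss node for training
ag_gather_mse <- function(grid, idx, target) {
  sel <- grid$val[idx]
  diff <- sel - target
  v <- mean(diff * diff)
  ag_node(v, backfn = function(g) {
    gg <- matrix(0, nrow(grid$val), ncol(grid$val))
    gg[idx] <- gg[idx] + 2 * diff / length(diff) * g
    ag_accum(grid, gg)
  })
}
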