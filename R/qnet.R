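# Structure-conditioned action-value network.
#
# Encoder: dot-bracket token embedding -> learned LSTM positional encoding ->
# 1-D convolution -> contact-graph message passing -> multi-head
# self-attention stack.  Decoder: causal transformer over the right-shifted
# sequence (START token first) with an added paired/unpaired flag embedding,
# LSTM positional encoding, causal convolution, masked self-attention,
# cross-attention to the encoder context, and a linear head onto the four
# nucleotide actions.  Two forward implementations share the same
# parameters: a tape-recorded one used for training, and a key-value cached
# stepwise one used for generation; their agreement is tested.

#' Q-network configuration
#'
#' All sizes of the action-value network.  Defaults are desk-scale.
#'
#' @param embed_dim embedding / model width (must be divisible by
#'   \code{attention_heads}).
#' @param encoder_layers number of encoder self-attention blocks.
#' @param decoder_layers number of decoder blocks.
#' @param attention_heads attention heads per block.
#' @param conv_kernel odd width of the convolutional layers.
#' @param gcn_layers rounds of contact-graph message passing (0 disables).
#' @param ffn_mult feed-forward width as a multiple of \code{embed_dim}.
#' @param seed weight-initialisation seed.
#' @return a \code{qnet_config} list.
#' @export
qnet_config <- function(embed_dim = 64L, encoder_layers = 2L,
                        decoder_layers = 2L, attention_heads = 4L,
                        conv_kernel = 5L, gcn_layers = 1L, ffn_mult = 2L,
                        seed = 42L) {
  embed_dim <- as.integer(embed_dim)
  attention_heads <- as.integer(attention_heads)
  conv_kernel <- as.integer(conv_kernel)
  stopifnot(embed_dim > 0L, encoder_layers > 0L, decoder_layers > 0L,
            attention_heads > 0L, gcn_layers >= 0L, ffn_mult > 0L)
  if (embed_dim %% attention_heads != 0L) {
    stop("embed_dim must be divisible by attention_heads")
  }
  if (conv_kernel < 1L || conv_kernel %% 2L == 0L) {
    stop("conv_kernel must be an odd positive integer")
  }
  structure(
    list(embed_dim = embed_dim,
         encoder_layers = as.integer(encoder_layers),
         decoder_layers = as.integer(decoder_layers),
         attention_heads = attention_heads,
         conv_kernel = conv_kernel,
         gcn_layers = as.integer(gcn_layers),
         ffn_mult = as.integer(ffn_mult),
         seed = as.integer(seed)),
    class = "qnet_config"
  )
}

# uniform fan-in initialisation
qn_init_mat <- function(nr, nc) {
  s <- 1 / sqrt(nr)
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

qn_init_params <- function(cfg) {
  d <- cfg$embed_dim
  fd <- d * cfg$ffn_mult
  P <- list()
  with_seed(cfg$seed, {
    P$enc_embed <- qn_init_mat(length(ENC_VOCAB), d)
    P$enc_lstm_Wx <- qn_init_mat(d, 4L * d)
    P$enc_lstm_Wh <- qn_init_mat(d, 4L * d)
    b <- matrix(0, 1L, 4L * d); b[1L, d + seq_len(d)] <- 1  # forget bias
    P$enc_lstm_b <- b
    P$enc_conv_W <- qn_init_mat(cfg$conv_kernel * d, d)
    P$enc_conv_b <- matrix(0, 1L, d)
    for (g in seq_len(cfg$gcn_layers)) {
      P[[paste0("gcn", g, "_W")]] <- qn_init_mat(d, d)
      P[[paste0("gcn", g, "_b")]] <- matrix(0, 1L, d)
    }
    for (l in seq_len(cfg$encoder_layers)) {
      pre <- paste0("enc", l, "_")
      for (nm in c("Wq", "Wk", "Wv", "Wo")) {
        P[[paste0(pre, nm)]] <- qn_init_mat(d, d)
      }
      P[[paste0(pre, "bo")]] <- matrix(0, 1L, d)
      P[[paste0(pre, "ffn_W1")]] <- qn_init_mat(d, fd)
      P[[paste0(pre, "ffn_b1")]] <- matrix(0, 1L, fd)
      P[[paste0(pre, "ffn_W2")]] <- qn_init_mat(fd, d)
      P[[paste0(pre, "ffn_b2")]] <- matrix(0, 1L, d)
      for (ln in c("ln1", "ln2")) {
        P[[paste0(pre, ln, "_g")]] <- matrix(1, 1L, d)
        P[[paste0(pre, ln, "_b")]] <- matrix(0, 1L, d)
      }
    }
    P$dec_embed <- qn_init_mat(length(DEC_VOCAB), d)
    P$flag_embed <- qn_init_mat(2L, d)
    P$dec_lstm_Wx <- qn_init_mat(d, 4L * d)
    P$dec_lstm_Wh <- qn_init_mat(d, 4L * d)
    b <- matrix(0, 1L, 4L * d); b[1L, d + seq_len(d)] <- 1
    P$dec_lstm_b <- b
    P$dec_conv_W <- qn_init_mat(cfg$conv_kernel * d, d)
    P$dec_conv_b <- matrix(0, 1L, d)
    for (l in seq_len(cfg$decoder_layers)) {
      pre <- paste0("dec", l, "_")
      for (blk in c("self_", "cross_")) {
        for (nm in c("Wq", "Wk", "Wv", "Wo")) {
          P[[paste0(pre, blk, nm)]] <- qn_init_mat(d, d)
        }
        P[[paste0(pre, blk, "bo")]] <- matrix(0, 1L, d)
      }
      P[[paste0(pre, "ffn_W1")]] <- qn_init_mat(d, fd)
      P[[paste0(pre, "ffn_b1")]] <- matrix(0, 1L, fd)
      P[[paste0(pre, "ffn_W2")]] <- qn_init_mat(fd, d)
      P[[paste0(pre, "ffn_b2")]] <- matrix(0, 1L, d)
      for (ln in c("ln1", "ln2", "ln3")) {
        P[[paste0(pre, ln, "_g")]] <- matrix(1, 1L, d)
        P[[paste0(pre, ln, "_b")]] <- matrix(0, 1L, d)
      }
    }
    P$out_W <- qn_init_mat(d, 4L)
    P$out_b <- matrix(0, 1L, 4L)
  })
  P
}

#' Create an action-value network
#'
#' @param config a \code{\link{qnet_config}}.
#' @return a \code{qnet} object (an environment so training updates in
#'   place) with elements \code{config} and \code{params}.
#' @export
qnet_new <- function(config = qnet_config()) {
  stopifnot(inherits(config, "qnet_config"))
  net <- new.env(parent = emptyenv())
  net$config <- config
  net$params <- qn_init_params(config)
  net$opt <- NULL
  class(net) <- "qnet"
  net
}

#' @export
print.qnet <- function(x, ...) {
  cat(sprintf("qnet: embed %d, %d+%d layers, %d heads, %d parameters\n",
              x$config$embed_dim, x$config$encoder_layers,
              x$config$decoder_layers, x$config$attention_heads,
              qnet_param_count(x)))
  invisible(x)
}

#' Total number of learnable parameters
#'
#' @param network a \code{qnet}.
#' @return integer parameter count.
#' @export
qnet_param_count <- function(network) {
  sum(vapply(network$params, length, integer(1)))
}

# same architecture (the initialisation seed does not affect compatibility)
qnet_config_compatible <- function(a, b) {
  fields <- setdiff(names(a), "seed")
  identical(unclass(a)[fields], unclass(b)[fields])
}

# tokenise a dot-bracket string for the encoder
structure_tokens <- function(db) {
  idx <- match(strsplit(db, "", fixed = TRUE)[[1L]], ENC_VOCAB)
  if (anyNA(idx)) stop("invalid structure token")
  idx
}

# degree-normalised contact propagation matrix (A + I) row-normalised
gcn_propagation_matrix <- function(structure) {
  A <- contact_matrix(structure) + diag(structure$length)
  A / rowSums(A)
}

## ---- shared forward (autograd nodes) -------------------------------------

qn_mhsa <- function(P, pre, cfg, X, mask = NULL, kv = NULL) {
  h <- cfg$attention_heads
  dh <- cfg$embed_dim %/% h
  src <- if (is.null(kv)) X else kv
  Q <- ag_mm(X, P[[paste0(pre, "Wq")]])
  K <- ag_mm(src, P[[paste0(pre, "Wk")]])
  V <- ag_mm(src, P[[paste0(pre, "Wv")]])
  heads <- lapply(seq_len(h), function(i) {
    cols <- (i - 1L) * dh + seq_len(dh)
    ag_attention(ag_slice_cols(Q, cols), ag_slice_cols(K, cols),
                 ag_slice_cols(V, cols), mask)
  })
  ag_add_bias(ag_mm(ag_cbind(heads), P[[paste0(pre, "Wo")]]),
              P[[paste0(pre, "bo")]])
}

qn_ffn <- function(P, pre, X) {
  h1 <- ag_relu(ag_add_bias(ag_mm(X, P[[paste0(pre, "ffn_W1")]]),
                            P[[paste0(pre, "ffn_b1")]]))
  ag_add_bias(ag_mm(h1, P[[paste0(pre, "ffn_W2")]]),
              P[[paste0(pre, "ffn_b2")]])
}

qn_ln <- function(P, pre, ln, X) {
  ag_layernorm(X, P[[paste0(pre, ln, "_g")]], P[[paste0(pre, ln, "_b")]])
}

qn_encode_fwd <- function(P, cfg, tokens, M) {
  k <- cfg$conv_kernel
  X <- ag_embed(P$enc_embed, tokens)
  X <- ag_add(X, ag_lstm(X, P$enc_lstm_Wx, P$enc_lstm_Wh, P$enc_lstm_b))
  off <- seq.int(-(k %/% 2L), k %/% 2L)
  X <- ag_add(X, ag_tanh(ag_add_bias(
    ag_mm(ag_shift_stack(X, off), P$enc_conv_W), P$enc_conv_b)))
  if (cfg$gcn_layers > 0L) {
    Mn <- ag_const(M)
    for (g in seq_len(cfg$gcn_layers)) {
      X <- ag_add(X, ag_tanh(ag_add_bias(
        ag_mm(ag_mm(Mn, X), P[[paste0("gcn", g, "_W")]]),
        P[[paste0("gcn", g, "_b")]])))
    }
  }
  for (l in seq_len(cfg$encoder_layers)) {
    pre <- paste0("enc", l, "_")
    X <- qn_ln(P, pre, "ln1", ag_add(X, qn_mhsa(P, pre, cfg, X)))
    X <- qn_ln(P, pre, "ln2", ag_add(X, qn_ffn(P, pre, X)))
  }
  X
}

causal_mask <- function(n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- -Inf
  m
}

qn_decode_fwd <- function(P, cfg, prefix_tokens, paired_flags, context) {
  n <- length(prefix_tokens)
  k <- cfg$conv_kernel
  X <- ag_add(ag_embed(P$dec_embed, prefix_tokens),
              ag_embed(P$flag_embed, paired_flags + 1L))
  X <- ag_add(X, ag_lstm(X, P$dec_lstm_Wx, P$dec_lstm_Wh, P$dec_lstm_b))
  off <- seq.int(-(k - 1L), 0L)             # causal: past positions only
  X <- ag_add(X, ag_tanh(ag_add_bias(
    ag_mm(ag_shift_stack(X, off), P$dec_conv_W), P$dec_conv_b)))
  mask <- causal_mask(n)
  for (l in seq_len(cfg$decoder_layers)) {
    pre <- paste0("dec", l, "_")
    X <- qn_ln(P, pre, "ln1",
               ag_add(X, qn_mhsa(P, paste0(pre, "self_"), cfg, X, mask)))
    X <- qn_ln(P, pre, "ln2",
               ag_add(X, qn_mhsa(P, paste0(pre, "cross_"), cfg, X,
                                 kv = context)))
    X <- qn_ln(P, pre, "ln3", ag_add(X, qn_ffn(P, pre, X)))
  }
  ag_add_bias(ag_mm(X, P$out_W), P$out_b)
}

## ---- user-facing forward API ---------------------------------------------

#' Encode a target structure into context embeddings
#'
#' @param network a \code{qnet}.
#' @param structure a \code{secondary_structure} (or dot-bracket string).
#' @return L x embed_dim context matrix.
#' @export
qnet_encode <- function(network, structure) {
  stopifnot(inherits(network, "qnet"))
  if (is.character(structure)) structure <- parse_dotbracket(structure)
  tokens <- structure_tokens(dotbracket(structure))
  M <- gcn_propagation_matrix(structure)
  P <- lapply(network$params, ag_const)
  qn_encode_fwd(P, network$config, tokens, M)$val
}

#' Full-grid decoding of action values
#'
#' Computes the L x 4 grid of action values for a complete decoder input:
#' the right-shifted sequence starting with the START token, with the
#' paired/unpaired flag of the position being predicted added at each slot.
#' Row t depends only on prefix tokens 1..t (causal).
#'
#' @param network a \code{qnet}.
#' @param prefix_tokens integer token ids (1=A, 2=C, 3=G, 4=U, 5=START);
#'   must begin with START.
#' @param paired_flags 0/1 vector, one per output position.
#' @param context encoder context from \code{\link{qnet_encode}}.
#' @return numeric matrix, rows = positions, columns = actions A, C, G, U.
#' @export
qnet_decode_full <- function(network, prefix_tokens, paired_flags, context) {
  stopifnot(inherits(network, "qnet"))
  if (length(prefix_tokens) == 0L || prefix_tokens[1L] != START_TOKEN) {
    stop("decoder input must begin with the START token")
  }
  if (length(paired_flags) != length(prefix_tokens)) {
    stop("paired_flags must match prefix length")
  }
  P <- lapply(network$params, ag_const)
  grid <- qn_decode_fwd(P, network$config, prefix_tokens,
                        as.integer(paired_flags), ag_const(context))$val
  colnames(grid) <- RNA_BASES
  grid
}

## ---- stepwise decoding with key-value cache ------------------------------

#' Initialise an incremental decoding cache
#'
#' Precomputes cross-attention keys/values from the encoder context and
#' empty per-layer self-attention caches.
#'
#' @param network a \code{qnet}.
#' @param context encoder context matrix.
#' @return an opaque cache list for \code{\link{qnet_decode_step}}.
#' @export
qnet_decode_init <- function(network, context) {
  stopifnot(inherits(network, "qnet"))
  P <- network$params
  cfg <- network$config
  layers <- lapply(seq_len(cfg$decoder_layers), function(l) {
    pre <- paste0("dec", l, "_cross_")
    list(K = matrix(0, 0L, cfg$embed_dim), V = matrix(0, 0L, cfg$embed_dim),
         Kc = context %*% P[[paste0(pre, "Wk")]],
         Vc = context %*% P[[paste0(pre, "Wv")]])
  })
  list(t = 0L,
       h = numeric(cfg$embed_dim), c = numeric(cfg$embed_dim),
       conv_buf = matrix(0, cfg$conv_kernel - 1L, cfg$embed_dim),
       layers = layers)
}

# forward-only single-row helpers
row_ln <- function(x, g, b, eps = 1e-5) {
  mu <- mean(x); xc <- x - mu
  xc / sqrt(mean(xc * xc) + eps) * as.numeric(g) + as.numeric(b)
}

row_attention <- function(q, K, V, heads) {
  d <- length(q); dh <- d %/% heads
  out <- numeric(d)
  for (i in seq_len(heads)) {
    cols <- (i - 1L) * dh + seq_len(dh)
    s <- as.numeric(K[, cols, drop = FALSE] %*% q[cols]) / sqrt(dh)
    w <- exp(s - max(s)); w <- w / sum(w)
    out[cols] <- as.numeric(w %*% V[, cols, drop = FALSE])
  }
  out
}

#' One step of cached autoregressive decoding
#'
#' Feeds a single decoder input token (START for the first step, then the
#' previously chosen nucleotide) together with the paired flag of the
#' position being predicted, and returns that position's four action values
#' plus the updated cache.  Stepwise decoding over a full sequence
#' reproduces \code{\link{qnet_decode_full}} up to float tolerance.
#'
#' @param network a \code{qnet}.
#' @param cache cache from \code{\link{qnet_decode_init}} (not mutated).
#' @param token integer token id of the input at this slot.
#' @param flag paired flag (0/1) of the position being predicted.
#' @return list with \code{q} (named numeric of length 4) and \code{cache}.
#' @export
qnet_decode_step <- function(network, cache, token, flag) {
  stopifnot(inherits(network, "qnet"))
  P <- network$params
  cfg <- network$config
  d <- cfg$embed_dim
  if (cache$t == 0L && token != START_TOKEN) {
    stop("first decoder input must be the START token")
  }
  x <- P$dec_embed[token, ] + P$flag_embed[flag + 1L, ]
  # LSTM positional step
  z <- as.numeric(x %*% P$dec_lstm_Wx) +
    as.numeric(cache$h %*% P$dec_lstm_Wh) + as.numeric(P$dec_lstm_b)
  ix <- seq_len(d)
  i <- 1 / (1 + exp(-z[ix])); f <- 1 / (1 + exp(-z[d + ix]))
  g_ <- tanh(z[2L * d + ix]); o <- 1 / (1 + exp(-z[3L * d + ix]))
  cc <- f * cache$c + i * g_
  h <- o * tanh(cc)
  x <- x + h
  x_conv_in <- x
  # causal convolution over the last conv_kernel post-LSTM rows
  stacked <- c(t(rbind(cache$conv_buf, matrix(x_conv_in, 1L))))
  x <- x + tanh(as.numeric(stacked %*% P$dec_conv_W) +
                  as.numeric(P$dec_conv_b))
  nb <- rbind(cache$conv_buf, matrix(x_conv_in, 1L))
  conv_buf <- nb[-1L, , drop = FALSE]         # keep the last k-1 rows
  layers <- cache$layers
  for (l in seq_len(cfg$decoder_layers)) {
    pre <- paste0("dec", l, "_")
    sp <- paste0(pre, "self_")
    q <- as.numeric(x %*% P[[paste0(sp, "Wq")]])
    k_new <- as.numeric(x %*% P[[paste0(sp, "Wk")]])
    v_new <- as.numeric(x %*% P[[paste0(sp, "Wv")]])
    K <- rbind(layers[[l]]$K, k_new)
    V <- rbind(layers[[l]]$V, v_new)
    layers[[l]]$K <- K
    layers[[l]]$V <- V
    att <- row_attention(q, K, V, cfg$attention_heads)
    o_self <- as.numeric(att %*% P[[paste0(sp, "Wo")]]) +
      as.numeric(P[[paste0(sp, "bo")]])
    x <- row_ln(x + o_self, P[[paste0(pre, "ln1_g")]],
                P[[paste0(pre, "ln1_b")]])
    cp <- paste0(pre, "cross_")
    qc <- as.numeric(x %*% P[[paste0(cp, "Wq")]])
    attc <- row_attention(qc, layers[[l]]$Kc, layers[[l]]$Vc,
                          cfg$attention_heads)
    o_cross <- as.numeric(attc %*% P[[paste0(cp, "Wo")]]) +
      as.numeric(P[[paste0(cp, "bo")]])
    x <- row_ln(x + o_cross, P[[paste0(pre, "ln2_g")]],
                P[[paste0(pre, "ln2_b")]])
    h1 <- pmax(as.numeric(x %*% P[[paste0(pre, "ffn_W1")]]) +
                 as.numeric(P[[paste0(pre, "ffn_b1")]]), 0)
    o_ffn <- as.numeric(h1 %*% P[[paste0(pre, "ffn_W2")]]) +
      as.numeric(P[[paste0(pre, "ffn_b2")]])
    x <- row_ln(x + o_ffn, P[[paste0(pre, "ln3_g")]],
                P[[paste0(pre, "ln3_b")]])
  }
  qv <- as.numeric(x %*% P$out_W) + as.numeric(P$out_b)
  names(qv) <- RNA_BASES
  list(q = qv,
       cache = list(t = cache$t + 1L, h = h, c = cc,
                    conv_buf = conv_buf, layers = layers))
}

## ---- checkpoints ---------------------------------------------------------

CHECKPOINT_VERSION <- 1L

#' Save a network checkpoint
#'
#' @param network a \code{qnet}.
#' @param path file path.
#' @export
qnet_save <- function(network, path) {
  stopifnot(inherits(network, "qnet"))
  saveRDS(list(format = "qrnadesign-checkpoint",
               version = CHECKPOINT_VERSION,
               config = network$config,
               params = network$params), path)
  invisible(path)
}

#' Load a network checkpoint
#'
#' @param path file path written by \code{\link{qnet_save}}.
#' @param config optional expected \code{qnet_config}; a mismatch with the
#'   stored configuration is an error.
#' @return a \code{qnet}.
#' @export
qnet_load <- function(path, config = NULL) {
  obj <- readRDS(path)
  if (!identical(obj$format, "qrnadesign-checkpoint")) {
    stop("not a qrnadesign checkpoint: ", path)
  }
  if (!identical(obj$version, CHECKPOINT_VERSION)) {
    stop("unsupported checkpoint version: ", obj$version)
  }
  if (!is.null(config) && !qnet_config_compatible(config, obj$config)) {
    stop("checkpoint configuration does not match the requested config")
  }
  net <- qnet_new(obj$config)
  net$params <- obj$params
  net
}
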