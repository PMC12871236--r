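# Independent brute-force oracles used across the suite.

# maximum number of canonical pairs over all *nested* pairings, by plain
# recursive enumeration on the leftmost position (no DP table shared with
# the implementation under test)
bf_max_nested_pairs <- function(codes, min_loop = 3L) {
  canp <- function(a, b) {
    x <- min(a, b); y <- max(a, b)
    (x == 1L && y == 4L) || (x == 2L && y == 3L) || (x == 3L && y == 4L)
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    best <- rec(i + 1L, j)                       # leftmost position unpaired
    for (k in seq.int(i + min_loop + 1L, j)) {
      if (canp(codes[i + 1L], codes[k + 1L])) {
        v <- 1L + rec(i + 1L, k - 1L) +
          (if (k < j) rec(k + 1L, j) else 0L)
        if (v > best) best <- v
      }
    }
    best
  }
  rec(0L, length(codes) - 1L)
}

# all permutations of 1..n as an (n!) x n matrix
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, p + (p >= k))
  }))
}

# brute-force analogue of extract_pairs_hungarian: enumerate every
# one-to-one assignment, take the maximum-weight one, keep mutual pairs
# over threshold
bf_extract_pairs <- function(prob, threshold = 0.5, min_loop = 3L) {
  n <- nrow(prob)
  w <- (prob + t(prob)) / 2
  w[abs(row(w) - col(w)) <= min_loop] <- 0
  perms <- all_perms(n)
  wvec <- as.numeric(w)
  scores <- rowSums(vapply(seq_len(n), function(i) {
    wvec[(perms[, i] - 1L) * n + i]
  }, numeric(nrow(perms))))
  sigma <- perms[which.max(scores), ]
  i <- seq_len(n)
  mutual <- sigma[sigma[i]] == i & sigma[i] != i
  keep <- which(mutual & i < sigma[i])
  keep <- keep[w[cbind(keep, sigma[keep])] >= threshold]
  if (length(keep) == 0L) matrix(integer(0), ncol = 2L)
  else cbind(keep - 1L, sigma[keep] - 1L)
}

# O(m^2) crossing check, independent of the vectorised implementation
bf_crossing_pairs <- function(pairs) {
  m <- nrow(pairs)
  if (m == 0L) return(pairs)
  keep <- logical(m)
  for (a in seq_len(m)) {
    for (b in seq_len(m)) {
      if (a == b) next
      i <- pairs[a, 1L]; j <- pairs[a, 2L]
      k <- pairs[b, 1L]; l <- pairs[b, 2L]
      if ((i < k && k < j && j < l) || (k < i && i < l && l < j)) {
        keep[a] <- TRUE
      }
    }
  }
  pairs[keep, , drop = FALSE]
}

# random renderable structures (hairpins, pseudoknots, fold-derived)
rand_structure <- function(seed) {
  set.seed(seed)
  kind <- sample(3L, 1L)
  if (kind == 1L) {
    make_hairpin(sample(1:6, 1L), sample(3:8, 1L))
  } else if (kind == 2L) {
    make_htype_pseudoknot(sample(1:4, 1L), sample(0:4, 1L),
                          sample(3:4, 1L), sample(3:5, 1L),
                          tail = sample(0:3, 1L))
  } else {
    codes <- sample(4L, 25L, replace = TRUE, prob = c(.2, .3, .3, .2))
    nussinov_fold(paste(c("A", "C", "G", "U")[codes], collapse = ""))
  }
}

# random RNA string of length n using the active RNG stream
rand_seq <- function(n, prob = c(.25, .25, .25, .25)) {
  paste(c("A", "C", "G", "U")[sample.int(4L, n, TRUE, prob = prob)],
        collapse = "")
}

# small network for decoder tests
tiny_qnet <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(embed_dim = 16L, encoder_layers = 1L, decoder_layers = 1L,
                   attention_heads = 2L, conv_kernel = 3L, gcn_layers = 1L,
                   seed = seed)
  defaults[names(args)] <- args
  qnet_new(do.call(qnet_config, defaults))
}

# cumulative Q of a fixed sequence under a network/target (teacher forcing)
cumulative_q_of <- function(net, target, codes) {
  st <- target$structure
  ctx <- qnet_encode(net, st)
  flags <- as.integer(!is.na(pairing_partner(st)))
  grid <- qnet_decode_full(net, c(5L, codes[-length(codes)]), flags, ctx)
  sum(grid[cbind(seq_along(codes), codes)])
}
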