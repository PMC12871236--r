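# Playing and training: experience collection against the environment,
# reward reweighting, position-dependent discounting, TD targets from a
# frozen target network, and the twice-shifted action-value training epoch
# (decoder input right-shifted with START; next-state maxima left-shifted).

#' Design target
#'
#' A target structure to design against, optionally with explicit SHAPE
#' constraint thresholds used in the reward.
#'
#' @param structure a \code{secondary_structure} or dot-bracket string.
#' @param id label used in experience files and reports.
#' @param unpaired_min,paired_max optional SHAPE reward thresholds; when
#'   \code{NULL}, package defaults (0.5 / 0.25) apply if the environment
#'   provides SHAPE.
#' @return a \code{design_target}.
#' @export
design_target <- function(structure, id = "target",
                          unpaired_min = NULL, paired_max = NULL) {
  if (is.character(structure)) structure <- parse_dotbracket(structure)
  stopifnot(is_secondary_structure(structure))
  structure(list(structure = structure, id = id,
                 unpaired_min = unpaired_min, paired_max = paired_max),
            class = "design_target")
}

#' Training configuration
#'
#' @param gamma_start discount factor at the first position (in [0, 1)).
#' @param gamma_end discount factor at the last position
#'   (\code{gamma_end <= gamma_start}).
#' @param epsilon probability of a uniformly random (valid) action per
#'   position during play.
#' @param learning_rate Adam step size.
#' @param batch_size episodes per gradient update.
#' @param target_sync_epochs epochs between target-network syncs.
#' @param grad_clip global gradient-norm clip.
#' @param seed RNG seed for shuffling and exploration.
#' @return a \code{training_config} list.
#' @export
training_config <- function(gamma_start = 0.95, gamma_end = 0.5,
                            epsilon = 0.1, learning_rate = 1e-3,
                            batch_size = 8L, target_sync_epochs = 5L,
                            grad_clip = 5, seed = 42L) {
  stopifnot(gamma_start >= 0, gamma_start < 1, gamma_end >= 0,
            gamma_end <= gamma_start, epsilon >= 0, epsilon <= 1,
            learning_rate > 0, batch_size >= 1L, target_sync_epochs >= 1L,
            grad_clip > 0)
  structure(list(gamma_start = gamma_start, gamma_end = gamma_end,
                 epsilon = epsilon, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 target_sync_epochs = as.integer(target_sync_epochs),
                 grad_clip = grad_clip, seed = as.integer(seed)),
            class = "training_config")
}

#' Valid nucleotide actions at a position
#'
#' If the target pairs the position with an already-decoded partner, only
#' bases forming a canonical pair (A-U, G-C, G-U) with the decoded partner
#' base are allowed; otherwise all four bases are.
#'
#' @param target a \code{design_target}.
#' @param position 0-based position being decoded.
#' @param partial_sequence character string (or code vector) of the already
#'   decoded bases at positions < \code{position}.
#' @return named logical vector over A, C, G, U.
#' @export
valid_actions <- function(target, position, partial_sequence) {
  stopifnot(inherits(target, "design_target"))
  codes <- if (is.character(partial_sequence)) {
    if (nchar(partial_sequence) > 0L) seq_to_codes(partial_sequence)
    else integer(0)
  } else as.integer(partial_sequence)
  if (position >= target$structure$length) stop("position out of range")
  if (length(codes) < position) {
    stop("partial sequence must cover all positions before 'position'")
  }
  mask <- rep(TRUE, 4L)
  names(mask) <- RNA_BASES
  partner <- pairing_partner(target$structure)[position + 1L]
  if (!is.na(partner) && partner < position) {
    partner_base <- RNA_BASES[codes[partner + 1L]]
    mask[] <- RNA_BASES %in% CANONICAL_COMPLEMENTS[[partner_base]]
  }
  mask
}

#' Exponential reward reweighting
#'
#' Scales every entry of a reward vector by \code{exp(mean(r))}, boosting
#' higher-scoring episodes so that near-perfect sequences still generate
#' training signal.
#'
#' @param rewards numeric vector with entries in [0, 1].
#' @return reweighted reward vector.
#' @export
reweight_rewards <- function(rewards) {
  if (length(rewards) == 0L) stop("empty reward vector")
  rewards * exp(mean(rewards))
}

#' Linearly decayed position-dependent discounts
#'
#' gamma_t = gamma_start - (t / (L - 1)) * (gamma_start - gamma_end) for
#' t = 0..L-1: early positions look further ahead than late ones.
#'
#' @param L sequence length.
#' @param gamma_start,gamma_end schedule endpoints.
#' @return numeric vector of length L.
#' @export
discount_schedule <- function(L, gamma_start = 0.95, gamma_end = 0.5) {
  stopifnot(L >= 1L, gamma_end <= gamma_start)
  if (L == 1L) return(gamma_start)
  t <- seq.int(0L, L - 1L)
  gamma_start - (t / (L - 1)) * (gamma_start - gamma_end)
}

#' Temporal-difference targets
#'
#' \code{Q_hat_t = r_t + gamma_t * max_next_t}, where \code{max_next} is the
#' left-shifted per-position maximum of the frozen target network's values
#' (0 at the final position: no successor state).
#'
#' @param rewards (reweighted) reward vector.
#' @param next_max_q left-shifted next-state maxima, terminal entry 0.
#' @param discounts per-position discount factors.
#' @return TD target vector.
#' @export
td_targets <- function(rewards, next_max_q, discounts) {
  n <- length(rewards)
  if (length(next_max_q) != n || length(discounts) != n) {
    stop("rewards, next_max_q and discounts must have equal length")
  }
  rewards + discounts * next_max_q
}

# paired flag (0/1) per position of a structure
paired_flags_of <- function(structure) {
  as.integer(!is.na(pairing_partner(structure)))
}

# decoder input tokens for a realised sequence: START + all but the last base
shifted_input_tokens <- function(codes) {
  c(START_TOKEN, codes[-length(codes)])
}

#' Play episodes against the environment
#'
#' For each target, decodes a sequence autoregressively: greedily by maximal
#' action value, except that with probability \code{epsilon} per position an
#' action is drawn uniformly from the valid-action mask.  The finished
#' sequence is folded by the environment, per-position rewards are computed,
#' and complete (target, sequence, reward) records are returned.  A target
#' whose environment call fails is skipped with a warning.
#'
#' @param network a \code{qnet}.
#' @param env a \code{design_env}.
#' @param targets list of \code{design_target}s.
#' @param epsilon exploration probability in [0, 1].
#' @param seed RNG seed; play is reproducible given (network, env, seed).
#' @return list of episode records (each \code{list(target, sequence,
#'   rewards)}), with attribute \code{mean_reward}.
#' @export
play_episodes <- function(network, env, targets, epsilon = 0.1, seed = 1L) {
  stopifnot(inherits(network, "qnet"), inherits(env, "design_env"),
            epsilon >= 0, epsilon <= 1)
  records <- with_seed(seed, {
    out <- vector("list", length(targets))
    for (ti in seq_along(targets)) {
      target <- targets[[ti]]
      dec <- decode_sequence(network, target, epsilon = epsilon)
      rec <- tryCatch({
        predicted <- env_fold(env, dec$sequence)
        shape <- env_shape(env, dec$sequence)
        rewards <- compute_rewards(
          predicted, target$structure, shape,
          unpaired_min = target$unpaired_min %||% 0.5,
          paired_max = target$paired_max %||% 0.25)
        list(target = target, sequence = dec$sequence, rewards = rewards)
      }, error = function(e) {
        warning(sprintf("episode for target '%s' failed: %s",
                        target$id, conditionMessage(e)))
        NULL
      })
      out[[ti]] <- rec
    }
    out
  })
  records <- Filter(Negate(is.null), records)
  mr <- if (length(records) > 0L) {
    mean(vapply(records, function(r) mean(r$rewards), numeric(1)))
  } else NA_real_
  attr(records, "mean_reward") <- mr
  records
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# autoregressive decode with the cached stepwise network.
# epsilon > 0 draws uniform valid actions with that probability (uses the
# current RNG stream); force = optional code vector overriding all choices.
decode_sequence <- function(network, target, epsilon = 0, force = NULL) {
  st <- target$structure
  L <- st$length
  flags <- paired_flags_of(st)
  context <- qnet_encode(network, st)
  cache <- qnet_decode_init(network, context)
  codes <- integer(L)
  cumq <- 0
  prev <- START_TOKEN
  for (t in seq_len(L)) {
    stp <- qnet_decode_step(network, cache, prev, flags[t])
    cache <- stp$cache
    mask <- valid_actions(target, t - 1L, codes[seq_len(t - 1L)])
    if (!is.null(force)) {
      a <- force[t]
      if (!mask[a]) stop("forced action violates the valid-action mask")
    } else if (epsilon > 0 && stats::runif(1) < epsilon) {
      valid <- which(mask)
      a <- valid[sample.int(length(valid), 1L)]
    } else {
      qm <- ifelse(mask, stp$q, -Inf)
      a <- which.max(qm)                      # ties: lowest index (A<C<G<U)
    }
    codes[t] <- a
    cumq <- cumq + unname(stp$q[a])
    prev <- a
  }
  list(sequence = codes_to_seq(codes), codes = codes, cumulative_q = cumq)
}

## ---- gradient update machinery -------------------------------------------

qn_zero_like <- function(params) lapply(params, function(p) p * 0)

qn_global_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
}

qn_adam_step <- function(net, grads, lr, clip, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  gn <- qn_global_norm(grads)
  if (is.finite(gn) && gn > clip) {
    grads <- lapply(grads, function(g) g * (clip / gn))
  }
  if (is.null(net$opt)) {
    net$opt <- list(m = qn_zero_like(net$params),
                    v = qn_zero_like(net$params), t = 0L)
  }
  net$opt$t <- net$opt$t + 1L
  tt <- net$opt$t
  for (nm in names(net$params)) {
    g <- grads[[nm]]
    net$opt$m[[nm]] <- beta1 * net$opt$m[[nm]] + (1 - beta1) * g
    net$opt$v[[nm]] <- beta2 * net$opt$v[[nm]] + (1 - beta2) * g * g
    mhat <- net$opt$m[[nm]] / (1 - beta1^tt)
    vhat <- net$opt$v[[nm]] / (1 - beta2^tt)
    net$params[[nm]] <- net$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(net)
}

# recorded forward pass for one episode; returns list(loss, grads)
qn_episode_loss_grads <- function(net, episode, targets_q) {
  cfg <- net$config
  st <- episode$target$structure
  codes <- seq_to_codes(episode$sequence)
  ag_begin()
  on.exit(ag_stop())
  P <- lapply(net$params, ag_leaf)
  ctx <- qn_encode_fwd(P, cfg, structure_tokens(dotbracket(st)),
                       gcn_propagation_matrix(st))
  grid <- qn_decode_fwd(P, cfg, shifted_input_tokens(codes),
                        paired_flags_of(st), ctx)
  loss <- ag_gather_mse(grid, cbind(seq_along(codes), codes), targets_q)
  ag_backward(loss)
  grads <- lapply(P, function(p) if (is.null(p$grad)) p$val * 0 else p$grad)
  list(loss = loss$val, grads = grads)
}

# frozen-network next-state maxima for one episode (left-shifted, terminal 0)
qn_frozen_next_max <- function(frozen, episode, ctx_cache = NULL) {
  st <- episode$target$structure
  codes <- seq_to_codes(episode$sequence)
  db <- dotbracket(st)
  ctx <- if (!is.null(ctx_cache) && !is.null(ctx_cache[[db]])) {
    ctx_cache[[db]]
  } else {
    cx <- qnet_encode(frozen, st)
    if (!is.null(ctx_cache)) ctx_cache[[db]] <- cx
    cx
  }
  grid <- qnet_decode_full(frozen, shifted_input_tokens(codes),
                           paired_flags_of(st), ctx)
  mx <- apply(grid, 1L, max)
  c(mx[-1L], 0)
}

#' One epoch of twice-shifted action-value training
#'
#' Processes the episode list in minibatches.  Per episode: rewards are
#' exponentially reweighted; the decoder input is the realised sequence
#' shifted right with a START token; the frozen target network provides the
#' left-shifted next-state maxima; TD targets are
#' \code{r_t + gamma_t * max_next_t}; the squared error between the
#' predicted values of the taken actions and the TD targets is minimised
#' with Adam under a global gradient-norm clip.  The frozen network is not
#' updated here (see \code{\link{sync_target}}).
#'
#' @param network a \code{qnet}; updated in place.
#' @param frozen_network the frozen target \code{qnet}.
#' @param episodes list of episode records from \code{\link{play_episodes}}.
#' @param config a \code{\link{training_config}}.
#' @return mean loss over episodes.
#' @export
train_epoch <- function(network, frozen_network, episodes, config) {
  stopifnot(inherits(network, "qnet"), inherits(frozen_network, "qnet"),
            inherits(config, "training_config"))
  if (length(episodes) == 0L) stop("no episodes to train on")
  ctx_cache <- new.env(parent = emptyenv())
  losses <- numeric(length(episodes))
  idx <- seq_along(episodes)
  batches <- split(idx, ceiling(idx / config$batch_size))
  for (batch in batches) {
    acc <- NULL
    for (ei in batch) {
      ep <- episodes[[ei]]
      L <- length(ep$rewards)
      rw <- reweight_rewards(ep$rewards)
      gam <- discount_schedule(L, config$gamma_start, config$gamma_end)
      nmx <- qn_frozen_next_max(frozen_network, ep, ctx_cache)
      tq <- td_targets(rw, nmx, gam)
      res <- qn_episode_loss_grads(network, ep, tq)
      losses[ei] <- res$loss
      acc <- if (is.null(acc)) res$grads
             else mapply(`+`, acc, res$grads, SIMPLIFY = FALSE)
    }
    acc <- lapply(acc, function(g) g / length(batch))
    qn_adam_step(network, acc, config$learning_rate, config$grad_clip)
  }
  mean(losses)
}

#' Synchronise the frozen target network with the policy network
#'
#' @param network policy \code{qnet}.
#' @param frozen_network target \code{qnet}; receives a copy of the policy
#'   parameters (configs must match).
#' @export
sync_target <- function(network, frozen_network) {
  stopifnot(inherits(network, "qnet"), inherits(frozen_network, "qnet"))
  if (!qnet_config_compatible(network$config, frozen_network$config)) {
    stop("network configurations do not match")
  }
  frozen_network$params <- network$params
  invisible(frozen_network)
}

## ---- experience store ----------------------------------------------------

#' Write episode records to a tab-separated experience file
#'
#' Columns: id, dotbracket, sequence, comma-joined reward vector.  Appends
#' when \code{append = TRUE}, so repeated play phases can share a store.
#'
#' @param episodes list of episode records.
#' @param path output file.
#' @param append append instead of overwrite (default FALSE).
#' @export
write_episodes <- function(episodes, path, append = FALSE) {
  lines <- vapply(episodes, function(ep) {
    paste(ep$target$id, dotbracket(ep$target$structure), ep$sequence,
          paste(format(ep$rewards, trim = TRUE, scientific = FALSE),
                collapse = ","),
          sep = "\t")
  }, character(1))
  if (append && file.exists(path)) {
    cat(lines, file = path, sep = "\n", append = TRUE)
  } else {
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read an experience file written by \code{\link{write_episodes}}
#'
#' @param path experience file path.
#' @return list of episode records.
#' @export
read_episodes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) != 4L) stop("malformed experience record: ", ln)
    list(target = design_target(f[2L], id = f[1L]),
         sequence = f[3L],
         rewards = as.numeric(strsplit(f[4L], ",", fixed = TRUE)[[1L]]))
  })
}
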