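# Sequence generation strategies over learned action values, plus the
# rescue repair procedure and screening-driven candidate selection.

#' Design candidate
#'
#' @param sequence RNA string.
#' @param cumulative_q sum of the selected action values across positions.
#' @param provenance one of "greedy", "beam", "random", "rescued".
#' @param report optional \code{score_report}.
#' @return a \code{design_candidate}.
#' @export
design_candidate <- function(sequence, cumulative_q = NA_real_,
                             provenance = "greedy", report = NULL) {
  structure(list(sequence = sequence, cumulative_q = cumulative_q,
                 provenance = provenance, report = report),
            class = "design_candidate")
}

#' Greedy decoding
#'
#' Picks the valid action with the highest value at every position
#' (equivalent to beam search with width 1).
#'
#' @param network a \code{qnet}.
#' @param target a \code{design_target}.
#' @return a single \code{design_candidate}.
#' @export
greedy_decode <- function(network, target) {
  dec <- decode_sequence(network, target, epsilon = 0)
  design_candidate(dec$sequence, dec$cumulative_q, "greedy")
}

#' Beam search over cumulative action values
#'
#' Standard beam: every retained prefix is expanded by all valid actions,
#' prefixes are scored by the sum of the selected action values, and the
#' top-k are kept.  Ties are broken lexicographically by sequence, so the
#' result is deterministic.
#'
#' @param network a \code{qnet}.
#' @param target a \code{design_target}.
#' @param k beam width (>= 1).
#' @return list of up to k \code{design_candidate}s sorted by
#'   \code{cumulative_q} descending.
#' @export
beam_search <- function(network, target, k = 16L) {
  stopifnot(inherits(network, "qnet"), inherits(target, "design_target"),
            k >= 1L)
  st <- target$structure
  L <- st$length
  flags <- paired_flags_of(st)
  context <- qnet_encode(network, st)
  cache0 <- qnet_decode_init(network, context)
  s0 <- qnet_decode_step(network, cache0, START_TOKEN, flags[1L])
  # beam element: codes, cumq, cache (after consuming its tokens), qrow for
  # the next position
  beams <- list(list(codes = integer(0), cumq = 0,
                     cache = s0$cache, qrow = s0$q))
  for (t in seq_len(L)) {
    cand_parent <- integer(0)
    cand_action <- integer(0)
    cand_score <- numeric(0)
    cand_key <- character(0)
    for (b in seq_along(beams)) {
      bm <- beams[[b]]
      mask <- valid_actions(target, t - 1L, bm$codes)
      for (a in which(mask)) {
        cand_parent <- c(cand_parent, b)
        cand_action <- c(cand_action, a)
        cand_score <- c(cand_score, bm$cumq + bm$qrow[a])
        cand_key <- c(cand_key,
                      paste(c(RNA_BASES[bm$codes], RNA_BASES[a]),
                            collapse = ""))
      }
    }
    ord <- order(-cand_score, cand_key)
    keep <- ord[seq_len(min(k, length(ord)))]
    beams <- lapply(keep, function(ci) {
      parent <- beams[[cand_parent[ci]]]
      codes <- c(parent$codes, cand_action[ci])
      nb <- list(codes = codes, cumq = cand_score[ci],
                 cache = NULL, qrow = NULL)
      if (t < L) {
        stp <- qnet_decode_step(network, parent$cache, cand_action[ci],
                                flags[t + 1L])
        nb$cache <- stp$cache
        nb$qrow <- stp$q
      }
      nb
    })
  }
  keys <- vapply(beams, function(b) codes_to_seq(b$codes), character(1))
  scores <- vapply(beams, function(b) b$cumq, numeric(1))
  ord <- order(-scores, keys)
  lapply(ord, function(i) {
    design_candidate(keys[i], scores[i], "beam")
  })
}

#' Random search decoding
#'
#' Per position, with probability \code{uniform_prob} a valid action is
#' sampled uniformly; otherwise it is sampled from a softmax of the action
#' values (restricted to valid actions) at the given temperature.
#'
#' @param network a \code{qnet}.
#' @param target a \code{design_target}.
#' @param n number of sequences to sample.
#' @param temperature softmax temperature (> 0; lower is greedier).
#' @param uniform_prob probability of uniform sampling per position.
#' @param seed RNG seed; same seed, same sample set.
#' @return list of n \code{design_candidate}s (provenance "random").
#' @export
random_search <- function(network, target, n = 16L, temperature = 1,
                          uniform_prob = 0, seed = 1L) {
  stopifnot(n >= 1L, temperature > 0, uniform_prob >= 0, uniform_prob <= 1)
  st <- target$structure
  L <- st$length
  flags <- paired_flags_of(st)
  context <- qnet_encode(network, st)
  with_seed(seed, {
    lapply(seq_len(n), function(s) {
      cache <- qnet_decode_init(network, context)
      codes <- integer(L)
      cumq <- 0
      prev <- START_TOKEN
      for (t in seq_len(L)) {
        stp <- qnet_decode_step(network, cache, prev, flags[t])
        cache <- stp$cache
        mask <- valid_actions(target, t - 1L, codes[seq_len(t - 1L)])
        valid <- which(mask)
        if (stats::runif(1) < uniform_prob) {
          a <- valid[sample.int(length(valid), 1L)]
        } else {
          z <- stp$q[valid] / temperature
          p <- exp(z - max(z))
          p <- p / sum(p)
          a <- valid[sample.int(length(valid), 1L, prob = p)]
        }
        codes[t] <- a
        cumq <- cumq + unname(stp$q[a])
        prev <- a
      }
      design_candidate(codes_to_seq(codes), cumq, "random")
    })
  })
}

#' Rescue repair of a near-miss sequence
#'
#' Identifies positions whose pairing status under the environment's fold
#' disagrees with the target.  When the mismatched positions fall into at
#' most \code{max_mismatch_pairs} target pairs (plus target-unpaired
#' singles), all canonical base assignments of those pairs (6 each) and all
#' four bases at each unpaired mismatch are enumerated; each variant is
#' refolded and the first exact match is returned, or the highest-Jaccard
#' improvement if no variant is exact.
#'
#' @param sequence candidate RNA string.
#' @param target a \code{design_target}.
#' @param env a \code{design_env}.
#' @param max_mismatch_pairs cap on mismatched target pairs enumerated
#'   (default 2).
#' @param max_variants safety cap on the total enumeration size.
#' @return a \code{design_candidate} (provenance "rescued"), the input
#'   unchanged if it already matches, or \code{NULL} when the mismatch is
#'   over cap or nothing improves.
#' @export
rescue <- function(sequence, target, env, max_mismatch_pairs = 2L,
                   max_variants = 4096L) {
  stopifnot(max_mismatch_pairs >= 1L)
  st <- target$structure
  codes <- seq_to_codes(sequence)
  if (length(codes) != st$length) stop("sequence/target length mismatch")
  pred0 <- env_fold(env, sequence)
  jac0 <- jaccard_basepairs(pred0, st)
  if (jac0 == 1) return(design_candidate(sequence, provenance = "rescued"))
  tp <- pairing_partner(st)
  pp <- pairing_partner(pred0)
  mismatch <- which(!((is.na(tp) & is.na(pp)) |
                        (!is.na(tp) & !is.na(pp) & tp == pp))) - 1L
  # group mismatched positions by target pair membership
  pair_ids <- unique(t(apply(
    cbind(mismatch, tp[mismatch + 1L]), 1L,
    function(z) if (is.na(z[2L])) c(z[1L], NA) else sort(z))))
  is_pair <- !is.na(pair_ids[, 2L])
  mm_pairs <- pair_ids[is_pair, , drop = FALSE]
  mm_single <- pair_ids[!is_pair, 1L]
  if (nrow(mm_pairs) > max_mismatch_pairs) {
    message(sprintf(
      "rescue: %d mismatched target pairs exceed cap %d; giving up",
      nrow(mm_pairs), max_mismatch_pairs))
    return(NULL)
  }
  canonical <- list(c(1L, 4L), c(4L, 1L), c(3L, 2L), c(2L, 3L),
                    c(3L, 4L), c(4L, 3L))            # AU UA GC CG GU UG
  n_var <- 6^nrow(mm_pairs) * 4^length(mm_single)
  if (n_var > max_variants) {
    message(sprintf("rescue: %d variants exceed cap %d; giving up",
                    n_var, max_variants))
    return(NULL)
  }
  choice_sets <- c(
    lapply(seq_len(nrow(mm_pairs)), function(i) seq_len(6L)),
    lapply(seq_along(mm_single), function(i) seq_len(4L)))
  grid_idx <- if (length(choice_sets) > 0L) {
    as.matrix(do.call(expand.grid, choice_sets))
  } else matrix(integer(0), 1L, 0L)
  best <- NULL
  best_jac <- jac0
  for (r in seq_len(nrow(grid_idx))) {
    var_codes <- codes
    ci <- 0L
    for (pi in seq_len(nrow(mm_pairs))) {
      ci <- ci + 1L
      asg <- canonical[[grid_idx[r, ci]]]
      var_codes[mm_pairs[pi, 1L] + 1L] <- asg[1L]
      var_codes[mm_pairs[pi, 2L] + 1L] <- asg[2L]
    }
    for (si in seq_along(mm_single)) {
      ci <- ci + 1L
      var_codes[mm_single[si] + 1L] <- grid_idx[r, ci]
    }
    var_seq <- codes_to_seq(var_codes)
    pred <- env_fold(env, var_seq)
    jac <- jaccard_basepairs(pred, st)
    if (jac == 1) {
      return(design_candidate(var_seq, provenance = "rescued"))
    }
    if (jac > best_jac) {
      best_jac <- jac
      best <- var_seq
    }
  }
  if (is.null(best)) NULL
  else design_candidate(best, provenance = "rescued")
}

#' Screen and rank candidates
#'
#' Folds and (when available) SHAPE-profiles every candidate through the
#' environment, computes base-pair Jaccard against the target and the
#' OpenKnot score report, deduplicates by sequence, and ranks by
#' (jaccard, openknot) lexicographically descending.
#'
#' @param candidates list of \code{design_candidate}s.
#' @param target a \code{design_target}.
#' @param env a \code{design_env}.
#' @param shape_source optional function(sequence) returning a
#'   \code{shape_profile} to use instead of the environment's predictor
#'   (e.g. measured data).
#' @param flank,flank_weight passed to
#'   \code{\link{crossed_pair_quality_score}}.
#' @return ranked list of \code{design_candidate}s with reports attached.
#' @export
screen <- function(candidates, target, env, shape_source = NULL,
                   flank = list(), flank_weight = 0.5) {
  stopifnot(inherits(target, "design_target"), inherits(env, "design_env"))
  seqs <- vapply(candidates, function(cn) cn$sequence, character(1))
  keep <- !duplicated(seqs)
  candidates <- candidates[keep]
  scored <- lapply(candidates, function(cn) {
    pred <- env_fold(env, cn$sequence)
    jac <- jaccard_basepairs(pred, target$structure)
    shape <- if (!is.null(shape_source)) shape_source(cn$sequence)
             else env_shape(env, cn$sequence)
    rep <- if (!is.null(shape)) {
      openknot_score(pred, normalize_shape(shape), flank, flank_weight,
                     jaccard = jac)
    } else {
      structure(list(jaccard = jac, eterna_classic = NA_real_,
                     crossed_pair_quality = NA_real_, openknot = NA_real_),
                class = "score_report")
    }
    cn$report <- rep
    cn
  })
  jac <- vapply(scored, function(cn) cn$report$jaccard, numeric(1))
  ok <- vapply(scored, function(cn) {
    if (is.na(cn$report$openknot)) -Inf else cn$report$openknot
  }, numeric(1))
  sq <- vapply(scored, function(cn) cn$sequence, character(1))
  scored[order(-jac, -ok, sq)]
}
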