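# The reward-providing environment: a pluggable pair of predictors mapping a
# candidate sequence to (i) a secondary structure (directly, as dot-bracket,
# or as an L x L pairing-probability matrix put through Hungarian extraction)
# and (ii) optionally a SHAPE reactivity profile.  The shipped reference
# environment folds with a deterministic Nussinov maximum-pairing oracle and
# derives SHAPE reactivities from pairing status.

seq_to_codes <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  codes <- match(chars, RNA_BASES)
  if (anyNA(codes)) {
    stop(sprintf("invalid character '%s' in RNA sequence (alphabet ACGU)",
                 chars[which(is.na(codes))[1L]]))
  }
  codes
}

codes_to_seq <- function(codes) paste(RNA_BASES[codes], collapse = "")

# evaluate code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Maximum base-pair (Nussinov) folding
#'
#' Deterministic reference folder: maximises the number of canonical pairs
#' (A-U, G-C, G-U) subject to nesting and a minimum hairpin-loop span of
#' \code{min_loop} unpaired positions.  Traceback ties are broken by
#' preferring "j unpaired" over pairing j, then the smallest partner index,
#' so the result is a pure function of the sequence.
#'
#' @param sequence RNA string over ACGU.
#' @param min_loop minimum number of positions strictly between a pair
#'   (default 3).
#' @return a \code{secondary_structure}.
#' @examples
#' dotbracket(nussinov_fold("GGGAAACCC"))
#' @export
nussinov_fold <- function(sequence, min_loop = 3L) {
  stopifnot(min_loop >= 0L)
  codes <- seq_to_codes(sequence)
  pairs <- nussinov_pairs_cpp(codes, as.integer(min_loop))
  secondary_structure(pairs, length(codes))
}

#' SHAPE reactivity profile
#'
#' @param reactivities non-negative numeric vector, one value per position.
#' @param normalized has the profile been scaled to a 90th percentile of 1?
#' @return an object of class \code{shape_profile}.
#' @export
shape_profile <- function(reactivities, normalized = FALSE) {
  reactivities <- as.numeric(reactivities)
  if (any(reactivities < 0)) stop("SHAPE reactivities must be non-negative")
  structure(list(reactivities = reactivities, normalized = isTRUE(normalized)),
            class = "shape_profile")
}

#' @export
print.shape_profile <- function(x, ...) {
  cat(sprintf("shape_profile: %d positions, %snormalized\n",
              length(x$reactivities), if (x$normalized) "" else "not "))
  invisible(x)
}

#' Structure-derived SHAPE oracle
#'
#' Emits the idealised chemical-probing signal of a structure: paired
#' positions are rigid (base reactivity 0.1), unpaired positions flexible
#' (0.9), plus optional zero-mean Gaussian noise clipped at zero.  Used as
#' the SHAPE-predictive half of the reference environment.
#'
#' @param sequence RNA string (length only is used; kept in the signature so
#'   the oracle satisfies the predictor contract).
#' @param structure the \code{secondary_structure} the profile reflects.
#' @param noise_sd standard deviation of the additive noise (default 0).
#' @param seed RNG seed for the noise; same seed, same profile.
#' @return a \code{shape_profile} (not normalized).
#' @export
oracle_shape <- function(sequence, structure, noise_sd = 0, seed = 1L) {
  stopifnot(noise_sd >= 0)
  n <- nchar(sequence)
  if (n != structure$length) {
    stop(sprintf("sequence length %d does not match structure length %d",
                 n, structure$length))
  }
  paired <- !is.na(pairing_partner(structure))
  base <- ifelse(paired, 0.1, 0.9)
  if (noise_sd > 0) {
    noise <- with_seed(seed, stats::rnorm(n, mean = 0, sd = noise_sd))
    base <- pmax(base + noise, 0)
  }
  shape_profile(base)
}

#' Extract base pairs from a pairing-probability matrix
#'
#' Solves a maximum-weight one-to-one assignment on the (symmetric)
#' probability matrix with the Hungarian method, then keeps only mutually
#' assigned pairs i <-> j with probability at least \code{threshold}.
#' Self-pairs and pairs closer than \code{min_loop} are excluded by zeroing
#' the near-diagonal band before assignment.
#'
#' @param prob square symmetric matrix with entries in [0, 1].
#' @param threshold minimum probability for a retained pair (default 0.5).
#' @param min_loop minimum loop span enforced on extracted pairs (default 3).
#' @param tol symmetry tolerance (default 1e-8).
#' @return a \code{secondary_structure}.
#' @export
extract_pairs_hungarian <- function(prob, threshold = 0.5, min_loop = 3L,
                                    tol = 1e-8) {
  stopifnot(is.matrix(prob), nrow(prob) == ncol(prob))
  stopifnot(threshold > 0, threshold < 1)
  if (max(abs(prob - t(prob))) > tol) {
    stop("pairing-probability matrix is not symmetric within tolerance")
  }
  if (min(prob) < 0 || max(prob) > 1) {
    stop("pairing probabilities must lie in [0, 1]")
  }
  n <- nrow(prob)
  w <- (prob + t(prob)) / 2
  band <- abs(row(w) - col(w)) <= min_loop   # includes the diagonal
  w[band] <- 0
  assign_col <- hungarian_cpp(-w) + 1L       # max weight = min of negated
  i <- seq_len(n)
  mutual <- assign_col[assign_col[i]] == i & assign_col[i] != i
  keep <- which(mutual & i < assign_col[i])
  keep <- keep[w[cbind(keep, assign_col[keep])] >= threshold]
  pairs <- if (length(keep) > 0L) cbind(keep - 1L, assign_col[keep] - 1L)
           else matrix(integer(0), ncol = 2L)
  secondary_structure(pairs, n)
}

#' Is the SHAPE constraint satisfied at one position?
#'
#' Unpaired positions must be reactive (reactivity strictly above
#' \code{unpaired_min}); paired positions must be protected (strictly below
#' \code{paired_max}).
#'
#' @param position_paired logical (may be a vector).
#' @param reactivity numeric reactivity value(s).
#' @param unpaired_min lower threshold for unpaired positions (default 0.5).
#' @param paired_max upper threshold for paired positions (default 0.25).
#' @return logical of the common length.
#' @export
shape_constraint_satisfied <- function(position_paired, reactivity,
                                       unpaired_min = 0.5, paired_max = 0.25) {
  stopifnot(unpaired_min > paired_max)
  position_paired <- rep_len(position_paired, length(reactivity))
  ifelse(position_paired, reactivity < paired_max, reactivity > unpaired_min)
}

#' Per-position design rewards
#'
#' The reward at position t is the product of two indicators: the pairing
#' status (partner index, or unpaired) of the predicted structure matches
#' the target, and — when a SHAPE profile is supplied — the SHAPE constraint
#' is satisfied for the target pairing status.  Structure-only mode
#' (\code{shape = NULL}) drops the second term.
#'
#' @param predicted \code{secondary_structure} predicted from the candidate
#'   sequence by the environment.
#' @param target \code{secondary_structure} the design must fold into.
#' @param shape optional \code{shape_profile} of the candidate.
#' @param unpaired_min,paired_max SHAPE thresholds, see
#'   \code{\link{shape_constraint_satisfied}}.
#' @return numeric vector of 0/1 rewards, one per position.
#' @export
compute_rewards <- function(predicted, target, shape = NULL,
                            unpaired_min = 0.5, paired_max = 0.25) {
  if (predicted$length != target$length) {
    stop(sprintf("predicted length %d does not match target length %d",
                 predicted$length, target$length))
  }
  pp <- pairing_partner(predicted)
  tp <- pairing_partner(target)
  status_ok <- (is.na(pp) & is.na(tp)) | (!is.na(pp) & !is.na(tp) & pp == tp)
  r <- as.numeric(status_ok)
  if (!is.null(shape)) {
    if (length(shape$reactivities) != target$length) {
      stop("SHAPE profile length does not match structure length")
    }
    ok <- shape_constraint_satisfied(!is.na(tp), shape$reactivities,
                                     unpaired_min, paired_max)
    r <- r * as.numeric(ok)
  }
  r
}

#' Build a design environment from predictor functions
#'
#' A design environment bundles the two predictors of the reward loop.  The
#' fold predictor may return a \code{secondary_structure}, a dot-bracket
#' string, or an L x L pairing-probability matrix (which is put through
#' \code{\link{extract_pairs_hungarian}}).  External neural predictors
#' attach here without changes elsewhere.
#'
#' @param fold function(sequence) returning a structure in one of the three
#'   accepted forms.
#' @param shape optional function(sequence) returning a
#'   \code{shape_profile}; \code{NULL} for structure-only environments.
#' @param threshold probability threshold for Hungarian extraction.
#' @param min_loop loop-span constraint for Hungarian extraction.
#' @param name label used in logs.
#' @return an object of class \code{design_env}.
#' @export
design_env <- function(fold, shape = NULL, threshold = 0.5, min_loop = 3L,
                       name = "custom") {
  stopifnot(is.function(fold), is.null(shape) || is.function(shape))
  structure(list(fold = fold, shape = shape, threshold = threshold,
                 min_loop = as.integer(min_loop), name = name),
            class = "design_env")
}

#' The reference Nussinov environment
#'
#' Folds with \code{\link{nussinov_fold}} and (optionally) derives SHAPE
#' reactivities from the fold with \code{\link{oracle_shape}}.  Both
#' predictors are pure functions of the sequence: the SHAPE noise seed is
#' derived deterministically from the sequence content.
#'
#' @param min_loop loop-span constraint of the folder (default 3).
#' @param with_shape attach the SHAPE oracle? (default FALSE:
#'   structure-only rewards).
#' @param noise_sd SHAPE noise level (default 0).
#' @param shape_seed base seed mixed with the sequence hash for SHAPE noise.
#' @return a \code{design_env}.
#' @export
nussinov_environment <- function(min_loop = 3L, with_shape = FALSE,
                                 noise_sd = 0, shape_seed = 1L) {
  fold <- function(sequence) nussinov_fold(sequence, min_loop)
  shape <- NULL
  if (with_shape) {
    shape <- function(sequence) {
      st <- nussinov_fold(sequence, min_loop)
      codes <- seq_to_codes(sequence)
      seed <- (shape_seed + sum(codes * seq_along(codes))) %% 2147483647L
      oracle_shape(sequence, st, noise_sd = noise_sd, seed = as.integer(seed))
    }
  }
  design_env(fold, shape, min_loop = min_loop, name = "nussinov")
}

#' Fold a sequence through an environment
#'
#' @param env a \code{design_env}.
#' @param sequence RNA string.
#' @return a \code{secondary_structure}.
#' @export
env_fold <- function(env, sequence) {
  stopifnot(inherits(env, "design_env"))
  out <- env$fold(sequence)
  if (is_secondary_structure(out)) return(out)
  if (is.character(out)) return(parse_dotbracket(out))
  if (is.matrix(out)) {
    return(extract_pairs_hungarian(out, threshold = env$threshold,
                                   min_loop = env$min_loop))
  }
  stop("fold predictor must return a structure, dot-bracket, or matrix")
}

#' SHAPE-profile a sequence through an environment
#'
#' @param env a \code{design_env}.
#' @param sequence RNA string.
#' @return a \code{shape_profile}, or \code{NULL} for structure-only
#'   environments.
#' @export
env_shape <- function(env, sequence) {
  stopifnot(inherits(env, "design_env"))
  if (is.null(env$shape)) return(NULL)
  env$shape(sequence)
}
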