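# Screening metrics: base-pair Jaccard, Eterna Classic Score, Crossed Pair
# Quality Score, and their mean, the OpenKnot score (all on a 0-100 scale).

#' Jaccard index of two base-pair sets
#'
#' Intersection over union of the pair sets of two structures of equal
#' length.  Two structures with no pairs at all agree perfectly and score 1.
#'
#' @param predicted,target \code{secondary_structure} objects of equal length.
#' @return numeric in [0, 1].
#' @export
jaccard_basepairs <- function(predicted, target) {
  stopifnot(is_secondary_structure(predicted), is_secondary_structure(target))
  if (predicted$length != target$length) {
    stop("structures must have equal length")
  }
  a <- paste(predicted$pairs[, 1L], predicted$pairs[, 2L])
  b <- paste(target$pairs[, 1L], target$pairs[, 2L])
  if (length(a) == 0L && length(b) == 0L) return(1.0)
  length(intersect(a, b)) / length(union(a, b))
}

#' Normalise a SHAPE profile to a 90th percentile of 1
#'
#' Divides all reactivities by the 90th-percentile value, computed with
#' linear interpolation between order statistics (the default quantile
#' convention).  Idempotent on already-normalised profiles.
#'
#' @param profile a \code{shape_profile} with at least one positive value.
#' @return the normalised \code{shape_profile}.
#' @export
normalize_shape <- function(profile) {
  stopifnot(inherits(profile, "shape_profile"))
  q90 <- stats::quantile(profile$reactivities, probs = 0.9, names = FALSE,
                         type = 7)
  if (!is.finite(q90) || q90 <= 0) {
    stop("cannot normalise: 90th-percentile reactivity is not positive")
  }
  shape_profile(profile$reactivities / q90, normalized = TRUE)
}

# residue-level SHAPE consistency: paired residues must not be too reactive,
# unpaired residues must not be too protected; values exactly at a threshold
# count as consistent (penalties use strict inequalities > 0.5 / < 0.125)
shape_consistent <- function(paired, reactivity) {
  paired <- rep_len(paired, length(reactivity))
  ifelse(paired, reactivity <= 0.5, reactivity >= 0.125)
}

#' Eterna Classic Score
#'
#' Fraction (x 100) of residues whose normalised SHAPE reactivity is
#' consistent with their pairing status in the structure: a paired residue
#' is penalised when reactivity > 0.5, an unpaired residue when
#' reactivity < 0.125.
#'
#' @param structure a \code{secondary_structure}.
#' @param shape a normalised \code{shape_profile} of the same length.
#' @return numeric in [0, 100].
#' @export
eterna_classic_score <- function(structure, shape) {
  stopifnot(is_secondary_structure(structure), inherits(shape, "shape_profile"))
  if (!shape$normalized) {
    stop("SHAPE profile must be normalised (see normalize_shape)")
  }
  if (length(shape$reactivities) != structure$length) {
    stop("profile length does not match structure length")
  }
  paired <- !is.na(pairing_partner(structure))
  100 * mean(shape_consistent(paired, shape$reactivities))
}

#' Crossed Pair Quality Score
#'
#' The Eterna Classic consistency rule restricted to residues that take part
#' in crossing (pseudoknotted) base pairs, after removing singlet pairs.
#' Residues whose pairing partner falls inside a designated flanking region
#' contribute with weight \code{flank_weight} to both numerator and
#' denominator.  A structure with no crossing pairs left scores 0.
#'
#' @param structure a \code{secondary_structure}.
#' @param shape a normalised \code{shape_profile}.
#' @param flank list of 0-based inclusive intervals \code{c(a, b)} defining
#'   the flanking region(s); empty by default.
#' @param flank_weight weight in [0, 1] for residues partnered into a flank
#'   (default 0.5).
#' @return numeric in [0, 100].
#' @export
crossed_pair_quality_score <- function(structure, shape, flank = list(),
                                       flank_weight = 0.5) {
  stopifnot(is_secondary_structure(structure), inherits(shape, "shape_profile"))
  if (!shape$normalized) {
    stop("SHAPE profile must be normalised (see normalize_shape)")
  }
  if (length(shape$reactivities) != structure$length) {
    stop("profile length does not match structure length")
  }
  if (flank_weight < 0 || flank_weight > 1) {
    stop("flank_weight must lie in [0, 1]")
  }
  cp <- crossing_pairs(remove_singlets(structure))
  if (nrow(cp) == 0L) return(0.0)
  res <- c(cp[, 1L], cp[, 2L])          # residues in crossing pairs
  partner <- c(cp[, 2L], cp[, 1L])
  in_flank <- rep(FALSE, length(partner))
  for (iv in flank) {
    in_flank <- in_flank | (partner >= iv[1L] & partner <= iv[2L])
  }
  w <- ifelse(in_flank, flank_weight, 1)
  consistent <- shape_consistent(TRUE, shape$reactivities[res + 1L])
  if (sum(w) == 0) return(0.0)
  100 * sum(w * consistent) / sum(w)
}

#' OpenKnot score report
#'
#' The OpenKnot score is the mean of the Eterna Classic Score and the
#' Crossed Pair Quality Score, quantifying how well SHAPE data support a
#' design, with pseudoknotted pairs given dedicated weight.
#'
#' @inheritParams crossed_pair_quality_score
#' @param jaccard optional base-pair Jaccard against a target, carried into
#'   the report when known.
#' @return a \code{score_report} list with elements \code{jaccard},
#'   \code{eterna_classic}, \code{crossed_pair_quality}, \code{openknot}.
#' @export
openknot_score <- function(structure, shape, flank = list(),
                           flank_weight = 0.5, jaccard = NA_real_) {
  ecs <- eterna_classic_score(structure, shape)
  cpq <- crossed_pair_quality_score(structure, shape, flank, flank_weight)
  structure(
    list(jaccard = jaccard, eterna_classic = ecs, crossed_pair_quality = cpq,
         openknot = (ecs + cpq) / 2),
    class = "score_report"
  )
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf(
    "score_report: jaccard %.3f | ECS %.1f | CPQ %.1f | OpenKnot %.1f\n",
    x$jaccard, x$eterna_classic, x$crossed_pair_quality, x$openknot))
  invisible(x)
}
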