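# Seeded generation of designable targets: hairpins, H-type pseudoknots,
# and fold-derived structures (targets obtained by folding random sequences,
# hence solvable by construction under the reference environment).

#' Simple hairpin structure
#'
#' Pairs \code{(i, L-1-i)} for \code{i < stem}, \code{L = 2*stem + loop}.
#'
#' @param stem helix length (>= 1).
#' @param loop loop length (>= 3, the folding oracle's minimum span).
#' @return a \code{secondary_structure}.
#' @examples
#' dotbracket(make_hairpin(3, 3))   # "(((...)))"
#' @export
make_hairpin <- function(stem, loop) {
  stopifnot(stem >= 1L)
  if (loop < 3L) stop("loop must be >= 3 to satisfy the minimum loop span")
  L <- 2L * stem + loop
  i <- seq_len(stem) - 1L
  secondary_structure(cbind(i, L - 1L - i), L)
}

#' H-type pseudoknot structure
#'
#' Two helices whose pair sets mutually cross: stem 1 pairs the 5' end with
#' the region between the two loops, stem 2 pairs the region after loop 1
#' with the 3' end.  Layout: S1open, loop1, S2open, S1close, loop2, S2close,
#' tail.
#'
#' @param stem1,stem2 helix lengths (>= 1).
#' @param loop1,loop2 loop lengths.
#' @param tail unpaired 3' tail length (default 0).
#' @return a \code{secondary_structure} with non-empty
#'   \code{\link{crossing_pairs}}.
#' @export
make_htype_pseudoknot <- function(stem1 = 3L, loop1 = 2L, stem2 = 3L,
                                  loop2 = 2L, tail = 0L) {
  a <- as.integer(stem1); b <- as.integer(loop1)
  c_ <- as.integer(stem2); d <- as.integer(loop2); tl <- as.integer(tail)
  stopifnot(a >= 1L, c_ >= 1L, b >= 0L, d >= 0L, tl >= 0L)
  # innermost spans enclosed by each helix must satisfy the min-loop rule
  if (b + c_ < 3L || a + d < 3L) {
    stop("infeasible geometry: enclosed spans (loop1+stem2, stem1+loop2) ",
         "must both be >= 3")
  }
  L <- 2L * a + b + 2L * c_ + d + tl
  i1 <- seq_len(a) - 1L
  p1 <- cbind(i1, (a + b + c_) + (a - 1L - i1))
  i2 <- seq_len(c_) - 1L
  p2 <- cbind(a + b + i2, (2L * a + b + c_ + d) + (c_ - 1L - i2))
  secondary_structure(rbind(p1, p2), L)
}

#' Random hairpin targets of fixed length
#'
#' Draws stem lengths uniformly in the feasible range (stem >= 3 so helices
#' are well stacked; loop = length - 2*stem >= 3) and returns hairpin
#' design targets.
#'
#' @param n number of targets.
#' @param length target length.
#' @param seed RNG seed.
#' @return list of \code{design_target}s.
#' @export
make_hairpin_targets <- function(n, length = 20L, seed = 1L) {
  length <- as.integer(length)
  smax <- (length - 3L) %/% 2L
  if (smax < 3L) stop("length too short for a stem of 3")
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      stem <- sample.int(smax - 2L, 1L) + 2L      # uniform on 3..smax
      design_target(make_hairpin(stem, length - 2L * stem),
                    id = sprintf("hairpin_%03d", i))
    })
  })
}

#' Fold-derived designable targets
#'
#' Draws random GC-biased sequences, folds each with
#' \code{\link{nussinov_fold}}, and keeps structures with at least
#' \code{length/6} pairs.  Every returned target is designable by
#' construction: its source sequence solves it exactly.
#'
#' @param n number of targets to return.
#' @param length sequence length.
#' @param seed RNG seed.
#' @param gc_bias total probability mass on G and C (default 0.6).
#' @param min_loop folding oracle loop constraint.
#' @return list of \code{list(sequence, structure)} of length n.
#' @export
make_fold_derived_targets <- function(n, length = 30L, seed = 1L,
                                      gc_bias = 0.6, min_loop = 3L) {
  stopifnot(n >= 1L)
  probs <- c(A = (1 - gc_bias) / 2, C = gc_bias / 2,
             G = gc_bias / 2, U = (1 - gc_bias) / 2)
  min_pairs <- length %/% 6L
  with_seed(seed, {
    out <- list()
    tries <- 0L
    while (base::length(out) < n && tries < 1000L * n) {
      tries <- tries + 1L
      codes <- sample.int(4L, length, replace = TRUE, prob = probs)
      sq <- codes_to_seq(codes)
      st <- nussinov_fold(sq, min_loop)
      if (nrow(st$pairs) >= min_pairs) {
        out[[base::length(out) + 1L]] <- list(sequence = sq, structure = st)
      }
    }
    if (base::length(out) < n) {
      stop("could not generate enough fold-derived targets")
    }
    out
  })
}

#' Hairpin targets with known Watson-Crick solutions
#'
#' Builds random hairpin targets together with a solving sequence: each stem
#' pair is assigned G-C or C-G at random and the loop is filled with A, so
#' the solution contains no U and the loop cannot pair.  Only (target,
#' sequence) couples whose fold is exactly the target are returned, making
#' them convenient ground truth for repair experiments.
#'
#' @param n number of couples to return.
#' @param length hairpin length.
#' @param seed RNG seed.
#' @return list of \code{list(target, sequence)}.
#' @export
make_solved_hairpins <- function(n, length = 20L, seed = 1L) {
  gc_combos <- list(c(3L, 2L), c(2L, 3L))
  with_seed(seed, {
    out <- list()
    tries <- 0L
    while (base::length(out) < n && tries < 100L * n) {
      tries <- tries + 1L
      smax <- (length - 3L) %/% 2L
      stem <- sample.int(smax - 2L, 1L) + 2L
      st <- make_hairpin(stem, length - 2L * stem)
      codes <- rep(1L, length)
      for (r in seq_len(nrow(st$pairs))) {
        asg <- gc_combos[[sample.int(2L, 1L)]]
        codes[st$pairs[r, 1L] + 1L] <- asg[1L]
        codes[st$pairs[r, 2L] + 1L] <- asg[2L]
      }
      sq <- codes_to_seq(codes)
      if (same_structure(nussinov_fold(sq), st)) {
        out[[base::length(out) + 1L]] <-
          list(target = design_target(st, id = sprintf(
            "solved_%03d", base::length(out) + 1L)), sequence = sq)
      }
    }
    if (base::length(out) < n) stop("could not generate enough couples")
    out
  })
}
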