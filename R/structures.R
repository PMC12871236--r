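# Pseudoknotted RNA secondary structures as explicit base-pair sets.
#
# Conventions used throughout the package:
#   * positions are 0-based and inclusive;
#   * pairs are stored as a two-column integer matrix with i < j, sorted by i;
#   * up to four bracket tiers "()", "[]", "{}", "<>" encode pseudoknot order.

#' Construct a secondary structure from a base-pair set
#'
#' A secondary structure is a sequence length together with a set of base
#' pairs \code{(i, j)}, \code{0 <= i < j < length}, in which every position
#' participates in at most one pair.  Crossing pairs (pseudoknots) are
#' allowed.  No minimum hairpin-loop span is enforced here: structures
#' produced by other tools may violate the folding oracle's loop rule and
#' must still be representable.
#'
#' @param pairs two-column matrix (or empty) of 0-based pair indices; rows
#'   may be in either order, they are normalised to i < j and sorted.
#' @param length sequence length in nucleotides (positive integer).
#' @param dotbracket optional known dot-bracket rendering (cached; it is
#'   recomputed on demand otherwise).
#' @return an object of class \code{secondary_structure} with elements
#'   \code{length} and \code{pairs}.
#' @examples
#' secondary_structure(rbind(c(0, 8), c(1, 7), c(2, 6)), 9)
#' @export
secondary_structure <- function(pairs, length, dotbracket = NULL) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) {
    stop("structure length must be a positive integer")
  }
  if (is.null(pairs) || (is.matrix(pairs) && nrow(pairs) == 0L) ||
      (!is.matrix(pairs) && length(pairs) == 0L)) {
    pairs <- matrix(integer(0), ncol = 2L)
  } else {
    pairs <- matrix(as.integer(pairs), ncol = 2L)
  }
  if (nrow(pairs) > 0L) {
    ij <- cbind(pmin(pairs[, 1L], pairs[, 2L]), pmax(pairs[, 1L], pairs[, 2L]))
    if (any(ij[, 1L] == ij[, 2L])) stop("a position cannot pair with itself")
    if (any(ij < 0L) || any(ij >= length)) {
      stop("pair index out of range [0, length)")
    }
    idx <- c(ij[, 1L], ij[, 2L])
    if (anyDuplicated(idx)) {
      stop("position ", idx[duplicated(idx)][1L],
           " participates in more than one pair")
    }
    pairs <- ij[order(ij[, 1L]), , drop = FALSE]
  }
  colnames(pairs) <- c("i", "j")
  structure(
    list(length = length, pairs = pairs, dotbracket = dotbracket),
    class = "secondary_structure"
  )
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("secondary_structure: length %d, %d pairs\n",
              x$length, nrow(x$pairs)))
  db <- tryCatch(dotbracket(x), error = function(e) NULL)
  if (!is.null(db)) cat(" ", db, "\n")
  invisible(x)
}

#' @export
length.secondary_structure <- function(x) x$length

is_secondary_structure <- function(x) inherits(x, "secondary_structure")

#' Per-position pairing partner
#'
#' @param structure a \code{secondary_structure}.
#' @return integer vector of length \code{length(structure)} giving the
#'   0-based partner of each position, or \code{NA} where unpaired.
#' @export
pairing_partner <- function(structure) {
  stopifnot(is_secondary_structure(structure))
  partner <- rep(NA_integer_, structure$length)
  p <- structure$pairs
  if (nrow(p) > 0L) {
    partner[p[, 1L] + 1L] <- p[, 2L]
    partner[p[, 2L] + 1L] <- p[, 1L]
  }
  partner
}

#' Parse dot-bracket notation into a secondary structure
#'
#' Accepts the four bracket tiers \code{()}, \code{[]}, \code{{}} and
#' \code{<>}; each tier is matched with its own stack, so crossing tiers
#' encode pseudoknots.  Any other character except \code{.} is an error.
#'
#' @param text dot-bracket string.
#' @return a \code{secondary_structure}.
#' @examples
#' parse_dotbracket("(((...)))")
#' parse_dotbracket("((..[[..))..]]")   # H-type pseudoknot
#' @export
parse_dotbracket <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  stacks <- rep(list(integer(0)), 4L)
  pairs <- matrix(integer(0), ncol = 2L)
  acc_i <- integer(0)
  acc_j <- integer(0)
  for (pos in seq_len(n)) {
    ch <- chars[pos]
    if (ch == ".") next
    tier <- match(ch, BRACKET_OPEN)
    if (!is.na(tier)) {
      stacks[[tier]] <- c(stacks[[tier]], pos - 1L)
      next
    }
    tier <- match(ch, BRACKET_CLOSE)
    if (is.na(tier)) {
      stop(sprintf("unknown character '%s' at position %d (0-based)",
                   ch, pos - 1L))
    }
    st <- stacks[[tier]]
    if (length(st) == 0L) {
      stop(sprintf("unbalanced '%s' at position %d (0-based): no open '%s'",
                   ch, pos - 1L, BRACKET_OPEN[tier]))
    }
    acc_i <- c(acc_i, st[length(st)])
    acc_j <- c(acc_j, pos - 1L)
    stacks[[tier]] <- st[-length(st)]
  }
  open_left <- vapply(stacks, length, integer(1))
  if (any(open_left > 0L)) {
    tier <- which(open_left > 0L)[1L]
    st <- stacks[[tier]]
    stop(sprintf("unbalanced '%s' opened at position %d (0-based)",
                 BRACKET_OPEN[tier], st[length(st)]))
  }
  if (n == 0L) stop("empty dot-bracket string")
  if (length(acc_i) > 0L) pairs <- cbind(acc_i, acc_j)
  secondary_structure(pairs, n, dotbracket = text)
}

#' Render a secondary structure as dot-bracket text
#'
#' Crossing pairs are assigned to distinct bracket tiers by greedy colouring
#' of the pair-crossing graph, in tier order \code{()}, \code{[]},
#' \code{{}}, \code{<>}.  More than four mutually crossing families cannot
#' be rendered and raise an error stating the tier count required.
#'
#' @param structure a \code{secondary_structure}.
#' @return dot-bracket string of length \code{length(structure)}.
#' @export
render_dotbracket <- function(structure) {
  stopifnot(is_secondary_structure(structure))
  n <- structure$length
  p <- structure$pairs
  out <- rep(".", n)
  m <- nrow(p)
  if (m > 0L) {
    cross <- crossing_matrix(p)
    tier <- integer(m)            # 0 = unassigned
    for (k in seq_len(m)) {
      used <- tier[which(cross[k, ])]
      t_k <- 1L
      while (t_k %in% used) t_k <- t_k + 1L
      if (t_k > length(BRACKET_OPEN)) {
        stop(sprintf(
          "structure needs %d bracket tiers but only %d are supported",
          t_k, length(BRACKET_OPEN)))
      }
      tier[k] <- t_k
    }
    out[p[, 1L] + 1L] <- BRACKET_OPEN[tier]
    out[p[, 2L] + 1L] <- BRACKET_CLOSE[tier]
  }
  paste(out, collapse = "")
}

#' Dot-bracket rendering, cached
#'
#' @param structure a \code{secondary_structure}.
#' @return the stored dot-bracket string if the structure was parsed from
#'   one, otherwise a fresh rendering.
#' @export
dotbracket <- function(structure) {
  if (!is.null(structure$dotbracket)) return(structure$dotbracket)
  render_dotbracket(structure)
}

# m x m logical matrix: do pairs k and l cross?
crossing_matrix <- function(pairs) {
  m <- nrow(pairs)
  i <- pairs[, 1L]; j <- pairs[, 2L]
  ik <- matrix(i, m, m); jk <- matrix(j, m, m)
  il <- t(ik); jl <- t(jk)
  (ik < il & il < jk & jk < jl) | (il < ik & ik < jl & jl < jk)
}

#' Pairs involved in pseudoknots
#'
#' Returns every pair \code{(i, j)} crossed by some other pair
#' \code{(k, l)}, i.e. \code{i < k < j < l} or \code{k < i < l < j}.
#'
#' @param structure a \code{secondary_structure}.
#' @return two-column integer matrix of crossing pairs (possibly empty).
#' @export
crossing_pairs <- function(structure) {
  stopifnot(is_secondary_structure(structure))
  p <- structure$pairs
  if (nrow(p) == 0L) return(p)
  keep <- rowSums(crossing_matrix(p)) > 0
  p[keep, , drop = FALSE]
}

#' Remove singlet (isolated) base pairs
#'
#' A pair \code{(i, j)} is a singlet when it has no stacked neighbour,
#' i.e. neither \code{(i-1, j+1)} nor \code{(i+1, j-1)} is in the pair set.
#'
#' @param structure a \code{secondary_structure}.
#' @return a new \code{secondary_structure} with all singlets dropped.
#' @export
remove_singlets <- function(structure) {
  stopifnot(is_secondary_structure(structure))
  p <- structure$pairs
  if (nrow(p) == 0L) return(structure)
  key <- paste(p[, 1L], p[, 2L])
  outer_nb <- paste(p[, 1L] - 1L, p[, 2L] + 1L) %in% key
  inner_nb <- paste(p[, 1L] + 1L, p[, 2L] - 1L) %in% key
  secondary_structure(p[outer_nb | inner_nb, , drop = FALSE], structure$length)
}

#' Binary contact matrix of a structure
#'
#' @param structure a \code{secondary_structure}.
#' @return symmetric L x L 0/1 matrix with ones at paired index pairs and a
#'   zero diagonal.
#' @export
contact_matrix <- function(structure) {
  stopifnot(is_secondary_structure(structure))
  n <- structure$length
  m <- matrix(0, n, n)
  p <- structure$pairs
  if (nrow(p) > 0L) {
    m[cbind(p[, 1L] + 1L, p[, 2L] + 1L)] <- 1
    m[cbind(p[, 2L] + 1L, p[, 1L] + 1L)] <- 1
  }
  m
}

#' Set equality of two structures
#'
#' @param a,b \code{secondary_structure} objects.
#' @return TRUE when lengths and pair sets agree exactly.
#' @export
same_structure <- function(a, b) {
  a$length == b$length && nrow(a$pairs) == nrow(b$pairs) &&
    all(a$pairs == b$pairs)
}
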