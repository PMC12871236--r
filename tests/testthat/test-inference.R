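test_that("beam width 1 equals greedy decoding", {
  net <- tiny_qnet(5)
  for (seed in 1:6) {
    st <- rand_structure(1100 + seed)
    target <- design_target(st)
    g <- greedy_decode(net, target)
    b <- beam_search(net, target, k = 1L)
    expect_equal(length(b), 1L)
    expect_equal(b[[1]]$sequence, g$sequence)
    expect_equal(b[[1]]$cumulative_q, g$cumulative_q, tolerance = 1e-8)
  }
})

test_that("wide beam recovers the exhaustive ranking on length-4 targets", {
  net <- tiny_qnet(15)
  for (db in c("....", "(..).....")) {
    st <- parse_dotbracket(db)
    target <- design_target(st)
    L <- st$length
    # exhaustive enumeration of all mask-consistent sequences
    combos <- as.matrix(expand.grid(rep(list(1:4), L)))
    ok <- apply(combos, 1, function(codes) {
      for (t in seq_len(L)) {
        m <- valid_actions(target, t - 1L, codes[seq_len(t - 1L)])
        if (!m[codes[t]]) return(FALSE)
      }
      TRUE
    })
    combos <- combos[ok, , drop = FALSE]
    scores <- apply(combos, 1, function(codes) {
      cumulative_q_of(net, target, as.integer(codes))
    })
    seqs <- apply(combos, 1, function(codes) {
      paste(c("A", "C", "G", "U")[codes], collapse = "")
    })
    ord <- order(-scores, seqs)
    got <- beam_search(net, target, k = 256L)
    topn <- min(10L, length(got))
    expect_equal(vapply(got[1:topn], `[[`, character(1), "sequence"),
                 seqs[ord][1:topn], label = db)
    expect_equal(vapply(got[1:topn], `[[`, numeric(1), "cumulative_q"),
                 scores[ord][1:topn], tolerance = 1e-6)
  }
})

test_that("beam quality is non-decreasing in beam width", {
  net <- tiny_qnet(25)
  st <- rand_structure(1301)
  target <- design_target(st)
  best <- -Inf
  for (k in c(1L, 2L, 4L, 8L)) {
    b <- beam_search(net, target, k = k)
    expect_gte(b[[1]]$cumulative_q, best - 1e-9)
    best <- max(best, b[[1]]$cumulative_q)
  }
})

test_that("all decoding strategies respect the valid-action mask", {
  net <- tiny_qnet(35)
  env <- nussinov_environment()
  check_mask <- function(target, sequence) {
    codes <- qrnadesign:::seq_to_codes(sequence)
    for (t in seq_along(codes)) {
      m <- valid_actions(target, t - 1L, codes[seq_len(t - 1L)])
      expect_true(m[codes[t]])
    }
  }
  for (seed in 1:4) {
    st <- rand_structure(1400 + seed)
    target <- design_target(st)
    check_mask(target, greedy_decode(net, target)$sequence)
    for (cn in beam_search(net, target, k = 3L)) {
      check_mask(target, cn$sequence)
    }
    for (cn in random_search(net, target, n = 3L, uniform_prob = 0.5,
                             seed = seed)) {
      check_mask(target, cn$sequence)
    }
  }
})

test_that("random search is reproducible and uniform at uniform_prob 1", {
  net <- tiny_qnet(45, embed_dim = 8L)
  target <- design_target("....")
  a <- random_search(net, target, n = 20, seed = 3)
  b <- random_search(net, target, n = 20, seed = 3)
  expect_identical(lapply(a, `[[`, "sequence"), lapply(b, `[[`, "sequence"))
  # empirical frequencies under pure uniform sampling
  s <- random_search(net, target, n = 10000, uniform_prob = 1, seed = 11)
  seqs <- vapply(s, `[[`, character(1), "sequence")
  mat <- do.call(rbind, strsplit(seqs, ""))
  for (pos in 1:4) {
    freq <- table(factor(mat[, pos], levels = c("A", "C", "G", "U"))) / 10000
    # binomial sd at p=0.25, n=10000 is ~0.0043; allow 5 sd
    expect_true(all(abs(freq - 0.25) < 5 * sqrt(0.25 * 0.75 / 10000)),
                label = paste("position", pos))
  }
})

test_that("near-greedy sampling approaches the greedy sequence", {
  net <- tiny_qnet(55)
  target <- design_target(make_hairpin(3, 4))
  g <- greedy_decode(net, target)
  s <- random_search(net, target, n = 5, temperature = 1e-6,
                     uniform_prob = 0, seed = 1)
  for (cn in s) expect_equal(cn$sequence, g$sequence)
})

test_that("rescue restores a hairpin broken at one stem pair", {
  env <- nussinov_environment()
  solved <- make_solved_hairpins(5, 20, seed = 31)
  set.seed(17)
  for (f in solved) {
    codes <- qrnadesign:::seq_to_codes(f$sequence)
    p <- f$target$structure$pairs[
      sample(nrow(f$target$structure$pairs), 1L), ]
    # break the pair with an A (a non-complement of both G and C) so the
    # mutation itself cannot create new pairing potential
    codes[p[1] + 1] <- 1L
    broken <- qrnadesign:::codes_to_seq(codes)
    expect_lt(jaccard_basepairs(env_fold(env, broken),
                                f$target$structure), 1.0)
    # the maximum-pairing tie-break can re-register a helix end, spreading
    # one broken pair over up to three mismatched target pairs
    fixed <- rescue(broken, f$target, env, max_mismatch_pairs = 3L)
    expect_false(is.null(fixed))
    expect_equal(jaccard_basepairs(env_fold(env, fixed$sequence),
                                   f$target$structure), 1.0)
  }
})

test_that("rescue returns matches unchanged and respects its cap", {
  env <- nussinov_environment()
  fd <- make_fold_derived_targets(1, 24, seed = 41)[[1]]
  target <- design_target(fd$structure)
  same <- rescue(fd$sequence, target, env)
  expect_equal(same$sequence, fd$sequence)
  # a hopeless input: every position mismatched on a many-pair target
  big <- design_target(make_hairpin(8, 4))
  all_a <- paste(rep("A", 20), collapse = "")
  expect_message(out <- rescue(all_a, big, env, max_mismatch_pairs = 2),
                 "exceed cap")
  expect_null(out)
})

test_that("rescue never lowers the jaccard of its input", {
  env <- nussinov_environment()
  set.seed(23)
  fd <- make_fold_derived_targets(6, 20, seed = 51)
  for (f in fd) {
    target <- design_target(f$structure)
    codes <- qrnadesign:::seq_to_codes(f$sequence)
    idx <- sample(length(codes), 2L)
    codes[idx] <- sample(4L, 2L, replace = TRUE)
    sq <- qrnadesign:::codes_to_seq(codes)
    before <- jaccard_basepairs(env_fold(env, sq), target$structure)
    fixed <- suppressMessages(rescue(sq, target, env))
    if (!is.null(fixed)) {
      after <- jaccard_basepairs(env_fold(env, fixed$sequence),
                                 target$structure)
      expect_gte(after, before)
    }
  }
})

test_that("screening ranks by jaccard then openknot and deduplicates", {
  net <- tiny_qnet(65)
  env <- nussinov_environment(with_shape = TRUE)
  fd <- make_fold_derived_targets(1, 24, seed = 61)[[1]]
  target <- design_target(fd$structure)
  cands <- c(
    list(design_candidate(fd$sequence, 1.0, "greedy"),
         design_candidate(fd$sequence, 1.0, "greedy")),   # duplicate
    random_search(net, target, n = 4, uniform_prob = 1, seed = 2))
  ranked <- screen(cands, target, env)
  seqs <- vapply(ranked, `[[`, character(1), "sequence")
  expect_equal(anyDuplicated(seqs), 0L)
  expect_equal(length(ranked), length(unique(c(fd$sequence, vapply(
    cands[-(1:2)], `[[`, character(1), "sequence")))))
  # the solving sequence folds exactly and must rank first
  expect_equal(ranked[[1]]$sequence, fd$sequence)
  expect_equal(ranked[[1]]$report$jaccard, 1.0)
  jac <- vapply(ranked, function(cn) cn$report$jaccard, numeric(1))
  expect_true(all(diff(jac) <= 1e-12))
})
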