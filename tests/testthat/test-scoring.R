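test_that("jaccard of base pairs follows intersection over union", {
  a <- secondary_structure(rbind(c(0, 8), c(1, 7)), 9)
  expect_equal(jaccard_basepairs(a, a), 1.0)
  b <- secondary_structure(rbind(c(2, 6)), 9)
  expect_equal(jaccard_basepairs(a, b), 0.0)
  c_ <- secondary_structure(rbind(c(0, 8), c(2, 6)), 9)
  expect_equal(jaccard_basepairs(a, c_), 1 / 3)
  empty <- secondary_structure(matrix(integer(0), 0, 2), 9)
  expect_equal(jaccard_basepairs(empty, empty), 1.0)
  expect_error(jaccard_basepairs(a, secondary_structure(rbind(c(0, 4)), 5)),
               "equal length")
})

test_that("SHAPE normalisation scales the 90th percentile to one", {
  p <- shape_profile(seq(0.2, 2, length.out = 10))
  q90 <- unname(quantile(p$reactivities, 0.9))
  np <- normalize_shape(p)
  expect_equal(np$reactivities, p$reactivities / q90)
  expect_equal(unname(quantile(np$reactivities, 0.9)), 1.0)
  expect_true(np$normalized)
  # idempotent
  expect_equal(normalize_shape(np)$reactivities, np$reactivities)
  # constant profile normalises to all ones
  expect_equal(normalize_shape(shape_profile(rep(4, 7)))$reactivities,
               rep(1, 7))
  expect_error(normalize_shape(shape_profile(rep(0, 5))), "not positive")
})

test_that("eterna classic score counts threshold-consistent residues", {
  st <- parse_dotbracket("(((...)))")
  perfect <- shape_profile(c(.1, .1, .1, .9, .9, .9, .1, .1, .1), TRUE)
  expect_equal(eterna_classic_score(st, perfect), 100.0)
  # every residue violating its rule
  allbad <- shape_profile(c(.9, .9, .9, .05, .05, .05, .9, .9, .9), TRUE)
  expect_equal(eterna_classic_score(st, allbad), 0.0)
  # L=10, 6 paired residues at 0.9 (bad), 4 unpaired at 0.9 (good) -> 40
  st10 <- parse_dotbracket("(((....)))")
  expect_equal(sum(!is.na(pairing_partner(st10))), 6L)
  expect_equal(eterna_classic_score(st10, shape_profile(rep(.9, 10), TRUE)),
               40.0)
  # boundary values count as consistent
  border <- shape_profile(c(.5, .5, .5, .125, .125, .125, .5, .5, .5), TRUE)
  expect_equal(eterna_classic_score(st, border), 100.0)
  expect_error(eterna_classic_score(st, shape_profile(rep(.5, 9))),
               "normalised")
})

test_that("crossed pair quality scores crossing residues only", {
  pk <- secondary_structure(rbind(c(0, 9), c(1, 8), c(4, 13), c(5, 12)), 14)
  all_protected <- shape_profile(rep(0.1, 14), TRUE)
  expect_equal(crossed_pair_quality_score(pk, all_protected), 100.0)
  nested <- parse_dotbracket("(((...)))")
  expect_equal(crossed_pair_quality_score(
    nested, shape_profile(rep(.1, 9), TRUE)), 0.0)
  # 4 of the 8 crossing residues reactive -> 50
  r <- rep(0.1, 14); r[c(1, 2, 5, 6)] <- 0.9
  expect_equal(crossed_pair_quality_score(pk, shape_profile(r, TRUE)), 50.0)
  expect_error(crossed_pair_quality_score(pk, all_protected,
                                          flank_weight = 1.5), "flank_weight")
})

test_that("singlets are removed before crossing analysis", {
  # one stacked crossing family plus an isolated crossing pair
  pairs <- rbind(c(0, 10), c(1, 9), c(5, 15), c(6, 14), c(3, 20))
  s <- secondary_structure(pairs, 22)
  r <- rep(0.1, 22); r[4] <- 0.9    # the singlet residue is reactive
  # singlet (3,20) dropped: its reactive residue must not lower the score
  expect_equal(crossed_pair_quality_score(s, shape_profile(r, TRUE)), 100.0)
})

test_that("flank-partnered residues are downweighted", {
  pk <- secondary_structure(rbind(c(0, 9), c(1, 8), c(4, 13), c(5, 12)), 14)
  r <- rep(0.1, 14)
  r[1] <- 0.9                       # position 0 (partner 9) inconsistent
  # no flank: 7 of 8 consistent
  expect_equal(crossed_pair_quality_score(pk, shape_profile(r, TRUE)),
               100 * 7 / 8)
  # flank covering partners 8..9 downweights positions 0 and 1 (and the
  # residues 8, 9 themselves partner 1, 0 - not in flank)
  got <- crossed_pair_quality_score(pk, shape_profile(r, TRUE),
                                    flank = list(c(8, 9)), flank_weight = 0.5)
  # weights: pos0 .5 (bad), pos1 .5, others 1 -> (0.5 + 6) / 7
  expect_equal(got, 100 * 6.5 / 7)
})

test_that("openknot score is the mean of its two components", {
  pk <- secondary_structure(rbind(c(0, 9), c(1, 8), c(4, 13), c(5, 12)), 14)
  prof <- shape_profile(c(rep(.1, 10), .9, .9, .1, .1), TRUE)
  rep_ <- openknot_score(pk, prof)
  expect_equal(rep_$openknot,
               (rep_$eterna_classic + rep_$crossed_pair_quality) / 2)
  # all-consistent pseudoknot scores 100 overall
  allgood <- shape_profile(ifelse(is.na(pairing_partner(pk)), .9, .1), TRUE)
  full <- openknot_score(pk, allgood)
  expect_equal(full$eterna_classic, 100.0)
  expect_equal(full$crossed_pair_quality, 100.0)
  expect_equal(full$openknot, 100.0)
})

test_that("scores stay in range over random structure/profile fixtures", {
  set.seed(77)
  for (i in 1:1000) {
    s <- rand_structure(2000 + i)
    prof <- normalize_shape(shape_profile(runif(s$length, 0.01, 2)))
    ecs <- eterna_classic_score(s, prof)
    cpq <- crossed_pair_quality_score(s, prof)
    ok <- openknot_score(s, prof)$openknot
    expect_true(ecs >= 0 && ecs <= 100)
    expect_true(cpq >= 0 && cpq <= 100)
    expect_true(ok >= 0 && ok <= 100)
    jac <- jaccard_basepairs(s, s)
    expect_equal(jac, 1.0)
  }
})

test_that("raising one paired residue past 0.5 never raises the score", {
  st <- parse_dotbracket("((((....))))")
  base <- rep(0.3, 12)
  s0 <- eterna_classic_score(st, shape_profile(base, TRUE))
  for (v in c(0.50, 0.51, 0.7, 1.5)) {
    r <- base; r[1] <- v
    s1 <- eterna_classic_score(st, shape_profile(r, TRUE))
    expect_lte(s1, s0)
  }
})
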