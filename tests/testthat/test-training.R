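test_that("valid actions enforce canonical pairing with decoded partners", {
  target <- design_target("((....))")
  # partner of position 7 is 0; decoded G allows C or U
  m <- valid_actions(target, 7L, "GGAAAAC")
  expect_equal(names(which(m)), c("C", "U"))
  # partner decoded as A allows only U
  m <- valid_actions(target, 7L, "AGAAAAC")
  expect_equal(names(which(m)), "U")
  # unpaired position: all four allowed
  expect_true(all(valid_actions(target, 2L, "AG")))
  # left half of a pair (partner not yet decoded): unconstrained
  expect_true(all(valid_actions(target, 0L, "")))
  # full canonical-complement table
  expected <- list(A = "U", C = "G", G = c("C", "U"), U = c("A", "G"))
  for (b in names(expected)) {
    seq7 <- paste0(b, "GAAAAC")
    m <- valid_actions(target, 7L, seq7)
    expect_equal(names(which(m)), expected[[b]], label = b)
  }
})

test_that("reward reweighting applies the exponential of the mean", {
  expect_equal(reweight_rewards(c(1, 1, 1)), rep(exp(1), 3),
               tolerance = 1e-9)
  expect_equal(reweight_rewards(c(0, 0, 0, 0)), rep(0, 4))
  r <- reweight_rewards(c(1, 0, 1, 0))
  expect_equal(r, c(exp(0.5), 0, exp(0.5), 0), tolerance = 1e-9)
  expect_error(reweight_rewards(numeric(0)), "empty")
  # zero pattern is invariant
  set.seed(3)
  for (i in 1:20) {
    v <- rbinom(12, 1, 0.5)
    expect_equal(reweight_rewards(v) == 0, v == 0)
  }
})

test_that("discount schedule decays linearly between its endpoints", {
  g <- discount_schedule(11, 0.95, 0.5)
  expect_equal(g[1], 0.95, tolerance = 1e-9)
  expect_equal(g[11], 0.5, tolerance = 1e-9)
  expect_equal(g[6], 0.725, tolerance = 1e-9)   # t = 5
  expect_equal(diff(g), rep(-0.045, 10), tolerance = 1e-9)
  expect_equal(discount_schedule(1, 0.9, 0.4), 0.9)
})

test_that("TD targets combine reward, discount and shifted next maxima", {
  got <- td_targets(c(1, 0, 1), c(0.5, 0.2, 0), rep(0.9, 3))
  expect_equal(got, c(1.45, 0.18, 1.0), tolerance = 1e-9)
  expect_equal(td_targets(rep(0, 4), rep(0, 4), rep(0.9, 4)), rep(0, 4))
  expect_error(td_targets(c(1, 0), c(0, 0, 0), c(0.9, 0.9)), "equal length")
})

test_that("the terminal TD target equals its reward", {
  set.seed(8)
  net <- tiny_qnet(1)
  frozen <- tiny_qnet(2)
  ep <- list(target = design_target(make_hairpin(2, 4)),
             sequence = "GGAAAACC", rewards = rbinom(8, 1, .5))
  nmx <- qrnadesign:::qn_frozen_next_max(frozen, ep)
  expect_equal(nmx[8], 0)
  rw <- reweight_rewards(ep$rewards)
  tq <- td_targets(rw, nmx, discount_schedule(8, 0.95, 0.5))
  expect_equal(tq[8], rw[8])
})

test_that("play is deterministic at epsilon 0 and reproducible otherwise", {
  net <- tiny_qnet(4)
  env <- nussinov_environment()
  targets <- make_hairpin_targets(4, 16, seed = 3)
  a <- play_episodes(net, env, targets, epsilon = 0, seed = 1)
  b <- play_episodes(net, env, targets, epsilon = 0, seed = 99)
  expect_identical(lapply(a, `[[`, "sequence"), lapply(b, `[[`, "sequence"))
  c1 <- play_episodes(net, env, targets, epsilon = 1, seed = 5)
  c2 <- play_episodes(net, env, targets, epsilon = 1, seed = 5)
  expect_identical(lapply(c1, `[[`, "sequence"), lapply(c2, `[[`, "sequence"))
  c3 <- play_episodes(net, env, targets, epsilon = 1, seed = 6)
  expect_false(identical(lapply(c1, `[[`, "sequence"),
                         lapply(c3, `[[`, "sequence")))
  expect_equal(attr(a, "mean_reward"),
               mean(vapply(a, function(r) mean(r$rewards), numeric(1))))
})

test_that("forcing the solving sequence yields an all-ones reward vector", {
  net <- tiny_qnet(9)
  env <- nussinov_environment()
  fd <- make_fold_derived_targets(5, 24, seed = 21)
  for (f in fd) {
    target <- design_target(f$structure)
    codes <- qrnadesign:::seq_to_codes(f$sequence)
    dec <- qrnadesign:::decode_sequence(net, target, force = codes)
    expect_equal(dec$sequence, f$sequence)
    r <- compute_rewards(env_fold(env, dec$sequence), target$structure)
    expect_equal(r, rep(1, target$structure$length))
  }
})

test_that("training on a frozen batch drives the loss down", {
  net <- tiny_qnet(31)
  frozen <- tiny_qnet(31)
  sync_target(net, frozen)
  env <- nussinov_environment()
  targets <- make_hairpin_targets(6, 16, seed = 13)
  eps <- play_episodes(net, env, targets, epsilon = 0.3, seed = 2)
  tc <- training_config(learning_rate = 3e-3, batch_size = 3, seed = 1)
  first <- train_epoch(net, frozen, eps, tc)
  last <- NA
  for (i in 1:50) last <- train_epoch(net, frozen, eps, tc)
  expect_lt(last, first)
  expect_error(train_epoch(net, frozen, list(), tc), "no episodes")
})

test_that("a hand-built L=3 episode reproduces the TD-target arithmetic", {
  # reward [1,0,1], constant frozen grid, check the loss reproduces the
  # composition reweight -> shift -> discount -> squared error
  net <- tiny_qnet(41, conv_kernel = 1L)
  frozen <- tiny_qnet(42, conv_kernel = 1L)
  st <- secondary_structure(matrix(integer(0), 0, 2), 3)
  ep <- list(target = design_target(st), sequence = "ACG",
             rewards = c(1, 0, 1))
  nmx <- qrnadesign:::qn_frozen_next_max(frozen, ep)
  gam <- discount_schedule(3, 0.9, 0.9)
  tq <- td_targets(reweight_rewards(ep$rewards), nmx, gam)
  manual <- reweight_rewards(c(1, 0, 1)) + 0.9 * nmx
  expect_equal(tq, manual, tolerance = 1e-6)
  res <- qrnadesign:::qn_episode_loss_grads(net, ep, tq)
  ctx <- qnet_encode(net, st)
  grid <- qnet_decode_full(net, c(5L, 1L, 2L), c(0L, 0L, 0L), ctx)
  sel <- grid[cbind(1:3, c(1L, 2L, 3L))]
  expect_equal(res$loss, mean((sel - tq)^2), tolerance = 1e-6)
})

test_that("target-network sync copies parameters and is idempotent", {
  net <- tiny_qnet(51)
  frozen <- tiny_qnet(52)
  st <- make_hairpin(3, 4)
  ctx_n <- qnet_encode(net, st)
  ctx_f <- qnet_encode(frozen, st)
  expect_gt(max(abs(ctx_n - ctx_f)), 0)   # different before sync
  sync_target(net, frozen)
  expect_identical(frozen$params, net$params)
  expect_equal(qnet_encode(frozen, st), ctx_n)
  sync_target(net, frozen)
  expect_identical(frozen$params, net$params)
  other <- tiny_qnet(1, embed_dim = 8L)
  expect_error(sync_target(net, other), "do not match")
})

test_that("experience files round-trip", {
  net <- tiny_qnet(61)
  env <- nussinov_environment()
  targets <- make_hairpin_targets(3, 14, seed = 8)
  eps <- play_episodes(net, env, targets, epsilon = 0.2, seed = 4)
  path <- tempfile(fileext = ".tsv")
  write_episodes(eps, path)
  back <- read_episodes(path)
  expect_equal(length(back), length(eps))
  for (i in seq_along(eps)) {
    expect_equal(back[[i]]$sequence, eps[[i]]$sequence)
    expect_equal(back[[i]]$rewards, eps[[i]]$rewards)
    expect_true(same_structure(back[[i]]$target$structure,
                               eps[[i]]$target$structure))
  }
  write_episodes(eps[1], path, append = TRUE)
  expect_equal(length(read_episodes(path)), length(eps) + 1L)
})
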