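test_that("firing rate implements divisive normalization with the zero convention", {
  V0 <- matrix(0, 4, 5)
  expect_equal(firing_rate(V0, 0.5)$r, V0)
  expect_equal(firing_rate(V0, 0.5)$s_inh, 0)

  V1 <- matrix(0, 4, 5); V1[2, 3] <- 5
  fr <- firing_rate(V1, 0.5)
  expect_equal(fr$r[2, 3], 2)          # 25 / (0.5 * 25); single neuron r = 1/k
  expect_equal(sum(fr$r != 0), 1)

  # sum(r) = 1/k for any non-zero V
  set.seed(4)
  for (k in c(0.2, 0.5, 3)) {
    V <- matrix(rexp(30), 5, 6)
    expect_equal(sum(firing_rate(V, k)$r), 1 / k, tolerance = 1e-9)
  }
})

test_that("potential update convolves, adds stimulus, and clips at zero", {
  grid <- grid_spec(8, 8)
  st <- build_interaction_kernel(grid, kernel_spec(1, 1.5, 5))
  z <- matrix(0, 8, 8)
  expect_equal(update_potential(z, z, st, 10), z)

  neg <- z; neg[3, 3] <- -3
  expect_equal(update_potential(z, neg, st, 10), z)  # ReLU clips

  # uniform rates on the torus give a uniform potential beta * c * sum(stencil)
  r <- matrix(0.2, 8, 8)
  V <- update_potential(r, z, st, beta = 4)
  expect_equal(V, matrix(4 * 0.2 * sum(st), 8, 8), ignore_attr = TRUE)

  expect_error(update_potential(r, matrix(0, 3, 3), st, 1), "shape")
})

test_that("a formed bump persists and a stimulus seeds one", {
  grid <- grid_spec(30, 30)
  params <- test_params(1)
  st <- build_interaction_kernel(grid, test_kernel())
  state <- init_bump_state(grid, c(12, 17), params, st)
  z <- matrix(0, 30, 30)
  for (i in 1:15) state <- cann_step(state, z, params, st)
  expect_equal(predict_location(state$r), c(12L, 17L))

  seed <- matrix(0, 30, 30); seed[7, 9] <- 5
  st2 <- cann_step(zero_state(grid), seed, params, st)
  expect_equal(predict_location(st2$r), c(7L, 9L))
})

test_that("trajectories depend on beta and k only through their ratio", {
  fx <- tracking_fixture(n_frames = 4, n_iter = 5)
  p1 <- fx$params
  p2 <- dynamics_params(10 * p1$beta, 10 * p1$k, p1$n_iter)
  s1 <- init_bump_state(fx$grid, c(15, 28), p1, fx$stencil)
  s2 <- init_bump_state(fx$grid, c(15, 28), p2, fx$stencil)
  locs1 <- locs2 <- list()
  for (t in seq_along(fx$stimuli)) {
    for (i in seq_len(p1$n_iter)) {
      s1 <- cann_step(s1, fx$stimuli[[t]], p1, fx$stencil)
      s2 <- cann_step(s2, fx$stimuli[[t]], p2, fx$stencil)
      expect_equal(s1$V, s2$V, tolerance = 1e-9)
      expect_equal(s1$r, 10 * s2$r, tolerance = 1e-9)
      locs1[[length(locs1) + 1]] <- predict_location(s1$r)
      locs2[[length(locs2) + 1]] <- predict_location(s2$r)
    }
  }
  expect_identical(locs1, locs2)  # argmax sequence is bit-identical
})

test_that("state trajectory is equivariant to cyclic stimulus shifts", {
  fx <- tracking_fixture(n_frames = 4, n_iter = 5)
  dr <- 7L; dc <- 13L
  H <- fx$grid$height; W <- fx$grid$width
  roll <- function(m) m[((seq_len(H) - 1 - dr) %% H) + 1,
                        ((seq_len(W) - 1 - dc) %% W) + 1]
  s1 <- fx$init
  s2 <- cann_state(roll(fx$init$V), roll(fx$init$r), fx$init$s_inh)
  for (t in seq_along(fx$stimuli)) {
    s1 <- run_frame(s1, fx$stimuli[[t]], fx$params, fx$stencil)
    s2 <- run_frame(s2, roll(fx$stimuli[[t]]), fx$params, fx$stencil)
    expect_equal(roll(s1$V), s2$V, tolerance = 1e-9)
    l1 <- predict_location(s1$r); l2 <- predict_location(s2$r)
    expect_equal(((l1[1] - 1 + dr) %% H) + 1, l2[1])
    expect_equal(((l1[2] - 1 + dc) %% W) + 1, l2[2])
  }
})

test_that("run_frame iterates the step and settles on a blob", {
  fx <- tracking_fixture(n_frames = 3)
  s0 <- fx$init
  expect_identical(run_frame(s0, fx$stimuli[[1]],
                             dynamics_params(50, 0.5, 0), fx$stencil), s0)

  # bump persistence: 15 driven iterations then 15 zero-stimulus iterations
  s <- run_frame(s0, fx$stimuli[[1]], fx$params, fx$stencil)
  loc_driven <- predict_location(s$r)
  s <- run_frame(s, matrix(0, 30, 56), fx$params, fx$stencil)
  expect_equal(predict_location(s$r), loc_driven)
})

test_that("bump follows a moving point stimulus with bounded lag", {
  grid <- grid_spec(30, 56)
  params <- test_params(15)
  st <- build_interaction_kernel(grid, test_kernel())
  state <- init_bump_state(grid, c(15, 10), params, st)
  for (t in 0:15) {
    stim <- matrix(0, 30, 56); stim[15, 10 + t] <- 2
    state <- run_frame(state, stim, params, st)
    loc <- predict_location(state$r)
    expect_equal(loc[1], 15L)
    expect_lte(abs(loc[2] - (10 + t)), 3)
  }
})

test_that("argmax readout breaks ties row-major and handles degenerate fields", {
  r <- matrix(0, 10, 15); r[7, 12] <- 1
  expect_equal(predict_location(r), c(7L, 12L))

  r2 <- matrix(0, 6, 6); r2[3, 4] <- 1; r2[5, 1] <- 1
  expect_equal(predict_location(r2), c(3L, 4L))

  # cyclic shift moves the argmax by the same offset
  r3 <- matrix(runif(30), 5, 6)
  l <- predict_location(r3)
  shifted <- r3[c(5, 1:4), c(6, 1:5)]    # shift by (1, 1)
  ls <- predict_location(shifted)
  expect_equal(ls, c(l[1] %% 5 + 1L, l[2] %% 6 + 1L))

  z <- matrix(0, 9, 9)
  expect_equal(as.integer(predict_location(z, prev = c(2, 3))), c(2L, 3L))
  ctr <- predict_location(z)
  expect_true(isTRUE(attr(ctr, "degenerate")))
  expect_equal(as.integer(ctr), c(5L, 5L))
})

test_that("the fixed-scale tracker follows static and moving synthetic objects", {
  # static object: predictions stay within 2 native pixels of ground truth
  grid <- test_grid(); params <- test_params()
  st <- build_interaction_kernel(grid, test_kernel())
  cfg <- synthetic_scene_config(120, 224, n_frames = 8, speed = c(0, 0),
                                start = c(58, 110), noise_sd = 2, seed = 5)
  v <- generate_synthetic_video(cfg)
  rs <- resize_to_grid(v$frames, grid)
  stim <- difference_frames(rs, gain = 0.02)
  traj <- track_sequence(stim, as.numeric(v$gt[1, ]), params, st, attr(rs, "scale"))
  ce <- center_error(traj[, 1:4], v$gt)
  expect_lt(max(ce$delta), 2)

  # zero stimuli: the bump (and the box) never moves
  zstim <- replicate(5, matrix(0, 30, 56), simplify = FALSE)
  traj0 <- track_sequence(zstim, c(104, 52, 16, 16), params, st, c(4, 4))
  expect_equal(length(unique(traj0$row)), 1)
  expect_equal(length(unique(traj0$col)), 1)

  expect_error(track_sequence(list(), c(0, 0, 5, 5), params, st), "empty")

  # circular motion: mean centre error below the object radius
  cfg2 <- synthetic_scene_config(120, 224, n_frames = 25, trajectory = "sine",
                                 speed = c(0, 2.5), noise_sd = 4, seed = 9)
  v2 <- generate_synthetic_video(cfg2)
  rs2 <- resize_to_grid(v2$frames, grid)
  stim2 <- difference_frames(rs2, gain = 0.02)
  traj2 <- track_sequence(stim2, as.numeric(v2$gt[1, ]), params, st, attr(rs2, "scale"))
  ce2 <- center_error(traj2[, 1:4], v2$gt)
  expect_lt(ce2$mean, cfg2$object_size / 2)
})
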