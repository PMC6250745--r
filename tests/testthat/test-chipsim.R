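# direct unit-level checks of the core operation semantics
test_that("dendrite operations follow the table semantics", {
  spec <- fixed_point_spec()
  vmm <- list(id = 1L, dendrite = "VMM", weights = diag(4))
  expect_equal(exec_dendrite(vmm, list(x = c(1, -2, 3, 4)), spec), c(1, -2, 3, 4))

  vva <- list(id = 2L, dendrite = "VVA")
  expect_equal(exec_dendrite(vva, list(a = c(1, 2), b = c(3, 4)), spec), c(4, 6))

  vs <- list(id = 3L, dendrite = "VS")
  expect_equal(exec_dendrite(vs, list(scalar = 3, x = c(1, -2)), spec), c(3, -6))

  vvm <- list(id = 4L, dendrite = "VVM")
  expect_equal(exec_dendrite(vvm, list(x1 = c(2, 3), x2 = c(4, 5)), spec), c(8, 15))
  expect_error(exec_dendrite(vvm, list(x1 = 1, x2 = 2, x3 = 3), spec), "exactly 2")

  too_many <- stats::setNames(rep(list(1), 129), paste0("v", 1:129))
  expect_error(exec_dendrite(vva, too_many, spec), "128")

  vb <- list(id = 5L, dendrite = "VB")
  expect_equal(exec_dendrite(vb, list(x = c(9, 9)), spec), c(9, 9))
})

test_that("the soma truncates, looks up, and laterally accumulates", {
  spec <- fixed_point_spec()
  ident <- canntrack:::.linear_lut(spec, 0, 1)
  cfg <- list(lat_acc = FALSE, shift = 0L, lut = ident)
  expect_equal(exec_soma(cfg, c(5, -7, 100), spec), c(5, -7, 100))

  relu <- canntrack:::.linear_lut(spec, 0, 1, relu = TRUE)
  cfg_r <- list(lat_acc = FALSE, shift = 0L, lut = relu)
  expect_equal(exec_soma(cfg_r, c(-40, 12), spec), c(0, 12))

  cfg_acc <- list(lat_acc = TRUE, shift = 0L, lut = ident)
  expect_equal(exec_soma(cfg_acc, c(1, 2, 3), spec), 6)

  # no LUT: pure buffer passes the accumulator through
  expect_equal(exec_soma(list(lat_acc = FALSE, lut = NULL), c(3, 4), spec), c(3, 4))
})

test_that("routing delivers point-to-point and relays multicast chains", {
  pl <- plan_full_mapping(grid_spec(30, 56), test_kernel())
  fx <- tracking_fixture(n_frames = 2, n_iter = 2)
  calib <- calibrate_ranges(fx$stimuli, fx$init, fx$params, fx$stencil)
  chain <- solve_feedback_scaling(fixed_point_spec(), fx$params, fx$stencil,
                                  calib, groups = pl$col_slices)
  chip <- build_chip(pl, chain)
  bufs <- canntrack:::.init_bufs(chip)

  # AMC: one packet to a step-1 chain head lands in all 3 chain members
  head <- chip$step1_heads[4]
  members <- chip$chains[[4]]
  b2 <- route(list(list(dest = head, slot = "x", pos = 1:3,
                        values = c(7, 8, 9), amc = TRUE)), chip, bufs)
  for (m in members) expect_equal(b2[[m]]$x[1:3], c(7, 8, 9))
  expect_length(members, 3)

  # plain P2P writes exactly one core
  tgt <- chip$placement$cores$id[chip$placement$cores$step == "4-2"][1]
  b3 <- route(list(list(dest = tgt, slot = "x", pos = 2, values = 5, amc = FALSE)),
              chip, bufs)
  expect_equal(b3[[tgt]]$x[2], 5)
  expect_equal(sum(vapply(b3, function(s) sum(unlist(s) != 0), numeric(1))), 1)

  # a core outside any chain behaves as plain P2P even when marked amc
  b4 <- route(list(list(dest = tgt, slot = "x", pos = 1, values = 1, amc = TRUE)),
              chip, bufs)
  expect_equal(b4[[tgt]]$x[1], 1)

  # collisions and capacity overruns are errors
  expect_error(route(list(
    list(dest = tgt, slot = "x", pos = 1, values = 1, amc = FALSE),
    list(dest = tgt, slot = "x", pos = 1, values = 2, amc = FALSE)), chip, bufs),
    "collision")
  expect_error(route(list(list(dest = tgt, slot = "x", pos = 10000, values = 1,
                               amc = FALSE)), chip, bufs), "capacity")
})

test_that("the mapped network is bit-exact against the direct integer pipeline", {
  for (dims in list(c(16, 16, 5), c(20, 28, 15))) {
    grid <- grid_spec(dims[1], dims[2])
    kernel <- kernel_spec(1, 2, dims[3])
    st <- build_interaction_kernel(grid, kernel)
    params <- test_params(5)
    cfg <- synthetic_scene_config(dims[1] * 4, dims[2] * 4, n_frames = 4,
                                  object_size = 8, speed = c(1, 2),
                                  noise_sd = 3, seed = 2)
    v <- generate_synthetic_video(cfg)
    rs <- resize_to_grid(v$frames, grid)
    stim <- difference_frames(rs, gain = 0.02)
    init <- init_bump_state(grid, c(dims[1] / 2, dims[2] / 2), params, st)
    calib <- calibrate_ranges(stim, init, params, st)
    pl <- plan_full_mapping(grid, kernel)
    chain <- solve_feedback_scaling(fixed_point_spec(), params, st, calib,
                                    groups = pl$col_slices)
    r0 <- quantize_array(init$r, chain$rho_r, 8L)
    ref <- run_quantized(stim, r0, chain, params$n_iter)
    chip <- build_chip(pl, chain)
    mapped <- run_mapped_network(chip, stim, r0, params$n_iter)
    for (i in seq_along(ref$r_iters)) {
      expect_identical(mapped$r_iters[[i]], ref$r_iters[[i]])
    }
    # phase accounting: 5 phases per iteration
    expect_equal(mapped$phases, 5 * params$n_iter * length(stim))
  }
})

test_that("zero state and stimuli produce zero activity in every phase", {
  grid <- grid_spec(16, 16)
  kernel <- kernel_spec(1, 1.5, 5)
  st <- build_interaction_kernel(grid, kernel)
  params <- test_params(3)
  calib <- list(V1 = 1, stim = 1, V = 1, V2 = 1, S = 1, s = 1, r = 1)
  pl <- plan_full_mapping(grid, kernel)
  chain <- solve_feedback_scaling(fixed_point_spec(), params, st, calib,
                                  groups = pl$col_slices)
  chip <- build_chip(pl, chain)
  z <- matrix(0, 16, 16)
  out <- run_mapped_network(chip, list(z, z), z, params$n_iter, trace = TRUE)
  for (rr in out$r_iters) expect_equal(rr, z)
  expect_true(all(out$trace$checksum == 0))
})

test_that("an invalid placement is rejected at chip build time", {
  pl <- plan_full_mapping(grid_spec(30, 56), test_kernel())
  fx <- tracking_fixture(n_frames = 2, n_iter = 2)
  calib <- calibrate_ranges(fx$stimuli, fx$init, fx$params, fx$stencil)
  chain <- solve_feedback_scaling(fixed_point_spec(), fx$params, fx$stencil,
                                  calib, groups = pl$col_slices)
  bad <- pl; bad$cores$fan_in[1] <- 300L
  expect_error(build_chip(bad, chain), "violates core constraints")
})
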