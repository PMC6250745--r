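test_that("array quantization rounds half away from zero and saturates", {
  expect_equal(as.numeric(quantize_array(200, 1, 8)), 127)
  expect_equal(as.numeric(quantize_array(-300, 1, 8)), -128)
  expect_equal(as.numeric(quantize_array(17, 1, 8)), 17)
  expect_equal(as.numeric(quantize_array(0.005, 100, 8)), 1)   # round(0.5) -> 1
  expect_equal(as.numeric(quantize_array(-0.005, 100, 8)), -1)
  q <- quantize_array(c(200, 1, -500), 1, 8)
  expect_equal(attr(q, "saturated"), 2)
  expect_error(quantize_array(1, 0, 8), "rho")
})

test_that("the scaling chain rule propagates product and sum stages", {
  expect_equal(propagate_scaling(4, 8, 2, "multiply"), 16)
  expect_equal(propagate_scaling(1, 1, 1, "multiply"), 1)
  expect_equal(propagate_scaling(6, 6, 3, "add"), 2)
  expect_error(propagate_scaling(2, 3, 1, "add"), "same scale")
})

test_that("the solved chain closes the recurrent loop exactly", {
  fx <- tracking_fixture(n_frames = 5, n_iter = 15)
  calib <- calibrate_ranges(fx$stimuli, fx$init, fx$params, fx$stencil)
  for (io in c(8L, 12L)) {
    chain <- solve_feedback_scaling(fixed_point_spec(io), fx$params,
                                    fx$stencil, calib)
    expect_equal(chain_loop_scale(chain), chain$rho_r, tolerance = 1e-12)
  }
  # weights use the full signed I/O range
  chain8 <- solve_feedback_scaling(fixed_point_spec(), fx$params, fx$stencil, calib)
  expect_equal(max(abs(chain8$w_int)), 127)
})

test_that("doubling a calibrated accumulator range inserts exactly one extra shift", {
  fx <- tracking_fixture(n_frames = 5, n_iter = 15)
  calib <- calibrate_ranges(fx$stimuli, fx$init, fx$params, fx$stencil)
  calib2 <- calib; calib2$V1 <- 2 * calib$V1
  c1 <- solve_feedback_scaling(fixed_point_spec(), fx$params, fx$stencil, calib)
  c2 <- solve_feedback_scaling(fixed_point_spec(), fx$params, fx$stencil, calib2)
  expect_equal(c2$shifts[["step1"]], c1$shifts[["step1"]] + 1)
})

test_that("the inhibition LUT is the clipped reciprocal with a zero origin", {
  spec <- fixed_point_spec()
  lut <- build_inhibition_lut(k = 0.5, rho_sum = 2, rho_s = 100, spec)
  v <- lut$values
  expect_length(v, 1024)
  expect_equal(v[1], 0)                      # entry[0]: zero-activity convention
  expect_true(all(diff(v[-1]) <= 0))         # non-increasing for i >= 1
  expect_equal(v[2], 127)                    # small sums saturate at the output clip
  # a mid-table entry matches the direct formula
  i <- 500
  expect_equal(v[i + 1], min(127, round(100 * 2 / (0.5 * i))))
})

test_that("a quantized iteration tracks the float iteration to LSB accuracy", {
  fx <- tracking_fixture(n_frames = 3, n_iter = 15)
  calib <- calibrate_ranges(fx$stimuli, fx$init, fx$params, fx$stencil)
  spec <- fixed_point_spec()
  chain <- solve_feedback_scaling(spec, fx$params, fx$stencil, calib)
  r_int <- quantize_array(fx$init$r, chain$rho_r, spec$io_bits)
  stim_int <- quantize_array(fx$stimuli[[1]], chain$rho_ext, spec$io_bits)

  out <- quantized_step(r_int, stim_int, chain)
  flt <- cann_step(fx$init, fx$stimuli[[1]], fx$params, fx$stencil)

  # de-quantized potential within a few LSBs of the float potential
  expect_lt(max(abs(out$V / chain$rho_V - flt$V)), 4 / chain$rho_V)
  expect_lt(max(abs(out$r / chain$rho_r - flt$r)), 4 / chain$rho_r)
  # zero state and stimulus stay zero
  z <- matrix(0, 30, 56)
  out0 <- quantized_step(z, z, chain)
  expect_equal(out0$r, z)
})

test_that("integer rates neither explode nor vanish over 200 free iterations", {
  fx <- tracking_fixture(n_frames = 3, n_iter = 15)
  calib <- calibrate_ranges(fx$stimuli, fx$init, fx$params, fx$stencil)
  spec <- fixed_point_spec()
  chain <- solve_feedback_scaling(spec, fx$params, fx$stencil, calib)
  r <- quantize_array(fx$init$r, chain$rho_r, spec$io_bits)
  z <- matrix(0, 30, 56)
  for (i in 1:15) r <- quantized_step(r, z, chain)$r  # let the bump form
  sum0 <- sum(abs(r))
  for (i in 1:200) r <- quantized_step(r, z, chain)$r
  expect_gte(sum(abs(r)), 0.5 * sum0)
  expect_lte(sum(abs(r)), 2 * sum0)
})

test_that("the integer/float ratio stays bounded and a broken chain drifts", {
  fx <- tracking_fixture(n_frames = 10, n_iter = 15)
  calib <- calibrate_ranges(fx$stimuli, fx$init, fx$params, fx$stencil)
  spec <- fixed_point_spec()
  chain <- solve_feedback_scaling(spec, fx$params, fx$stencil, calib)
  r0 <- quantize_array(fx$init$r, chain$rho_r, spec$io_bits)
  qt <- run_quantized(fx$stimuli, r0, chain, fx$params$n_iter)
  s <- fx$init; r_float <- list()
  for (t in seq_along(fx$stimuli)) {
    for (i in seq_len(fx$params$n_iter)) {
      s <- cann_step(s, fx$stimuli[[t]], fx$params, fx$stencil)
      r_float[[length(r_float) + 1]] <- s$r
    }
  }
  tr <- trace_scaling_ratio(r_float, qt$r_iters, chain)
  expect_lt(tr$max_dev, 0.2)    # fluctuation, not drift

  # negative control: halving the step-5 truncation scale doubles the output
  # scale each pass until the datapath saturates at its rails
  broken <- chain
  broken$shifts[["step5"]] <- broken$shifts[["step5"]] - 1L
  qb <- run_quantized(fx$stimuli[1], r0, broken, fx$params$n_iter)
  trb <- trace_scaling_ratio(r_float[1:15], qb$r_iters, chain)
  expect_gt(max(trb$ratio, na.rm = TRUE), 3)
})

test_that("widening the I/O width never increases the rate error", {
  fx <- tracking_fixture(n_frames = 5, n_iter = 15)
  calib <- calibrate_ranges(fx$stimuli, fx$init, fx$params, fx$stencil)
  s <- fx$init; r_float <- list()
  for (t in seq_along(fx$stimuli)) {
    for (i in seq_len(fx$params$n_iter)) {
      s <- cann_step(s, fx$stimuli[[t]], fx$params, fx$stencil)
      r_float[[length(r_float) + 1]] <- s$r
    }
  }
  err <- vapply(c(8L, 12L, 16L), function(io) {
    spec <- fixed_point_spec(io)
    chain <- solve_feedback_scaling(spec, fx$params, fx$stencil, calib)
    r0 <- quantize_array(fx$init$r, chain$rho_r, spec$io_bits)
    qt <- run_quantized(fx$stimuli, r0, chain, fx$params$n_iter)
    mean(vapply(seq_along(r_float), function(i)
      mean(abs(qt$r_iters[[i]] / chain$rho_r - r_float[[i]])), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(err) <= 1e-12))
})

test_that("the chain JSON sidecar round-trips losslessly", {
  fx <- tracking_fixture(n_frames = 3, n_iter = 5)
  calib <- calibrate_ranges(fx$stimuli, fx$init, fx$params, fx$stencil)
  spec <- fixed_point_spec()
  groups <- plan_full_mapping(fx$grid, fx$kernel)$col_slices
  chain <- solve_feedback_scaling(spec, fx$params, fx$stencil, calib,
                                  groups = groups)
  path <- withr::local_tempfile(fileext = ".json")
  write_chain_json(chain, path)
  back <- read_chain_json(path)
  expect_equal(back$rho_r, chain$rho_r)
  expect_equal(back$shifts, chain$shifts)
  expect_equal(unname(back$w_int), unname(chain$w_int), ignore_attr = TRUE)
  expect_equal(back$luts$step4$values, chain$luts$step4$values)
  # an identical integer step results from the reloaded chain
  r_int <- quantize_array(fx$init$r, chain$rho_r, spec$io_bits)
  stim_int <- quantize_array(fx$stimuli[[1]], chain$rho_ext, spec$io_bits)
  expect_identical(quantized_step(r_int, stim_int, back)$r,
                   quantized_step(r_int, stim_int, chain)$r)
})
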