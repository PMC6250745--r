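# Shared fixtures: the small study network, synthetic scenes, and the
# brute-force interaction oracle.

test_grid <- function() grid_spec(30, 56)
test_kernel <- function(R = 15) kernel_spec(J0 = 1, a = 2, R = R)
test_params <- function(n_iter = 15) dynamics_params(beta = 50, k = 0.5, n_iter = n_iter)

# stimuli + initialized state on the 30x56 network from a synthetic scene
tracking_fixture <- function(n_frames = 10, seed = 1, speed = c(0.5, 3),
                             noise_sd = 4, n_iter = 15,
                             trajectory = "linear") {
  grid <- test_grid(); kernel <- test_kernel()
  params <- test_params(n_iter)
  stencil <- build_interaction_kernel(grid, kernel)
  cfg <- synthetic_scene_config(height = 120, width = 224, n_frames = n_frames,
                                trajectory = trajectory, speed = speed,
                                noise_sd = noise_sd, seed = seed)
  video <- generate_synthetic_video(cfg)
  resized <- resize_to_grid(video$frames, grid)
  stimuli <- difference_frames(resized, gain = 0.02)
  gt1 <- as.numeric(video$gt[1, c("x", "y", "w", "h")])
  scale <- attr(resized, "scale")
  c_grid <- map_coords(c(gt1[2] + gt1[4] / 2, gt1[1] + gt1[3] / 2), scale, "grid")
  init <- init_bump_state(grid, c_grid + 1, params, stencil)
  list(grid = grid, kernel = kernel, params = params, stencil = stencil,
       video = video, stimuli = stimuli, init = init, scale = scale)
}

# the synthetic benchmark: three motion patterns, fixed seeds
benchmark_battery <- function(n_frames = 70) {
  list(
    linear = synthetic_scene_config(120, 224, n_frames = n_frames,
                                    trajectory = "linear", speed = c(0.5, 3),
                                    noise_sd = 4, seed = 1),
    sine = synthetic_scene_config(120, 224, n_frames = n_frames,
                                  trajectory = "sine", speed = c(0, 2.5),
                                  noise_sd = 4, seed = 2),
    walk = synthetic_scene_config(120, 224, n_frames = n_frames,
                                  trajectory = "random-walk", speed = c(2, 2),
                                  noise_sd = 4, seed = 3)
  )
}

# brute-force recurrent drive: explicit double loop over all neuron pairs
# with the toroidal Gaussian weights and the R x R connection-field cutoff
brute_recurrent <- function(r, grid, kernel, beta) {
  H <- grid$height; W <- grid$width
  half <- (kernel$R - 1) / 2
  peak <- kernel$J0 / (2 * pi * kernel$a^2)
  out <- matrix(0, H, W)
  for (r1 in seq_len(H)) for (c1 in seq_len(W)) {
    acc <- 0
    for (r2 in seq_len(H)) for (c2 in seq_len(W)) {
      drm <- min(abs(r2 - r1), H - abs(r2 - r1))
      dcm <- min(abs(c2 - c1), W - abs(c2 - c1))
      if (drm <= half && dcm <= half) {
        acc <- acc + peak * exp(-(drm^2 + dcm^2) / (2 * kernel$a^2)) * r[r2, c2]
      }
    }
    out[r1, c1] <- beta * acc
  }
  out
}

# ground-truth-echoing oracle tracker for protocol tests
oracle_tracker <- function(gt) {
  force(gt)
  function(frames, init_box) gt
}
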