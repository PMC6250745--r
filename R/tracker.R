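#' Build a CANN tracker function
#'
#' Returns a tracker closure `(frames, init_box) -> boxes` suitable for the
#' evaluation protocols. The backend is selected with `mode`:
#' \describe{
#'   \item{float}{the floating-point reference dynamics}
#'   \item{quantized}{the fixed-point five-step pipeline; the scaling chain
#'     is calibrated on a floating-point dry run of the same sequence}
#'   \item{mapped}{the behavioral many-core simulator executing the planned
#'     placement (bit-exact with `quantized`)}
#' }
#'
#' @param grid a [grid_spec()]
#' @param kernel a [kernel_spec()]
#' @param params a [dynamics_params()]
#' @param gain stimulus gain applied to frame differences (default 0.02 on
#'   0-255 intensities)
#' @param mode `"float"`, `"quantized"` or `"mapped"`
#' @param spec a [fixed_point_spec()] for the integer backends
#' @param constraints a [core_constraints()] for the mapped backend
#' @return tracker function; its result carries the backend name as
#'   attribute `mode`
#' @export
cann_tracker <- function(grid, kernel, params, gain = 0.02,
                         mode = c("float", "quantized", "mapped"),
                         spec = fixed_point_spec(),
                         constraints = core_constraints()) {
  mode <- match.arg(mode)
  stencil <- build_interaction_kernel(grid, kernel)
  function(frames, init_box) {
    rs <- resize_to_grid(frames, grid)
    scale <- attr(rs, "scale")
    stimuli <- difference_frames(rs, gain = gain)
    if (mode == "float") {
      out <- track_sequence(stimuli, init_box, params, stencil, scale)
      attr(out, "mode") <- mode
      return(out)
    }
    c_native <- c(init_box[2] + init_box[4] / 2, init_box[1] + init_box[3] / 2)
    init <- init_bump_state(grid, map_coords(c_native, scale, "grid") + 1,
                            params, stencil)
    calib <- calibrate_ranges(stimuli, init, params, stencil)
    if (mode == "quantized") {
      chain <- solve_feedback_scaling(spec, params, stencil, calib)
      r0 <- quantize_array(init$r, chain$rho_r, spec$io_bits)
      run <- run_quantized(stimuli, r0, chain, params$n_iter)
    } else {
      placement <- plan_full_mapping(grid, kernel, constraints)
      chain <- solve_feedback_scaling(spec, params, stencil, calib,
                                      groups = placement$col_slices)
      r0 <- quantize_array(init$r, chain$rho_r, spec$io_bits)
      chip <- build_chip(placement, chain)
      run <- run_mapped_network(chip, stimuli, r0, params$n_iter)
    }
    loc <- predict_location(init$r)
    out <- matrix(NA_real_, length(stimuli) + 1, 6)
    out[1, ] <- c(init_box, loc)
    for (t in seq_along(run$r_frames)) {
      loc <- predict_location(run$r_frames[[t]], prev = loc)
      p_native <- map_coords(as.numeric(loc) - 1, scale, "native")
      out[t + 1, ] <- c(p_native[2] - init_box[3] / 2,
                        p_native[1] - init_box[4] / 2,
                        init_box[3], init_box[4], loc)
    }
    res <- as.data.frame(out)
    names(res) <- c("x", "y", "w", "h", "row", "col")
    attr(res, "mode") <- mode
    res
  }
}
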