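#' Fixed-point format specification
#'
#' Bit widths of the integer datapath: `io_bits` for signed core inputs and
#' outputs (8 bits gives the range \[-128, 127\]), `accum_bits` for the
#' dendrite accumulator, `lut_in_bits` for the truncated accumulator fed to
#' the table lookup, and `lut_out_bits` for table outputs.
#'
#' @param io_bits signed I/O width (default 8)
#' @param lut_in_bits LUT index width (default `io_bits + 2`)
#' @param lut_out_bits LUT output width (default `io_bits`)
#' @param accum_bits accumulator width (default `max(24, 2*io_bits + 8)`)
#' @return an object of class `fixed_point_spec`
#' @export
fixed_point_spec <- function(io_bits = 8L,
                             lut_in_bits = io_bits + 2L,
                             lut_out_bits = io_bits,
                             accum_bits = max(24L, 2L * io_bits + 8L)) {
  if (!(io_bits <= lut_in_bits && lut_in_bits <= accum_bits)) {
    stop("fixed_point_spec: need io_bits <= lut_in_bits <= accum_bits", call. = FALSE)
  }
  structure(list(io_bits = as.integer(io_bits),
                 accum_bits = as.integer(accum_bits),
                 lut_in_bits = as.integer(lut_in_bits),
                 lut_out_bits = as.integer(lut_out_bits)),
            class = "fixed_point_spec")
}

# rounding: half away from zero (one rule fixed for reproducibility)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

.clip <- function(x, bits) {
  lo <- -2^(bits - 1); hi <- 2^(bits - 1) - 1
  pmin(pmax(x, lo), hi)
}

.sat_count <- function(x, bits) {
  lo <- -2^(bits - 1); hi <- 2^(bits - 1) - 1
  sum(x < lo | x > hi)
}

# arithmetic right shift (floor division by a power of two)
.rshift <- function(x, s) if (s == 0) x else floor(x / 2^s)

#' Quantize a real array to a signed integer grid
#'
#' Computes `clip(round(rho * x))` with rounding half away from zero and
#' clipping to the signed range of `bits`. Saturation is the defined
#' behaviour, not an error; the number of clipped entries is attached as
#' attribute `saturated`.
#'
#' @param x numeric vector/matrix
#' @param rho scaling factor (> 0)
#' @param bits signed integer width
#' @return integer-valued numeric array of the same shape
#' @export
quantize_array <- function(x, rho, bits = 8L) {
  if (rho <= 0) stop("quantize_array: rho must be > 0", call. = FALSE)
  y <- round_half_away(rho * x)
  out <- .clip(y, bits)
  attr(out, "saturated") <- .sat_count(y, bits)
  out
}

#' Propagate a scaling factor through one fixed-point stage
#'
#' The scaling chain rule: for a product stage the output scale is
#' `rho_x * rho_y / rho_F`; for a sum stage both addends must share a scale
#' `rho` and the output scale is `rho / rho_F`, where `rho_F` is the
#' equivalent scale of the truncation-plus-LUT of that stage.
#'
#' @param rho_x,rho_y input scales (for `add`, both must be equal)
#' @param rho_F equivalent truncation/LUT scale of the stage
#' @param op `"multiply"` or `"add"`
#' @return the output scale `rho_z`
#' @export
propagate_scaling <- function(rho_x, rho_y, rho_F, op = c("multiply", "add")) {
  op <- match.arg(op)
  if (op == "add") {
    if (!isTRUE(all.equal(rho_x, rho_y))) {
      stop("propagate_scaling: addends must share the same scale", call. = FALSE)
    }
    return(rho_x / rho_F)
  }
  rho_x * rho_y / rho_F
}


# shift needed so that |acc| * margin fits the LUT index range
.shift_for <- function(acc_max, idx_max, margin) {
  max(0L, as.integer(ceiling(log2(max(acc_max, 1) * margin / idx_max))))
}

#' Calibrate floating-point value ranges for quantization
#'
#' Runs the floating-point model over the calibration stimuli and records
#' the dynamic ranges of every signal of the five-step pipeline: the
#' recurrent drive, the stimulus, the membrane potential, its square, the
#' squared-potential sum, the inhibition factor and the firing rate. These
#' ranges drive the choice of scaling factors and right-shift amounts.
#'
#' @param stimuli list of stimulus matrices
#' @param init a `cann_state` to start from (typically [init_bump_state()])
#' @param params a [dynamics_params()]
#' @param stencil weight stencil
#' @return list of range statistics (maxima over the calibration run)
#' @export
calibrate_ranges <- function(stimuli, init, params, stencil) {
  st <- init
  mx <- list(V1 = 0, stim = 0, V = max(st$V), V2 = max(st$V)^2,
             S = sum(st$V^2), s = if (sum(st$V^2) > 0) st$s_inh else 0,
             r = max(st$r))
  for (stim in stimuli) {
    mx$stim <- max(mx$stim, max(abs(stim)))
    for (i in seq_len(params$n_iter)) {
      V1 <- recurrent_drive(st$r, stencil, params$beta)
      V <- pmax(V1 + stim, 0)
      fr <- firing_rate(V, params$k)
      st <- cann_state(V, fr$r, fr$s_inh)
      S <- sum(V^2)
      mx$V1 <- max(mx$V1, max(V1))
      mx$V <- max(mx$V, max(V))
      mx$V2 <- max(mx$V2, max(V)^2)
      mx$S <- max(mx$S, S)
      if (S > 0) mx$s <- max(mx$s, fr$s_inh)
      mx$r <- max(mx$r, max(fr$r))
    }
  }
  mx
}

#' Solve the feedback-constant scaling chain
#'
#' Chooses weight and signal scaling factors and per-step right-shifts so
#' that propagating the firing-rate scale `rho_r` through the five execution
#' steps returns exactly `rho_r` (the constant-scaling restriction on the
#' recurrent loop), and builds the step LUTs. Truncations are powers of two
#' (arithmetic right-shifts sized from the calibrated accumulator ranges);
#' signal scales are fitted exactly to the calibrated I/O ranges and the
#' non-power residual of each stage is folded into its LUT contents, so
#' per-step saturation on calibration-like data is rare and counted.
#'
#' @param spec a [fixed_point_spec()]
#' @param params a [dynamics_params()]
#' @param stencil float weight stencil from [build_interaction_kernel()]
#' @param calib range statistics from [calibrate_ranges()]
#' @param rho_r target firing-rate scale; default fits the calibrated peak
#'   rate to the I/O range
#' @param groups list of column-index vectors giving the per-slice
#'   decomposition of the step-1 VMM (default: a single group covering the
#'   whole grid); partial recurrent drives are truncated to I/O width per
#'   group exactly as on the mapped cores
#' @param io_margin head-room factor on I/O signal ranges (default 1:
#'   ranges fitted exactly to the calibration run; out-of-range values
#'   saturate and are counted)
#' @param acc_margin head-room factor on accumulator ranges (default 1.5)
#' @return an object of class `scaling_chain` holding the scales
#'   (`rho_J`, `rho_r`, `rho_V1`, `rho_V`, `rho_V2`, `rho_s`), the
#'   equivalent per-step truncation/LUT scales (`rho_F`), the right-shifts
#'   (`shifts`), the quantized weight stencil (`w_int`), the five LUTs and
#'   the slice decomposition
#' @export
solve_feedback_scaling <- function(spec, params, stencil, calib,
                                   rho_r = NULL, groups = NULL,
                                   io_margin = 1, acc_margin = 1.5) {
  io_max <- 2^(spec$io_bits - 1) - 1
  idx_max_s <- 2^(spec$lut_in_bits - 1) - 1   # signed LUT index range
  idx_max_u <- 2^spec$lut_in_bits - 1         # unsigned (non-negative sums)

  for (nm in c("V1", "V", "V2", "S", "s", "r")) {
    if (!is.finite(calib[[nm]]) || calib[[nm]] <= 0) {
      stop(sprintf("solve_feedback_scaling: degenerate calibration range for %s", nm),
           call. = FALSE)
    }
  }
  if (is.null(rho_r)) rho_r <- io_max / (calib$r * io_margin)
  rho_J <- io_max / (params$beta * max(stencil))
  w_int <- quantize_array(params$beta * stencil, rho_J, spec$io_bits)
  attributes(w_int) <- attributes(stencil)

  # step 1: VMM accumulator rho_J*rho_r, truncated+scaled to the shared
  # partial-potential/stimulus scale rho_V1
  rho_V1 <- io_max / (max(calib$V1, calib$stim, 1e-12) * io_margin)
  s1 <- .shift_for(rho_J * rho_r * calib$V1, idx_max_s, acc_margin)
  # step 2: VVA of partials + stimulus at rho_V1, ReLU LUT to rho_V
  rho_V <- io_max / (calib$V * io_margin)
  s2 <- .shift_for(rho_V1 * (calib$V1 + calib$stim), idx_max_s, acc_margin)
  # step 3: VVM square at rho_V^2, to rho_V2
  rho_V2 <- io_max / (calib$V2 * io_margin)
  s3 <- .shift_for((rho_V * calib$V)^2, idx_max_s, acc_margin)
  # step 4: VVA+Lat_Acc sum at rho_V2 (non-negative; unsigned index),
  # nonlinear 1/x LUT to rho_s
  rho_s <- io_max / (calib$s * io_margin)
  s4 <- .shift_for(rho_V2 * calib$S, idx_max_u, acc_margin)
  # step 5: VS product at rho_V2*rho_s, back to exactly rho_r
  s5 <- .shift_for(io_max^2, idx_max_s, 1)

  rho_F <- c(step1 = rho_J * rho_r / rho_V1,
             step2 = rho_V1 / rho_V,
             step3 = rho_V^2 / rho_V2,
             step4 = NA_real_,              # nonlinear stage, scale set by the LUT
             step5 = rho_V2 * rho_s / rho_r)
  shifts <- c(step1 = s1, step2 = s2, step3 = s3, step4 = s4, step5 = s5)

  luts <- list(
    step1 = .linear_lut(spec, s1, rho_F[["step1"]], relu = FALSE),
    step2 = .linear_lut(spec, s2, rho_F[["step2"]], relu = TRUE),
    step3 = .linear_lut(spec, s3, rho_F[["step3"]], relu = FALSE),
    step4 = build_inhibition_lut(params$k, rho_V2 / 2^s4, rho_s, spec),
    step5 = .linear_lut(spec, s5, rho_F[["step5"]], relu = FALSE)
  )

  if (is.null(groups)) groups <- "all"  # resolved to the full grid at use
  structure(list(spec = spec, params = list(beta = params$beta, k = params$k),
                 rho_J = rho_J, rho_r = rho_r, rho_V1 = rho_V1, rho_V = rho_V,
                 rho_V2 = rho_V2, rho_s = rho_s, rho_ext = rho_V1,
                 rho_F = rho_F, shifts = shifts, w_int = w_int,
                 luts = luts, groups = groups),
            class = "scaling_chain")
}

# linear LUT: index i (signed, post-shift) -> clip(round(i * 2^s / rho_F)),
# optionally ReLU-clipped at zero; stored over the full signed index range
.linear_lut <- function(spec, s, rho_F, relu = FALSE) {
  n <- 2^spec$lut_in_bits
  idx <- seq.int(-n / 2, n / 2 - 1)
  v <- idx * 2^s / rho_F
  if (relu) v <- pmax(v, 0)
  list(values = .clip(round_half_away(v), spec$lut_out_bits),
       signed = TRUE, offset = n / 2 + 1)
}

#' Build the inhibition-factor lookup table
#'
#' The nonlinear soma LUT that implements the division of the global
#' inhibition: an (unsigned) index `i` encodes the truncated
#' squared-potential sum `S = i / rho_sum`; the entry holds the quantized
#' inhibition factor `clip(round(rho_s / (k * S)))`. Entry 0 is defined as 0
#' (the zero-activity convention resolving the singular all-zero state).
#'
#' @param k global-inhibition strength
#' @param rho_sum scale of the truncated index (`rho_V2 / 2^shift`)
#' @param rho_s output scale of the inhibition factor
#' @param spec a [fixed_point_spec()]
#' @return LUT list with `values` (length `2^lut_in_bits`), `signed = FALSE`,
#'   `offset = 1`
#' @export
build_inhibition_lut <- function(k, rho_sum, rho_s, spec) {
  n <- 2^spec$lut_in_bits
  i <- seq_len(n - 1)
  v <- c(0, .clip(round_half_away(rho_s * rho_sum / (k * i)), spec$lut_out_bits))
  list(values = v, signed = FALSE, offset = 1)
}

# truncate an accumulator by `s` bits, clip to the LUT index range, and look
# up; returns values plus the number of saturated indices
.lut_apply <- function(acc, s, lut, spec) {
  idx <- .rshift(acc, s)
  if (lut$signed) {
    lo <- -2^(spec$lut_in_bits - 1); hi <- 2^(spec$lut_in_bits - 1) - 1
  } else {
    lo <- 0; hi <- 2^spec$lut_in_bits - 1
  }
  sat <- sum(idx < lo | idx > hi)
  idx <- pmin(pmax(idx, lo), hi)
  out <- lut$values[idx + lut$offset]
  if (is.matrix(acc)) out <- matrix(out, nrow(acc), ncol(acc))
  attr(out, "saturated") <- sat
  out
}

.check_accum <- function(acc, spec, where) {
  lim <- 2^(spec$accum_bits - 1) - 1
  if (max(abs(acc)) > lim) {
    stop(sprintf("accumulator overflow beyond %d bits at %s", spec$accum_bits, where),
         call. = FALSE)
  }
  acc
}

# resolve the lazily-specified full-grid group set against an actual width
.resolve_groups <- function(chain, W) {
  if (identical(chain$groups, "all") || is.null(chain$groups)) {
    return(list(seq_len(W)))
  }
  chain$groups
}

#' One fully integer iteration of the five-step pipeline
#'
#' Executes the discretized dynamics in pure integer arithmetic: per-slice
#' VMM of the quantized weights against the integer rates with accumulation
#' checked against the accumulator width, truncation to the LUT index width,
#' table lookups for ReLU and the inhibition division, and the final
#' vector-scalar product back to the firing-rate scale. Deterministic.
#'
#' @param r_int integer firing-rate matrix at scale `rho_r`
#' @param stim_int integer stimulus matrix at scale `rho_ext`
#' @param chain a solved [solve_feedback_scaling()] chain
#' @return list with integer fields `r`, `V`, `V2`, scalar `s`, and
#'   `saturated` (total clipped values this iteration)
#' @export
quantized_step <- function(r_int, stim_int, chain) {
  spec <- chain$spec
  H <- nrow(r_int); W <- ncol(r_int)
  groups <- .resolve_groups(chain, W)
  sat <- 0
  partial <- matrix(0, H, W)
  for (g in groups) {
    src <- matrix(0, H, W)
    src[, g] <- r_int[, g]
    acc <- .check_accum(recurrent_drive(src, chain$w_int, 1), spec, "step 1")
    p <- .lut_apply(acc, chain$shifts[["step1"]], chain$luts$step1, spec)
    sat <- sat + attr(p, "saturated")
    partial <- partial + p
  }
  acc2 <- .check_accum(partial + stim_int, spec, "step 2")
  V_int <- .lut_apply(acc2, chain$shifts[["step2"]], chain$luts$step2, spec)
  sat <- sat + attr(V_int, "saturated")
  acc3 <- .check_accum(V_int * V_int, spec, "step 3")
  V2_int <- .lut_apply(acc3, chain$shifts[["step3"]], chain$luts$step3, spec)
  sat <- sat + attr(V2_int, "saturated")
  acc4 <- .check_accum(sum(V2_int), spec, "step 4")
  s_int <- .lut_apply(acc4, chain$shifts[["step4"]], chain$luts$step4, spec)
  sat <- sat + attr(s_int, "saturated")
  acc5 <- .check_accum(V2_int * as.numeric(s_int), spec, "step 5")
  r_out <- .lut_apply(acc5, chain$shifts[["step5"]], chain$luts$step5, spec)
  sat <- sat + attr(r_out, "saturated")
  list(r = matrix(as.numeric(r_out), H, W), V = V_int, V2 = V2_int,
       s = as.numeric(s_int), saturated = sat)
}

#' Run the integer pipeline over a stimulus sequence
#'
#' @param stimuli list of float stimulus matrices (quantized internally at
#'   `chain$rho_ext`)
#' @param r0_int initial integer rate matrix
#' @param chain a solved scaling chain
#' @param n_iter iterations per frame
#' @return list with `r_frames` (integer rate grid after each frame),
#'   `r_iters` (after every iteration), and `saturated` total
#' @export
run_quantized <- function(stimuli, r0_int, chain, n_iter) {
  r <- r0_int
  r_frames <- vector("list", length(stimuli))
  r_iters <- list()
  sat <- 0
  for (t in seq_along(stimuli)) {
    stim_int <- quantize_array(stimuli[[t]], chain$rho_ext, chain$spec$io_bits)
    for (i in seq_len(n_iter)) {
      out <- quantized_step(r, stim_int, chain)
      r <- out$r
      r_iters[[length(r_iters) + 1L]] <- r
      sat <- sat + out$saturated
    }
    r_frames[[t]] <- r
  }
  list(r_frames = r_frames, r_iters = r_iters, saturated = sat)
}

#' Check the closed-loop scaling restriction
#'
#' Propagates `rho_r` through the five steps with [propagate_scaling()] and
#' returns the resulting output scale; for a valid chain this equals
#' `chain$rho_r` exactly.
#'
#' @param chain a scaling chain
#' @return the propagated firing-rate scale
#' @export
chain_loop_scale <- function(chain) {
  rho_V1 <- propagate_scaling(chain$rho_J, chain$rho_r, chain$rho_F[["step1"]], "multiply")
  rho_V <- propagate_scaling(rho_V1, rho_V1, chain$rho_F[["step2"]], "add")
  rho_V2 <- propagate_scaling(rho_V, rho_V, chain$rho_F[["step3"]], "multiply")
  # step 4 is the nonlinear division; its output scale is set by the LUT
  propagate_scaling(rho_V2, chain$rho_s, chain$rho_F[["step5"]], "multiply")
}

#' Integer/float scaling-ratio trace
#'
#' For matched float and integer trajectories, computes the per-iteration
#' ratio of summed integer rate magnitude to `rho_r` times the summed float
#' rate magnitude. A correctly closed chain keeps the ratio near 1 with
#' bounded fluctuation (rounding noise); a mis-scaled chain drifts.
#'
#' @param r_float list of float rate matrices per iteration
#' @param r_int list of integer rate matrices per iteration
#' @param chain the scaling chain (for `rho_r`)
#' @return list with `ratio` series, `mean`, and `max_dev` (max |ratio - 1|)
#' @export
trace_scaling_ratio <- function(r_float, r_int, chain) {
  n <- min(length(r_float), length(r_int))
  ratio <- vapply(seq_len(n), function(i) {
    denom <- chain$rho_r * sum(abs(r_float[[i]]))
    if (denom == 0) return(NA_real_)
    sum(abs(r_int[[i]])) / denom
  }, numeric(1))
  list(ratio = ratio, mean = mean(ratio, na.rm = TRUE),
       max_dev = max(abs(ratio - 1), na.rm = TRUE))
}

#' Serialize a scaling chain to JSON
#'
#' Writes scales, shifts, quantized weights, LUT contents and the slice
#' decomposition to a JSON sidecar so the mapper and chip simulator consume
#' exactly the calibrated configuration.
#'
#' @param chain a scaling chain
#' @param path output file
#' @return `path`, invisibly
#' @export
write_chain_json <- function(chain, path) {
  obj <- list(
    spec = unclass(chain$spec), params = chain$params,
    rho = list(J = chain$rho_J, r = chain$rho_r, V1 = chain$rho_V1,
               V = chain$rho_V, V2 = chain$rho_V2, s = chain$rho_s,
               ext = chain$rho_ext),
    rho_F = as.list(chain$rho_F), shifts = as.list(chain$shifts),
    w_int = list(values = as.vector(chain$w_int), nrow = nrow(chain$w_int),
                 offsets_row = attr(chain$w_int, "offsets_row"),
                 offsets_col = attr(chain$w_int, "offsets_col")),
    luts = lapply(chain$luts, function(l) l[c("values", "signed", "offset")]),
    groups = chain$groups
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scaling chain from its JSON sidecar
#' @param path file written by [write_chain_json()]
#' @return a `scaling_chain`
#' @export
read_chain_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- matrix(obj$w_int$values, nrow = obj$w_int$nrow)
  attr(w, "offsets_row") <- obj$w_int$offsets_row
  attr(w, "offsets_col") <- obj$w_int$offsets_col
  attr(w, "center") <- (obj$w_int$nrow + 1L) %/% 2L
  groups <- obj$groups
  if (is.matrix(groups)) groups <- lapply(seq_len(nrow(groups)), function(i) groups[i, ])
  structure(list(spec = do.call(fixed_point_spec, as.list(obj$spec)),
                 params = as.list(obj$params),
                 rho_J = obj$rho$J, rho_r = obj$rho$r, rho_V1 = obj$rho$V1,
                 rho_V = obj$rho$V, rho_V2 = obj$rho$V2, rho_s = obj$rho$s,
                 rho_ext = obj$rho$ext,
                 rho_F = unlist(obj$rho_F), shifts = unlist(obj$shifts),
                 w_int = w, luts = lapply(obj$luts, as.list),
                 groups = groups),
            class = "scaling_chain")
}
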