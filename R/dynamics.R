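#' Divisively normalized firing rate
#'
#' Computes `r(x) = V(x)^2 / (k * sum(V^2))`. The `1 +` term of the original
#' continuous-time model is dropped in the discretized network, which makes
#' the all-zero state singular; by convention `r = 0` everywhere when
#' `sum(V^2) == 0`. For any non-zero `V` the rates obey the algebraic
#' identity `sum(r) = 1/k`.
#'
#' @param V membrane-potential matrix (elementwise >= 0)
#' @param k global-inhibition strength (> 0)
#' @return list with `r` (rate matrix) and `s_inh` (the scalar
#'   `1/(k * sum(V^2))`, 0 for an all-zero V)
#' @export
firing_rate <- function(V, k) {
  S <- sum(V^2)
  if (S == 0) {
    return(list(r = matrix(0, nrow(V), ncol(V)), s_inh = 0))
  }
  s <- 1 / (k * S)
  list(r = V^2 * s, s_inh = s)
}

# toroidal gather indices for a shift by `d` along an axis of length `n`
.wrap_idx <- function(n, d) ((seq_len(n) - 1L + d) %% n) + 1L

#' Recurrent potential update
#'
#' Computes `V(x) = max(0, beta * sum_{x' in CF(x)} J(x, x') r(x') +
#' V_ext(x))` with the connection field wrapped toroidally. The ReLU clips
#' net-negative drive (difference-frame stimuli are signed).
#'
#' @param r firing-rate matrix
#' @param V_ext external stimulus matrix (same shape; signed)
#' @param stencil weight stencil from [build_interaction_kernel()]
#' @param beta recurrent-input gain
#' @param cols optional integer vector of source columns; when given, only
#'   firing rates in those columns contribute (used to reproduce per-slice
#'   partial potentials of the mapped network) and no stimulus/ReLU is
#'   applied — the raw partial recurrent drive is returned
#' @return potential matrix (ReLU-clipped unless `cols` is given)
#' @export
update_potential <- function(r, V_ext, stencil, beta, cols = NULL) {
  if (!is.null(V_ext) && !all(dim(r) == dim(V_ext))) {
    stop("update_potential: stimulus shape does not match rate field", call. = FALSE)
  }
  src <- r
  if (!is.null(cols)) {
    src <- matrix(0, nrow(r), ncol(r))
    src[, cols] <- r[, cols]
  }
  acc <- recurrent_drive(src, stencil, beta)
  if (!is.null(cols)) return(acc)
  pmax(acc + V_ext, 0)
}

# beta-scaled toroidal correlation of the rate field with the stencil:
# acc[x] = beta * sum_off w[off] * r[x + off]
recurrent_drive <- function(r, stencil, beta) {
  H <- nrow(r); W <- ncol(r)
  offr <- attr(stencil, "offsets_row")
  offc <- attr(stencil, "offsets_col")
  acc <- matrix(0, H, W)
  for (i in seq_along(offr)) {
    ri <- .wrap_idx(H, offr[i])
    row_w <- stencil[i, ]
    nz <- which(row_w != 0)
    for (j in nz) {
      ci <- .wrap_idx(W, offc[j])
      acc <- acc + row_w[j] * r[ri, ci]
    }
  }
  beta * acc
}

#' One iteration of the discretized dynamics
#'
#' Applies the potential update followed by the firing-rate normalization,
#' i.e. the dataflow `{r(t), V_ext(t)} -> V(t+1) -> r(t+1)`.
#'
#' @param state a [cann_state()]
#' @param stim external stimulus matrix
#' @param params a [dynamics_params()]
#' @param stencil weight stencil from [build_interaction_kernel()]
#' @return the updated `cann_state`
#' @export
cann_step <- function(state, stim, params, stencil) {
  V <- update_potential(state$r, stim, stencil, params$beta)
  fr <- firing_rate(V, params$k)
  cann_state(V, fr$r, fr$s_inh)
}

#' Run all iterations for one difference frame
#'
#' Applies [cann_step()] `params$n_iter` times with the stimulus held
#' constant (the stimulus is indexed by frame, not by iteration).
#' `n_iter = 0` returns the state unchanged.
#'
#' @inheritParams cann_step
#' @return the updated `cann_state`
#' @export
run_frame <- function(state, stim, params, stencil) {
  n <- params$n_iter
  while (n > 0) {
    state <- cann_step(state, stim, params, stencil)
    n <- n - 1L
  }
  state
}

#' Read out the bump location
#'
#' Returns the (row, col) coordinates of the maximum firing rate. Ties are
#' broken by smallest row, then smallest column. An all-zero (or
#' non-finite-max) rate field carries no location information: the previous
#' location is returned if supplied, else the grid centre, with attribute
#' `degenerate = TRUE`.
#'
#' @param r firing-rate matrix
#' @param prev optional previous (row, col) to fall back to
#' @return integer vector `c(row, col)` (1-based)
#' @export
predict_location <- function(r, prev = NULL) {
  m <- max(r)
  if (m <= 0) {
    loc <- if (!is.null(prev)) as.integer(prev)
           else as.integer(c((nrow(r) + 1) %/% 2, (ncol(r) + 1) %/% 2))
    attr(loc, "degenerate") <- TRUE
    return(loc)
  }
  hits <- which(r == m, arr.ind = TRUE)
  o <- order(hits[, 1L], hits[, 2L])
  loc <- as.integer(hits[o[1L], ])
  names(loc) <- NULL
  loc
}

#' Seed the network state from an initial bounding box
#'
#' Injects a bump shaped like the interaction stencil at the grid position of
#' the box centre, with peak value `beta/k` times the stencil centre weight
#' (an empirically stable amplitude for the divisive-inhibition fixed
#' point), then normalizes to obtain the rates.
#'
#' @param grid a [grid_spec()]
#' @param center_grid numeric `(row, col)` of the bump centre in grid
#'   coordinates (1-based; fractional values are rounded)
#' @param params a [dynamics_params()]
#' @param stencil weight stencil
#' @return a `cann_state` with a formed bump
#' @export
init_bump_state <- function(grid, center_grid, params, stencil) {
  H <- grid$height; W <- grid$width
  V <- matrix(0, H, W)
  cr <- ((round(center_grid[1]) - 1) %% H) + 1
  cc <- ((round(center_grid[2]) - 1) %% W) + 1
  offr <- attr(stencil, "offsets_row")
  offc <- attr(stencil, "offsets_col")
  amp <- params$beta / params$k
  ri <- ((cr - 1 + offr) %% H) + 1
  ci <- ((cc - 1 + offc) %% W) + 1
  V[ri, ci] <- pmax(V[ri, ci], amp * stencil)
  fr <- firing_rate(V, params$k)
  cann_state(V, fr$r, fr$s_inh)
}

#' Map between native pixel and grid coordinates
#'
#' Pixel centres are aligned between resolutions: 0-based centre `u` at
#' native scale maps to `(u + 0.5)/s - 0.5` on the grid, where `s` is the
#' native-to-grid scale factor per axis.
#'
#' @param xy numeric `(row, col)` position, 0-based
#' @param scale numeric `(row_scale, col_scale)` = native size / grid size
#' @param to `"grid"` or `"native"`
#' @return transformed `(row, col)`, 0-based
#' @export
map_coords <- function(xy, scale, to = c("grid", "native")) {
  to <- match.arg(to)
  if (to == "grid") (xy + 0.5) / scale - 0.5 else (xy + 0.5) * scale - 0.5
}

#' Track an object through a stimulus sequence
#'
#' Fixed-scale CANN tracker: the network is seeded with a bump at the
#' first-frame ground-truth centre; each difference-frame stimulus is then
#' integrated for `params$n_iter` iterations, the bump centre is read out,
#' mapped back to native pixel coordinates, and emitted as a box with the
#' initial box's width and height.
#'
#' @param stimuli list of H x W stimulus matrices (one per difference frame)
#' @param init_box numeric `(x, y, w, h)` first-frame ground truth in native
#'   pixels, 0-based top-left origin
#' @param params a [dynamics_params()]
#' @param stencil weight stencil
#' @param scale numeric `(row_scale, col_scale)` = native size / grid size
#' @return data.frame of predicted boxes `(x, y, w, h)` with one row per
#'   input frame (the first row echoes `init_box`), plus columns
#'   `row`, `col` of the grid-space bump centre
#' @export
track_sequence <- function(stimuli, init_box, params, stencil, scale = c(1, 1)) {
  if (length(stimuli) < 1) stop("track_sequence: empty stimulus sequence", call. = FALSE)
  H <- nrow(stimuli[[1]]); W <- ncol(stimuli[[1]])
  grid <- grid_spec(H, W)
  c_native <- c(init_box[2] + init_box[4] / 2, init_box[1] + init_box[3] / 2)
  c_grid0 <- map_coords(c_native, scale, "grid")   # 0-based (row, col)
  state <- init_bump_state(grid, c_grid0 + 1, params, stencil)
  n <- length(stimuli)
  out <- matrix(NA_real_, n + 1, 6)
  loc <- predict_location(state$r)
  out[1, ] <- c(init_box, loc)
  for (t in seq_len(n)) {
    state <- run_frame(state, stimuli[[t]], params, stencil)
    loc <- predict_location(state$r, prev = loc)
    p_native <- map_coords(as.numeric(loc) - 1, scale, "native")
    out[t + 1, ] <- c(p_native[2] - init_box[3] / 2, p_native[1] - init_box[4] / 2,
                      init_box[3], init_box[4], loc)
  }
  res <- as.data.frame(out)
  names(res) <- c("x", "y", "w", "h", "row", "col")
  res
}
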