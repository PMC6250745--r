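#' Neuron grid specification
#'
#' Defines the 2D sheet of rate neurons on which the attractor dynamics run.
#' The sheet is toroidal: the topmost and bottommost rows (and leftmost and
#' rightmost columns) are adjacent, so neuronal distance is circular and the
#' activity bump is stable at the boundary.
#'
#' @param height number of neuron rows (H >= 1)
#' @param width number of neuron columns (W >= 1)
#' @return an object of class `grid_spec` with fields `height`, `width`,
#'   `toroidal` (always `TRUE` in the reference model)
#' @export
grid_spec <- function(height, width) {
  if (!is.numeric(height) || !is.numeric(width) ||
      height < 1 || width < 1 ||
      height != round(height) || width != round(width)) {
    stop("grid_spec: height and width must be positive integers", call. = FALSE)
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 toroidal = TRUE),
            class = "grid_spec")
}

#' Gaussian interaction kernel specification
#'
#' The synaptic weight from neuron x' to neuron x is
#' `J(x, x') = J0/(2*pi*a^2) * exp(-|x - x'|^2 / (2*a^2))`, restricted to a
#' local connection field (CF): each neuron only keeps synapses from the
#' R x R square of neurons centred on it. `J0/(2*pi*a^2)` is the maximum
#' interaction (the self weight).
#'
#' @param J0 interaction strength constant (> 0)
#' @param a Gaussian interaction range in neuron-grid units (> 0)
#' @param R connection-field side length in neurons (odd integer)
#' @return an object of class `kernel_spec`
#' @export
kernel_spec <- function(J0, a, R) {
  if (!is.numeric(J0) || J0 <= 0) stop("kernel_spec: J0 must be > 0", call. = FALSE)
  if (!is.numeric(a) || a <= 0) stop("kernel_spec: a must be > 0", call. = FALSE)
  if (!is.numeric(R) || R < 1 || R != round(R) || R %% 2 == 0) {
    stop("kernel_spec: R must be a positive odd integer", call. = FALSE)
  }
  structure(list(J0 = J0, a = a, R = as.integer(R)), class = "kernel_spec")
}

#' Global dynamics parameters
#'
#' Parameters of the discretized state update. `beta` scales the recurrent
#' input relative to the external stimulus; `k` sets the strength of divisive
#' global inhibition (for any non-zero state the firing rates sum to `1/k`);
#' `n_iter` is the number of state-update iterations run per difference
#' frame. The time constant tau is fixed to 1 by the discretization and is
#' not configurable.
#'
#' @param beta recurrent-input gain (> 0)
#' @param k global-inhibition strength (> 0)
#' @param n_iter iterations per difference frame (>= 0)
#' @return an object of class `dynamics_params`
#' @export
dynamics_params <- function(beta, k, n_iter = 15L) {
  if (!is.numeric(beta) || beta <= 0) stop("dynamics_params: beta must be > 0", call. = FALSE)
  if (!is.numeric(k) || k <= 0) stop("dynamics_params: k must be > 0", call. = FALSE)
  if (!is.numeric(n_iter) || n_iter < 0 || n_iter != round(n_iter)) {
    stop("dynamics_params: n_iter must be a non-negative integer", call. = FALSE)
  }
  structure(list(beta = beta, k = k, n_iter = as.integer(n_iter), tau = 1),
            class = "dynamics_params")
}

#' Network state container
#'
#' Holds the membrane-potential field `V` (H x W, elementwise >= 0 — the
#' update applies a ReLU), the firing-rate field `r` (>= 0), and the scalar
#' inhibition factor `s_inh = 1/(k * sum(V^2))` from the last update (0 by
#' convention when V is identically zero).
#'
#' @param V membrane-potential matrix
#' @param r firing-rate matrix
#' @param s_inh scalar inhibition factor
#' @return an object of class `cann_state`
#' @export
cann_state <- function(V, r = NULL, s_inh = 0) {
  stopifnot(is.matrix(V))
  if (is.null(r)) r <- matrix(0, nrow(V), ncol(V))
  stopifnot(is.matrix(r), all(dim(r) == dim(V)))
  structure(list(V = V, r = r, s_inh = s_inh), class = "cann_state")
}

#' Zero network state for a grid
#' @param grid a [grid_spec()]
#' @return a `cann_state` with all-zero fields
#' @export
zero_state <- function(grid) {
  cann_state(matrix(0, grid$height, grid$width))
}
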