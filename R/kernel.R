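#' Build the local-connection interaction stencil
#'
#' Evaluates the Gaussian interaction profile on the R x R connection field
#' and returns it as a translation-invariant weight stencil. Entry
#' `[i, j]` of the stencil is the weight for source offset
#' `(i - c, j - c)` with `c = (R + 1)/2` the centre row/column, so the
#' centre entry equals the self weight `J0/(2*pi*a^2)`. Distances are
#' minimum-image Euclidean on the torus defined by `grid`; offsets outside
#' the connection field are not represented (implicitly zero weight).
#'
#' @param grid a [grid_spec()]
#' @param kernel a [kernel_spec()]
#' @return an R x R numeric matrix with attributes `offsets_row`,
#'   `offsets_col` (integer offset vectors) and `center` (centre index)
#' @export
build_interaction_kernel <- function(grid, kernel) {
  R <- kernel$R
  if (R %% 2 == 0) stop("connection field side R must be odd", call. = FALSE)
  if (R > min(grid$height, grid$width)) {
    stop("connection field R exceeds grid dimensions", call. = FALSE)
  }
  half <- (R - 1L) %/% 2L
  off <- seq.int(-half, half)
  # minimum-image displacement on the torus; R <= min(H, W) keeps |off|
  # within half the grid except in the degenerate R == H (or W) case
  dr <- pmin(abs(off), grid$height - abs(off))
  dc <- pmin(abs(off), grid$width - abs(off))
  d2 <- outer(dr^2, dc^2, `+`)
  w <- kernel$J0 / (2 * pi * kernel$a^2) * exp(-d2 / (2 * kernel$a^2))
  attr(w, "offsets_row") <- off
  attr(w, "offsets_col") <- off
  attr(w, "center") <- half + 1L
  w
}
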