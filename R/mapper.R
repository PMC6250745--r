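#' Per-core hardware constraints
#'
#' Limits of one functional core (FunC): 256 fan-ins and 256 fan-outs set by
#' the 256 x 256 synapse array, up to 128 stored vectors for the
#' multi-vector accumulate (VVA) — the dynamic synapse memory is organised
#' as two ping-pong banks of 128 x 256 8-bit entries — and 16 MAC groups of
#' 16 columns for the vector-matrix multiply.
#'
#' @param fan_in maximum fan-in per core (default 256)
#' @param fan_out maximum fan-out per core (default 256)
#' @param synapse_rows,synapse_cols synapse array shape (default 256 x 256)
#' @param vva_max_vectors maximum vectors in one VVA (default 128)
#' @param mac_groups,mac_group_cols MAC organisation (default 16 x 16)
#' @return an object of class `core_constraints`
#' @export
core_constraints <- function(fan_in = 256L, fan_out = 256L,
                             synapse_rows = 256L, synapse_cols = 256L,
                             vva_max_vectors = 128L,
                             mac_groups = 16L, mac_group_cols = 16L) {
  stopifnot(fan_in > 0, fan_out > 0, synapse_rows > 0, synapse_cols > 0,
            vva_max_vectors > 0)
  structure(list(fan_in = as.integer(fan_in), fan_out = as.integer(fan_out),
                 synapse_rows = as.integer(synapse_rows),
                 synapse_cols = as.integer(synapse_cols),
                 vva_max_vectors = as.integer(vva_max_vectors),
                 mac_groups = as.integer(mac_groups),
                 mac_group_cols = as.integer(mac_group_cols)),
            class = "core_constraints")
}

.divisors <- function(n) which(n %% seq_len(n) == 0)

#' Plan the column-wise input slices of the step-1 multiply
#'
#' The recurrent-input VMM is split into column-wise input slices whose
#' width is jointly determined by the network height and the core fan-in:
#' `w = min(floor(fan_in/H), (R-1)/2)`, snapped down to the largest divisor
#' of W so the slices tile the grid exactly. When the whole grid fits the
#' fan-in no slicing is needed and a single full-width slice is returned.
#'
#' @param H,W grid dimensions
#' @param R connection-field side (odd)
#' @param constraints a [core_constraints()]
#' @return list of integer column-index vectors (the slices, in order), with
#'   attribute `width`
#' @export
plan_column_slices <- function(H, W, R, constraints = core_constraints()) {
  if (H > constraints$fan_in) {
    stop(sprintf("plan_column_slices: network height %d exceeds the %d-core fan-in; multi-row splitting is unsupported",
                 H, constraints$fan_in), call. = FALSE)
  }
  if (R %% 2 == 0) stop("plan_column_slices: R must be odd", call. = FALSE)
  w_max <- constraints$fan_in %/% H
  if (w_max >= W) {
    w <- W
  } else {
    w <- min(w_max, (R - 1L) %/% 2L)
    divs <- .divisors(W)
    divs <- divs[divs <= w]
    if (length(divs) == 0) stop("plan_column_slices: no feasible slice width", call. = FALSE)
    w <- max(divs)
  }
  slices <- split(seq_len(W), rep(seq_len(W %/% w), each = w))
  names(slices) <- NULL
  attr(slices, "width") <- as.integer(w)
  slices
}

#' Plan the row-wise output slices
#'
#' Each input slice of width `w` affects a span of `w + R - 1` columns; the
#' outputs of that span are split into the smallest number of equal-height
#' row bands (a divisor of H) such that each band's `(H/n) * span` output
#' neurons fit the core fan-out.
#'
#' @param H grid height
#' @param w column-slice width
#' @param R connection-field side
#' @param constraints a [core_constraints()]
#' @param W optional grid width, capping the affected span for full-width
#'   slices
#' @return list of integer row-index vectors, with attribute `span` (the
#'   affected-column count)
#' @export
plan_row_slices <- function(H, w, R, constraints = core_constraints(), W = NULL) {
  span <- w + R - 1L
  if (!is.null(W)) span <- min(span, W)
  n_row <- NA_integer_
  for (n in .divisors(H)) {
    if ((H %/% n) * span <= constraints$fan_out) { n_row <- n; break }
  }
  if (is.na(n_row)) stop("plan_row_slices: no feasible row split", call. = FALSE)
  out <- split(seq_len(H), rep(seq_len(n_row), each = H %/% n_row))
  names(out) <- NULL
  attr(out, "span") <- as.integer(span)
  out
}

# near-equal contiguous split of N neurons into blocks of <= fan_out
.vector_blocks <- function(N, fan_out) {
  n <- as.integer(ceiling(N / fan_out))
  sizes <- rep(N %/% n, n)
  rem <- N - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  Map(function(s, e) seq.int(s, e), starts, ends)
}

#' Plan the full five-step mapping
#'
#' Deterministically places each of the five execution steps of the
#' discretized dynamics onto fan-in/fan-out-constrained cores:
#' \describe{
#'   \item{step 1}{one VMM core per (column slice x row slice); the cores of
#'     a column slice share their inputs over an adjacent-multicast (AMC)
#'     chain}
#'   \item{step 2}{VVA cores integrating the per-neuron partial potentials
#'     plus the external stimulus, neurons split near-equally over
#'     `ceil(N/fan_out)` cores, duplicated x2 (the squaring step consumes
#'     two operand copies)}
#'   \item{step 3}{VVM squaring cores, same split, duplicated x2 (feeding
#'     the inhibition sum and the potential delay)}
#'   \item{step 4-1}{one VVA + lateral-accumulate + nonlinear-LUT core per
#'     step-5 core (copies), full-grid fan-in, fan-out 1 (the scalar
#'     inhibition factor)}
#'   \item{step 4-2}{vector-buffer delay cores aligning the squared
#'     potential with the inhibition factor}
#'   \item{step 5}{vector-scaling cores (fan-in = block + 1 scalar)}
#' }
#'
#' @param grid a [grid_spec()]
#' @param kernel a [kernel_spec()]
#' @param constraints a [core_constraints()]
#' @return an object of class `placement`: list with `grid`, `kernel`,
#'   `constraints`, `col_slices`, `row_slices`, `span_cols` (per-slice
#'   affected columns), `blocks` (vector-core neuron index sets,
#'   column-major), `slice_of_col`, `cores` (data.frame, one row per core)
#'   and `amc_chains`
#' @export
plan_full_mapping <- function(grid, kernel, constraints = core_constraints()) {
  H <- grid$height; W <- grid$width; R <- kernel$R
  N <- H * W
  col_slices <- plan_column_slices(H, W, R, constraints)
  w <- attr(col_slices, "width")
  row_slices <- plan_row_slices(H, w, R, constraints, W = W)
  n_cs <- length(col_slices); n_rs <- length(row_slices)
  span <- min(w + R - 1L, W)
  half <- (R - 1L) %/% 2L

  # columns affected by each input slice (toroidal)
  span_cols <- lapply(col_slices, function(cols) {
    lo <- min(cols) - half; hi <- max(cols) + half
    if (hi - lo + 1L >= W) seq_len(W)
    else ((seq.int(lo, hi) - 1L) %% W) + 1L
  })
  # number of slices contributing to any one neuron's potential
  n_overlap <- if (n_cs == 1L) 1L else min(as.integer(ceiling((R - 1L) / w)) + 1L, n_cs)

  blocks <- .vector_blocks(N, constraints$fan_out)
  n_vec <- length(blocks)
  bsz <- lengths(blocks)

  rows <- list()
  add <- function(step, role, dendrite, soma, fan_in, fan_out, copy,
                  n_vectors, vec_len, slice = NA, rslice = NA, block = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      step = step, role = role, dendrite = dendrite, soma = soma,
      fan_in = fan_in, fan_out = fan_out, copy = copy,
      n_vectors = n_vectors, vec_len = vec_len,
      slice = slice, rslice = rslice, block = block,
      stringsAsFactors = FALSE)
  }
  for (j in seq_len(n_cs)) {
    for (k in seq_len(n_rs)) {
      add("1", "recurrent input", "VMM", "LUT_Fun+Out_Trans",
          H * w, length(row_slices[[k]]) * span, 1L, 0L, 0L, slice = j, rslice = k)
    }
  }
  for (cp in 1:2) for (b in seq_len(n_vec)) {
    add("2", "membrane potential", "VVA", "LUT_Fun+Out_Trans",
        bsz[b] * (n_overlap + 1L), bsz[b], cp, n_overlap + 1L, bsz[b], block = b)
  }
  for (cp in 1:2) for (b in seq_len(n_vec)) {
    add("3", "potential squared", "VVM", "LUT_Fun+Out_Trans",
        bsz[b] * 2L, bsz[b], cp, 2L, bsz[b], block = b)
  }
  for (cp in seq_len(n_vec)) {
    add("4-1", "inhibition factor", "VVA", "Lat_Acc+LUT_Fun+Out_Trans",
        N, 1L, cp, n_vec, max(bsz))
  }
  for (b in seq_len(n_vec)) {
    add("4-2", "potential delay", "VB", "Out_Trans", bsz[b], bsz[b], 1L,
        1L, bsz[b], block = b)
  }
  for (b in seq_len(n_vec)) {
    add("5", "firing rate", "VS", "LUT_Fun+Out_Trans", bsz[b] + 1L, bsz[b], 1L,
        1L, bsz[b], block = b)
  }
  cores <- do.call(rbind, rows)
  cores$id <- seq_len(nrow(cores))

  amc_chains <- c(
    lapply(seq_len(n_cs), function(j) cores$id[cores$step == "1" & cores$slice == j]),
    lapply(seq_len(n_vec), function(b) cores$id[cores$step == "2" & cores$block == b]),
    lapply(seq_len(n_vec), function(b) cores$id[cores$step == "3" & cores$block == b]),
    list(cores$id[cores$step == "4-1"])
  )

  structure(list(grid = grid, kernel = kernel, constraints = constraints,
                 col_slices = col_slices, row_slices = row_slices,
                 span_cols = span_cols, n_overlap = n_overlap,
                 blocks = blocks, cores = cores, amc_chains = amc_chains),
            class = "placement")
}

#' Per-step resource accounting
#'
#' @param placement a [plan_full_mapping()] result
#' @return an object of class `resource_report`: data.frame with one row per
#'   step (`step`, `role`, `operation`, `cores`, `fan_in`, `fan_out`) plus
#'   attribute `total`; printed as a table
#' @export
resource_report <- function(placement) {
  cs <- placement$cores
  if (is.null(cs) || nrow(cs) == 0) {
    rep <- data.frame(step = character(0), role = character(0),
                      operation = character(0), cores = integer(0),
                      fan_in = character(0), fan_out = character(0))
    attr(rep, "total") <- 0L
    class(rep) <- c("resource_report", "data.frame")
    return(rep)
  }
  steps <- unique(cs$step)
  rep <- do.call(rbind, lapply(steps, function(s) {
    sub <- cs[cs$step == s, ]
    data.frame(step = s, role = sub$role[1], operation = sub$dendrite[1],
               cores = nrow(sub),
               fan_in = paste(sort(unique(sub$fan_in)), collapse = "/"),
               fan_out = paste(sort(unique(sub$fan_out)), collapse = "/"),
               stringsAsFactors = FALSE)
  }))
  attr(rep, "total") <- nrow(cs)
  class(rep) <- c("resource_report", "data.frame")
  rep
}

#' @export
print.resource_report <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, ...)
  cat(sprintf("Total: %d cores\n", attr(x, "total")))
  invisible(x)
}

#' Validate a placement against the core constraints
#'
#' Checks every core's fan-in/fan-out against the axon and routing limits,
#' the static synapse capacity for VMM cores, and the dynamic-vector
#' capacity (vector count and per-vector length) for element-wise cores.
#' Violations are returned as data, not raised.
#'
#' @param placement a `placement`
#' @param constraints a [core_constraints()] (defaults to the placement's)
#' @return character vector of violation messages (empty when valid)
#' @export
validate_placement <- function(placement, constraints = placement$constraints) {
  v <- character(0)
  cs <- placement$cores
  for (i in seq_len(nrow(cs))) {
    core <- cs[i, ]
    vec_op <- core$dendrite %in% c("VVA", "VVM", "VS", "VB")
    if (vec_op) {
      # element-wise operands live in the dynamic synapse banks
      if (core$dendrite == "VVM" && core$n_vectors != 2) {
        v <- c(v, sprintf("core %d: VVM requires exactly 2 vectors, has %d",
                          core$id, core$n_vectors))
      }
      if (core$n_vectors > constraints$vva_max_vectors) {
        v <- c(v, sprintf("core %d: %d vectors exceed the VVA limit %d",
                          core$id, core$n_vectors, constraints$vva_max_vectors))
      }
      if (core$vec_len > constraints$synapse_cols) {
        v <- c(v, sprintf("core %d: vector length %d exceeds synapse row %d",
                          core$id, core$vec_len, constraints$synapse_cols))
      }
      if (core$fan_in > constraints$vva_max_vectors * constraints$synapse_cols) {
        v <- c(v, sprintf("core %d: fan-in %d exceeds dynamic synapse capacity",
                          core$id, core$fan_in))
      }
    } else {
      if (core$fan_in > constraints$fan_in) {
        v <- c(v, sprintf("core %d: fan-in %d exceeds limit %d",
                          core$id, core$fan_in, constraints$fan_in))
      }
      if (core$fan_in > constraints$synapse_rows) {
        v <- c(v, sprintf("core %d: weight rows %d exceed synapse array", core$id, core$fan_in))
      }
    }
    if (core$fan_out > constraints$fan_out) {
      v <- c(v, sprintf("core %d: fan-out %d exceeds limit %d",
                        core$id, core$fan_out, constraints$fan_out))
    }
  }
  v
}

#' Serialize a placement to JSON
#' @param placement a `placement`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_placement_json <- function(placement, path) {
  obj <- list(
    grid = unclass(placement$grid),
    kernel = unclass(placement$kernel),
    constraints = unclass(placement$constraints),
    col_slices = placement$col_slices,
    row_slices = placement$row_slices,
    span_cols = placement$span_cols,
    n_overlap = placement$n_overlap,
    blocks = placement$blocks,
    cores = placement$cores,
    amc_chains = placement$amc_chains
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a placement from JSON
#' @param path file written by [write_placement_json()]
#' @return a `placement`
#' @export
read_placement_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tolist <- function(x) if (is.matrix(x)) lapply(seq_len(nrow(x)), function(i) x[i, ]) else as.list(x)
  structure(list(
    grid = grid_spec(obj$grid$height, obj$grid$width),
    kernel = kernel_spec(obj$kernel$J0, obj$kernel$a, obj$kernel$R),
    constraints = do.call(core_constraints, as.list(obj$constraints)[c(
      "fan_in", "fan_out", "synapse_rows", "synapse_cols", "vva_max_vectors",
      "mac_groups", "mac_group_cols")]),
    col_slices = tolist(obj$col_slices),
    row_slices = tolist(obj$row_slices),
    span_cols = tolist(obj$span_cols),
    n_overlap = obj$n_overlap,
    blocks = tolist(obj$blocks),
    cores = as.data.frame(obj$cores),
    amc_chains = tolist(obj$amc_chains)
  ), class = "placement")
}
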