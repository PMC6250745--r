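#' @title Behavioral simulator of the mapped many-core network
#' @description
#' Executes a planned placement phase by phase with the functional-core
#' operation semantics: a dendrite integration (VMM / VVM / VVA / VS / VB)
#' into a wide accumulator, a soma transformation (optional lateral
#' accumulation, bit truncation, table lookup) down to I/O width, and packet
#' routing (point-to-point, plus adjacent-multicast relay chains for bulk
#' input sharing). One iteration of the dynamics is five global phases, each
#' a compute round followed by a communication barrier; packets written
#' during a phase land in the inactive buffer bank and become readable after
#' the barrier.
#' @name chip_sim
NULL

# toroidal signed displacement folded into [-n/2, n/2)
.wrap_disp <- function(d, n) ((d + n %/% 2) %% n) - n %/% 2

# neuron ids are column-major over the H x W grid: id = (col-1)*H + row
.neuron_ids <- function(rows, cols, H) {
  as.vector(outer(rows, (cols - 1L) * H, `+`))
}

# static VMM weight block: rows = output neurons, cols = input neurons
.vmm_weights <- function(out_ids, in_ids, H, w_int) {
  half <- (nrow(w_int) - 1L) %/% 2L
  W_grid <- attr(w_int, "ncols_grid")
  r_o <- ((out_ids - 1L) %% H) + 1L; c_o <- ((out_ids - 1L) %/% H) + 1L
  r_i <- ((in_ids - 1L) %% H) + 1L; c_i <- ((in_ids - 1L) %/% H) + 1L
  dr <- .wrap_disp(outer(r_i, r_o, `-`), H)           # in x out
  dc <- .wrap_disp(outer(c_i, c_o, `-`), W_grid)
  ok <- abs(dr) <= half & abs(dc) <= half
  Wm <- matrix(0, length(in_ids), length(out_ids))
  Wm[ok] <- w_int[cbind(dr[ok] + half + 1L, dc[ok] + half + 1L)]
  t(Wm)                                               # out x in
}

#' Instantiate the cores of a placement
#'
#' Builds per-core configuration (weight blocks, operand slots, soma shift
#' and LUT, output routing) from a validated placement and a solved scaling
#' chain.
#'
#' @param placement a [plan_full_mapping()] result
#' @param chain a [solve_feedback_scaling()] chain (its quantized weight
#'   stencil and step LUTs are loaded into the cores)
#' @return an object of class `chip` (list of core configs plus lookup
#'   tables used by the router)
#' @export
build_chip <- function(placement, chain) {
  viol <- validate_placement(placement)
  if (length(viol) > 0) {
    stop(paste("build_chip: placement violates core constraints:",
               paste(viol, collapse = "; ")), call. = FALSE)
  }
  H <- placement$grid$height; W <- placement$grid$width
  N <- H * W
  cs <- placement$cores
  w_int <- chain$w_int
  attr(w_int, "ncols_grid") <- W

  n_cs <- length(placement$col_slices)
  n_vec <- length(placement$blocks)
  blocks <- placement$blocks
  block_of <- integer(N); pos_in_block <- integer(N)
  for (b in seq_len(n_vec)) {
    block_of[blocks[[b]]] <- b
    pos_in_block[blocks[[b]]] <- seq_along(blocks[[b]])
  }
  slice_in_ids <- lapply(placement$col_slices, function(cols)
    .neuron_ids(seq_len(H), cols, H))
  pos_in_slice <- lapply(slice_in_ids, function(ids) {
    p <- integer(N); p[ids] <- seq_along(ids); p
  })
  # contributing slices per column, ascending; defines the partial-slot order
  contrib <- lapply(seq_len(W), function(c0) {
    which(vapply(placement$span_cols, function(sc) c0 %in% sc, logical(1)))
  })
  slot_of <- matrix(0L, N, n_cs)  # neuron x slice -> partial slot
  for (c0 in seq_len(W)) {
    ids <- .neuron_ids(seq_len(H), c0, H)
    for (k in seq_along(contrib[[c0]])) slot_of[ids, contrib[[c0]][k]] <- k
  }

  chains <- placement$amc_chains
  chain_head <- vapply(chains, function(ch) as.numeric(ch[1]), numeric(1))

  id_step <- function(st, ...) {
    sel <- cs$step == st
    extra <- list(...)
    for (nm in names(extra)) sel <- sel & cs[[nm]] %in% extra[[nm]]
    cs$id[sel]
  }

  cores <- vector("list", nrow(cs))
  for (i in seq_len(nrow(cs))) {
    core <- as.list(cs[i, ])
    cfg <- list(id = core$id, step = core$step, dendrite = core$dendrite,
                lat_acc = grepl("Lat_Acc", core$soma))
    if (core$step == "1") {
      j <- core$slice; k <- core$rslice
      out_ids <- .neuron_ids(placement$row_slices[[k]], placement$span_cols[[j]], H)
      cfg$in_len <- length(slice_in_ids[[j]])
      cfg$slots <- list(x = cfg$in_len)
      cfg$weights <- .vmm_weights(out_ids, slice_in_ids[[j]], H, w_int)
      cfg$shift <- chain$shifts[["step1"]]; cfg$lut <- chain$luts$step1
      # partial potentials scatter to the step-2 chain head of each block
      cfg$out <- list(list(kind = "partial", out_ids = out_ids, slice = j))
    } else if (core$step == "2") {
      b <- core$block
      cfg$slots <- c(stats::setNames(
        as.list(rep(length(blocks[[b]]), placement$n_overlap)),
        paste0("p", seq_len(placement$n_overlap))),
        list(stim = length(blocks[[b]])))
      cfg$shift <- chain$shifts[["step2"]]; cfg$lut <- chain$luts$step2
      cfg$block <- b
      cfg$out <- if (core$copy == 1L) {
        list(list(kind = "p2p_chainhead", dest = id_step("3", copy = 1L, block = b), slot = "x1"))
      } else {
        list(list(kind = "p2p_chainhead", dest = id_step("3", copy = 1L, block = b), slot = "x2"))
      }
    } else if (core$step == "3") {
      b <- core$block
      cfg$slots <- list(x1 = length(blocks[[b]]), x2 = length(blocks[[b]]))
      cfg$shift <- chain$shifts[["step3"]]; cfg$lut <- chain$luts$step3
      cfg$block <- b
      cfg$out <- if (core$copy == 1L) {
        list(list(kind = "p2p_chainhead", dest = id_step("4-1")[1], slot = paste0("v", b)))
      } else {
        list(list(kind = "p2p", dest = id_step("4-2", block = b), slot = "x"))
      }
    } else if (core$step == "4-1") {
      # operand vectors are padded to a common length; the lateral sum is
      # unaffected by the zero padding
      cfg$slots <- stats::setNames(as.list(rep(max(lengths(blocks)), n_vec)),
                                   paste0("v", seq_len(n_vec)))
      cfg$shift <- chain$shifts[["step4"]]; cfg$lut <- chain$luts$step4
      cfg$out <- list(list(kind = "p2p", dest = id_step("5")[core$copy], slot = "scalar"))
    } else if (core$step == "4-2") {
      b <- core$block
      cfg$slots <- list(x = length(blocks[[b]]))
      cfg$shift <- NULL; cfg$lut <- NULL
      cfg$block <- b
      cfg$out <- list(list(kind = "p2p", dest = id_step("5", block = b), slot = "x"))
    } else if (core$step == "5") {
      b <- core$block
      cfg$slots <- list(scalar = 1L, x = length(blocks[[b]]))
      cfg$shift <- chain$shifts[["step5"]]; cfg$lut <- chain$luts$step5
      cfg$block <- b
      cfg$out <- list(list(kind = "rate_out", out_ids = blocks[[b]]))
    }
    cores[[core$id]] <- cfg
  }

  structure(list(cores = cores, placement = placement, chain = chain,
                 H = H, W = W, N = N,
                 blocks = blocks, block_of = block_of,
                 pos_in_block = pos_in_block,
                 slice_in_ids = slice_in_ids, pos_in_slice = pos_in_slice,
                 slot_of = slot_of,
                 chains = chains, chain_head = chain_head,
                 step2_heads = id_step("2", copy = 1L),
                 step1_heads = chain_head[seq_len(n_cs)]),
            class = "chip")
}

#' Dendrite integration of one core
#'
#' Table-of-operations semantics: VMM `y = W x`; VVM elementwise product of
#' exactly two stored vectors; VVA elementwise sum of up to 128 stored
#' vectors; VS stored vector times the scalar from the axon; VB copy.
#' Accumulation is checked against the accumulator width.
#'
#' @param cfg core config from [build_chip()]
#' @param buf named list of operand vectors (the core's readable bank)
#' @param spec a [fixed_point_spec()]
#' @return accumulator vector
#' @export
exec_dendrite <- function(cfg, buf, spec) {
  acc <- switch(cfg$dendrite,
    VMM = as.vector(cfg$weights %*% buf$x),
    VVM = {
      if (length(buf) != 2) stop("VVM requires exactly 2 vectors", call. = FALSE)
      buf$x1 * buf$x2
    },
    VVA = {
      if (length(buf) > 128) stop("VVA supports at most 128 vectors", call. = FALSE)
      Reduce(`+`, buf)
    },
    VS = as.numeric(buf$scalar) * buf$x,
    VB = buf$x,
    stop(sprintf("unknown dendrite op %s", cfg$dendrite), call. = FALSE))
  lim <- 2^(spec$accum_bits - 1) - 1
  if (max(abs(acc)) > lim) {
    stop(sprintf("core %d: accumulator overflow beyond %d bits", cfg$id, spec$accum_bits),
         call. = FALSE)
  }
  acc
}

#' Soma transformation of one core
#'
#' Optionally laterally accumulates the accumulator to a running scalar
#' (`y_j = x_j + y_{j-1}`), truncates by the configured arithmetic
#' right-shift to the LUT index width, and applies the table lookup down to
#' I/O width. Cores without a LUT (pure buffers) pass the accumulator
#' through.
#'
#' @param cfg core config
#' @param acc accumulator vector from [exec_dendrite()]
#' @param spec a [fixed_point_spec()]
#' @return output value vector at I/O width
#' @export
exec_soma <- function(cfg, acc, spec) {
  if (isTRUE(cfg$lat_acc)) acc <- sum(acc)
  if (is.null(cfg$lut)) return(acc)
  out <- .lut_apply(acc, cfg$shift, cfg$lut, spec)
  as.numeric(out)
}

#' Deliver routed packets into core buffers
#'
#' Point-to-point packets write their payload at the target slot positions
#' of the destination core. A packet addressed to the head of an
#' adjacent-multicast chain is relayed unchanged along the whole chain, so
#' every member receives the same payload. Same-phase write collisions on a
#' (core, slot, position) cell violate the single-writer contract and raise
#' an error.
#'
#' @param packets list of packets `list(dest, slot, pos, values, amc)`
#' @param chip a [build_chip()] object
#' @param bufs current buffer state (list per core of named slot vectors)
#' @return updated buffer state
#' @export
route <- function(packets, chip, bufs) {
  written <- new.env(hash = TRUE)
  for (pk in packets) {
    dests <- pk$dest
    if (isTRUE(pk$amc)) {
      ci <- which(vapply(chip$chains, function(ch) ch[1] == pk$dest, logical(1)))
      if (length(ci) == 1) dests <- chip$chains[[ci]]
    }
    for (d in dests) {
      slot <- bufs[[d]][[pk$slot]]
      if (is.null(slot)) {
        stop(sprintf("route: core %d has no slot %s", d, pk$slot), call. = FALSE)
      }
      if (max(pk$pos) > length(slot)) {
        stop(sprintf("route: write past bank capacity at core %d slot %s", d, pk$slot),
             call. = FALSE)
      }
      key <- paste0(d, ".", pk$slot)
      seen <- written[[key]]
      if (any(pk$pos %in% seen)) {
        stop(sprintf("route: same-phase write collision at core %d slot %s", d, pk$slot),
             call. = FALSE)
      }
      written[[key]] <- c(seen, pk$pos)
      slot[pk$pos] <- pk$values
      bufs[[d]][[pk$slot]] <- slot
    }
  }
  bufs
}

# empty (zeroed) buffers for every core
.init_bufs <- function(chip) {
  lapply(chip$cores, function(cfg) {
    lapply(cfg$slots, function(len) numeric(len))
  })
}

# packets distributing a global rate grid to the step-1 chain heads
.rate_packets <- function(chip, r_vec) {
  lapply(seq_along(chip$step1_heads), function(j) {
    ids <- chip$slice_in_ids[[j]]
    list(dest = chip$step1_heads[j], slot = "x",
         pos = seq_along(ids), values = r_vec[ids], amc = TRUE)
  })
}

# packets distributing the stimulus to the step-2 chain heads (relayed to
# the second copy over the chain)
.stim_packets <- function(chip, stim_vec) {
  lapply(seq_along(chip$blocks), function(b) {
    ids <- chip$blocks[[b]]
    list(dest = chip$step2_heads[b], slot = "stim",
         pos = seq_along(ids), values = stim_vec[ids], amc = TRUE)
  })
}

#' Run the mapped network
#'
#' Executes `n_iter` iterations of five phases per difference frame on the
#' instantiated chip: step-1 VMM cores consume the rates shared over their
#' slice chains; step-2 cores integrate partial potentials and stimulus;
#' step-3 cores square; step-4 cores produce the inhibition scalar and the
#' delayed squared potential; step-5 cores emit the next rates, which are
#' routed back to step 1. Bit-exact against the direct quantized pipeline.
#'
#' @param chip a [build_chip()] object
#' @param stimuli list of float stimulus matrices (quantized at the chain's
#'   stimulus scale)
#' @param r0_int initial integer rate matrix
#' @param n_iter iterations per frame
#' @param trace if `TRUE`, per-phase execution records (core, op, checksum)
#'   are collected
#' @return list with `r_frames`, `r_iters` (integer H x W rate grids),
#'   `phases` (total phase count), and `trace`
#' @export
run_mapped_network <- function(chip, stimuli, r0_int, n_iter, trace = FALSE) {
  spec <- chip$chain$spec
  bufs <- .init_bufs(chip)
  bufs <- route(.rate_packets(chip, as.vector(r0_int)), chip, bufs)
  step_of_phase <- list("1", "2", "3", c("4-1", "4-2"), "5")
  cs <- chip$placement$cores
  r_frames <- vector("list", length(stimuli))
  r_iters <- list()
  phases <- 0L
  tr <- if (trace) list() else NULL

  for (t in seq_along(stimuli)) {
    stim_int <- quantize_array(stimuli[[t]], chip$chain$rho_ext, spec$io_bits)
    bufs <- route(.stim_packets(chip, as.vector(stim_int)), chip, bufs)
    for (it in seq_len(n_iter)) {
      r_grid <- matrix(NA_real_, chip$H, chip$W)
      for (ph in seq_along(step_of_phase)) {
        phases <- phases + 1L
        active <- cs$id[cs$step %in% step_of_phase[[ph]]]
        packets <- list()
        for (cid in active) {
          cfg <- chip$cores[[cid]]
          acc <- exec_dendrite(cfg, bufs[[cid]], spec)
          out <- exec_soma(cfg, acc, spec)
          if (trace) {
            tr[[length(tr) + 1L]] <- data.frame(
              phase = phases, core = cid, op = cfg$dendrite, checksum = sum(out))
          }
          for (edge in cfg$out) {
            if (edge$kind == "partial") {
              # scatter partial potentials to both step-2 copies by chain;
              # the slot a contribution lands in depends on the order of the
              # destination neuron's contributing slices
              blk <- chip$block_of[edge$out_ids]
              slot_k <- chip$slot_of[cbind(edge$out_ids, edge$slice)]
              for (grp in split(seq_along(edge$out_ids),
                                paste0(blk, ".", slot_k))) {
                b <- blk[grp[1]]
                packets[[length(packets) + 1L]] <- list(
                  dest = chip$step2_heads[b],
                  slot = paste0("p", slot_k[grp[1]]),
                  pos = chip$pos_in_block[edge$out_ids[grp]],
                  values = out[grp], amc = TRUE)
              }
            } else if (edge$kind == "p2p_chainhead") {
              packets[[length(packets) + 1L]] <- list(
                dest = edge$dest, slot = edge$slot,
                pos = seq_along(out), values = out, amc = TRUE)
            } else if (edge$kind == "p2p") {
              packets[[length(packets) + 1L]] <- list(
                dest = edge$dest, slot = edge$slot,
                pos = seq_along(out), values = out, amc = FALSE)
            } else if (edge$kind == "rate_out") {
              r_grid[edge$out_ids] <- out
              packets[[length(packets) + 1L]] <- list(
                dest = NA, slot = "rate", pos = edge$out_ids, values = out,
                amc = FALSE, rate = TRUE)
            }
          }
        }
        rate_pk <- Filter(function(p) isTRUE(p$rate), packets)
        packets <- Filter(function(p) !isTRUE(p$rate), packets)
        bufs <- route(packets, chip, bufs)
        if (length(rate_pk) > 0) {
          r_vec <- numeric(chip$N)
          for (p in rate_pk) r_vec[p$pos] <- p$values
          bufs <- route(.rate_packets(chip, r_vec), chip, bufs)
        }
      }
      if (anyNA(r_grid)) stop("run_mapped_network: incomplete rate assembly", call. = FALSE)
      r_iters[[length(r_iters) + 1L]] <- r_grid
    }
    r_frames[[t]] <- r_iters[[length(r_iters)]]
  }
  list(r_frames = r_frames, r_iters = r_iters, phases = phases,
       trace = if (trace) do.call(rbind, tr) else NULL)
}
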