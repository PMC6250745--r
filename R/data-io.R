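#' Synthetic scene configuration
#'
#' Describes a deterministic synthetic grayscale sequence: a bright object
#' (square or Gaussian blob) moving over a noisy background, with exact
#' per-frame ground-truth boxes. Stands in for benchmark videos so the whole
#' stack is testable without external data.
#'
#' @param height,width native frame size in pixels
#' @param n_frames number of frames (>= 2 for tracking)
#' @param object_shape `"square"` or `"gaussian"`
#' @param object_size object side length in pixels (box width = height)
#' @param object_intensity peak object intensity (0-255)
#' @param background background gray level (0-255)
#' @param noise_sd additive Gaussian noise sigma (gray levels)
#' @param trajectory `"linear"`, `"sine"` or `"random-walk"`
#' @param speed pixels per frame: `(dy, dx)` for linear, amplitude of the
#'   per-frame step otherwise
#' @param start `(row, col)` object centre in frame 1 (0-based); default
#'   frame centre
#' @param occlusion optional list(frames = integer vector) of frames where
#'   the object is hidden (drawn at background level)
#' @param seed RNG seed; output is a pure function of this configuration
#' @return an object of class `synthetic_scene_config`
#' @export
synthetic_scene_config <- function(height = 120, width = 160, n_frames = 40,
                                   object_shape = c("square", "gaussian"),
                                   object_size = 16,
                                   object_intensity = 210,
                                   background = 40, noise_sd = 4,
                                   trajectory = c("linear", "sine", "random-walk"),
                                   speed = c(1, 2), start = NULL,
                                   occlusion = NULL, seed = 1L) {
  object_shape <- match.arg(object_shape)
  trajectory <- match.arg(trajectory)
  if (object_size >= min(height, width)) {
    stop("synthetic_scene_config: object larger than frame", call. = FALSE)
  }
  if (is.null(start)) start <- c(height / 2, width / 2)
  structure(list(height = height, width = width, n_frames = n_frames,
                 object_shape = object_shape, object_size = object_size,
                 object_intensity = object_intensity, background = background,
                 noise_sd = noise_sd, trajectory = trajectory,
                 speed = speed, start = start, occlusion = occlusion,
                 seed = as.integer(seed)),
            class = "synthetic_scene_config")
}

# reflect a coordinate into [lo, hi] (bouncing boundary)
.reflect <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

#' Generate a synthetic video with ground truth
#'
#' @param cfg a [synthetic_scene_config()]
#' @return list with `frames` (list of height x width matrices, 0-255) and
#'   `gt` (data.frame of `(x, y, w, h)` boxes, 0-based top-left origin, one
#'   row per frame)
#' @export
generate_synthetic_video <- function(cfg) {
  set.seed(cfg$seed)
  H <- cfg$height; W <- cfg$width; n <- cfg$n_frames
  half <- cfg$object_size / 2
  # trajectory of object centres (0-based), reflected to keep the object
  # fully inside the frame
  t <- seq_len(n) - 1
  ctr <- switch(cfg$trajectory,
    linear = cbind(cfg$start[1] + cfg$speed[1] * t,
                   cfg$start[2] + cfg$speed[2] * t),
    sine = cbind(cfg$start[1] + (H / 4) * sin(2 * pi * t / max(n - 1, 1)),
                 cfg$start[2] + cfg$speed[2] * t),
    `random-walk` = {
      steps <- matrix(stats::rnorm(2 * n, sd = max(cfg$speed)), n, 2)
      steps[1, ] <- 0
      cbind(cfg$start[1] + cumsum(steps[, 1]),
            cfg$start[2] + cumsum(steps[, 2]))
    })
  ctr[, 1] <- .reflect(ctr[, 1], half, H - half)
  ctr[, 2] <- .reflect(ctr[, 2], half, W - half)

  occl <- if (!is.null(cfg$occlusion)) cfg$occlusion$frames else integer(0)
  rows <- seq_len(H) - 1; cols <- seq_len(W) - 1
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    f <- matrix(cfg$background, H, W)
    if (!(i %in% occl)) {
      if (cfg$object_shape == "square") {
        rsel <- rows >= ctr[i, 1] - half & rows < ctr[i, 1] + half
        csel <- cols >= ctr[i, 2] - half & cols < ctr[i, 2] + half
        f[rsel, csel] <- cfg$object_intensity
      } else {
        sig <- cfg$object_size / 4
        g <- outer(exp(-(rows - ctr[i, 1])^2 / (2 * sig^2)),
                   exp(-(cols - ctr[i, 2])^2 / (2 * sig^2)))
        f <- f + (cfg$object_intensity - cfg$background) * g
      }
    }
    if (cfg$noise_sd > 0) {
      f <- f + matrix(stats::rnorm(H * W, sd = cfg$noise_sd), H, W)
    }
    frames[[i]] <- pmin(pmax(f, 0), 255)
  }
  gt <- data.frame(x = ctr[, 2] - half, y = ctr[, 1] - half,
                   w = cfg$object_size, h = cfg$object_size)
  list(frames = frames, gt = gt)
}

#' Write a sequence in OTB folder layout
#'
#' Writes `<path>/img/%04d.png` frames plus `<path>/groundtruth_rect.txt`
#' with one `x,y,w,h` line per frame (1-based top-left origin, the OTB
#' convention).
#'
#' @param video list with `frames` and `gt` as from
#'   [generate_synthetic_video()]
#' @param path output sequence directory
#' @return `path`, invisibly
#' @export
write_otb_sequence <- function(video, path) {
  img_dir <- file.path(path, "img")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(video$frames)) {
    png::writePNG(video$frames[[i]] / 255,
                  file.path(img_dir, sprintf("%04d.png", i)))
  }
  gt <- video$gt
  lines <- sprintf("%g,%g,%g,%g", gt$x + 1, gt$y + 1, gt$w, gt$h)
  writeLines(lines, file.path(path, "groundtruth_rect.txt"))
  invisible(path)
}

# ITU-R 601 luma conversion for H x W x 3 arrays; pass-through for matrices
.to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3) {
    ch <- dim(img)[3]
    if (ch >= 3) {
      return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
    }
    return(img[, , 1])
  }
  stop("unsupported image array", call. = FALSE)
}

#' Load an OTB-convention sequence
#'
#' Reads `<path>/img/*.png` frames (sorted by index) and the per-frame
#' ground-truth rectangles from `groundtruth_rect.txt` (or the first
#' `groundtruth_rect*` file found). Box lines may be comma-, tab- or
#' space-delimited; 1-based OTB box origins are converted to the package's
#' 0-based convention. Color frames are converted to grayscale with ITU-R
#' 601 luma weights.
#'
#' @param path sequence directory
#' @return list with `frames` (grayscale matrices, 0-255) and `gt`
#'   (data.frame `(x, y, w, h)`, 0-based)
#' @export
load_otb_sequence <- function(path) {
  img_dir <- file.path(path, "img")
  files <- list.files(img_dir, pattern = "\\.(png|PNG)$", full.names = TRUE)
  if (length(files) == 0) {
    stop(sprintf("load_otb_sequence: no frames found under %s", img_dir), call. = FALSE)
  }
  files <- files[order(as.integer(sub("\\D*(\\d+)\\..*$", "\\1", basename(files))))]
  frames <- lapply(files, function(f) .to_gray(png::readPNG(f)) * 255)
  sizes <- vapply(frames, dim, integer(2))
  if (any(sizes[1, ] != sizes[1, 1]) || any(sizes[2, ] != sizes[2, 1])) {
    stop("load_otb_sequence: non-uniform frame sizes", call. = FALSE)
  }
  gt_file <- file.path(path, "groundtruth_rect.txt")
  if (!file.exists(gt_file)) {
    cand <- list.files(path, pattern = "^groundtruth_rect", full.names = TRUE)
    if (length(cand) == 0) {
      stop(sprintf("load_otb_sequence: missing ground-truth file in %s", path), call. = FALSE)
    }
    gt_file <- cand[1]
  }
  lines <- readLines(gt_file)
  lines <- lines[nzchar(trimws(lines))]
  vals <- lapply(strsplit(lines, "[,\t ]+"), as.numeric)
  if (any(vapply(vals, length, 1L) < 4) || anyNA(unlist(vals))) {
    stop(sprintf("load_otb_sequence: malformed box line in %s", gt_file), call. = FALSE)
  }
  gt <- do.call(rbind, lapply(vals, function(v) v[1:4]))
  if (nrow(gt) != length(frames)) {
    stop(sprintf("load_otb_sequence: %d frames but %d boxes in %s",
                 length(frames), nrow(gt), gt_file), call. = FALSE)
  }
  gt <- data.frame(x = gt[, 1] - 1, y = gt[, 2] - 1, w = gt[, 3], h = gt[, 4])
  list(frames = frames, gt = gt)
}

# resampling weight matrix mapping n_in samples to n_out (rows: out, cols:
# in); triangle (bilinear) kernel, widened by the scale ratio when
# downsampling so that decimation is antialiased (area-average in the limit)
.resample_matrix <- function(n_in, n_out) {
  if (n_in == n_out) return(diag(n_in))
  ratio <- n_out / n_in
  s <- min(ratio, 1)
  Wm <- matrix(0, n_out, n_in)
  for (o in seq_len(n_out)) {
    c_in <- (o - 0.5) / ratio - 0.5       # 0-based input coordinate
    lo <- floor(c_in - 1 / s); hi <- ceiling(c_in + 1 / s)
    idx <- lo:hi
    wt <- s * pmax(0, 1 - abs(s * (idx - c_in)))
    idx <- pmin(pmax(idx, 0), n_in - 1)   # clamp at the border
    for (m in seq_along(idx)) {
      Wm[o, idx[m] + 1] <- Wm[o, idx[m] + 1] + wt[m]
    }
  }
  sweep(Wm, 1, rowSums(Wm), "/")
}

#' Resize frames to the network grid
#'
#' Separable antialiased bilinear resampling of each frame to H x W. The
#' native-to-grid scale factors are attached for coordinate mapping.
#'
#' @param frames list of native-resolution matrices
#' @param grid a [grid_spec()]
#' @return list of H x W matrices with attribute `scale` =
#'   `(native_H/H, native_W/W)`
#' @export
resize_to_grid <- function(frames, grid) {
  H0 <- nrow(frames[[1]]); W0 <- ncol(frames[[1]])
  Mr <- .resample_matrix(H0, grid$height)
  Mc <- t(.resample_matrix(W0, grid$width))
  out <- lapply(frames, function(f) Mr %*% f %*% Mc)
  attr(out, "scale") <- c(H0 / grid$height, W0 / grid$width)
  out
}

#' Frame-difference stimulus encoding
#'
#' The network's external stimulus is the signed difference of adjacent
#' (already resized) frames: `stimulus_t = frame_{t+1} - frame_t`, scaled by
#' `gain`. T frames yield T - 1 stimuli.
#'
#' @param frames list of >= 2 equally sized matrices
#' @param gain multiplicative stimulus gain (default 1)
#' @return list of T - 1 signed stimulus matrices (attribute `scale`
#'   propagated if present)
#' @export
difference_frames <- function(frames, gain = 1) {
  if (length(frames) < 2) {
    stop("difference_frames: need at least two frames", call. = FALSE)
  }
  out <- lapply(seq_len(length(frames) - 1), function(t) {
    gain * (frames[[t + 1]] - frames[[t]])
  })
  attr(out, "scale") <- attr(frames, "scale")
  out
}
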