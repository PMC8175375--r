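#' Construct a cine loop
#'
#' A cine loop is an ordered stack of 2-D 8-bit grayscale frames together
#' with the acquisition frame rate. All downstream quantification (TIC
#' extraction, AUC, phase segmentation) operates on this representation.
#'
#' @param frames 3-D integer array, `time x rows x cols`, values in 0..255.
#' @param frame_rate_hz Positive frame rate in frames per second. The frame
#'   rate is always caller-supplied metadata: scanner exports report it
#'   inconsistently, so it is never inferred from the file.
#' @param origin_time_s Time of frame 0 in seconds relative to contrast
#'   injection; 0 when unknown or when the recording started at injection.
#' @return An object of class `cine_loop` with fields `frames`,
#'   `frame_rate_hz`, `origin_time_s`.
#' @export
cine_loop <- function(frames, frame_rate_hz, origin_time_s = 0) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("`frames` must be a 3-D array (time x rows x cols)", call. = FALSE)
  }
  if (dim(frames)[1] < 1L || dim(frames)[2] < 1L || dim(frames)[3] < 1L) {
    stop("cine loop must contain at least one non-empty frame", call. = FALSE)
  }
  if (anyNA(frames)) stop("cine frames contain missing values", call. = FALSE)
  if (any(frames < 0) || any(frames > 255)) {
    stop("cine intensities must lie in [0, 255]", call. = FALSE)
  }
  if (any(frames != round(frames))) {
    stop("cine intensities must be integers; use to_grayscale_8bit() first",
         call. = FALSE)
  }
  if (!is.numeric(frame_rate_hz) || length(frame_rate_hz) != 1L ||
      !is.finite(frame_rate_hz) || frame_rate_hz <= 0) {
    stop("`frame_rate_hz` must be a positive number", call. = FALSE)
  }
  if (!is.numeric(origin_time_s) || length(origin_time_s) != 1L ||
      !is.finite(origin_time_s)) {
    stop("`origin_time_s` must be a finite number", call. = FALSE)
  }
  storage.mode(frames) <- "integer"
  structure(
    list(frames = frames,
         frame_rate_hz = as.numeric(frame_rate_hz),
         origin_time_s = as.numeric(origin_time_s)),
    class = "cine_loop"
  )
}

#' @export
print.cine_loop <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<cine_loop> %d frames of %dx%d px, %.6g Hz (%.3g s), origin %.6g s\n",
              d[1], d[2], d[3], x$frame_rate_hz, n_frames(x) / x$frame_rate_hz,
              x$origin_time_s))
  invisible(x)
}

#' Number of frames in a cine loop
#' @param cine A `cine_loop`.
#' @return Integer frame count.
#' @export
n_frames <- function(cine) {
  stopifnot(inherits(cine, "cine_loop"))
  dim(cine$frames)[1]
}

#' Frame acquisition times of a cine loop
#' @param cine A `cine_loop`.
#' @return Numeric vector, `origin_time_s + (0:(n-1)) / frame_rate_hz`.
#' @export
frame_times <- function(cine) {
  stopifnot(inherits(cine, "cine_loop"))
  cine$origin_time_s + (seq_len(n_frames(cine)) - 1) / cine$frame_rate_hz
}

#' Duration of a cine loop
#'
#' Total recorded timespan, `n_frames / frame_rate_hz` seconds (the span
#' covered by the frames, counting each frame as one sampling interval).
#'
#' @param cine A `cine_loop`.
#' @return Duration in seconds.
#' @export
cine_duration_s <- function(cine) {
  n_frames(cine) / cine$frame_rate_hz
}

# round half away from zero; base round() is half-to-even
round_half_up <- function(x) floor(x + 0.5)

#' Convert an intensity stack to the canonical 8-bit grayscale form
#'
#' RGB stacks (trailing 3-channel axis) are collapsed with ITU-R BT.601 luma
#' weights (0.299, 0.587, 0.114), rounded half-up and clipped to 0..255.
#' Single-channel input already inside [0, 255] is kept as is (rounded to
#' integers); single-channel input with values outside that range is linearly
#' rescaled from its min-max range to [0, 255], a constant stack mapping to
#' all zeros.
#'
#' @param frames 3-D array (`time x rows x cols`) or 4-D array with a
#'   trailing channel axis of size 1 or 3.
#' @return 3-D integer array in 0..255, same leading dimensions.
#' @export
to_grayscale_8bit <- function(frames) {
  if (!is.array(frames) || !(length(dim(frames)) %in% c(3L, 4L))) {
    stop("`frames` must be a 3-D or 4-D array", call. = FALSE)
  }
  d <- dim(frames)
  if (length(d) == 4L) {
    if (d[4] == 1L) {
      frames <- array(frames, dim = d[1:3])
    } else if (d[4] == 3L) {
      y <- 0.299 * frames[, , , 1, drop = FALSE] +
           0.587 * frames[, , , 2, drop = FALSE] +
           0.114 * frames[, , , 3, drop = FALSE]
      y <- round_half_up(y)
      y[y < 0] <- 0
      y[y > 255] <- 255
      out <- array(as.integer(y), dim = d[1:3])
      return(out)
    } else {
      stop("channel axis must have size 1 or 3, got ", d[4], call. = FALSE)
    }
  }
  if (anyNA(frames)) stop("frames contain missing values", call. = FALSE)
  rng <- range(frames)
  if (rng[1] < 0 || rng[2] > 255) {
    span <- rng[2] - rng[1]
    if (span == 0) {
      frames <- array(0, dim = dim(frames))
    } else {
      frames <- (frames - rng[1]) / span * 255
    }
  }
  out <- round_half_up(frames)
  out[out < 0] <- 0
  out[out > 255] <- 255
  storage.mode(out) <- "integer"
  out
}

#' Load a cine loop from a multi-page TIFF
#'
#' Each TIFF page becomes one frame, in page order. RGB pages are converted
#' to 8-bit grayscale via [to_grayscale_8bit()]; pages stored at a higher
#' bit depth are rescaled into the 8-bit range.
#'
#' @param path Path to a readable multi-page TIFF.
#' @param frame_rate_hz Positive frame rate (frames per second); always
#'   supplied by the caller, never parsed from the file.
#' @param origin_time_s Time of frame 0 relative to injection (default 0).
#' @return A [cine_loop()].
#' @export
load_cine <- function(path, frame_rate_hz, origin_time_s = 0) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("cannot read cine: no such file: ", path, call. = FALSE)
  }
  if (!is.numeric(frame_rate_hz) || length(frame_rate_hz) != 1L ||
      !is.finite(frame_rate_hz) || frame_rate_hz <= 0) {
    stop("`frame_rate_hz` must be a positive number", call. = FALSE)
  }
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) {
      stop("failed to read TIFF '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("TIFF '", path, "' has zero pages", call. = FALSE)

  dims <- lapply(pages, function(p) dim(p)[1:2])
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    stop("TIFF pages differ in height/width: ", path, call. = FALSE)
  }
  nr <- dims[[1]][1]; nc <- dims[[1]][2]
  n <- length(pages)

  # readTIFF returns normalized doubles in [0,1] for some sample formats
  # (notably RGB) even with as.is = TRUE; undo that before conversion.
  pages <- lapply(pages, function(p) {
    if (is.double(p) && max(p) <= 1 && min(p) >= 0) p * 255 else p
  })

  nchan <- vapply(pages, function(p) {
    if (length(dim(p)) == 3L) dim(p)[3] else 1L
  }, integer(1))
  if (length(unique(nchan)) != 1L) {
    stop("TIFF pages differ in channel count: ", path, call. = FALSE)
  }
  if (nchan[1] == 1L || nchan[1] == 3L) {
    stack <- array(0, dim = c(n, nr, nc, nchan[1]))
    for (k in seq_len(n)) {
      stack[k, , , ] <- if (nchan[1] == 1L) pages[[k]] else pages[[k]][, , 1:3]
    }
    frames <- to_grayscale_8bit(stack)
  } else if (nchan[1] == 4L) {
    stack <- array(0, dim = c(n, nr, nc, 3L))  # drop alpha
    for (k in seq_len(n)) stack[k, , , ] <- pages[[k]][, , 1:3]
    frames <- to_grayscale_8bit(stack)
  } else {
    stop("unsupported channel count ", nchan[1], " in ", path, call. = FALSE)
  }
  cine_loop(frames, frame_rate_hz, origin_time_s)
}

#' Write a cine loop to a multi-page 8-bit grayscale TIFF
#'
#' One page per frame; `load_cine(save_cine(x, p), fps)` reproduces the
#' frame stack bit-exactly.
#'
#' @param cine A [cine_loop()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_cine <- function(cine, path) {
  stopifnot(inherits(cine, "cine_loop"))
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("cannot write cine: no such directory: ", dir, call. = FALSE)
  }
  pages <- lapply(seq_len(n_frames(cine)), function(k) {
    matrix(cine$frames[k, , ] / 255,
           nrow = dim(cine$frames)[2], ncol = dim(cine$frames)[3])
  })
  ok <- tryCatch(
    tiff::writeTIFF(pages, path, bits.per.sample = 8L),
    error = function(e) {
      stop("failed to write TIFF '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  invisible(path)
}
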