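#' Construct a time-intensity curve
#'
#' A TIC is the mean 8-bit ROI intensity per frame, divided by 255 so that
#' all reported intensities live in [0, 1] ("arbitrary units"), against the
#' frame acquisition times in seconds.
#'
#' @param times_s Strictly increasing numeric times in seconds.
#' @param intensities Numeric intensities in [0, 1], same length.
#' @param roi_label Tissue tag of the ROI the curve was extracted from.
#' @param patient_id Free-text patient identifier.
#' @return An object of class `tic`.
#' @export
tic <- function(times_s, intensities, roi_label = "other:unlabelled",
                patient_id = "") {
  if (length(times_s) != length(intensities)) {
    stop("times and intensities must have equal length", call. = FALSE)
  }
  if (length(times_s) < 1L) stop("TIC must be non-empty", call. = FALSE)
  if (anyNA(times_s) || anyNA(intensities)) {
    stop("TIC contains missing values", call. = FALSE)
  }
  if (length(times_s) > 1L && any(diff(times_s) <= 0)) {
    stop("TIC times must be strictly increasing", call. = FALSE)
  }
  if (any(intensities < 0) || any(intensities > 1)) {
    stop("TIC intensities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(times_s = as.numeric(times_s),
                 intensities = as.numeric(intensities),
                 roi_label = roi_label, patient_id = patient_id),
            class = "tic")
}

#' @export
print.tic <- function(x, ...) {
  cat(sprintf("<tic> %s%s: %d frames, t = [%.3g, %.3g] s, I = [%.4g, %.4g]\n",
              if (nzchar(x$patient_id)) paste0(x$patient_id, " / ") else "",
              x$roi_label, length(x$times_s), min(x$times_s), max(x$times_s),
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
as.data.frame.tic <- function(x, ...) {
  data.frame(patient_id = x$patient_id, roi_label = x$roi_label,
             frame_index = seq_along(x$times_s) - 1L,
             time_s = x$times_s, intensity = x$intensities)
}

#' Extract the time-intensity curve of an ROI
#'
#' For every frame, the arithmetic mean of the 8-bit intensities over the
#' ROI's pixel mask, divided by 255.
#'
#' @param cine A [cine_loop()].
#' @param roi A `ceus_roi` (rasterized against the cine's frame shape).
#' @param patient_id Patient identifier carried on the curve.
#' @return A [tic()].
#' @export
extract_tic <- function(cine, roi, patient_id = "") {
  stopifnot(inherits(cine, "cine_loop"), inherits(roi, "ceus_roi"))
  shape <- dim(cine$frames)[2:3]
  rm <- tryCatch(rasterize(roi, shape), error = function(e) {
    stop("ROI '", roi$label, "': ", conditionMessage(e), call. = FALSE)
  })
  n <- n_frames(cine)
  flat <- matrix(cine$frames, nrow = n)  # frame-major: column = pixel
  sel <- as.vector(rm$mask)
  means <- rowMeans(flat[, sel, drop = FALSE])
  tic(frame_times(cine), means / 255, roi_label = roi$label,
      patient_id = patient_id)
}

#' Optional moving-average smoothing of a TIC
#'
#' Centered moving average of odd width; endpoints use the partial window.
#' Peak extraction operates on the raw curve by default — smoothing is
#' offered for noisy single-pixel ROIs and is off unless requested.
#'
#' @param x A [tic()].
#' @param width Odd window width in frames; `width <= 1` returns the input.
#' @return A smoothed [tic()].
#' @export
smooth_tic <- function(x, width = 5L) {
  stopifnot(inherits(x, "tic"))
  if (width <= 1L) return(x)
  if (width %% 2L == 0L) stop("smoothing width must be odd", call. = FALSE)
  h <- (width - 1L) %/% 2L
  n <- length(x$intensities)
  sm <- vapply(seq_len(n), function(i) {
    mean(x$intensities[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
  tic(x$times_s, sm, x$roi_label, x$patient_id)
}

#' Peak enhancement of a TIC
#'
#' The maximum intensity of the curve and the time of the earliest frame
#' attaining it (ties break to the earliest frame).
#'
#' @param x A [tic()].
#' @return List with `pe` (intensity in [0, 1]) and `peak_time_s`.
#' @export
peak_enhancement <- function(x) {
  stopifnot(inherits(x, "tic"))
  i <- which.max(x$intensities)
  list(pe = x$intensities[i], peak_time_s = x$times_s[i], peak_index = i - 1L)
}

#' Area under a time-intensity curve
#'
#' Trapezoidal integral of intensity over time in seconds, so the value is
#' invariant to the frame rate. By default no baseline is subtracted (the
#' raw integral of the curve); with `baseline_subtract = TRUE` the
#' integrand is `max(intensity - baseline, 0)`.
#'
#' @param x A [tic()] with at least 2 points.
#' @param baseline_subtract Subtract a baseline before integrating?
#' @param baseline Baseline level in [0, 1] used when subtracting.
#' @return Intensity-seconds, >= 0.
#' @export
tic_auc <- function(x, baseline_subtract = FALSE, baseline = 0) {
  stopifnot(inherits(x, "tic"))
  if (length(x$times_s) < 2L) {
    stop("AUC needs a TIC with at least 2 points", call. = FALSE)
  }
  y <- if (baseline_subtract) pmax(x$intensities - baseline, 0) else
    x$intensities
  pracma::trapz(x$times_s, y)
}

#' Artery-normalized AUC
#'
#' Ratio of a tissue TIC's AUC to the same clip's arterial AUC. Dividing by
#' the arterial integral compensates for acquisition durations that differ
#' between patients.
#'
#' @param tissue_tic,artery_tic [tic()]s extracted from the same cine
#'   (identical time axes).
#' @return Non-negative ratio; the artery against itself gives exactly 1.
#' @export
normalized_auc <- function(tissue_tic, artery_tic) {
  stopifnot(inherits(tissue_tic, "tic"), inherits(artery_tic, "tic"))
  if (length(tissue_tic$times_s) != length(artery_tic$times_s) ||
      !isTRUE(all.equal(tissue_tic$times_s, artery_tic$times_s,
                        tolerance = 1e-9))) {
    stop("tissue and artery TICs have mismatched time axes", call. = FALSE)
  }
  a <- tic_auc(artery_tic)
  if (a == 0) {
    stop("degenerate artery reference: arterial AUC is zero", call. = FALSE)
  }
  tic_auc(tissue_tic) / a
}

#' Detect contrast arrival on a TIC
#'
#' The baseline level is the mean of the first `baseline_frames`
#' intensities; arrival is the time of the first frame that begins a run of
#' at least `min_consecutive` frames all exceeding
#' `baseline + k_sigma * sd(baseline window)`. When no such run exists —
#' a flat curve, or a recording started after the bolus — arrival is
#' reported absent (`NA`) and downstream phase segmentation degrades
#' gracefully.
#'
#' @param x A [tic()] longer than the baseline window.
#' @param baseline_frames Frames in the baseline window (>= 2).
#' @param k_sigma Detection threshold in baseline standard deviations.
#' @param min_consecutive Frames a super-threshold run must last.
#' @return List with `arrival_time_s` (`NA` when absent), `arrival_index`
#'   (0-based, `NA` when absent), `baseline`, `threshold`.
#' @export
detect_arrival <- function(x, baseline_frames = 10L, k_sigma = 4,
                           min_consecutive = 3L) {
  stopifnot(inherits(x, "tic"))
  if (baseline_frames < 2L) {
    stop("baseline window must contain at least 2 frames", call. = FALSE)
  }
  n <- length(x$intensities)
  if (n <= baseline_frames) {
    stop("TIC (", n, " frames) is not longer than the baseline window (",
         baseline_frames, ")", call. = FALSE)
  }
  bwin <- x$intensities[seq_len(baseline_frames)]
  baseline <- mean(bwin)
  thr <- baseline + k_sigma * stats::sd(bwin)
  above <- x$intensities > thr
  # first index starting a run of >= min_consecutive TRUEs
  run <- 0L
  start <- NA_integer_
  for (i in seq_len(n)) {
    if (above[i]) {
      run <- run + 1L
      if (run == min_consecutive) {
        start <- i - min_consecutive + 1L
        break
      }
    } else run <- 0L
  }
  if (is.na(start)) {
    list(arrival_time_s = NA_real_, arrival_index = NA_integer_,
         baseline = baseline, threshold = thr)
  } else {
    list(arrival_time_s = x$times_s[start], arrival_index = start - 1L,
         baseline = baseline, threshold = thr)
  }
}

#' Segment a TIC into the five bolus phases
#'
#' The bolus passage is partitioned into baseline, wash-in, peak, early
#' wash-out and late wash-out. Baseline runs up to (not including) the
#' arrival frame; wash-in from arrival to the earliest peak frame; the peak
#' is that single frame; early wash-out extends until the intensity first
#' falls below `baseline + washout_fraction * (PE - baseline)`; late
#' wash-out is the remainder. When the curve never falls below the cut,
#' early wash-out extends to the last frame and late wash-out is empty.
#'
#' @param x A [tic()].
#' @param arrival Result of [detect_arrival()] on the same curve; arrival
#'   must be present.
#' @param washout_fraction Fraction of peak-over-baseline defining the
#'   early/late wash-out split (default 0.5, the half-enhancement point).
#' @return An object of class `phase_segmentation`: 0-based boundary
#'   indices `baseline_end` (first wash-in frame), `washin_end` (peak
#'   frame), `early_washout_end` (last early-wash-out frame), `last_frame`,
#'   and `labels`, a factor over frames with levels baseline, wash_in,
#'   peak, early_wash_out, late_wash_out.
#' @export
segment_phases <- function(x, arrival = detect_arrival(x),
                           washout_fraction = 0.5) {
  stopifnot(inherits(x, "tic"))
  if (is.na(arrival$arrival_index)) {
    stop("cannot segment phases: no contrast arrival was detected",
         call. = FALSE)
  }
  if (washout_fraction <= 0 || washout_fraction >= 1) {
    stop("`washout_fraction` must lie in (0, 1)", call. = FALSE)
  }
  n <- length(x$intensities)
  arr <- arrival$arrival_index            # 0-based
  pk <- peak_enhancement(x)
  peak <- pk$peak_index                   # 0-based, earliest maximum
  if (peak < arr) {
    stop("peak precedes detected arrival; segmentation undefined",
         call. = FALSE)
  }
  cut <- arrival$baseline +
    washout_fraction * (pk$pe - arrival$baseline)
  post <- which(x$intensities < cut)      # 1-based frame numbers
  post <- post[post - 1L > peak]
  split <- if (length(post)) post[1] - 1L else n  # 0-based; n => no late phase
  ew_end <- min(split - 1L, n - 1L)
  if (ew_end < peak) ew_end <- peak

  idx <- seq_len(n) - 1L
  labels <- character(n)
  labels[idx < arr] <- "baseline"
  labels[idx >= arr & idx < peak] <- "wash_in"
  labels[idx == peak] <- "peak"
  labels[idx > peak & idx <= ew_end] <- "early_wash_out"
  labels[idx > ew_end] <- "late_wash_out"
  structure(list(baseline_end = arr, washin_end = peak,
                 early_washout_end = ew_end, last_frame = n - 1L,
                 labels = factor(labels, levels = c("baseline", "wash_in",
                                                    "peak", "early_wash_out",
                                                    "late_wash_out"))),
            class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  counts <- table(x$labels)
  cat("<phase_segmentation> frames per phase:\n")
  print(counts)
  invisible(x)
}

#' Threshold highlighting of frames
#'
#' Pixels at or above `upper` are pushed to white (255); pixels at or below
#' `lower` are pushed to black (0); all other intensities pass through. The
#' operation is idempotent and is a display aid to highlight prominently
#' enhancing areas, not a quantification step.
#'
#' @param x A [cine_loop()], a 3-D frame stack, or a single frame matrix.
#' @param lower,upper Integer cut levels in [0, 255] with `lower <= upper`.
#' @return Same type and shape as the input.
#' @export
apply_threshold <- function(x, lower = 0L, upper = 255L) {
  if (lower > upper) stop("`lower` must be <= `upper`", call. = FALSE)
  if (lower < 0 || upper > 255) {
    stop("threshold levels must lie in [0, 255]", call. = FALSE)
  }
  thr <- function(v) {
    v[v >= upper] <- 255L
    v[v <= lower] <- 0L
    v
  }
  if (inherits(x, "cine_loop")) {
    cine_loop(thr(x$frames), x$frame_rate_hz, x$origin_time_s)
  } else {
    thr(x)
  }
}

#' Frame-to-frame motion score
#'
#' Mean absolute intensity difference (8-bit units) between consecutive
#' frames. Probe or tissue motion shows up as an outlying score; a clip is
#' flagged — never silently dropped — when any score exceeds the threshold.
#'
#' @param cine A [cine_loop()] with >= 2 frames.
#' @param threshold Flagging threshold in 8-bit units (default 25).
#' @return List with `scores` (length `n_frames - 1`), `flagged`, and
#'   `max_score`.
#' @export
motion_score <- function(cine, threshold = 25) {
  stopifnot(inherits(cine, "cine_loop"))
  n <- n_frames(cine)
  if (n < 2L) stop("motion score needs at least 2 frames", call. = FALSE)
  flat <- matrix(as.numeric(cine$frames), nrow = n)
  scores <- rowMeans(abs(flat[-1, , drop = FALSE] - flat[-n, , drop = FALSE]))
  list(scores = scores, flagged = any(scores > threshold),
       max_score = max(scores))
}

#' Per-ROI summary of one cine loop
#'
#' Runs the whole per-clip pipeline for a set of ROIs: TIC extraction,
#' peak enhancement, arrival detection, AUC, artery-normalized AUC (when an
#' `artery`-labelled ROI is present; the artery's own normalized AUC is 1 by
#' definition and reported as `NA` to keep it out of cohort comparisons),
#' and the clip-level motion flag.
#'
#' @param cine A [cine_loop()].
#' @param rois List of `ceus_roi`.
#' @param patient_id Patient identifier.
#' @param baseline_frames,k_sigma,min_consecutive Arrival-rule constants,
#'   see [detect_arrival()].
#' @param motion_threshold Motion-flag threshold, see [motion_score()].
#' @return A `data.frame` with one row per ROI: `patient_id`, `roi_label`,
#'   `peak_enhancement`, `peak_time_s`, `baseline`, `arrival_time_s`,
#'   `auc`, `normalized_auc`, `motion_flag`.
#' @export
analyze_cine <- function(cine, rois, patient_id = "",
                         baseline_frames = 10L, k_sigma = 4,
                         min_consecutive = 3L, motion_threshold = 25) {
  stopifnot(inherits(cine, "cine_loop"), is.list(rois), length(rois) >= 1L)
  tics <- lapply(rois, extract_tic, cine = cine, patient_id = patient_id)
  labels <- vapply(tics, `[[`, "", "roi_label")
  artery_tic <- if ("artery" %in% labels) tics[[match("artery", labels)]]
  motion <- motion_score(cine, threshold = motion_threshold)

  rows <- lapply(tics, function(tt) {
    pk <- peak_enhancement(tt)
    arr <- if (length(tt$intensities) > baseline_frames) {
      detect_arrival(tt, baseline_frames, k_sigma, min_consecutive)
    } else {
      list(arrival_time_s = NA_real_, baseline = mean(tt$intensities))
    }
    nauc <- if (!is.null(artery_tic) && tt$roi_label != "artery") {
      normalized_auc(tt, artery_tic)
    } else NA_real_
    data.frame(patient_id = patient_id, roi_label = tt$roi_label,
               peak_enhancement = pk$pe, peak_time_s = pk$peak_time_s,
               baseline = arr$baseline, arrival_time_s = arr$arrival_time_s,
               auc = tic_auc(tt), normalized_auc = nauc,
               motion_flag = motion$flagged)
  })
  do.call(rbind, rows)
}

#' Write TICs to CSV
#'
#' Long format, one row per (curve, frame): `patient_id`, `roi_label`,
#' `frame_index`, `time_s`, `intensity` (6 decimal places).
#'
#' @param tics A [tic()] or list of them.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tics_csv <- function(tics, path) {
  if (inherits(tics, "tic")) tics <- list(tics)
  df <- do.call(rbind, lapply(tics, as.data.frame))
  df$time_s <- sprintf("%.6f", df$time_s)
  df$intensity <- sprintf("%.6f", df$intensity)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
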