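make_tic <- function(y, fps = 10, origin = 0) {
  tic((seq_along(y) - 1) / fps + origin, y)
}

test_that("extract_tic equals the per-pixel brute-force mean", {
  cine <- constant_cine(100L)
  tt <- extract_tic(cine, roi_circle("artery", c(4, 4), 2))
  expect_equal(tt$intensities, rep(100 / 255, 5))

  checker <- array(c(0L, 255L, 255L, 0L), dim = c(1, 2, 2))
  tt <- extract_tic(cine_loop(checker, 10),
                    roi_rectangle("tumor", 0, 0, 2, 2))
  expect_equal(tt$intensities, 0.5)

  withr::local_seed(21)
  frames <- array(sample(0:255, 20 * 16 * 16, replace = TRUE),
                  dim = c(20, 16, 16))
  cine <- cine_loop(frames, 8)
  roi <- roi_polygon("white_matter",
                     cbind(c(2, 3, 13, 14, 8), c(3, 12, 14, 4, 1)))
  tt <- extract_tic(cine, roi, patient_id = "P09")
  expect_equal(tt$intensities,
               oracle_tic_values(frames, oracle_mask(roi, c(16, 16))))
  expect_equal(tt$times_s, (0:19) / 8)
  expect_equal(tt$patient_id, "P09")
})

test_that("peak enhancement takes the maximum, ties to the earliest frame", {
  pk <- peak_enhancement(make_tic(c(0.1, 0.5, 0.3)))
  expect_equal(pk$pe, 0.5)
  expect_equal(pk$peak_time_s, 0.1)

  pk <- peak_enhancement(make_tic(rep(0.25, 8)))
  expect_equal(pk$peak_time_s, 0)
  expect_equal(pk$pe, 0.25)

  pk <- peak_enhancement(make_tic(c(0.1, 0.9, 0.2, 0.9)))
  expect_equal(pk$peak_time_s, 0.1)
})

test_that("AUC matches closed forms and is additive under splitting", {
  const <- make_tic(rep(0.3, 11))  # duration 1 s
  expect_equal(tic_auc(const), 0.3 * 1.0)

  # symmetric triangle 0 -> h -> 0: trapezoid rule is exact on piecewise
  # linear input, area h * T / 2
  h <- 0.8
  tri <- make_tic(h * c(0:5, 4:0) / 5)  # T = 1 s at 10 Hz
  expect_equal(tic_auc(tri), h * 1.0 / 2)

  doubled <- make_tic(2 * 0.4 * c(0:5, 4:0) / 5)
  expect_equal(tic_auc(doubled), 2 * tic_auc(make_tic(0.4 * c(0:5, 4:0) / 5)))

  withr::local_seed(3)
  y <- runif(40)
  full <- make_tic(y)
  for (cut in c(2, 17, 39)) {
    left <- tic(full$times_s[1:cut], y[1:cut])
    right <- tic(full$times_s[cut:40], y[cut:40])
    expect_equal(tic_auc(left) + tic_auc(right), tic_auc(full))
  }

  expect_equal(tic_auc(const, baseline_subtract = TRUE, baseline = 0.1),
               0.2 * 1.0)
  expect_error(tic_auc(tic(0, 0.5)), "at least 2 points")
})

test_that("normalized AUC is a ratio with the documented degeneracies", {
  withr::local_seed(5)
  artery <- make_tic(runif(30, 0.2, 0.9))
  expect_equal(normalized_auc(artery, artery), 1.0)

  half <- tic(artery$times_s, artery$intensities / 2)
  expect_equal(normalized_auc(half, artery), 0.5)

  # jointly rescaling both curves leaves the ratio unchanged
  s <- 0.37
  expect_equal(
    normalized_auc(tic(artery$times_s, s * half$intensities),
                   tic(artery$times_s, s * artery$intensities)),
    normalized_auc(half, artery))

  zero <- tic(artery$times_s, rep(0, 30))
  expect_error(normalized_auc(half, zero), "degenerate artery")
  other <- make_tic(runif(30), fps = 5)
  expect_error(normalized_auc(other, artery), "mismatched time axes")
})

test_that("arrival detection finds steps and stays silent on flat curves", {
  withr::local_seed(9)
  flat <- make_tic(0.1 + rnorm(60, sd = 1e-4))
  expect_true(is.na(detect_arrival(flat)$arrival_time_s))

  step <- make_tic(c(rep(0, 20), rep(0.5, 30)))
  arr <- detect_arrival(step)
  expect_equal(arr$arrival_time_s, 2.0)  # frame 20 at 10 Hz
  expect_equal(arr$arrival_index, 20L)
  expect_equal(arr$baseline, 0)

  expect_error(detect_arrival(make_tic(rep(0.1, 5))), "baseline window")
})

test_that("arrival lands within 3 frames of a sharp bolus onset at SNR 20", {
  # gamma-variate bolus at 10 Hz: onset 2 s, 0.5 s to peak, amplitude 0.8,
  # additive noise sd = amplitude / 20
  spec <- compartment_spec("artery", roi_circle("artery", c(1, 1), 1),
                           baseline = 0.05, amplitude = 0.8, onset_s = 2,
                           time_to_peak_s = 0.5, shape_alpha = 2)
  times <- (0:99) / 10
  clean <- bolus_curve(spec, times)
  for (s in 1:100) {
    withr::local_seed(7000 + s)
    y <- pmin(pmax(clean + rnorm(100, sd = 0.8 / 20), 0), 1)
    arr <- detect_arrival(tic(times, y))
    expect_false(is.na(arr$arrival_time_s), label = sprintf("seed %d", s))
    expect_gte(arr$arrival_time_s, 2.0)
    expect_lte(arr$arrival_time_s, 2.0 + 3 / 10)
  }
})

test_that("phase segmentation partitions the clip in order", {
  # plateau step: wash-in collapses onto the peak frame, no late wash-out
  step <- make_tic(c(rep(0, 15), rep(1, 25)))
  seg <- segment_phases(step, detect_arrival(step))
  expect_equal(seg$baseline_end, 15L)
  expect_equal(seg$washin_end, 15L)
  expect_equal(seg$early_washout_end, 39L)
  expect_equal(sum(seg$labels == "late_wash_out"), 0L)
  expect_equal(as.integer(table(seg$labels)["baseline"]), 15L)

  # triangle: the early/late boundary is the first sample below half-max
  y <- c(rep(0, 12), seq(0, 1, by = 0.1), seq(0.95, 0, by = -0.05))
  tri <- make_tic(y)
  seg <- segment_phases(tri, detect_arrival(tri))
  first_late <- which(seg$labels == "late_wash_out")[1] - 1L  # 0-based
  pk <- peak_enhancement(tri)
  cut <- 0 + 0.5 * pk$pe
  below <- which(y < cut & seq_along(y) - 1 > pk$peak_index)[1] - 1L
  expect_equal(first_late, below)

  # boundaries are monotone and label the whole clip
  expect_true(seg$baseline_end <= seg$washin_end)
  expect_true(seg$washin_end <= seg$early_washout_end)
  expect_true(seg$early_washout_end <= seg$last_frame)
  expect_equal(length(seg$labels), length(y))
  expect_false(anyNA(seg$labels))

  flat <- make_tic(rep(0.1, 30))
  expect_error(segment_phases(flat, detect_arrival(flat)), "no contrast")
})

test_that("threshold highlighting is boundary-exact and idempotent", {
  frames <- array(as.integer(c(0, 50, 200, 255)), dim = c(1, 2, 2))
  cine <- cine_loop(frames, 10)

  all_white <- apply_threshold(cine, lower = 0, upper = 0)
  expect_true(all(all_white$frames == 255L))

  ramp <- array(0:254, dim = c(1, 5, 51))
  out <- apply_threshold(ramp, lower = 0, upper = 255)
  expect_equal(sum(out == 255L), 0L)  # nothing reaches the upper cut

  once <- apply_threshold(cine, lower = 60, upper = 190)
  twice <- apply_threshold(once, lower = 60, upper = 190)
  expect_identical(once$frames, twice$frames)
  expect_equal(as.vector(once$frames), c(0L, 0L, 255L, 255L))

  expect_error(apply_threshold(cine, lower = 100, upper = 50), "<=")
})

test_that("motion score is zero when static and spikes on a frame shift", {
  expect_equal(motion_score(constant_cine(80L))$scores, rep(0, 4))

  withr::local_seed(31)
  base <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32, 32)
  frames <- array(0L, dim = c(6, 32, 32))
  for (k in 1:6) frames[k, , ] <- base
  shifted <- base
  shifted[, 6:32] <- base[, 1:27]  # 5-pixel lateral shift on frame 4
  frames[4, , ] <- shifted
  ms <- motion_score(cine_loop(frames, 10))
  expect_true(all(ms$scores[c(3, 4)] > 0))
  expect_true(min(ms$scores[c(3, 4)]) > max(ms$scores[-c(3, 4)]))
  expect_true(ms$flagged)

  rev_frames <- frames[6:1, , , drop = FALSE]
  expect_equal(rev(motion_score(cine_loop(rev_frames, 10))$scores),
               ms$scores)
  expect_error(motion_score(cine_loop(array(0L, dim = c(1, 2, 2)), 10)),
               "at least 2 frames")
})

test_that("smoothing preserves length and flattens noise", {
  withr::local_seed(13)
  y <- 0.5 + rnorm(50, sd = 0.05)
  noisy <- make_tic(pmin(pmax(y, 0), 1))
  sm <- smooth_tic(noisy, 5)
  expect_equal(length(sm$intensities), 50L)
  expect_lt(sd(sm$intensities), sd(noisy$intensities))
  expect_identical(smooth_tic(noisy, 1), noisy)
  expect_error(smooth_tic(noisy, 4), "odd")
})

test_that("analyze_cine assembles the per-ROI summary with normalization", {
  sim <- generate_cine(default_scene(noise_sigma = 0, duration_s = 40))
  df <- analyze_cine(sim$cine, sim$rois, patient_id = "P01")
  expect_equal(nrow(df), 3L)
  expect_setequal(df$roi_label, c("artery", "tumor", "white_matter"))
  a <- df[df$roi_label == "artery", ]
  expect_true(is.na(a$normalized_auc))
  other <- df[df$roi_label != "artery", ]
  expect_true(all(other$normalized_auc > 0 & other$normalized_auc < 1))
  expect_false(any(df$motion_flag))
  expect_true(all(df$peak_enhancement >= df$baseline))
})
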