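#' Compartment specification for synthetic cines
#'
#' One spatial compartment (a tissue region) of a synthetic bolus-passage
#' cine, with the parameters of its enhancement curve: a gamma-variate
#' wash-in/wash-out kernel plus a saturating tail that creates a
#' distinguishable late-wash-out plateau.
#'
#' @param label Tissue tag (see [roi_circle()] for the accepted set).
#' @param geometry A `ceus_roi` giving the region the compartment occupies.
#' @param baseline Pre-contrast level in [0, 1].
#' @param amplitude Peak enhancement above baseline; `baseline + amplitude`
#'   must not exceed 1.
#' @param onset_s Bolus arrival time in seconds (>= 0, relative to
#'   injection).
#' @param time_to_peak_s Seconds from onset to the gamma-variate peak (> 0).
#' @param shape_alpha Gamma-variate sharpness (> 0); larger is a steeper,
#'   narrower bolus.
#' @param tail_level Late plateau as a fraction of `amplitude` in [0, 1];
#'   0 decays back to baseline.
#' @return An object of class `compartment_spec`.
#' @export
compartment_spec <- function(label, geometry, baseline, amplitude, onset_s,
                             time_to_peak_s, shape_alpha = 2.5,
                             tail_level = 0) {
  stopifnot(inherits(geometry, "ceus_roi"))
  check_label(label)
  if (baseline < 0 || baseline > 1) stop("baseline must be in [0, 1]",
                                         call. = FALSE)
  if (amplitude < 0 || baseline + amplitude > 1) {
    stop("amplitude must satisfy 0 <= amplitude <= 1 - baseline",
         call. = FALSE)
  }
  if (onset_s < 0) stop("onset_s must be >= 0", call. = FALSE)
  if (time_to_peak_s <= 0) stop("time_to_peak_s must be > 0", call. = FALSE)
  if (shape_alpha <= 0) stop("shape_alpha must be > 0", call. = FALSE)
  if (tail_level < 0 || tail_level > 1) {
    stop("tail_level must be in [0, 1]", call. = FALSE)
  }
  structure(list(label = label, geometry = geometry, baseline = baseline,
                 amplitude = amplitude, onset_s = onset_s,
                 time_to_peak_s = time_to_peak_s, shape_alpha = shape_alpha,
                 tail_level = tail_level),
            class = "compartment_spec")
}

#' Model enhancement curve of a compartment
#'
#' For `t <= onset` the curve sits at baseline. Afterwards, with
#' `tau = (t - onset) / time_to_peak`, the enhancement is
#' `baseline + amplitude * ((1 - tail) * tau^alpha * exp(alpha * (1 - tau))
#'  + tail * (1 - exp(-tau)))`, clipped to [0, 1]. The gamma-variate factor
#' peaks at exactly `tau = 1` with value 1, giving a single peak at
#' `onset + time_to_peak` when `tail = 0`; the saturating tail adds a late
#' plateau at `tail * amplitude` above baseline.
#'
#' @param spec A [compartment_spec()].
#' @param t Time(s) in seconds, >= 0 (vectorized).
#' @return Intensities in [0, 1], same length as `t`.
#' @export
bolus_curve <- function(spec, t) {
  stopifnot(inherits(spec, "compartment_spec"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  tau <- pmax(t - spec$onset_s, 0) / spec$time_to_peak_s
  a <- spec$shape_alpha
  gv <- tau^a * exp(a * (1 - tau))
  y <- spec$baseline + spec$amplitude *
    ((1 - spec$tail_level) * gv + spec$tail_level * (1 - exp(-tau)))
  pmin(pmax(y, 0), 1)
}

#' Scene specification for synthetic cines
#'
#' @param compartments Non-empty list of [compartment_spec()]; on overlap,
#'   later compartments overwrite earlier ones pixel-wise.
#' @param frame_shape Integer `(rows, cols)`.
#' @param frame_rate_hz Frames per second (> 0).
#' @param duration_s Clip length in seconds; defaults to 45 s, a typical
#'   intraoperative bolus recording.
#' @param noise_sigma Speckle fluctuation scale, >= 0 (see
#'   [generate_cine()] for the noise model); 0 disables noise.
#' @param background Constant level of pixels belonging to no compartment,
#'   in [0, 1].
#' @param seed Integer seed; the generated cine is a pure function of the
#'   scene, including this seed.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(compartments, frame_shape = c(64L, 64L),
                       frame_rate_hz = 10, duration_s = 45,
                       noise_sigma = 0.15, background = 0.02, seed = 1L) {
  if (!is.list(compartments) || length(compartments) == 0L ||
      !all(vapply(compartments, inherits, TRUE, "compartment_spec"))) {
    stop("`compartments` must be a non-empty list of compartment_spec",
         call. = FALSE)
  }
  if (duration_s * frame_rate_hz < 2) {
    stop("scene must span at least 2 frames", call. = FALSE)
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (background < 0 || background > 1) {
    stop("background must be in [0, 1]", call. = FALSE)
  }
  structure(list(compartments = compartments,
                 frame_shape = as.integer(frame_shape),
                 frame_rate_hz = frame_rate_hz, duration_s = duration_s,
                 noise_sigma = noise_sigma, background = background,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Default three-compartment scene
#'
#' A vertical arterial band, a circular tumor blob and a rectangular
#' white-matter region on a dark background, all mutually disjoint.
#' Defaults encode the enhancement pattern of an intraoperative cerebral
#' bolus passage: arterial arrival 25 s after injection, tumor and white
#' matter staggered by 1 s each; arterial wash-in peaking ~7 s after
#' arrival; amplitudes ordered artery > tumor > white matter and sized so
#' the peak enhancements land near 0.58, 0.44 and 0.18 units; white matter
#' the faintest, slowest compartment with the most persistent tail.
#'
#' @param frame_shape Integer `(rows, cols)`, at least 64x64 for the
#'   default geometry.
#' @param frame_rate_hz Frames per second.
#' @param duration_s Clip length in seconds.
#' @param noise_sigma Speckle scale (0 disables noise).
#' @param seed Integer seed.
#' @return A [scene_spec()].
#' @export
default_scene <- function(frame_shape = c(64L, 64L), frame_rate_hz = 10,
                          duration_s = 45, noise_sigma = 0.15, seed = 1L) {
  artery <- compartment_spec(
    label = "artery",
    geometry = roi_rectangle("artery", top = 0L, left = 6L,
                             height = frame_shape[1], width = 6L),
    baseline = 0.02, amplitude = 0.57, onset_s = 25, time_to_peak_s = 7,
    shape_alpha = 3, tail_level = 0.05)
  tumor <- compartment_spec(
    label = "tumor",
    geometry = roi_circle("tumor", center = c(44, 40), radius = 10),
    baseline = 0.02, amplitude = 0.43, onset_s = 26, time_to_peak_s = 8,
    shape_alpha = 2.5, tail_level = 0.10)
  wm <- compartment_spec(
    label = "white_matter",
    geometry = roi_rectangle("white_matter", top = 4L, left = 24L,
                             height = 22L, width = 34L),
    baseline = 0.02, amplitude = 0.165, onset_s = 27, time_to_peak_s = 8,
    shape_alpha = 2.5, tail_level = 0.15)
  scene_spec(list(wm, tumor, artery), frame_shape = frame_shape,
             frame_rate_hz = frame_rate_hz, duration_s = duration_s,
             noise_sigma = noise_sigma, seed = seed)
}

# unit-mean speckle factors: 1 + sigma * (R - 1) with R a Rayleigh draw
# normalized to unit mean; R >= 0 keeps factors >= 1 - sigma >= 0
speckle_factors <- function(n, sigma) {
  if (sigma == 0) return(rep(1, n))
  rayleigh <- sqrt(-2 * log(stats::runif(n)))   # scale 1, mean sqrt(pi/2)
  r_unit <- rayleigh / sqrt(pi / 2)
  1 + sigma * (r_unit - 1)
}

#' Generate a synthetic bolus-passage cine
#'
#' Every pixel's clean value at frame `k` is its compartment's
#' [bolus_curve()] evaluated at `k / frame_rate_hz` (background pixels hold
#' a low constant). Speckle is modelled multiplicatively: each pixel/frame
#' value is multiplied by an independent unit-mean factor
#' `1 + noise_sigma * (R - 1)`, `R` a unit-mean Rayleigh draw, so the
#' expected image equals the clean image at any noise level. Values are
#' clipped to [0, 1] and quantized to 8 bits. The whole stack is a
#' deterministic function of the scene (including its seed); the caller's
#' RNG state is left untouched.
#'
#' @param scene A [scene_spec()].
#' @return List with `cine` (a [cine_loop()]) and `rois` (the compartment
#'   geometries, one `ceus_roi` per compartment, in scene order).
#' @export
generate_cine <- function(scene) {
  stopifnot(inherits(scene, "scene_spec"))
  nr <- scene$frame_shape[1]; nc <- scene$frame_shape[2]
  n <- floor(scene$duration_s * scene$frame_rate_hz)
  times <- (seq_len(n) - 1) / scene$frame_rate_hz

  # compartment id per pixel; later compartments overwrite earlier
  comp_id <- matrix(0L, nr, nc)
  for (i in seq_along(scene$compartments)) {
    m <- rasterize(scene$compartments[[i]]$geometry, c(nr, nc))
    comp_id[m$mask] <- i
  }
  exclusive <- tabulate(comp_id[comp_id > 0L],
                        nbins = length(scene$compartments))
  starved <- which(exclusive == 0L)
  if (length(starved)) {
    warning("compartment(s) fully overwritten by later ones: ",
            paste(vapply(scene$compartments[starved], `[[`, "", "label"),
                  collapse = ", "), call. = FALSE)
  }

  # curve value per compartment (rows) per frame (cols)
  curves <- rbind(
    rep(scene$background, n),
    t(vapply(scene$compartments, bolus_curve, numeric(n), t = times))
  )

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(scene$seed)

  frames <- array(0L, dim = c(n, nr, nc))
  lookup <- as.vector(comp_id) + 1L    # row index into `curves`
  npix <- nr * nc
  for (k in seq_len(n)) {
    clean <- curves[lookup, k]
    noisy <- clean * speckle_factors(npix, scene$noise_sigma)
    noisy <- pmin(pmax(noisy, 0), 1)
    frames[k, , ] <- as.integer(round_half_up(noisy * 255))
  }
  rois <- lapply(scene$compartments, `[[`, "geometry")
  list(cine = cine_loop(frames, scene$frame_rate_hz), rois = rois)
}

.table2_means <- c(artery = 0.584, tumor = 0.436, white_matter = 0.175)
.table2_sds <- sqrt(c(artery = 0.048, tumor = 0.046, white_matter = 0.034))

#' Generate a synthetic per-patient cohort of metric values
#'
#' Each patient receives one value per tissue: a shared standard-normal
#' "perfusion factor" induces within-patient coupling across tissues
#' (cross-tissue correlation `within_patient_rho`), plus independent
#' per-tissue noise, scaled by the tissue standard deviation and shifted to
#' the tissue mean. Values are clipped to [0, 1]. Defaults reproduce a
#' cohort of 19 patients with peak-enhancement means 0.584 (artery), 0.436
#' (tumor) and 0.175 (white matter) and matching spreads.
#'
#' @param n_patients Number of patients (>= 2).
#' @param tissue_means,tissue_sds Named numeric vectors over tissues.
#' @param within_patient_rho Cross-tissue correlation in [0, 1); default
#'   0.8, a strongly coupled cohort in which a well-perfused patient is
#'   bright in every tissue.
#' @param metric Metric name recorded in the table.
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return A [cohort_table()].
#' @export
generate_cohort <- function(n_patients = 19L,
                            tissue_means = .table2_means,
                            tissue_sds = .table2_sds,
                            within_patient_rho = 0.8,
                            metric = "peak_enhancement", seed = 1L) {
  if (n_patients < 2L) stop("need at least 2 patients", call. = FALSE)
  if (any(tissue_sds < 0)) stop("tissue sds must be >= 0", call. = FALSE)
  if (within_patient_rho < 0 || within_patient_rho >= 1) {
    stop("within_patient_rho must lie in [0, 1)", call. = FALSE)
  }
  tissues <- names(tissue_means)
  if (is.null(tissues) || !setequal(names(tissue_sds), tissues)) {
    stop("tissue_means and tissue_sds must share tissue names", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  rho <- within_patient_rho
  shared <- stats::rnorm(n_patients)
  rows <- lapply(tissues, function(tt) {
    eps <- stats::rnorm(n_patients)
    z <- sqrt(rho) * shared + sqrt(1 - rho) * eps
    v <- tissue_means[[tt]] + tissue_sds[[tt]] * z
    data.frame(patient_id = sprintf("P%02d", seq_len(n_patients)),
               tissue_label = tt, metric_name = metric,
               value = pmin(pmax(v, 0), 1))
  })
  cohort_table(do.call(rbind, rows))
}
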