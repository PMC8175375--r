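# Independent brute-force oracles used across the suite. These deliberately
# re-derive every quantity with the plainest possible scalar code so that
# the vectorized implementation paths are checked against something that
# cannot share their bugs.

# scalar point-in-shape membership at a single pixel center (0-based r, c)
oracle_point_in_roi <- function(roi, r, c) {
  if (roi$shape == "circle") {
    return(sqrt((r - roi$center[1])^2 + (c - roi$center[2])^2) <= roi$radius)
  }
  if (roi$shape == "rectangle") {
    return(r >= roi$top && r < roi$top + roi$height &&
           c >= roi$left && c < roi$left + roi$width)
  }
  v <- roi$vertices
  n <- nrow(v)
  # on-edge check: distance from point to each closed segment
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ar <- v[i, 1]; ac <- v[i, 2]; br <- v[j, 1]; bc <- v[j, 2]
    len2 <- (br - ar)^2 + (bc - ac)^2
    t <- if (len2 == 0) 0 else
      max(0, min(1, ((r - ar) * (br - ar) + (c - ac) * (bc - ac)) / len2))
    pr <- ar + t * (br - ar); pc <- ac + t * (bc - ac)
    if ((r - pr)^2 + (c - pc)^2 <= 1e-18) return(TRUE)
  }
  # classic scalar even-odd ray cast (ray towards +col)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((v[i, 1] > r) != (v[j, 1] > r)) {
      xint <- v[j, 2] + (r - v[j, 1]) * (v[i, 2] - v[j, 2]) /
        (v[i, 1] - v[j, 1])
      if (c < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# exhaustive membership mask over a whole frame
oracle_mask <- function(roi, frame_shape) {
  nr <- frame_shape[1]; nc <- frame_shape[2]
  m <- matrix(FALSE, nr, nc)
  for (r in 0:(nr - 1)) for (c in 0:(nc - 1)) {
    m[r + 1, c + 1] <- oracle_point_in_roi(roi, r, c)
  }
  m
}

# per-frame mean ROI intensity by an explicit double loop over masked pixels
oracle_tic_values <- function(frames, mask) {
  n <- dim(frames)[1]
  out <- numeric(n)
  for (k in seq_len(n)) {
    acc <- 0; cnt <- 0
    for (r in seq_len(dim(frames)[2])) for (c in seq_len(dim(frames)[3])) {
      if (mask[r, c]) {
        acc <- acc + frames[k, r, c]
        cnt <- cnt + 1
      }
    }
    out[k] <- acc / cnt / 255
  }
  out
}

# a random valid ROI of any shape inside an nr x nc frame
random_roi <- function(nr, nc, label = "tumor") {
  shape <- sample(c("circle", "rectangle", "polygon"), 1)
  if (shape == "circle") {
    roi_circle(label,
               center = c(runif(1, 2, nr - 3), runif(1, 2, nc - 3)),
               radius = runif(1, 1, min(nr, nc) / 3))
  } else if (shape == "rectangle") {
    top <- sample.int(nr - 2L, 1) - 1L
    left <- sample.int(nc - 2L, 1) - 1L
    roi_rectangle(label, top, left,
                  height = sample.int(nr - top - 1L, 1),
                  width = sample.int(nc - left - 1L, 1))
  } else {
    k <- sample(3:8, 1)
    # star-shaped polygon around a random center: always simple, area > 0
    cr <- runif(1, nr / 4, 3 * nr / 4)
    cc <- runif(1, nc / 4, 3 * nc / 4)
    ang <- sort(runif(k, 0, 2 * pi))
    rad <- runif(k, 2, min(nr, nc) / 3)
    roi_polygon(label, cbind(cr + rad * sin(ang), cc + rad * cos(ang)))
  }
}

# mean of a N(mu, sd) variate clipped to [0, 1], in closed form
clipped_normal_mean <- function(mu, sd) {
  if (sd == 0) return(min(max(mu, 0), 1))
  a <- (0 - mu) / sd
  b <- (1 - mu) / sd
  (1 - pnorm(b)) + mu * (pnorm(b) - pnorm(a)) - sd * (dnorm(b) - dnorm(a))
}

# constant-valued test cine
constant_cine <- function(value, n = 5L, nr = 8L, nc = 8L, fps = 10) {
  cine_loop(array(as.integer(value), dim = c(n, nr, nc)), fps)
}
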