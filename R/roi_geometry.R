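#' Regions of interest
#'
#' ROIs come in the three shapes a reviewer draws on a CEUS frame: circles,
#' axis-aligned rectangles and freehand polygons. Coordinates are 0-based,
#' row-major pixel indices; a pixel's reference point is its center, so the
#' pixel at index (r, c) is the point (r, c) for membership tests.
#'
#' @param label Tissue tag: one of `"artery"`, `"tumor"`, `"white_matter"`,
#'   `"grey_matter"`, or `"other:<free text>"`.
#' @param center Numeric `(row, col)` of the circle center, 0-based.
#' @param radius Circle radius in pixels, > 0.
#' @return An object of class `ceus_roi`.
#' @name roi
NULL

.roi_labels <- c("artery", "tumor", "white_matter", "grey_matter")

check_label <- function(label) {
  if (!is.character(label) || length(label) != 1L || is.na(label)) {
    stop("ROI label must be a single string", call. = FALSE)
  }
  if (!(label %in% .roi_labels || startsWith(label, "other:"))) {
    stop("unknown ROI label '", label, "'; expected one of ",
         paste(.roi_labels, collapse = ", "), " or 'other:<text>'",
         call. = FALSE)
  }
  label
}

#' @rdname roi
#' @export
roi_circle <- function(label, center, radius) {
  check_label(label)
  if (!is.numeric(center) || length(center) != 2L || anyNA(center)) {
    stop("circle center must be numeric (row, col)", call. = FALSE)
  }
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0) {
    stop("circle radius must be > 0", call. = FALSE)
  }
  structure(list(label = label, shape = "circle",
                 center = as.numeric(center), radius = as.numeric(radius)),
            class = "ceus_roi")
}

#' @rdname roi
#' @param top,left 0-based index of the rectangle's top-left pixel.
#' @param height,width Rectangle extent in pixels, >= 1; the rectangle covers
#'   the half-open index block `[top, top+height) x [left, left+width)`.
#' @export
roi_rectangle <- function(label, top, left, height, width) {
  check_label(label)
  vals <- c(top = top, left = left, height = height, width = width)
  if (!is.numeric(vals) || anyNA(vals) || any(vals != round(vals))) {
    stop("rectangle bounds must be integers", call. = FALSE)
  }
  if (height < 1 || width < 1) {
    stop("rectangle height and width must be >= 1", call. = FALSE)
  }
  structure(list(label = label, shape = "rectangle",
                 top = as.integer(top), left = as.integer(left),
                 height = as.integer(height), width = as.integer(width)),
            class = "ceus_roi")
}

#' @rdname roi
#' @param vertices Numeric matrix with one `(row, col)` vertex per row,
#'   >= 3 vertices, in drawing order (the closing edge back to the first
#'   vertex is implicit).
#' @export
roi_polygon <- function(label, vertices) {
  check_label(label)
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2L || anyNA(vertices)) {
    stop("polygon vertices must be a numeric n x 2 (row, col) matrix",
         call. = FALSE)
  }
  if (nrow(vertices) < 3L) {
    stop("polygon needs at least 3 vertices, got ", nrow(vertices),
         call. = FALSE)
  }
  dimnames(vertices) <- NULL
  structure(list(label = label, shape = "polygon", vertices = vertices),
            class = "ceus_roi")
}

#' @export
print.ceus_roi <- function(x, ...) {
  desc <- switch(x$shape,
    circle = sprintf("circle center (%g, %g) r = %g", x$center[1], x$center[2],
                     x$radius),
    rectangle = sprintf("rect [%d, %d) x [%d, %d)", x$top, x$top + x$height,
                        x$left, x$left + x$width),
    polygon = sprintf("polygon, %d vertices", nrow(x$vertices)))
  cat(sprintf("<ceus_roi> %s: %s\n", x$label, desc))
  invisible(x)
}

# even-odd crossing-number test for points against polygon edges, vectorized
# over points; boundary points handled separately by the caller
polygon_crossings_odd <- function(pr, pc, vr, vc) {
  n <- length(vr)
  inside <- logical(length(pr))
  j <- n
  for (i in seq_len(n)) {
    # edge from vertex j to vertex i; ray cast in +col direction
    straddles <- (vr[i] > pr) != (vr[j] > pr)
    if (any(straddles)) {
      xint <- vc[j] + (pr - vr[j]) * (vc[i] - vc[j]) / (vr[i] - vr[j])
      hit <- straddles & (pc < xint)
      inside <- xor(inside, hit)
    }
    j <- i
  }
  inside
}

# TRUE where point (pr, pc) lies on any polygon edge segment (within eps)
polygon_on_boundary <- function(pr, pc, vr, vc, eps = 1e-9) {
  n <- length(vr)
  on_edge <- logical(length(pr))
  j <- n
  for (i in seq_len(n)) {
    ar <- vr[j]; ac <- vc[j]; br <- vr[i]; bc <- vc[i]
    dr <- br - ar; dc <- bc - ac
    len2 <- dr * dr + dc * dc
    if (len2 == 0) {
      d2 <- (pr - ar)^2 + (pc - ac)^2
      on_edge <- on_edge | d2 <= eps^2
    } else {
      t <- ((pr - ar) * dr + (pc - ac) * dc) / len2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (pr - (ar + t * dr))^2 + (pc - (ac + t * dc))^2
      on_edge <- on_edge | d2 <= eps^2
    }
    j <- i
  }
  on_edge
}

#' Rasterize an ROI to a pixel mask
#'
#' Membership is decided at pixel centers: a circle keeps pixels whose
#' centers lie within Euclidean distance `radius` of the center (boundary
#' included); a rectangle keeps its half-open index block; a polygon keeps
#' pixel centers strictly inside by the even-odd rule plus centers lying
#' exactly on an edge. Masks are clipped to the frame; an ROI that leaves no
#' pixel inside the frame is an error.
#'
#' @param roi A `ceus_roi`.
#' @param frame_shape Integer `(rows, cols)` of the target frame.
#' @return An object of class `roi_mask`: list with `mask` (logical
#'   `rows x cols` matrix) and `pixel_count`.
#' @export
rasterize <- function(roi, frame_shape) {
  stopifnot(inherits(roi, "ceus_roi"))
  if (!is.numeric(frame_shape) || length(frame_shape) != 2L ||
      any(frame_shape < 1)) {
    stop("`frame_shape` must be positive (rows, cols)", call. = FALSE)
  }
  nr <- as.integer(frame_shape[1]); nc <- as.integer(frame_shape[2])
  mask <- matrix(FALSE, nr, nc)

  if (roi$shape == "rectangle") {
    r0 <- max(roi$top, 0L); r1 <- min(roi$top + roi$height - 1L, nr - 1L)
    c0 <- max(roi$left, 0L); c1 <- min(roi$left + roi$width - 1L, nc - 1L)
    if (r0 <= r1 && c0 <= c1) mask[(r0:r1) + 1L, (c0:c1) + 1L] <- TRUE
  } else if (roi$shape == "circle") {
    r0 <- max(floor(roi$center[1] - roi$radius), 0)
    r1 <- min(ceiling(roi$center[1] + roi$radius), nr - 1)
    c0 <- max(floor(roi$center[2] - roi$radius), 0)
    c1 <- min(ceiling(roi$center[2] + roi$radius), nc - 1)
    if (r0 <= r1 && c0 <= c1) {
      rows <- r0:r1; cols <- c0:c1
      dist2 <- outer((rows - roi$center[1])^2, (cols - roi$center[2])^2, `+`)
      mask[rows + 1L, cols + 1L] <- dist2 <= roi$radius^2
    }
  } else {  # polygon
    vr <- roi$vertices[, 1]; vc <- roi$vertices[, 2]
    r0 <- max(floor(min(vr)), 0); r1 <- min(ceiling(max(vr)), nr - 1)
    c0 <- max(floor(min(vc)), 0); c1 <- min(ceiling(max(vc)), nc - 1)
    if (r0 <= r1 && c0 <= c1) {
      grid <- expand.grid(row = r0:r1, col = c0:c1)
      member <- polygon_crossings_odd(grid$row, grid$col, vr, vc) |
        polygon_on_boundary(grid$row, grid$col, vr, vc)
      mask[cbind(grid$row + 1L, grid$col + 1L)] <- member
    }
  }

  count <- sum(mask)
  if (count == 0L) {
    stop("ROI '", roi$label, "' rasterizes to an empty mask in a ",
         nr, "x", nc, " frame", call. = FALSE)
  }
  structure(list(mask = mask, pixel_count = count), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d px in %dx%d frame\n", x$pixel_count,
              nrow(x$mask), ncol(x$mask)))
  invisible(x)
}

roi_to_record <- function(roi) {
  switch(roi$shape,
    circle = list(label = roi$label, shape = "circle",
                  center = roi$center, radius = roi$radius),
    rectangle = list(label = roi$label, shape = "rectangle",
                     bounds = c(roi$top, roi$left, roi$height, roi$width)),
    polygon = list(label = roi$label, shape = "polygon",
                   vertices = lapply(seq_len(nrow(roi$vertices)),
                                     function(i) roi$vertices[i, ])))
}

record_to_roi <- function(rec, index) {
  fail <- function(msg) {
    stop("ROI record ", index, ": ", msg, call. = FALSE)
  }
  if (!is.list(rec) || is.null(rec$label) || is.null(rec$shape)) {
    fail("missing 'label' or 'shape'")
  }
  shape <- rec$shape
  out <- tryCatch(
    switch(shape,
      circle = {
        if (is.null(rec$center) || is.null(rec$radius)) {
          fail("circle needs 'center' and 'radius'")
        }
        roi_circle(rec$label, unlist(rec$center), rec$radius)
      },
      rectangle = {
        if (is.null(rec$bounds) || length(unlist(rec$bounds)) != 4L) {
          fail("rectangle needs 'bounds' = [top, left, height, width]")
        }
        b <- unlist(rec$bounds)
        roi_rectangle(rec$label, b[1], b[2], b[3], b[4])
      },
      polygon = {
        if (is.null(rec$vertices)) fail("polygon needs 'vertices'")
        v <- rec$vertices
        if (is.list(v)) v <- do.call(rbind, lapply(v, unlist))
        roi_polygon(rec$label, v)
      },
      fail(paste0("unknown shape '", shape, "'"))
    ),
    error = function(e) {
      msg <- conditionMessage(e)
      if (startsWith(msg, "ROI record")) stop(e) else fail(msg)
    }
  )
  out
}

#' Read ROI definitions from JSON
#'
#' The document is a top-level list of records, e.g.
#' `[{"label": "artery", "shape": "circle", "center": [r, c], "radius": x},
#'   {"label": "tumor", "shape": "rectangle", "bounds": [top, left, height, width]},
#'   {"label": "white_matter", "shape": "polygon", "vertices": [[r, c], ...]}]`.
#' Invalid records are rejected with their (1-based) index. Duplicate labels
#' are allowed — several ROIs may probe one tissue — but trigger a warning.
#'
#' @param path Path to a JSON file.
#' @return List of `ceus_roi` objects.
#' @export
parse_rois <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read ROIs: no such file: ", path, call. = FALSE)
  }
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("malformed ROI JSON '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (!is.list(doc)) stop("ROI JSON must be a top-level list", call. = FALSE)
  rois <- lapply(seq_along(doc), function(i) record_to_roi(doc[[i]], i))
  labels <- vapply(rois, `[[`, "", "label")
  if (anyDuplicated(labels)) {
    warning("duplicate ROI labels: ",
            paste(unique(labels[duplicated(labels)]), collapse = ", "),
            call. = FALSE)
  }
  rois
}

#' Write ROI definitions to JSON
#'
#' Inverse of [parse_rois()]; the written document round-trips losslessly.
#'
#' @param rois List of `ceus_roi` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
serialize_rois <- function(rois, path) {
  stopifnot(is.list(rois), all(vapply(rois, inherits, TRUE, "ceus_roi")))
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("cannot write ROIs: no such directory: ", dir, call. = FALSE)
  }
  records <- lapply(rois, roi_to_record)
  jsonlite::write_json(records, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
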