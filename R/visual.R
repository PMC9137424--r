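#' Canonical 66-point facial landmark layout
#'
#' The package's canonical index layout for the 66 facial landmarks
#' consumed from a frame-by-frame detector: 0-16 lower-face perimeter
#' (jaw), 17-26 eyebrows, 27-30 nose bridge (27 is the top of the bridge),
#' 31-35 nostril base, 36-47 eyes, 48-65 lips (outer then inner rim).
#'
#' @return A tibble with `point_id` (0-65) and `group`.
#' @export
landmark_groups <- function() {
  tibble(
    point_id = 0:65,
    group = c(rep("jaw", 17), rep("brows", 10), rep("nose", 4), rep("nose", 5),
              rep("eyes", 12), rep("lips", 18))
  )
}

#' Validate a landmark frame
#'
#' A landmark frame is a data frame with columns `frame`, `point_id`
#' (0-65), `x`, `y` (pixel coordinates, origin top-left) holding exactly 66
#' points per frame. Lip points must lie inside the polygon of the
#' lower-face perimeter points, and all coordinates must be inside the
#' frame bounds.
#'
#' @param lm A data frame (one frame) with the columns above.
#' @param width,height Frame bounds in pixels (optional; checked if given).
#' @return `lm` as a tibble, invisibly, or an error naming the violated
#'   invariant.
#' @export
validate_landmark_frame <- function(lm, width = NULL, height = NULL) {
  lm <- as_tibble(lm)
  need <- c("point_id", "x", "y")
  if (!all(need %in% names(lm))) {
    abort(sprintf("Landmark frame must have columns %s.", paste(need, collapse = ", ")))
  }
  if (nrow(lm) != 66 || !setequal(lm$point_id, 0:65)) {
    abort(sprintf("Landmark frame must have exactly 66 points with ids 0-65 (got %d rows).",
                  nrow(lm)))
  }
  if (!all(is.finite(lm$x)) || !all(is.finite(lm$y))) {
    abort("Landmark coordinates must be finite.")
  }
  if (!is.null(width) && (any(lm$x < 0) || any(lm$x > width))) {
    abort("Landmark x coordinates fall outside the frame bounds.")
  }
  if (!is.null(height) && (any(lm$y < 0) || any(lm$y > height))) {
    abort("Landmark y coordinates fall outside the frame bounds.")
  }
  lm <- lm[order(lm$point_id), ]
  per <- lm[lm$point_id %in% 0:16, ]
  lips <- lm[lm$point_id %in% 48:65, ]
  inside <- pracma::inpolygon(lips$x, lips$y, per$x, per$y, boundary = TRUE)
  if (!all(inside)) {
    abort("Lip landmarks must lie inside the lower-face perimeter polygon.")
  }
  invisible(lm)
}

#' Mask shape specification
#'
#' @param kind `"none"` (transparent mask: nothing drawn), `"opaque"`
#'   (filled polygon over the lower face), or `"windowed"` (opaque with a
#'   transparent cutout over the mouth).
#' @param window_margin Cutout margin as a fraction of the mouth width
#'   (windowed only, default 0.2).
#' @param fill Fill color as RGB in `[0, 1]` (default pure white).
#' @return A `masksim_maskshape` object.
#' @export
mask_shape_spec <- function(kind = c("none", "opaque", "windowed"),
                            window_margin = 0.2, fill = c(1, 1, 1)) {
  kind <- match.arg(kind)
  if (window_margin < 0) abort("`window_margin` must be non-negative.")
  stopifnot(length(fill) == 3, all(fill >= 0 & fill <= 1))
  structure(list(kind = kind, window_margin = window_margin, fill = fill),
            class = "masksim_maskshape")
}

#' Build mask polygons from a landmark frame
#'
#' The opaque mask is a single polygon through the 17 lower-face perimeter
#' points plus the top nose-bridge point (18 vertices). The windowed mask
#' uses the same outer polygon with a rectangular hole: the axis-aligned
#' bounding box of the 18 lip points dilated by
#' `window_margin * mouth width` on every side.
#'
#' @param lm A validated landmark frame (see [validate_landmark_frame()]).
#' @param spec A [mask_shape_spec()].
#' @return A list of polygons; each polygon is a list with `x`, `y`
#'   (vertices) and `role` (`"outer"` or `"hole"`). Empty for
#'   `kind = "none"`.
#' @export
build_mask_polygons <- function(lm, spec = mask_shape_spec("opaque")) {
  lm <- validate_landmark_frame(lm)
  if (spec$kind == "none") return(list())
  per <- lm[lm$point_id %in% 0:16, ]
  bridge <- lm[lm$point_id == 27, ]
  outer <- list(x = c(per$x, bridge$x), y = c(per$y, bridge$y), role = "outer")
  if (spec$kind == "opaque") return(list(outer))
  lips <- lm[lm$point_id %in% 48:65, ]
  mouth_w <- max(lips$x) - min(lips$x)
  m <- spec$window_margin * mouth_w
  x0 <- min(lips$x) - m; x1 <- max(lips$x) + m
  y0 <- min(lips$y) - m; y1 <- max(lips$y) + m
  hole <- list(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1), role = "hole")
  list(outer, hole)
}

# Logical fill mask for an image of the given size: TRUE where a pixel
# center is inside an outer polygon and not inside any hole.
polygon_fill_mask <- function(polygons, width, height) {
  inside <- matrix(FALSE, nrow = height, ncol = width)
  if (length(polygons) == 0) return(inside)
  cx <- rep(seq_len(width) - 0.5, each = height)
  cy <- rep(seq_len(height) - 0.5, times = width)
  for (p in polygons) {
    hit <- matrix(pracma::inpolygon(cx, cy, p$x, p$y, boundary = FALSE),
                  nrow = height)
    if (p$role == "outer") inside <- inside | hit else inside <- inside & !hit
  }
  inside
}

#' Superimpose a simulated mask onto a frame
#'
#' Pixels whose centers lie strictly inside the filled region (outer
#' polygons minus holes) are set to the fill color; every other pixel is
#' unchanged. No anti-aliasing is applied, so repeated rendering is
#' byte-exact idempotent.
#'
#' @param frame An image array (`height x width` grayscale or
#'   `height x width x 3` RGB, values in `[0, 1]`; the format returned by
#'   [png::readPNG()]).
#' @param polygons Polygon list from [build_mask_polygons()].
#' @param fill Fill color (RGB in `[0, 1]`).
#' @return The rendered image array.
#' @export
render_mask <- function(frame, polygons, fill = c(1, 1, 1)) {
  stopifnot(is.array(frame) || is.matrix(frame))
  dims <- dim(frame)
  h <- dims[1]; w <- dims[2]
  mask <- polygon_fill_mask(polygons, w, h)
  if (length(dims) == 2) {
    frame[mask] <- mean(fill)
  } else {
    nc <- dims[3]
    for (ch in seq_len(min(nc, 3))) {
      plane <- frame[, , ch]
      plane[mask] <- fill[ch]
      frame[, , ch] <- plane
    }
  }
  frame
}

#' Landmark occlusion report
#'
#' Fraction of the landmarks in each anatomical group (lips, jaw, eyes,
#' brows, nose) whose coordinates fall inside the filled mask region.
#' A quality-control check for simulated masks: an opaque mask must occlude
#' every lip landmark, a windowed mask none.
#'
#' @param lm A landmark frame.
#' @param polygons Polygon list from [build_mask_polygons()].
#' @return A tibble with `group`, `n`, `n_occluded`, `fraction`.
#' @export
occlusion_report <- function(lm, polygons) {
  lm <- validate_landmark_frame(lm)
  groups <- landmark_groups()
  lm <- left_join(lm, groups, by = "point_id")
  occluded <- rep(FALSE, nrow(lm))
  for (p in polygons) {
    hit <- pracma::inpolygon(lm$x, lm$y, p$x, p$y, boundary = (p$role == "outer"))
    if (p$role == "outer") occluded <- occluded | hit else occluded <- occluded & !hit
  }
  lm$occluded <- occluded
  lm %>%
    group_by(.data$group) %>%
    summarise(n = n(), n_occluded = sum(.data$occluded),
              fraction = mean(.data$occluded), .groups = "drop")
}

#' Read / write video frame images
#'
#' Thin wrappers over [png::readPNG()] / [png::writePNG()] returning the
#' array format consumed by [render_mask()].
#'
#' @param path PNG path.
#' @return An image array (read) or `path` invisibly (write).
#' @export
read_frame_png <- function(path) {
  if (!file.exists(path)) abort(sprintf("Frame image not found: %s", path))
  png::readPNG(path)
}

#' @rdname read_frame_png
#' @param frame An image array in `[0, 1]`.
#' @export
write_frame_png <- function(frame, path) {
  png::writePNG(frame, path)
  invisible(path)
}

#' Read / write landmark tables
#'
#' CSV format: columns `frame`, `point_id`, `x`, `y`, 66 rows per frame.
#'
#' @param path CSV path.
#' @return A tibble of landmarks (read) or `path` invisibly (write).
#' @export
read_landmarks_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  stopifnot(all(c("frame", "point_id", "x", "y") %in% names(d)))
  for (fr in unique(d$frame)) validate_landmark_frame(d[d$frame == fr, ])
  d
}

#' @rdname read_landmarks_csv
#' @param lm Landmark tibble with columns `frame`, `point_id`, `x`, `y`.
#' @export
write_landmarks_csv <- function(lm, path) {
  readr::write_csv(lm[, c("frame", "point_id", "x", "y")], path)
  invisible(path)
}
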