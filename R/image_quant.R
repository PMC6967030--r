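#' Region-of-interest polygon
#'
#' A simple (non-self-intersecting) closed polygon in pixel coordinates:
#' 0-based, origin top-left, half-open pixel convention — a pixel belongs to
#' the ROI iff its centre `(col - 0.5, row - 0.5)` is inside the polygon.
#'
#' @param x,y Numeric vertex coordinates (>= 3 vertices).
#' @return An object of class `roi_polygon`.
#' @export
roi_polygon <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("an ROI polygon needs >= 3 (x, y) vertices", call. = FALSE)
  }
  n <- length(x)
  # reject self-intersection between non-adjacent edges
  seg_int <- function(p1, p2, p3, p4) {
    d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
      (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  pts <- cbind(x, y)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) <= 1L || (i == 1L && j == n) || (j == 1L && i == n)) next
      if (seg_int(pts[i, ], pts[i %% n + 1L, ],
                  pts[j, ], pts[j %% n + 1L, ])) {
        stop("ROI polygon is self-intersecting", call. = FALSE)
      }
    }
  }
  structure(list(x = as.numeric(x), y = as.numeric(y)),
            class = "roi_polygon")
}

# Even-odd (ray casting) point-in-polygon test, vectorized over points.
point_in_polygon <- function(px, py, poly) {
  n <- length(poly$x)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly$x[i]; yi <- poly$y[i]
    xj <- poly$x[j]; yj <- poly$y[j]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Restrict an image to a region of interest
#'
#' Pixels outside the polygon are voided (set to 0 and masked out of all
#' downstream area measurements).
#'
#' @param image height x width x 3 array in [0,1].
#' @param roi A [roi_polygon()] within the image bounds.
#' @return A list of class `masked_image`: `image`, logical `roi_mask`
#'   (TRUE inside), and `roi_area` (pixels).
#' @export
apply_roi <- function(image, roi) {
  stopifnot(length(dim(image)) == 3L, inherits(roi, "roi_polygon"))
  h <- dim(image)[1]; w <- dim(image)[2]
  if (any(roi$x < 0 | roi$x > w | roi$y < 0 | roi$y > h)) {
    stop("ROI vertices outside image bounds", call. = FALSE)
  }
  # shoelace area; degenerate polygons are rejected
  n <- length(roi$x)
  shoelace <- abs(sum(roi$x * roi$y[c(2:n, 1)] -
                      roi$x[c(2:n, 1)] * roi$y)) / 2
  if (shoelace <= .Machine$double.eps) {
    stop("degenerate ROI polygon (zero area)", call. = FALSE)
  }
  cx <- rep(seq_len(w) - 0.5, each = h)
  cy <- rep(seq_len(h) - 0.5, times = w)
  mask <- matrix(point_in_polygon(cx, cy, roi), nrow = h)
  out <- image
  idx <- which(!mask)
  npix <- h * w
  out[c(idx, idx + npix, idx + 2L * npix)] <- 0
  structure(list(image = out, roi_mask = mask, roi_area = sum(mask)),
            class = "masked_image")
}

#' Calibrate a per-image white balance
#'
#' Computes a per-channel affine map sending the mean of the designated
#' background pixels to 0 and the mean of the designated class foreground
#' pixels to full scale (1), mirroring the per-image white balance set before
#' applying uniform colour thresholds. The mean colour of the designated
#' autofluorescence pixels is stored so those pixels can be voided before
#' classification.
#'
#' @param image height x width x 3 array in [0,1].
#' @param background_px,autofluorescence_px Two-column matrices of (row, col)
#'   1-based pixel indices; `autofluorescence_px` may be NULL.
#' @param foreground_px Named list of (row, col) matrices, one per class.
#' @param targets Named list mapping each foreground class to its reference
#'   RGB colour (defaults to the saturated display palette: green, red,
#'   purple). Per channel, the gain is the through-origin least-squares slope
#'   of the target intensities on the background-subtracted foreground means,
#'   so a channel-wise affine cast (including photobleaching and a uniform
#'   offset) is inverted exactly and an already-balanced image gets the
#'   identity map.
#' @param min_contrast Minimum Euclidean RGB distance between the background
#'   and each foreground reference (default 10/255).
#' @return A `white_balance_calibration`: `gain`, `offset` (per channel),
#'   `background_ref`, `foreground_ref`, `autofluorescence_ref`.
#' @export
calibrate_white_balance <- function(image, background_px, foreground_px,
                                    autofluorescence_px = NULL,
                                    targets = list(cd1a = c(0, 1, 0),
                                                   cd3cd8neg = c(1, 0, 0),
                                                   cd3cd8pos = c(0.6, 0, 0.8)),
                                    min_contrast = 10 / 255) {
  px_mean <- function(px) {
    if (is.null(px) || nrow(px) == 0L) {
      stop("a designated pixel set is empty", call. = FALSE)
    }
    vapply(1:3, function(ch) mean(image[cbind(px, ch)]), numeric(1))
  }
  bg <- px_mean(background_px)
  fgs <- lapply(foreground_px, px_mean)
  for (nm in names(fgs)) {
    if (sqrt(sum((fgs[[nm]] - bg)^2)) < min_contrast) {
      stop(sprintf(
        "insufficient contrast between background and '%s' foreground", nm),
        call. = FALSE)
    }
  }
  if (!all(names(fgs) %in% names(targets))) {
    stop("every foreground class needs a target colour", call. = FALSE)
  }
  fmat <- do.call(rbind, fgs)                       # classes x channels
  tmat <- do.call(rbind, targets[names(fgs)])
  gain <- offset <- numeric(3)
  for (ch in 1:3) {
    x <- fmat[, ch] - bg[ch]
    t <- tmat[, ch]
    if (sum(x^2) < 1e-12 || sum(t^2) < 1e-12) {
      gain[ch] <- 1                                  # channel unconstrained
    } else {
      gain[ch] <- sum(t * x) / sum(x^2)
    }
    offset[ch] <- -bg[ch] * gain[ch]
  }
  af <- if (!is.null(autofluorescence_px)) {
    raw <- px_mean(autofluorescence_px)
    raw * gain + offset
  } else NULL
  structure(list(gain = gain, offset = offset, background_ref = bg,
                 foreground_ref = fgs, autofluorescence_ref = af),
            class = "white_balance_calibration")
}

#' Apply a white-balance calibration to an image
#'
#' @param image height x width x 3 array.
#' @param calib A [calibrate_white_balance()] result.
#' @param clip Clamp the output into [0,1] (default TRUE).
#' @return The calibrated array.
#' @export
apply_white_balance <- function(image, calib, clip = TRUE) {
  stopifnot(inherits(calib, "white_balance_calibration"))
  out <- image
  for (ch in 1:3) {
    out[, , ch] <- image[, , ch] * calib$gain[ch] + calib$offset[ch]
  }
  if (clip) {
    out[out < 0] <- 0
    out[out > 1] <- 1
  }
  out
}

#' Uniform HSV colour thresholds for the three stained classes
#'
#' Hue windows are in degrees (0-360, wrap-around allowed); saturation and
#' value cutoffs in [0,1]. The same thresholds must be applied to every image
#' of a batch. Windows must be pairwise disjoint; classification still assigns
#' at most one class per pixel with priority purple > red > green.
#'
#' @param green,red,purple Lists with `hue` (length-2), `min_s`, `min_v`.
#' @return An object of class `color_thresholds`.
#' @export
color_thresholds <- function(green = list(hue = c(90, 150), min_s = 0.3,
                                          min_v = 0.15),
                             red = list(hue = c(330, 30), min_s = 0.3,
                                        min_v = 0.15),
                             purple = list(hue = c(250, 320), min_s = 0.3,
                                           min_v = 0.15)) {
  th <- list(green = green, red = red, purple = purple)
  win <- function(hh) {
    if (hh[1] <= hh[2]) list(hh) else list(c(hh[1], 360), c(0, hh[2]))
  }
  segs <- lapply(th, function(t) win(t$hue %% 360))
  nms <- names(segs)
  for (i in 1:2) for (j in (i + 1):3) {
    for (a in segs[[i]]) for (b in segs[[j]]) {
      if (max(a[1], b[1]) < min(a[2], b[2])) {
        stop(sprintf("hue windows of '%s' and '%s' overlap", nms[i], nms[j]),
             call. = FALSE)
      }
    }
  }
  structure(th, class = "color_thresholds")
}

hue_in_window <- function(hue_deg, window) {
  w <- window %% 360
  if (w[1] <= w[2]) hue_deg >= w[1] & hue_deg <= w[2]
  else hue_deg >= w[1] | hue_deg <= w[2]
}

#' Classify in-ROI pixels into the three stained classes
#'
#' Each in-ROI, non-autofluorescent pixel is assigned to at most one class iff
#' its HSV coordinates lie inside that class's hue window and exceed the
#' saturation/value cutoffs; on (theoretical) window overlap the priority is
#' purple > red > green, so the returned masks are always pairwise disjoint.
#'
#' @param image Calibrated height x width x 3 array.
#' @param thresholds A [color_thresholds()].
#' @param roi_mask Optional logical matrix (TRUE = in ROI).
#' @param autofluorescence_ref Optional RGB triple; pixels within
#'   `autofluorescence_tol` Euclidean RGB distance of it are voided.
#' @param autofluorescence_tol Exclusion radius in RGB space (default 0.15).
#' @return List of logical matrices `green`, `red`, `purple`, plus
#'   `unclassified` (in-ROI pixels assigned to no class).
#' @export
classify_pixels <- function(image, thresholds, roi_mask = NULL,
                            autofluorescence_ref = NULL,
                            autofluorescence_tol = 0.15) {
  stopifnot(inherits(thresholds, "color_thresholds"))
  h <- dim(image)[1]; w <- dim(image)[2]
  r <- as.vector(image[, , 1]); g <- as.vector(image[, , 2])
  b <- as.vector(image[, , 3])
  hsv <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 1)
  hue <- hsv[1, ] * 360; sat <- hsv[2, ]; val <- hsv[3, ]
  eligible <- rep(TRUE, h * w)
  if (!is.null(roi_mask)) eligible <- eligible & as.vector(roi_mask)
  if (!is.null(autofluorescence_ref)) {
    d2 <- (r - autofluorescence_ref[1])^2 + (g - autofluorescence_ref[2])^2 +
      (b - autofluorescence_ref[3])^2
    eligible <- eligible & d2 > autofluorescence_tol^2
  }
  in_class <- function(t) {
    eligible & hue_in_window(hue, t$hue) & sat >= t$min_s & val >= t$min_v
  }
  purple <- in_class(thresholds$purple)
  red <- in_class(thresholds$red) & !purple
  green <- in_class(thresholds$green) & !purple & !red
  unclassified <- eligible & !purple & !red & !green
  lapply(list(green = green, red = red, purple = purple,
              unclassified = unclassified),
         matrix, nrow = h)
}

#' Measure cumulative class areas
#'
#' @param masks List with logical matrices `green`, `red`, `purple` of equal
#'   shape (as from [classify_pixels()]).
#' @param image_id Optional identifier.
#' @param roi_area ROI size in pixels (defaults to the mask size).
#' @return An `area_quant_result` with the three cumulative pixel areas; ratios
#'   are added by [compute_area_ratios()].
#' @export
measure_cumulative_areas <- function(masks, image_id = NA_character_,
                                     roi_area = NULL) {
  dims <- lapply(masks[c("green", "red", "purple")], dim)
  if (length(unique(dims)) != 1L) {
    stop("class masks have mismatching shapes", call. = FALSE)
  }
  structure(list(
    image_id = image_id,
    green_area = sum(masks$green), red_area = sum(masks$red),
    purple_area = sum(masks$purple),
    roi_area = roi_area %||% prod(dims[[1]]),
    cd3_to_cd1a_ratio = NA_real_, cd8_to_cd1a_ratio = NA_real_
  ), class = "area_quant_result")
}

#' Accumulate area results over the images of one patient
#'
#' @param results List of `area_quant_result`s.
#' @param image_id Identifier for the aggregate (default "aggregate").
#' @return A single `area_quant_result` with summed areas.
#' @export
aggregate_area_results <- function(results, image_id = "aggregate") {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, logical(1), "area_quant_result")))
  pick <- function(f) sum(vapply(results, `[[`, numeric(1), f))
  structure(list(
    image_id = image_id,
    green_area = pick("green_area"), red_area = pick("red_area"),
    purple_area = pick("purple_area"), roi_area = pick("roi_area"),
    cd3_to_cd1a_ratio = NA_real_, cd8_to_cd1a_ratio = NA_real_
  ), class = "area_quant_result")
}

#' Compute the area ratios of an area quantification result
#'
#' `cd3_to_cd1a_ratio = (red + purple) / green` and
#' `cd8_to_cd1a_ratio = purple / green`. A zero green (CD1a+) area makes the
#' ratios undefined and is an error: the patient must be flagged, not silently
#' scored 0.
#'
#' @param result An `area_quant_result` with areas filled in.
#' @return The completed `area_quant_result`.
#' @export
compute_area_ratios <- function(result) {
  stopifnot(inherits(result, "area_quant_result"))
  if (result$green_area <= 0) {
    stop("green (CD1a+) area is zero: area ratios are undefined",
         call. = FALSE)
  }
  result$cd3_to_cd1a_ratio <-
    (result$red_area + result$purple_area) / result$green_area
  result$cd8_to_cd1a_ratio <- result$purple_area / result$green_area
  result
}

#' One-call automated area quantification of a lesion image
#'
#' Convenience wrapper chaining ROI masking, classification against uniform
#' thresholds, cumulative area measurement and ratio computation. White
#' balance is the caller's responsibility (it is per-image by design).
#'
#' @param image (Calibrated) height x width x 3 array.
#' @param thresholds A [color_thresholds()].
#' @param roi Optional [roi_polygon()].
#' @param image_id Identifier.
#' @param ... Passed to [classify_pixels()].
#' @return A completed `area_quant_result`.
#' @export
quantify_image <- function(image, thresholds = color_thresholds(),
                           roi = NULL, image_id = NA_character_, ...) {
  roi_mask <- NULL
  roi_area <- NULL
  if (!is.null(roi)) {
    m <- apply_roi(image, roi)
    image <- m$image
    roi_mask <- m$roi_mask
    roi_area <- m$roi_area
  }
  masks <- classify_pixels(image, thresholds, roi_mask = roi_mask, ...)
  res <- measure_cumulative_areas(masks, image_id = image_id,
                                  roi_area = roi_area)
  compute_area_ratios(res)
}
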