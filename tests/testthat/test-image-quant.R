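# a small noiseless image with known truth, shared across blocks
mk_noiseless <- function(seed = 7, w = 150, h = 150) {
  spec <- lesion_image_spec(width = w, height = h, n_cd1a = 20,
                            n_cd3cd8neg = 8, n_cd3cd8pos = 4,
                            cell_radius_range = c(3, 5),
                            background_level = 0, seed = seed)
  generate_lesion_image(spec)
}

test_that("apply_roi: identity rectangle, triangle oracle, degenerate error", {
  r <- mk_noiseless()
  full <- roi_polygon(c(0, 150, 150, 0), c(0, 0, 150, 150))
  m <- apply_roi(r$image, full)
  expect_equal(m$roi_area, 150 * 150)
  expect_identical(m$image, r$image)

  # non-lattice vertices so no pixel centre sits exactly on an edge and the
  # two rasterization conventions agree
  tri <- list(v1 = c(10.2, 10.1), v2 = c(140.3, 20.7), v3 = c(60.1, 130.9))
  roi <- roi_polygon(c(10.2, 140.3, 60.1), c(10.1, 20.7, 130.9))
  m2 <- apply_roi(r$image, roi)
  expect_equal(m2$roi_area,
               oracle_triangle_pixel_count(tri$v1, tri$v2, tri$v3, 150, 150))

  expect_error(apply_roi(r$image, roi_polygon(c(1, 1, 1), c(1, 1, 1))),
               "degenerate")
  expect_error(roi_polygon(c(0, 10, 10, 0), c(0, 10, 0, 10)),
               "self-intersecting")
})

test_that("ROI exclusion removes the cells it excludes", {
  r <- mk_noiseless(seed = 6)
  cells <- r$truth$cells
  red <- cells[cells$class == "cd3cd8neg", ]
  # half-plane strictly left of every red cell (seed chosen so cut > 10)
  cut <- min(red$x - red$radius) - 1
  expect_gt(cut, 10)
  roi <- roi_polygon(c(0, cut, cut, 0), c(0, 0, 150, 150))
  m <- apply_roi(r$image, roi)
  masks <- classify_pixels(m$image, color_thresholds(), roi_mask = m$roi_mask)
  expect_equal(sum(masks$red), 0)
})

test_that("white balance: identity on balanced input, inverts a cast", {
  r <- mk_noiseless()
  cells <- r$truth$cells
  centre_px <- function(cl) {
    cc <- cells[cells$class == cl, ][1, ]
    cbind(row = round(cc$y), col = round(cc$x))
  }
  bg_px <- cbind(row = 1:3, col = 1:3)  # corner is background (level 0)
  fg_px <- list(cd1a = centre_px("cd1a"),
                cd3cd8neg = centre_px("cd3cd8neg"),
                cd3cd8pos = centre_px("cd3cd8pos"))
  cal <- calibrate_white_balance(r$image, bg_px, fg_px)
  expect_equal(unname(cal$gain), rep(1, 3))
  expect_equal(unname(cal$offset), rep(0, 3))
  expect_equal(apply_white_balance(r$image, cal), r$image, tolerance = 1e-12)

  # affine cast (bleach gain + uniform +20/255 offset) is inverted exactly
  cast <- r$image * (1 - 20 / 255) + 20 / 255
  cal2 <- calibrate_white_balance(cast, bg_px, fg_px)
  restored <- apply_white_balance(cast, cal2, clip = FALSE)
  expect_equal(restored, r$image, tolerance = 1e-9)

  expect_error(calibrate_white_balance(r$image, bg_px, list(cd1a = bg_px)),
               "insufficient contrast")
})

test_that("classify_pixels: empty cases and exact oracle equivalence", {
  black <- array(0, dim = c(32, 32, 3))
  masks <- classify_pixels(black, color_thresholds())
  expect_equal(sum(masks$green) + sum(masks$red) + sum(masks$purple), 0)

  r <- mk_noiseless()
  masks <- classify_pixels(r$image, color_thresholds())
  expect_equal(sum(masks$green), unname(r$truth$true_pixel_area["cd1a"]))
  expect_equal(sum(masks$red), unname(r$truth$true_pixel_area["cd3cd8neg"]))
  expect_equal(sum(masks$purple), unname(r$truth$true_pixel_area["cd3cd8pos"]))
  # disjointness + conservation over the (full-image) ROI
  total <- sum(masks$green) + sum(masks$red) + sum(masks$purple) +
    sum(masks$unclassified)
  expect_equal(total, 150 * 150)
  expect_equal(sum(masks$green & masks$red), 0)
  expect_equal(sum(masks$red & masks$purple), 0)

  # vacuous threshold
  th <- color_thresholds(green = list(hue = c(90, 150), min_s = 0.3,
                                      min_v = 1.01),
                         red = list(hue = c(330, 30), min_s = 0.3,
                                    min_v = 1.01),
                         purple = list(hue = c(250, 320), min_s = 0.3,
                                       min_v = 1.01))
  m2 <- classify_pixels(r$image, th)
  expect_equal(sum(m2$green) + sum(m2$red) + sum(m2$purple), 0)

  expect_error(color_thresholds(green = list(hue = c(90, 150), min_s = .3,
                                             min_v = .15),
                                red = list(hue = c(100, 160), min_s = .3,
                                           min_v = .15)),
               "overlap")
})

test_that("autofluorescence reference pixels are voided before classification", {
  img <- array(0, dim = c(20, 20, 3))
  img[5:8, 5:8, 1] <- 1  # a red patch
  img[12:15, 12:15, 1] <- 1; img[12:15, 12:15, 2] <- 1  # a yellow blob
  m_plain <- classify_pixels(img, color_thresholds())
  m_af <- classify_pixels(img, color_thresholds(),
                          autofluorescence_ref = c(1, 1, 0),
                          autofluorescence_tol = 0.1)
  expect_equal(sum(m_plain$red), 16)
  expect_equal(sum(m_af$red), 16)
  expect_equal(sum(m_af$unclassified), sum(m_plain$unclassified) - 16)
})

test_that("cumulative areas: zeros, additivity, disk area tolerance", {
  z <- matrix(FALSE, 30, 30)
  res <- measure_cumulative_areas(list(green = z, red = z, purple = z))
  expect_equal(res$green_area + res$red_area + res$purple_area, 0)

  r1 <- mk_noiseless(seed = 1)
  r2 <- mk_noiseless(seed = 2)
  q1 <- quantify_image(r1$image)
  q2 <- quantify_image(r2$image)
  agg <- aggregate_area_results(list(q1, q2))
  expect_equal(agg$green_area, q1$green_area + q2$green_area)

  # single r = 10 disk: area within 4r of pi r^2
  img <- array(0, dim = c(50, 50, 3))
  img <- lchquant:::paint_disk(img, 25, 25, 10, c(0, 1, 0))$img
  masks <- classify_pixels(img, color_thresholds())
  expect_lt(abs(sum(masks$green) - pi * 100), 40)

  expect_error(measure_cumulative_areas(
    list(green = z, red = z, purple = matrix(FALSE, 10, 10))), "shape")
})

test_that("area ratios: arithmetic, zero numerators, zero-green guard", {
  mk <- function(g, r, p) {
    structure(list(image_id = "x", green_area = g, red_area = r,
                   purple_area = p, roi_area = 1e4,
                   cd3_to_cd1a_ratio = NA_real_, cd8_to_cd1a_ratio = NA_real_),
              class = "area_quant_result")
  }
  res <- compute_area_ratios(mk(1000, 50, 10))
  expect_equal(res$cd3_to_cd1a_ratio, 0.06)
  expect_equal(res$cd8_to_cd1a_ratio, 0.01)
  res0 <- compute_area_ratios(mk(1000, 0, 0))
  expect_equal(res0$cd3_to_cd1a_ratio, 0)
  expect_equal(res0$cd8_to_cd1a_ratio, 0)
  expect_error(compute_area_ratios(mk(0, 5, 5)), "undefined")
  # invariant: cd3 ratio >= cd8 ratio
  expect_gte(res$cd3_to_cd1a_ratio, res$cd8_to_cd1a_ratio)
})

test_that("batch uniformity: calibrating one image never changes another", {
  rA <- mk_noiseless(seed = 31)
  rB <- mk_noiseless(seed = 32)
  th <- color_thresholds()
  before <- classify_pixels(rA$image, th)
  # calibrate and classify B in between
  bg_px <- cbind(row = 1:5, col = 1:5)
  gB <- rB$truth$cells[rB$truth$cells$class == "cd1a", ][1, ]
  calB <- calibrate_white_balance(rB$image, bg_px,
                                  list(cd1a = cbind(row = round(gB$y),
                                                    col = round(gB$x))))
  invisible(classify_pixels(apply_white_balance(rB$image, calB), th))
  after <- classify_pixels(rA$image, th)
  expect_identical(before, after)
})
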