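#' Specification for a synthetic multiplex immunofluorescence lesion image
#'
#' Describes a simulated three-colour stained lesion field: CD1a+ histiocytes
#' (green), CD3+CD8- T cells (red) and CD3+CD8+ T cells (purple) drawn as
#' opaque non-overlapping disks over a noisy background, optionally with
#' autofluorescent blobs in a none-of-the-above colour and a global
#' photobleaching factor.
#'
#' @param width,height Image size in pixels.
#' @param n_cd1a,n_cd3cd8neg,n_cd3cd8pos Cell counts per class (>= 0).
#' @param cell_radius_range Length-2 numeric, min/max cell radius in pixels.
#' @param channel_colors Named list mapping class to an RGB triple in [0,1].
#'   Classes are `cd1a`, `cd3cd8neg`, `cd3cd8pos` plus `autofluorescence`.
#' @param background_level Background intensity in [0,1); background noise has
#'   standard deviation `0.15 * background_level`, so a zero background is
#'   exactly noiseless.
#' @param autofluorescence_blob_count Number of autofluorescent blobs.
#' @param bleach_factor Multiplicative signal retention in (0,1]; 1 = no
#'   photobleaching.
#' @param seed Integer seed; identical spec + seed gives a bit-identical image.
#' @return An object of class `lesion_image_spec`.
#' @export
lesion_image_spec <- function(width = 400L, height = 400L,
                              n_cd1a = 40L, n_cd3cd8neg = 10L, n_cd3cd8pos = 4L,
                              cell_radius_range = c(4, 8),
                              channel_colors = list(
                                cd1a            = c(0, 1, 0),
                                cd3cd8neg       = c(1, 0, 0),
                                cd3cd8pos       = c(0.6, 0, 0.8),
                                autofluorescence = c(1, 1, 0)),
                              background_level = 0.05,
                              autofluorescence_blob_count = 0L,
                              bleach_factor = 1,
                              seed = 1L) {
  stopifnot_scalar_number(width, "width", 16)
  stopifnot_scalar_number(height, "height", 16)
  for (nm in c("n_cd1a", "n_cd3cd8neg", "n_cd3cd8pos")) {
    stopifnot_scalar_number(get(nm), nm, 0)
  }
  if (length(cell_radius_range) != 2L || any(cell_radius_range <= 0) ||
      cell_radius_range[1] > cell_radius_range[2]) {
    stop("`cell_radius_range` must be increasing positive (min, max)",
         call. = FALSE)
  }
  needed <- c("cd1a", "cd3cd8neg", "cd3cd8pos", "autofluorescence")
  if (!all(needed %in% names(channel_colors))) {
    stop("`channel_colors` must name: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  cols <- do.call(rbind, channel_colors[needed])
  if (anyDuplicated(cols[1:3, , drop = FALSE])) {
    stop("class colours must be pairwise distinct", call. = FALSE)
  }
  stopifnot_scalar_number(background_level, "background_level", 0, 0.99)
  stopifnot_scalar_number(bleach_factor, "bleach_factor", 1e-8, 1)
  stopifnot_scalar_number(autofluorescence_blob_count,
                          "autofluorescence_blob_count", 0)
  structure(list(
    width = as.integer(width), height = as.integer(height),
    n_cd1a = as.integer(n_cd1a), n_cd3cd8neg = as.integer(n_cd3cd8neg),
    n_cd3cd8pos = as.integer(n_cd3cd8pos),
    cell_radius_range = as.numeric(cell_radius_range),
    channel_colors = channel_colors,
    background_level = background_level,
    autofluorescence_blob_count = as.integer(autofluorescence_blob_count),
    bleach_factor = bleach_factor,
    seed = as.integer(seed)
  ), class = "lesion_image_spec")
}

# Paint an opaque disk into an image array; returns the linear pixel indices
# painted. Pixel (i, j) has centre (j - 0.5, i - 0.5) in 0-based coordinates
# with the origin at the top-left corner.
paint_disk <- function(img, cx, cy, r, rgb) {
  h <- dim(img)[1]; w <- dim(img)[2]
  i0 <- max(1L, floor(cy - r)); i1 <- min(h, ceiling(cy + r) + 1L)
  j0 <- max(1L, floor(cx - r)); j1 <- min(w, ceiling(cx + r) + 1L)
  ii <- i0:i1; jj <- j0:j1
  dy2 <- (ii - 0.5 - cy)^2
  dx2 <- (jj - 0.5 - cx)^2
  inside <- outer(dy2, dx2, `+`) <= r^2
  if (!any(inside)) return(list(img = img, idx = integer(0)))
  rows <- ii[row(inside)[inside]]
  cols <- jj[col(inside)[inside]]
  idx <- rows + (cols - 1L) * h
  n <- h * w
  img[idx] <- rgb[1]
  img[idx + n] <- rgb[2]
  img[idx + 2L * n] <- rgb[3]
  list(img = img, idx = idx)
}

#' Render a synthetic lesion image with per-cell ground truth
#'
#' Cells are opaque, non-overlapping disks placed by rejection sampling (at
#' most 1000 retries per cell). Autofluorescent blobs are drawn first, cells on
#' top, so the per-class pixel areas recorded in the ground truth are exact.
#'
#' @param spec A [lesion_image_spec()].
#' @return A list with components `image` (height x width x 3 array in [0,1])
#'   and `truth`, a `ground_truth_cell_map`: data frame `cells`
#'   (x, y, radius, class), named `true_counts` and `true_pixel_area`.
#' @export
generate_lesion_image <- function(spec) {
  stopifnot(inherits(spec, "lesion_image_spec"))
  classes <- c("cd1a", "cd3cd8neg", "cd3cd8pos")
  counts <- c(cd1a = spec$n_cd1a, cd3cd8neg = spec$n_cd3cd8neg,
              cd3cd8pos = spec$n_cd3cd8pos)
  with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    img <- array(spec$background_level, dim = c(h, w, 3))
    if (spec$background_level > 0) {
      img <- img + array(stats::rnorm(h * w * 3, 0,
                                      0.15 * spec$background_level),
                         dim = c(h, w, 3))
    }
    if (spec$autofluorescence_blob_count > 0) {
      for (b in seq_len(spec$autofluorescence_blob_count)) {
        r <- stats::runif(1, spec$cell_radius_range[2],
                          3 * spec$cell_radius_range[2])
        cx <- stats::runif(1, 0, w); cy <- stats::runif(1, 0, h)
        img <- paint_disk(img, cx, cy, r,
                          spec$channel_colors$autofluorescence)$img
      }
    }
    # rejection-sample non-overlapping cell centres
    total <- sum(counts)
    xs <- ys <- rs <- numeric(total)
    cls <- character(total)
    k <- 0L
    for (cl in classes) {
      for (i in seq_len(counts[[cl]])) {
        placed <- FALSE
        for (try in seq_len(1000L)) {
          r <- stats::runif(1, spec$cell_radius_range[1],
                            spec$cell_radius_range[2])
          cx <- stats::runif(1, r, w - r)
          cy <- stats::runif(1, r, h - r)
          if (k == 0L ||
              all((xs[1:k] - cx)^2 + (ys[1:k] - cy)^2 > (rs[1:k] + r)^2)) {
            k <- k + 1L
            xs[k] <- cx; ys[k] <- cy; rs[k] <- r; cls[k] <- cl
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop(sprintf(
            "could not place a '%s' cell without overlap in 1000 retries", cl),
            call. = FALSE)
        }
      }
    }
    area <- c(cd1a = 0, cd3cd8neg = 0, cd3cd8pos = 0)
    if (k > 0L) {
      for (i in seq_len(k)) {
        pd <- paint_disk(img, xs[i], ys[i], rs[i],
                         spec$channel_colors[[cls[i]]])
        img <- pd$img
        area[[cls[i]]] <- area[[cls[i]]] + length(pd$idx)
      }
    }
    img <- img * spec$bleach_factor
    img[img < 0] <- 0
    img[img > 1] <- 1
    cells <- data.frame(x = xs[seq_len(k)], y = ys[seq_len(k)],
                        radius = rs[seq_len(k)],
                        class = cls[seq_len(k)],
                        stringsAsFactors = FALSE)
    truth <- structure(list(
      cells = cells,
      true_counts = counts,
      true_pixel_area = area
    ), class = "ground_truth_cell_map")
    list(image = img, truth = truth)
  })
}

#' Specification of a synthetic LCH patient cohort
#'
#' States the world of the simulated cohort: two BRAF strata of lognormal CD8
#' ratios, independent HLA loci with stated allele frequencies, exponential
#' event times whose hazard may depend on the log ratio, and multi-observer
#' count noise.
#'
#' Default group medians (0.0316 for BRAF V600E, 0.0775 for wildtype) are the
#' stated lesional CD8 ratio medians; `ratio_log_sd = 1.1` is a free spread
#' parameter chosen so a cohort of ~100 spans roughly 0.00-5 (see vignette).
#'
#' @param n_patients Number of patients (>= 2).
#' @param braf_pos_fraction Probability a patient is BRAF V600E positive.
#' @param median_ratio_brafpos,median_ratio_brafwt Group median CD8 ratios.
#' @param ratio_log_sd Standard deviation of log CD8 ratio, shared by groups.
#' @param allele_freqs Named numeric vector of population allele frequencies;
#'   names like `"A*03:01"` (locus prefix before `*`). Residual frequency at
#'   each locus is assigned to a pooled `"<locus>*other"` allele.
#' @param event_rate Baseline hazard (events / follow-up year).
#' @param effect_of_ratio_on_hazard Log-hazard increment per unit log ratio.
#' @param counter_cv Coefficient of variation of simulated human counts.
#' @param admin_horizon_years Administrative censoring horizon.
#' @param seed Integer seed.
#' @export
cohort_spec <- function(n_patients = 101L,
                        braf_pos_fraction = 48 / 93,
                        median_ratio_brafpos = 0.0316,
                        median_ratio_brafwt = 0.0775,
                        ratio_log_sd = 1.1,
                        allele_freqs = c("A*03:01" = 0.128, "A*11:01" = 0.06,
                                         "A*02:01" = 0.28),
                        event_rate = 0.03,
                        effect_of_ratio_on_hazard = 0,
                        counter_cv = 0.05,
                        admin_horizon_years = 15,
                        seed = 1L) {
  stopifnot_scalar_number(n_patients, "n_patients", 2)
  stopifnot_scalar_number(braf_pos_fraction, "braf_pos_fraction", 0, 1)
  stopifnot_scalar_number(median_ratio_brafpos, "median_ratio_brafpos", 1e-12)
  stopifnot_scalar_number(median_ratio_brafwt, "median_ratio_brafwt", 1e-12)
  stopifnot_scalar_number(ratio_log_sd, "ratio_log_sd", 0)
  stopifnot_scalar_number(event_rate, "event_rate", 0)
  stopifnot_scalar_number(counter_cv, "counter_cv", 0)
  if (length(allele_freqs) < 1L || is.null(names(allele_freqs)) ||
      any(allele_freqs < 0 | allele_freqs > 1)) {
    stop("`allele_freqs` must be a non-empty named vector of frequencies in [0,1]",
         call. = FALSE)
  }
  if (!all(grepl("\\*", names(allele_freqs)))) {
    stop("allele names must carry a locus prefix, e.g. 'A*03:01'", call. = FALSE)
  }
  structure(list(
    n_patients = as.integer(n_patients),
    braf_pos_fraction = braf_pos_fraction,
    median_ratio_brafpos = median_ratio_brafpos,
    median_ratio_brafwt = median_ratio_brafwt,
    ratio_log_sd = ratio_log_sd,
    allele_freqs = allele_freqs,
    event_rate = event_rate,
    effect_of_ratio_on_hazard = effect_of_ratio_on_hazard,
    counter_cv = counter_cv,
    admin_horizon_years = admin_horizon_years,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# draw two alleles per locus per subject, with replacement
draw_locus_alleles <- function(freqs, n) {
  resid <- 1 - sum(freqs)
  if (resid < -1e-9) stop("allele frequencies at one locus exceed 1",
                          call. = FALSE)
  locus <- sub("\\*.*$", "", names(freqs)[1])
  alleles <- names(freqs)
  p <- as.numeric(freqs)
  if (resid > 1e-12) {
    alleles <- c(alleles, paste0(locus, "*other"))
    p <- c(p, resid)
  }
  a1 <- sample(alleles, n, replace = TRUE, prob = p)
  a2 <- sample(alleles, n, replace = TRUE, prob = p)
  list(a1 = a1, a2 = a2)
}

#' Generate a synthetic patient cohort table
#'
#' @param spec A [cohort_spec()].
#' @return A data frame with one row per patient: clinical covariates
#'   (`age_group`, `sex`, `extent`, `biopsy_site`, `braf`), true lesional
#'   ratios (`cd8_ratio`, `cd3_ratio`), true total cell counts
#'   (`cd1a_true`, `cd3cd8neg_true`, `cd3cd8pos_true`, `n_images`), a
#'   semi-quantitative density score (`semiquant`), HLA allele columns
#'   (`<locus>_1`, `<locus>_2`) and survival fields
#'   (`followup_years`, `event`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_patients
    braf <- ifelse(stats::rbinom(n, 1, spec$braf_pos_fraction) == 1,
                   "V600E", "WT")
    med <- ifelse(braf == "V600E", spec$median_ratio_brafpos,
                  spec$median_ratio_brafwt)
    cd8_ratio <- stats::rlnorm(n, meanlog = log(med),
                               sdlog = spec$ratio_log_sd)
    # CD3+CD8- component; medians roughly 3x the CD8 compartment
    neg_ratio <- stats::rlnorm(n, meanlog = log(0.15), sdlog = 0.9)
    cd3_ratio <- cd8_ratio + neg_ratio
    # demographics drawn once from the marginal mix of the studied cohort
    age_group <- sample(c("pediatric", "adult"), n, TRUE, c(0.84, 0.16))
    sex <- sample(c("male", "female"), n, TRUE, c(0.52, 0.48))
    extent <- sample(c("SS", "MS RO-", "MS RO+"), n, TRUE,
                     c(0.77, 0.12, 0.11))
    biopsy_site <- sample(c("bone", "skin", "other"), n, TRUE,
                          c(0.60, 0.25, 0.15))
    n_images <- pmax(2L, as.integer(round_half_up(
      stats::rlnorm(n, log(16), 0.5))))
    cd1a_true <- pmax(50L, as.integer(round_half_up(
      stats::rlnorm(n, log(1400), 0.7))))
    cd3cd8pos_true <- as.integer(round_half_up(cd8_ratio * cd1a_true))
    cd3cd8neg_true <- as.integer(round_half_up(neg_ratio * cd1a_true))
    semiquant <- as.integer(cut(rank(cd3_ratio, ties.method = "first"),
                                breaks = 4, labels = FALSE))
    chemo_fdo <- stats::runif(n) < 0.34
    # survival: exponential with hazard modulated by centred log ratio
    lp <- spec$effect_of_ratio_on_hazard *
      (log(cd8_ratio) - mean(log(cd8_ratio)))
    hazard <- spec$event_rate * exp(lp)
    t_event <- if (spec$event_rate > 0) stats::rexp(n, rate = hazard) else
      rep(Inf, n)
    followup_years <- pmin(t_event, spec$admin_horizon_years)
    event <- t_event <= spec$admin_horizon_years
    out <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      age_group = age_group, sex = sex, extent = extent,
      biopsy_site = biopsy_site, braf = braf,
      cd8_ratio = cd8_ratio, cd3_ratio = cd3_ratio,
      cd1a_true = cd1a_true, cd3cd8neg_true = cd3cd8neg_true,
      cd3cd8pos_true = cd3cd8pos_true, n_images = n_images,
      semiquant = semiquant, chemo_fdo = chemo_fdo,
      followup_years = followup_years, event = event,
      stringsAsFactors = FALSE)
    # independent loci
    loci <- split(spec$allele_freqs,
                  sub("\\*.*$", "", names(spec$allele_freqs)))
    for (locus in names(loci)) {
      dr <- draw_locus_alleles(loci[[locus]], n)
      out[[paste0("hla_", tolower(locus), "_1")]] <- dr$a1
      out[[paste0("hla_", tolower(locus), "_2")]] <- dr$a2
    }
    out
  })
}

#' Simulate independent human counters around a true count
#'
#' Each counter's count is `round(truth * m)` with `m` a mean-1 lognormal
#' multiplier of coefficient of variation `counter_cv`, floored at zero.
#'
#' @param truth Named numeric vector of true per-class counts, or a
#'   `ground_truth_cell_map` (its `true_counts` is used).
#' @param counter_cv Coefficient of variation of the multiplicative error.
#' @param n_counters Number of counters (>= 1).
#' @param seed Integer seed.
#' @return Integer matrix, `n_counters` rows x classes.
#' @export
simulate_counters <- function(truth, counter_cv, n_counters = 2L, seed = 1L) {
  if (inherits(truth, "ground_truth_cell_map")) truth <- truth$true_counts
  stopifnot(is.numeric(truth), all(truth >= 0))
  stopifnot_scalar_number(counter_cv, "counter_cv", 0)
  stopifnot_scalar_number(n_counters, "n_counters", 1)
  with_seed(seed, {
    sdlog <- sqrt(log(1 + counter_cv^2))
    m <- matrix(stats::rlnorm(n_counters * length(truth),
                              meanlog = -sdlog^2 / 2, sdlog = sdlog),
                nrow = n_counters)
    counts <- matrix(pmax(0, round_half_up(sweep(m, 2, truth, `*`))),
                     nrow = n_counters)
    storage.mode(counts) <- "integer"
    colnames(counts) <- names(truth)
    rownames(counts) <- paste0("counter", seq_len(n_counters))
    counts
  })
}

# 4-parameter logistic response at concentration x
four_pl <- function(x, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (x / ic50)^hill)
}

#' Simulate a competition-binding titration
#'
#' Signal follows a four-parameter logistic (4PL) curve of the competitor
#' concentration with multiplicative mean-1 lognormal noise; at the true IC50
#' the noiseless signal equals the 4PL midpoint `(top + bottom) / 2`.
#'
#' @param true_ic50 True half-inhibitory concentration (nM).
#' @param hill Hill slope.
#' @param concentrations Competitor concentrations (nM), >= 4 positive values.
#' @param noise_cv Multiplicative noise coefficient of variation.
#' @param seed Integer seed.
#' @param top,bottom 4PL asymptotes in signal units.
#' @return Data frame (`concentration_nM`, `signal`) with attribute `truth`.
#' @export
generate_binding_curve <- function(true_ic50, hill = 1, concentrations,
                                   noise_cv = 0, seed = 1L,
                                   top = 1, bottom = 0) {
  stopifnot_scalar_number(true_ic50, "true_ic50", 1e-12)
  if (length(concentrations) < 4L || any(concentrations <= 0)) {
    stop("need >= 4 positive concentrations", call. = FALSE)
  }
  with_seed(seed, {
    mu <- four_pl(concentrations, top, bottom, true_ic50, hill)
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      mu <- mu * stats::rlnorm(length(mu), -sdlog^2 / 2, sdlog)
    }
    structure(data.frame(concentration_nM = concentrations, signal = mu),
              truth = list(ic50 = true_ic50, hill = hill,
                           top = top, bottom = bottom))
  })
}

#' Simulate a targeted-peptidomics (PRM) transition report
#'
#' For each peptide, paired light (endogenous) and heavy (spiked isotope
#' labelled) rows are produced per transition, with peak areas proportional to
#' amount via a shared per-transition response factor. A peptide with
#' `true_amount = 0` has light areas at the noise floor only and a
#' non-coeluting light retention time.
#'
#' @param peptides Character vector of peptide sequences.
#' @param true_amounts Numeric vector (fmol) of endogenous amounts, recycled.
#' @param heavy_spike Spiked heavy amount per peptide (fmol), > 0.
#' @param n_transitions Transitions monitored per peptide.
#' @param noise_cv Multiplicative area noise coefficient of variation.
#' @param seed Integer seed.
#' @return Data frame: `peptide`, `label` ("light"/"heavy"), `transition`,
#'   `area`, `rt` (minutes), with attribute `truth`.
#' @export
generate_prm_report <- function(peptides, true_amounts, heavy_spike = 40,
                                n_transitions = 5L, noise_cv = 0, seed = 1L) {
  stopifnot_scalar_number(heavy_spike, "heavy_spike", 1e-12)
  stopifnot(length(peptides) >= 1L, all(true_amounts >= 0))
  true_amounts <- rep_len(true_amounts, length(peptides))
  with_seed(seed, {
    rows <- vector("list", length(peptides))
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- function(k) if (noise_cv > 0)
      stats::rlnorm(k, -sdlog^2 / 2, sdlog) else rep(1, k)
    for (p in seq_along(peptides)) {
      f <- stats::rlnorm(n_transitions, log(1e5), 0.3)  # response factors
      trans <- paste0("y", seq(3, length.out = n_transitions))
      heavy_rt <- stats::runif(1, 10, 60)
      heavy_area <- f * heavy_spike * noise(n_transitions)
      amt <- true_amounts[p]
      if (amt > 0) {
        light_area <- f * amt * noise(n_transitions)
        light_rt <- heavy_rt +
          if (noise_cv > 0) stats::rnorm(1, 0, 0.02) else 0
      } else {
        # integration noise floor: ~1e-5 of the heavy response, random order
        light_area <- f * heavy_spike * stats::runif(n_transitions, 0, 1e-5)
        light_rt <- heavy_rt + stats::runif(1, 2, 10) * sample(c(-1, 1), 1)
      }
      rows[[p]] <- data.frame(
        peptide = peptides[p],
        label = rep(c("light", "heavy"), each = n_transitions),
        transition = c(trans, trans),
        area = c(light_area, heavy_area),
        rt = c(rep(light_rt, n_transitions), rep(heavy_rt, n_transitions)),
        stringsAsFactors = FALSE)
    }
    structure(do.call(rbind, rows),
              truth = list(true_amounts = stats::setNames(true_amounts,
                                                          peptides),
                           heavy_spike = heavy_spike))
  })
}

#' Write / read an RGB image as plain-text PPM (P3)
#'
#' Text-only image interchange used for fixtures; values are quantized to
#' 8-bit.
#'
#' @param image height x width x 3 array in [0,1].
#' @param path File path.
#' @return `read_ppm` returns the array (values in [0,1]).
#' @export
write_ppm <- function(image, path) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  h <- dim(image)[1]; w <- dim(image)[2]
  vals <- as.integer(round(pmin(pmax(image, 0), 1) * 255))
  # PPM is row-major, channels interleaved
  arr <- aperm(array(vals, dim = c(h, w, 3)), c(3, 2, 1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(w, h), "255"), con)
  writeLines(paste(as.vector(arr), collapse = " "), con)
  invisible(path)
}

#' @rdname write_ppm
#' @export
read_ppm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P3") stop("only ASCII PPM (P3) supported", call. = FALSE)
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  maxv <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)]) / maxv
  aperm(array(vals, dim = c(3, w, h)), c(3, 2, 1))
}
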