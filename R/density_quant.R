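# Connected components (4-connectivity) of a logical matrix via row runs and
# union-find; returns the component pixel sizes.
component_sizes <- function(mask) {
  h <- nrow(mask)
  parent <- integer(0)
  size <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union2 <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) {
      parent[rb] <<- ra
      size[ra] <<- size[ra] + size[rb]
    }
  }
  prev_runs <- NULL  # matrix: start, end, id
  for (i in seq_len(h)) {
    row <- mask[i, ]
    if (!any(row)) {
      prev_runs <- NULL
      next
    }
    r <- rle(row)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    runs <- cbind(start = starts[keep], end = ends[keep], id = NA_integer_)
    for (k in seq_len(nrow(runs))) {
      id <- length(parent) + 1L
      parent[id] <- id
      size[id] <- runs[k, "end"] - runs[k, "start"] + 1L
      runs[k, "id"] <- id
      if (!is.null(prev_runs)) {
        ov <- prev_runs[, "start"] <= runs[k, "end"] &
          prev_runs[, "end"] >= runs[k, "start"]
        for (pid in prev_runs[ov, "id"]) union2(pid, id)
      }
    }
    prev_runs <- runs
  }
  if (length(parent) == 0L) return(integer(0))
  roots <- vapply(seq_along(parent), find, integer(1))
  as.integer(size[sort(unique(roots))])
}

#' Count cells on class masks by connected-component labelling
#'
#' Emulates a human counter on classified pixel masks for pipeline testing:
#' the per-class count is the number of 4-connected components of area at
#' least `min_cell_area` pixels. A cell split by the ROI boundary into two
#' sufficiently large fragments is counted twice; this is a documented
#' limitation of the definition.
#'
#' @param masks List with disjoint logical matrices `green`, `red`, `purple`.
#' @param min_cell_area Minimum component area in pixels (default 20).
#' @return Named integer vector `c(cd1a, cd3cd8neg, cd3cd8pos)`.
#' @export
count_cells_from_masks <- function(masks, min_cell_area = 20) {
  if (any(masks$green & masks$red) || any(masks$green & masks$purple) ||
      any(masks$red & masks$purple)) {
    stop("class masks must be pairwise disjoint", call. = FALSE)
  }
  cnt <- function(m) sum(component_sizes(m) >= min_cell_area)
  c(cd1a = cnt(masks$green), cd3cd8neg = cnt(masks$red),
    cd3cd8pos = cnt(masks$purple))
}

#' Sum per-image counts into per-patient, per-counter totals
#'
#' @param records Data frame with columns `patient_id`, `counter_id`, and the
#'   class counts `cd1a`, `cd3cd8neg`, `cd3cd8pos` (one row per image).
#' @return Named numeric vector of per-class totals.
#' @export
aggregate_counts <- function(records) {
  need <- c("patient_id", "counter_id", "cd1a", "cd3cd8neg", "cd3cd8pos")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(records$patient_id)) != 1L ||
      length(unique(records$counter_id)) != 1L) {
    stop("records mix patients or counters; aggregate one (patient, counter)",
         call. = FALSE)
  }
  c(cd1a = sum(records$cd1a), cd3cd8neg = sum(records$cd3cd8neg),
    cd3cd8pos = sum(records$cd3cd8pos))
}

#' Adjudicate the totals of two independent counters
#'
#' Per class, the relative discrepancy is `|A - B| / mean(A, B)` (0 when both
#' are zero). If no class exceeds 10%, the final count is the rounded
#' (half-up) mean. Otherwise a referee selection is required: for each class
#' the referee value must equal counter A's or counter B's total.
#'
#' @param a,b Named per-class totals from the two counters (same classes).
#' @param referee Optional named per-class referee selection.
#' @param max_discrepancy Adjudication trigger (default 0.10).
#' @return An `adjudicated_count`: `final` counts, `discrepancy` per class,
#'   logical `adjudicated`.
#' @export
adjudicate_counts <- function(a, b, referee = NULL, max_discrepancy = 0.10) {
  stopifnot(identical(names(a), names(b)), all(a >= 0), all(b >= 0))
  m <- (a + b) / 2
  disc <- ifelse(m == 0, 0, abs(a - b) / m)
  needs <- any(disc > max_discrepancy)
  if (!needs) {
    final <- round_half_up(m)
  } else {
    if (is.null(referee)) {
      stop(sprintf(
        "counter totals differ by more than %.0f%%: referee selection required",
        100 * max_discrepancy), call. = FALSE)
    }
    stopifnot(identical(names(referee), names(a)))
    ok <- referee == a | referee == b
    if (!all(ok)) {
      stop("referee selection must equal counter A's or B's total per class",
           call. = FALSE)
    }
    final <- referee
  }
  structure(list(final = stats::setNames(as.numeric(final), names(a)),
                 discrepancy = stats::setNames(as.numeric(disc), names(a)),
                 adjudicated = needs),
            class = "adjudicated_count")
}

#' Referee emulation: pick, per class, the counter closer to ground truth
#'
#' Used only in synthetic runs where the truth is known; real analyses must
#' supply a human referee selection.
#'
#' @param a,b Counter totals; `truth` the true counts (same classes).
#' @return Named per-class selection drawn from `a`/`b` (ties go to A).
#' @export
referee_from_truth <- function(a, b, truth) {
  stopifnot(identical(names(a), names(b)))
  sel <- ifelse(abs(a - truth) <= abs(b - truth), a, b)
  stats::setNames(as.numeric(sel), names(a))
}

#' Density ratios from final adjudicated counts
#'
#' `cd3_ratio = (CD3+CD8- + CD3+CD8+) / CD1a`, `cd8_ratio = CD3+CD8+ / CD1a`;
#' `cells_per_tcell` is the rounded reciprocal of the CD8 ratio (the
#' "1 CD8+ T cell per N CD1a+ LCH-cells" statement), defined only for a
#' positive CD8 ratio.
#'
#' @param counts Named vector with `cd1a`, `cd3cd8neg`, `cd3cd8pos`.
#' @return A list `density_ratios`: `cd3_ratio`, `cd8_ratio`,
#'   `cells_per_tcell` (NA when `cd8_ratio` is 0).
#' @export
compute_density_ratios <- function(counts) {
  need <- c("cd1a", "cd3cd8neg", "cd3cd8pos")
  stopifnot(all(need %in% names(counts)))
  if (counts[["cd1a"]] <= 0) {
    stop("CD1a count is zero: density ratios are undefined", call. = FALSE)
  }
  cd8 <- counts[["cd3cd8pos"]] / counts[["cd1a"]]
  cd3 <- (counts[["cd3cd8neg"]] + counts[["cd3cd8pos"]]) / counts[["cd1a"]]
  structure(list(
    cd3_ratio = cd3, cd8_ratio = cd8,
    cells_per_tcell = if (cd8 > 0) as.integer(round(1 / cd8)) else NA_integer_
  ), class = "density_ratios")
}

#' Consensus of three semi-quantitative density scores
#'
#' Scores are integers 1-4 ("1+, no or sporadic T cells" up to "4+, highly
#' abundant"). If the maximum pairwise difference is at most 1, the final
#' score is the rounded (half-up) average. Otherwise the three scorers must
#' reach a collective consensus, supplied via `consensus`.
#'
#' @param scores Integer vector of exactly three scores in 1..4.
#' @param consensus Optional consensus score (1..4) used when required.
#' @return A `consensus_score`: `final`, `consensus_required`, `method`.
#' @export
consensus_score <- function(scores, consensus = NULL) {
  if (length(scores) != 3L || any(!scores %in% 1:4)) {
    stop("exactly three scores in 1..4 are required", call. = FALSE)
  }
  needs <- (max(scores) - min(scores)) > 1L
  if (!needs) {
    final <- as.integer(round_half_up(mean(scores)))
    method <- "rounded-average"
  } else {
    if (is.null(consensus)) {
      stop("scores differ by more than 1: a consensus score is required",
           call. = FALSE)
    }
    if (!consensus %in% 1:4) stop("consensus must be in 1..4", call. = FALSE)
    final <- as.integer(consensus)
    method <- "consensus"
  }
  structure(list(final = final, consensus_required = needs, method = method),
            class = "consensus_score")
}

#' Concordance between the three density quantification methods
#'
#' Pairwise Spearman rank correlations (with p-values) between the
#' count-based CD8 ratio, the area-based CD8 ratio and the semi-quantitative
#' score, plus a contingency table of score against ratio quartile.
#'
#' @param count_ratio,area_ratio Numeric per-patient CD8 ratios.
#' @param semiquant Integer per-patient scores 1..4.
#' @return A `concordance_report`: data frame `correlations`
#'   (pair, rho, p) and matrix `score_vs_quartile`.
#' @export
method_concordance <- function(count_ratio, area_ratio, semiquant) {
  n <- length(count_ratio)
  if (length(area_ratio) != n || length(semiquant) != n) {
    stop("inputs must be parallel per-patient vectors", call. = FALSE)
  }
  ok <- stats::complete.cases(count_ratio, area_ratio, semiquant)
  if (sum(ok) < 10L) {
    stop("need >= 10 patients with all three methods", call. = FALSE)
  }
  cr <- count_ratio[ok]; ar <- area_ratio[ok]; sq <- semiquant[ok]
  sp <- function(x, y) {
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    c(rho = unname(ct$estimate), p = ct$p.value)
  }
  cors <- rbind(count_vs_area = sp(cr, ar),
                count_vs_score = sp(cr, sq),
                area_vs_score = sp(ar, sq))
  quart <- cut(cr, breaks = stats::quantile(cr, probs = seq(0, 1, 0.25)),
               include.lowest = TRUE, labels = paste0("Q", 1:4))
  structure(list(
    correlations = data.frame(pair = rownames(cors), rho = cors[, "rho"],
                              p = cors[, "p"], row.names = NULL),
    score_vs_quartile = table(score = sq, quartile = quart)
  ), class = "concordance_report")
}
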