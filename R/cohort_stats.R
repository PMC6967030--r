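#' Median split of a continuous variable into HIGH / LOW groups
#'
#' Values strictly above the cohort median are HIGH; ties with the median go
#' LOW (this tie rule yields a 50/51 split of 101 distinct values).
#'
#' @param values Numeric vector (NAs allowed, labelled NA).
#' @return Character vector of labels `"HIGH"` / `"LOW"`.
#' @export
median_split <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2L) stop("need >= 2 non-missing values", call. = FALSE)
  med <- stats::median(values[ok])
  if (all(values[ok] == values[ok][1])) {
    warning("all values identical: degenerate split, everything LOW")
  }
  out <- ifelse(values > med, "HIGH", "LOW")
  out[!ok] <- NA_character_
  out
}

#' Mann-Whitney U comparison of two groups
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test: exact when both groups
#' have at most 8 observations and no ties, otherwise the tie-corrected
#' normal approximation with continuity correction.
#'
#' @param group_a,group_b Numeric vectors (each non-empty).
#' @param exact Force exact (`TRUE`) or asymptotic (`FALSE`); default decides
#'   by group size.
#' @return A `group_comparison` list: `statistic` (U), `p`, `test`.
#' @export
compare_continuous <- function(group_a, group_b, exact = NULL) {
  if (length(group_a) < 1L || length(group_b) < 1L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (is.null(exact)) exact <- length(group_a) <= 8L && length(group_b) <= 8L
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE))
  structure(list(statistic = unname(wt$statistic), p = wt$p.value,
                 test = "Mann-Whitney"),
            class = "group_comparison")
}

#' Fisher's exact comparison of a categorical variable between two groups
#'
#' @param tab 2x2 matrix of counts.
#' @return A `group_comparison` list: `statistic` (NA), `p`, `test`.
#' @export
compare_categorical <- function(tab) {
  structure(list(statistic = NA_real_, p = fisher_exact_2x2(tab),
                 test = "Fisher"),
            class = "group_comparison")
}

#' Kaplan-Meier curves with a log-rank comparison
#'
#' Product-limit estimates per group with right censoring; the two (or more)
#' group survival distributions are compared with the log-rank test. With no
#' events the log-rank statistic is undefined: the Kaplan-Meier fit is still
#' returned, with `logrank_p = NA` and an explanatory `logrank_error`.
#'
#' @param time Follow-up times (years).
#' @param event Logical/0-1 event indicators.
#' @param group Group labels.
#' @return A `survival_fit` list: `km` (a [survival::survfit()] object),
#'   `logrank_chisq`, `logrank_p`, `logrank_error` (NULL when defined).
#' @export
km_logrank <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  event <- as.integer(as.logical(event))
  df <- data.frame(time = time, event = event, group = factor(group))
  km <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  if (sum(event) == 0L || length(unique(df$group)) < 2L) {
    msg <- if (sum(event) == 0L) "no events: log-rank undefined" else
      "log-rank needs >= 2 groups"
    return(structure(list(km = km, logrank_chisq = NA_real_,
                          logrank_p = NA_real_, logrank_error = msg),
                     class = "survival_fit"))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1, lower.tail = FALSE)
  structure(list(km = km, logrank_chisq = unname(sd$chisq), logrank_p = p,
                 logrank_error = NULL),
            class = "survival_fit")
}

#' Univariate Cox regression on the log-transformed CD8 ratio
#'
#' Fits a Cox proportional hazards model (Efron tie handling) of event-free
#' survival on the natural-log CD8 ratio. Zero ratios are replaced by half
#' the smallest positive ratio in the cohort before the transform.
#'
#' @param records Data frame with `cd8_ratio`, `followup_years`, `event`.
#' @return A `cox_fit` list: `hr` (per unit log ratio), `ci_low`, `ci_high`,
#'   `p`, `beta`, `n_events`.
#' @export
cox_univariate_logratio <- function(records) {
  need <- c("cd8_ratio", "followup_years", "event")
  stopifnot(all(need %in% names(records)))
  df <- records[stats::complete.cases(records[, need]), need]
  if (sum(df$event) < 1L) stop("need >= 1 event for Cox regression",
                               call. = FALSE)
  r <- df$cd8_ratio
  if (any(r < 0)) stop("negative CD8 ratios", call. = FALSE)
  if (any(r == 0)) {
    pos <- r[r > 0]
    if (length(pos) == 0L) stop("all CD8 ratios are zero", call. = FALSE)
    r[r == 0] <- min(pos) / 2
  }
  df$log_ratio <- log(r)
  fit <- tryCatch(
    survival::coxph(
      survival::Surv(followup_years, as.integer(event)) ~ log_ratio,
      data = df, ties = "efron"),
    warning = function(w) stop("Cox fit did not converge cleanly: ",
                               conditionMessage(w), call. = FALSE))
  s <- summary(fit)
  structure(list(hr = unname(s$conf.int[1, "exp(coef)"]),
                 ci_low = unname(s$conf.int[1, "lower .95"]),
                 ci_high = unname(s$conf.int[1, "upper .95"]),
                 p = unname(s$coefficients[1, "Pr(>|z|)"]),
                 beta = unname(stats::coef(fit)[1]),
                 n_events = sum(df$event)),
            class = "cox_fit")
}

table1_row <- function(var, level, in_level, labels) {
  hi <- labels == "HIGH"; lo <- labels == "LOW"
  data.frame(variable = var, level = level,
             all_n = sum(in_level),
             all_pct = round(100 * mean(in_level)),
             high_n = sum(in_level & hi),
             high_pct = round(100 * sum(in_level & hi) / sum(hi)),
             low_n = sum(in_level & lo),
             low_pct = round(100 * sum(in_level & lo) / sum(lo)),
             p = NA_real_, stringsAsFactors = FALSE)
}

#' Patient-characteristics table stratified by the CD8-ratio median split
#'
#' Counts and column percentages per stratum with a Fisher exact p per
#' categorical variable (computed on the binary collapse of each row against
#' the rest), a Mann-Whitney p for follow-up, and BRAF-unknown patients shown
#' but excluded from the BRAF test.
#'
#' @param records A cohort data frame (see [generate_cohort()]); must carry
#'   `sex`, `age_group`, `extent`, `braf`, `chemo_fdo`, `followup_years`.
#' @param labels HIGH/LOW labels from [median_split()].
#' @return Data frame with one row per variable level plus a header `Patients`
#'   row; `p` is filled on the first row of each tested variable.
#' @export
build_table1 <- function(records, labels) {
  stopifnot(nrow(records) == length(labels))
  hi <- labels == "HIGH"; lo <- labels == "LOW"
  rows <- list(table1_row("Patients", "", rep(TRUE, nrow(records)), labels))
  add_cat <- function(var, field, levels) {
    first <- TRUE
    for (lv in levels) {
      r <- table1_row(var, lv, records[[field]] == lv, labels)
      if (first) {
        tab <- matrix(c(sum(records[[field]] == lv & hi),
                        sum(records[[field]] == lv & lo),
                        sum(records[[field]] != lv & hi),
                        sum(records[[field]] != lv & lo)), nrow = 2)
        r$p <- fisher_exact_2x2(tab)
        first <- FALSE
      }
      rows[[length(rows) + 1L]] <<- r
    }
  }
  add_cat("Gender", "sex", c("male", "female"))
  add_cat("Age distribution", "age_group", c("pediatric", "adult"))
  # disease extension: each stratum tested against the rest
  for (lv in c("SS", "MS RO-", "MS RO+")) {
    r <- table1_row("Disease extension", lv, records$extent == lv, labels)
    tab <- matrix(c(sum(records$extent == lv & hi),
                    sum(records$extent == lv & lo),
                    sum(records$extent != lv & hi),
                    sum(records$extent != lv & lo)), nrow = 2)
    r$p <- fisher_exact_2x2(tab)
    rows[[length(rows) + 1L]] <- r
  }
  # BRAF: unknown shown, excluded from the test
  known <- records$braf %in% c("V600E", "WT")
  r_pos <- table1_row("Mutation status", "V600E", records$braf == "V600E",
                      labels)
  tab <- matrix(c(sum(records$braf == "V600E" & hi),
                  sum(records$braf == "V600E" & lo),
                  sum(records$braf == "WT" & hi),
                  sum(records$braf == "WT" & lo)), nrow = 2)
  r_pos$p <- fisher_exact_2x2(tab)
  rows[[length(rows) + 1L]] <- r_pos
  rows[[length(rows) + 1L]] <- table1_row("Mutation status", "WT",
                                          records$braf == "WT", labels)
  if (any(!known)) {
    rows[[length(rows) + 1L]] <- table1_row("Mutation status", "unknown",
                                            !known, labels)
  }
  if ("chemo_fdo" %in% names(records)) {
    r <- table1_row("Chemotherapy for FDO", "yes", records$chemo_fdo, labels)
    tab <- matrix(c(sum(records$chemo_fdo & hi), sum(records$chemo_fdo & lo),
                    sum(!records$chemo_fdo & hi), sum(!records$chemo_fdo & lo)),
                  nrow = 2)
    r$p <- fisher_exact_2x2(tab)
    rows[[length(rows) + 1L]] <- r
  }
  fu <- table1_row("Follow-up", "median (years)", rep(TRUE, nrow(records)),
                   labels)
  fu$all_n <- stats::median(records$followup_years)
  fu$high_n <- stats::median(records$followup_years[hi])
  fu$low_n <- stats::median(records$followup_years[lo])
  fu$all_pct <- fu$high_pct <- fu$low_pct <- NA_real_
  fu$p <- compare_continuous(records$followup_years[hi],
                             records$followup_years[lo])$p
  rows[[length(rows) + 1L]] <- fu
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
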