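#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by summation over the hypergeometric support: the
#' p-value is the total probability of all tables with the observed margins
#' whose probability does not exceed that of the observed table (tie handling
#' with relative tolerance 1e-7). A table with an empty margin carries no
#' information and has p = 1 by definition.
#'
#' @param tab 2x2 matrix of non-negative integer counts
#'   (rows = groups, columns = outcome).
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0) ||
      any(tab != round(tab))) {
    stop("`tab` must be a 2x2 matrix of non-negative integers", call. = FALSE)
  }
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(c1, support) + lchoose(c2, r1 - support) - lchoose(n, r1)
  p_obs <- logp[support == tab[1, 1]]
  min(1, sum(exp(logp[logp <= p_obs + log1p(1e-7)])))
}

#' Exact Hardy-Weinberg equilibrium test (biallelic collapse)
#'
#' Exact conditional test: given the allele counts, the p-value is the summed
#' probability of all heterozygote counts no more probable than the one
#' observed. Multi-allelic HLA loci are handled upstream by collapsing each
#' allele against all others.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (carrier homozygote, heterozygote,
#'   non-carrier homozygote).
#' @return Exact p-value.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers", call. = FALSE)
  }
  n <- sum(counts)
  if (n < 1L) stop("need at least one genotype", call. = FALSE)
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n - nA
  if (nA == 0 || na == 0) return(1)  # monomorphic: single configuration
  h <- seq(nA %% 2, min(nA, na), by = 2)
  logp <- h * log(2) + lfactorial(n) + lfactorial(nA) + lfactorial(na) -
    lfactorial((nA - h) / 2) - lfactorial(h) - lfactorial((na - h) / 2) -
    lfactorial(2 * n)
  p_obs <- logp[h == n_Aa]
  min(1, sum(exp(logp[logp <= p_obs + log1p(1e-7)])))
}

#' Sidak correction for multiple comparisons
#'
#' @param p_raw Raw p-value(s) in [0,1].
#' @param n_tests Number of tests in the family (>= 1).
#' @return Adjusted p-value(s) `1 - (1 - p)^n`.
#' @export
sidak_correct <- function(p_raw, n_tests) {
  stopifnot(all(p_raw >= 0 & p_raw <= 1), n_tests >= 1)
  1 - (1 - p_raw)^n_tests
}

#' Woolf odds ratio with the Haldane correction
#'
#' Adds 0.5 to every cell before forming the odds ratio and its Woolf
#' (log-scale) 95% confidence interval, keeping both finite with zero cells.
#'
#' @param tab 2x2 matrix `[[a, b], [c, d]]` (carriers/non-carriers by group).
#' @return List: `or`, `ci_low`, `ci_high`.
#' @export
woolf_haldane_or <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  a <- tab[1, 1] + 0.5; b <- tab[1, 2] + 0.5
  c <- tab[2, 1] + 0.5; d <- tab[2, 2] + 0.5
  or <- a * d / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or,
       ci_low = exp(log(or) - 1.96 * se),
       ci_high = exp(log(or) + 1.96 * se))
}

#' Standard (maximum allowed) control-group size
#'
#' The control group is capped at the number of cases plus three times the
#' number of cases, i.e. four times the case count.
#'
#' @param n_cases Number of cases (>= 1).
#' @return The standard control size `4 * n_cases`.
#' @export
standard_control_size <- function(n_cases) {
  stopifnot_scalar_number(n_cases, "n_cases", 1)
  as.integer(n_cases + 3 * n_cases)
}

#' Good's sample-size standardization of a p-value
#'
#' Standardizes a p-value obtained against an oversized control group to the
#' standard control size: `min(0.5, p * sqrt(n_actual / n_standard))` when the
#' actual control group exceeds the standard size, unchanged otherwise.
#'
#' @param p_raw Raw p-value.
#' @param n_controls_actual Actual control-group size.
#' @param n_control_standard Standard control-group size
#'   (see [standard_control_size()]).
#' @return Standardized p-value.
#' @export
good_standardized_p <- function(p_raw, n_controls_actual,
                                n_control_standard) {
  stopifnot(all(p_raw >= 0 & p_raw <= 1),
            n_controls_actual >= 1, n_control_standard >= 1)
  if (n_controls_actual <= n_control_standard) return(p_raw)
  pmin(0.5, p_raw * sqrt(n_controls_actual / n_control_standard))
}

allele_resolution <- function(allele) {
  ifelse(grepl(":", allele, fixed = TRUE), "high", "low")
}

#' Carrier 2x2 contingency table for one allele
#'
#' A subject is a carrier iff the allele appears at least once in its genotype
#' (dominance coding); homozygous carriers count once.
#'
#' @param cases,controls Genotype tables: data frames with columns `subject`,
#'   `locus`, `allele1`, `allele2` (one row per subject-locus).
#' @param allele Allele name at the table's resolution (e.g. `"A*03:01"`).
#' @return A `carrier_contingency`: `allele` and counts `a` (case carriers),
#'   `b` (case non-carriers), `c` (control carriers), `d`.
#' @export
carrier_table <- function(cases, controls, allele) {
  locus <- sub("\\*.*$", "", allele)
  count_side <- function(g) {
    g <- g[g$locus == locus, , drop = FALSE]
    if (nrow(g) == 0L) {
      stop(sprintf("no genotypes at locus '%s'", locus), call. = FALSE)
    }
    res <- allele_resolution(c(g$allele1, g$allele2))
    res <- res[!grepl("\\*other$", c(g$allele1, g$allele2))]
    if (length(res) && !all(res == allele_resolution(allele))) {
      stop(sprintf(
        "allele '%s' is %s-resolution but the table mixes resolutions at %s",
        allele, allele_resolution(allele), locus), call. = FALSE)
    }
    carrier <- g$allele1 == allele | g$allele2 == allele
    c(carrier = sum(carrier), non = sum(!carrier))
  }
  cs <- count_side(cases)
  ct <- count_side(controls)
  structure(list(allele = allele, a = unname(cs["carrier"]),
                 b = unname(cs["non"]), c = unname(ct["carrier"]),
                 d = unname(ct["non"])),
            class = "carrier_contingency")
}

as_matrix_2x2 <- function(ct) {
  matrix(c(ct$a, ct$c, ct$b, ct$d), nrow = 2,
         dimnames = list(c("case", "control"), c("carrier", "non-carrier")))
}

#' Convert wide per-patient HLA columns to a long genotype table
#'
#' @param cohort A [generate_cohort()] data frame with `hla_<locus>_1/2`
#'   columns.
#' @return Data frame `subject`, `locus`, `allele1`, `allele2`.
#' @export
genotypes_from_cohort <- function(cohort) {
  cols <- grep("^hla_.*_1$", names(cohort), value = TRUE)
  if (length(cols) == 0L) stop("cohort has no hla_* columns", call. = FALSE)
  out <- lapply(cols, function(c1) {
    locus <- toupper(sub("^hla_(.*)_1$", "\\1", c1))
    data.frame(subject = cohort$patient_id, locus = locus,
               allele1 = cohort[[c1]],
               allele2 = cohort[[sub("_1$", "_2", c1)]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Case-control HLA association scan
#'
#' For every allele with at least one carrier among cases and controls (the
#' pooled `*other` allele is excluded), builds the carrier 2x2 table, runs the
#' two-sided Fisher test, applies a per-locus Sidak correction, computes the
#' Woolf-Haldane odds ratio with 95% CI, the Hardy-Weinberg exact p in cases
#' (biallelic collapse of the allele vs the rest), and standardizes the raw
#' p-value to the standard control size following Good when the control group
#' is larger.
#'
#' @param cases,controls Genotype tables (see [carrier_table()]). Controls may
#'   instead be a population reference data frame with columns `allele` and
#'   `carrier_freq` together with `n_controls`.
#' @param n_controls Control-group size; required when `controls` is a
#'   frequency table, otherwise inferred.
#' @return Data frame (one row per allele): `allele`, `locus`, `a`, `b`, `c`,
#'   `d`, `or`, `ci_low`, `ci_high`, `p_raw`, `p_sidak`, `p_standardized`,
#'   `p_hwe_cases`, `n_tests`, `n_control_standard`; sorted by
#'   `p_standardized`.
#' @export
run_association_scan <- function(cases, controls, n_controls = NULL) {
  is_freq <- is.data.frame(controls) && "carrier_freq" %in% names(controls)
  if (is_freq && is.null(n_controls)) {
    stop("`n_controls` is required with a frequency-table control reference",
         call. = FALSE)
  }
  n_cases_by_locus <- tapply(cases$subject, cases$locus,
                             function(s) length(unique(s)))
  if (is_freq) {
    # synthesize control carrier counts from carrier frequencies
    controls_gt <- NULL
  } else {
    controls_gt <- controls
  }
  locus_of <- function(a) sub("\\*.*$", "", a)
  case_alleles <- unique(c(cases$allele1, cases$allele2))
  ctrl_alleles <- if (is_freq) unique(controls$allele) else
    unique(c(controls$allele1, controls$allele2))
  alleles <- setdiff(union(case_alleles, ctrl_alleles), character(0))
  alleles <- alleles[!grepl("\\*other$", alleles)]
  rows <- list()
  for (al in alleles) {
    locus <- locus_of(al)
    n_cases <- n_cases_by_locus[[locus]]
    if (is.null(n_cases)) next
    g <- cases[cases$locus == locus, , drop = FALSE]
    case_car <- g$allele1 == al | g$allele2 == al
    a <- sum(case_car); b <- sum(!case_car)
    if (is_freq) {
      fr <- controls$carrier_freq[controls$allele == al]
      cc <- if (length(fr) == 1L) as.integer(round(fr * n_controls)) else 0L
      dd <- n_controls - cc
    } else {
      gc <- controls_gt[controls_gt$locus == locus, , drop = FALSE]
      ctrl_car <- gc$allele1 == al | gc$allele2 == al
      cc <- sum(ctrl_car); dd <- sum(!ctrl_car)
    }
    if (a + cc == 0L) next  # no carriers anywhere: untestable
    n_hom <- sum(g$allele1 == al & g$allele2 == al)
    n_het <- sum(case_car) - n_hom
    rows[[al]] <- data.frame(
      allele = al, locus = locus, a = a, b = b, c = cc, d = dd,
      p_hwe_cases = hwe_exact_test(n_hom, n_het, b),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no testable alleles", call. = FALSE)
  res <- do.call(rbind, rows)
  n_tests_by_locus <- table(res$locus)
  res$n_tests <- as.integer(n_tests_by_locus[res$locus])
  res$p_raw <- vapply(seq_len(nrow(res)), function(i) {
    fisher_exact_2x2(matrix(c(res$a[i], res$c[i], res$b[i], res$d[i]), 2))
  }, numeric(1))
  res$p_sidak <- sidak_correct(res$p_raw, res$n_tests)
  ors <- lapply(seq_len(nrow(res)), function(i) {
    woolf_haldane_or(matrix(c(res$a[i], res$c[i], res$b[i], res$d[i]), 2))
  })
  res$or <- vapply(ors, `[[`, numeric(1), "or")
  res$ci_low <- vapply(ors, `[[`, numeric(1), "ci_low")
  res$ci_high <- vapply(ors, `[[`, numeric(1), "ci_high")
  res$n_control_standard <- vapply(res$locus, function(l) {
    standard_control_size(n_cases_by_locus[[l]])
  }, integer(1))
  n_ctrl <- res$c + res$d
  res$p_standardized <- mapply(good_standardized_p, res$p_raw, n_ctrl,
                               res$n_control_standard)
  res <- res[order(res$p_standardized, res$p_raw), ]
  rownames(res) <- NULL
  res[, c("allele", "locus", "a", "b", "c", "d", "or", "ci_low", "ci_high",
          "p_raw", "p_sidak", "p_standardized", "p_hwe_cases", "n_tests",
          "n_control_standard")]
}
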