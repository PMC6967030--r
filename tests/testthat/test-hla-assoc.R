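test_that("fisher_exact_2x2 reproduces printed and derived values", {
  expect_equal(round(fisher_exact_2x2(matrix(c(18, 30, 28, 17), 2)), 2), 0.02)
  expect_equal(round(fisher_exact_2x2(matrix(c(39, 39, 11, 12), 2)), 2), 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  # empty margin carries no information
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 5, 7), 2)), 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("fisher_exact_2x2 equals the enumeration oracle on random tables", {
  set.seed(101)
  for (i in 1:300) {
    tab <- matrix(rpois(4, lambda = sample(c(2, 5, 15), 1)), 2)
    expect_equal(fisher_exact_2x2(tab), oracle_fisher_p(tab),
                 tolerance = 1e-10)
    # invariance under simultaneous row+column transposition
    expect_equal(fisher_exact_2x2(tab), fisher_exact_2x2(tab[2:1, 2:1]),
                 tolerance = 1e-12)
  }
})

test_that("HWE exact test matches the enumeration oracle", {
  expect_equal(hwe_exact_test(1, 2, 1), 1)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-10)
  expect_equal(hwe_exact_test(25, 0, 0), 1)  # monomorphic
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
  set.seed(7)
  for (i in 1:100) {
    g <- as.vector(stats::rmultinom(1, size = sample(5:60, 1),
                                    prob = c(0.2, 0.5, 0.3)))
    expect_equal(hwe_exact_test(g[1], g[2], g[3]),
                 oracle_hwe_p(g[1], g[2], g[3]), tolerance = 1e-9)
  }
})

test_that("Sidak correction: closed form, endpoints, monotonicity", {
  expect_equal(sidak_correct(0.2, 1), 0.2)
  expect_equal(sidak_correct(0.01, 10), 1 - 0.99^10)
  expect_equal(round(sidak_correct(0.01, 10), 4), 0.0956)
  expect_equal(sidak_correct(0, 5), 0)
  expect_equal(sidak_correct(1, 5), 1)
  ps <- seq(0, 1, by = 0.05)
  expect_true(all(diff(sidak_correct(ps, 7)) >= 0))
  expect_true(all(sidak_correct(0.02, 1:20) >= 0.02))
  # first-order agreement with Bonferroni for small n*p
  for (n in c(2, 5, 10)) {
    p <- 0.005
    expect_lte(abs(sidak_correct(p, n) - n * p), (n * p)^2)
  }
})

test_that("Woolf-Haldane odds ratios: worked values and reciprocity", {
  w <- woolf_haldane_or(matrix(c(18, 30, 28, 17), 2))
  expect_equal(w$or, 0.372, tolerance = 2e-3)
  expect_equal(w$ci_low, 0.163, tolerance = 5e-3)
  expect_equal(w$ci_high, 0.854, tolerance = 2e-3)
  expect_true(w$ci_low <= w$or && w$or <= w$ci_high)

  expect_equal(woolf_haldane_or(matrix(c(5, 5, 5, 5), 2))$or, 1)
  wz <- woolf_haldane_or(matrix(c(0, 10, 5, 5), 2))
  expect_equal(wz$or, 0.0476, tolerance = 2e-3)
  expect_true(is.finite(wz$ci_low) && is.finite(wz$ci_high))

  set.seed(3)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 8), 2)
    expect_equal(woolf_haldane_or(tab)$or,
                 1 / woolf_haldane_or(tab[2:1, ])$or, tolerance = 1e-12)
  }
})

test_that("standard control size and Good standardization", {
  expect_equal(standard_control_size(94), 376L)
  expect_equal(standard_control_size(1), 4L)
  expect_equal(standard_control_size(104), 416L)
  expect_equal(good_standardized_p(0.03, 376, 376), 0.03)
  expect_equal(good_standardized_p(0.03, 100, 376), 0.03)
  expect_equal(good_standardized_p(0.01, 5604, 376),
               0.01 * sqrt(5604 / 376))
  expect_equal(round(good_standardized_p(0.01, 5604, 376), 4), 0.0386)
  expect_equal(good_standardized_p(0.4, 4 * 376, 376), 0.5)  # capped
})

test_that("carrier tables use dominance coding", {
  cases <- make_genotype_table(104, 25, "A*03:01")
  controls <- make_genotype_table(200, 40, "A*03:01")
  ct <- carrier_table(cases, controls, "A*03:01")
  expect_equal(c(ct$a, ct$b, ct$c, ct$d), c(25, 79, 40, 160))
  expect_equal(round(100 * ct$a / (ct$a + ct$b)), 24)

  # homozygotes count once
  hom <- make_genotype_table(50, 10, "A*03:01", n_homozygous = 10)
  ct2 <- carrier_table(hom, controls, "A*03:01")
  expect_equal(ct2$a, 10)

  # no carriers anywhere is a valid table; Haldane keeps the OR finite
  none <- carrier_table(make_genotype_table(20, 0),
                        make_genotype_table(20, 0), "A*03:01")
  expect_equal(c(none$a, none$c), c(0, 0))
  expect_true(is.finite(woolf_haldane_or(lchquant:::as_matrix_2x2(none))$or))

  # resolution mismatch
  low <- data.frame(subject = "S1", locus = "A",
                    allele1 = "A*03", allele2 = "A*01")
  expect_error(carrier_table(low, low, "A*03:01"), "resolution")
})

test_that("association scan: single-allele locus and planted-effect power", {
  # single-allele locus (rest of the locus pooled): Sidak is the identity
  cases <- make_genotype_table(60, 12, other = "A*other")
  controls <- make_genotype_table(120, 20, other = "A*other")
  res <- run_association_scan(cases, controls)
  one <- res[res$allele == "A*03:01", ]
  expect_equal(one$n_tests, 1L)
  expect_equal(one$p_sidak, one$p_raw)
  expect_equal(one$n_control_standard, 240L)
  expect_true(all(res$p_sidak >= res$p_raw))
  expect_true(all(res$p_standardized <= pmax(res$p_raw, 0.5) + 1e-12))

  expect_error(run_association_scan(
    data.frame(subject = "S1", locus = "A",
               allele1 = "A*other", allele2 = "A*other"),
    data.frame(subject = "C1", locus = "A",
               allele1 = "A*other", allele2 = "A*other")),
    "no testable")

  # planted OR ~3 allele ranks first by standardized p in most replicates
  freqs <- stats::setNames(rep(0.03, 20), sprintf("A*%02d:01", 1:20))
  planted <- "A*07:01"
  hits <- 0L
  n_rep <- 60
  set.seed(19)
  for (r in seq_len(n_rep)) {
    draw <- function(n, f) {
      lchquant:::with_seed(sample.int(1e8, 1), {
        d <- lchquant:::draw_locus_alleles(f, n)
        data.frame(subject = seq_len(n), locus = "A",
                   allele1 = d$a1, allele2 = d$a2)
      })
    }
    f_case <- freqs
    f_case[planted] <- min(0.5, 3 * freqs[planted])  # allele-freq bump
    cs <- draw(500, f_case)
    ct <- draw(2000, freqs)
    sc <- run_association_scan(cs, ct)
    if (sc$allele[1] == planted) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})
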