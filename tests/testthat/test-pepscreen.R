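# synthetic BRAF-like context: valine at residue 600 inside the real local
# motif KIGDFGLATVKSRWSGSHQ (positions 591-609); the flanking sequence is a
# synthetic stand-in, not the full kinase
braf_context <- function() {
  paste0(strrep("M", 590), "KIGDFGLATVKSRWSGSHQ")
}

test_that("mutation-spanning enumeration: counts, offsets, worked peptides", {
  v <- protein_variant(braf_context(), 600, "V", "E")
  pep <- enumerate_mutation_spanning_peptides(v, 8:12)
  # interior variant: sum of lengths = 50 windows before dedup; flanking
  # homopolymer makes some windows identical, so assert via a unique context
  expect_true(all(pep$contains_variant))
  off <- mapply(substr, pep$sequence, pep$variant_offset, pep$variant_offset)
  expect_true(all(off == "E"))

  expect_true("KIGDFGLATE" %in% pep$sequence[pep$length == 10])
  expect_true("KIGDFGLATEK" %in% pep$sequence[pep$length == 11])
  k11 <- pep[pep$sequence == "KIGDFGLATEK", ]
  expect_equal(k11$start, 591L)
  expect_equal(k11$variant_offset, 10L)

  # fully distinct context: exactly sum(8:12) = 50 windows
  set.seed(2)
  aa <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTWY", "")[[1]], 60,
                     replace = TRUE), collapse = "")
  v2 <- protein_variant(aa, 30, substr(aa, 30, 30),
                        setdiff(c("V", "E"), substr(aa, 30, 30))[1])
  pep2 <- enumerate_mutation_spanning_peptides(v2, 8:12)
  expect_equal(nrow(pep2), 50L)
  expect_equal(as.vector(table(pep2$length)), c(8L, 9L, 10L, 11L, 12L))
  # sorted by (length, start)
  expect_false(is.unsorted(pep2$length))

  # variant near a terminus of a short protein: no fitting window
  v3 <- protein_variant("MKVLA", 3, "V", "E")
  expect_equal(nrow(enumerate_mutation_spanning_peptides(v3, 8)), 0L)

  expect_error(protein_variant("MKVLA", 9, "V", "E"), "outside")
  expect_error(protein_variant("MKVLA", 3, "K", "E"), "not")
  expect_error(protein_variant("MKVLA", 3, "V", "V"), "differ")
})

test_that("IC50 fitting: round trip, sentinel, rescaling invariance", {
  conc <- 10^seq(-1, 5, by = 0.5)
  tab <- generate_binding_curve(100, hill = 1, concentrations = conc,
                                noise_cv = 0, seed = 1)
  fit <- fit_ic50(tab)
  expect_lt(abs(fit$ic50 - 100) / 100, 1e-6)
  expect_equal(fit$hill, 1, tolerance = 1e-4)
  expect_false(fit$no_binding)
  expect_lt(fit$bottom, fit$top)

  # flat signal: no measurable binding sentinel
  flat <- data.frame(concentration_nM = conc, signal = rep(0.8, length(conc)))
  ff <- fit_ic50(flat)
  expect_true(ff$no_binding)
  expect_equal(ff$ic50, Inf)

  # rescaling signal units leaves ratio-based parameters unchanged
  tab2 <- tab
  tab2$signal <- tab2$signal * 1e4
  fit2 <- fit_ic50(tab2)
  expect_equal(fit2$ic50, fit$ic50, tolerance = 1e-6)
  expect_equal(fit2$hill, fit$hill, tolerance = 1e-4)

  expect_error(fit_ic50(data.frame(concentration_nM = c(1, 2, 4, 8),
                                   signal = 1:4)), "2 logs")
  expect_error(fit_ic50(tab[1:3, ]), ">= 4")
})

test_that("relative binding and classification follow the worked regimes", {
  expect_equal(relative_binding(260, 250)$ratio, 1.04)
  expect_equal(relative_binding(100, 5)$ratio, 20)
  expect_equal(relative_binding(672, 297)$ratio, 2.2626, tolerance = 1e-4)
  expect_equal(relative_binding(300, 300)$ratio, 1)
  expect_error(relative_binding(100, Inf), "no measurable")

  expect_equal(classify_binding(45), "strong")
  expect_equal(classify_binding(50), "strong")     # inclusive boundary
  expect_equal(classify_binding(297), "intermediate")
  expect_equal(classify_binding(672), "weak/non-binder")
  expect_equal(classify_binding(672, relative = 672 / 297),
               "intermediate-by-ratio")
  expect_equal(classify_binding(Inf), "weak/non-binder")
})

test_that("PRM abundance: arithmetic, linearity, permutation invariance", {
  tab <- data.frame(
    label = rep(c("light", "heavy"), each = 4),
    transition = rep(paste0("y", 3:6), 2),
    area = c(100, 150, 120, 130, 400, 600, 480, 520),
    rt = 25)
  q <- prm_abundance(tab, heavy_spike = 40)
  expect_equal(q$abundance, 40 * 500 / 2000)
  expect_equal(q$abundance, 10)

  # permutation of transitions
  qp <- prm_abundance(tab[sample(nrow(tab)), ], heavy_spike = 40)
  expect_equal(qp$abundance, q$abundance)

  # linear in summed light, inverse in summed heavy
  tab2 <- tab
  tab2$area[tab2$label == "light"] <- 2 * tab2$area[tab2$label == "light"]
  expect_equal(prm_abundance(tab2, 40)$abundance, 2 * q$abundance)

  tab0 <- tab
  tab0$area[tab0$label == "light"] <- 0
  expect_equal(prm_abundance(tab0, 40)$abundance, 0)

  tabh <- tab
  tabh$area[tabh$label == "heavy"] <- 0
  expect_error(prm_abundance(tabh, 40), "internal standard")
})

test_that("detection calls enforce co-elution, rank agreement and ratio", {
  rep1 <- generate_prm_report("PEPTIDEK", true_amounts = 10,
                              heavy_spike = 40, n_transitions = 5,
                              noise_cv = 0, seed = 4)
  q1 <- prm_abundance(rep1, 40)
  expect_true(as.logical(call_detection(q1)))

  rep0 <- generate_prm_report("PEPTIDEK", true_amounts = 0,
                              heavy_spike = 40, n_transitions = 5,
                              noise_cv = 0, seed = 4)
  expect_false(as.logical(call_detection(prm_abundance(rep0, 40))))

  # light signal at one transition only with min_transitions = 3
  tab <- data.frame(
    label = rep(c("light", "heavy"), each = 4),
    transition = rep(paste0("y", 3:6), 2),
    area = c(500, 0, 0, 0, 400, 600, 480, 520),
    rt = 25)
  q <- prm_abundance(tab, 40)
  expect_false(as.logical(call_detection(q, min_transitions = 3)))
})
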