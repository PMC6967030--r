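# Independent oracles used across the suite. These deliberately take
# different computational routes than the package implementation.

# Two-sided Fisher p via stats::fisher.test (the package enumerates lchoose
# terms itself).
oracle_fisher_p <- function(tab) {
  stats::fisher.test(tab)$p.value
}

# HWE exact p by enumerating unnormalized configuration weights
# w(h) = 2^h / (nAA! nAa! naa!) over the heterozygote support and normalizing,
# instead of the closed-form conditional probability.
oracle_hwe_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n - nA
  if (nA == 0 || na == 0) return(1)
  h <- seq(nA %% 2, min(nA, na), by = 2)
  logw <- h * log(2) - lfactorial((nA - h) / 2) - lfactorial(h) -
    lfactorial((na - h) / 2)
  w <- exp(logw - max(logw))
  p <- w / sum(w)
  obs <- p[h == n_Aa]
  sum(p[p <= obs * (1 + 1e-7)])
}

# Brute-force triangle rasterization by barycentric sign tests on each pixel
# centre (package route: even-odd ray casting).
oracle_triangle_pixel_count <- function(v1, v2, v3, width, height) {
  sgn <- function(p, a, b) {
    (p[1] - b[1]) * (a[2] - b[2]) - (a[1] - b[1]) * (p[2] - b[2])
  }
  count <- 0L
  for (i in seq_len(height)) {
    for (j in seq_len(width)) {
      p <- c(j - 0.5, i - 0.5)
      d1 <- sgn(p, v1, v2); d2 <- sgn(p, v2, v3); d3 <- sgn(p, v3, v1)
      neg <- (d1 < 0) || (d2 < 0) || (d3 < 0)
      pos <- (d1 > 0) || (d2 > 0) || (d3 > 0)
      if (!(neg && pos)) count <- count + 1L
    }
  }
  count
}

# Re-rasterize the ground-truth disks of a synthetic image independently of
# the renderer's painting order and bounding boxes.
oracle_class_pixel_areas <- function(truth, width, height) {
  cx <- rep(seq_len(width) - 0.5, each = height)
  cy <- rep(seq_len(height) - 0.5, times = width)
  owner <- rep(NA_character_, width * height)
  cells <- truth$cells
  for (k in seq_len(nrow(cells))) {
    hit <- (cx - cells$x[k])^2 + (cy - cells$y[k])^2 <= cells$radius[k]^2
    owner[hit] <- cells$class[k]  # disks are non-overlapping by construction
  }
  tab <- table(factor(owner, levels = c("cd1a", "cd3cd8neg", "cd3cd8pos")))
  as.numeric(tab)
}

# A small genotype table with a stated number of carriers of one allele.
make_genotype_table <- function(n, n_carriers, allele = "A*03:01",
                                other = "A*01:01", n_homozygous = 0) {
  locus <- sub("\\*.*$", "", allele)
  a1 <- rep(other, n)
  a2 <- rep(other, n)
  if (n_carriers > 0) a1[seq_len(n_carriers)] <- allele
  if (n_homozygous > 0) a2[seq_len(n_homozygous)] <- allele
  data.frame(subject = sprintf("S%04d", seq_len(n)), locus = locus,
             allele1 = a1, allele2 = a2, stringsAsFactors = FALSE)
}
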