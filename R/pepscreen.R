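#' A single amino-acid substitution in a protein
#'
#' @param sequence Amino-acid string (one-letter codes).
#' @param position 1-based residue index of the substitution.
#' @param ref_aa,alt_aa Reference and alternate residues (must differ; the
#'   sequence must carry `ref_aa` at `position`).
#' @return A `protein_variant` object.
#' @export
protein_variant <- function(sequence, position, ref_aa, alt_aa) {
  sequence <- toupper(gsub("\\s", "", sequence))
  stopifnot_scalar_number(position, "position", 1)
  if (position > nchar(sequence)) {
    stop("variant position outside the sequence", call. = FALSE)
  }
  if (substr(sequence, position, position) != ref_aa) {
    stop(sprintf("sequence has '%s' at position %d, not '%s'",
                 substr(sequence, position, position), position, ref_aa),
         call. = FALSE)
  }
  if (ref_aa == alt_aa) stop("ref and alt residues must differ",
                             call. = FALSE)
  structure(list(sequence = sequence, position = as.integer(position),
                 ref_aa = ref_aa, alt_aa = alt_aa),
            class = "protein_variant")
}

#' Enumerate mutation-spanning peptides of given lengths
#'
#' All windows of each requested length that lie fully inside the protein and
#' cover the variant position, with the alternate residue substituted.
#' Duplicate sequences are removed (first occurrence kept); results are
#' sorted by (length, start). A variant near a terminus simply yields fewer
#' windows.
#'
#' @param variant A [protein_variant()].
#' @param lengths Window lengths (default 8:12, the HLA class I range).
#' @return Data frame: `sequence`, `start` (1-based), `length`,
#'   `variant_offset` (1-based position of the substituted residue within the
#'   peptide), `contains_variant` (always TRUE).
#' @export
enumerate_mutation_spanning_peptides <- function(variant, lengths = 8:12) {
  stopifnot(inherits(variant, "protein_variant"), all(lengths >= 1))
  mut <- variant$sequence
  substr(mut, variant$position, variant$position) <- variant$alt_aa
  n <- nchar(mut)
  pos <- variant$position
  rows <- list()
  for (L in sort(unique(as.integer(lengths)))) {
    starts <- seq.int(max(1L, pos - L + 1L), min(pos, n - L + 1L))
    starts <- starts[starts >= 1L & starts + L - 1L <= n]
    for (s in starts) {
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = substr(mut, s, s + L - 1L),
        start = s, length = L, variant_offset = pos - s + 1L,
        contains_variant = TRUE, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(sequence = character(), start = integer(),
                      length = integer(), variant_offset = integer(),
                      contains_variant = logical()))
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out$sequence), ]
  out <- out[order(out$length, out$start), ]
  rownames(out) <- NULL
  out
}

#' Fit a four-parameter logistic competition-binding curve
#'
#' Least-squares 4PL fit of signal against log10 concentration, returning the
#' half-inhibitory concentration (IC50, nM), Hill slope and asymptotes. Data
#' whose fitted dynamic range is below three times the residual noise are
#' reported as "no measurable binding" with an infinite IC50 sentinel rather
#' than an extrapolated number.
#'
#' @param titration Data frame with `concentration_nM` and `signal`.
#' @return An `ic50_fit` list: `ic50`, `hill`, `top`, `bottom`,
#'   `residual_sd`, `no_binding` flag.
#' @export
fit_ic50 <- function(titration) {
  need <- c("concentration_nM", "signal")
  stopifnot(all(need %in% names(titration)))
  x <- titration$concentration_nM
  y <- titration$signal
  if (length(x) < 4L || any(x <= 0)) {
    stop("need >= 4 positive concentration points", call. = FALSE)
  }
  if (max(x) / min(x) < 100) {
    stop("concentrations must span >= 2 logs", call. = FALSE)
  }
  scale <- max(abs(y), 1e-12)
  ys <- y / scale
  lx <- log10(x)
  sse <- function(th) {
    mu <- th[2] + (th[1] - th[2]) / (1 + 10^((lx - th[3]) * exp(th[4])))
    sum((ys - mu)^2)
  }
  # starts: asymptotes from the data, midpoint from the closest point
  mid <- (max(ys) + min(ys)) / 2
  l0 <- lx[which.min(abs(ys - mid))]
  starts <- list(c(max(ys), min(ys), l0, 0),
                 c(max(ys), min(ys), stats::median(lx), 0),
                 c(max(ys), min(ys), l0, log(2)))
  best <- NULL
  for (st in starts) {
    f <- stats::optim(st, sse, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-15))
    f <- stats::optim(f$par, sse, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-15))
    if (is.null(best) || f$value < best$value) best <- f
  }
  th <- best$par
  top <- th[1] * scale; bottom <- th[2] * scale
  ic50 <- 10^th[3]; hill <- exp(th[4])
  resid_sd <- sqrt(best$value / max(1, length(ys) - 4)) * scale
  dynamic_range <- abs(top - bottom)
  no_binding <- dynamic_range < max(3 * resid_sd, 1e-3 * scale) ||
    ic50 > 1e3 * max(x)
  if (bottom > top) {  # canonical orientation: signal decreases with dose
    tmp <- top; top <- bottom; bottom <- tmp
  }
  structure(list(
    ic50 = if (no_binding) Inf else ic50,
    hill = hill, top = top, bottom = bottom, residual_sd = resid_sd,
    no_binding = no_binding
  ), class = "ic50_fit")
}

#' Relative binding capacity against a strong-binding reference peptide
#'
#' The IC50 ratio of a target to an established strong-binding reference
#' carries more information on true HLA binding capacity than the absolute
#' IC50 (compare 260 vs 250 against 100 vs 5).
#'
#' @param ic50_target,ic50_reference Positive finite IC50s (nM).
#' @return List: `ratio`, `interpretation`.
#' @export
relative_binding <- function(ic50_target, ic50_reference) {
  if (!is.finite(ic50_reference) || ic50_reference <= 0) {
    stop("reference peptide shows no measurable binding", call. = FALSE)
  }
  if (!is.finite(ic50_target) || ic50_target <= 0) {
    stop("target IC50 must be finite and positive", call. = FALSE)
  }
  ratio <- ic50_target / ic50_reference
  interpretation <- if (ratio <= 3) {
    "binding capacity comparable to the strong-binding reference"
  } else if (ratio <= 20) {
    "markedly weaker binding than the reference"
  } else {
    "negligible binding relative to the reference"
  }
  list(ratio = ratio, interpretation = interpretation)
}

#' Classify an IC50 into binding strength classes
#'
#' Cutoffs anchor at 50 nM (strong, inclusive) and 500 nM (intermediate,
#' inclusive); above 500 nM is weak/non-binder and the no-binding sentinel
#' (infinite IC50) is a non-binder. When the IC50 falls in (500, 1000] but the
#' relative binding ratio against the reference is below 3, the label
#' `"intermediate-by-ratio"` is used instead, reflecting the reference-ratio
#' interpretation of borderline absolute IC50s.
#'
#' @param ic50 IC50 in nM (may be `Inf`).
#' @param relative Optional relative binding ratio (target/reference).
#' @return Class label: `"strong"`, `"intermediate"`,
#'   `"intermediate-by-ratio"` or `"weak/non-binder"`.
#' @export
classify_binding <- function(ic50, relative = NULL) {
  stopifnot(ic50 > 0)
  if (!is.finite(ic50)) return("weak/non-binder")
  if (ic50 <= 50) return("strong")
  if (ic50 <= 500) return("intermediate")
  if (ic50 <= 1000 && !is.null(relative) && relative < 3) {
    return("intermediate-by-ratio")
  }
  "weak/non-binder"
}

#' Light/heavy abundance quantitation of one PRM peptide
#'
#' Abundance is the heavy spike scaled by the summed light over summed heavy
#' peak areas across the transitions shared by both labels.
#'
#' @param transitions Transition table for one peptide: columns `label`
#'   ("light"/"heavy"), `transition`, `area`, and optionally `rt`.
#' @param heavy_spike Spiked heavy amount (fmol).
#' @return A `prm_quant` list: `abundance` (fmol), `ratio`, per-transition
#'   `light_area`, `heavy_area`, `light_rt`, `heavy_rt`, `transitions`.
#' @export
prm_abundance <- function(transitions, heavy_spike = 40) {
  need <- c("label", "transition", "area")
  stopifnot(all(need %in% names(transitions)), heavy_spike > 0)
  if ("peptide" %in% names(transitions) &&
      length(unique(transitions$peptide)) > 1L) {
    stop("pass the transitions of a single peptide", call. = FALSE)
  }
  li <- transitions[transitions$label == "light", , drop = FALSE]
  he <- transitions[transitions$label == "heavy", , drop = FALSE]
  shared <- intersect(li$transition, he$transition)
  if (length(shared) == 0L) stop("no shared transitions", call. = FALSE)
  li <- li[match(shared, li$transition), ]
  he <- he[match(shared, he$transition), ]
  if (sum(he$area) <= 0) {
    stop("internal standard failure: all heavy areas are zero", call. = FALSE)
  }
  ratio <- sum(li$area) / sum(he$area)
  structure(list(
    abundance = heavy_spike * ratio, ratio = ratio,
    light_area = stats::setNames(li$area, shared),
    heavy_area = stats::setNames(he$area, shared),
    light_rt = if ("rt" %in% names(li)) stats::setNames(li$rt, shared) else NULL,
    heavy_rt = if ("rt" %in% names(he)) stats::setNames(he$rt, shared) else NULL,
    transitions = shared, heavy_spike = heavy_spike
  ), class = "prm_quant")
}

#' Present/absent detection call for a PRM-quantified peptide
#'
#' Detected iff (i) at least `min_transitions` light transitions have positive
#' area and co-elute with the heavy standard (|delta RT| within
#' `rt_tolerance`), (ii) the light and heavy transition intensities agree in
#' rank (Spearman correlation >= `min_rank_cor`), and (iii) the summed
#' light/heavy abundance ratio is at least `min_ratio`.
#'
#' @param quant A [prm_abundance()] result with retention times.
#' @param min_transitions Minimum co-eluting transitions (default 3).
#' @param min_ratio Minimum abundance ratio (default 0.001).
#' @param rt_tolerance Co-elution tolerance in minutes (default 0.5).
#' @param min_rank_cor Minimum light/heavy intensity rank correlation.
#' @return Logical detection flag, with attribute `checks`.
#' @export
call_detection <- function(quant, min_transitions = 3L, min_ratio = 0.001,
                           rt_tolerance = 0.5, min_rank_cor = 0.9) {
  stopifnot(inherits(quant, "prm_quant"))
  if (is.null(quant$light_rt) || is.null(quant$heavy_rt)) {
    stop("detection calling needs retention times", call. = FALSE)
  }
  coelute <- quant$light_area > 0 &
    abs(quant$light_rt - quant$heavy_rt) <= rt_tolerance
  n_coeluting <- sum(coelute)
  rank_cor <- if (length(quant$transitions) >= 3L &&
                  stats::sd(quant$light_area) > 0 &&
                  stats::sd(quant$heavy_area) > 0) {
    suppressWarnings(stats::cor(quant$light_area, quant$heavy_area,
                                method = "spearman"))
  } else 0
  checks <- c(coelution = n_coeluting >= min_transitions,
              rank_correlation = isTRUE(rank_cor >= min_rank_cor),
              abundance = quant$ratio >= min_ratio)
  structure(all(checks), checks = checks, n_coeluting = n_coeluting,
            rank_cor = rank_cor)
}

#' Read a protein FASTA (first record)
#'
#' Uses Biostrings when available, otherwise a minimal text parser.
#'
#' @param path FASTA file path.
#' @return Amino-acid sequence string.
#' @export
read_protein_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    return(as.character(Biostrings::readAAStringSet(path)[[1]]))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^>", lines)]
  toupper(gsub("\\s", "", paste(lines, collapse = "")))
}
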