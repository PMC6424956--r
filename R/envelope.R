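# Isotopologue envelopes aggregated by nominal mass offset k (unit-mass
# bins), matching unit-mass-resolved MALDI-TOF. The exact m/z reported per
# bin is the abundance-weighted mean of the isotopologue masses in it.

# single-atom offset distribution for one element:
# list(p = abundance by k = 0..K, m = mean atom mass by k)
.atom_dist <- function(element) {
  iso <- .isotope_data[[element]]
  offset <- as.integer(round(iso$mass - iso$mass[1]))
  kmax <- max(offset)
  p <- numeric(kmax + 1)
  m <- numeric(kmax + 1)
  p[offset + 1] <- iso$abundance
  m[offset + 1] <- iso$mass
  list(p = p, m = m)
}

# convolve two (p, mass-mean) distributions over nominal offsets
.convolve_dist <- function(a, b, tail_cut) {
  na <- length(a$p)
  nb <- length(b$p)
  n <- na + nb - 1
  p <- numeric(n)
  wm <- numeric(n) # probability-weighted mass sum
  for (i in seq_len(na)) {
    if (a$p[i] == 0) next
    idx <- i:(i + nb - 1)
    contrib <- a$p[i] * b$p
    p[idx] <- p[idx] + contrib
    wm[idx] <- wm[idx] + contrib * (a$m[i] + b$m)
  }
  m <- ifelse(p > 0, wm / p, 0)
  # drop a vanishing tail to keep the vectors short
  keep <- which(p >= tail_cut)
  if (length(keep) > 0) {
    last <- max(keep)
    p <- p[seq_len(last)]
    m <- m[seq_len(last)]
  }
  list(p = p, m = m)
}

.dist_power <- function(base, n, tail_cut) {
  result <- list(p = 1, m = 0)
  while (n > 0) {
    if (n %% 2 == 1) result <- .convolve_dist(result, base, tail_cut)
    base_next <- if (n > 1) .convolve_dist(base, base, tail_cut) else base
    base <- base_next
    n <- n %/% 2
  }
  result
}

#' Isotopologue envelope of a composition
#'
#' Computes the natural-abundance isotopologue envelope by per-element
#' multinomial expansion combined by convolution over nominal mass offsets
#' k = 0, 1, 2, ... Peaks beyond the last offset whose abundance reaches
#' `truncation` are pruned and the envelope is renormalized to sum exactly
#' to 1. Explicit-isotope pseudo-elements (13C, 2H) contribute a fixed mass
#' and no envelope spread.
#'
#' @param x An [composition()] or a [peptide_species()] (composed first).
#' @param truncation Abundance fraction below which trailing peaks are
#'   pruned; in (0, 1).
#' @return A tibble of class `isotope_pattern` with columns `k` (nominal
#'   mass offset), `mz` (exact neutral isotopologue mass in Da,
#'   abundance-weighted within the unit-mass bin) and `abundance`
#'   (fractions summing to 1).
#' @export
#' @examples
#' isotope_pattern(parse_formula("C1")) # 0.9893 / 0.0107
#' isotope_pattern(peptide_species("HAIYPRH",
#'   n_terminus = "acetyl_light",
#'   c_terminus = "amide"
#' ))
isotope_pattern <- function(x, truncation = 1e-6) {
  if (inherits(x, "peptide_species")) x <- compose_peptide(x)
  stopifnot(inherits(x, "elemental_composition"))
  stopifnot(truncation > 0, truncation < 1)
  tail_cut <- min(truncation * 1e-4, 1e-12)
  dist <- list(p = 1, m = 0)
  for (el in names(x)) {
    el_dist <- .dist_power(.atom_dist(el), unclass(x)[[el]], tail_cut)
    dist <- .convolve_dist(dist, el_dist, tail_cut)
  }
  p <- dist$p
  m <- dist$m
  keep_last <- max(c(1, which(p >= truncation)))
  p <- p[seq_len(keep_last)]
  m <- m[seq_len(keep_last)]
  out <- tibble::tibble(
    k = seq_along(p) - 1L,
    mz = m,
    abundance = p / sum(p)
  )
  out <- out[out$abundance > 0 | out$k == 0L, ]
  structure(out, class = c("isotope_pattern", class(tibble::tibble())))
}

#' Light-envelope abundance in the heavy monoisotopic region
#'
#' The +4 label places the heavy monoisotopic peak four unit masses above
#' the light one, so any light-envelope abundance at offsets k >= 4
#' overlaps the heavy signal. This reports that summed abundance and flags
#' it when it exceeds `min_fraction`; for peptides below ~1.5 kDa it is
#' small, which is the premise of the label design.
#'
#' @param light An `isotope_pattern` of the light species.
#' @param min_fraction Overlap abundance fraction above which the flag is
#'   raised; in (0, 1).
#' @return A list with `overlap_abundance`, `flag`, and `min_fraction`.
#' @export
overlap_risk <- function(light, min_fraction = 0.05) {
  stopifnot(inherits(light, "isotope_pattern"))
  stopifnot(min_fraction > 0, min_fraction < 1)
  ab <- sum(light$abundance[light$k >= 4L])
  list(
    overlap_abundance = ab,
    flag = ab > min_fraction,
    min_fraction = min_fraction
  )
}
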