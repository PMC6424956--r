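# Peak picking, light/heavy envelope matching and the area-ratio
# quantification at the heart of the internal-standard method. Areas, not
# apex heights, are the default response.

#' Quantification settings
#'
#' @param snr_threshold Minimum apex signal-to-noise for a peak; the noise
#'   is estimated as 1.4826 x the median absolute deviation of the
#'   intensities after excluding the top 5 percent of values.
#' @param window Half-width (Da) for centroiding and trapezoidal area
#'   integration around each apex, and the minimum separation between
#'   reported peaks.
#' @param tol Matching tolerance (Da) between a picked centroid and a
#'   theoretical isotopologue m/z. The default 0.15 Da suits unit-mass
#'   resolved MALDI-TOF with some calibration drift.
#' @param k_range Number of isotopologue offsets (k = 0..k_range-1) summed
#'   per species. The default 3 stays inside the overlap-free zone
#'   guaranteed by the +4 label for light peptides.
#' @param adducts Adducts used for quantification; default `"H"` only,
#'   since adduct propensity can vary spot to spot even when equal between
#'   light and heavy.
#' @param correct_overlap If `TRUE`, subtract the predicted light-envelope
#'   tail (offsets k >= 4) from the heavy areas; needed for heavier
#'   analytes whose envelope reaches the heavy monoisotopic region.
#' @param use `"area"` (default) or `"apex"` response.
#' @param truncation Envelope truncation for the theoretical patterns.
#' @param on_missing_heavy `"error"` (default) or `"na"`: what to do when
#'   the heavy internal standard is not found in the spectrum.
#' @return A `quant_settings` list.
#' @export
quant_settings <- function(snr_threshold = 3,
                           window = 0.3,
                           tol = 0.15,
                           k_range = 3,
                           adducts = "H",
                           correct_overlap = FALSE,
                           use = c("area", "apex"),
                           truncation = 1e-8,
                           on_missing_heavy = c("error", "na")) {
  use <- match.arg(use)
  on_missing_heavy <- match.arg(on_missing_heavy)
  stopifnot(snr_threshold > 0, window > 0, tol > 0, k_range >= 1)
  stopifnot(all(adducts %in% c("H", "Na", "K")))
  structure(
    list(
      snr_threshold = snr_threshold, window = window, tol = tol,
      k_range = as.integer(k_range), adducts = adducts,
      correct_overlap = isTRUE(correct_overlap), use = use,
      truncation = truncation, on_missing_heavy = on_missing_heavy
    ),
    class = "quant_settings"
  )
}

# robust noise level: sd-scaled MAD after dropping the top 5% of intensities
.noise_estimate <- function(intensity) {
  if (length(intensity) == 0) return(0)
  trimmed <- intensity[intensity <= stats::quantile(intensity, 0.95, names = FALSE)]
  if (length(trimmed) == 0) trimmed <- intensity
  stats::mad(trimmed, constant = 1.4826)
}

#' Pick peaks from a profile spectrum
#'
#' Local maxima whose baseline-subtracted apex exceeds `snr_threshold`
#' times the robust noise estimate are reported, strongest first within a
#' `window` exclusion zone so one peak yields one entry. The centroid is
#' the intensity-weighted mean m/z and the area the trapezoidal integral of
#' the baseline-subtracted intensities within +/- `window` of the apex. The
#' baseline is the median intensity.
#'
#' @param spectrum A [mass_spectrum()] (any tibble with `mz`, `intensity`).
#' @param snr_threshold,window See [quant_settings()].
#' @return Tibble with columns `centroid_mz`, `apex_intensity`
#'   (baseline-subtracted), `area`, `snr`, sorted by `centroid_mz`. `snr`
#'   is `Inf` on a noiseless spectrum.
#' @export
pick_peaks <- function(spectrum, snr_threshold = 3, window = 0.3) {
  stopifnot(snr_threshold > 0, window > 0)
  empty <- tibble::tibble(
    centroid_mz = numeric(), apex_intensity = numeric(),
    area = numeric(), snr = numeric()
  )
  if (is.null(spectrum) || nrow(spectrum) < 3) return(empty)
  mz <- spectrum$mz
  y <- spectrum$intensity
  baseline <- stats::median(y)
  noise <- .noise_estimate(y)
  threshold <- baseline + snr_threshold * noise
  n <- length(y)
  interior <- 2:(n - 1)
  is_max <- y[interior] > y[interior - 1] & y[interior] >= y[interior + 1]
  cand <- interior[is_max & y[interior] > threshold & y[interior] > baseline]
  if (length(cand) == 0) return(empty)
  cand <- cand[order(y[cand], decreasing = TRUE)]
  accepted <- integer()
  for (i in cand) {
    if (length(accepted) == 0 || all(abs(mz[i] - mz[accepted]) >= window)) {
      accepted <- c(accepted, i)
    }
  }
  rows <- purrr::map_dfr(accepted, function(i) {
    sel <- which(mz >= mz[i] - window & mz <= mz[i] + window)
    w <- pmax(y[sel] - baseline, 0)
    centroid <- if (sum(w) > 0) sum(mz[sel] * w) / sum(w) else mz[i]
    area <- .trapz(mz[sel], y[sel] - baseline)
    tibble::tibble(
      centroid_mz = centroid,
      apex_intensity = y[i] - baseline,
      area = area,
      snr = if (noise > 0) (y[i] - baseline) / noise else Inf
    )
  })
  dplyr::arrange(rows, .data$centroid_mz)
}

.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' Match picked peaks to a theoretical isotopologue envelope
#'
#' For each offset k = 0..k_range-1 the nearest unassigned picked peak
#' within `tol` of the theoretical m/z (pattern m/z plus adduct shift) is
#' assigned; ties break toward lower m/z, missing offsets are recorded, and
#' a peak is assigned to at most one offset.
#'
#' @param peaks Tibble from [pick_peaks()].
#' @param pattern An [isotope_pattern()] of the neutral species.
#' @param adduct `"H"`, `"Na"` or `"K"`.
#' @param tol,k_range See [quant_settings()].
#' @return Tibble with one row per k: `k`, `mz_theoretical`, `matched`,
#'   `centroid_mz`, `apex_intensity`, `area`, `snr` (NA when unmatched).
#' @export
match_envelope <- function(peaks, pattern, adduct = "H", tol = 0.15, k_range = 3) {
  stopifnot(tol > 0, k_range >= 1)
  shift <- adduct_shift(adduct)
  ks <- 0:(k_range - 1)
  theo <- vapply(ks, function(k) {
    hit <- pattern$mz[pattern$k == k]
    if (length(hit) == 0) NA_real_ else hit[1] + shift
  }, numeric(1))
  assigned <- rep(NA_integer_, length(ks))
  taken <- rep(FALSE, nrow(peaks))
  for (j in seq_along(ks)) {
    if (is.na(theo[j])) next
    d <- abs(peaks$centroid_mz - theo[j])
    d[taken] <- Inf
    ok <- which(d <= tol)
    if (length(ok) == 0) next
    best <- ok[order(d[ok], peaks$centroid_mz[ok])][1]
    assigned[j] <- best
    taken[best] <- TRUE
  }
  tibble::tibble(
    k = ks,
    mz_theoretical = theo,
    matched = !is.na(assigned),
    centroid_mz = ifelse(is.na(assigned), NA_real_, peaks$centroid_mz[assigned]),
    apex_intensity = ifelse(is.na(assigned), NA_real_, peaks$apex_intensity[assigned]),
    area = ifelse(is.na(assigned), NA_real_, peaks$area[assigned]),
    snr = ifelse(is.na(assigned), NA_real_, peaks$snr[assigned])
  )
}

#' Matched light/heavy peak pair for one adduct
#'
#' Bundles the matched envelopes of the light and heavy species observed
#' under the same adduct, with summed response areas.
#'
#' @param light,heavy Matched tibbles from [match_envelope()].
#' @param adduct The adduct both envelopes were matched under.
#' @param use `"area"` or `"apex"` response column.
#' @return A `peak_pair` list with elements `light`, `heavy`, `adduct`,
#'   `light_area`, `heavy_area`, `corrected` (FALSE), `clipped` (FALSE).
#' @export
peak_pair <- function(light, heavy, adduct = "H", use = "area") {
  col <- if (use == "apex") "apex_intensity" else "area"
  structure(
    list(
      light = light, heavy = heavy, adduct = adduct, use = use,
      light_area = sum(light[[col]], na.rm = TRUE),
      heavy_area = sum(heavy[[col]], na.rm = TRUE),
      corrected = FALSE, clipped = FALSE
    ),
    class = "peak_pair"
  )
}

#' Correct heavy areas for light-envelope overlap
#'
#' The light envelope at offsets k >= 4 lands under the heavy envelope at
#' offsets j = k - 4. This subtracts from each matched heavy response at
#' offset j the predicted light contribution, estimated from the measured
#' light monoisotopic response as
#' `light(k=0) * abundance(4+j) / abundance(0)`. Corrected responses that
#' would go negative are clipped to zero and flagged.
#'
#' @param pair A [peak_pair()] whose light monoisotopic offset is matched.
#' @param light_pattern The [isotope_pattern()] of the light species.
#' @return The pair with a `corrected_area` column on `$heavy`, updated
#'   `heavy_area`, `corrected = TRUE`, and `clipped` set if any response
#'   was clipped at zero.
#' @export
correct_overlap <- function(pair, light_pattern) {
  stopifnot(inherits(pair, "peak_pair"))
  col <- if (pair$use == "apex") "apex_intensity" else "area"
  light0 <- pair$light[[col]][pair$light$k == 0L]
  if (length(light0) != 1 || is.na(light0)) {
    stop("overlap correction requires a matched light monoisotopic peak", call. = FALSE)
  }
  ab <- function(k) {
    hit <- light_pattern$abundance[light_pattern$k == k]
    if (length(hit) == 0) 0 else hit[1]
  }
  ab0 <- ab(0L)
  heavy <- pair$heavy
  predicted <- vapply(heavy$k, function(j) light0 * ab(j + 4L) / ab0, numeric(1))
  raw <- heavy[[col]] - predicted
  clipped <- any(!is.na(raw) & raw < 0 & predicted > 0)
  heavy$corrected_area <- pmax(raw, 0)
  pair$heavy <- heavy
  pair$heavy_area <- sum(heavy$corrected_area, na.rm = TRUE)
  pair$corrected <- TRUE
  pair$clipped <- clipped
  pair
}

#' Light/heavy quantification ratio from a spectrum
#'
#' Runs the full quantification for one light/heavy pair: peak picking,
#' envelope matching for each enabled adduct, optional overlap correction,
#' and summing responses over the configured isotopologue offsets. Each
#' species' summed response is normalized by its theoretical envelope
#' coverage over the matched offsets (the label removes one natural carbon
#' and three natural hydrogens, so the two envelopes differ slightly), and
#' the combined ratio is the total normalized light response over the total
#' normalized heavy response across adducts (the response-weighted
#' combination of the per-adduct ratios).
#'
#' @param spectrum A [mass_spectrum()].
#' @param light,heavy [peptide_species()] of the same sequence in light and
#'   heavy label states.
#' @param settings A [quant_settings()].
#' @return A `quant_result` with elements `ratio`, `below_detection`,
#'   `per_adduct` (tibble), `pairs` (list of [peak_pair()]), `settings`.
#'   If no heavy peak is found the behavior follows
#'   `settings$on_missing_heavy`.
#' @export
#' @examples
#' light <- peptide_species("HAIYPRH", n_terminus = "acetyl_light", c_terminus = "amide")
#' heavy <- peptide_species("HAIYPRH", n_terminus = "acetyl_heavy", c_terminus = "amide")
#' cfg <- sim_config(noise_sd = 0, baseline_level = 0, seed = 1)
#' s <- simulate_spectrum(list(light, heavy), c(2, 1), cfg)
#' light_heavy_ratio(s, light, heavy)$ratio # ~2
light_heavy_ratio <- function(spectrum, light, heavy, settings = quant_settings()) {
  stopifnot(inherits(light, "peptide_species"), inherits(heavy, "peptide_species"))
  if (identical(label_state(light), label_state(heavy))) {
    stop("light and heavy species must differ in label state", call. = FALSE)
  }
  peaks <- pick_peaks(spectrum, settings$snr_threshold, settings$window)
  light_pat <- isotope_pattern(light, truncation = settings$truncation)
  heavy_pat <- isotope_pattern(heavy, truncation = settings$truncation)
  pairs <- purrr::map(settings$adducts, function(ad) {
    ml <- match_envelope(peaks, light_pat, ad, settings$tol, settings$k_range)
    mh <- match_envelope(peaks, heavy_pat, ad, settings$tol, settings$k_range)
    p <- peak_pair(ml, mh, adduct = ad, use = settings$use)
    if (settings$correct_overlap && any(ml$matched & ml$k == 0L)) {
      p <- correct_overlap(p, light_pat)
    }
    p
  })
  names(pairs) <- settings$adducts
  # normalize each summed response by the species' theoretical envelope
  # coverage over its matched offsets: light and heavy envelopes are not
  # identical (the label removes one natural C and three natural H), and
  # missing offsets would otherwise bias the ratio
  coverage <- function(matched, pattern) {
    ks <- matched$k[matched$matched]
    sum(pattern$abundance[pattern$k %in% ks])
  }
  per_adduct <- purrr::map_dfr(pairs, function(p) {
    cov_l <- coverage(p$light, light_pat)
    cov_h <- coverage(p$heavy, heavy_pat)
    norm_l <- if (cov_l > 0) p$light_area / cov_l else NA_real_
    norm_h <- if (cov_h > 0) p$heavy_area / cov_h else NA_real_
    tibble::tibble(
      adduct = p$adduct,
      light_area = p$light_area,
      heavy_area = p$heavy_area,
      light_norm = norm_l,
      heavy_norm = norm_h,
      n_light = sum(p$light$matched),
      n_heavy = sum(p$heavy$matched),
      ratio = ifelse(!is.na(norm_h) & norm_h > 0, norm_l / norm_h, NA_real_),
      corrected = p$corrected,
      clipped = p$clipped
    )
  })
  heavy_found <- sum(per_adduct$n_heavy) > 0
  light_found <- sum(per_adduct$n_light) > 0
  if (!heavy_found) {
    if (settings$on_missing_heavy == "error") {
      stop("internal standard missing: no heavy peaks matched", call. = FALSE)
    }
    ratio <- NA_real_
  } else if (!light_found) {
    ratio <- 0
  } else {
    use <- per_adduct$n_heavy > 0
    tot_heavy <- sum(per_adduct$heavy_norm[use])
    tot_light <- sum(per_adduct$light_norm[use], na.rm = TRUE)
    ratio <- if (tot_heavy > 0) tot_light / tot_heavy else NA_real_
  }
  structure(
    list(
      ratio = ratio,
      below_detection = heavy_found && !light_found,
      per_adduct = per_adduct,
      pairs = pairs,
      settings = settings
    ),
    class = "quant_result"
  )
}

#' @export
print.quant_result <- function(x, ...) {
  cat("<quant result> light/heavy ratio = ", format(x$ratio, digits = 6), sep = "")
  if (x$below_detection) cat("  [below detection]")
  cat("\n adducts: ", paste(x$per_adduct$adduct, collapse = ", "),
    "; k offsets 0-", x$settings$k_range - 1,
    "; response: ", x$settings$use,
    if (any(x$per_adduct$corrected)) "; overlap-corrected" else "",
    "\n",
    sep = ""
  )
  invisible(x)
}
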