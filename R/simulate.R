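# Synthetic MALDI-TOF profile spectra for light/heavy peptide mixtures:
# Gaussian peaks (area-true) for every species x adduct x isotopologue,
# constant-FWHM-resolving-power instrument model, additive baseline and
# seeded Gaussian noise. Light and heavy species are given identical
# desorption/ionization efficiency, which is the premise of the
# internal-standard design.

#' Simulation settings for synthetic MALDI-TOF spectra
#'
#' @param resolution FWHM resolving power m/dm (dimensionless). Default
#'   10000, reflector-MALDI class.
#' @param mz_range Numeric length-2 m/z window in Da, or `NULL` to derive
#'   it from the simulated peaks (10 Da padding).
#' @param step Sampling step in Da.
#' @param adduct_abundances Named relative fractions for the H, Na and K
#'   adducts; H must be positive.
#' @param baseline_level Constant baseline intensity (arbitrary units).
#' @param noise_sd Additive Gaussian noise standard deviation (arbitrary
#'   units).
#' @param noise_cv Optional intensity-proportional noise coefficient: the
#'   per-point noise sd is `noise_sd + noise_cv * signal`.
#' @param intensity_scale Peak area (intensity units x Da) generated per
#'   unit molar abundance (per uM) for a peak of relative abundance 1.
#' @param truncation Envelope truncation passed to [isotope_pattern()].
#' @param seed Integer seed; identical configuration and seed give a
#'   bit-identical spectrum.
#' @return A `sim_config` list.
#' @export
sim_config <- function(resolution = 10000,
                       mz_range = NULL,
                       step = 0.01,
                       adduct_abundances = c(H = 1.0, Na = 0.3, K = 0.1),
                       baseline_level = 2,
                       noise_sd = 1,
                       noise_cv = 0,
                       intensity_scale = 500,
                       truncation = 1e-6,
                       seed = 1L) {
  stopifnot(resolution > 0, step > 0)
  stopifnot(all(adduct_abundances >= 0))
  if (!"H" %in% names(adduct_abundances) || adduct_abundances[["H"]] <= 0) {
    stop("adduct_abundances must include a positive H fraction", call. = FALSE)
  }
  stopifnot(baseline_level >= 0, noise_sd >= 0, noise_cv >= 0, intensity_scale > 0)
  if (!is.null(mz_range)) {
    stopifnot(length(mz_range) == 2, mz_range[1] < mz_range[2])
  }
  structure(
    list(
      resolution = resolution, mz_range = mz_range, step = step,
      adduct_abundances = adduct_abundances, baseline_level = baseline_level,
      noise_sd = noise_sd, noise_cv = noise_cv,
      intensity_scale = intensity_scale, truncation = truncation,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Construct a mass spectrum
#'
#' @param mz Strictly increasing m/z values in Da.
#' @param intensity Non-negative intensities, same length as `mz`.
#' @param metadata Free-form provenance list stored as an attribute.
#' @return A tibble of class `mass_spectrum` with columns `mz` and
#'   `intensity`.
#' @export
mass_spectrum <- function(mz, intensity, metadata = list()) {
  stopifnot(length(mz) == length(intensity))
  if (length(mz) > 1 && any(diff(mz) <= 0)) {
    stop("mz must be strictly increasing", call. = FALSE)
  }
  if (any(intensity < 0)) stop("intensities must be non-negative", call. = FALSE)
  structure(
    tibble::tibble(mz = as.numeric(mz), intensity = as.numeric(intensity)),
    metadata = metadata,
    class = c("mass_spectrum", class(tibble::tibble()))
  )
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(
    "<mass spectrum> ", nrow(x), " points",
    if (nrow(x) > 0) {
      paste0(
        ", m/z ", format(min(x$mz), nsmall = 2), "-", format(max(x$mz), nsmall = 2)
      )
    },
    "\n",
    sep = ""
  )
  NextMethod()
}

#' Theoretical peak list for a species mixture
#'
#' Expands species x adduct x isotopologue into (m/z, area) rows under a
#' simulation configuration. Used internally by [simulate_spectrum()] and
#' useful as ground truth in tests.
#'
#' @param species_list List of [peptide_species()] (or a single one).
#' @param abundances Molar abundances (uM), one per species.
#' @param config A [sim_config()].
#' @return Tibble with columns `species`, `adduct`, `k`, `mz`, `area`.
#' @export
theoretical_peaks <- function(species_list, abundances, config = sim_config()) {
  if (inherits(species_list, "peptide_species")) species_list <- list(species_list)
  stopifnot(length(species_list) == length(abundances), all(abundances >= 0))
  if (length(species_list) == 0) {
    return(tibble::tibble(
      species = character(), adduct = character(), k = integer(),
      mz = numeric(), area = numeric()
    ))
  }
  purrr::map2_dfr(species_list, abundances, function(sp, ab) {
    pat <- isotope_pattern(sp, truncation = config$truncation)
    purrr::imap_dfr(config$adduct_abundances, function(frac, ad) {
      if (frac <= 0) {
        return(tibble::tibble(
          species = character(), adduct = character(), k = integer(),
          mz = numeric(), area = numeric()
        ))
      }
      tibble::tibble(
        species = sp$name,
        adduct = ad,
        k = pat$k,
        mz = pat$mz + adduct_shift(ad),
        area = ab * frac * pat$abundance * config$intensity_scale
      )
    })
  })
}

#' Simulate a MALDI-TOF profile spectrum
#'
#' Adds, for every species x adduct x isotopologue, a Gaussian of area
#' proportional to molar abundance x adduct fraction x isotopologue
#' abundance x intensity scale, with FWHM = m/z / resolution, on a regular
#' m/z grid; then adds the baseline and seeded Gaussian noise and clips
#' negative intensities to zero.
#'
#' @inheritParams theoretical_peaks
#' @return A [mass_spectrum()]; its `metadata` attribute records the
#'   configuration, seed, species names and true abundances.
#' @export
#' @examples
#' light <- peptide_species("HAIYPRH", n_terminus = "acetyl_light", c_terminus = "amide")
#' heavy <- peptide_species("HAIYPRH", n_terminus = "acetyl_heavy", c_terminus = "amide")
#' s <- simulate_spectrum(list(light, heavy), c(2, 2), sim_config(seed = 7))
simulate_spectrum <- function(species_list, abundances, config = sim_config()) {
  if (inherits(species_list, "peptide_species")) species_list <- list(species_list)
  stopifnot(length(species_list) == length(abundances))
  peaks <- theoretical_peaks(species_list, abundances, config)
  rng <- config$mz_range
  if (is.null(rng)) {
    if (nrow(peaks) == 0) {
      rng <- c(400, 410)
    } else {
      rng <- c(min(peaks$mz) - 10, max(peaks$mz) + 10)
    }
  }
  grid <- seq(rng[1], rng[2], by = config$step)
  signal <- numeric(length(grid))
  dropped <- 0L
  for (i in seq_len(nrow(peaks))) {
    mu <- peaks$mz[i]
    if (mu < rng[1] || mu > rng[2]) {
      dropped <- dropped + 1L
      next
    }
    sigma <- mu / config$resolution / (2 * sqrt(2 * log(2)))
    lo <- findInterval(mu - 8 * sigma, grid) + 1L
    hi <- findInterval(mu + 8 * sigma, grid)
    if (hi < lo) next
    idx <- lo:hi
    signal[idx] <- signal[idx] + peaks$area[i] * stats::dnorm(grid[idx], mu, sigma)
  }
  warn <- NULL
  if (nrow(peaks) > 0 && dropped == nrow(peaks)) {
    warn <- "mz_range excludes all theoretical peaks; baseline-only spectrum"
    warning(warn, call. = FALSE)
  }
  intensity <- withr::with_seed(config$seed, {
    y <- signal + config$baseline_level
    if (config$noise_sd > 0 || config$noise_cv > 0) {
      sd_pt <- config$noise_sd + config$noise_cv * signal
      y <- y + stats::rnorm(length(y), 0, sd_pt)
    }
    y
  })
  intensity[intensity < 0] <- 0
  mass_spectrum(
    grid, intensity,
    metadata = list(
      generator = "isopair::simulate_spectrum",
      config = config,
      species = purrr::map_chr(species_list, "name"),
      abundances = abundances,
      n_peaks = nrow(peaks) - dropped,
      warning = warn
    )
  )
}

# deterministic child seed for series member i (kept below 2^31)
.child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + (i + 1) * 16807) %% 2147483647)
}

#' Simulate a serial-dilution series of light/heavy mixtures
#'
#' Member i (i = 0..n_dilutions) holds the light species at
#' `start_conc * fold^-i` and the heavy species at `heavy_factor` times
#' that, each simulated independently with a child seed derived
#' deterministically from `(config$seed, i)`. The default geometry follows
#' the serial 1/3 dilution protocol: 200 uM down through eleven dilutions
#' to about 1.1 nM, with the heavy internal standard at twice the light
#' concentration.
#'
#' @param light,heavy [peptide_species()] for the light and heavy forms.
#' @param start_conc Starting light concentration (uM).
#' @param fold Dilution factor per step (> 1).
#' @param n_dilutions Number of dilution steps (the series has
#'   `n_dilutions + 1` members including the undiluted one).
#' @param config A [sim_config()].
#' @param heavy_factor Heavy:light concentration ratio in every member.
#' @return Tibble with columns `member`, `concentration_um`, `seed`, and a
#'   `spectrum` list-column of [mass_spectrum()] objects.
#' @export
simulate_dilution_series <- function(light, heavy,
                                     start_conc = 200,
                                     fold = 3,
                                     n_dilutions = 11,
                                     config = sim_config(),
                                     heavy_factor = 2) {
  stopifnot(start_conc > 0, n_dilutions >= 1, heavy_factor > 0)
  if (fold <= 1) stop("fold must be > 1", call. = FALSE)
  members <- 0:n_dilutions
  conc <- start_conc * fold^-members
  spectra <- purrr::map(members, function(i) {
    cfg <- config
    cfg$seed <- .child_seed(config$seed, i)
    simulate_spectrum(list(light, heavy), c(conc[i + 1], heavy_factor * conc[i + 1]), cfg)
  })
  tibble::tibble(
    member = members,
    concentration_um = conc,
    seed = purrr::map_int(members, ~ .child_seed(config$seed, .x)),
    spectrum = spectra
  )
}
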