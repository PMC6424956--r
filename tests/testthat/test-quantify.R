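test_that("peak picking handles empty and flat spectra", {
  expect_identical(nrow(pick_peaks(mass_spectrum(numeric(), numeric()))), 0L)
  flat <- mass_spectrum(seq(100, 101, 0.01), rep(0, 101))
  expect_identical(nrow(pick_peaks(flat)), 0L)
})

test_that("picked peaks recover simulated centroids and areas", {
  # a single noiseless Gaussian at 500 Da (built directly on the grid)
  grid <- seq(495, 505, 0.01)
  sigma <- 500 / 10000 / (2 * sqrt(2 * log(2)))
  y <- 7 * dnorm(grid, 500, sigma)
  pk <- pick_peaks(mass_spectrum(grid, y))
  expect_identical(nrow(pk), 1L)
  expect_lt(abs(pk$centroid_mz - 500), 0.005)
  expect_lt(abs(pk$area / 7 - 1), 1e-6)
  expect_identical(pk$snr, Inf)

  # two Gaussians of equal area pick with equal areas
  y2 <- 5 * dnorm(grid, 498, sigma) + 5 * dnorm(grid, 502, sigma)
  pk2 <- pick_peaks(mass_spectrum(grid, y2))
  expect_identical(nrow(pk2), 2L)
  expect_lt(abs(pk2$area[1] / pk2$area[2] - 1), 1e-6)
})

test_that("envelope matching respects tolerance and tie-breaks", {
  pat <- isotope_pattern(compose_peptide(hai_light()), truncation = 1e-8)
  theo <- pat$mz[pat$k %in% 0:2] + adduct_shift("H")
  peaks <- tibble::tibble(
    centroid_mz = theo,
    apex_intensity = c(3, 2, 1), area = c(3, 2, 1), snr = Inf
  )
  m <- match_envelope(peaks, pat, "H", tol = 0.15, k_range = 3)
  expect_true(all(m$matched))
  expect_equal(m$area, c(3, 2, 1))

  # nearest peak just beyond tolerance stays unassigned
  off <- peaks
  off$centroid_mz[2] <- theo[2] + 0.15 + 1e-6
  m2 <- match_envelope(off, pat, "H", tol = 0.15, k_range = 3)
  expect_identical(m2$matched, c(TRUE, FALSE, TRUE))

  # equidistant candidates break toward lower m/z; one peak, one offset
  two <- tibble::tibble(
    centroid_mz = c(theo[1] - 0.05, theo[1] + 0.05),
    apex_intensity = c(1, 9), area = c(1, 9), snr = Inf
  )
  m3 <- match_envelope(two, pat, "H", tol = 0.15, k_range = 1)
  expect_identical(m3$centroid_mz[1], theo[1] - 0.05)
})

test_that("overlap correction subtracts the predicted light tail", {
  pat_small <- isotope_pattern(parse_formula("C2H3O"))
  mk <- function(areas) {
    tibble::tibble(
      k = seq_along(areas) - 1L, mz_theoretical = NA_real_,
      matched = TRUE, centroid_mz = NA_real_,
      apex_intensity = areas, area = areas, snr = Inf
    )
  }
  pair <- peak_pair(mk(c(10, 2)), mk(c(5, 1)))
  # no abundance at k >= 4: heavy areas unchanged
  corrected <- correct_overlap(pair, pat_small)
  expect_equal(corrected$heavy$corrected_area, c(5, 1))
  expect_false(corrected$clipped)

  # heavy response exactly equal to the predicted tail clips to zero
  pat_big <- isotope_pattern(compose_peptide(big_species("light")), truncation = 1e-10)
  ab <- function(k) pat_big$abundance[pat_big$k == k]
  light0 <- 10
  tail4 <- light0 * ab(4) / ab(0)
  pair2 <- peak_pair(mk(c(light0, 2)), mk(tail4))
  corrected2 <- correct_overlap(pair2, pat_big)
  expect_equal(corrected2$heavy$corrected_area, 0)
  expect_equal(corrected2$heavy_area, 0)
})

test_that("light/heavy ratios are exact on noiseless spectra", {
  cfg <- clean_config()
  s21 <- simulate_spectrum(list(hai_light(), hai_heavy()), c(2, 1), cfg)
  q <- light_heavy_ratio(s21, hai_light(), hai_heavy(),
    quant_settings(correct_overlap = TRUE)
  )
  expect_lt(abs(q$ratio - 2), 2e-6)
  expect_false(q$below_detection)

  s11 <- simulate_spectrum(list(hai_light(), hai_heavy()), c(1, 1), cfg)
  q11 <- light_heavy_ratio(s11, hai_light(), hai_heavy(),
    quant_settings(correct_overlap = TRUE)
  )
  expect_lt(abs(q11$ratio - 1), 1e-6)
})

test_that("overlap correction matters for heavy analytes", {
  cfg <- clean_config()
  s <- simulate_spectrum(list(big_species("light"), big_species("heavy")), c(1, 1), cfg)
  plain <- light_heavy_ratio(s, big_species("light"), big_species("heavy"),
    quant_settings(correct_overlap = FALSE)
  )
  corrected <- light_heavy_ratio(s, big_species("light"), big_species("heavy"),
    quant_settings(correct_overlap = TRUE)
  )
  expect_lt(abs(corrected$ratio - 1), abs(plain$ratio - 1))
  expect_lt(abs(corrected$ratio - 1), 1e-3)
  # uncorrected heavy area is inflated by the light tail, biasing the ratio low
  expect_lt(plain$ratio, 1)
})

test_that("missing species raise the documented flags and errors", {
  cfg <- clean_config()
  only_heavy <- simulate_spectrum(list(hai_heavy()), 1, cfg)
  q <- light_heavy_ratio(only_heavy, hai_light(), hai_heavy())
  expect_identical(q$ratio, 0)
  expect_true(q$below_detection)

  # with the envelope tail truncated, a light-only spectrum has no signal
  # at the heavy positions and genuinely lacks the internal standard
  gly_l <- peptide_species("G", "acetyl_light", "amide", name = "gly_light")
  gly_h <- peptide_species("G", "acetyl_heavy", "amide", name = "gly_heavy")
  only_light <- simulate_spectrum(list(gly_l), 1, clean_config(truncation = 1e-3))
  expect_error(
    light_heavy_ratio(only_light, gly_l, gly_h),
    "internal standard missing"
  )
  q2 <- light_heavy_ratio(only_light, gly_l, gly_h,
    quant_settings(on_missing_heavy = "na")
  )
  expect_true(is.na(q2$ratio))

  expect_error(
    light_heavy_ratio(only_light, hai_light(), hai_light()),
    "label state"
  )
})

test_that("the ratio is invariant to intensity scaling", {
  cfg <- clean_config()
  s <- simulate_spectrum(list(hai_light(), hai_heavy()), c(3, 1), cfg)
  q1 <- light_heavy_ratio(s, hai_light(), hai_heavy())
  scaled <- mass_spectrum(s$mz, s$intensity * 37.5)
  q2 <- light_heavy_ratio(scaled, hai_light(), hai_heavy())
  expect_equal(q2$ratio, q1$ratio, tolerance = 1e-12)
})

test_that("per-adduct ratios agree under equal adduct propensity", {
  cfg <- sim_config(
    noise_sd = 0, baseline_level = 0,
    adduct_abundances = c(H = 1, Na = 0.3, K = 0.1),
    intensity_scale = 100, seed = 5
  )
  s <- simulate_spectrum(list(hai_light(), hai_heavy()), c(2, 1), cfg)
  q <- light_heavy_ratio(s, hai_light(), hai_heavy(),
    quant_settings(adducts = c("H", "Na", "K"), correct_overlap = TRUE)
  )
  ratios <- q$per_adduct$ratio
  expect_identical(length(ratios), 3L)
  expect_lt(max(abs(ratios / ratios[1] - 1)), 1e-5)
  expect_lt(abs(q$ratio - 2), 1e-4)
  expect_identical(tidy(q), q$per_adduct)
  expect_identical(glance(q)$ratio, q$ratio)
})
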