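# Transwell transport (%) and apparent permeability, in HPLC-area,
# MALDI-ratio and amount modes, plus PAMPA effective permeability.
# Unit conventions, package-wide: volumes uL (converted to cm3 internally),
# time s for Papp and h for Pe, concentrations uM, amounts pmol.

#' Transwell assay geometry
#'
#' @param v_donor_ul Donor well volume (uL).
#' @param v_acceptor_ul Acceptor well volume (uL).
#' @param time_s Assay duration (s).
#' @param area_cm2 Transwell membrane area (cm2); default 1.12, a standard
#'   12-well insert.
#' @param c_donor0_um Initial donor concentration (uM).
#' @return A `well_assay` list.
#' @export
#' @examples
#' well_assay() # the 200/800 uL, 2 h geometry
well_assay <- function(v_donor_ul = 200,
                       v_acceptor_ul = 800,
                       time_s = 7200,
                       area_cm2 = 1.12,
                       c_donor0_um = 200) {
  stopifnot(
    v_donor_ul > 0, v_acceptor_ul > 0, time_s > 0, area_cm2 > 0,
    c_donor0_um > 0
  )
  structure(
    list(
      v_donor_ul = v_donor_ul, v_acceptor_ul = v_acceptor_ul,
      time_s = time_s, area_cm2 = area_cm2, c_donor0_um = c_donor0_um
    ),
    class = "well_assay"
  )
}

#' Transport from amounts
#'
#' Transport is the amount of analyte in the acceptor well at assay end
#' divided by the initial amount in the donor well, times 100.
#'
#' @param q_acceptor_pmol Amount in the acceptor well at time t (pmol).
#' @param q_donor0_pmol Initial amount in the donor well (pmol).
#' @return Transport in percent (vectorized).
#' @export
#' @examples
#' transport_amounts(1600, 40000) # 4 %
transport_amounts <- function(q_acceptor_pmol, q_donor0_pmol) {
  if (any(q_donor0_pmol <= 0)) {
    stop("initial donor amount must be positive", call. = FALSE)
  }
  q_acceptor_pmol / q_donor0_pmol * 100
}

#' Transport from HPLC chromatogram areas
#'
#' Acceptor/donor concentration ratio from integrated chromatogram areas
#' corrected by injected volumes, converted to an amount ratio by the well
#' volumes:
#' `T = (A_acceptor / A_donor) * (V_inj_donor / V_inj_acceptor) *
#' (V_well_acceptor / V_well_donor) * 100`.
#'
#' @param data Data frame with one row per replicate well and columns
#'   `area_acceptor`, `area_donor`, `v_inj_acceptor_ul`, `v_inj_donor_ul`.
#' @param assay A [well_assay()].
#' @return The input as a tibble with added `transport_pct` and
#'   `papp_cm_s` columns.
#' @export
#' @examples
#' transport_hplc(
#'   tibble::tibble(
#'     area_acceptor = 10, area_donor = 1000,
#'     v_inj_acceptor_ul = 20, v_inj_donor_ul = 20
#'   ),
#'   well_assay()
#' )
transport_hplc <- function(data, assay = well_assay()) {
  need <- c("area_acceptor", "area_donor", "v_inj_acceptor_ul", "v_inj_donor_ul")
  .require_cols(data, need, "transport_hplc")
  if (any(data$area_donor <= 0)) {
    stop("transport undefined: donor chromatogram area must be positive", call. = FALSE)
  }
  stopifnot(all(data$v_inj_acceptor_ul > 0), all(data$v_inj_donor_ul > 0))
  t_pct <- with(
    data,
    area_acceptor / area_donor * (v_inj_donor_ul / v_inj_acceptor_ul) *
      (assay$v_acceptor_ul / assay$v_donor_ul) * 100
  )
  dplyr::mutate(
    tibble::as_tibble(data),
    transport_pct = t_pct,
    papp_cm_s = apparent_permeability(t_pct, assay)
  )
}

#' Transport from MALDI light/heavy ratios
#'
#' Donor and acceptor aliquots are each mixed 1:1 with a heavy internal
#' standard; the donor spike is `R` times more concentrated than the
#' acceptor spike (200 uM vs 2 uM gives R = 100). With measured
#' light/heavy area ratios the transport is
#' `T = (ratio_acceptor / ratio_donor) * (1 / R) *
#' (V_well_acceptor / V_well_donor) * 100`,
#' which reproduces the amount-based definition exactly. The arrangement
#' that treats the factor `1/R` as already absorbed into the measured donor
#' ratio (and so applies no explicit `1/R`) is available via
#' `as_printed = TRUE` for auditability; used with measured ratios it
#' overstates T by a factor R relative to the amount-based definition.
#'
#' @param data Data frame with columns `ratio_acceptor`, `ratio_donor`,
#'   `spike_donor_um`, `spike_acceptor_um` (one row per replicate).
#' @param assay A [well_assay()].
#' @param as_printed Use the as-printed arrangement (see above).
#' @return The input as a tibble with added `spike_ratio_R`,
#'   `transport_pct` and `papp_cm_s` columns.
#' @export
#' @examples
#' transport_maldi(
#'   tibble::tibble(
#'     ratio_acceptor = 1, ratio_donor = 1,
#'     spike_donor_um = 200, spike_acceptor_um = 2
#'   ),
#'   well_assay()
#' ) # 4 %
transport_maldi <- function(data, assay = well_assay(), as_printed = FALSE) {
  need <- c("ratio_acceptor", "ratio_donor", "spike_donor_um", "spike_acceptor_um")
  .require_cols(data, need, "transport_maldi")
  stopifnot(all(data$spike_donor_um > 0), all(data$spike_acceptor_um > 0))
  if (any(data$ratio_donor <= 0)) {
    stop("transport undefined: donor light/heavy ratio must be positive", call. = FALSE)
  }
  if (any(data$ratio_acceptor < 0)) {
    stop("acceptor ratio must be non-negative", call. = FALSE)
  }
  r_spike <- data$spike_donor_um / data$spike_acceptor_um
  vol <- assay$v_acceptor_ul / assay$v_donor_ul
  t_pct <- if (as_printed) {
    data$ratio_acceptor / data$ratio_donor * vol * 100
  } else {
    data$ratio_acceptor / data$ratio_donor / r_spike * vol * 100
  }
  dplyr::mutate(
    tibble::as_tibble(data),
    spike_ratio_R = r_spike,
    transport_pct = t_pct,
    papp_cm_s = apparent_permeability(t_pct, assay)
  )
}

#' Apparent permeability from transport
#'
#' `Papp = (V_donor / t) * (1 / A) * (T / 100)` in cm/s, the
#' single-timepoint (initial-slope) form, with the donor volume converted
#' from uL to cm3.
#'
#' @param transport_pct Transport in percent (vectorized).
#' @param assay A [well_assay()].
#' @return Apparent permeability in cm/s.
#' @export
#' @examples
#' apparent_permeability(4, well_assay()) # 9.92e-7 cm/s
apparent_permeability <- function(transport_pct, assay = well_assay()) {
  stopifnot(all(transport_pct >= 0))
  v_cm3 <- assay$v_donor_ul * 1e-3
  v_cm3 / assay$time_s / assay$area_cm2 * transport_pct / 100
}

#' PAMPA effective permeability
#'
#' Double-sink PAMPA permeability from the acceptor/donor concentration
#' ratio at a single timepoint:
#' `Pe = (-218.3 / t) * log10(1 - 2 C_A(t) / C_D(t0)) * 1e-6` cm/s with t
#' in hours. The argument of the logarithm must stay positive, i.e. the
#' system must be short of its equal-concentration equilibrium.
#' Classification thresholds for passive-diffusion propensity: poor below
#' 2.0e-6 cm/s, uncertain between 2.0e-6 and 4.0e-6, excellent above
#' 4.0e-6.
#'
#' @param c_acceptor_um Acceptor concentration at time t (uM), vectorized.
#' @param c_donor0_um Donor concentration at time zero (uM).
#' @param time_h Run time in hours (default 4).
#' @return Effective permeability in cm/s.
#' @export
#' @examples
#' pampa_pe(2, 200, time_h = 4) # 4.79e-7 cm/s
pampa_pe <- function(c_acceptor_um, c_donor0_um, time_h = 4) {
  stopifnot(all(c_acceptor_um >= 0), all(c_donor0_um > 0), time_h > 0)
  x <- 2 * c_acceptor_um / c_donor0_um
  if (any(x >= 1)) {
    stop(
      "equilibrium exceeded: 2 C_A(t) / C_D(t0) must be < 1 for a finite Pe",
      call. = FALSE
    )
  }
  -218.3 / time_h * log10(1 - x) * 1e-6
}

#' @rdname pampa_pe
#' @param pe_cm_s Effective permeability values (cm/s).
#' @export
classify_pe <- function(pe_cm_s) {
  factor(
    ifelse(pe_cm_s < 2.0e-6, "poor",
      ifelse(pe_cm_s <= 4.0e-6, "uncertain", "excellent")
    ),
    levels = c("poor", "uncertain", "excellent")
  )
}

#' PAMPA transport
#'
#' Amount in the acceptor well at time t over the initial donor amount,
#' times 100. Identical arithmetic to [transport_amounts()], provided for
#' the PAMPA workflow.
#'
#' @inheritParams transport_amounts
#' @return Transport in percent.
#' @export
pampa_transport <- function(q_acceptor_pmol, q_donor0_pmol) {
  transport_amounts(q_acceptor_pmol, q_donor0_pmol)
}

#' PAMPA analysis of a measurement table
#'
#' @param data Data frame with columns `c_acceptor_um`, `c_donor0_um` and
#'   optionally `q_acceptor_pmol`, `q_donor0_pmol` for transport.
#' @param time_h Run time in hours.
#' @return The input as a tibble with added `pe_cm_s`, `pe_class` and
#'   (when amounts are present) `transport_pct` columns.
#' @export
pampa <- function(data, time_h = 4) {
  .require_cols(data, c("c_acceptor_um", "c_donor0_um"), "pampa")
  out <- dplyr::mutate(
    tibble::as_tibble(data),
    pe_cm_s = pampa_pe(.data$c_acceptor_um, .data$c_donor0_um, time_h),
    pe_class = classify_pe(.data$pe_cm_s)
  )
  if (all(c("q_acceptor_pmol", "q_donor0_pmol") %in% names(data))) {
    out <- dplyr::mutate(
      out,
      transport_pct = pampa_transport(.data$q_acceptor_pmol, .data$q_donor0_pmol)
    )
  }
  out
}

.require_cols <- function(data, cols, fn) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    stop(
      fn, "() needs column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(data)
}
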