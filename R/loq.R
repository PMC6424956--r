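# Serial-dilution limit-of-quantification: per-member response ratios R_i,
# the reference mean R_bar over retained members, relative deviations in
# percent, and the LOQ call against a deviation threshold.

#' HPLC response ratio for a dilution-series member
#'
#' Total absorbance area corrected by the injected volume and the
#' fold-dilution of the member: `R_i = A * d / V`.
#'
#' @param area Integrated absorbance area.
#' @param fold_dilution Cumulative fold-dilution of the member (>= 1).
#' @param v_inj_ul Injected volume (uL).
#' @return The response ratio (vectorized).
#' @export
#' @examples
#' response_ratio_hplc(100, 3, 10) # 30
response_ratio_hplc <- function(area, fold_dilution, v_inj_ul) {
  if (any(v_inj_ul <= 0)) stop("injected volume must be positive", call. = FALSE)
  stopifnot(all(fold_dilution >= 1), all(area >= 0))
  area * fold_dilution / v_inj_ul
}

#' Deviations of a dilution series from its reference mean
#'
#' The reference mean `R_bar` is the mean response over the members
#' excluding the trailing `n_discard` most-dilute ones (1 for the MALDI
#' ratio protocol, 5 for the HPLC protocol); members with missing
#' responses are also excluded from the mean. Each member's deviation is
#' `(R_i / R_bar - 1) * 100` percent.
#'
#' @param data Data frame with columns `concentration_um` (strictly
#'   decreasing) and `response` (light/heavy ratio in MALDI mode, or
#'   [response_ratio_hplc()] output in HPLC mode); at least 3 members.
#' @param n_discard Number of trailing (most dilute) members excluded from
#'   the reference mean.
#' @return The input as a tibble with added `retained` and `deviation_pct`
#'   columns; the reference mean is stored in the `r_bar` attribute.
#' @export
#' @examples
#' loq_deviations(
#'   tibble::tibble(
#'     concentration_um = c(9, 3, 1, 1 / 3),
#'     response = c(1, 1, 1, 1.2)
#'   ),
#'   n_discard = 1
#' )
loq_deviations <- function(data, n_discard = 1) {
  .require_cols(data, c("concentration_um", "response"), "loq_deviations")
  n <- nrow(data)
  if (n < 3) stop("a dilution series needs at least 3 members", call. = FALSE)
  if (any(diff(data$concentration_um) >= 0)) {
    stop("concentrations must be strictly decreasing", call. = FALSE)
  }
  if (n_discard < 0 || n_discard >= n) {
    stop("n_discard must be in [0, number of members)", call. = FALSE)
  }
  retained <- seq_len(n) <= n - n_discard
  kept <- data$response[retained]
  kept <- kept[!is.na(kept)]
  if (length(kept) == 0) stop("no retained members with responses", call. = FALSE)
  r_bar <- mean(kept)
  if (r_bar == 0) stop("reference mean response is zero", call. = FALSE)
  out <- dplyr::mutate(
    tibble::as_tibble(data),
    retained = retained,
    deviation_pct = (.data$response / r_bar - 1) * 100
  )
  attr(out, "r_bar") <- r_bar
  out
}

#' Call the limit of quantification from member deviations
#'
#' With the default `"strict"` rule the LOQ is the lowest concentration c
#' such that every member at or above c has `|deviation| <= threshold`
#' (members with missing deviations count as failing). If all members
#' qualify, the LOQ is the lowest tested concentration and
#' `below_lowest_tested` is set. The `"per_member"` rule instead returns
#' the lowest concentration whose own member passes.
#'
#' @param deviations Output of [loq_deviations()].
#' @param threshold Deviation threshold in percent, applied two-sided
#'   (default 8).
#' @param rule `"strict"` (default) or `"per_member"`.
#' @return A list with `loq_concentration_um` (NA if even the least dilute
#'   member fails), `below_lowest_tested`, `threshold`, `rule`.
#' @export
call_loq <- function(deviations, threshold = 8, rule = c("strict", "per_member")) {
  rule <- match.arg(rule)
  .require_cols(deviations, c("concentration_um", "deviation_pct"), "call_loq")
  stopifnot(threshold >= 0)
  ok <- !is.na(deviations$deviation_pct) &
    abs(deviations$deviation_pct) <= threshold
  n <- length(ok)
  if (rule == "strict") {
    fail <- which(!ok)
    m <- if (length(fail) == 0) n else min(fail) - 1L
  } else {
    m <- if (any(ok)) max(which(ok)) else 0L
  }
  if (m == 0L) {
    return(list(
      loq_concentration_um = NA_real_, below_lowest_tested = FALSE,
      threshold = threshold, rule = rule
    ))
  }
  list(
    loq_concentration_um = deviations$concentration_um[m],
    below_lowest_tested = (m == n),
    threshold = threshold,
    rule = rule
  )
}

#' Serial-dilution LOQ analysis
#'
#' Convenience wrapper: computes the reference mean and deviations with the
#' protocol-appropriate trailing exclusion (`mode = "maldi"` discards the
#' last member from the mean, `mode = "hplc"` the last five) and calls the
#' LOQ at the given threshold.
#'
#' @inheritParams loq_deviations
#' @inheritParams call_loq
#' @param mode `"maldi"` or `"hplc"`; sets the default `n_discard`.
#' @param n_discard Override the protocol default.
#' @return A `loq_result`: list with `table` (deviations tibble), `r_bar`,
#'   `threshold`, `rule`, `mode`, `loq_concentration_um`,
#'   `below_lowest_tested`.
#' @export
#' @examples
#' series <- tibble::tibble(
#'   concentration_um = 200 * 3^-(0:11),
#'   response = c(rep(0.5, 11), 0.62)
#' )
#' loq_analysis(series, mode = "maldi")
loq_analysis <- function(data,
                         mode = c("maldi", "hplc"),
                         threshold = 8,
                         rule = c("strict", "per_member"),
                         n_discard = NULL) {
  mode <- match.arg(mode)
  rule <- match.arg(rule)
  n_discard <- n_discard %||% switch(mode, maldi = 1L, hplc = 5L)
  dev <- loq_deviations(data, n_discard = n_discard)
  call <- call_loq(dev, threshold = threshold, rule = rule)
  structure(
    list(
      table = dev,
      r_bar = attr(dev, "r_bar"),
      threshold = threshold,
      rule = rule,
      mode = mode,
      n_discard = n_discard,
      loq_concentration_um = call$loq_concentration_um,
      below_lowest_tested = call$below_lowest_tested
    ),
    class = "loq_result"
  )
}

#' @export
print.loq_result <- function(x, ...) {
  cat("<LOQ analysis> mode: ", x$mode,
    "; threshold: ", x$threshold, "% (", x$rule, " rule)\n",
    sep = ""
  )
  if (is.na(x$loq_concentration_um)) {
    cat(" no concentration qualifies at this threshold\n")
  } else {
    cat(
      " LOQ = ", format(x$loq_concentration_um, digits = 4), " uM",
      if (x$below_lowest_tested) " (all members qualify; below lowest tested)",
      "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Quantify a simulated or measured dilution series
#'
#' Runs [light_heavy_ratio()] over the spectra of a dilution series (e.g.
#' from [simulate_dilution_series()]) and returns the (concentration,
#' response) table expected by [loq_analysis()]. Members whose internal
#' standard is not found get an `NA` response.
#'
#' @param series Tibble with columns `concentration_um` and `spectrum`
#'   (list of [mass_spectrum()]).
#' @param light,heavy [peptide_species()] of the pair.
#' @param settings A [quant_settings()]; `on_missing_heavy` is forced to
#'   `"na"` so that undetectable members are reported rather than fatal.
#' @return Tibble with columns `concentration_um`, `response`,
#'   `below_detection`.
#' @export
quantify_dilution_series <- function(series, light, heavy,
                                     settings = quant_settings()) {
  .require_cols(series, c("concentration_um", "spectrum"), "quantify_dilution_series")
  settings$on_missing_heavy <- "na"
  rows <- purrr::map(series$spectrum, function(s) {
    q <- light_heavy_ratio(s, light, heavy, settings)
    tibble::tibble(response = q$ratio, below_detection = q$below_detection)
  })
  dplyr::bind_cols(
    tibble::tibble(concentration_um = series$concentration_um),
    dplyr::bind_rows(rows)
  )
}
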