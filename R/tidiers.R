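# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a quantification result
#'
#' One row per adduct with the matched responses and per-adduct ratio.
#'
#' @param x A `quant_result` from [light_heavy_ratio()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy quant_result
#' @export
tidy.quant_result <- function(x, ...) {
  x$per_adduct
}

#' @rdname tidy.quant_result
#' @method glance quant_result
#' @export
glance.quant_result <- function(x, ...) {
  tibble::tibble(
    ratio = x$ratio,
    below_detection = x$below_detection,
    n_adducts = nrow(x$per_adduct),
    k_range = x$settings$k_range,
    response = x$settings$use,
    overlap_corrected = any(x$per_adduct$corrected)
  )
}

#' Tidy an LOQ analysis
#'
#' One row per dilution-series member with its response, retention in the
#' reference mean, and deviation.
#'
#' @param x An `loq_result` from [loq_analysis()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy loq_result
#' @export
tidy.loq_result <- function(x, ...) {
  tibble::as_tibble(x$table)
}

#' @rdname tidy.loq_result
#' @method glance loq_result
#' @export
glance.loq_result <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    n_members = nrow(x$table),
    n_discard = x$n_discard,
    r_bar = x$r_bar,
    threshold_pct = x$threshold,
    rule = x$rule,
    loq_concentration_um = x$loq_concentration_um,
    below_lowest_tested = x$below_lowest_tested
  )
}
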