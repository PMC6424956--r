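# Embedded isotope table (IUPAC 2021 atomic masses and representative
# natural abundances). The pseudo-elements "13C" and "2H" model chemically
# defined labeled positions: a single isotope at abundance 1.

.isotope_data <- list(
  H = list(mass = c(1.00782503224, 2.01410177811), abundance = c(0.999885, 0.000115)),
  C = list(mass = c(12.0, 13.00335483521), abundance = c(0.9893, 0.0107)),
  N = list(mass = c(14.00307400446, 15.00010889894), abundance = c(0.99636, 0.00364)),
  O = list(
    mass = c(15.99491461960, 16.99913175664, 17.99915961284),
    abundance = c(0.99757, 0.00038, 0.00205)
  ),
  S = list(
    mass = c(31.97207117443, 32.97145890985, 33.96786701, 35.96708070),
    abundance = c(0.9499, 0.0075, 0.0425, 0.0001)
  ),
  F = list(mass = 18.99840316, abundance = 1),
  P = list(mass = 30.97376200, abundance = 1),
  Na = list(mass = 22.98976928, abundance = 1),
  K = list(
    mass = c(38.96370648, 39.963998, 40.96182526),
    abundance = c(0.932581, 0.000117, 0.067302)
  ),
  `13C` = list(mass = 13.00335483521, abundance = 1),
  `2H` = list(mass = 2.01410177811, abundance = 1)
)

.electron_mass <- 0.000548579909

#' Isotope masses and natural abundances used by the package
#'
#' Returns the isotope table embedded in the package: per element, the
#' isotope masses (Da) and natural abundance fractions, plus the nominal
#' mass offset of each isotope relative to the lightest one. The
#' pseudo-elements `"13C"` and `"2H"` carry a single isotope at abundance 1
#' and are used to model chemically defined labeled positions (the heavy
#' acetyl group) rather than perturbed natural abundances.
#'
#' @return A tibble with columns `element`, `isotope_mass`, `abundance`,
#'   and `offset` (nominal mass difference to the element's lightest
#'   isotope, in unit masses).
#' @export
#' @examples
#' isotope_table()
isotope_table <- function() {
  purrr::imap_dfr(.isotope_data, function(x, el) {
    tibble::tibble(
      element = el,
      isotope_mass = x$mass,
      abundance = x$abundance,
      offset = as.integer(round(x$mass - x$mass[1]))
    )
  })
}

.known_elements <- names(.isotope_data)

# most-abundant-isotope mass per element (monoisotopic convention)
.mono_mass <- vapply(
  .isotope_data,
  function(x) x$mass[which.max(x$abundance)],
  numeric(1)
)

#' Elemental compositions
#'
#' An elemental composition is a multiset of element counts, stored as a
#' named integer vector with class `"elemental_composition"`. Supported
#' elements are C, H, N, O, S, Na, K and the explicit-isotope
#' pseudo-elements 13C and 2H. Compositions add and subtract element-wise
#' with `+` and `-`; subtracting below zero is an error.
#'
#' @param counts Named numeric vector or list of non-negative integer
#'   counts, names are element symbols (e.g. `c(C = 2, H = 3, O = 1)`).
#' @return An `elemental_composition` object.
#' @export
#' @examples
#' composition(c(C = 2, H = 3, O = 1))
#' composition(c(C = 2, H = 2, O = 1)) + composition(c(H = 2))
composition <- function(counts = numeric()) {
  counts <- unlist(counts)
  if (length(counts) == 0) {
    x <- stats::setNames(numeric(0), character(0))
    return(structure(x, class = "elemental_composition"))
  }
  if (is.null(names(counts)) || any(names(counts) == "")) {
    stop("composition counts must be a named vector of element counts", call. = FALSE)
  }
  unknown <- setdiff(names(counts), .known_elements)
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("element counts must be non-negative integers", call. = FALSE)
  }
  counts <- counts[counts > 0]
  # canonical order: Hill system (C, H, then alphabetical), labels after parent
  ord <- c("C", "13C", "H", "2H", "F", "K", "N", "Na", "O", "P", "S")
  counts <- counts[order(match(names(counts), ord))]
  structure(as.numeric(counts), names = names(counts), class = "elemental_composition")
}

#' @export
`+.elemental_composition` <- function(e1, e2) {
  els <- union(names(e1), names(e2))
  out <- stats::setNames(numeric(length(els)), els)
  out[names(e1)] <- out[names(e1)] + unclass(e1)
  out[names(e2)] <- out[names(e2)] + unclass(e2)
  composition(out)
}

#' @export
`-.elemental_composition` <- function(e1, e2) {
  if (missing(e2)) stop("unary minus is not defined for compositions", call. = FALSE)
  els <- union(names(e1), names(e2))
  out <- stats::setNames(numeric(length(els)), els)
  out[names(e1)] <- out[names(e1)] + unclass(e1)
  out[names(e2)] <- out[names(e2)] - unclass(e2)
  if (any(out < 0)) {
    bad <- names(out)[out < 0]
    stop(
      "subtraction yields negative count for element(s): ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  composition(out)
}

#' @export
`==.elemental_composition` <- function(e1, e2) {
  identical(
    unclass(composition(stats::setNames(as.numeric(e1), names(e1)))),
    unclass(composition(stats::setNames(as.numeric(e2), names(e2))))
  )
}

#' @export
format.elemental_composition <- function(x, ...) {
  if (length(x) == 0) return("")
  symbols <- names(x)
  # bracket explicit isotopes so the output re-parses unambiguously
  symbols <- ifelse(grepl("^[0-9]", symbols), paste0("[", symbols, "]"), symbols)
  paste0(
    symbols,
    ifelse(unclass(x) == 1, "", as.character(unclass(x))),
    collapse = ""
  )
}

#' @export
print.elemental_composition <- function(x, ...) {
  cat(
    "<elemental composition> ",
    if (length(x) == 0) "(empty)" else format(x),
    "  (", format(monoisotopic_mass(x), nsmall = 5), " Da)\n",
    sep = ""
  )
  invisible(x)
}

#' Parse a Hill-notation molecular formula
#'
#' Parses strings such as `"C6H11NO"` into an [composition()]. Explicit
#' isotopes are written with their mass number prefix either in brackets
#' (`"C[13C][2H]3O"`) or as whitespace-separated groups
#' (`"C1 13C1 2H3 O1"`, the heavy acetyl group); whitespace always
#' separates groups, so an isotope prefix is never confused with a
#' preceding count.
#'
#' @param text Formula string; `""` yields the empty composition.
#' @return An `elemental_composition`.
#' @export
#' @examples
#' parse_formula("C2H3O")
#' parse_formula("C6H11NO") # Ile residue
#' parse_formula("C1 13C1 2H3 O1") # heavy acetyl group
#' parse_formula("C[13C][2H]3O") # same, bracket notation
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  chunks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  chunks <- chunks[nzchar(chunks)]
  if (length(chunks) == 0) return(composition())
  token_re <- "\\[(13C|2H)\\]([0-9]*)|(13C|2H)([0-9]*)|([A-Z][a-z]?)([0-9]*)"
  all_els <- character()
  all_ns <- numeric()
  for (chunk in chunks) {
    matches <- gregexpr(token_re, chunk, perl = TRUE)[[1]]
    tokens <- regmatches(chunk, list(matches))[[1]]
    if (matches[1] == -1 || sum(attr(matches, "match.length")) != nchar(chunk)) {
      leftover <- chunk
      for (tok in tokens) leftover <- sub(tok, "", leftover, fixed = TRUE)
      stop(
        "malformed formula '", text, "': unparseable token(s) near '",
        leftover, "'",
        call. = FALSE
      )
    }
    els <- sub(token_re, "\\1\\3\\5", tokens, perl = TRUE)
    ns <- sub(token_re, "\\2\\4\\6", tokens, perl = TRUE)
    ns <- ifelse(ns == "", "1", ns)
    unknown <- setdiff(els, .known_elements)
    if (length(unknown) > 0) {
      stop(
        "unknown element symbol(s) in formula: ",
        paste(unique(unknown), collapse = ", "),
        call. = FALSE
      )
    }
    all_els <- c(all_els, els)
    all_ns <- c(all_ns, as.numeric(ns))
  }
  counts <- tapply(all_ns, all_els, sum)
  composition(stats::setNames(as.numeric(counts), names(counts)))
}

#' Monoisotopic mass of an elemental composition
#'
#' Sum over elements of count times the most-abundant-isotope mass;
#' explicit-isotope pseudo-elements (13C, 2H) contribute their own mass.
#'
#' @param x An [composition()] object.
#' @return Mass in Da.
#' @export
#' @examples
#' monoisotopic_mass(parse_formula("C2H6N2O")) # Gly amide, 74.04801 Da
monoisotopic_mass <- function(x) {
  stopifnot(inherits(x, "elemental_composition"))
  if (length(x) == 0) return(0)
  sum(unclass(x) * .mono_mass[names(x)])
}

#' Adduct m/z of a neutral mass
#'
#' Singly charged cationization: the m/z equals the neutral mass plus the
#' cation mass, where the cation mass is the atomic mass minus one electron
#' mass.
#'
#' @param neutral_mass Neutral monoisotopic (or isotopologue) mass in Da.
#' @param adduct One of `"H"`, `"Na"`, `"K"`.
#' @return m/z in Da (charge +1).
#' @export
#' @examples
#' adduct_mz(1000, "H") # 1001.00728
#' adduct_mz(1000, "Na") # 1022.98922
adduct_mz <- function(neutral_mass, adduct = c("H", "Na", "K")) {
  adduct <- match.arg(adduct)
  stopifnot(all(neutral_mass > 0))
  neutral_mass + adduct_shift(adduct)
}

#' @rdname adduct_mz
#' @export
adduct_shift <- function(adduct = c("H", "Na", "K")) {
  adduct <- match.arg(adduct)
  .mono_mass[[adduct]] - .electron_mass
}
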