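# Residue compositions are for the *residue* (amino acid minus water), so a
# peptide chain is sum(residues) + N-terminal H + C-terminal OH (free acid)
# or NH2 (amide). D-amino acids (lowercase codes) share the composition of
# their L-forms; stereochemistry does not change mass.

.canonical_residues <- c(
  G = "C2H3NO", A = "C3H5NO", S = "C3H5NO2", P = "C5H7NO", V = "C5H9NO",
  T = "C4H7NO2", C = "C3H5NOS", L = "C6H11NO", I = "C6H11NO", N = "C4H6N2O2",
  D = "C4H5NO3", Q = "C5H8N2O2", K = "C6H12N2O", E = "C5H7NO3", M = "C5H9NOS",
  H = "C6H7N3O", F = "C9H9NO", R = "C6H12N4O", Y = "C9H9NO2", W = "C11H10N2O"
)

#' Built-in residue formula table
#'
#' Residue (amino acid minus water) elemental formulas for the 20 canonical
#' amino acids, in Hill notation. Non-natural residues are supplied by the
#' user, either through the `residue_formulas` argument of
#' [peptide_species()] or via [read_residue_table()].
#'
#' @return A tibble with columns `code` and `formula`.
#' @export
residue_table <- function() {
  tibble::tibble(code = names(.canonical_residues), formula = unname(.canonical_residues))
}

#' Read a user residue formula table
#'
#' Reads a CSV with columns `code` (residue code as used in sequences) and
#' `formula` (Hill notation, e.g. `"C6H11NO"`). Returned as a named list of
#' compositions suitable for the `residue_formulas` argument of
#' [peptide_species()].
#'
#' @param path Path to the CSV file.
#' @return Named list of [composition()] objects.
#' @export
read_residue_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("code", "formula") %in% names(df))) {
    stop("residue table must have columns 'code' and 'formula': ", path, call. = FALSE)
  }
  stats::setNames(lapply(df$formula, parse_formula), df$code)
}

.default_residue_formulas <- function() {
  stats::setNames(lapply(.canonical_residues, parse_formula), names(.canonical_residues))
}

#' Define a peptide species
#'
#' A peptide species is a sequence of residue codes plus terminal groups and
#' a label state. The N-terminus is free or acetylated; the heavy acetyl
#' group carries one carbon-13 and three deuterium atoms, giving a nominal
#' +4 mass shift over the light acetyl while leaving the chemistry
#' identical. Lowercase codes (D-amino acids) resolve to the composition of
#' the uppercase form; codes not in the built-in table must be supplied via
#' `residue_formulas`.
#'
#' @param sequence Residue-code string, e.g. `"HAIYPRH"` or `"hrpyiah"`.
#' @param n_terminus `"free"`, `"acetyl_light"` or `"acetyl_heavy"`.
#' @param c_terminus `"free_acid"` or `"amide"`.
#' @param residue_formulas Optional named list of [composition()] objects
#'   (or Hill-notation strings) overriding/extending the built-in residue
#'   table, e.g. for non-natural residues.
#' @param name Optional display name.
#' @return A `peptide_species` object.
#' @export
#' @examples
#' light <- peptide_species("HAIYPRH", n_terminus = "acetyl_light", c_terminus = "amide")
#' heavy <- peptide_species("HAIYPRH", n_terminus = "acetyl_heavy", c_terminus = "amide")
#' monoisotopic_mass(compose_peptide(heavy)) - monoisotopic_mass(compose_peptide(light))
peptide_species <- function(sequence,
                            n_terminus = c("free", "acetyl_light", "acetyl_heavy"),
                            c_terminus = c("free_acid", "amide"),
                            residue_formulas = NULL,
                            name = NULL) {
  n_terminus <- match.arg(n_terminus)
  c_terminus <- match.arg(c_terminus)
  stopifnot(is.character(sequence), length(sequence) == 1, nchar(sequence) > 0)
  formulas <- .default_residue_formulas()
  if (!is.null(residue_formulas)) {
    extra <- lapply(residue_formulas, function(f) {
      if (inherits(f, "elemental_composition")) f else parse_formula(f)
    })
    formulas[names(extra)] <- extra
  }
  codes <- strsplit(sequence, "")[[1]]
  resolved <- ifelse(codes %in% names(formulas), codes, toupper(codes))
  missing <- unique(resolved[!resolved %in% names(formulas)])
  if (length(missing) > 0) {
    stop(
      "unknown residue code(s): ", paste(missing, collapse = ", "),
      "; supply them via residue_formulas",
      call. = FALSE
    )
  }
  structure(
    list(
      sequence = sequence,
      codes = resolved,
      n_terminus = n_terminus,
      c_terminus = c_terminus,
      residue_formulas = formulas,
      name = name %||% sequence
    ),
    class = "peptide_species"
  )
}

#' @export
print.peptide_species <- function(x, ...) {
  prefix <- switch(x$n_terminus,
    free = "H-", acetyl_light = "Ac-", acetyl_heavy = "Ac*-"
  )
  suffix <- switch(x$c_terminus, free_acid = "-OH", amide = "-NH2")
  cat(
    "<peptide species> ", prefix, x$sequence, suffix,
    " (", label_state(x), ", ",
    format(monoisotopic_mass(compose_peptide(x)), nsmall = 4), " Da)\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname peptide_species
#' @param x A `peptide_species`.
#' @export
label_state <- function(x) {
  stopifnot(inherits(x, "peptide_species"))
  if (x$n_terminus == "acetyl_heavy") "heavy" else "light"
}

#' Elemental composition of a peptide species
#'
#' Sums the residue compositions and adds the terminal groups: an H on the
#' free N-terminus (replaced net by the acetyl group when acetylated), and
#' OH (free acid) or NH2 (amide) on the C-terminus. The light acetyl adds
#' C2H2O net of the displaced amine H; the heavy acetyl adds C(13C)(2H)3O
#' net of the same H.
#'
#' @param species A [peptide_species()].
#' @return An [composition()].
#' @export
compose_peptide <- function(species) {
  stopifnot(inherits(species, "peptide_species"))
  comp <- Reduce(`+`, species$residue_formulas[species$codes], composition())
  comp <- comp + composition(c(H = 1)) # N-terminal H
  comp <- comp + switch(species$c_terminus,
    free_acid = composition(c(O = 1, H = 1)),
    amide = composition(c(N = 1, H = 2))
  )
  switch(species$n_terminus,
    free = comp,
    acetyl_light = comp + composition(c(C = 2, H = 2, O = 1)),
    acetyl_heavy = comp + composition(c(C = 1, `13C` = 1, `2H` = 3, O = 1)) -
      composition(c(H = 1))
  )
}

#' Mass shift of the heavy acetyl label
#'
#' The heavy acetyl group replaces one carbon-12 by carbon-13 and three
#' hydrogens by deuterium, so the heavy-minus-light shift is
#' (m(13C) - m(12C)) + 3 (m(2H) - m(1H)) = 4.022185 Da, nominally +4 unit
#' masses, for every peptide regardless of sequence.
#'
#' @param nominal If `TRUE`, return the integer nominal shift (4).
#' @return Mass shift in Da (or unit masses when `nominal = TRUE`).
#' @export
#' @examples
#' label_mass_shift() # 4.022185
#' label_mass_shift(nominal = TRUE) # 4
label_mass_shift <- function(nominal = FALSE) {
  if (nominal) return(4L)
  heavy <- composition(c(`13C` = 1, `2H` = 3))
  light <- composition(c(C = 1, H = 3))
  monoisotopic_mass(heavy) - monoisotopic_mass(light)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
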