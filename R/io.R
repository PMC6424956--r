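# Readers and writers: two-column text spectra (read/write), mzML (read,
# via mzR), CSV result tables with provenance comment headers, and the YAML
# run configuration.

#' Read a mass spectrum from file
#'
#' Two-column text (`m/z intensity`, whitespace- or comma-delimited, `#`
#' comments) or mzML (first spectrum; requires the mzR package). Rows with
#' non-increasing m/z are sorted with a warning and duplicate m/z values
#' are merged by summing their intensities.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"text"` or `"mzml"`.
#' @return A [mass_spectrum()] with the source path in its metadata.
#' @export
read_spectrum <- function(path, format = c("auto", "text", "mzml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "text"
  }
  if (format == "mzml") {
    if (!requireNamespace("mzR", quietly = TRUE)) {
      stop("reading mzML requires the mzR package", call. = FALSE)
    }
    handle <- mzR::openMSfile(path)
    on.exit(mzR::close(handle), add = TRUE)
    pk <- mzR::peaks(handle, 1)
    mz <- pk[, 1]
    intensity <- pk[, 2]
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) {
      return(mass_spectrum(numeric(), numeric(), metadata = list(source = path)))
    }
    fields <- strsplit(lines, "[,[:space:]]+")
    bad <- which(vapply(fields, length, integer(1)) < 2)
    if (length(bad) > 0) {
      stop(
        "ill-formed spectrum file ", path, ": line ", bad[1],
        " does not have two columns",
        call. = FALSE
      )
    }
    mz <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 1)))
    intensity <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
    if (anyNA(mz) || anyNA(intensity)) {
      bad <- which(is.na(mz) | is.na(intensity))[1]
      stop(
        "ill-formed spectrum file ", path, ": non-numeric value on data line ", bad,
        call. = FALSE
      )
    }
  }
  if (is.unsorted(mz, strictly = TRUE)) {
    warning("m/z values not strictly increasing in ", path,
      "; sorting (duplicates merged by intensity sum)",
      call. = FALSE
    )
    ord <- order(mz)
    mz <- mz[ord]
    intensity <- intensity[ord]
    if (anyDuplicated(mz)) {
      intensity <- as.numeric(tapply(intensity, mz, sum))
      mz <- sort(unique(mz))
    }
  }
  mass_spectrum(mz, intensity, metadata = list(source = path, format = format))
}

#' Write a mass spectrum as two-column text
#'
#' Full double precision, whitespace-delimited, with `#` comment headers
#' carrying provenance; [read_spectrum()] round-trips the arrays exactly.
#'
#' @param spectrum A [mass_spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  meta <- attr(spectrum, "metadata")
  header <- c(
    "# isopair spectrum (m/z intensity)",
    if (!is.null(meta$species)) {
      paste0("# species: ", paste(meta$species, collapse = ", "))
    },
    if (!is.null(meta$abundances)) {
      paste0("# abundances_um: ", paste(format(meta$abundances, digits = 17), collapse = ", "))
    },
    if (!is.null(meta$config$seed)) paste0("# seed: ", meta$config$seed)
  )
  body <- sprintf("%.17g %.17g", spectrum$mz, spectrum$intensity)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read and write the run configuration
#'
#' The run configuration is a YAML file bundling peptide definitions (name,
#' sequence, terminal groups), an optional residue-formula CSV path, assay
#' geometry, quantification, simulation and LOQ settings, and the seed. It
#' round-trips through [write_run_config()] unchanged and is validated on
#' read.
#'
#' @param path Path to the YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config A `run_config` list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname read_run_config
#' @export
validate_run_config <- function(config) {
  stopifnot(is.list(config))
  residues <- NULL
  if (!is.null(config$residue_table)) {
    residues <- read_residue_table(config$residue_table)
  }
  if (!is.null(config$peptides)) {
    for (p in config$peptides) {
      if (is.null(p$sequence)) stop("peptide entry without sequence", call. = FALSE)
      # resolves every referenced residue or errors
      peptide_species(
        p$sequence,
        n_terminus = p$n_terminus %||% "acetyl_light",
        c_terminus = p$c_terminus %||% "amide",
        residue_formulas = residues,
        name = p$name
      )
    }
  }
  if (!is.null(config$assay)) do.call(well_assay, config$assay)
  if (!is.null(config$sim)) do.call(sim_config, config$sim)
  if (!is.null(config$quant)) do.call(quant_settings, config$quant)
  if (!is.null(config$seed)) stopifnot(is.numeric(config$seed))
  structure(config, class = c("run_config", "list"))
}

# peptide_species from a config entry
.config_species <- function(config, name, label = c("light", "heavy")) {
  label <- match.arg(label)
  entry <- NULL
  for (p in config$peptides %||% list()) {
    if (identical(p$name, name)) entry <- p
  }
  if (is.null(entry)) stop("peptide '", name, "' not found in config", call. = FALSE)
  residues <- if (!is.null(config$residue_table)) {
    read_residue_table(config$residue_table)
  }
  peptide_species(
    entry$sequence,
    n_terminus = if (label == "heavy") "acetyl_heavy" else entry$n_terminus %||% "acetyl_light",
    c_terminus = entry$c_terminus %||% "amide",
    residue_formulas = residues,
    name = paste0(name, "_", label)
  )
}

#' Write a result table as CSV with a provenance header
#'
#' @param data A data frame.
#' @param path Output path.
#' @param provenance Named character-coercible list written as `# key: value`
#'   comment lines.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(data, path, provenance = list()) {
  provenance <- c(list(package = paste0("isopair ", .pkg_version())), provenance)
  header <- vapply(
    names(provenance),
    function(k) paste0("# ", k, ": ", paste(format(provenance[[k]]), collapse = " ")),
    character(1)
  )
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(header, con)
  utils::write.csv(data, con, row.names = FALSE)
  invisible(path)
}

#' Read a result CSV written by [write_result_csv()]
#'
#' @param path Path to the CSV.
#' @return A tibble (provenance comment lines are skipped).
#' @export
read_result_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE))
}

.pkg_version <- function() {
  as.character(utils::packageVersion("isopair"))
}
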