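# Shared fixtures and independent oracles.

# Exhaustive isotopologue enumeration for small compositions (<= ~10 atoms):
# every atom independently takes one of its isotopes; the full cross product
# of assignments is kept (probability product, summed nominal offset, summed
# exact mass) and only aggregated by nominal offset at the very end.
oracle_envelope <- function(comp) {
  iso <- isotope_table()
  states <- data.frame(p = 1, k = 0L, m = 0)
  for (el in names(comp)) {
    tab <- iso[iso$element == el, ]
    for (atom in seq_len(unclass(comp)[[el]])) {
      states <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
        data.frame(
          p = states$p * tab$abundance[i],
          k = states$k + tab$offset[i],
          m = states$m + tab$isotope_mass[i]
        )
      }))
    }
  }
  agg_p <- tapply(states$p, states$k, sum)
  agg_m <- tapply(states$p * states$m, states$k, sum) / agg_p
  tibble::tibble(
    k = as.integer(names(agg_p)),
    mz = as.numeric(agg_m),
    abundance = as.numeric(agg_p)
  )
}

hai_light <- function() {
  peptide_species("HAIYPRH",
    n_terminus = "acetyl_light", c_terminus = "amide",
    name = "HAI_light"
  )
}

hai_heavy <- function() {
  peptide_species("HAIYPRH",
    n_terminus = "acetyl_heavy", c_terminus = "amide",
    name = "HAI_heavy"
  )
}

# noiseless, protonated-only instrument settings for exact-recovery tests
clean_config <- function(seed = 1, ...) {
  sim_config(
    noise_sd = 0, baseline_level = 0,
    adduct_abundances = c(H = 1),
    intensity_scale = 100,
    seed = seed,
    ...
  )
}

trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

# a synthetic heavy analyte: single pseudo-residue large enough that its
# natural envelope reaches offsets k >= 4 with non-negligible abundance
big_species <- function(label = c("light", "heavy")) {
  label <- match.arg(label)
  peptide_species(
    "X",
    n_terminus = if (label == "heavy") "acetyl_heavy" else "acetyl_light",
    c_terminus = "amide",
    residue_formulas = list(X = "C150H244N40O45"),
    name = paste0("big_", label)
  )
}
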