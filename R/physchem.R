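#' Build a component registry
#'
#' A component registry is a tibble with one row per molecular species
#' (protein, peptide, ssDNA, dsDNA or dye) carrying its molar mass,
#' partial specific volume and molar extinction coefficients. It is the
#' bookkeeping backbone for buoyancy arithmetic, synthetic-data scenarios
#' and stoichiometry enumeration.
#'
#' @param ... One or more component records, each a list with elements
#'   `name`, `molar_mass` (g/mol), `vbar` (ml/g), `kind` (one of
#'   `"protein"`, `"peptide"`, `"ssDNA"`, `"dsDNA"`, `"dye"`), and
#'   optionally `extinction` (named numeric, names are wavelengths in nm,
#'   values in M^-1 cm^-1) and `sequence` (residue string; when given and
#'   `molar_mass` is absent the mass is derived with
#'   [molar_mass_from_sequence()]).
#'
#' @return A tibble of class `component_registry` with columns `name`,
#'   `molar_mass`, `vbar`, `kind`, `extinction` (list column) and
#'   `sequence`.
#' @examples
#' reg <- component_registry(
#'   list(name = "RecO", molar_mass = 26964, vbar = 0.734, kind = "protein",
#'        extinction = c("280" = 2.44e4))
#' )
#' @export
component_registry <- function(...) {
  records <- list(...)
  if (length(records) == 1L && is.null(records[[1]]$name) &&
      all(vapply(records[[1]], is.list, logical(1)))) {
    records <- records[[1]]  # a bare list of records
  }
  rows <- purrr::map(records, validate_component)
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(out$name)) {
    rlang::abort("duplicate component names in registry")
  }
  class(out) <- c("component_registry", class(out))
  out
}

validate_component <- function(rec) {
  if (is.null(rec$name) || !nzchar(rec$name)) {
    rlang::abort("component record needs a non-empty name")
  }
  kind <- rlang::arg_match0(
    rec$kind %||% "protein",
    c("protein", "peptide", "ssDNA", "dsDNA", "dye")
  )
  if (is.null(rec$molar_mass) && !is.null(rec$sequence)) {
    seq_kind <- if (kind %in% c("ssDNA", "dsDNA")) "ssDNA" else "peptide"
    rec$molar_mass <- molar_mass_from_sequence(
      rec$sequence, kind = seq_kind, adducts = rec$adducts %||% character()
    )
  }
  if (is.null(rec$molar_mass) || rec$molar_mass <= 0) {
    rlang::abort(sprintf("component '%s': molar_mass must be > 0", rec$name))
  }
  if (is.null(rec$vbar) || rec$vbar <= 0.4 || rec$vbar >= 1.0) {
    rlang::abort(sprintf(
      "component '%s': vbar must lie in (0.4, 1.0) ml/g", rec$name
    ))
  }
  ext <- rec$extinction
  if (!is.null(ext)) {
    ext <- unlist(ext)
    if (any(ext <= 0)) {
      rlang::abort(sprintf(
        "component '%s': extinction coefficients must be > 0", rec$name
      ))
    }
  }
  tibble::tibble(
    name = rec$name,
    molar_mass = as.numeric(rec$molar_mass),
    vbar = as.numeric(rec$vbar),
    kind = kind,
    extinction = list(ext),
    sequence = rec$sequence %||% NA_character_
  )
}

#' Read a component registry from a YAML file
#'
#' The file holds a list of component records under the top-level key
#' `components` (or as a bare list), with the same fields as
#' [component_registry()]. Records with a `sequence` but no `molar_mass`
#' get their mass derived from the shipped residue mass tables.
#'
#' @param path Path to a YAML file.
#' @return A `component_registry` tibble.
#' @export
read_component_registry <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("registry file not found: %s", path))
  }
  raw <- yaml::read_yaml(path)
  records <- raw$components %||% raw
  component_registry(records)
}

#' Describe a molecular composition
#'
#' A composition is a multiset of registry components with integer copy
#' numbers, e.g. one RecO, one SSB-Ct peptide and one Cy3-(dT)15.
#'
#' @param registry A `component_registry` tibble.
#' @param counts Named integer vector of copy numbers; names must match
#'   registry component names. Zero-copy entries are dropped.
#' @return A tibble of class `composition` with columns `name`, `copies`,
#'   `molar_mass`, `vbar`, and a `total_mass` attribute (g/mol).
#' @examples
#' \dontrun{
#' comp <- composition(reg, c(RecO = 1, `SSB-Ct` = 1))
#' composite_vbar(comp)
#' }
#' @export
composition <- function(registry, counts) {
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    rlang::abort("counts must be a named vector")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    rlang::abort("copy numbers must be non-negative integers")
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0L) {
    rlang::abort("composition needs at least one component with copies >= 1")
  }
  missing <- setdiff(names(counts), registry$name)
  if (length(missing) > 0L) {
    rlang::abort(sprintf(
      "components not in registry: %s", paste(missing, collapse = ", ")
    ))
  }
  out <- tibble::tibble(name = names(counts), copies = as.integer(counts)) |>
    dplyr::left_join(
      dplyr::select(tibble::as_tibble(registry), "name", "molar_mass", "vbar"),
      by = "name"
    )
  attr(out, "total_mass") <- sum(out$copies * out$molar_mass)
  class(out) <- c("composition", class(out))
  out
}

#' Total molar mass of a composition
#' @param composition A `composition` tibble.
#' @return Molar mass in g/mol.
#' @export
composition_mass <- function(composition) {
  sum(composition$copies * composition$molar_mass)
}

#' Mass-weighted partial specific volume of a complex
#'
#' For a complex of several species the partial specific volume is taken
#' as additive: the mass-weighted mean
#' \deqn{\bar v = \sum_i n_i M_i \bar v_i / \sum_i n_i M_i}
#' over the components, the standard approximation for rigid complexes.
#'
#' @param composition A `composition` tibble (see [composition()]), or any
#'   data frame with columns `copies`, `molar_mass`, `vbar`.
#' @return Partial specific volume in ml/g, bounded by the component vbars.
#' @export
composite_vbar <- function(composition) {
  if (is.null(composition) || nrow(composition) == 0L) {
    rlang::abort("empty composition")
  }
  if (any(composition$copies < 0)) rlang::abort("negative copy number")
  w <- composition$copies * composition$molar_mass
  if (sum(w) <= 0) rlang::abort("composition has zero total mass")
  sum(w * composition$vbar) / sum(w)
}

#' Buoyant molar mass factor
#'
#' The effective mass driving sedimentation, \eqn{M (1 - \bar v \rho)}.
#' Vectorized over all arguments.
#'
#' @param molar_mass Molar mass, g/mol (> 0).
#' @param vbar Partial specific volume, ml/g (> 0).
#' @param density Solvent density, g/ml (> 0).
#' @return Buoyant molar mass in g/mol; zero at neutral buoyancy
#'   (`vbar * density == 1`), negative for floating species.
#' @export
buoyant_factor <- function(molar_mass, vbar, density) {
  if (any(molar_mass <= 0) || any(vbar <= 0) || any(density <= 0)) {
    rlang::abort("molar_mass, vbar and density must all be > 0")
  }
  molar_mass * (1 - vbar * density)
}

#' Percent difference between measured and calculated vbar
#'
#' Reported relative to the calculated value and rounded to one decimal,
#' the convention used when comparing experimentally determined partial
#' specific volumes with composition-based (SEDNTERP-style) estimates.
#'
#' @param measured Measured vbar, ml/g.
#' @param calculated Calculated vbar, ml/g (denominator).
#' @return Percent difference, one decimal place.
#' @export
vbar_percent_difference <- function(measured, calculated) {
  if (any(measured <= 0)) rlang::abort("measured vbar must be > 0")
  if (any(calculated == 0)) rlang::abort("calculated vbar must be non-zero")
  round(100 * abs(calculated - measured) / calculated, 1)
}

#' Molar mass from a residue sequence
#'
#' Sums average residue masses from the shipped tables plus a terminal
#' correction and any named adduct masses. Conventions: peptides gain one
#' water for the free termini; oligodeoxynucleotides are 5'-OH / 3'-OH with
#' one phosphodiester linkage mass per internal bond.
#'
#' @param sequence Residue string: one-letter amino acids for `"peptide"`,
#'   `ACGT` for `"ssDNA"`.
#' @param kind `"peptide"` or `"ssDNA"`.
#' @param adducts Character vector of adduct names (see `ADDUCT_MASS`,
#'   currently `"cy3"`), or a named numeric vector of masses in g/mol.
#' @return Molar mass in g/mol.
#' @examples
#' molar_mass_from_sequence("PSNEPPMDFDDDIPF", kind = "peptide")
#' molar_mass_from_sequence(strrep("T", 15), kind = "ssDNA", adducts = "cy3")
#' @export
molar_mass_from_sequence <- function(sequence,
                                     kind = c("peptide", "ssDNA"),
                                     adducts = character()) {
  kind <- rlang::arg_match(kind)
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    rlang::abort("sequence must be a non-empty string")
  }
  chars <- strsplit(toupper(sequence), "")[[1]]
  table <- switch(kind, peptide = AA_RESIDUE_MASS, ssDNA = DNA_NUCLEOSIDE_MASS)
  bad <- setdiff(unique(chars), names(table))
  if (length(bad) > 0L) {
    rlang::abort(sprintf(
      "unknown %s residue(s): %s", kind, paste(bad, collapse = ", ")
    ))
  }
  core <- sum(table[chars])
  terminal <- switch(
    kind,
    peptide = WATER_MASS,
    ssDNA = (length(chars) - 1L) * DNA_LINKAGE_MASS
  )
  if (is.numeric(adducts)) {
    adduct_mass <- sum(adducts)
  } else if (length(adducts) > 0L) {
    unknown <- setdiff(tolower(adducts), names(ADDUCT_MASS))
    if (length(unknown) > 0L) {
      rlang::abort(sprintf(
        "unknown adduct(s): %s", paste(unknown, collapse = ", ")
      ))
    }
    adduct_mass <- sum(ADDUCT_MASS[tolower(adducts)])
  } else {
    adduct_mass <- 0
  }
  unname(core + terminal + adduct_mass)
}

#' Molar concentration from absorbance (Beer-Lambert)
#'
#' @param absorbance Absorbance, AU (>= 0).
#' @param epsilon Molar extinction coefficient, M^-1 cm^-1 (> 0).
#' @param pathlength Optical pathlength, cm (> 0; 1.2 cm for a standard
#'   AUC centerpiece).
#' @return Concentration in mol/l.
#' @export
concentration_from_absorbance <- function(absorbance, epsilon, pathlength) {
  if (any(absorbance < 0)) rlang::abort("absorbance must be >= 0")
  if (any(epsilon <= 0) || any(pathlength <= 0)) {
    rlang::abort("epsilon and pathlength must be > 0")
  }
  absorbance / (epsilon * pathlength)
}

#' Buffer state
#'
#' Solvent density, viscosity and temperature used in all sedimentation
#' arithmetic. Values are inputs (measured or estimated externally); the
#' package does not estimate them from buffer composition.
#'
#' @param density g/ml, in (0.9, 1.3).
#' @param viscosity poise (> 0).
#' @param temperature K (> 0). Default 298.15 K (25 degrees C).
#' @return A list of class `buffer_state`.
#' @export
buffer_state <- function(density = 1.05, viscosity = 0.020,
                         temperature = 298.15) {
  if (density <= 0.9 || density >= 1.3) {
    rlang::abort("density must lie in (0.9, 1.3) g/ml")
  }
  if (viscosity <= 0) rlang::abort("viscosity must be > 0")
  if (temperature <= 0) rlang::abort("temperature must be > 0")
  structure(
    list(density = density, viscosity = viscosity, temperature = temperature),
    class = "buffer_state"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
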