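#' Example component registry for the RecO / RecR / SSB-Ct / (dT)L system
#'
#' Builds a registry for the study system from the shipped residue mass
#' tables and the printed complex masses. The SSB-Ct peptide and
#' Cy3-(dT)L oligonucleotide masses come from their sequences; the RecO
#' monomer mass is backed out from the 33.8 kDa single-RecO complex and
#' four RecR from the 121.5 - 33.8 kDa difference (see
#' [derive_component_masses_from_complexes()]). Partial specific volumes
#' are the experimentally determined 0.734 (RecO) and 0.711 (RecR) ml/g,
#' the calculated 0.704 ml/g for the peptide, and 0.56 ml/g for DNA.
#'
#' @return A `component_registry` tibble with RecO, RecR, SSB-Ct,
#'   Cy3-dT15 and Cy3-dT35.
#' @export
example_registry <- function() {
  m_pep <- molar_mass_from_sequence("PSNEPPMDFDDDIPF", kind = "peptide")
  m_dna15 <- molar_mass_from_sequence(strrep("T", 15), kind = "ssDNA",
                                      adducts = "cy3")
  m_dna35 <- molar_mass_from_sequence(strrep("T", 35), kind = "ssDNA",
                                      adducts = "cy3")
  solved <- derive_component_masses_from_complexes(list(
    list(counts = c(grp1 = 1), mass = 33800),
    list(counts = c(grp1 = 1, recr4 = 1), mass = 121500)
  ))
  grp1 <- solved$molar_mass[solved$component == "grp1"]
  m_reco <- grp1 - m_pep - m_dna15
  m_recr <- solved$molar_mass[solved$component == "recr4"] / 4
  component_registry(
    list(name = "RecO", molar_mass = m_reco, vbar = 0.734, kind = "protein",
         extinction = c("280" = 2.44e4)),
    list(name = "RecR", molar_mass = m_recr, vbar = 0.711, kind = "protein",
         extinction = c("280" = 5.96e3)),
    list(name = "SSB_Ct", molar_mass = m_pep, vbar = 0.704, kind = "peptide",
         extinction = c("258" = 390), sequence = "PSNEPPMDFDDDIPF"),
    list(name = "Cy3_dT15", molar_mass = m_dna15, vbar = 0.56, kind = "ssDNA",
         extinction = c("260" = 15 * 8.1e3)),
    list(name = "Cy3_dT35", molar_mass = m_dna35, vbar = 0.56, kind = "ssDNA",
         extinction = c("260" = 35 * 8.1e3))
  )
}

#' Generate a synthetic sedimentation-equilibrium dataset
#'
#' Closed-form equilibrium profiles (single exponential species) at each
#' rotor speed, with per-speed baseline offsets drawn uniformly from a
#' small documented range and additive i.i.d. Gaussian noise. Amplitudes
#' at every speed derive from one shared loading signal, so mass
#' conservation across speeds holds exactly in the noiseless limit. The
#' closed form is used deliberately (never the Lamm solver) so that
#' equilibrium round-trip tests are independent of PDE discretization.
#'
#' @param mass Molar mass of the species, g/mol.
#' @param vbar Partial specific volume, ml/g.
#' @param buffer A [buffer_state()].
#' @param speeds Rotor speeds, rev/min (default 18000/23000/28000).
#' @param geometry Solution column (default short equilibrium column,
#'   6.9-7.2 cm).
#' @param mean_signal Sector-averaged baseline-subtracted signal, AU.
#' @param noise_sigma Gaussian noise sd, AU (default 0.005).
#' @param baseline_range Uniform range for per-speed baselines, AU.
#' @param grid_step Radial scan step, cm (default 0.003).
#' @param seed Integer seed (recorded in the output attributes).
#' @return An [se_profile_set()] with attribute `scenario` describing the
#'   generating parameters, plus `true_mass`.
#' @export
gen_se_dataset <- function(mass, vbar, buffer, speeds = c(18000, 23000, 28000),
                           geometry = cell_geometry(6.9, 7.2),
                           mean_signal = 0.25, noise_sigma = 0.005,
                           baseline_range = c(-0.01, 0.01),
                           grid_step = 0.003, seed = NULL) {
  if (length(speeds) == 0L) rlang::abort("speeds must be non-empty")
  r0 <- (geometry$meniscus + geometry$bottom) / 2
  radius <- seq(geometry$meniscus, geometry$bottom, by = grid_step)
  # shared sector loading: mean_signal times the sector measure
  loading <- mean_signal * (geometry$bottom^2 - geometry$meniscus^2) / 2
  make <- function() {
    purrr::map_dfr(speeds, function(rpm) {
      sigma <- se_sigma(mass, vbar, buffer, rpm)
      if (sigma * (geometry$bottom^2 - r0^2) > 500) {
        rlang::abort(
          "equilibrium exponent overflows: use a lower rotor speed"
        )
      }
      a_r0 <- loading / se_shape_integral(sigma, r0, geometry)
      b <- stats::runif(1, baseline_range[1], baseline_range[2])
      sig <- a_r0 * exp(sigma * (radius^2 - r0^2)) + b
      if (noise_sigma > 0) {
        sig <- sig + stats::rnorm(length(sig), sd = noise_sigma)
      }
      tibble::tibble(rpm = rpm, radius_cm = radius, signal = sig)
    })
  }
  data <- if (is.null(seed)) make() else withr::with_seed(seed, make())
  out <- se_profile_set(data, geometry, r0 = r0)
  attr(out, "scenario") <- list(
    mass = mass, vbar = vbar, speeds = speeds, mean_signal = mean_signal,
    noise_sigma = noise_sigma, baseline_range = baseline_range,
    grid_step = grid_step, seed = seed,
    buffer = unclass(buffer)
  )
  attr(out, "true_mass") <- mass
  out
}

#' Generate a synthetic sedimentation-velocity scan set
#'
#' Thin wrapper around [simulate_sv()] with a scan schedule derived from
#' the slowest species: scans are spread evenly until the non-diffusing
#' boundary of the principal species would reach 90% of the column.
#'
#' @param species Data frame with `s` (Svedberg) and `loading_signal`
#'   (AU); see [simulate_sv()].
#' @param vbar Partial specific volume for the s->D mapping, ml/g.
#' @param buffer A [buffer_state()].
#' @param rpm Rotor speed (default 42000).
#' @param geometry Cell geometry (default 6.0-7.2 cm).
#' @param n_scans Number of scans (default 10).
#' @param times Optional explicit scan times, s.
#' @param noise_sigma Gaussian noise sd, AU.
#' @param frictional_ratio f/f0 for the s->D mapping.
#' @param seed Integer seed.
#' @param ... Passed to [simulate_sv()] (e.g. `n_cells`, `dt_max`).
#' @return An `sv_scan_set`.
#' @export
gen_sv_dataset <- function(species, vbar, buffer, rpm = 42000,
                           geometry = cell_geometry(6.0, 7.2),
                           n_scans = 10, times = NULL, noise_sigma = 0.005,
                           frictional_ratio = 1.2, seed = NULL, ...) {
  species <- tibble::as_tibble(species)
  if (is.null(times)) {
    s_ref <- max(species$s)
    if (s_ref <= 0) rlang::abort("need a species with s > 0 for auto times")
    omega <- omega_from_rpm(rpm)
    t_end <- 0.9 * log(geometry$bottom / geometry$meniscus) /
      (s_ref * SVEDBERG * omega^2)
    times <- seq(t_end / n_scans, t_end, length.out = n_scans)
  }
  simulate_sv(
    species, geometry, rpm, buffer, times,
    noise_sigma = noise_sigma, seed = seed, vbar = vbar,
    frictional_ratio = frictional_ratio, ...
  )
}

#' Generate a synthetic light-scattering titration series
#'
#' Flat-then-rising hinge on the normalized intensity scale: zero mean
#' below the onset ratio, linear rise above, plus Gaussian noise. Raw
#' intensities are reconstructed as `I0 * (1 + norm)` so the series
#' round-trips through [normalize_series()].
#'
#' @param onset_ratio Breakpoint molar ratio.
#' @param n_points Number of titration points (default 40).
#' @param ratio_max Maximum molar ratio (default 16).
#' @param post_slope Normalized-intensity slope above onset (default 0.8).
#' @param noise_sigma Gaussian noise sd on the normalized scale
#'   (default 0.02).
#' @param i0 Initial raw intensity, counts.
#' @param seed Integer seed.
#' @return A [titration_series()] with attribute `scenario`.
#' @export
gen_titration_series <- function(onset_ratio, n_points = 40, ratio_max = 16,
                                 post_slope = 0.8, noise_sigma = 0.02,
                                 i0 = 1000, seed = NULL) {
  ratios <- seq(0, ratio_max, length.out = n_points)
  make <- function() {
    norm <- post_slope * pmax(ratios - onset_ratio, 0)
    if (noise_sigma > 0) {
      norm <- norm + stats::rnorm(n_points, sd = noise_sigma)
    }
    norm
  }
  norm <- if (is.null(seed)) make() else withr::with_seed(seed, make())
  out <- titration_series(ratios, i0 * (1 + norm), i0 = i0)
  attr(out, "scenario") <- list(
    onset_ratio = onset_ratio, n_points = n_points, ratio_max = ratio_max,
    post_slope = post_slope, noise_sigma = noise_sigma, i0 = i0, seed = seed
  )
  out
}

#' Named study scenarios
#'
#' The scenario table mirrors the study conditions: equilibrium datasets
#' at the expected complex masses (33.8, 69.5 and 121.5 kDa, composite
#' vbars from the component registry), velocity datasets at 42 000 rpm
#' for each reported weight-average sedimentation coefficient, and
#' titration hinges at the reported aggregation-onset ratios
#' (5.2, 6, 7.1).
#'
#' @return A tibble with columns `name`, `kind` and `params` (list).
#' @export
paper_scenarios <- function() {
  reg <- example_registry()
  vb <- function(counts) composite_vbar(composition(reg, counts))
  vbar_33_8 <- vb(c(RecO = 1, SSB_Ct = 1, Cy3_dT15 = 1))
  vbar_69_5 <- vb(c(RecO = 2, SSB_Ct = 2, Cy3_dT35 = 1))
  vbar_121_5 <- vb(c(RecR = 4, RecO = 1, SSB_Ct = 1, Cy3_dT15 = 1))
  se <- function(mass, vbar) {
    list(mass = mass, vbar = vbar)
  }
  sv_s <- c(0.5, 0.6, 0.7, 0.9, 1.0, 1.2, 1.9, 2.1, 2.3, 2.6, 2.9,
            3.8, 4.7, 4.8, 5.4, 5.7, 6.3)
  rows <- dplyr::bind_rows(
    tibble::tibble(
      name = c("SE-33.8k", "SE-69.5k", "SE-121.5k"), kind = "se",
      params = list(
        se(33800, vbar_33_8), se(69500, vbar_69_5), se(121500, vbar_121_5)
      )
    ),
    tibble::tibble(
      name = sprintf("SV-%.1fS", sv_s), kind = "sv",
      params = purrr::map(sv_s, ~ list(s = .x, vbar = vbar_121_5))
    ),
    tibble::tibble(
      name = sprintf("TI-%g", c(5.2, 6, 7.1)), kind = "titration",
      params = purrr::map(c(5.2, 6, 7.1), ~ list(onset_ratio = .x))
    )
  )
  rows
}

#' Realize a named scenario into a dataset
#'
#' @param name Scenario name from [paper_scenarios()].
#' @param seed Integer seed (recorded in the result).
#' @param buffer A [buffer_state()].
#' @param ... Overrides passed to the underlying generator.
#' @return The generated dataset (`se_profile_set`, `sv_scan_set` or
#'   `titration_series`).
#' @export
realize_scenario <- function(name, seed = 1L, buffer = buffer_state(), ...) {
  tab <- paper_scenarios()
  row <- tab[tab$name == name, ]
  if (nrow(row) == 0L) {
    rlang::abort(sprintf(
      "unknown scenario '%s'; see paper_scenarios()", name
    ))
  }
  p <- row$params[[1]]
  switch(
    row$kind,
    se = gen_se_dataset(p$mass, p$vbar, buffer, seed = seed, ...),
    sv = gen_sv_dataset(
      tibble::tibble(s = p$s, loading_signal = 0.5),
      vbar = p$vbar, buffer = buffer, seed = seed, ...
    ),
    titration = gen_titration_series(p$onset_ratio, seed = seed, ...)
  )
}
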