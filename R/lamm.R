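#' Sector-cell geometry
#'
#' @param meniscus Meniscus radius, cm.
#' @param bottom Cell bottom radius, cm.
#' @param limits Physical rotor range the positions must fall in, cm.
#' @return A list of class `cell_geometry`.
#' @export
cell_geometry <- function(meniscus = 6.0, bottom = 7.2, limits = c(5.8, 7.3)) {
  if (!(meniscus >= limits[1] && meniscus < bottom && bottom <= limits[2])) {
    rlang::abort(sprintf(
      "need %.2f <= meniscus < bottom <= %.2f (got %.3f, %.3f)",
      limits[1], limits[2], meniscus, bottom
    ))
  }
  structure(list(meniscus = meniscus, bottom = bottom), class = "cell_geometry")
}

#' Angular velocity from rotor speed
#' @param rpm Rotor speed, rev/min.
#' @return omega in rad/s.
#' @export
omega_from_rpm <- function(rpm) 2 * pi * rpm / 60

#' Hydrodynamic quantities implied by a sedimentation coefficient
#'
#' Under the standard c(s) parameterization, a species' molar mass and
#' diffusion coefficient follow from its sedimentation coefficient, the
#' partial specific volume, the solvent, and a single frictional ratio
#' f/f0: the Svedberg relation plus a Stokes sphere of the anhydrous
#' radius scaled by f/f0. Since s scales as M^(2/3) at fixed f/f0, M is
#' recovered in closed form and D = kT / (6 pi eta (f/f0) R0).
#'
#' @param s Sedimentation coefficient, Svedberg.
#' @param buffer A [buffer_state()].
#' @param vbar Partial specific volume, ml/g.
#' @param frictional_ratio f/f0, dimensionless (>= 1 physically).
#' @return A tibble with columns `s`, `molar_mass` (g/mol), `diffusion`
#'   (cm^2/s) and `stokes_radius` (cm).
#' @export
species_from_s <- function(s, buffer, vbar, frictional_ratio = 1.2) {
  if (any(s <= 0)) rlang::abort("s must be > 0 for the s->D mapping")
  buoy <- 1 - vbar * buffer$density
  if (buoy <= 0) rlang::abort("non-sedimenting species: vbar * density >= 1")
  s_sec <- s * SVEDBERG
  eta <- buffer$viscosity
  # s = M (1 - vbar rho) / (N_A f),  f = (f/f0) 6 pi eta R0,
  # R0 = (3 M vbar / (4 pi N_A))^(1/3)  =>  M^(2/3) known in closed form.
  geom <- (3 * vbar / (4 * pi * AVOGADRO))^(1 / 3)
  m23 <- s_sec * AVOGADRO * frictional_ratio * 6 * pi * eta * geom / buoy
  molar_mass <- m23^(3 / 2)
  r0 <- (3 * molar_mass * vbar / (4 * pi * AVOGADRO))^(1 / 3)
  diffusion <- BOLTZMANN_ERG * buffer$temperature /
    (6 * pi * eta * frictional_ratio * r0)
  tibble::tibble(
    s = s, molar_mass = molar_mass, diffusion = diffusion, stokes_radius = r0
  )
}

# Cell centers of the uniform finite-volume grid on [meniscus, bottom].
lamm_cell_centers <- function(geometry, n_cells) {
  h <- (geometry$bottom - geometry$meniscus) / n_cells
  geometry$meniscus + h * (seq_len(n_cells) - 0.5)
}

# Bernoulli function B(x) = x / (exp(x) - 1), stable near 0.
bernoulli_fn <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-8
  out[small] <- 1 - x[small] / 2
  xl <- x[!small]
  out[!small] <- ifelse(xl > 0, xl * exp(-xl) / (1 - exp(-xl)),
                        xl / (expm1(xl)))
  out
}

# Backward-Euler step matrix (dense inverse) for one species on the
# finite-volume grid. Scharfetter-Gummel exponential-fitted fluxes give an
# M-matrix: solutions stay non-negative and sector mass sum(c_j r_j h) is
# conserved exactly (zero-flux walls, telescoping fluxes).
lamm_step_matrix <- function(s_sec, D, omega, geometry, n_cells, dt) {
  h <- (geometry$bottom - geometry$meniscus) / n_cells
  r_face <- geometry$meniscus + h * (0:n_cells)
  r_c <- lamm_cell_centers(geometry, n_cells)
  v_face <- s_sec * omega^2 * r_face        # outward drift velocity at faces
  pe <- v_face * h / D
  bm <- bernoulli_fn(-pe)                    # weight on inner (left) cell
  bp <- bernoulli_fn(pe)                     # weight on outer (right) cell
  # flux through interior face f (between cells j and j+1), times r_f:
  #   r_f * (D/h) * (bm_f * c_j - bp_f * c_{j+1})
  iface <- 2:n_cells                         # interior faces
  coef <- D / h * r_face[iface]
  lower <- coef * bm[iface]                  # multiplies c_j in cell j+1 eqn
  upper <- coef * bp[iface]                  # multiplies c_{j+1} in cell j eqn
  diag_a <- numeric(n_cells)
  diag_a[1:(n_cells - 1)] <- diag_a[1:(n_cells - 1)] - lower
  diag_a[2:n_cells] <- diag_a[2:n_cells] - upper
  # dc_j/dt = (1 / (r_j h)) * (inflow - outflow)
  w <- 1 / (r_c * h)
  A <- matrix(0, n_cells, n_cells)
  idx <- seq_len(n_cells - 1)
  A[cbind(idx + 1, idx)] <- w[idx + 1] * lower      # from inner neighbour
  A[cbind(idx, idx + 1)] <- w[idx] * upper          # from outer neighbour
  diag(A) <- w * diag_a
  M <- diag(n_cells) - dt * A
  solve(M)
}

# Propagate one species' concentration to the requested times.
lamm_solve_species <- function(s_svedberg, D, loading, omega, geometry,
                               n_cells, times, dt_max) {
  s_sec <- s_svedberg * SVEDBERG
  conc <- rep(loading, n_cells)
  out <- matrix(NA_real_, length(times), n_cells)
  if (s_sec == 0 && D <= 0) {
    for (k in seq_along(times)) out[k, ] <- conc
    return(out)
  }
  if (D <= 0) rlang::abort("diffusion coefficient must be > 0")
  t_now <- 0
  step_cache <- list()
  for (k in seq_along(times)) {
    span <- times[k] - t_now
    if (span < 0) rlang::abort("times must be non-decreasing")
    if (span > 0) {
      n_sub <- ceiling(span / dt_max)
      dt <- span / n_sub
      if (!is.finite(dt) || dt <= 0) {
        rlang::abort(sprintf("unstable step size dt = %g s", dt))
      }
      key <- sprintf("%.12g", dt)
      if (is.null(step_cache[[key]])) {
        step_cache[[key]] <- lamm_step_matrix(
          s_sec, D, omega, geometry, n_cells, dt
        )
      }
      P <- step_cache[[key]]
      for (i in seq_len(n_sub)) conc <- P %*% conc
      conc <- as.numeric(conc)
      t_now <- times[k]
    }
    out[k, ] <- conc
  }
  out
}

#' Simulate sedimentation-velocity scans (Lamm equation forward model)
#'
#' Solves the Lamm equation for each ideal, non-interacting species with a
#' conservative finite-volume discretization (Scharfetter-Gummel
#' exponential-fitted fluxes, implicit Euler stepping) on a uniform radial
#' grid in a sector-shaped cell, starting from a uniform loading
#' concentration with zero-flux walls at meniscus and bottom. Species
#' solutions superpose linearly; i.i.d. Gaussian noise is added per point.
#'
#' @param species A data frame with columns `s` (Svedberg), `loading_signal`
#'   (AU) and optionally `D` (cm^2/s). Missing `D` values are filled from
#'   `s` via [species_from_s()] using `vbar` and `frictional_ratio`.
#' @param geometry A [cell_geometry()].
#' @param rpm Rotor speed, rev/min.
#' @param buffer A [buffer_state()] (used for the s->D mapping).
#' @param times Scan times, s (non-decreasing, measured from speed
#'   attainment).
#' @param radius_grid Radii to report scans on, cm; `NULL` (default) uses
#'   the solver's cell centers, on which the sector integral is exact.
#' @param noise_sigma Gaussian noise standard deviation, AU.
#' @param seed Optional integer seed for the noise.
#' @param vbar Partial specific volume used for the s->D mapping, ml/g.
#' @param frictional_ratio f/f0 for the s->D mapping.
#' @param n_cells Number of finite-volume cells (default 400).
#' @param dt_max Maximum implicit time step, s.
#' @return An object of class `sv_scan_set`: a list with `scans` (tibble
#'   with columns `time_s`, `radius_cm`, `signal`), `geometry`, `rpm`,
#'   `times`, `radius_grid`, `noise_sigma`, `seed`, `n_cells`.
#' @export
simulate_sv <- function(species, geometry, rpm, buffer, times,
                        radius_grid = NULL, noise_sigma = 0, seed = NULL,
                        vbar = 0.73, frictional_ratio = 1.2,
                        n_cells = 400, dt_max = 20) {
  species <- tibble::as_tibble(species)
  if (nrow(species) == 0L) rlang::abort("need at least one species")
  if (any(species$s < 0)) rlang::abort("s must be >= 0")
  if (any(species$loading_signal < 0)) {
    rlang::abort("loading_signal must be >= 0")
  }
  if (rpm <= 0) rlang::abort("rpm must be > 0")
  if (any(times < 0)) rlang::abort("times must be >= 0")
  times <- sort(times)
  if (!("D" %in% names(species))) species$D <- NA_real_
  need_d <- is.na(species$D)
  if (any(need_d)) {
    pos <- need_d & species$s > 0
    if (any(pos)) {
      species$D[pos] <-
        species_from_s(species$s[pos], buffer, vbar, frictional_ratio)$diffusion
    }
    # s = 0 with unspecified D: quasi-inert tracer, tiny diffusion
    species$D[need_d & species$s == 0] <- 1e-9
  }
  if (any(species$D <= 0)) rlang::abort("D must be > 0")
  cells <- lamm_cell_centers(geometry, n_cells)
  if (is.null(radius_grid)) {
    radius_grid <- cells
    interpolate <- FALSE
  } else {
    if (any(radius_grid < geometry$meniscus - 1e-9) ||
        any(radius_grid > geometry$bottom + 1e-9)) {
      rlang::abort("radius_grid extends outside the cell geometry")
    }
    if (any(diff(radius_grid) <= 0)) {
      rlang::abort("radius_grid must be strictly increasing")
    }
    interpolate <- TRUE
  }
  omega <- omega_from_rpm(rpm)
  total <- matrix(0, length(times), length(radius_grid))
  for (i in seq_len(nrow(species))) {
    sol <- lamm_solve_species(
      species$s[i], species$D[i], species$loading_signal[i],
      omega, geometry, n_cells, times, dt_max
    )
    if (interpolate) {
      sol <- t(apply(sol, 1, function(row) {
        stats::approx(cells, row, xout = radius_grid, rule = 2)$y
      }))
    }
    total <- total + sol
  }
  noiseless <- total
  if (noise_sigma > 0) {
    add_noise <- function() {
      total + matrix(
        stats::rnorm(length(total), sd = noise_sigma),
        nrow(total), ncol(total)
      )
    }
    total <- if (is.null(seed)) add_noise() else {
      withr::with_seed(seed, add_noise())
    }
  }
  # expand_grid enumerates radius fastest within each time; t(total) matches
  scans <- tidyr::expand_grid(time_s = times, radius_cm = radius_grid)
  scans$signal <- as.vector(t(total))
  structure(
    list(
      scans = scans, geometry = geometry, rpm = rpm, times = times,
      radius_grid = radius_grid, noise_sigma = noise_sigma, seed = seed,
      n_cells = n_cells, noiseless = noiseless
    ),
    class = "sv_scan_set"
  )
}

#' Sector-integrated signal of each scan
#'
#' Computes the sector mass integral of the (noiseless, when available)
#' signal over the cell for every scan time. On the solver's native cell
#' centers the midpoint rule is the exact finite-volume mass and is used;
#' otherwise the trapezoidal rule is applied.
#'
#' @param scan_set An `sv_scan_set` from [simulate_sv()].
#' @param use_noiseless Use the stored noiseless field if present.
#' @return Tibble with columns `time_s` and `sector_mass`.
#' @export
sector_mass <- function(scan_set, use_noiseless = TRUE) {
  r <- scan_set$radius_grid
  sig <- if (use_noiseless && !is.null(scan_set$noiseless)) {
    scan_set$noiseless
  } else {
    matrix(scan_set$scans$signal, length(scan_set$times), length(r),
           byrow = TRUE)
  }
  h <- diff(r)
  uniform <- length(unique(round(h, 12))) == 1L
  mass <- apply(sig, 1, function(row) {
    if (uniform) sum(row * r) * h[1] else pracma::trapz(r, row * r)
  })
  tibble::tibble(time_s = scan_set$times, sector_mass = mass)
}
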