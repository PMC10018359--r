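test_that("a non-sedimenting, non-diffusing species stays uniform", {
  buf <- test_buffer()
  sv <- simulate_sv(
    tibble::tibble(s = 0, loading_signal = 0.8, D = 1e-12),
    cell_geometry(6.0, 7.2), 42000, buf,
    times = c(0, 2000, 8000), noise_sigma = 0, n_cells = 100
  )
  expect_lt(max(abs(sv$noiseless - 0.8)), 1e-9)
})

test_that("boundary midpoint obeys the analytic radial velocity early on", {
  buf <- test_buffer()
  sv <- simulate_sv(
    tibble::tibble(s = 3, loading_signal = 1),
    cell_geometry(6.0, 7.2), 42000, buf,
    times = c(3500, 5500), noise_sigma = 0, n_cells = 400
  )
  w <- omega_from_rpm(42000)
  for (k in 1:2) {
    prof <- sv$noiseless[k, ]
    plateau <- stats::median(
      prof[sv$radius_grid > 6.7 & sv$radius_grid < 6.95]
    )
    i <- which(diff(sign(prof - plateau / 2)) != 0)[1]
    r_mid <- stats::approx(prof[i:(i + 1)], sv$radius_grid[i:(i + 1)],
                           xout = plateau / 2)$y
    expect_equal(log(r_mid / 6.0), 3e-13 * w^2 * sv$times[k],
                 tolerance = 0.02)
  }
})

test_that("multi-species simulation is the pointwise sum of singles", {
  buf <- test_buffer()
  geom <- cell_geometry(6.0, 7.2)
  times <- c(1000, 4000)
  one <- simulate_sv(tibble::tibble(s = 2, loading_signal = 0.4),
                     geom, 42000, buf, times, noise_sigma = 0, n_cells = 150)
  two <- simulate_sv(tibble::tibble(s = 6, loading_signal = 0.6),
                     geom, 42000, buf, times, noise_sigma = 0, n_cells = 150)
  both <- simulate_sv(
    tibble::tibble(s = c(2, 6), loading_signal = c(0.4, 0.6)),
    geom, 42000, buf, times, noise_sigma = 0, n_cells = 150
  )
  expect_equal(both$noiseless, one$noiseless + two$noiseless,
               tolerance = 1e-12)
})

test_that("sector mass is conserved and solutions stay non-negative", {
  buf <- test_buffer()
  sv <- simulate_sv(
    tibble::tibble(s = c(1.5, 5), loading_signal = c(0.5, 0.5)),
    cell_geometry(6.0, 7.2), 42000, buf,
    times = seq(0, 20000, length.out = 6), noise_sigma = 0, n_cells = 300
  )
  m <- sector_mass(sv)
  expect_lt(diff(range(m$sector_mass)) / mean(m$sector_mass), 1e-3)
  expect_gte(min(sv$noiseless), 0)
})

test_that("halving grid spacing and time step barely changes the scans", {
  buf <- test_buffer()
  geom <- cell_geometry(6.0, 7.2)
  times <- c(2000, 6000)
  # compare on the analysis region: the thin back-diffusion layer at the
  # cell bottom holds a near-singular gradient that no scan analysis uses
  probe <- lamm_cell_centers_probe(geom, 200)
  probe <- probe[probe < geom$bottom - 0.05]
  base <- simulate_sv(tibble::tibble(s = 3, loading_signal = 1), geom,
                      42000, buf, times, radius_grid = probe,
                      noise_sigma = 0, n_cells = 400, dt_max = 20)
  fine <- simulate_sv(tibble::tibble(s = 3, loading_signal = 1), geom,
                      42000, buf, times, radius_grid = probe,
                      noise_sigma = 0, n_cells = 800, dt_max = 10)
  rms <- sqrt(mean((base$noiseless - fine$noiseless)^2))
  expect_lt(rms, 0.002)  # < 0.2% of the unit loading signal
})

test_that("input validation catches bad grids and geometries", {
  buf <- test_buffer()
  geom <- cell_geometry(6.0, 7.2)
  expect_error(
    simulate_sv(tibble::tibble(s = 1, loading_signal = 1), geom, 42000,
                buf, times = c(0, 100), radius_grid = c(5.0, 6.5)),
    "outside"
  )
  expect_error(cell_geometry(7.3, 6.0), "meniscus")
  expect_error(cell_geometry(5.0, 7.0), "meniscus")
  expect_error(
    simulate_sv(tibble::tibble(s = -1, loading_signal = 1), geom, 42000,
                buf, times = c(0, 100)),
    "s must be"
  )
})

test_that("seeded noise is reproducible and has the requested scale", {
  buf <- test_buffer()
  geom <- cell_geometry(6.0, 7.2)
  a <- simulate_sv(tibble::tibble(s = 2, loading_signal = 0.5), geom,
                   42000, buf, c(1000, 3000), noise_sigma = 0.005,
                   seed = 99, n_cells = 100)
  b <- simulate_sv(tibble::tibble(s = 2, loading_signal = 0.5), geom,
                   42000, buf, c(1000, 3000), noise_sigma = 0.005,
                   seed = 99, n_cells = 100)
  expect_identical(a$scans$signal, b$scans$signal)
  resid <- a$scans$signal - as.vector(t(a$noiseless))
  expect_equal(stats::sd(resid), 0.005, tolerance = 0.15)
})

test_that("the s->D mapping matches the Svedberg relation", {
  buf <- test_buffer()
  sp <- species_from_s(2.9, buf, 0.71, frictional_ratio = 1.2)
  # D = s R T / (M (1 - vbar rho)) must hold self-consistently
  d_svedberg <- 2.9e-13 * 8.31446e7 * buf$temperature /
    (sp$molar_mass * (1 - 0.71 * buf$density))
  expect_equal(sp$diffusion, d_svedberg, tolerance = 1e-10)
  expect_error(species_from_s(2.9, buf, vbar = 1.0), "non-sedimenting")
})
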