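test_that("equilibrium model limits: zero mass, reference point, slope", {
  buf <- test_buffer()
  r <- seq(6.9, 7.2, by = 0.01)
  flat <- se_model(r, tibble::tibble(molar_mass = 0, vbar = 0.7, a_r0 = 0.3),
                   23000, 7.05, buf, baseline = 0.02)
  expect_equal(flat, rep(0.32, length(r)))
  sp <- tibble::tibble(molar_mass = 33800, vbar = 0.706, a_r0 = 0.3)
  sig <- se_model(r, sp, 23000, 7.05, buf, baseline = 0.02)
  expect_equal(sig[which.min(abs(r - 7.05))], 0.32, tolerance = 1e-9)
  # strictly increasing toward the bottom for positive buoyant mass
  expect_true(all(diff(sig) > 0))
})

test_that("the exponent coefficient evaluates the buoyant-mass formula", {
  buf <- test_buffer()
  omega <- 2 * pi * 23000 / 60
  expected <- 33800 * (1 - 0.706 * buf$density) * omega^2 /
    (2 * 8.31446e7 * buf$temperature)
  expect_equal(se_sigma(33800, 0.706, buf, 23000), expected)
  expect_equal(expected, 1.0, tolerance = 0.03)  # ~1 cm^-2 at these values
})

test_that("noiseless global fit recovers the generating mass to 0.1%", {
  buf <- test_buffer()
  for (m in c(69500, 121500)) {
    ds <- gen_se_dataset(m, 0.705, buf, noise_sigma = 0, seed = 1)
    fit <- fit_one_species_global(ds, 0.705, buf)
    expect_equal(fit$molar_mass, m, tolerance = 1e-3)
  }
  # a different speed pair inside the working range
  ds2 <- gen_se_dataset(50000, 0.72, buf, speeds = c(18000, 28000),
                        noise_sigma = 0, seed = 1)
  expect_equal(fit_one_species_global(ds2, 0.72, buf)$molar_mass, 50000,
               tolerance = 1e-3)
})

test_that("noisy fits recover the mass within two standard errors", {
  buf <- test_buffer()
  ds <- gen_se_dataset(121500, 0.7092, buf, noise_sigma = 0.005, seed = 1)
  fit <- fit_one_species_global(ds, 0.7092, buf)
  expect_lt(abs(fit$molar_mass - 121500), 2 * fit$std_error)
  expect_gt(fit$std_error, 0)
  expect_false(fit$unidentifiable)
})

test_that("pure-baseline profiles are flagged unidentifiable", {
  buf <- test_buffer()
  geom <- cell_geometry(6.9, 7.2)
  r <- seq(6.9, 7.2, by = 0.003)
  data <- purrr::map_dfr(c(18000, 23000, 28000), function(rpm) {
    tibble::tibble(rpm = rpm, radius_cm = r,
                   signal = 0.05 + stats::rnorm(length(r), sd = 1e-4))
  })
  withr::with_seed(2, data$signal <- data$signal)
  profiles <- se_profile_set(data, geom)
  expect_warning(fit <- fit_one_species_global(profiles, 0.7, buf),
                 "poorly identified")
  expect_true(fit$unidentifiable)
})

test_that("mass conservation makes fitted loading speed-invariant", {
  buf <- test_buffer()
  ds <- gen_se_dataset(69500, 0.7044, buf, noise_sigma = 0.005, seed = 1)
  fit <- fit_one_species_global(ds, 0.7044, buf, mass_conservation = TRUE)
  spread <- diff(range(fit$loading[, 1])) / mean(fit$loading[, 1])
  expect_lt(spread, 1e-6)
  expect_error(
    fit_one_species_global(ds[ds$rpm == 18000, ] |>
                             se_profile_set(attr(ds, "geometry")),
                           0.7044, buf),
    ">= 2 speeds"
  )
})

test_that("fitted mass is invariant to the reference radius", {
  buf <- test_buffer()
  ds <- gen_se_dataset(69500, 0.7044, buf, noise_sigma = 0.005, seed = 1)
  f1 <- fit_one_species_global(ds, 0.7044, buf)
  ds2 <- ds
  attr(ds2, "r0") <- stats::setNames(
    rep(6.95, 3), sort(unique(ds$rpm))
  )
  f2 <- fit_one_species_global(ds2, 0.7044, buf)
  expect_equal(f1$molar_mass, f2$molar_mass, tolerance = 1e-6)
})

test_that("two-species fit on single-species data pins species 2 near zero", {
  buf <- test_buffer()
  ds <- gen_se_dataset(33800, 0.7067, buf, noise_sigma = 0.005, seed = 1)
  fit <- fit_two_species_global(ds, 0.7067, 0.56, buf, fix_m2 = 5008)
  expect_lt(fit$fractions[2], 0.01)
  expect_equal(fit$molar_mass, 33800, tolerance = 0.02)
})

test_that("a genuine 50:50 mixture is recovered with correct fractions", {
  buf <- test_buffer()
  dA <- gen_se_dataset(30000, 0.73, buf, noise_sigma = 0,
                       mean_signal = 0.15, seed = 1)
  dB <- gen_se_dataset(120000, 0.73, buf, noise_sigma = 0,
                       mean_signal = 0.15, seed = 2)
  mix <- dA
  mix$signal <- dA$signal + dB$signal
  fit <- fit_two_species_global(mix, 0.73, 0.73, buf, fix_m2 = 120000)
  expect_equal(fit$fractions[1], 0.5, tolerance = 0.05)
  expect_equal(fit$fractions[2], 0.5, tolerance = 0.05)
  expect_equal(fit$molar_mass, 30000, tolerance = 0.02)
})

test_that("identical species masses trigger a degeneracy warning", {
  buf <- test_buffer()
  ds <- gen_se_dataset(69500, 0.71, buf, noise_sigma = 0.002, seed = 1)
  expect_warning(
    expect_warning(
      fit_two_species_global(ds, 0.71, 0.71, buf, fix_m2 = 69500),
      "correlated"
    )
  )
})

test_that("tidy and glance summarize equilibrium fits", {
  buf <- test_buffer()
  ds <- gen_se_dataset(33800, 0.7067, buf, noise_sigma = 0.005, seed = 1)
  fit <- fit_one_species_global(ds, 0.7067, buf)
  td <- tidy(fit)
  expect_equal(nrow(td), 1L)
  expect_equal(td$estimate, fit$molar_mass)
  gl <- glance(fit)
  expect_equal(gl$n_speeds, 3L)
  expect_true(gl$mass_conservation)
})
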