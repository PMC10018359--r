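test_that("composite vbar is the mass-weighted mean of component vbars", {
  reg <- toy_registry()
  # single component: identity for any copy number
  for (n in c(1, 3)) {
    expect_equal(composite_vbar(composition(reg, c(A = n))), 0.734)
  }
  # equal masses: plain mean
  expect_equal(
    composite_vbar(composition(reg, c(A = 1, B = 1))),
    (0.734 + 0.56) / 2
  )
  # hand-summed three-component complex (protein + peptide + labelled DNA)
  reg2 <- component_registry(
    list(name = "prot", molar_mass = 27000, vbar = 0.734, kind = "protein"),
    list(name = "pep", molar_mass = 1740, vbar = 0.704, kind = "peptide"),
    list(name = "dna", molar_mass = 5100, vbar = 0.56, kind = "ssDNA")
  )
  hand <- (27000 * 0.734 + 1740 * 0.704 + 5100 * 0.56) /
    (27000 + 1740 + 5100)
  expect_equal(
    composite_vbar(composition(reg2, c(prot = 1, pep = 1, dna = 1))),
    hand
  )
  expect_equal(round(hand, 3), 0.706)
})

test_that("composite vbar is bounded by components and permutation invariant", {
  reg <- toy_registry()
  counts <- c(A = 2, B = 1, C = 3)
  v <- composite_vbar(composition(reg, counts))
  expect_gte(v, min(reg$vbar))
  expect_lte(v, max(reg$vbar))
  v_perm <- composite_vbar(composition(reg, counts[c(3, 1, 2)]))
  expect_equal(v, v_perm)
  expect_error(composition(reg, c(A = 0)), "at least one")
})

test_that("buoyant factor follows M(1 - vbar rho)", {
  expect_equal(buoyant_factor(1000, 0.5, 2.0), 0)  # neutral buoyancy
  expect_equal(buoyant_factor(1000, 0.5, 1.0), 500)
  expect_equal(buoyant_factor(33800, 0.706, 1.05),
               33800 * (1 - 0.706 * 1.05))
  # linear in M, strictly decreasing in vbar
  expect_equal(buoyant_factor(2000, 0.7, 1.0),
               2 * buoyant_factor(1000, 0.7, 1.0))
  vb <- seq(0.5, 0.9, by = 0.1)
  expect_true(all(diff(buoyant_factor(1e4, vb, 1.05)) < 0))
  expect_error(buoyant_factor(-1, 0.7, 1), "must all be")
})

test_that("vbar percent difference reproduces the reporting convention", {
  expect_equal(vbar_percent_difference(0.734, 0.743), 1.2)
  expect_equal(vbar_percent_difference(0.711, 0.731), 2.7)
  expect_equal(vbar_percent_difference(0.7, 0.7), 0)
  expect_error(vbar_percent_difference(0.7, 0), "non-zero")
})

test_that("sequence masses sum residue tables with terminal corrections", {
  # 15-residue acidic-tip peptide, free termini (+H2O)
  expect_equal(
    molar_mass_from_sequence("PSNEPPMDFDDDIPF", kind = "peptide"),
    1735.9, tolerance = 1e-4
  )
  # Cy3-labelled (dT)15: nucleosides + 14 linkages + dye adduct
  m15 <- molar_mass_from_sequence(strrep("T", 15), kind = "ssDNA",
                                  adducts = "cy3")
  expect_equal(m15, 5100, tolerance = 0.02)
  expect_error(molar_mass_from_sequence("", kind = "peptide"), "non-empty")
  expect_error(molar_mass_from_sequence("PSX", kind = "peptide"), "X")
  expect_error(molar_mass_from_sequence("ACGU", kind = "ssDNA"), "U")
})

test_that("sequence mass is additive under concatenation", {
  a <- "PSNEP"
  b <- "MDFDD"
  expect_equal(
    molar_mass_from_sequence(paste0(a, b), kind = "peptide"),
    molar_mass_from_sequence(a, kind = "peptide") +
      molar_mass_from_sequence(b, kind = "peptide") - 18.02
  )
  d1 <- strrep("T", 6)
  d2 <- "ACGT"
  expect_equal(
    molar_mass_from_sequence(paste0(d1, d2), kind = "ssDNA"),
    molar_mass_from_sequence(d1, kind = "ssDNA") +
      molar_mass_from_sequence(d2, kind = "ssDNA") + 61.96
  )
})

test_that("Beer-Lambert concentration conversion", {
  expect_equal(concentration_from_absorbance(0.39, 390, 1.0), 1e-3)
  expect_equal(concentration_from_absorbance(0, 390, 1.0), 0)
  expect_equal(concentration_from_absorbance(0.244, 2.44e4, 1.2),
               0.244 / (2.44e4 * 1.2))
  expect_error(concentration_from_absorbance(-0.1, 390, 1), ">= 0")
})

test_that("component and buffer validation enforce physical invariants", {
  expect_error(
    component_registry(list(name = "x", molar_mass = -5, vbar = 0.7,
                            kind = "protein")),
    "molar_mass"
  )
  expect_error(
    component_registry(list(name = "x", molar_mass = 100, vbar = 1.2,
                            kind = "protein")),
    "vbar"
  )
  expect_error(
    component_registry(list(name = "x", molar_mass = 100, vbar = 0.7,
                            kind = "protein", extinction = c("280" = -1))),
    "extinction"
  )
  expect_error(buffer_state(density = 2), "density")
  expect_error(buffer_state(viscosity = -1), "viscosity")
})

test_that("registry YAML loader derives masses from sequences", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "components:",
    "  - name: pep",
    "    kind: peptide",
    "    vbar: 0.704",
    "    sequence: PSNEPPMDFDDDIPF",
    "    extinction: {258: 390}",
    "  - name: prot",
    "    kind: protein",
    "    vbar: 0.734",
    "    molar_mass: 27000"
  ), path)
  reg <- read_component_registry(path)
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$molar_mass[reg$name == "pep"], 1735.9, tolerance = 1e-4)
  expect_error(read_component_registry("no/such/file.yaml"), "not found")
})
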