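test_that("a fitted mass with 2-SE window selects the unique composition", {
  reg <- example_registry()
  matches <- enumerate_matches(
    131100, 9200, reg,
    bounds = list(RecO = c(1, 2), RecR = c(4, 4), SSB_Ct = c(1, 2),
                  Cy3_dT15 = c(1, 2)),
    constraints = list("SSB_Ct == RecO", "Cy3_dT15 == RecO"),
    window_k = 2
  )
  expect_equal(nrow(matches), 2L)
  expect_equal(sum(matches$within_window), 1L)
  winner <- matches[matches$within_window, ]
  expect_equal(winner$counts[[1]][["RecR"]], 4L)
  expect_equal(winner$counts[[1]][["RecO"]], 1L)
  expect_equal(winner$predicted_mass, 121500, tolerance = 0.005)
  # the double complex (~155 kDa) is excluded
  loser <- matches[!matches$within_window, ]
  expect_equal(loser$predicted_mass, 155600, tolerance = 0.005)
})

test_that("exact matches rank first with zero deviation", {
  reg <- toy_registry()
  m <- enumerate_matches(27000 + 1740, 500, reg,
                         bounds = list(A = 2, C = 2), window_k = 2)
  expect_equal(m$deviation[1], 0)
  expect_equal(m$composition[1], "A:1 C:1")
  expect_true(m$within_window[1])
})

test_that("window semantics: filter never truncates the ranking", {
  reg <- toy_registry()
  m <- enumerate_matches(1e6, 100, reg, bounds = list(A = 2, B = 2),
                         window_k = 2)
  expect_gt(nrow(m), 0)
  expect_false(any(m$within_window))
  # window_k -> large: everything within; small: only exact matches
  m_all <- enumerate_matches(27000, 100, reg, bounds = list(A = 2, B = 1),
                             window_k = 1e9)
  expect_true(all(m_all$within_window))
  m_tight <- enumerate_matches(27000, 100, reg, bounds = list(A = 2, B = 1),
                               window_k = 1e-9)
  expect_equal(sum(m_tight$within_window), sum(m_tight$deviation == 0))
})

test_that("predicted masses are additive and the order deterministic", {
  regA <- component_registry(
    list(name = "X", molar_mass = 10000, vbar = 0.7, kind = "protein")
  )
  regB <- component_registry(
    list(name = "X", molar_mass = 20000, vbar = 0.7, kind = "protein")
  )
  mA <- enumerate_matches(40000, 1000, regA, bounds = list(X = c(2, 4)))
  mB <- enumerate_matches(40000, 1000, regB, bounds = list(X = c(1, 2)))
  expect_equal(sort(mA$predicted_mass), sort(mB$predicted_mass))
  # equal-deviation candidates tie-break lexicographically
  reg2 <- component_registry(
    list(name = "P", molar_mass = 1000, vbar = 0.7, kind = "protein"),
    list(name = "Q", molar_mass = 1000, vbar = 0.7, kind = "protein")
  )
  m2 <- enumerate_matches(1000, 10, reg2, bounds = list(P = 1, Q = 1),
                          constraints = list("P + Q == 1"))
  expect_equal(m2$composition, c("P:1", "Q:1"))
})

test_that("constraint rules and error cases behave as documented", {
  reg <- toy_registry()
  m <- enumerate_matches(
    30000, 1000, reg, bounds = list(A = 2, C = 2),
    constraints = list(function(n) n[["C"]] <= n[["A"]])
  )
  bad <- purrr::map_lgl(m$counts, ~ .x[["C"]] > .x[["A"]])
  expect_false(any(bad))
  expect_error(enumerate_matches(1e5, 100, reg[0, ], list(A = 1)), "empty")
  expect_error(enumerate_matches(1e5, 100, reg, list()), "bounds")
  expect_error(enumerate_matches(1e5, 100, reg, list(Z = 1)), "unknown")
  expect_error(enumerate_matches(1e5, 100, reg, list(A = 1), window_k = 0),
               "window_k")
})

test_that("complex-mass equations solve for component group masses", {
  # X = 33.8k and X + 4R = 121.5k  =>  4R = 87.7k
  sol <- derive_component_masses_from_complexes(list(
    list(counts = c(X = 1), mass = 33800),
    list(counts = c(X = 1, R4 = 1), mass = 121500)
  ))
  expect_equal(sol$molar_mass[sol$component == "R4"], 87700)
  expect_equal(attr(sol, "residual"), 0, tolerance = 1e-9)
  # single equation, single unknown: exact
  s1 <- derive_component_masses_from_complexes(list(
    list(counts = c(Y = 2), mass = 50000)
  ))
  expect_equal(s1$molar_mass, 25000)
  # inconsistent duplicates: least-squares average with residual
  s2 <- derive_component_masses_from_complexes(list(
    list(counts = c(X = 1), mass = 33800),
    list(counts = c(X = 1), mass = 34100)
  ))
  expect_equal(s2$molar_mass, 33950)
  expect_equal(attr(s2, "residual"), 150)
  # rank deficiency names the entangled components
  expect_error(
    derive_component_masses_from_complexes(list(
      list(counts = c(X = 1, Y = 1), mass = 50000)
    )),
    "rank deficient"
  )
})
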