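# Shared fixtures. Sedimentation problems are scaled down from the
# package defaults (fewer cells, coarser time steps, smaller s grids)
# where the property under test is insensitive to resolution.

test_buffer <- function() buffer_state()

# small component registry with round numbers for arithmetic tests
toy_registry <- function() {
  component_registry(
    list(name = "A", molar_mass = 27000, vbar = 0.734, kind = "protein",
         extinction = c("280" = 2.44e4)),
    list(name = "B", molar_mass = 27000, vbar = 0.56, kind = "ssDNA",
         extinction = c("260" = 1e5)),
    list(name = "C", molar_mass = 1740, vbar = 0.704, kind = "peptide",
         extinction = c("258" = 390))
  )
}

small_sv <- function(s, loading, seed = NULL, noise = 0, n_scans = 6,
                     vbar = 0.71, n_cells = 200, dt_max = 50) {
  gen_sv_dataset(
    tibble::tibble(s = s, loading_signal = loading),
    vbar = vbar, buffer = test_buffer(), n_scans = n_scans,
    noise_sigma = noise, seed = seed, n_cells = n_cells, dt_max = dt_max
  )
}

small_s_grid <- function(n = 40, lo = 0.5, hi = 10) {
  exp(seq(log(lo), log(hi), length.out = n))
}

lamm_cell_centers_probe <- function(geom, n) {
  sedstoich:::lamm_cell_centers(geom, n)
}

# direct construction of a c(s) object from a known density, for testing
# the distribution summaries independently of the fitter
manual_cs <- function(s_grid, density) {
  w <- sedstoich:::trapezoid_weights(s_grid)
  sedstoich:::new_cs_distribution(
    s_grid, density * w, 1.2, 0, 0, numeric(0), numeric(0)
  )
}
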