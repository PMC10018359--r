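#' Fit a c(s) sedimentation-coefficient distribution
#'
#' Inverts a sedimentation-velocity scan set into a regularized,
#' non-negative distribution of sedimentation coefficients. The data are
#' modelled as a superposition of noiseless single-species Lamm solutions
#' on a fixed s grid (each sharing one frictional ratio for the s->D
#' mapping), plus systematic baselines: a time-invariant radial baseline
#' and a per-scan (radially invariant) offset. The baseline subspace is
#' projected out analytically (double centering over the balanced
#' time x radius grid); the remaining amplitudes solve a non-negative
#' least-squares problem with a second-difference smoothness penalty.
#' The regularization strength is the largest alpha whose chi-square does
#' not exceed the unregularized chi-square by more than an F-ratio at the
#' requested confidence level.
#'
#' @param scan_set An `sv_scan_set` (from [simulate_sv()] or read from
#'   disk) with at least 5 scans.
#' @param buffer A [buffer_state()].
#' @param vbar Partial specific volume assumed for all species, ml/g.
#' @param s_grid Sedimentation-coefficient grid, Svedberg (default 100
#'   log-spaced points on 0.2-12 S). Must have at least 20 points.
#' @param frictional_ratio Shared f/f0 for the s->D mapping.
#' @param confidence Confidence level of the F-ratio criterion (0.68).
#' @param alpha Optional fixed regularization strength; skips the policy.
#' @param n_alpha Number of trial alphas for the policy search.
#' @param n_cells Finite-volume cells used for the kernel simulations.
#' @param dt_max Maximum implicit time step for kernel simulations, s.
#' @return An object of class `cs_distribution`: a list with
#'   `distribution` (tibble `s`, `c` in AU per Svedberg), `s_grid`,
#'   `amplitudes` (discrete AU per grid point), `frictional_ratio`,
#'   `regularization_alpha`, `fit_rmsd`, `baseline_radial`,
#'   `baseline_scan`.
#' @export
fit_cs <- function(scan_set, buffer, vbar,
                   s_grid = exp(seq(log(0.2), log(12), length.out = 100)),
                   frictional_ratio = 1.2, confidence = 0.68,
                   alpha = NULL, n_alpha = 12,
                   n_cells = scan_set$n_cells %||% 400, dt_max = 20) {
  if (length(scan_set$times) < 5L) {
    rlang::abort("need at least 5 scans spanning boundary movement")
  }
  if (length(s_grid) < 20L) {
    rlang::abort("s_grid too coarse: need at least 20 points")
  }
  if (any(diff(s_grid) <= 0)) rlang::abort("s_grid must be strictly increasing")
  r <- scan_set$radius_grid
  times <- scan_set$times
  n_t <- length(times)
  n_r <- length(r)
  y <- matrix(scan_set$scans$signal, n_t, n_r, byrow = TRUE)

  if (all(abs(y) < 1e-12)) {
    rlang::warn("all-zero signal: returning all-zero distribution")
    return(new_cs_distribution(
      s_grid, rep(0, length(s_grid)), frictional_ratio, 0, 0,
      rep(0, n_r), rep(0, n_t)
    ))
  }

  # kernel: noiseless unit-loading Lamm solution for every grid s
  kernel <- matrix(0, n_t * n_r, length(s_grid))
  for (j in seq_along(s_grid)) {
    sim <- simulate_sv(
      tibble::tibble(s = s_grid[j], loading_signal = 1),
      scan_set$geometry, scan_set$rpm, buffer, times,
      radius_grid = r, noise_sigma = 0, vbar = vbar,
      frictional_ratio = frictional_ratio, n_cells = n_cells,
      dt_max = dt_max
    )
    kernel[, j] <- as.vector(t(sim$noiseless))
  }

  # project out TI (per-radius) + RI (per-scan) baselines: double centering
  center2 <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    sweep(m, 1, rowMeans(m))
  }
  yc <- as.vector(t(center2(y)))
  kc <- apply(kernel, 2, function(col) {
    as.vector(t(center2(matrix(col, n_t, n_r, byrow = TRUE))))
  })

  # second-difference penalty operator
  p <- length(s_grid)
  L <- matrix(0, p - 2, p)
  for (i in seq_len(p - 2)) L[i, i:(i + 2)] <- c(1, -2, 1)

  solve_alpha <- function(a) {
    aug <- if (a > 0) rbind(kc, a * L) else kc
    rhs <- if (a > 0) c(yc, rep(0, p - 2)) else yc
    fit <- pracma::lsqnonneg(aug, rhs)
    x <- fit$x
    list(x = x, chisq = sum((kc %*% x - yc)^2))
  }

  if (is.null(alpha)) {
    base_fit <- solve_alpha(0)
    n_obs <- length(yc)
    dof <- max(n_obs - p, 1)
    # largest alpha whose chi-square stays under the F-ratio envelope
    ratio_max <- 1 + p / dof * stats::qf(confidence, p, dof)
    limit <- max(base_fit$chisq, 1e-300) * ratio_max
    col_scale <- sqrt(mean(colSums(kc^2)))
    alphas <- col_scale * 10^seq(-4, 2, length.out = n_alpha)
    best <- list(alpha = 0, fit = base_fit)
    for (a in alphas) {
      f <- solve_alpha(a)
      if (f$chisq <= limit) best <- list(alpha = a, fit = f)
    }
    alpha_used <- best$alpha
    fit <- best$fit
  } else {
    alpha_used <- alpha
    fit <- solve_alpha(alpha)
  }

  # recover baselines from the residual of the uncentered problem
  resid <- matrix(as.vector(t(y)) - kernel %*% fit$x, n_t, n_r, byrow = TRUE)
  b_scan <- rowMeans(resid) - mean(resid)
  b_radial <- colMeans(resid)
  full_resid <- sweep(sweep(resid, 2, b_radial), 1, b_scan)
  rmsd <- sqrt(mean(full_resid^2))

  new_cs_distribution(
    s_grid, fit$x, frictional_ratio, alpha_used, rmsd, b_radial, b_scan
  )
}

new_cs_distribution <- function(s_grid, amplitudes, frictional_ratio,
                                alpha, rmsd, b_radial, b_scan) {
  w <- trapezoid_weights(s_grid)
  distribution <- tibble::tibble(s = s_grid, c = amplitudes / w)
  structure(
    list(
      distribution = distribution, s_grid = s_grid, amplitudes = amplitudes,
      frictional_ratio = frictional_ratio, regularization_alpha = alpha,
      fit_rmsd = rmsd, baseline_radial = b_radial, baseline_scan = b_scan
    ),
    class = "cs_distribution"
  )
}

trapezoid_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  w[1] <- (x[2] - x[1]) / 2
  w[n] <- (x[n] - x[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  w
}

#' Weight-average sedimentation coefficient of a c(s) distribution
#'
#' Trapezoidal signal-weighted mean of s over the distribution (or a
#' sub-range).
#'
#' @param dist A `cs_distribution`.
#' @param s_range Optional `c(min, max)` range in Svedberg; default full
#'   grid.
#' @return Weight-average s, Svedberg.
#' @export
weight_average_s <- function(dist, s_range = NULL) {
  s <- dist$s_grid
  c_dens <- dist$distribution$c
  if (!is.null(s_range)) {
    keep <- s >= s_range[1] & s <= s_range[2]
    s <- s[keep]
    c_dens <- c_dens[keep]
  }
  if (length(s) < 2L) rlang::abort("s_range leaves fewer than 2 grid points")
  total <- pracma::trapz(s, c_dens)
  if (total <= 0) rlang::abort("zero integrated signal in range")
  pracma::trapz(s, s * c_dens) / total
}

#' Signal fractions below and above a sedimentation-coefficient boundary
#'
#' Splits the integrated c(s) area at `boundary_s` (with linear
#' interpolation inside the straddling interval) and returns the fraction
#' pair, which sums to 1 exactly.
#'
#' @param dist A `cs_distribution`.
#' @param boundary_s Boundary, Svedberg; must lie inside the s grid.
#' @return Named numeric `c(below = ..., above = ...)`.
#' @export
peak_fraction <- function(dist, boundary_s) {
  s <- dist$s_grid
  c_dens <- dist$distribution$c
  if (boundary_s < s[1] || boundary_s > s[length(s)]) {
    rlang::abort("boundary_s must lie inside the s grid")
  }
  total <- pracma::trapz(s, c_dens)
  if (total <= 0) rlang::abort("zero total area in distribution")
  c_b <- stats::approx(s, c_dens, xout = boundary_s)$y
  keep <- s < boundary_s
  s_lo <- c(s[keep], boundary_s)
  c_lo <- c(c_dens[keep], c_b)
  below <- if (length(s_lo) > 1L) pracma::trapz(s_lo, c_lo) / total else 0
  c(below = below, above = 1 - below)
}
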