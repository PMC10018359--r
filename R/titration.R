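#' Construct a light-scattering titration series
#'
#' @param molar_ratio Titrant:titrand molar ratio after each injection
#'   (molecule units; non-decreasing).
#' @param intensity Raw scattering intensity after each injection, counts.
#' @param i0 Initial intensity before any injection, counts (> 0).
#'   Defaults to the first intensity value.
#' @param volume Optional cumulative sample volume after each injection
#'   (same units throughout); enables dilution correction.
#' @return A tibble of class `titration_series` with attribute `i0`.
#' @export
titration_series <- function(molar_ratio, intensity, i0 = intensity[1],
                             volume = NULL) {
  if (any(diff(molar_ratio) < 0)) {
    rlang::abort("molar_ratio must be non-decreasing")
  }
  if (is.null(i0) || !is.finite(i0) || i0 <= 0) {
    rlang::abort("initial intensity i0 must be > 0")
  }
  out <- tibble::tibble(molar_ratio = molar_ratio, intensity = intensity)
  if (!is.null(volume)) out$volume <- volume
  attr(out, "i0") <- i0
  class(out) <- c("titration_series", class(out))
  out
}

#' Normalize a titration series
#'
#' Normalized scattering intensity after injection i is
#' \eqn{I_{i,norm} = (I_i - I_0) / I_0}. Optionally a buffer-only
#' reference titration (its intensity increments, interpolated onto the
#' sample molar-ratio grid) is subtracted from the raw intensities first,
#' and/or intensities are multiplied by `V_i / V_0` to correct for
#' titrant dilution.
#'
#' @param series A [titration_series()].
#' @param reference Optional reference `titration_series` (buffer only).
#' @param dilution_correct Apply `V_i / V_0` correction (requires a
#'   `volume` column).
#' @return The series tibble with an added `norm_intensity` column.
#' @export
normalize_series <- function(series, reference = NULL,
                             dilution_correct = FALSE) {
  i0 <- attr(series, "i0")
  if (is.null(i0) || i0 <= 0) rlang::abort("series i0 must be > 0")
  intensity <- series$intensity
  if (dilution_correct) {
    if (!("volume" %in% names(series))) {
      rlang::abort("dilution correction requires a volume column")
    }
    intensity <- intensity * series$volume / series$volume[1]
  }
  if (!is.null(reference)) {
    ref0 <- attr(reference, "i0")
    ref_inc <- stats::approx(
      reference$molar_ratio, reference$intensity - ref0,
      xout = series$molar_ratio, rule = 2
    )$y
    intensity <- intensity - ref_inc
  }
  series$norm_intensity <- (intensity - i0) / i0
  series
}

#' Detect the aggregation-onset molar ratio in a titration
#'
#' Fits a continuous two-segment (hinge) model to the normalized
#' intensity by exhaustive search of the breakpoint over the observed
#' molar-ratio grid, minimizing the residual sum of squares, with
#' parabolic refinement of the breakpoint between the best three grid
#' values. The onset is called detected when the hinge improves on a
#' single straight line by more than an F-ratio threshold and the
#' post-onset slope exceeds the pre-onset slope.
#'
#' @param series A normalized [titration_series()] (a `norm_intensity`
#'   column; [normalize_series()] is applied with defaults if missing).
#' @param min_points_per_segment Minimum points on each side (default 4).
#' @param f_threshold F-ratio for detection (default 4.0).
#' @return A list of class `onset_result`: `onset_ratio`, `pre_slope`,
#'   `post_slope`, `detected`, `fit_sse`, `f_stat`.
#' @export
detect_onset <- function(series, min_points_per_segment = 4,
                         f_threshold = 4.0) {
  if (!("norm_intensity" %in% names(series))) {
    series <- normalize_series(series)
  }
  x <- series$molar_ratio
  y <- series$norm_intensity
  n <- length(x)
  m <- min_points_per_segment
  if (n < 2 * m) {
    rlang::abort(sprintf(
      "need at least %d points for %d per segment", 2 * m, m
    ))
  }
  hinge_sse <- function(tau) {
    X <- cbind(1, pmin(x - tau, 0), pmax(x - tau, 0))
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }
  cand_idx <- m:(n - m)
  taus <- x[cand_idx]
  taus <- unique(taus)
  sses <- vapply(taus, hinge_sse, numeric(1))
  i_best <- which.min(sses)
  tau_best <- taus[i_best]
  # parabolic refinement through the best grid point and its neighbours
  if (i_best > 1 && i_best < length(taus)) {
    t3 <- taus[(i_best - 1):(i_best + 1)]
    s3 <- sses[(i_best - 1):(i_best + 1)]
    denom <- (t3[1] - t3[2]) * (t3[1] - t3[3]) * (t3[2] - t3[3])
    if (abs(denom) > 0) {
      a <- (t3[3] * (s3[2] - s3[1]) + t3[2] * (s3[1] - s3[3]) +
              t3[1] * (s3[3] - s3[2])) / denom
      bq <- (t3[3]^2 * (s3[1] - s3[2]) + t3[2]^2 * (s3[3] - s3[1]) +
               t3[1]^2 * (s3[2] - s3[3])) / denom
      if (a > 0) {
        vertex <- -bq / (2 * a)
        if (vertex > t3[1] && vertex < t3[3] &&
            hinge_sse(vertex) <= sses[i_best]) {
          tau_best <- vertex
        }
      }
    }
  }
  X <- cbind(1, pmin(x - tau_best, 0), pmax(x - tau_best, 0))
  fit <- stats::lm.fit(X, y)
  sse1 <- sum(fit$residuals^2)
  line <- stats::lm.fit(cbind(1, x), y)
  sse0 <- sum(line$residuals^2)
  dof <- max(n - 4, 1)
  f_stat <- ((sse0 - sse1) / 2) / max(sse1 / dof, .Machine$double.eps)
  pre <- unname(fit$coefficients[2])
  post <- unname(fit$coefficients[3])
  detected <- is.finite(f_stat) && f_stat > f_threshold && post > pre
  structure(
    list(
      onset_ratio = if (detected) tau_best else NA_real_,
      candidate_ratio = tau_best,
      pre_slope = pre, post_slope = post,
      detected = detected, fit_sse = sse1, f_stat = f_stat
    ),
    class = "onset_result"
  )
}

#' @export
print.onset_result <- function(x, ...) {
  if (x$detected) {
    cat(sprintf(
      "Aggregation onset at molar ratio %.2f (slopes %.3g -> %.3g, F = %.1f)\n",
      x$onset_ratio, x$pre_slope, x$post_slope, x$f_stat
    ))
  } else {
    cat(sprintf("No onset detected (F = %.2f)\n", x$f_stat))
  }
  invisible(x)
}

#' Equilibrium saturation of a 1:1 binding interaction
#'
#' Exact closed form for the fraction of receptor bound at equilibrium:
#' the complex concentration is the smaller root of
#' \eqn{C^2 - (R_t + L_t + 1/K) C + R_t L_t = 0},
#' evaluated in the numerically stable form
#' \eqn{C = 2 R_t L_t / (b + \sqrt{b^2 - 4 R_t L_t})} with
#' \eqn{b = R_t + L_t + 1/K}.
#'
#' @param K Association equilibrium constant, M^-1.
#' @param total_receptor Total receptor concentration R_t, M.
#' @param total_ligand Total ligand concentration L_t, M.
#' @return Fraction of receptor bound, in (0, 1).
#' @export
saturation_fraction <- function(K, total_receptor, total_ligand) {
  if (any(K <= 0) || any(total_receptor <= 0) || any(total_ligand <= 0)) {
    rlang::abort("K and total concentrations must all be > 0")
  }
  b <- total_receptor + total_ligand + 1 / K
  disc <- b^2 - 4 * total_receptor * total_ligand
  complex <- 2 * total_receptor * total_ligand / (b + sqrt(disc))
  complex / total_receptor
}
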