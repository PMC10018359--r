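#' Enumerate candidate complex compositions against a fitted molar mass
#'
#' Exhaustively enumerates copy-number combinations over a bounded integer
#' lattice, filters them by declarative constraints, and ranks them by the
#' absolute deviation of the predicted mass (sum of copy-weighted
#' component masses) from the fitted mass. A candidate is "within window"
#' when its deviation is at most `window_k` fitted standard errors.
#'
#' @param fitted_mass Fitted molar mass, g/mol.
#' @param std_error Standard error of the fitted mass, g/mol.
#' @param registry A `component_registry` tibble.
#' @param bounds Named list, one entry per enumerable component: either a
#'   single maximum copy number (copies 0..max) or a vector of allowed
#'   copy numbers (e.g. `RecR = c(0, 2, 4)`). Components absent from
#'   `bounds` are held at 0 copies.
#' @param constraints List of copy-number rules, each either a function
#'   taking the named copy vector and returning `TRUE`/`FALSE`, or a
#'   string expression over component names (e.g. `"SSB_Ct <= RecO"`;
#'   non-syntactic names must be backtick-quoted).
#' @param window_k Window half-width in standard errors (default 2).
#' @return A tibble of class `stoich_matches`, ranked by deviation, with
#'   columns `composition` (label), `counts` (list of named copy
#'   vectors), `predicted_mass`, `deviation` and `within_window`.
#' @export
enumerate_matches <- function(fitted_mass, std_error, registry, bounds,
                              constraints = list(), window_k = 2) {
  if (nrow(registry) == 0L) rlang::abort("empty registry")
  if (window_k <= 0) rlang::abort("window_k must be > 0")
  if (length(bounds) == 0L) rlang::abort("bounds must name >= 1 component")
  missing <- setdiff(names(bounds), registry$name)
  if (length(missing) > 0L) {
    rlang::abort(sprintf(
      "bounds name unknown components: %s", paste(missing, collapse = ", ")
    ))
  }
  sets <- purrr::map(bounds, function(b) {
    b <- as.integer(b)
    if (length(b) == 1L) 0:b else sort(unique(b))
  })
  lattice <- do.call(expand.grid, c(sets, KEEP.OUT.ATTRS = FALSE))
  lattice <- lattice[rowSums(lattice) > 0, , drop = FALSE]

  keep <- rep(TRUE, nrow(lattice))
  for (rule in constraints) {
    ok <- if (is.function(rule)) {
      apply(lattice, 1, function(row) isTRUE(rule(row)))
    } else {
      expr <- rlang::parse_expr(rule)
      apply(lattice, 1, function(row) {
        isTRUE(rlang::eval_tidy(expr, data = as.list(row)))
      })
    }
    keep <- keep & ok
  }
  lattice <- lattice[keep, , drop = FALSE]
  if (nrow(lattice) == 0L) {
    rlang::abort("no candidate compositions satisfy the constraints")
  }

  comp_mass <- stats::setNames(registry$molar_mass, registry$name)
  predicted <- as.numeric(
    as.matrix(lattice) %*% comp_mass[names(sets)]
  )
  deviation <- abs(predicted - fitted_mass)
  label <- unname(apply(lattice, 1, function(row) {
    nz <- row[row > 0]
    paste(sprintf("%s:%d", names(nz), nz), collapse = " ")
  }))
  # deterministic total order: deviation, then lexicographic composition
  ord <- order(deviation, label)
  dev_ord <- deviation[ord]
  out <- tibble::tibble(
    composition = label[ord],
    counts = purrr::map(ord, function(i) {
      stats::setNames(as.integer(lattice[i, ]), names(sets))
    }),
    predicted_mass = predicted[ord],
    deviation = dev_ord,
    within_window = dev_ord <= window_k * std_error
  )
  attr(out, "fitted_mass") <- fitted_mass
  attr(out, "std_error") <- std_error
  attr(out, "window_k") <- window_k
  class(out) <- c("stoich_matches", class(out))
  out
}

#' Derive component (group) masses from printed complex masses
#'
#' Solves the linear system formed by complex composition patterns and
#' their known total masses for the unknown component masses, in the
#' least-squares sense when over-determined. Used to back out masses that
#' are only reported as complex totals (e.g. 4x RecR from the difference
#' of two complexes).
#'
#' @param equations List of equations, each a list with `counts` (named
#'   numeric vector of copy numbers, group coefficients allowed) and
#'   `mass` (total molar mass, g/mol).
#' @return A tibble with columns `component` and `molar_mass`, with
#'   attribute `residual` (root-mean-square misfit of the equations).
#'   Errors with the unresolvable component names if the system is rank
#'   deficient for any requested unknown.
#' @export
derive_component_masses_from_complexes <- function(equations) {
  if (length(equations) == 0L) rlang::abort("no equations given")
  all_names <- sort(unique(unlist(purrr::map(equations, ~ names(.x$counts)))))
  A <- matrix(0, length(equations), length(all_names),
              dimnames = list(NULL, all_names))
  b <- numeric(length(equations))
  for (i in seq_along(equations)) {
    eq <- equations[[i]]
    A[i, names(eq$counts)] <- eq$counts
    b[i] <- eq$mass
  }
  eig <- eigen(crossprod(A), symmetric = TRUE)
  tol <- max(dim(A)) * max(eig$values, 0) * .Machine$double.eps
  rank <- sum(eig$values > tol)
  if (rank < ncol(A)) {
    null_idx <- seq(rank + 1, ncol(A))
    involved <- unique(unlist(purrr::map(null_idx, function(j) {
      all_names[abs(eig$vectors[, j]) > 1e-8]
    })))
    solvable <- setdiff(all_names, involved)
    rlang::abort(sprintf(
      "system is rank deficient: cannot separate {%s}; solvable: {%s}",
      paste(involved, collapse = ", "),
      paste(if (length(solvable)) solvable else "none", collapse = ", ")
    ))
  }
  x <- unname(qr.solve(A, b))
  resid <- sqrt(mean((A %*% x - b)^2))
  out <- tibble::tibble(component = all_names, molar_mass = x)
  attr(out, "residual") <- resid
  out
}
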