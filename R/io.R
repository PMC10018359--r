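MANIFEST_SCHEMA_VERSION <- 1L

#' Read a radial absorbance scan from CSV
#'
#' Expects a header and two numeric columns (radius in cm, absorbance in
#' AU). Duplicate radii are collapsed by averaging with a warning; radii
#' that remain non-monotonic after de-duplication are an error.
#'
#' @param path CSV file path.
#' @return A tibble of class `radial_scan` with columns `radius_cm`,
#'   `absorbance`.
#' @export
read_scan_csv <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    rlang::abort(sprintf("%s: empty or header-only scan file", path))
  }
  body <- lines[-1]
  parts <- strsplit(body, ",")
  for (i in seq_along(parts)) {
    vals <- suppressWarnings(as.numeric(trimws(parts[[i]])))
    if (length(vals) < 2L || anyNA(vals[1:2])) {
      rlang::abort(sprintf(
        "%s: cannot parse line %d: '%s'", path, i + 1L, body[i]
      ))
    }
  }
  mat <- do.call(rbind, purrr::map(parts, ~ as.numeric(trimws(.x))[1:2]))
  df <- tibble::tibble(radius_cm = mat[, 1], absorbance = mat[, 2])
  if (anyDuplicated(df$radius_cm)) {
    rlang::warn(sprintf("%s: duplicate radii collapsed by mean", path))
    df <- df |>
      dplyr::group_by(.data$radius_cm) |>
      dplyr::summarise(absorbance = mean(.data$absorbance), .groups = "drop")
  }
  if (any(diff(df$radius_cm) <= 0)) {
    bad <- which(diff(df$radius_cm) <= 0)[1] + 1L
    rlang::abort(sprintf(
      "%s: radii not strictly increasing at data row %d", path, bad
    ))
  }
  class(df) <- c("radial_scan", class(df))
  df
}

#' Write a radial scan to CSV
#' @param scan Data frame with columns `radius_cm` and a signal column.
#' @param path Output path.
#' @export
write_scan_csv <- function(scan, path) {
  sig <- if ("absorbance" %in% names(scan)) scan$absorbance else scan$signal
  utils::write.csv(
    data.frame(radius_cm = scan$radius_cm, absorbance = sig),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

write_manifest <- function(manifest, path) {
  manifest$schema_version <- MANIFEST_SCHEMA_VERSION
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

read_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(man$schema_version) ||
      man$schema_version != MANIFEST_SCHEMA_VERSION) {
    rlang::abort(sprintf(
      "%s: unsupported manifest schema version", path
    ))
  }
  man
}

#' Write a sedimentation-velocity scan set to a directory
#'
#' One CSV per scan (`radius_cm, absorbance`) plus a JSON manifest with
#' rotor speed, scan times, geometry, provenance (seed, noise sigma) and
#' per-file MD5 checksums.
#'
#' @param scan_set An `sv_scan_set`.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_sv_scan_set <- function(scan_set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- purrr::imap(scan_set$times, function(t, k) {
    fname <- sprintf("scan_%03d.csv", k)
    sub <- scan_set$scans[scan_set$scans$time_s == t, ]
    write_scan_csv(
      data.frame(radius_cm = sub$radius_cm, absorbance = sub$signal),
      file.path(dir, fname)
    )
    list(file = fname, time_s = t, rpm = scan_set$rpm)
  })
  checksums <- as.list(tools::md5sum(
    file.path(dir, vapply(files, `[[`, "", "file"))
  ))
  names(checksums) <- vapply(files, `[[`, "", "file")
  write_manifest(list(
    type = "sv_scan_set",
    rpm = scan_set$rpm,
    meniscus = scan_set$geometry$meniscus,
    bottom = scan_set$geometry$bottom,
    noise_sigma = scan_set$noise_sigma,
    seed = scan_set$seed,
    n_cells = scan_set$n_cells,
    files = files,
    checksums = checksums
  ), file.path(dir, "manifest.json"))
}

#' Read a sedimentation-velocity scan set from a directory
#' @param dir Directory written by [write_sv_scan_set()].
#' @return An `sv_scan_set`.
#' @export
read_sv_scan_set <- function(dir) {
  man <- read_manifest(file.path(dir, "manifest.json"))
  files <- man$files
  scans <- purrr::map_dfr(seq_len(nrow(files)), function(i) {
    fpath <- file.path(dir, files$file[i])
    if (!file.exists(fpath)) {
      rlang::abort(sprintf("manifest references missing file %s",
                           files$file[i]))
    }
    scan <- read_scan_csv(fpath)
    tibble::tibble(time_s = files$time_s[i], radius_cm = scan$radius_cm,
                   signal = scan$absorbance)
  })
  times <- sort(unique(scans$time_s))
  structure(
    list(
      scans = dplyr::arrange(scans, .data$time_s, .data$radius_cm),
      geometry = cell_geometry(man$meniscus, man$bottom),
      rpm = man$rpm, times = times,
      radius_grid = sort(unique(scans$radius_cm)),
      noise_sigma = man$noise_sigma, seed = man$seed,
      n_cells = man$n_cells %||% 400, noiseless = NULL
    ),
    class = "sv_scan_set"
  )
}

#' Write a sedimentation-equilibrium profile set to a directory
#'
#' One CSV per rotor speed plus a JSON manifest (speeds, reference
#' radius, geometry, provenance, checksums).
#'
#' @param profiles An [se_profile_set()].
#' @param dir Output directory.
#' @return The manifest path, invisibly.
#' @export
write_se_profile_set <- function(profiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geometry <- attr(profiles, "geometry")
  r0 <- attr(profiles, "r0")
  scenario <- attr(profiles, "scenario")
  speeds <- sort(unique(profiles$rpm))
  files <- purrr::map(speeds, function(sp) {
    fname <- sprintf("se_%06d.csv", sp)
    sub <- profiles[profiles$rpm == sp, ]
    write_scan_csv(
      data.frame(radius_cm = sub$radius_cm, absorbance = sub$signal),
      file.path(dir, fname)
    )
    list(file = fname, rpm = sp, r0 = unname(r0[[as.character(sp)]]))
  })
  checksums <- as.list(tools::md5sum(
    file.path(dir, vapply(files, `[[`, "", "file"))
  ))
  names(checksums) <- vapply(files, `[[`, "", "file")
  write_manifest(list(
    type = "se_profile_set",
    meniscus = geometry$meniscus, bottom = geometry$bottom,
    scenario = scenario, files = files, checksums = checksums
  ), file.path(dir, "manifest.json"))
}

#' Read a sedimentation-equilibrium profile set from a directory
#' @param dir Directory written by [write_se_profile_set()].
#' @return An [se_profile_set()].
#' @export
read_se_profile_set <- function(dir) {
  man <- read_manifest(file.path(dir, "manifest.json"))
  files <- man$files
  data <- purrr::map_dfr(seq_len(nrow(files)), function(i) {
    scan <- read_scan_csv(file.path(dir, files$file[i]))
    tibble::tibble(rpm = files$rpm[i], radius_cm = scan$radius_cm,
                   signal = scan$absorbance)
  })
  r0 <- stats::setNames(files$r0, files$rpm)
  out <- se_profile_set(data, cell_geometry(man$meniscus, man$bottom),
                        r0 = r0)
  attr(out, "scenario") <- man$scenario
  out
}

#' Write a c(s) distribution to CSV
#' @param dist A `cs_distribution`.
#' @param path Output path.
#' @export
write_cs_distribution <- function(dist, path) {
  utils::write.csv(
    data.frame(s_svedberg = dist$distribution$s,
               c_of_s = dist$distribution$c),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read a c(s) distribution from CSV
#' @param path CSV written by [write_cs_distribution()].
#' @return A `cs_distribution` (amplitude bookkeeping reconstructed from
#'   the density values).
#' @export
read_cs_distribution <- function(path) {
  df <- utils::read.csv(path)
  s <- df$s_svedberg
  new_cs_distribution(
    s, df$c_of_s * trapezoid_weights(s), NA_real_, NA_real_, NA_real_,
    numeric(0), numeric(0)
  )
}

PIPELINE_STAGES <- c("simulate", "fit_se", "fit_cs", "stoich", "titration")

#' Run a configured analysis pipeline
#'
#' Executes the requested stages in order against a shared state:
#' `simulate` realizes a named scenario; `fit_se` / `fit_cs` fit the
#' current equilibrium / velocity dataset; `stoich` ranks compositions
#' against the current equilibrium fit; `titration` normalizes the
#' current titration series and detects the onset. The returned report
#' embeds the fully resolved configuration and all seeds.
#'
#' @param config A list (or path to a YAML/JSON file) with optional
#'   sections `seed`, `buffer` (density/viscosity/temperature),
#'   `registry` (path to a components YAML), and `stages`: a list of
#'   stage specs, each a list with `stage` (one of `simulate`, `fit_se`,
#'   `fit_cs`, `stoich`, `titration`) plus stage parameters.
#' @param out Optional directory: the JSON report (and stage tables) are
#'   written there.
#' @return A list of class `pipeline_report` with elements `config`,
#'   `stages` (named results) and `seed`.
#' @export
run_pipeline <- function(config, out = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stages <- config$stages %||% list()
  bad <- setdiff(
    vapply(stages, function(s) s$stage %||% "", ""), PIPELINE_STAGES
  )
  if (length(bad) > 0L) {
    rlang::abort(sprintf(
      "unknown pipeline stage(s): %s", paste(bad, collapse = ", ")
    ))
  }
  registry <- if (!is.null(config$registry)) {
    if (!file.exists(config$registry)) {
      rlang::abort(sprintf("registry file not found: %s", config$registry))
    }
    read_component_registry(config$registry)
  } else {
    example_registry()
  }
  buffer <- do.call(buffer_state, config$buffer %||% list())
  seed <- config$seed %||% 1L

  state <- new.env(parent = emptyenv())
  results <- list()
  for (k in seq_along(stages)) {
    spec <- stages[[k]]
    nm <- sprintf("%02d_%s", k, spec$stage)
    results[[nm]] <- switch(
      spec$stage,
      simulate = {
        ds <- realize_scenario(spec$scenario, seed = spec$seed %||% seed,
                               buffer = buffer)
        if (inherits(ds, "se_profile_set")) state$se_data <- ds
        if (inherits(ds, "sv_scan_set")) state$sv_data <- ds
        if (inherits(ds, "titration_series")) state$titration <- ds
        list(scenario = spec$scenario, seed = spec$seed %||% seed,
             kind = class(ds)[1])
      },
      fit_se = {
        if (is.null(state$se_data)) {
          rlang::abort("fit_se: no equilibrium dataset in pipeline state")
        }
        vbar <- spec$vbar %||% attr(state$se_data, "scenario")$vbar
        fit <- fit_one_species_global(
          state$se_data, vbar = vbar, buffer = buffer,
          mass_conservation = spec$mass_conservation %||% TRUE
        )
        state$se_fit <- fit
        list(molar_mass = fit$molar_mass, std_error = fit$std_error,
             chisq_reduced = fit$chisq_reduced)
      },
      fit_cs = {
        if (is.null(state$sv_data)) {
          rlang::abort("fit_cs: no velocity dataset in pipeline state")
        }
        args <- c(list(scan_set = state$sv_data, buffer = buffer,
                       vbar = spec$vbar %||% 0.71),
                  spec[intersect(names(spec),
                                 c("s_grid", "frictional_ratio",
                                   "confidence", "n_cells", "dt_max"))])
        dist <- do.call(fit_cs, args)
        state$cs <- dist
        list(weight_average_s = weight_average_s(dist),
             fit_rmsd = dist$fit_rmsd,
             regularization_alpha = dist$regularization_alpha)
      },
      stoich = {
        if (is.null(state$se_fit)) {
          rlang::abort("stoich: no equilibrium fit in pipeline state")
        }
        matches <- enumerate_matches(
          state$se_fit$molar_mass, state$se_fit$std_error, registry,
          bounds = spec$bounds %||% list(RecO = 2, RecR = c(0, 2, 4),
                                         SSB_Ct = 2, Cy3_dT15 = 2),
          constraints = spec$constraints %||% list("SSB_Ct <= RecO"),
          window_k = spec$window_k %||% 2
        )
        state$stoich <- matches
        list(
          top_composition = matches$composition[1],
          top_predicted_mass = matches$predicted_mass[1],
          n_within_window = sum(matches$within_window)
        )
      },
      titration = {
        if (is.null(state$titration)) {
          rlang::abort("titration: no titration series in pipeline state")
        }
        norm <- normalize_series(state$titration)
        onset <- detect_onset(
          norm,
          min_points_per_segment = spec$min_points_per_segment %||% 4
        )
        state$onset <- onset
        list(detected = onset$detected, onset_ratio = onset$onset_ratio,
             post_slope = onset$post_slope)
      }
    )
  }
  report <- structure(
    list(config = config, seed = seed, stages = results),
    class = "pipeline_report"
  )
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(config = config, seed = seed, stages = results),
      file.path(out, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE, force = TRUE
    )
    if (!is.null(state$stoich)) {
      utils::write.csv(
        dplyr::select(tibble::as_tibble(state$stoich), -"counts"),
        file.path(out, "stoich_matches.csv"), row.names = FALSE
      )
    }
    if (!is.null(state$cs)) {
      write_cs_distribution(state$cs, file.path(out, "cs_distribution.csv"))
    }
  }
  report
}
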