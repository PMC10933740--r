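#' Scattering profile container
#'
#' A 1-D small-angle scattering curve: scattering vector `q` (nm^-1, strictly
#' increasing), intensity (arbitrary units, non-negative) and optional
#' per-point uncertainties.
#'
#' @param q strictly increasing scattering vectors, nm^-1.
#' @param intensity non-negative intensities.
#' @param sigma optional positive per-point uncertainties.
#' @param meta optional named metadata list (generator parameters, seed).
#' @return An object of class `scattering_profile`.
#' @export
scattering_profile <- function(q, intensity, sigma = NULL, meta = list()) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  if (length(q) != length(intensity)) stopf("q and intensity lengths differ")
  if (any(!is.finite(q)) || any(diff(q) <= 0)) stopf("q must be strictly increasing")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stopf("intensity must be non-negative")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q) || any(!is.finite(sigma)) || any(sigma <= 0))
      stopf("sigma, if present, must be positive for every point")
  }
  structure(list(q = q, intensity = intensity, sigma = sigma, meta = meta),
            class = "scattering_profile")
}

#' @export
print.scattering_profile <- function(x, ...) {
  cat(sprintf("<scattering_profile> %d points, q = %.4g..%.4g nm^-1%s\n",
              length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) "" else ", with uncertainties"))
  invisible(x)
}

#' Read a 2- or 3-column scattering profile (whitespace or comma separated)
#' @param path file with columns q, intensity and optionally sigma; lines
#'   beginning with `#` and a single non-numeric header line are skipped.
#' @return A [scattering_profile()].
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  split1 <- strsplit(trimws(lines[1]), "[,\\s]+")[[1]]
  if (any(is.na(suppressWarnings(as.numeric(split1))))) lines <- lines[-1]
  rows <- lapply(seq_along(lines), function(i) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "[,\\s]+")[[1]]))
    if (length(f) < 2 || length(f) > 3 || any(is.na(f)))
      stopf("%s line %d: malformed record (need 2-3 numeric fields)", path, i)
    f
  })
  ncols <- unique(vapply(rows, length, 1L))
  if (length(ncols) != 1) stopf("%s: inconsistent column counts", path)
  m <- do.call(rbind, rows)
  scattering_profile(m[, 1], m[, 2], if (ncols == 3) m[, 3] else NULL)
}

#' Write a scattering profile as CSV (`q,intensity[,sigma]` with header)
#' @param p a [scattering_profile()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(p, path) {
  if (!inherits(p, "scattering_profile")) stopf("p must be a scattering_profile")
  if (is.null(p$sigma)) {
    writeLines(c("q,intensity",
                 sprintf("%.15g,%.15g", p$q, p$intensity)), path)
  } else {
    writeLines(c("q,intensity,sigma",
                 sprintf("%.15g,%.15g,%.15g", p$q, p$intensity, p$sigma)), path)
  }
  invisible(path)
}

#' Run configuration
#'
#' Plumbing for reproducible multi-stage runs: a seed (mandatory, echoed into
#' every report), the global voxel pitch and contact gap tolerance, and named
#' per-stage parameter blocks.
#'
#' @param seed integer RNG seed; recorded in all outputs.
#' @param voxel_pitch voxel edge, nm.
#' @param contact_gap contact gap tolerance, nm (>= 0); the tomogram analysis
#'   convention is 15 nm, one voxel side.
#' @param scenario pipeline scenario name (see [run_pipeline()]).
#' @param output_dir where stage outputs are written (optional).
#' @param stages named list of per-stage parameter blocks.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed, voxel_pitch = 15, contact_gap = 15,
                       scenario = NULL, output_dir = NULL, stages = list()) {
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(as.integer(seed))))
    stopf("run_config requires an integer seed")
  if (contact_gap < 0) stopf("contact_gap must be >= 0")
  if (voxel_pitch <= 0) stopf("voxel_pitch must be > 0")
  structure(list(seed = as.integer(seed), voxel_pitch = voxel_pitch,
                 contact_gap = contact_gap, scenario = scenario,
                 output_dir = output_dir, stages = stages),
            class = "run_config")
}

#' Read a YAML run configuration
#' @param path YAML file with at least a `seed` field.
#' @return A [run_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stopf("%s: config must name a seed", path)
  run_config(seed = y$seed,
             voxel_pitch = y$voxel_pitch %||% 15,
             contact_gap = y$contact_gap %||% 15,
             scenario = y$scenario,
             output_dir = y$output_dir,
             stages = y$stages %||% list())
}
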