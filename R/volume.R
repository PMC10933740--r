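#' Voxel volume container
#'
#' A 3-D occupancy or label grid with a physical voxel pitch, standing in for
#' a segmented FIB-SEM tomogram. Voxel `(i, j, k)` (1-based) is centred at
#' `origin + (c(i, j, k) - 0.5) * voxel_pitch`.
#'
#' @param grid 3-D integer array; 0 = background, positive values are
#'   occupancy (1) or particle labels.
#' @param voxel_pitch voxel edge length, nm (> 0).
#' @param origin physical position of the grid corner, nm.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(grid, voxel_pitch, origin = c(0, 0, 0)) {
  if (length(dim(grid)) != 3) stopf("grid must be a 3-D array")
  if (any(dim(grid) < 1)) stopf("grid dimensions must all be >= 1")
  if (!is.numeric(voxel_pitch) || length(voxel_pitch) != 1 || voxel_pitch <= 0)
    stopf("voxel_pitch must be a positive scalar (nm)")
  if (any(grid < 0)) stopf("grid values must be non-negative")
  storage.mode(grid) <- "integer"
  structure(list(grid = grid, voxel_pitch = as.numeric(voxel_pitch),
                 origin = as.numeric(origin)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, pitch %.6g nm, %.1f%% occupied\n",
              d[1], d[2], d[3], x$voxel_pitch, 100 * mean(x$grid > 0)))
  invisible(x)
}

#' Write a voxel volume to disk
#'
#' Two formats are supported. `"nrrd"`: a single NRRD file (raw little-endian
#' int32 payload) carrying pitch and origin in the standard `space directions`
#' / `space origin` header fields. `"tiff-stack"`: a multi-page 16-bit TIFF of
#' z slices plus a JSON sidecar (`<path>.meta.json`) holding pitch and origin,
#' since baseline TIFF has no calibrated-pitch field; labels above 65535 are
#' rejected for TIFF.
#'
#' @param vol a [voxel_volume()].
#' @param path output file.
#' @param format `"nrrd"` or `"tiff-stack"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("nrrd", "tiff-stack")) {
  if (!inherits(vol, "voxel_volume")) stopf("vol must be a voxel_volume")
  format <- match.arg(format)
  d <- dim(vol$grid)
  if (format == "nrrd") {
    hdr <- c("NRRD0004",
             "# diamondpack voxel volume",
             "type: int32",
             "dimension: 3",
             sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
             "encoding: raw",
             "endian: little",
             "space dimension: 3",
             sprintf("space directions: (%.9g,0,0) (0,%.9g,0) (0,0,%.9g)",
                     vol$voxel_pitch, vol$voxel_pitch, vol$voxel_pitch),
             sprintf("space origin: (%.9g,%.9g,%.9g)",
                     vol$origin[1], vol$origin[2], vol$origin[3]),
             "")
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
    writeBin(as.integer(vol$grid), con, size = 4, endian = "little")
  } else {
    mx <- max(vol$grid)
    if (mx > 65535) stopf("labels exceed 16-bit TIFF range; use nrrd")
    slices <- lapply(seq_len(d[3]), function(k) vol$grid[, , k] / 65535)
    tiff::writeTIFF(slices, path, bits.per.sample = 16, compression = "none",
                    reduce = FALSE)
    jsonlite::write_json(list(voxel_pitch = vol$voxel_pitch,
                              origin = vol$origin, dims = d),
                         paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a voxel volume written by [write_volume()]
#'
#' @param path file to read.
#' @param format `"nrrd"`, `"tiff-stack"`, or `"auto"` (by extension).
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path, format = c("auto", "nrrd", "tiff-stack")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE))
      "tiff-stack" else "nrrd"
  if (format == "nrrd") {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr <- character()
    repeat {
      ln <- read_bin_line(con)
      if (is.null(ln)) stopf("%s: truncated NRRD header", path)
      if (ln == "") break
      hdr <- c(hdr, ln)
    }
    if (!grepl("^NRRD", hdr[1])) stopf("%s: not an NRRD file", path)
    gv <- function(key) {
      h <- hdr[grepl(paste0("^", key, ":"), hdr)]
      if (!length(h)) return(NULL)
      trimws(sub(paste0("^", key, ":"), "", h[1]))
    }
    sizes <- as.integer(strsplit(gv("sizes"), "\\s+")[[1]])
    if ((gv("type") %||% "") != "int32" || (gv("encoding") %||% "") != "raw")
      stopf("%s: only raw int32 NRRD payloads are supported", path)
    dirs <- gv("space directions")
    pitch <- as.numeric(sub("^\\(([^,]+),.*", "\\1", dirs))
    so <- gv("space origin") %||% "(0,0,0)"
    origin <- as.numeric(strsplit(gsub("[()]", "", so), ",")[[1]])
    n <- prod(sizes)
    v <- readBin(con, "integer", n = n, size = 4, endian = "little")
    if (length(v) != n) stopf("%s: truncated payload", path)
    voxel_volume(array(v, dim = sizes), pitch, origin)
  } else {
    slices <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(slices)) slices <- list(slices)
    meta_path <- paste0(path, ".meta.json")
    if (!file.exists(meta_path))
      stopf("%s: missing %s sidecar with voxel pitch", path, meta_path)
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    d <- c(nrow(slices[[1]]), ncol(slices[[1]]), length(slices))
    g <- array(0L, d)
    for (k in seq_len(d[3])) g[, , k] <- as.integer(round(slices[[k]] * 65535))
    voxel_volume(g, meta$voxel_pitch, meta$origin)
  }
}

read_bin_line <- function(con) {
  out <- raw()
  repeat {
    b <- readBin(con, "raw", n = 1)
    if (!length(b)) return(if (length(out)) rawToChar(out) else NULL)
    if (b == as.raw(10)) return(rawToChar(out))
    out <- c(out, b)
  }
}
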