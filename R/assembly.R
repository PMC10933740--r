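#' Sphere assembly container
#'
#' The universal currency of the package: particle centres and radii in
#' nanometres inside an orthorhombic box whose axes are individually periodic
#' or walled, with optional unit-quaternion orientations and integer labels.
#'
#' @param positions numeric N x 3 matrix of centres (nm).
#' @param radii numeric vector of N radii (nm), all positive.
#' @param box numeric length-3 edge lengths (nm).
#' @param periodic logical length-3: `TRUE` = periodic axis, `FALSE` = wall.
#' @param orientations optional N x 4 matrix of unit quaternions (w, x, y, z);
#'   identity orientation is assumed when absent.
#' @param labels optional integer vector of per-particle ids/flags.
#' @param meta optional named list of provenance metadata (seed, stage
#'   parameters); carried through transformations where meaningful.
#'
#' @return An object of class `sphere_assembly`.
#' @export
sphere_assembly <- function(positions, radii, box,
                            periodic = c(TRUE, TRUE, TRUE),
                            orientations = NULL, labels = NULL, meta = list()) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stopf("positions must be an N x 3 matrix")
  storage.mode(positions) <- "double"
  n <- nrow(positions)
  radii <- as.numeric(radii)
  if (length(radii) == 1L) radii <- rep(radii, n)
  if (length(radii) != n) stopf("length(radii) must match nrow(positions)")
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stopf("box must be 3 positive edge lengths")
  periodic <- as.logical(periodic)
  if (length(periodic) != 3) stopf("periodic must have length 3")
  a <- structure(list(positions = positions, radii = radii, box = box,
                      periodic = periodic, orientations = orientations,
                      labels = labels, meta = meta),
                 class = "sphere_assembly")
  validate_assembly(a)
  a
}

validate_assembly <- function(a) {
  n <- nrow(a$positions)
  if (any(!is.finite(a$positions))) stopf("non-finite particle position")
  if (any(!is.finite(a$radii)) || any(a$radii <= 0))
    stopf("all radii must be positive and finite")
  for (ax in 1:3) {
    if (!a$periodic[ax]) {
      x <- a$positions[, ax]
      if (n > 0 && (min(x) < -1e-9 || max(x) > a$box[ax] + 1e-9))
        stopf("positions outside the box along walled axis %d", ax)
    }
  }
  if (!is.null(a$orientations)) {
    q <- as.matrix(a$orientations)
    if (nrow(q) != n || ncol(q) != 4) stopf("orientations must be N x 4")
    nrm <- sqrt(rowSums(q^2))
    if (n > 0 && max(abs(nrm - 1)) > 1e-9)
      stopf("orientations must be unit quaternions (|q| - 1 <= 1e-9)")
  }
  if (!is.null(a$labels) && length(a$labels) != n)
    stopf("labels must have one entry per particle")
  invisible(a)
}

#' @export
print.sphere_assembly <- function(x, ...) {
  bc <- paste(ifelse(x$periodic, "p", "w"), collapse = " ")
  cat(sprintf("<sphere_assembly> N = %d, box = %.6g x %.6g x %.6g nm [%s]\n",
              nrow(x$positions), x$box[1], x$box[2], x$box[3], bc))
  if (nrow(x$positions) > 0)
    cat(sprintf("  radii: mean %.4g nm (range %.4g..%.4g)\n",
                mean(x$radii), min(x$radii), max(x$radii)))
  if (!is.null(x$orientations)) cat("  orientations: present\n")
  if (length(x$meta)) cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

n_particles <- function(a) nrow(a$positions)

# minimum-image displacement matrix helpers used across modules
min_image <- function(d, box, periodic) {
  for (ax in 1:3)
    if (periodic[ax]) d[, ax] <- d[, ax] - box[ax] * round(d[, ax] / box[ax])
  d
}

#' Read a sphere assembly from an extended XYZ file
#'
#' Dialect: first line is the particle count; the second (comment) line holds
#' `key=value` pairs, at minimum `box="Lx Ly Lz"` and `boundary="p p w"`
#' (p = periodic, w = wall); each record line has `x y z radius` and, when
#' orientations are stored, four further quaternion columns `qw qx qy qz`, and
#' optionally a final integer `label` column (declared by `columns=` in the
#' header). Malformed input is rejected with the offending line number; a
#' missing box header is an explicit error, never silently defaulted.
#'
#' @param path file to read.
#' @param format only `"xyz-ext"` is supported.
#' @return A [sphere_assembly()].
#' @export
read_assembly <- function(path, format = "xyz-ext") {
  format <- match.arg(format, "xyz-ext")
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stopf("%s: not an extended XYZ file (fewer than 2 lines)", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) stopf("%s line 1: invalid particle count (N >= 1 required)", path)
  hdr <- parse_kv(lines[2])
  if (is.null(hdr$box)) stopf("%s line 2: missing box=\"Lx Ly Lz\" header", path)
  box <- suppressWarnings(as.numeric(strsplit(trimws(hdr$box), "\\s+")[[1]]))
  if (length(box) != 3 || any(is.na(box)))
    stopf("%s line 2: box must hold three numbers", path)
  if (is.null(hdr$boundary)) stopf("%s line 2: missing boundary=\"p p p\" header", path)
  bflags <- strsplit(trimws(hdr$boundary), "\\s+")[[1]]
  if (length(bflags) != 3 || !all(bflags %in% c("p", "w")))
    stopf("%s line 2: boundary flags must be three of p|w", path)
  periodic <- bflags == "p"
  cols <- hdr$columns %||% "x y z r"
  colv <- strsplit(trimws(cols), "\\s+")[[1]]
  ncols <- length(colv)
  has_q <- "qw" %in% colv
  has_lab <- "label" %in% colv
  if (length(lines) < 2 + n) stopf("%s: expected %d records, found %d", path, n,
                                   length(lines) - 2)
  pos <- matrix(0, n, 3); rad <- numeric(n)
  quat <- if (has_q) matrix(0, n, 4) else NULL
  lab <- if (has_lab) integer(n) else NULL
  for (i in seq_len(n)) {
    ln <- 2 + i
    f <- suppressWarnings(as.numeric(strsplit(trimws(lines[ln]), "\\s+")[[1]]))
    if (length(f) != ncols || any(is.na(f)))
      stopf("%s line %d: malformed record (need %d numeric fields)", path, ln, ncols)
    pos[i, ] <- f[1:3]
    if (f[4] <= 0) stopf("%s line %d: non-positive radius", path, ln)
    rad[i] <- f[4]
    k <- 5
    if (has_q) { quat[i, ] <- f[k:(k + 3)]; k <- k + 4 }
    if (has_lab) lab[i] <- as.integer(f[k])
  }
  meta <- hdr[setdiff(names(hdr), c("box", "boundary", "columns"))]
  sphere_assembly(pos, rad, box, periodic, orientations = quat, labels = lab,
                  meta = meta)
}

parse_kv <- function(line) {
  out <- list()
  # key="quoted value" or key=value tokens
  pat <- '([A-Za-z_][A-Za-z0-9_]*)=("([^"]*)"|[^ \t]+)'
  m <- gregexpr(pat, line, perl = TRUE)[[1]]
  if (m[1] == -1) return(out)
  starts <- as.integer(m); lens <- attr(m, "match.length")
  for (k in seq_along(starts)) {
    tok <- substr(line, starts[k], starts[k] + lens[k] - 1)
    eq <- regexpr("=", tok, fixed = TRUE)
    key <- substr(tok, 1, eq - 1)
    val <- substr(tok, eq + 1, nchar(tok))
    val <- gsub('^"|"$', "", val)
    out[[key]] <- val
  }
  out
}

#' Write a sphere assembly to an extended XYZ file
#'
#' Inverse of [read_assembly()]; `read_assembly(write_assembly(a, f))`
#' reproduces `a` to the textual precision written (15 significant digits).
#'
#' @param a a [sphere_assembly()].
#' @param path output file.
#' @param format only `"xyz-ext"`.
#' @return `path`, invisibly.
#' @export
write_assembly <- function(a, path, format = "xyz-ext") {
  format <- match.arg(format, "xyz-ext")
  validate_assembly(a)
  n <- nrow(a$positions)
  colv <- c("x", "y", "z", "r")
  if (!is.null(a$orientations)) colv <- c(colv, "qw", "qx", "qy", "qz")
  if (!is.null(a$labels)) colv <- c(colv, "label")
  hdr <- sprintf('box="%s" boundary="%s" columns="%s"',
                 paste(sprintf("%.15g", a$box), collapse = " "),
                 paste(ifelse(a$periodic, "p", "w"), collapse = " "),
                 paste(colv, collapse = " "))
  extra <- a$meta[vapply(a$meta, function(v) is.character(v) || is.numeric(v), TRUE)]
  if (length(extra))
    hdr <- paste(hdr, paste(sprintf('%s="%s"', names(extra),
                                    vapply(extra, as.character, "")), collapse = " "))
  rows <- cbind(a$positions, a$radii)
  if (!is.null(a$orientations)) rows <- cbind(rows, a$orientations)
  if (!is.null(a$labels)) rows <- cbind(rows, a$labels)
  body <- apply(rows, 1, function(r) paste(sprintf("%.15g", r), collapse = " "))
  writeLines(c(as.character(n), hdr, body), path)
  invisible(path)
}
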