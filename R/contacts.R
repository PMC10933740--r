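#' Contact graph under the gap-tolerance criterion
#'
#' Two particles are touching neighbours when their minimum-image
#' centre-to-centre distance satisfies `d_ij <= r_i + r_j + gap_tol`. The
#' tomogram-analysis convention is `gap_tol = 15` nm, one voxel side, which
#' absorbs the finite voxel size of the imaging. Built with cell lists
#' (O(N) expected); exact agreement with the all-pairs brute force is part of
#' the test contract.
#'
#' @param a a [sphere_assembly()].
#' @param gap_tol gap tolerance in nm (>= 0).
#' @return An object of class `contact_graph`: `edges` (M x 2, i < j),
#'   `degree` (length N), `gap_tol`, `n`.
#' @export
contact_graph <- function(a, gap_tol = 15) {
  if (gap_tol < 0) stopf("gap_tol must be >= 0")
  n <- nrow(a$positions)
  edges <- cpp_contact_pairs(a$positions, a$radii, a$box, a$periodic, gap_tol)
  structure(list(edges = edges, degree = tabulate(c(edges), nbins = n),
                 gap_tol = gap_tol, n = n),
            class = "contact_graph")
}

#' @export
print.contact_graph <- function(x, ...) {
  cat(sprintf("<contact_graph> N = %d, %d edges, gap tolerance %.4g nm, mean degree %.3f\n",
              x$n, nrow(x$edges), x$gap_tol, mean(x$degree)))
  invisible(x)
}

#' Touching-neighbour (n_touch) distribution
#'
#' Integer histogram of per-particle contact counts with mean, standard
#' deviation and mode. The mean equals `2 * |edges| / N` exactly. Peaks of
#' the histogram quoted as non-integer values in tomographic work correspond
#' to the mean of the integer distribution; both mean and mode are reported.
#'
#' @param g a [contact_graph()], or a [sphere_assembly()] (then `gap_tol`
#'   applies).
#' @param gap_tol used only when `g` is an assembly.
#' @return A list of class `packing_summary` with `histogram` (named counts
#'   over 0..max degree), `n_touch_mean`, `n_touch_sd`, `n_touch_mode`, `n`,
#'   `gap_tol`.
#' @export
n_touch_distribution <- function(g, gap_tol = 15) {
  if (inherits(g, "sphere_assembly")) g <- contact_graph(g, gap_tol)
  deg <- g$degree
  h <- tabulate(deg + 1L, nbins = max(deg) + 1L)
  names(h) <- 0:max(deg)
  structure(list(histogram = h,
                 n_touch_mean = mean(deg),
                 n_touch_sd = if (length(deg) > 1) sd(deg) else 0,
                 n_touch_mode = as.integer(names(h)[which.max(h)]),
                 n = g$n, gap_tol = g$gap_tol),
            class = "packing_summary")
}

#' @export
print.packing_summary <- function(x, ...) {
  cat(sprintf("<packing_summary> N = %d, n_touch = %.2f +/- %.2f (mode %d), gap %.4g nm\n",
              x$n, x$n_touch_mean, x$n_touch_sd, x$n_touch_mode, x$gap_tol))
  if (!is.null(x$phi)) cat(sprintf("  packing fraction phi = %.4f\n", x$phi))
  invisible(x)
}

#' Packing (volume) fraction of a sphere assembly
#'
#' `method = "analytic"` sums sphere volumes clipped to the region with exact
#' spherical-cap corrections at each region face (faces treated independently,
#' so spheres straddling a region edge or corner are slightly
#' over-corrected -- keep region faces at least one radius apart).
#' `method = "voxel_mc"` Monte-Carlo point sampling, reported with a standard
#' error in `attr(, "se")`. Overlapping spheres make the analytic sum
#' double-count, so it falls back to Monte Carlo with a warning.
#'
#' @param a a [sphere_assembly()].
#' @param method `"analytic"` or `"voxel_mc"`.
#' @param region optional `list(lo = c(x,y,z), hi = c(x,y,z))` sub-box, nm;
#'   default is the full box.
#' @param mc_points sample count for Monte Carlo.
#' @param seed Monte-Carlo seed.
#' @return Packing fraction in `[0, 1)`; Monte-Carlo results carry `attr se`.
#' @export
packing_fraction <- function(a, method = c("analytic", "voxel_mc"),
                             region = NULL, mc_points = 200000L, seed = 1) {
  method <- match.arg(method)
  lo <- if (is.null(region)) c(0, 0, 0) else as.numeric(region$lo)
  hi <- if (is.null(region)) a$box else as.numeric(region$hi)
  if (any(lo < -1e-9) || any(hi > a$box + 1e-9) || any(hi <= lo))
    stopf("region must be a non-empty sub-box of the assembly box")
  if (method == "analytic") {
    ov <- cpp_contact_pairs(a$positions, a$radii, a$box, a$periodic,
                            -1e-7 * max(a$radii))
    if (nrow(ov) > 0) {
      warning("overlapping spheres: analytic volume would double-count; using voxel_mc",
              call. = FALSE)
      return(packing_fraction(a, "voxel_mc", region, mc_points, seed))
    }
    full_box <- is.null(region)
    if (full_box && all(a$periodic)) {
      # every sphere lies wholly inside the torus: no clipping needed
      return(sum(4 / 3 * pi * a$radii^3) / prod(a$box))
    }
    vol <- 0
    if (full_box) {
      # each sphere once, clipped at walled faces only (mass wrapped across
      # periodic faces is conserved)
      walled <- which(!a$periodic)
      for (i in seq_len(nrow(a$positions))) {
        x <- a$positions[i, ]
        x[a$periodic] <- x[a$periodic] %% a$box[a$periodic]
        vol <- vol + sphere_box_volume(x, a$radii[i], lo, hi, clip_axes = walled)
      }
    } else {
      for (i in seq_len(nrow(a$positions))) {
        r <- a$radii[i]
        # periodic images that can intersect the region
        cand <- image_positions(a$positions[i, ], a$box, a$periodic, lo - r, hi + r)
        for (k in seq_len(nrow(cand)))
          vol <- vol + sphere_box_volume(cand[k, ], r, lo, hi)
      }
    }
    vol / prod(hi - lo)
  } else {
    pts <- with_seed(seed, {
      m <- matrix(runif(3 * mc_points), mc_points, 3)
      sweep(sweep(m, 2, hi - lo, "*"), 2, lo, "+")
    })
    inside <- cpp_points_covered(pts, a$positions, a$radii, a$box, a$periodic)
    p <- mean(inside)
    se <- sqrt(max(p * (1 - p), 1e-12) / mc_points)
    structure(p, se = se)
  }
}

# periodic images of a centre that may touch the window [lo, hi]
image_positions <- function(x, box, periodic, lo, hi) {
  shifts <- lapply(1:3, function(ax) {
    if (!periodic[ax]) return(0)
    k <- seq(floor((lo[ax] - x[ax]) / box[ax]), ceiling((hi[ax] - x[ax]) / box[ax]))
    k * box[ax]
  })
  g <- expand.grid(shifts[[1]], shifts[[2]], shifts[[3]])
  out <- cbind(x[1] + g[, 1], x[2] + g[, 2], x[3] + g[, 3])
  keep <- out[, 1] >= lo[1] & out[, 1] <= hi[1] &
          out[, 2] >= lo[2] & out[, 2] <= hi[2] &
          out[, 3] >= lo[3] & out[, 3] <= hi[3]
  out[keep, , drop = FALSE]
}

# sphere volume inside an axis-aligned box, independent per-face cap clipping
sphere_box_volume <- function(c0, r, lo, hi, clip_axes = 1:3) {
  v <- 4 / 3 * pi * r^3
  for (ax in clip_axes) {
    d1 <- c0[ax] - lo[ax]              # signed distance inward from low face
    d2 <- hi[ax] - c0[ax]
    if (d1 <= -r || d2 <= -r) return(0)
    if (d1 < r) v <- v - spherical_cap(r, r - d1)
    if (d2 < r) v <- v - spherical_cap(r, r - d2)
  }
  max(v, 0)
}

spherical_cap <- function(r, h) pi * h^2 * (3 * r - h) / 3
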