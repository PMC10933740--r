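#' Reference-lattice builder
#'
#' Deterministic generators for the crystalline reference structures used to
#' anchor contact-number and bond-orientational-order analyses: simple cubic,
#' FCC, BCC, HCP and diamond cubic. All are built on rectangular periodic
#' boxes; HCP uses the 4-site orthorhombic supercell so that one box
#' representation serves the whole package. In `"touching"` mode the sphere
#' radius is exactly half the nearest-neighbour distance, so lattice contact
#' counts under a zero-gap criterion equal the crystallographic coordination
#' (sc 6, fcc 12, bcc 8, hcp 12, diamond 4).
#'
#' @param kind one of `"sc"`, `"fcc"`, `"bcc"`, `"hcp"`, `"diamond"`.
#' @param repeats integer length-3: unit-cell repeats per axis.
#' @param a lattice parameter, nm (cubic edge; HCP in-plane spacing is derived
#'   so the nearest-neighbour distance matches the stated `a` convention).
#' @param radius `"touching"` or an explicit radius in nm. An explicit radius
#'   that overlaps neighbours beyond numerical tolerance is an error.
#' @return A [sphere_assembly()] with a periodic box commensurate with the
#'   lattice.
#' @export
build_lattice <- function(kind = c("sc", "fcc", "bcc", "hcp", "diamond"),
                          repeats = c(3, 3, 3), a = 210,
                          radius = "touching") {
  kind <- match.arg(kind)
  repeats <- as.integer(repeats)
  if (length(repeats) != 3 || any(repeats < 1)) stopf("repeats must be >= 1 each axis")
  if (a <= 0) stopf("lattice parameter must be positive")
  cell <- switch(kind,
    sc = list(frac = rbind(c(0, 0, 0)), edge = c(1, 1, 1), nn = 1),
    fcc = list(frac = rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5),
                            c(0, 0.5, 0.5)),
               edge = c(1, 1, 1), nn = sqrt(2) / 2),
    bcc = list(frac = rbind(c(0, 0, 0), c(0.5, 0.5, 0.5)),
               edge = c(1, 1, 1), nn = sqrt(3) / 2),
    hcp = list(frac = rbind(c(0, 0, 0), c(0.5, 0.5, 0),
                            c(0.5, 1 / 6, 0.5), c(0, 2 / 3, 0.5)),
               edge = c(1, sqrt(3), sqrt(8 / 3)), nn = 1),
    diamond = list(frac = rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5),
                                c(0, 0.5, 0.5), c(0.25, 0.25, 0.25),
                                c(0.75, 0.75, 0.25), c(0.75, 0.25, 0.75),
                                c(0.25, 0.75, 0.75)),
                   edge = c(1, 1, 1), nn = sqrt(3) / 4))
  box <- cell$edge * a * repeats
  nb <- nrow(cell$frac)
  pos <- matrix(0, nb * prod(repeats), 3)
  k <- 0
  for (iz in seq_len(repeats[3]) - 1)
    for (iy in seq_len(repeats[2]) - 1)
      for (ix in seq_len(repeats[1]) - 1) {
        shift <- c(ix, iy, iz) * cell$edge * a
        pos[k + seq_len(nb), ] <- sweep(cell$frac * rep(cell$edge * a, each = nb),
                                        2, shift, "+")
        k <- k + nb
      }
  d_nn <- cell$nn * a
  if (identical(radius, "touching")) {
    r <- d_nn / 2
  } else {
    r <- as.numeric(radius)
    if (!is.finite(r) || r <= 0) stopf("explicit radius must be positive")
    if (2 * r > d_nn * (1 + 1e-9))
      stopf("explicit radius %.6g overlaps neighbours (nearest-neighbour distance %.6g)",
            r, d_nn)
  }
  sphere_assembly(pos, r, box, periodic = c(TRUE, TRUE, TRUE),
                  meta = list(kind = kind, lattice_parameter = a,
                              repeats = paste(repeats, collapse = "x"),
                              nn_distance = d_nn))
}

#' Jitter particle positions with isotropic Gaussian noise
#'
#' A robustness fixture: displaces every centre by a Gaussian of standard
#' deviation `amplitude` (nm) per axis, leaving radii untouched. Periodic axes
#' wrap; walled axes clamp to the box. Deterministic given `seed`.
#'
#' @param a a [sphere_assembly()].
#' @param amplitude displacement sd, nm (>= 0).
#' @param seed RNG seed.
#' @return The perturbed [sphere_assembly()].
#' @export
perturb_assembly <- function(a, amplitude, seed = 1) {
  if (amplitude < 0) stopf("amplitude must be >= 0")
  if (amplitude == 0) return(a)
  n <- nrow(a$positions)
  disp <- with_seed(seed, matrix(rnorm(3 * n, sd = amplitude), n, 3))
  pos <- a$positions + disp
  for (ax in 1:3) {
    if (a$periodic[ax]) pos[, ax] <- pos[, ax] %% a$box[ax]
    else pos[, ax] <- pmin(pmax(pos[, ax], 0), a$box[ax])
  }
  out <- a
  out$positions <- pos
  out$meta$perturbed <- amplitude
  out
}
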