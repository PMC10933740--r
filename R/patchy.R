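#' Tetrahedral patchy-particle interaction model
#'
#' Rigid spheres decorated with four attractive patches at tetrahedral angles.
#' Patch-patch attraction is a steep 2n-n Lennard-Jones acting between the
#' particle centres, `U_p(r) = 4 eps [ (sigma/r)^(2n) - (sigma/r)^n ]` with
#' `n = 24`, modulated by a smooth angular alignment factor (continuous
#' Kern-Frenkel form; see [patch_alignment_factor()]). `sigma` is the
#' centre-centre contact distance, i.e. the particle diameter, which puts the
#' potential minimum at `2^(1/n) sigma = 1.03 sigma`. Energies are in units
#' of kT; the default strengths are 8 kT (patch-patch), 3 kT (body-body) and
#' 10 kT (the WCA channel used for confining walls).
#'
#' The body-body channel has two modes. The default, `body_mode = "wca"`,
#' makes every non-patch contact purely repulsive (the truncated-shifted
#' repulsive-only form with `eps_body`): this is the physical statement of
#' the model -- directional adhesion only -- and is what produces open,
#' tetravalent sediments. `body_mode = "lj"` instead applies the full 2n-n
#' form, giving a weak isotropic 3 kT cohesion at contact; sticky spheres of
#' that kind collapse into dense amorphous beds with 7-8 touching
#' neighbours, a useful contrast case.
#'
#' @param diameter particle diameter = LJ contact distance sigma, nm.
#' @param n_exp steepness exponent n (even, >= 2).
#' @param eps_patch,eps_body,eps_wca well depths / repulsion strength, kT.
#' @param patch_halfwidth angular width delta of the patch modulation,
#'   degrees.
#' @param gravity downward force per particle, kT per nm (0 = off).
#' @param temperature reduced temperature (kT units; the model is defined at
#'   1).
#' @param patch_axes 4 x 3 matrix of unit patch directions in the particle
#'   frame; defaults to the regular tetrahedron. Pairwise angles must all be
#'   arccos(-1/3).
#' @param rcut pair cutoff in units of sigma.
#' @param body_mode `"wca"` (default: non-patch contacts purely repulsive) or
#'   `"lj"` (weak isotropic body-body attraction).
#' @return An object of class `patchy_model`.
#' @export
patchy_model <- function(diameter = 210, n_exp = 24L, eps_patch = 8,
                         eps_body = 3, eps_wca = 10, patch_halfwidth = 30,
                         gravity = 0, temperature = 1, patch_axes = NULL,
                         rcut = 1.5, body_mode = c("wca", "lj")) {
  body_mode <- match.arg(body_mode)
  if (n_exp < 2 || n_exp %% 2 != 0) stopf("n_exp must be even and >= 2")
  if (any(c(eps_patch, eps_body, eps_wca) < 0)) stopf("all eps must be >= 0")
  if (diameter <= 0) stopf("diameter must be positive")
  if (patch_halfwidth <= 0) stopf("patch_halfwidth must be positive")
  if (is.null(patch_axes)) {
    patch_axes <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  } else {
    patch_axes <- as.matrix(patch_axes)
    if (!all(dim(patch_axes) == c(4, 2 + 1))) stopf("patch_axes must be 4 x 3")
    patch_axes <- patch_axes / sqrt(rowSums(patch_axes^2))
    dots <- tcrossprod(patch_axes)
    off <- dots[upper.tri(dots)]
    if (max(abs(off + 1 / 3)) > 1e-9)
      stopf("patch axes must be tetrahedral: pairwise angles arccos(-1/3)")
  }
  structure(list(diameter = diameter, n_exp = as.integer(n_exp),
                 eps_patch = eps_patch, eps_body = eps_body, eps_wca = eps_wca,
                 patch_halfwidth = patch_halfwidth, gravity = gravity,
                 temperature = temperature, patch_axes = patch_axes,
                 rcut = rcut, body_mode = body_mode),
            class = "patchy_model")
}

#' @export
print.patchy_model <- function(x, ...) {
  cat(sprintf(paste0("<patchy_model> sigma = %.4g nm, n = %d, eps(patch/body/wca) = ",
                     "%.3g/%.3g/%.3g kT, patch halfwidth %.3g deg, g = %.3g kT/nm\n"),
              x$diameter, x$n_exp, x$eps_patch, x$eps_body, x$eps_wca,
              x$patch_halfwidth, x$gravity))
  invisible(x)
}

# reduced-unit model list handed to the C++ engine
model_to_cpp <- function(model) {
  list(sigma = 1.0, n_exp = model$n_exp, eps_patch = model$eps_patch,
       eps_body = model$eps_body, eps_wca = model$eps_wca,
       patch_halfwidth_rad = model$patch_halfwidth * pi / 180,
       gravity = model$gravity * model$diameter,   # kT/nm -> kT/sigma
       rcut = model$rcut, mass = 1.0, inertia = 0.1,
       body_wca = as.integer(identical(model$body_mode %||% "wca", "wca")),
       patch_axes = model$patch_axes)
}

#' Radial pair potentials of the patchy model
#'
#' The three radial channels: `patch_lj` and `body_lj` are the plain 2n-n
#' Lennard-Jones `4 eps [ (sigma/r)^(2n) - (sigma/r)^n ]` with their
#' respective well depths; `wca` is the truncated-shifted repulsive form
#' `4 eps [ (sigma/r)^(2n) - (sigma/r)^n + 1/4 ]` for `r <= 2^(1/n) sigma`
#' and exactly 0 beyond, continuous (with continuous derivative) at the
#' cutoff.
#'
#' `body_lj` always evaluates the plain 2n-n form; in simulations the body
#' channel follows the model's `body_mode` (the default `"wca"` mode uses the
#' repulsive-only form with `eps_body`).
#'
#' @param r centre-centre distance(s), nm (> 0).
#' @param kind `"patch_lj"`, `"body_lj"` or `"wca"`.
#' @param model a [patchy_model()].
#' @return Energy in kT, vectorized over `r`.
#' @export
radial_potential <- function(r, kind = c("patch_lj", "body_lj", "wca"),
                             model = patchy_model()) {
  kind <- match.arg(kind)
  if (any(r <= 0)) stopf("r must be positive")
  s <- (model$diameter / r)^model$n_exp
  eps <- switch(kind, patch_lj = model$eps_patch, body_lj = model$eps_body,
                wca = model$eps_wca)
  if (kind == "wca") {
    u <- 4 * eps * (s^2 - s + 0.25)
    u[r > 2^(1 / model$n_exp) * model$diameter] <- 0
    u
  } else {
    4 * eps * (s^2 - s)
  }
}

# quaternion -> rotated vector (R-side mirror of the engine)
quat_rotate <- function(q, v) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  t <- 2 * c(y * v[3] - z * v[2], z * v[1] - x * v[3], x * v[2] - y * v[1])
  v + w * t + c(y * t[3] - z * t[2], z * t[1] - x * t[3], x * t[2] - y * t[1])
}

#' Angular alignment factor of the patch-patch attraction
#'
#' The product `f_i f_j` of per-particle Gaussian alignment functions,
#' `f = exp(-theta^2 / (2 delta^2))`, where `theta` is the angle between the
#' best-aligned patch axis and the centre line (patch of particle `i` toward
#' `j`, patch of `j` toward `i`) and `delta` the patch halfwidth. Equals 1
#' when a patch of each particle points exactly along the centre line and
#' decays smoothly to 0 for misaligned pairs; symmetric under exchange of the
#' two particles.
#'
#' @param quat_i,quat_j unit quaternions (w, x, y, z).
#' @param r_ij separation vector from `i` to `j` (any units; only the
#'   direction matters).
#' @param model a [patchy_model()].
#' @return Scalar factor in `[0, 1]`.
#' @export
patch_alignment_factor <- function(quat_i, quat_j, r_ij, model = patchy_model()) {
  nr <- sqrt(sum(r_ij^2))
  if (nr <= 0) stopf("|r_ij| must be positive")
  u <- r_ij / nr
  delta <- model$patch_halfwidth * pi / 180
  best <- function(q, dir) {
    cmax <- -2
    for (a in 1:4) {
      p <- quat_rotate(q, model$patch_axes[a, ])
      cmax <- max(cmax, sum(p * dir))
    }
    acos(min(1, max(-1, cmax)))
  }
  thi <- best(quat_i, u)
  thj <- best(quat_j, -u)
  exp(-(thi^2 + thj^2) / (2 * delta^2))
}

identity_quats <- function(n) cbind(rep(1, n), 0, 0, 0)

random_quats <- function(n) {
  # Shoemake uniform random rotations
  u1 <- runif(n); u2 <- runif(n); u3 <- runif(n)
  cbind(sqrt(1 - u1) * sin(2 * pi * u2), sqrt(1 - u1) * cos(2 * pi * u2),
        sqrt(u1) * sin(2 * pi * u3), sqrt(u1) * cos(2 * pi * u3))
}

assembly_wall_mode <- function(a) {
  if (all(a$periodic)) return(FALSE)
  if (!a$periodic[3] && a$periodic[1] && a$periodic[2]) return(TRUE)
  stopf("walls are supported on the z axis only (periodic x, y)")
}

#' Total potential energy of a patchy-particle state
#'
#' Sum over pairs (within the cutoff) of the body Lennard-Jones term and the
#' alignment-modulated patch term, plus gravitational energy `g * z` and the
#' WCA wall terms when the z axis is walled. Invariant under global
#' translation along periodic axes and under global rotation about the
#' gravity axis. Overlapping particles (r < sigma/2) trigger a warning but
#' still return the (finite) energy.
#'
#' @param a a [sphere_assembly()] in nm; orientations default to identity.
#' @param model a [patchy_model()].
#' @param forces also return forces (kT/nm) and torques (kT)?
#' @return Energy in kT with attribute `breakdown` (pair / gravity / wall);
#'   with `forces = TRUE`, a list `energy`, `breakdown`, `forces`, `torques`.
#' @export
total_energy <- function(a, model = patchy_model(), forces = FALSE) {
  s <- model$diameter
  wall <- assembly_wall_mode(a)
  quat <- a$orientations %||% identity_quats(nrow(a$positions))
  res <- cpp_patchy_forces(a$positions / s, quat, model_to_cpp(model),
                           a$box / s, a$periodic, wall)
  close_pairs <- cpp_contact_pairs(a$positions, a$radii, a$box, a$periodic,
                                   -0.5 * s + 1e-12)
  if (nrow(close_pairs) > 0)
    warning(sprintf("%d particle pair(s) closer than sigma/2; energy is finite but extreme",
                    nrow(close_pairs)), call. = FALSE)
  breakdown <- c(pair = res$e_pair, gravity = res$e_gravity, wall = res$e_wall)
  if (forces) {
    list(energy = res$energy, breakdown = breakdown,
         forces = res$forces / s, torques = res$torques)
  } else {
    structure(res$energy, breakdown = breakdown)
  }
}

#' Langevin dynamics settings
#'
#' @param dt time step, reduced units (sigma = 1, m = 1, kT = 1).
#' @param steps number of steps.
#' @param friction,friction_rot translational / rotational Langevin drag
#'   rates; 0 gives microcanonical (NVE) dynamics.
#' @param seed RNG seed for thermal noise and initial velocities.
#' @param stride snapshot stride (0 = final state only).
#' @param energy_stride energy bookkeeping stride (0 = start/end only).
#' @param check_nve run the short NVE energy-conservation precondition
#'   (drift < `nve_tol` over `nve_steps` frictionless steps) before the
#'   production run?
#' @param nve_steps,nve_tol precondition parameters.
#' @return An object of class `sim_settings`.
#' @export
sim_settings <- function(dt = 0.002, steps = 10000L, friction = 1,
                         friction_rot = 3, seed = 1, stride = 0L,
                         energy_stride = 0L, check_nve = TRUE,
                         nve_steps = 100L, nve_tol = 0.01) {
  if (dt <= 0) stopf("dt must be > 0")
  if (steps < 1) stopf("steps must be >= 1")
  structure(list(dt = dt, steps = as.integer(steps), friction = friction,
                 friction_rot = friction_rot, seed = seed,
                 stride = as.integer(stride),
                 energy_stride = as.integer(energy_stride),
                 check_nve = isTRUE(check_nve),
                 nve_steps = as.integer(nve_steps), nve_tol = nve_tol),
            class = "sim_settings")
}

#' Run rigid-body Langevin dynamics of the patchy-particle model
#'
#' BAOAB Langevin integration for translations plus the rotational analogue
#' on unit quaternions (isotropic inertia). Velocities are drawn from the
#' Maxwell-Boltzmann distribution at the model temperature. Before the
#' production run a short frictionless (NVE) check verifies that the time
#' step conserves total energy to better than `nve_tol` (relative to the
#' larger of |E(0)| and the equipartition kinetic scale 3 N kT); a failing
#' check is an error asking for a smaller `dt`. Deterministic given the
#' settings seed; with a bottom wall particles cannot pass below z = 0.
#'
#' @param initial a [sphere_assembly()]; orientations default to random
#'   (seeded) because patch dynamics with all-identical orientations is a
#'   measure-zero artefact.
#' @param model a [patchy_model()].
#' @param settings a [sim_settings()].
#' @return An object of class `patchy_trajectory`: `final` (assembly with
#'   orientations), `snapshots` (list of assemblies, possibly empty),
#'   `energy_series` (data frame: time, potential, kinetic in kT),
#'   `model`, `settings`.
#' @export
run_langevin <- function(initial, model = patchy_model(), settings = sim_settings()) {
  s <- model$diameter
  n <- nrow(initial$positions)
  wall <- assembly_wall_mode(initial)
  pos <- initial$positions / s
  box <- initial$box / s
  state <- with_seed(settings$seed, {
    quat <- initial$orientations %||% random_quats(n)
    vel <- matrix(rnorm(3 * n, sd = sqrt(model$temperature)), n, 3)
    angvel <- matrix(rnorm(3 * n, sd = sqrt(model$temperature / 0.1)), n, 3)
    list(quat = quat, vel = vel, angvel = angvel)
  })
  cppm <- model_to_cpp(model)
  if (settings$check_nve && settings$friction > 0) {
    chk <- cpp_patchy_run(pos, state$quat, state$vel, state$angvel, cppm, box,
                          initial$periodic, wall, settings$dt,
                          settings$nve_steps, 0, 0, model$temperature,
                          settings$seed, 0L, 1L)
    es <- chk$energy_series
    etot <- es$potential + es$kinetic
    drift <- max(abs(etot - etot[1])) /
      max(abs(etot[1]), 3 * n * model$temperature)
    if (drift > settings$nve_tol)
      stopf("NVE precondition failed: %.2f%% energy drift over %d steps; reduce dt",
            100 * drift, settings$nve_steps)
  }
  res <- cpp_patchy_run(pos, state$quat, state$vel, state$angvel, cppm, box,
                        initial$periodic, wall, settings$dt, settings$steps,
                        settings$friction, settings$friction_rot,
                        model$temperature, settings$seed,
                        settings$stride, settings$energy_stride)
  mk_assembly <- function(p, q) {
    sphere_assembly(p * s, initial$radii, initial$box, initial$periodic,
                    orientations = q / sqrt(rowSums(q^2)),
                    labels = initial$labels,
                    meta = c(initial$meta[setdiff(names(initial$meta), "stage")],
                             list(stage = "langevin", seed = settings$seed)))
  }
  snaps <- lapply(res$snapshots, function(sn) mk_assembly(sn$pos, sn$quat))
  structure(list(final = mk_assembly(res$pos, res$quat),
                 snapshots = snaps,
                 energy_series = res$energy_series,
                 model = model, settings = settings),
            class = "patchy_trajectory")
}

#' @export
print.patchy_trajectory <- function(x, ...) {
  es <- x$energy_series
  cat(sprintf("<patchy_trajectory> N = %d, %d steps (dt %.4g), U(final) = %.4g kT\n",
              nrow(x$final$positions), x$settings$steps, x$settings$dt,
              es$potential[nrow(es)]))
  invisible(x)
}

#' Dilute gas initial configuration for sedimentation runs
#'
#' Particles on a jittered cubic grid filling a laterally periodic box with a
#' walled z axis, the standard starting point for gravity quenches.
#'
#' @param n particle count.
#' @param model a [patchy_model()] (sets the diameter).
#' @param lateral box edge in x and y, units of the diameter.
#' @param height box height, units of the diameter (must fit the grid).
#' @param seed jitter seed.
#' @return A [sphere_assembly()].
#' @export
initial_gas <- function(n, model = patchy_model(), lateral = 10, height = 36,
                        seed = 1) {
  s <- model$diameter
  L <- lateral * s
  Lz <- height * s
  spacing <- 1.25 * s
  per_layer <- floor(L / spacing)^2
  layers <- ceiling(n / per_layer)
  zmax <- 0.8 * s + layers * spacing
  if (zmax > Lz - s) stopf("box height %.3g d too small for %d particles", height, n)
  k <- floor(L / spacing)
  pos <- matrix(0, n, 3)
  i <- 0
  for (lz in seq_len(layers)) {
    for (iy in seq_len(k)) for (ix in seq_len(k)) {
      if (i >= n) break
      i <- i + 1
      pos[i, ] <- c((ix - 0.5) * spacing, (iy - 0.5) * spacing,
                    0.8 * s + (lz - 0.5) * spacing)
    }
  }
  # truncated jitter: bounds the closest possible approach at ~1.05 sigma so
  # no seed can start with a deep overlap of the stiff potential
  pos <- with_seed(seed, pos + 0.05 * s *
                     matrix(pmin(pmax(rnorm(3 * n), -2), 2), n, 3))
  pos[, 1] <- pos[, 1] %% L
  pos[, 2] <- pos[, 2] %% L
  pos[, 3] <- pmin(pmax(pos[, 3], 0.6 * s), Lz - 0.6 * s)
  sphere_assembly(pos, s / 2, c(L, L, Lz), periodic = c(TRUE, TRUE, FALSE),
                  meta = list(stage = "initial_gas", seed = seed))
}

# --- sediment bed analysis -------------------------------------------------

# packing-fraction profile in z slabs (exact sphere-slab volumes)
phi_profile <- function(a, slab = NULL) {
  s <- 2 * mean(a$radii)
  slab <- slab %||% (s / 4)
  zmax <- a$box[3]
  edges <- seq(0, zmax, by = slab)
  if (edges[length(edges)] < zmax) edges <- c(edges, zmax)
  area <- a$box[1] * a$box[2]
  zc <- a$positions[, 3]
  r <- a$radii
  # cumulative sphere volume below each edge
  vol_below <- vapply(edges, function(z) {
    h <- pmin(pmax(z - (zc - r), 0), 2 * r)
    sum(pi * h^2 * (3 * r - h) / 3)
  }, 0)
  phi <- diff(vol_below) / (area * diff(edges))
  data.frame(z_lo = edges[-length(edges)], z_hi = edges[-1],
             z_mid = (edges[-1] + edges[-length(edges)]) / 2, phi = phi)
}

# top surface of the settled bed: highest slab holding >= half the peak density
bed_surface <- function(a, prof = NULL) {
  prof <- prof %||% phi_profile(a)
  if (all(prof$phi <= 0)) return(0)
  k <- 3
  sm <- stats::filter(prof$phi, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- prof$phi[is.na(sm)]
  thr <- 0.5 * max(sm)
  idx <- which(sm >= thr)
  prof$z_hi[max(idx)]
}

#' Bulk region and statistics of a settled sediment
#'
#' The bulk excludes particles within `exclude` diameters of the bottom wall
#' and of the free surface (detected as the highest slab at half the peak
#' slab density), so boundary layering does not bias bed statistics.
#'
#' @param a a settled [sphere_assembly()] (walled z axis).
#' @param exclude boundary exclusion, particle diameters.
#' @return List: `phi` (mean slab packing fraction in the bulk), `z_range`,
#'   `bulk` (logical particle selector), `surface` (bed surface height, nm).
#' @export
sediment_bulk <- function(a, exclude = 1.5) {
  s <- 2 * mean(a$radii)
  prof <- phi_profile(a)
  zs <- bed_surface(a, prof)
  zlo <- exclude * s
  zhi <- zs - exclude * s
  if (zhi <= zlo) {  # no bulk (thin or dilute bed): fall back to everything below surface
    zlo <- 0
    zhi <- max(zs, a$box[3] * (zs <= 0))
    if (zhi <= 0) zhi <- a$box[3]
  }
  sel <- prof$z_lo >= zlo & prof$z_hi <= zhi
  phi <- if (any(sel)) mean(prof$phi[sel]) else
    sum(4 / 3 * pi * a$radii^3) / (a$box[1] * a$box[2] * zhi)
  bulk <- a$positions[, 3] >= zlo & a$positions[, 3] <= zhi
  list(phi = phi, z_range = c(zlo, zhi), bulk = bulk, surface = zs,
       profile = prof)
}

#' Tune gravity so a sediment equilibrates to a target packing fraction
#'
#' Bisection on the gravity strength g: each trial settles a dilute gas of
#' `n` particles under the model with that g and measures the bulk packing
#' fraction of the final bed (boundary layers excluded); the bed density
#' grows monotonically with g in the disordered regime, so the bracket is
#' halved geometrically until the bed lands within `tol` of the target.
#'
#' @param model a [patchy_model()] (its `gravity` field is ignored).
#' @param target_phi target bulk packing fraction, in (0, 0.74).
#' @param settings a [sim_settings()]; the default runs 93000 steps of
#'   dt = 0.003 (280 reduced time units), the package's standard
#'   sedimentation protocol.
#' @param n particle count.
#' @param lateral,height box dimensions in diameters (see [initial_gas()]).
#' @param g_bracket gravity bracket, kT/nm; the default spans the
#'   disordered-sediment regime (about 0.4-1.5 kT per diameter), which covers
#'   bed densities of roughly 0.40-0.55 -- pass a wider bracket for targets
#'   outside it.
#' @param tol acceptance band around the target.
#' @param max_iter bisection budget; exhausting it is an error reporting the
#'   achieved bracket.
#' @return List of class `sediment_fit`: `assembly`, `achieved_phi`,
#'   `gravity` (kT/nm), `history` (data frame g, phi), `trajectory`.
#' @export
equilibrate_to_density <- function(model, target_phi, settings = NULL,
                                   n = 1080, lateral = 10, height = 36,
                                   g_bracket = NULL, tol = 0.02,
                                   max_iter = 8L) {
  if (target_phi <= 0 || target_phi >= 0.74)
    stopf("target_phi must lie in (0, 0.74)")
  settings <- settings %||% sim_settings(dt = 0.003, steps = 93000L,
                                         friction = 1, friction_rot = 3,
                                         seed = 1)
  g_bracket <- g_bracket %||% (c(0.4, 1.5) / model$diameter)
  glo <- g_bracket[1]; ghi <- g_bracket[2]
  init <- initial_gas(n, model, lateral, height, seed = settings$seed)
  hist_g <- numeric(); hist_phi <- numeric()
  best <- NULL
  for (it in seq_len(max_iter)) {
    g <- sqrt(glo * ghi)
    m <- model
    m$gravity <- g
    tr <- run_langevin(init, m, settings)
    bulk <- sediment_bulk(tr$final)
    hist_g <- c(hist_g, g); hist_phi <- c(hist_phi, bulk$phi)
    if (is.null(best) || abs(bulk$phi - target_phi) < abs(best$achieved_phi - target_phi))
      best <- list(assembly = tr$final, achieved_phi = bulk$phi, gravity = g,
                   trajectory = tr)
    if (abs(bulk$phi - target_phi) <= tol) {
      return(structure(list(assembly = tr$final, achieved_phi = bulk$phi,
                            gravity = g,
                            history = data.frame(g = hist_g, phi = hist_phi),
                            trajectory = tr),
                       class = "sediment_fit"))
    }
    if (bulk$phi < target_phi) glo <- g else ghi <- g
    if (ghi / glo < 1.0001) break
  }
  stopf(paste("target phi %.3g unreachable in gravity bracket [%.3g, %.3g] kT/nm;",
              "closest achieved phi = %.3g at g = %.3g"),
        target_phi, g_bracket[1], g_bracket[2], best$achieved_phi, best$gravity)
}

#' @export
print.sediment_fit <- function(x, ...) {
  cat(sprintf("<sediment_fit> achieved phi = %.4f at g = %.4g kT/nm (%d trials)\n",
              x$achieved_phi, x$gravity, nrow(x$history)))
  invisible(x)
}
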