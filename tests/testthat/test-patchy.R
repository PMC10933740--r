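test_that("radial potentials follow the 2n-n Lennard-Jones algebra", {
  m <- patchy_model()
  s <- m$diameter
  # minimum location 2^(1/24) sigma, depth -eps, zero at sigma
  rmin <- optimize(function(r) radial_potential(r, "patch_lj", m),
                   c(0.9 * s, 1.2 * s), tol = 1e-10)$minimum
  expect_equal(rmin / s, 2^(1 / 24), tolerance = 1e-6)
  expect_equal(radial_potential(s, "patch_lj", m), 0, tolerance = 1e-12)
  expect_equal(radial_potential(2^(1 / 24) * s, "patch_lj", m), -m$eps_patch,
               tolerance = 1e-10)
  expect_equal(radial_potential(2^(1 / 24) * s, "body_lj", m), -m$eps_body,
               tolerance = 1e-10)
  # WCA: zero at/beyond the cutoff, continuous with flat derivative there
  rc <- 2^(1 / 24) * s
  expect_equal(radial_potential(rc, "wca", m), 0, tolerance = 1e-10)
  expect_equal(radial_potential(rc + 1e-9, "wca", m), 0)
  h <- 1e-6 * s
  slope <- (radial_potential(rc, "wca", m) -
            radial_potential(rc - h, "wca", m)) / h
  expect_lt(abs(slope), 1e-3)
  expect_error(radial_potential(c(100, -1), "wca", m), "positive")
})

test_that("patch alignment factor: construction, decay, exchange symmetry", {
  m <- patchy_model()
  v <- c(1, 1, 1) / sqrt(3)
  qi <- quat_between(v, c(1, 0, 0))
  qj <- quat_between(v, c(-1, 0, 0))
  r <- c(2^(1 / 24) * m$diameter, 0, 0)
  expect_equal(patch_alignment_factor(qi, qj, r, m), 1, tolerance = 1e-12)
  # worst alignment of one particle: centre line anti-parallel to a patch,
  # best remaining patch at acos(1/3) = 70.5 deg; partner perfectly aligned.
  # Frozen oracle: exp(-theta_w^2 / (2 delta^2)) with delta = 30 deg.
  th_w <- acos(1 / 3)
  q_worst <- quat_between(v, -c(1, 0, 0))   # patch 1 points along -x
  q_good <- quat_between(v, c(-1, 0, 0))    # partner faces the bond
  f <- patch_alignment_factor(q_worst, q_good, c(210, 0, 0), m)
  expect_equal(f, exp(-th_w^2 / (2 * (pi / 6)^2)), tolerance = 1e-9)
  expect_lt(f, 0.07)
  # exchange symmetry on random orientations
  set.seed(3)
  for (k in 1:5) {
    qa <- random_unit_quats(1, seed = k)[1, ]
    qb <- random_unit_quats(1, seed = k + 50)[1, ]
    rv <- rnorm(3)
    expect_equal(patch_alignment_factor(qa, qb, rv, m),
                 patch_alignment_factor(qb, qa, -rv, m), tolerance = 1e-12)
    expect_gte(patch_alignment_factor(qa, qb, rv, m), 0)
    expect_lte(patch_alignment_factor(qa, qb, rv, m), 1)
  }
})

test_that("patchy model validates the tetrahedral geometry", {
  expect_error(patchy_model(n_exp = 23), "even")
  expect_error(patchy_model(eps_patch = -1), ">= 0")
  bad_axes <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(-1, 0, 0))
  expect_error(patchy_model(patch_axes = bad_axes), "tetrahedral")
  dots <- tcrossprod(patchy_model()$patch_axes)
  expect_equal(unique(round(dots[upper.tri(dots)], 12)), -1 / 3)
})

test_that("total energy: bound dimer, lone particle, dilute gas", {
  s <- patchy_model()$diameter
  rmin <- 2^(1 / 24) * s
  v <- c(1, 1, 1) / sqrt(3)
  qi <- quat_between(v, c(1, 0, 0))
  qj <- quat_between(v, c(-1, 0, 0))
  dimer <- sphere_assembly(rbind(c(5 * s, 5 * s, 5 * s),
                                 c(5 * s + rmin, 5 * s, 5 * s)),
                           s / 2, rep(10 * s, 3),
                           orientations = rbind(qi, qj))
  # with the isotropic-cohesion variant both minima coincide: -(8 + 3) kT
  mlj <- patchy_model(body_mode = "lj")
  expect_equal(as.numeric(total_energy(dimer, mlj)),
               -(mlj$eps_patch + mlj$eps_body), tolerance = 1e-9)
  # default model: non-patch contacts repulsive, bond energy -eps_patch
  m <- patchy_model()
  expect_equal(as.numeric(total_energy(dimer, m)), -m$eps_patch,
               tolerance = 1e-9)
  # single particle at height z under gravity: U = g z (wall off at height)
  mg <- patchy_model(gravity = 0.002)
  one <- sphere_assembly(rbind(c(500, 500, 700)), 105, c(1000, 1000, 2000),
                         periodic = c(TRUE, TRUE, FALSE))
  e <- total_energy(one, mg)
  expect_equal(as.numeric(e), 0.002 * 700, tolerance = 1e-9)
  # all pairs beyond cutoff: zero energy
  far <- sphere_assembly(rbind(c(0, 0, 0), c(1000, 0, 0), c(0, 1000, 0)) + 200,
                         105, rep(3000, 3))
  expect_equal(as.numeric(total_energy(far, m)), 0)
  # translation invariance along periodic axes
  d2 <- dimer
  d2$positions <- sweep(d2$positions, 2, c(313, -97, 55), "+")
  expect_equal(as.numeric(total_energy(d2, m)),
               as.numeric(total_energy(dimer, m)), tolerance = 1e-10)
})

test_that("forces and torques are exact gradients of the energy", {
  m <- patchy_model(gravity = 0.001)
  s <- m$diameter
  a <- rsa_assembly(14, box = rep(4 * s, 3), min_sep = 0.95 * s, radius = s / 2,
                    periodic = c(TRUE, TRUE, FALSE), seed = 23)
  a$positions[, 3] <- 0.6 * s + a$positions[, 3] * (4 * s - 1.2 * s) / (4 * s)
  a$orientations <- random_unit_quats(14, seed = 24)
  ef <- total_energy(a, m, forces = TRUE)
  h <- 1e-5 * s
  for (i in c(1, 5, 9)) for (ax in 1:3) {
    ap <- a; ap$positions[i, ax] <- ap$positions[i, ax] + h
    am <- a; am$positions[i, ax] <- am$positions[i, ax] - h
    fnum <- -(as.numeric(total_energy(ap, m)) -
              as.numeric(total_energy(am, m))) / (2 * h)
    expect_equal(ef$forces[i, ax], fnum,
                 tolerance = 1e-6 * max(1, abs(fnum)))
  }
  # torques against rotational central differences about each axis
  for (i in c(2, 7)) for (ax in 1:3) {
    axis <- c(0, 0, 0); axis[ax] <- 1
    dth <- 1e-6
    rotq <- function(th) c(cos(th / 2), sin(th / 2) * axis)
    qmul <- function(p, q) c(
      p[1]*q[1] - p[2]*q[2] - p[3]*q[3] - p[4]*q[4],
      p[1]*q[2] + p[2]*q[1] + p[3]*q[4] - p[4]*q[3],
      p[1]*q[3] - p[2]*q[4] + p[3]*q[1] + p[4]*q[2],
      p[1]*q[4] + p[2]*q[3] - p[3]*q[2] + p[4]*q[1])
    ap <- a; ap$orientations[i, ] <- qmul(rotq(dth), a$orientations[i, ])
    am <- a; am$orientations[i, ] <- qmul(rotq(-dth), a$orientations[i, ])
    tnum <- -(as.numeric(total_energy(ap, m)) -
              as.numeric(total_energy(am, m))) / (2 * dth)
    expect_equal(ef$torques[i, ax], tnum,
                 tolerance = 1e-5 * max(1, abs(tnum)))
  }
})

test_that("with eps_patch = 0 and no gravity the model is plain LJ spheres", {
  m <- patchy_model(eps_patch = 0, eps_body = 3, body_mode = "lj")
  s <- m$diameter
  for (r in c(0.97, 1.0, 2^(1 / 24), 1.1, 1.4) * s) {
    pair <- sphere_assembly(rbind(c(4 * s, 4 * s, 4 * s),
                                  c(4 * s + r, 4 * s, 4 * s)), s / 2,
                            rep(8 * s, 3),
                            orientations = random_unit_quats(2, seed = 31))
    expect_equal(as.numeric(total_energy(pair, m)),
                 radial_potential(r, "body_lj", m), tolerance = 1e-10,
                 info = r)
  }
})

test_that("frictionless dynamics conserves energy; runs are seeded", {
  m <- patchy_model()
  s <- m$diameter
  rmin <- 2^(1 / 24) * s
  v <- c(1, 1, 1) / sqrt(3)
  dimer <- sphere_assembly(rbind(c(5 * s, 5 * s, 5 * s),
                                 c(5 * s + rmin, 5 * s, 5 * s)),
                           s / 2, rep(10 * s, 3),
                           orientations = rbind(quat_between(v, c(1, 0, 0)),
                                                quat_between(v, c(-1, 0, 0))))
  tr <- run_langevin(dimer, m, sim_settings(dt = 0.002, steps = 10000,
                                            friction = 0, friction_rot = 0,
                                            seed = 3, energy_stride = 200,
                                            check_nve = FALSE))
  es <- tr$energy_series
  etot <- es$potential + es$kinetic
  expect_lt(max(abs(etot - etot[1])) / abs(etot[1]), 0.01)
  # determinism: identical seeds give bit-identical trajectories
  st <- sim_settings(dt = 0.004, steps = 500, seed = 11, check_nve = FALSE)
  g <- initial_gas(40, m, lateral = 4, height = 12, seed = 2)
  t1 <- run_langevin(g, m, st)
  t2 <- run_langevin(g, m, st)
  expect_identical(t1$final$positions, t2$final$positions)
  expect_identical(t1$final$orientations, t2$final$orientations)
  t3 <- run_langevin(g, m, sim_settings(dt = 0.004, steps = 500, seed = 12,
                                        check_nve = FALSE))
  expect_false(identical(t1$final$positions, t3$final$positions))
  # the bottom wall is impenetrable
  mg <- patchy_model(gravity = 1 / 210)
  trg <- run_langevin(g, mg, sim_settings(dt = 0.004, steps = 3000, seed = 5,
                                          check_nve = FALSE))
  expect_true(all(trg$final$positions[, 3] > 0))
})

test_that("the NVE precondition rejects oversized time steps", {
  m <- patchy_model()
  g <- initial_gas(30, m, lateral = 4, height = 10, seed = 6)
  expect_error(run_langevin(g, m, sim_settings(dt = 0.15, steps = 100,
                                               seed = 1)),
               "NVE precondition|instability")
})

test_that("gravity strength separates open beds from dense 8-coordinated ones", {
  # dense limit: strong gravity crushes the gel into a high-coordination bed
  # whose modal touching-neighbour count is 8 (the weak-gravity tetrahedral
  # regime is covered by the sediment benchmark test)
  gm <- patchy_model(gravity = 4 / 210)
  init <- initial_gas(500, gm, lateral = 7, height = 30)
  tr <- run_langevin(init, gm, sim_settings(dt = 0.003, steps = 80000L,
                                            seed = 1))
  bulk <- sediment_bulk(tr$final)
  deg <- contact_graph(tr$final, 15)$degree[bulk$bulk]
  h <- table(deg)
  expect_equal(as.integer(names(h)[which.max(h)]), 8L)
  expect_gt(mean(deg), 7)
  expect_gt(bulk$phi, 0.55)
})
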