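test_that("spherical harmonics satisfy closed-form identities", {
  expect_equal(spherical_harmonic(0, 0, 0.7, 1.3), complex(real = 1 / sqrt(4 * pi)))
  # P_6(1) = 1 at the pole
  expect_equal(spherical_harmonic(6, 0, 0, 0), complex(real = sqrt(13 / (4 * pi))))
  set.seed(21)
  for (l in c(4, 6)) {
    theta <- runif(5, 0, pi)
    phi <- runif(5, -pi, pi)
    # addition theorem
    s <- Reduce(`+`, lapply(-l:l, function(m)
      Mod(spherical_harmonic(l, m, theta, phi))^2))
    expect_equal(s, rep((2 * l + 1) / (4 * pi), 5), tolerance = 1e-12)
    # conjugation symmetry
    for (m in 1:l)
      expect_equal(spherical_harmonic(l, -m, theta, phi),
                   (-1)^m * Conj(spherical_harmonic(l, m, theta, phi)),
                   tolerance = 1e-12)
    # against the independent table oracle
    for (m in -l:l)
      expect_equal(spherical_harmonic(l, m, theta, phi),
                   ylm_table(l, m, theta, phi), tolerance = 1e-12)
  }
  expect_error(spherical_harmonic(4, 5, 0.3, 0.3), "<= l")
})

test_that("q_l invariant: single bond gives 1, random bonds decay", {
  box <- rep(1000, 3)
  a <- sphere_assembly(rbind(c(500, 500, 500), c(500, 500, 700)), 90, box)
  for (l in c(4, 6)) {
    qlm <- qlm_vector(a, 1, 2, l)
    expect_equal(ql_invariant(qlm, l), 1, tolerance = 1e-12)
  }
  # isotropically random bonds: q_l ~ N^{-1/2} scaling
  set.seed(5)
  qls <- vapply(c(50, 800), function(nb) {
    u <- matrix(rnorm(3 * nb), nb, 3)
    mean(replicate(12, oracle_ql(matrix(rnorm(3 * nb), nb, 3), 6)))
  }, 0)
  expect_lt(qls[2], qls[1])
  expect_equal(qls[1] / qls[2], sqrt(800 / 50), tolerance = 0.35)
  # zero neighbours: flagged missing, not an error
  expect_true(all(is.na(qlm_vector(a, 1, integer(), 4))))
})

test_that("lattice invariants match the independent brute-force oracle", {
  # simple cubic: textbook q4 = sqrt(7/12)
  sc_bonds <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                    c(0, 0, 1), c(0, 0, -1))
  expect_equal(oracle_ql(sc_bonds, 4), sqrt(7 / 12), tolerance = 1e-12)
  a_sc <- build_lattice("sc", c(3, 3, 3), a = 210)
  b_sc <- averaged_boo(a_sc, gap_tol = 15)
  expect_equal(unname(b_sc$mean["q4"]), sqrt(7 / 12), tolerance = 1e-10)

  # fcc, hcp, diamond: package values vs direct sums over ideal bond sets
  for (k in c("fcc", "hcp", "diamond")) {
    lat <- build_lattice(k, c(3, 3, 3), a = 210)
    g <- contact_graph(lat, gap_tol = 15)
    b <- averaged_boo(lat, gap_tol = 15)
    nb <- c(g$edges[g$edges[, 1] == 1, 2], g$edges[g$edges[, 2] == 1, 1])
    d <- sweep(lat$positions[nb, , drop = FALSE], 2, lat$positions[1, ])
    for (ax in 1:3)
      d[, ax] <- d[, ax] - lat$box[ax] * round(d[, ax] / lat$box[ax])
    for (l in c(4, 6)) {
      expect_equal(unname(b$mean[paste0("q", l)]), oracle_ql(d, l),
                   tolerance = 1e-9, info = paste(k, l))
    }
  }
  # published Steinhardt values
  fcc <- averaged_boo(build_lattice("fcc", c(3, 3, 3), a = 210), 15)
  expect_equal(unname(fcc$mean["q6"]), 0.5745, tolerance = 1e-3)
  expect_equal(unname(fcc$mean["q4"]), 0.1909, tolerance = 1e-3)
  hcp <- averaged_boo(build_lattice("hcp", c(3, 3, 3), a = 210), 15)
  expect_equal(unname(hcp$mean["q6"]), 0.4848, tolerance = 1e-3)
  dia <- averaged_boo(build_lattice("diamond", c(3, 3, 3), a = 210), 15)
  expect_equal(unname(dia$mean["q4"]), 0.5092, tolerance = 1e-3)
  expect_equal(unname(dia$mean["q6"]), 0.6285, tolerance = 1e-3)
  # perfect lattices are homogeneous: per-particle spread is zero
  expect_equal(sd(dia$particles$q4), 0, tolerance = 1e-10)
  expect_equal(sd(dia$particles$q4bar), 0, tolerance = 1e-10)
})

test_that("q_l is invariant under global rotations to 1e-10", {
  a <- rsa_assembly(60, box = rep(1200, 3), min_sep = 170, radius = 85,
                    periodic = c(FALSE, FALSE, FALSE), seed = 13)
  b0 <- averaged_boo(a, gap_tol = 60)
  set.seed(14)
  for (rep in 1:3) {
    R <- rotmat(rnorm(3), runif(1, 0.2, 2.8))
    ctr <- a$box / 2
    rotpos <- sweep(sweep(a$positions, 2, ctr) %*% t(R), 2, ctr, "+")
    # keep everything in the box: use a larger walled box, same geometry
    sh <- 1200
    ar <- sphere_assembly(rotpos + sh, a$radii, a$box + 2 * sh,
                          periodic = c(FALSE, FALSE, FALSE))
    br <- averaged_boo(ar, gap_tol = 60)
    expect_equal(br$mean, b0$mean, tolerance = 1e-10)
  }
})

test_that("agreement with the direct oracle on random assemblies to 1e-9", {
  a <- rsa_assembly(80, box = rep(1400, 3), min_sep = 170, radius = 85,
                    periodic = c(FALSE, FALSE, FALSE), seed = 17)
  g <- contact_graph(a, gap_tol = 80)
  b <- averaged_boo(a, gap_tol = 80)
  nbrs <- lapply(seq_len(g$n), function(i)
    c(g$edges[g$edges[, 1] == i, 2], g$edges[g$edges[, 2] == i, 1]))
  for (i in which(g$degree > 0)) {
    d <- sweep(a$positions[nbrs[[i]], , drop = FALSE], 2, a$positions[i, ])
    for (l in c(4, 6))
      expect_equal(b$particles[[paste0("q", l)]][i], oracle_ql(d, l),
                   tolerance = 1e-9)
  }
})

test_that("reference points regenerate deterministically and classify", {
  refs <- reference_points(mrj_n = 300, mrj_seed = 7)
  refs2 <- reference_points(gap_tol = 15, mrj_n = 300, mrj_seed = 7)
  expect_equal(refs, refs2)
  expect_setequal(refs$label, c("hcp", "bcc", "fcc", "diamond", "mrj"))
  # exact reference coordinates in: zero distance, right label
  fcc <- refs[refs$label == "fcc", ]
  cls <- classify_structure(fcc$q4, fcc$q6, refs)
  expect_equal(cls$label, "fcc")
  expect_equal(cls$distances$distance[1], 0)
  expect_false(cls$tie)
  # equidistant point: reported as a tie
  two <- data.frame(label = c("a", "b"), q4 = c(0, 1), q6 = c(0, 0),
                    provenance = "computed")
  tie <- classify_structure(0.5, 0.3, two)
  expect_true(tie$tie)
  expect_setequal(tie$label, c("a", "b"))
  # the MRJ point is distinct from diamond and classifies as itself
  mrj <- refs[refs$label == "mrj", ]
  dia <- refs[refs$label == "diamond", ]
  expect_gt(sqrt((mrj$q4 - dia$q4)^2 + (mrj$q6 - dia$q6)^2), 0.1)
  cls2 <- classify_structure(mrj$q4, mrj$q6, refs)
  expect_equal(cls2$label, "mrj")
})

test_that("jittered diamond lattices still classify as diamond", {
  lat <- build_lattice("diamond", c(3, 3, 3), a = 210)
  f <- 210 / (2 * lat$radii[1])
  lat <- rescale_assembly(lat, f)   # diameters 210 nm, criterion-compatible
  refs <- reference_points(mrj_n = 300, mrj_seed = 7)
  for (seed in 1:3) {
    pert <- perturb_assembly(lat, amplitude = 2, seed = seed)
    b <- averaged_boo(pert, gap_tol = 15)
    cls <- classify_structure(b$mean["q4"], b$mean["q6"], refs)
    expect_equal(cls$label, "diamond", info = seed)
  }
})
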