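test_that("extended-XYZ writer/reader round-trips assemblies exactly", {
  a <- sphere_assembly(rbind(c(0, 0, 0), c(300, 0, 0)), 105, rep(1000, 3))
  f <- withr::local_tempfile(fileext = ".xyz")
  write_assembly(a, f)
  b <- read_assembly(f)
  expect_equal(nrow(b$positions), 2)
  expect_equal(b$positions, a$positions)
  expect_equal(b$radii, a$radii)
  expect_equal(b$box, a$box)
  # textual idempotence: write(read(f)) == f
  f2 <- withr::local_tempfile(fileext = ".xyz")
  write_assembly(b, f2)
  expect_identical(readLines(f), readLines(f2))

  # orientations and labels survive, with randomized content
  set.seed(11)
  q <- random_unit_quats(5, seed = 11)
  a2 <- sphere_assembly(matrix(runif(15, 10, 900), 5, 3),
                        runif(5, 50, 120), rep(1000, 3),
                        periodic = c(TRUE, FALSE, TRUE),
                        orientations = q, labels = c(3L, 1L, 4L, 1L, 5L))
  write_assembly(a2, f)
  b2 <- read_assembly(f)
  expect_equal(b2$orientations, a2$orientations, tolerance = 1e-12)
  expect_identical(b2$labels, a2$labels)
  expect_identical(b2$periodic, a2$periodic)
})

test_that("assembly reader rejects malformed input with line numbers", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", 'box="1000 1000 1000" boundary="p p p" columns="x y z r"',
               "0 0 0 105", "300 0 0 -5"), f)
  expect_error(read_assembly(f), "line 4")
  writeLines(c("2", 'boundary="p p p" columns="x y z r"',
               "0 0 0 105", "300 0 0 105"), f)
  expect_error(read_assembly(f), "missing box")
  writeLines(c("2", 'box="1000 1000 1000" boundary="p p p" columns="x y z r"',
               "0 0 0 105", "300 0 nonsense 105"), f)
  expect_error(read_assembly(f), "line 4")
  writeLines(c("2", 'box="1000 1000 1000" boundary="p p p" columns="x y z r"',
               "0 0 0 105"), f)
  expect_error(read_assembly(f), "expected 2 records")
})

test_that("assembly constructor enforces its invariants", {
  expect_error(sphere_assembly(rbind(c(0, 0, 0)), -1, rep(100, 3)), "radii")
  expect_error(sphere_assembly(rbind(c(0, 0, 500)), 10, rep(100, 3),
                               periodic = c(FALSE, FALSE, FALSE)),
               "outside the box")
  q <- matrix(c(2, 0, 0, 0), 1, 4)
  expect_error(sphere_assembly(rbind(c(50, 50, 50)), 10, rep(100, 3),
                               orientations = q), "unit quaternion")
  # periodic positions outside the box are fine (wrappable)
  expect_silent(sphere_assembly(rbind(c(-50, 250, 50)), 10, rep(100, 3)))
})

test_that("voxel volumes round-trip through NRRD and TIFF", {
  for (fmt in c("nrrd", "tiff-stack")) {
    ext <- if (fmt == "nrrd") ".nrrd" else ".tif"
    f <- withr::local_tempfile(fileext = ext)
    g <- array(0L, c(10, 10, 10))
    v <- voxel_volume(g, 15)
    write_volume(v, f, fmt)
    v2 <- read_volume(f, fmt)
    expect_identical(v2$grid, v$grid)
    expect_equal(sum(v2$grid), 0)
    expect_equal(v2$voxel_pitch, 15, tolerance = 1e-6)

    set.seed(4)
    g2 <- array(sample(0:2, 4 * 5 * 6, replace = TRUE), c(4, 5, 6))
    v3 <- voxel_volume(g2, 7.5, origin = c(1, 2, 3))
    write_volume(v3, f, fmt)
    v4 <- read_volume(f, fmt)
    expect_identical(v4$grid, v3$grid)
    expect_equal(v4$voxel_pitch, 7.5, tolerance = 1e-6)
    expect_equal(v4$origin, c(1, 2, 3))
  }
  expect_error(write_volume(voxel_volume(array(0L, c(2, 2, 2)), 1), "x.foo",
                            "foo"))
})

test_that("scattering profiles round-trip and validate", {
  q <- exp(seq(log(0.004), log(0.2), length.out = 50))
  I <- 100 / (1 + (q * 100)^2)
  p <- scattering_profile(q, I, sigma = 0.02 * I)
  f <- withr::local_tempfile(fileext = ".csv")
  write_profile(p, f)
  p2 <- read_profile(f)
  expect_equal(p2$q, p$q)
  expect_equal(p2$intensity, p$intensity)
  expect_equal(p2$sigma, p$sigma)
  expect_error(scattering_profile(c(1, 1, 2), c(1, 1, 1)), "increasing")
  expect_error(scattering_profile(c(1, 2), c(-1, 1)), "non-negative")
  expect_error(scattering_profile(c(1, 2), c(1, 1), sigma = c(0, 1)), "sigma")
})

test_that("run configuration requires a seed and reads YAML", {
  expect_error(run_config(), "seed")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 42", "contact_gap: 15", "scenario: saxs-roundtrip",
               "stages:", "  saxs:", "    d_mean: 218"), f)
  cfg <- read_config(f)
  expect_equal(cfg$seed, 42L)
  expect_equal(cfg$contact_gap, 15)
  expect_equal(cfg$stages$saxs$d_mean, 218)
  writeLines("contact_gap: 15", f)
  expect_error(read_config(f), "seed")
})
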