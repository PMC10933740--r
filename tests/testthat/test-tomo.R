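test_that("voxelization converges to the analytic sphere volume", {
  a <- sphere_assembly(rbind(c(500, 500, 500)), 105, rep(1000, 3),
                       periodic = c(FALSE, FALSE, FALSE))
  v5 <- voxelize(a, pitch = 5)
  vol5 <- sum(v5$grid) * 5^3
  expect_lt(abs(vol5 - 4 / 3 * pi * 105^3) / (4 / 3 * pi * 105^3), 0.02)
  # refinement monotonicity on the same fixture
  truth <- 4 / 3 * pi * 105^3 / 1000^3
  err <- vapply(c(20, 10, 5), function(p) {
    v <- voxelize(a, pitch = p)
    abs(mean(v$grid) - truth)
  }, 0)
  expect_true(all(diff(err) < 0))
  # empty assembly: all-zero grid
  empty <- sphere_assembly(matrix(0, 0, 3), numeric(0), rep(300, 3))
  expect_equal(sum(voxelize(empty, pitch = 15)$grid), 0)
  # memory guard
  expect_error(voxelize(a, pitch = 0.5, max_voxels = 1e6), "pitch")
})

test_that("degradation: identity, volumetric shrink law, determinism", {
  a <- sphere_assembly(rbind(c(500, 500, 500)), 105, rep(1000, 3),
                       periodic = c(FALSE, FALSE, FALSE))
  vol <- voxelize(a, pitch = 5)
  id <- degrade(vol, degradation_spec(shrink_factor = 1, deform_amplitude = 0,
                                      noise_rate = 0, seed = 1))
  expect_identical(id$grid, vol$grid)
  # shrink 0.8: occupied volume ratio ~ 0.8^3 within 5%
  sh <- degrade(vol, degradation_spec(shrink_factor = 0.8,
                                      deform_amplitude = 0, noise_rate = 0,
                                      seed = 1))
  expect_equal(sum(sh$grid) / sum(vol$grid), 0.8^3, tolerance = 0.05)
  # deterministic given the seed, sensitive to it
  d1 <- degrade(vol, degradation_spec(0.85, 8, 25, 0.01, seed = 4))
  d2 <- degrade(vol, degradation_spec(0.85, 8, 25, 0.01, seed = 4))
  d3 <- degrade(vol, degradation_spec(0.85, 8, 25, 0.01, seed = 5))
  expect_identical(d1$grid, d2$grid)
  expect_false(identical(d1$grid, d3$grid))
})

test_that("extraction recovers isolated spheres and degenerate grids", {
  pos <- rbind(c(300, 300, 300), c(750, 400, 350), c(450, 750, 700))
  a <- sphere_assembly(pos, 105, rep(1050, 3), periodic = c(FALSE, FALSE, FALSE))
  vol <- voxelize(a, pitch = 15)
  ext <- extract_spheres(vol)
  expect_equal(nrow(ext$positions), 3)
  # match recovered to true centres
  ord <- apply(ext$positions, 1, function(p)
    which.min(colSums((t(pos) - p)^2)))
  expect_setequal(ord, 1:3)
  err <- sqrt(rowSums((ext$positions - pos[ord, ])^2))
  expect_lt(max(err), 15)                       # within one voxel pitch
  expect_lt(max(abs(ext$radii - 105) / 105), 0.05)
  # empty volume: empty assembly, not an error
  e <- extract_spheres(voxel_volume(array(0L, c(8, 8, 8)), 15))
  expect_equal(nrow(e$positions), 0)
  # all-occupied grid: a single particle spanning the grid
  f <- extract_spheres(voxel_volume(array(1L, c(8, 8, 8)), 15))
  expect_equal(nrow(f$positions), 1)
  expect_equal(4 / 3 * pi * f$radii^3, 8^3 * 15^3, tolerance = 1e-6)
})

test_that("voxelize -> extract round-trips a dense disordered assembly", {
  jam <- generate_jammed_packing(200, polydispersity = 0.05, seed = 12,
                                 diameter = 210)
  # shrink radii a touch so most particle surfaces are separated
  a <- jam
  a$radii <- jam$radii * 0.95
  vol <- voxelize(a, pitch = 15)
  ext <- extract_spheres(vol, expected_radius = mean(a$radii))
  # particles wrapping the box faces are split into caps by the bounded
  # volume (as in a real tomogram), so counts are compared over the interior
  m <- 2 * mean(a$radii)
  interior <- function(p, box) p[, 1] > m & p[, 1] < box[1] - m &
    p[, 2] > m & p[, 2] < box[2] - m & p[, 3] > m & p[, 3] < box[3] - m
  wrap <- a$positions %% a$box[1]
  n_true <- sum(interior(wrap, a$box))
  n_rec <- sum(interior(ext$positions, ext$box))
  expect_lt(abs(n_rec - n_true) / n_true, 0.05)
  # interior packing fraction recovered within 0.03
  reg <- list(lo = rep(m, 3), hi = a$box - m)
  phi_t <- suppressWarnings(as.numeric(packing_fraction(a, "voxel_mc",
                                                        region = reg,
                                                        mc_points = 100000L)))
  keep <- interior(ext$positions, ext$box)
  phi_r <- sum(4 / 3 * pi * ext$radii[keep]^3) / prod(a$box - 2 * m)
  expect_lt(abs(phi_r - phi_t), 0.03)
  # recovered interior radii close to the generating ones
  expect_lt(abs(mean(ext$radii[keep]) - mean(a$radii)) / mean(a$radii), 0.06)
})

test_that("rescaling is linear and leaves phi and contacts invariant", {
  jam <- generate_jammed_packing(150, seed = 5, diameter = 208)
  expect_equal(mean(2 * jam$radii), 208, tolerance = 1e-9)
  up <- rescale_assembly(jam, 1.2)
  expect_equal(mean(2 * up$radii), 249.6, tolerance = 1e-9)
  expect_equal(suppressWarnings(as.numeric(packing_fraction(up))),
               suppressWarnings(as.numeric(packing_fraction(jam))),
               tolerance = 1e-12)
  # contact histogram identical when the gap scales with the assembly
  h0 <- n_touch_distribution(jam, gap_tol = 15)
  h1 <- n_touch_distribution(up, gap_tol = 15 * 1.2)
  expect_identical(h0$histogram, h1$histogram)
  expect_identical(rescale_assembly(jam, 1)$positions, jam$positions)
})

test_that("regularization sets one diameter and reports overlaps", {
  pos <- rbind(c(300, 300, 300), c(640, 300, 300), c(300, 700, 300))
  a <- sphere_assembly(pos, c(90, 100, 110), rep(1000, 3),
                       periodic = c(FALSE, FALSE, FALSE))
  reg <- regularize_spheres(a, 252)
  expect_equal(unique(2 * reg$radii), 252)
  expect_equal(reg$positions, a$positions)
  rep_ <- attr(reg, "overlap_report")
  expect_equal(rep_$n_overlaps, 0)  # 340 nm spacing > 252
  # shrink target below all spacings: zero overlaps again
  reg2 <- regularize_spheres(a, 100)
  expect_equal(attr(reg2, "overlap_report")$n_overlaps, 0)
  # force an overlap and check the depth bookkeeping
  reg3 <- regularize_spheres(a, 400)
  rep3 <- attr(reg3, "overlap_report")
  expect_gt(rep3$n_overlaps, 0)
  expect_equal(rep3$max_depth, 400 - 340, tolerance = 1e-9)
})

test_that("the full degradation chain preserves contact statistics", {
  jam <- generate_jammed_packing(200, polydispersity = 0.05, seed = 21,
                                 diameter = 252)
  g0 <- contact_graph(jam, gap_tol = 15)
  vol <- voxelize(jam, pitch = 15)
  dg <- degrade(vol, degradation_spec(shrink_factor = 1 / 1.2,
                                      deform_amplitude = 6,
                                      noise_rate = 0.001, seed = 2))
  ext <- extract_spheres(dg, expected_radius = mean(jam$radii) / 1.2)
  # match every (contracted-frame) truth particle to its nearest recovered
  # particle; boundary caps in the bounded volume stay unmatched
  truew <- (jam$positions %% jam$box[1]) / 1.2
  D2 <- outer(rowSums(truew^2), rep(1, nrow(ext$positions))) +
    outer(rep(1, nrow(truew)), rowSums(ext$positions^2)) -
    2 * truew %*% t(ext$positions)
  nn_idx <- apply(D2, 1, which.min)
  nn_d <- sqrt(D2[cbind(seq_len(nrow(truew)), nn_idx)])
  found <- nn_d < 0.5 * mean(jam$radii) / 1.2
  expect_gt(mean(found), 0.95)        # recovery rate of true particles
  # contact statistics after the 1.2x rescale + 252 nm regularization:
  # evaluate over recovered particles matched to interior truth particles
  m <- 2 * mean(jam$radii)
  tw <- jam$positions %% jam$box[1]
  sel_t <- tw[, 1] > m & tw[, 1] < jam$box[1] - m &
    tw[, 2] > m & tw[, 2] < jam$box[2] - m &
    tw[, 3] > m & tw[, 3] < jam$box[3] - m
  truth_nt <- mean(g0$degree[sel_t])
  corr <- regularize_spheres(rescale_assembly(ext, 1.2), 252)
  got_nt <- mean(contact_graph(corr, gap_tol = 15)$degree[nn_idx[sel_t & found]])
  expect_lt(abs(got_nt - truth_nt), 0.5)
})
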