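test_that("sphere form factor: normalization, first zero, Guinier limit", {
  expect_equal(sphere_form_factor(0, 105), 1)
  # first zero at qR = 4.4934 (root of tan x = x)
  R <- 105
  x0 <- uniroot(function(x) sin(x) - x * cos(x), c(3.5, 5.5), tol = 1e-12)$root
  expect_equal(x0, 4.4934, tolerance = 1e-4)
  expect_lt(sphere_form_factor(x0 / R, R), 1e-10)
  # Guinier: P(q) ~ exp(-q^2 Rg^2 / 3), Rg^2 = 3/5 R^2, to 1% for q Rg < 0.5
  Rg <- sqrt(3 / 5) * R
  q <- seq(0.01, 0.5, by = 0.05) / Rg
  expect_equal(sphere_form_factor(q, R), exp(-q^2 * Rg^2 / 3),
               tolerance = 0.01)
})

test_that("Percus-Yevick structure factor limits and compressibility", {
  q <- exp(seq(log(0.004), log(0.2), length.out = 120))
  expect_equal(py_structure_factor(q, 109, 0), rep(1, 120))
  # S(0) equals the PY compressibility at the blue-scale volume fraction
  expect_equal(py_structure_factor(0, 109, 0.49),
               (1 - 0.49)^4 / (1 + 2 * 0.49)^2, tolerance = 1e-10)
  expect_equal(py_structure_factor(1e-9, 109, 0.49),
               (1 - 0.49)^4 / (1 + 2 * 0.49)^2, tolerance = 1e-6)
  # high-q limit -> 1
  expect_equal(py_structure_factor(150 / 109, 109, 0.49), 1, tolerance = 1e-3)
  expect_error(py_structure_factor(q, 109, 0.8), "phi")
})

test_that("sticky hard spheres reduce to PY as tau grows; S(0) rises as tau falls", {
  q <- exp(seq(log(0.004), log(0.2), length.out = 150))
  for (phi in c(0.3, 0.49)) {
    s_py <- py_structure_factor(q, 109, phi)
    s_st <- sticky_hs_structure_factor(q, 109, phi, tau = 1e6)
    expect_lt(max(abs(s_py - s_st)), 1e-3)
  }
  expect_equal(sticky_hs_structure_factor(q, 109, 0, 0.2), rep(1, 150))
  # decreasing tau at fixed phi raises the zero-angle limit (compressibility
  # grows with attraction)
  s0 <- vapply(c(1e4, 10, 1, 0.5, 0.2),
               function(tau) sticky_hs_structure_factor(1e-4, 109, 0.3, tau), 0)
  expect_true(all(diff(s0) > 0))
  # unphysical corner of the Baxter solution is a clear error: at low phi the
  # quadratic loses its real roots once tau is small enough
  expect_error(sticky_hs_structure_factor(q, 109, 0.2, 0.05), "Baxter|discriminant")
})

test_that("model intensity: dilute limit, polydispersity damping, peak spacing", {
  q <- exp(seq(log(0.004), log(0.2), length.out = 200))
  p0 <- saxs_params(d_mean = 218, d_sd = 0, phi = 0, scale = 2.5,
                    background = 0.1)
  expect_equal(as.numeric(model_intensity(q, p0)),
               2.5 * sphere_form_factor(q, 109) + 0.1, tolerance = 1e-12)
  # 10% polydispersity fills in the form-factor minima by > 5x
  mono <- as.numeric(model_intensity(q, saxs_params(d_sd = 0, phi = 0)))
  poly <- as.numeric(model_intensity(q, saxs_params(d_sd = 21.8, phi = 0)))
  qmin <- q[which(q > 4.4934 / 109)[1]]
  i_at <- function(I) I[which.min(abs(q - qmin))]
  expect_gt(i_at(poly) / max(i_at(mono), 1e-15), 5)
  # structure-factor peak near 2 pi / mean spacing at phi ~ 0.5, with the
  # mean centre-centre spacing taken as the number-density scale rho^(-1/3)
  S <- py_structure_factor(q, 109, 0.5)
  qstar <- q[which.max(S)]
  spacing <- 218 * (pi / (6 * 0.5))^(1 / 3)
  expect_lt(abs(2 * pi / qstar - spacing) / spacing, 0.15)
})

test_that("Debye sum: single sphere, two-sphere closed form, S(q) peak", {
  q <- exp(seq(log(0.004), log(0.2), length.out = 80))
  one <- sphere_assembly(rbind(c(2000, 2000, 2000)), 109, rep(4000, 3),
                         periodic = c(FALSE, FALSE, FALSE))
  I1 <- debye_intensity(one, q)
  P <- sphere_form_factor(q, 109)
  expect_equal(I1 / I1[1], P / P[1], tolerance = 1e-10)
  # two spheres at distance D: I = 2 f^2 (1 + sinc(qD))
  D <- 500
  two <- sphere_assembly(rbind(c(2000, 2000, 2000), c(2000 + D, 2000, 2000)),
                         109, rep(4000, 3), periodic = c(FALSE, FALSE, FALSE))
  I2 <- debye_intensity(two, q)
  V <- 4 / 3 * pi * 109^3
  f <- V * 3 * (sin(q * 109) - q * 109 * cos(q * 109)) / (q * 109)^3
  expect_equal(I2, 2 * f^2 * (1 + sin(q * D) / (q * D)), tolerance = 1e-10)
  expect_error(debye_intensity(two, q, cap = 1), "cap")
})

test_that("Debye oracle agrees with the PY model on a jammed packing", {
  jam <- generate_jammed_packing(500, polydispersity = 0.03, seed = 9,
                                 diameter = 218)
  q <- exp(seq(log(0.01), log(0.1), length.out = 400))
  # point-scatterer Debye sum isolates the structure function of the packing
  pts <- jam
  pts$radii <- rep(1, nrow(jam$positions))
  Id <- debye_intensity(pts, q)
  S <- py_structure_factor(q, mean(jam$radii), jam$meta$phi)
  band <- q > 0.02 & q < 0.06
  qd <- q[band][which.max(Id[band])]
  qa <- q[band][which.max(S[band])]
  expect_lt(abs(qd - qa) / qa, 0.10)
})

test_that("round-trip SAXS fits recover the generating parameters", {
  # design grid: both beetle-scale parameter sets
  cases <- list(list(d = 254, sd = 28, phi = 0.53),
                list(d = 218, sd = 26, phi = 0.49))
  for (cs in cases) {
    truth <- saxs_params(d_mean = cs$d, d_sd = cs$sd, phi = cs$phi,
                         scale = 3, background = 1e-4)
    prof <- simulate_saxs_profile(truth, noise = 0.02, seed = 101)
    init <- saxs_params(d_mean = cs$d * 1.2, d_sd = cs$d * 0.05, phi = 0.35,
                        scale = 1, background = 1e-3)
    fit <- fit_saxs(prof, "py", init)
    expect_lt(abs(fit$params$d_mean - cs$d) / cs$d, 0.05)
    expect_lt(abs(fit$params$phi - cs$phi) / cs$phi, 0.05)
    expect_lt(abs(fit$params$d_sd - cs$sd) / cs$sd, 0.20)
  }
})

test_that("noise-free self-consistent fit converges immediately", {
  truth <- saxs_params(d_mean = 218, d_sd = 26, phi = 0.49, scale = 2)
  prof <- simulate_saxs_profile(truth, noise = 0, seed = 1)
  fit <- fit_saxs(prof, "py", init = truth)
  expect_lte(fit$niter, 3)
  expect_lt(fit$chisq_red, 1e-10)
})

test_that("sticky model on hard-sphere data drives tau to the PY limit", {
  truth <- saxs_params(d_mean = 218, d_sd = 26, phi = 0.49, scale = 2)
  prof <- simulate_saxs_profile(truth, model = "py", noise = 0.01, seed = 7)
  init <- saxs_params(d_mean = 230, d_sd = 20, phi = 0.4, tau = 2, scale = 1.5)
  fit <- fit_saxs(prof, "sticky", init)
  expect_gt(fit$params$tau, 50)
  expect_lt(abs(fit$params$d_mean - 218) / 218, 0.05)
  expect_lt(abs(fit$params$phi - 0.49) / 0.49, 0.05)
})

test_that("saxs_fit behaves like a standard R model object", {
  truth <- saxs_params(d_mean = 218, d_sd = 26, phi = 0.49)
  prof <- simulate_saxs_profile(truth, noise = 0.02, seed = 3)
  fit <- fit_saxs(prof, "py", saxs_params(d_mean = 240, d_sd = 20, phi = 0.4))
  expect_s3_class(fit, "saxs_fit")
  expect_named(coef(fit))
  expect_length(predict(fit), length(prof$q))
  expect_length(residuals(fit), length(prof$q))
  expect_equal(predict(fit, q = prof$q[1:5]),
               as.numeric(model_intensity(prof$q[1:5], fit$params, "py")))
  expect_output(print(fit), "saxs_fit")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
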