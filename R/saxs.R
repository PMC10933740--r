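#' SAXS model parameters for polydisperse sphere assemblies
#'
#' @param d_mean mean sphere diameter, nm.
#' @param d_sd Gaussian standard deviation of the diameter, nm.
#' @param phi hard-sphere volume fraction, in `[0, 0.74)`.
#' @param r_hs effective hard-sphere (interaction) radius, nm; defaults to
#'   `d_mean / 2` but is independently fittable since the interaction range
#'   need not equal the geometric radius.
#' @param tau Baxter stickiness parameter (sticky model only; larger = less
#'   sticky, the hard-sphere limit is `tau -> Inf`).
#' @param scale intensity scale factor.
#' @param background constant background.
#' @return An object of class `saxs_params`.
#' @export
saxs_params <- function(d_mean = 218, d_sd = 26, phi = 0.49, r_hs = NULL,
                        tau = 0.5, scale = 1, background = 0) {
  if (d_mean <= 0) stopf("d_mean must be > 0")
  if (d_sd < 0) stopf("d_sd must be >= 0")
  if (phi < 0 || phi >= 0.74) stopf("phi must lie in [0, 0.74)")
  structure(list(d_mean = d_mean, d_sd = d_sd, phi = phi,
                 r_hs = r_hs %||% (d_mean / 2), tau = tau, scale = scale,
                 background = background),
            class = "saxs_params")
}

#' Normalized sphere form factor P(q)
#'
#' `P(q) = [ 3 (sin(qR) - qR cos(qR)) / (qR)^3 ]^2`, continuously extended to
#' `P(0) = 1`. Its low-q limit is the Guinier law with `Rg^2 = (3/5) R^2`.
#'
#' @param q scattering vector(s), nm^-1 (>= 0).
#' @param R sphere radius, nm.
#' @return P(q) in `[0, 1]`.
#' @export
sphere_form_factor <- function(q, R) {
  if (R <= 0) stopf("R must be > 0")
  x <- q * R
  out <- numeric(length(x))
  small <- x < 1e-3
  out[small] <- (1 - x[small]^2 / 10)^2   # series of the amplitude, squared
  xb <- x[!small]
  out[!small] <- (3 * (sin(xb) - xb * cos(xb)) / xb^3)^2
  out
}

# G(A)-brackets of the Ashcroft-Lekner solution, series-stabilized near 0
py_t1 <- function(A) ifelse(A < 0.2, A^3 / 3 - A^5 / 30 + A^7 / 840,
                            sin(A) - A * cos(A))
py_t2 <- function(A) ifelse(A < 0.2, A^4 / 4 - A^6 / 36 + A^8 / 960,
                            2 * A * sin(A) + (2 - A^2) * cos(A) - 2)
py_t3 <- function(A) ifelse(A < 0.5, A^6 / 6 - A^8 / 48 + A^10 / 1200,
                            -A^4 * cos(A) +
                              4 * ((3 * A^2 - 6) * cos(A) + (A^3 - 6 * A) * sin(A) + 6))

#' Percus-Yevick hard-sphere structure factor
#'
#' Analytic Ashcroft-Lekner solution of the PY closure for hard spheres of
#' radius `r_hs` at volume fraction `phi`. `S(q) -> 1` at large q and
#' `S(0) = (1 - phi)^4 / (1 + 2 phi)^2` (the PY compressibility).
#'
#' @param q scattering vector(s), nm^-1.
#' @param r_hs hard-sphere radius, nm.
#' @param phi volume fraction, `[0, 0.74)`.
#' @return S(q).
#' @export
py_structure_factor <- function(q, r_hs, phi) {
  if (phi < 0 || phi >= 0.74) stopf("phi must lie in [0, 0.74)")
  if (phi == 0) return(rep(1, length(q)))
  al <- (1 + 2 * phi)^2 / (1 - phi)^4
  be <- -6 * phi * (1 + phi / 2)^2 / (1 - phi)^4
  ga <- phi * al / 2
  A <- 2 * q * r_hs            # q times hard-sphere diameter
  G <- al * py_t1(A) / A^2 + be * py_t2(A) / A^3 + ga * py_t3(A) / A^5
  # q = 0 exactly: closed-form compressibility limit
  S <- 1 / (1 + 24 * phi * G / A)
  S[A == 0] <- (1 - phi)^4 / (1 + 2 * phi)^2
  S
}

#' Baxter sticky-hard-sphere structure factor
#'
#' One-component Baxter adhesive-sphere model in the PY closure, computed
#' from the Wiener-Hopf factor function:
#' `S(q) = 1 / |Qhat(kappa)|^2` with
#' `Qhat(kappa) = 1 - 12 phi int_0^1 e^(i kappa u) q(u) du`,
#' `q(u) = a (u^2 - 1)/2 + b (u - 1) + lambda/12`, where `lambda` is the
#' smaller root of the Baxter quadratic
#' `phi/12 lambda^2 - (tau + phi/(1-phi)) lambda + (1 + phi/2)/(1-phi)^2 = 0`,
#' `mu = lambda phi (1 - phi)`, `a = (1 + 2 phi - mu)/(1-phi)^2`,
#' `b = (mu - 3 phi)/(2 (1-phi)^2)`. Reduces to the Percus-Yevick
#' hard-sphere solution as `tau -> Inf` (lambda -> 0).
#'
#' @param q scattering vector(s), nm^-1.
#' @param r_hs hard-sphere radius, nm.
#' @param phi volume fraction.
#' @param tau stickiness (> 0); parameter regions where the Baxter quadratic
#'   has no real root are an error naming the region.
#' @return S(q).
#' @export
sticky_hs_structure_factor <- function(q, r_hs, phi, tau) {
  if (phi < 0 || phi >= 0.74) stopf("phi must lie in [0, 0.74)")
  if (phi == 0) return(rep(1, length(q)))
  if (tau <= 0) stopf("tau must be > 0")
  aq <- phi / 12
  bq <- -(tau + phi / (1 - phi))
  cq <- (1 + phi / 2) / (1 - phi)^2
  disc <- bq^2 - 4 * aq * cq
  if (disc < 0)
    stopf("no real Baxter solution at phi = %.3g, tau = %.3g (discriminant < 0)",
          phi, tau)
  lam <- (-bq - sqrt(disc)) / (2 * aq)   # smaller root (physical branch)
  mu <- lam * phi * (1 - phi)
  a <- (1 + 2 * phi - mu) / (1 - phi)^2
  b <- (mu - 3 * phi) / (2 * (1 - phi)^2)
  kap <- 2 * q * r_hs
  Qhat <- vapply(kap, function(k) {
    if (k < 1e-6) {
      # int q(u) du = -a/3 - b/2 + lam/12
      return(complex(real = 1 - 12 * phi * (-a / 3 - b / 2 + lam / 12)))
    }
    ik <- 1i * k
    e <- exp(ik)
    I0 <- (e - 1) / ik
    I1 <- (e * (ik - 1) + 1) / ik^2          # int u e^(iku) du
    I2 <- (e * (ik^2 - 2 * ik + 2) - 2) / ik^3  # int u^2 e^(iku) du
    1 - 12 * phi * (a * (I2 - I0) / 2 + b * (I1 - I0) + lam / 12 * I0)
  }, complex(1))
  1 / Mod(Qhat)^2
}

#' Model SAXS intensity for polydisperse interacting spheres
#'
#' `I(q) = scale * <P(q; R)> * S(q) + background`, with the Gaussian diameter
#' distribution averaged by Gauss-Legendre quadrature (truncated at 4 sd and
#' at R > 0, weighted by R^6 so large spheres carry their scattering power)
#' and the structure factor evaluated at the mean hard-sphere radius (the
#' local-monodisperse approximation, recorded in `attr(, "metadata")`).
#'
#' @param q scattering vector grid, nm^-1.
#' @param params a [saxs_params()].
#' @param model `"py"` (hard spheres) or `"sticky"` (Baxter).
#' @param n_quad quadrature points for the size average.
#' @return Intensity vector with attribute `metadata`.
#' @export
model_intensity <- function(q, params, model = c("py", "sticky"), n_quad = 41) {
  model <- match.arg(model)
  Rm <- params$d_mean / 2
  Rsd <- params$d_sd / 2
  if (Rsd <= 0) {
    Pq <- sphere_form_factor(q, Rm)
  } else {
    lo <- max(Rm - 4 * Rsd, 1e-6 * Rm)
    hi <- Rm + 4 * Rsd
    gl <- gauss_legendre(n_quad, lo, hi)
    w <- gl$w * exp(-(gl$x - Rm)^2 / (2 * Rsd^2)) * gl$x^6
    w <- w / sum(w)
    Pmat <- vapply(seq_along(gl$x),
                   function(k) sphere_form_factor(q, gl$x[k]), numeric(length(q)))
    Pq <- as.numeric(Pmat %*% w)
  }
  S <- if (params$phi <= 0) rep(1, length(q)) else switch(model,
    py = py_structure_factor(q, params$r_hs, params$phi),
    sticky = sticky_hs_structure_factor(q, params$r_hs, params$phi, params$tau))
  I <- params$scale * Pq * S + params$background
  attr(I, "metadata") <- list(model = model,
                              polydispersity = "Gaussian diameters, R^6-weighted quadrature",
                              structure_factor = "local-monodisperse (evaluated at r_hs)")
  I
}

# Gauss-Legendre nodes/weights on [a, b] (Golub-Welsch via symmetric tridiagonal)
gauss_legendre <- function(n, a, b) {
  i <- seq_len(n - 1)
  bet <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- bet
  J[cbind(i + 1, i)] <- bet
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(x = (b - a) / 2 * x[ord] + (a + b) / 2, w = (b - a) / 2 * w[ord])
}

#' Debye-sum scattering intensity from explicit coordinates
#'
#' Orientation-averaged Debye sum over sphere pairs with per-sphere amplitude
#' form factors:
#' `I(q) = sum_ij f_i(q) f_j(q) sinc(q d_ij)`, `f(q) = V 3(sin x - x cos x)/x^3`.
#' An independent oracle for the analytic models; the assembly is treated as
#' a finite cluster (no periodic images), so only features above the
#' finite-size cutoff are meaningful. Cost is O(N^2) per q point; `cap`
#' guards against accidental huge inputs.
#'
#' @param a a [sphere_assembly()].
#' @param q scattering vector grid, nm^-1.
#' @param cap maximum particle count accepted.
#' @return Intensity vector (arbitrary units).
#' @export
debye_intensity <- function(a, q, cap = 2000) {
  n <- nrow(a$positions)
  if (n > cap)
    stopf("N = %d exceeds the Debye-sum cap (%d); subsample the assembly", n, cap)
  V <- 4 / 3 * pi * a$radii^3
  amp <- function(qk) {
    x <- qk * a$radii
    f <- ifelse(x < 1e-6, 1 - x^2 / 10, 3 * (sin(x) - x * cos(x)) / x^3)
    V * f
  }
  dmat <- as.matrix(stats::dist(a$positions))
  vapply(q, function(qk) {
    f <- amp(qk)
    x <- qk * dmat
    sc <- ifelse(x < 1e-9, 1, sin(x) / x)
    as.numeric(t(f) %*% sc %*% f)
  }, 0)
}

#' Simulate a synthetic SAXS profile with counting noise
#'
#' Evaluates [model_intensity()] on a log-spaced grid spanning the
#' experiment's usable range (0.004-0.2 nm^-1 by default) and adds Gaussian
#' counting noise of relative size `noise`; `sigma = noise * I` is stored per
#' point. Deterministic given `seed`.
#'
#' @param params a [saxs_params()].
#' @param model `"py"` or `"sticky"`.
#' @param q optional explicit grid; default 200 log-spaced points.
#' @param q_range grid range, nm^-1.
#' @param n_q number of grid points.
#' @param noise relative noise level.
#' @param seed RNG seed.
#' @return A [scattering_profile()] whose `meta` echoes the generator.
#' @export
simulate_saxs_profile <- function(params, model = c("py", "sticky"), q = NULL,
                                  q_range = c(0.004, 0.2), n_q = 200,
                                  noise = 0.02, seed = 1) {
  model <- match.arg(model)
  q <- q %||% exp(seq(log(q_range[1]), log(q_range[2]), length.out = n_q))
  I <- as.numeric(model_intensity(q, params, model))
  sig <- pmax(noise * I, 1e-12 * max(I))
  In <- if (noise > 0) with_seed(seed, pmax(I + rnorm(length(q), sd = sig), 0)) else I
  scattering_profile(q, In, if (noise > 0) sig else NULL,
                     meta = list(model = model, seed = seed, noise = noise,
                                 truth = unclass(params)))
}

#' Fit a SAXS model to a scattering profile
#'
#' Weighted least squares (weights `1/sigma^2` when uncertainties are
#' present) via Levenberg-Marquardt. Any subset of the parameters can be
#' frozen with `fixed`; the effective hard-sphere radius tracks `d_mean / 2`
#' during fitting. Returns a classed model object
#' with `print`, `summary`, `coef`, `predict`, `plot` and `residuals`
#' methods. Non-convergence is an error carrying the last iterate; a
#' degenerate covariance flags the uncertainties as unavailable (NA) rather
#' than failing.
#'
#' @param profile a [scattering_profile()] with at least 10 points.
#' @param model `"py"` or `"sticky"`.
#' @param init a [saxs_params()] starting point.
#' @param fixed character vector of parameter names to hold fixed.
#' @param max_iter Levenberg-Marquardt iteration budget.
#' @return An object of class `saxs_fit`.
#' @export
fit_saxs <- function(profile, model = c("py", "sticky"),
                     init = saxs_params(), fixed = character(),
                     max_iter = 200) {
  model <- match.arg(model)
  if (length(profile$q) < 10) stopf("need >= 10 data points")
  all_par <- c("d_mean", "d_sd", "phi", "tau", "scale", "background")
  if (model == "py") fixed <- union(fixed, "tau")
  free <- setdiff(all_par, fixed)
  if (!length(free)) stopf("no free parameters")
  w <- if (is.null(profile$sigma)) rep(1, length(profile$q)) else 1 / profile$sigma
  lower <- c(d_mean = 1e-3, d_sd = 0, phi = 0, tau = 1e-3, scale = 1e-12,
             background = 0)
  upper <- c(d_mean = Inf, d_sd = Inf, phi = 0.73, tau = Inf, scale = Inf,
             background = Inf)
  p0 <- unlist(unclass(init)[all_par])
  make_params <- function(pv) {
    p <- as.list(p0)
    p[free] <- pv[free]
    saxs_params(d_mean = p$d_mean, d_sd = p$d_sd, phi = p$phi,
                r_hs = p$d_mean / 2, tau = p$tau, scale = p$scale,
                background = p$background)
  }
  resid_fn <- function(pv) {
    names(pv) <- free
    pr <- make_params(pv)
    w * (as.numeric(model_intensity(profile$q, pr, model)) - profile$intensity)
  }
  fit <- minpack.lm::nls.lm(par = p0[free], fn = resid_fn,
                            lower = lower[free], upper = upper[free],
                            control = minpack.lm::nls.lm.control(
                              maxiter = max_iter, ftol = 1e-12, ptol = 1e-12))
  if (fit$info %in% c(0, 9))
    stop(errorCondition(
      sprintf("SAXS fit did not converge (%s)", fit$message),
      class = c("diamondpack_fit_error", "error"), last = fit$par))
  est <- fit$par
  names(est) <- free
  nfree <- length(free)
  dof <- max(length(profile$q) - nfree, 1)
  chisq_red <- sum(fit$fvec^2) / dof
  se <- setNames(rep(NA_real_, nfree), free)
  cov_ok <- FALSE
  hess <- try(chol2inv(chol(fit$hessian)), silent = TRUE)
  if (!inherits(hess, "try-error") && all(is.finite(diag(hess))) &&
      all(diag(hess) >= 0)) {
    se[] <- sqrt(diag(hess) * chisq_red)
    cov_ok <- TRUE
  }
  params <- make_params(est)
  structure(list(params = params, estimate = est, se = se,
                 fixed = p0[setdiff(all_par, free)], model = model,
                 chisq_red = chisq_red, dof = dof, niter = fit$niter,
                 cov_ok = cov_ok, profile = profile,
                 fitted = as.numeric(model_intensity(profile$q, params, model))),
            class = "saxs_fit")
}

#' @export
print.saxs_fit <- function(x, ...) {
  cat(sprintf("<saxs_fit> %s model, %d iterations, reduced chi^2 = %.4g\n",
              x$model, x$niter, x$chisq_red))
  for (nm in names(x$estimate))
    cat(sprintf("  %-10s %.5g %s\n", nm, x$estimate[nm],
                if (is.na(x$se[nm])) "(se unavailable)" else
                  sprintf("+/- %.3g", x$se[nm])))
  invisible(x)
}

#' @export
summary.saxs_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  fixed: %s\n",
              paste(sprintf("%s = %.4g", names(object$fixed), object$fixed),
                    collapse = ", ")))
  cat(sprintf("  recovered diameter %.4g +/- %.4g nm (Gaussian sd), phi = %.4g\n",
              object$params$d_mean, object$params$d_sd, object$params$phi))
  invisible(object)
}

#' @export
coef.saxs_fit <- function(object, ...) object$estimate

#' @export
predict.saxs_fit <- function(object, q = NULL, ...) {
  q <- q %||% object$profile$q
  as.numeric(model_intensity(q, object$params, object$model))
}

#' @export
residuals.saxs_fit <- function(object, ...) {
  object$profile$intensity - object$fitted
}

#' @export
plot.saxs_fit <- function(x, ...) {
  plot(x$profile$q, x$profile$intensity, log = "xy", pch = 16, cex = 0.5,
       xlab = expression(q ~ (nm^-1)), ylab = "I(q) (a.u.)", ...)
  lines(x$profile$q, x$fitted, col = "darkorange", lwd = 2)
  legend("bottomleft", c("data", sprintf("%s fit", x$model)),
         pch = c(16, NA), lty = c(NA, 1), col = c("black", "darkorange"),
         bty = "n")
  invisible(x)
}
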