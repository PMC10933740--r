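#' Generate a jammed sphere packing by growth and quench
#'
#' Produces a mechanically stable disordered packing of frictionless soft
#' spheres in a fully periodic box: particles are grown stepwise and the
#' harmonic overlap energy is minimized (FIRE) after each step; the packing
#' fraction is then bisected until the residual energy per particle falls in
#' a narrow just-jammed window, the standard signature of the jamming point.
#' Monodisperse packings produced this way land at the maximally-random-jammed
#' benchmark, packing fraction close to 0.64 with close to 6 contacts per
#' non-rattler particle (isostaticity in three dimensions).
#'
#' Rattlers -- particles with fewer than 4 contacts at force balance, found by
#' iterative pruning -- are flagged in `labels` (1 = rattler, 0 = backbone).
#' They are excluded from the mean-contact statistic but included in the
#' packing fraction.
#'
#' @param n particle count (>= 4).
#' @param polydispersity relative standard deviation of the radii (Gaussian,
#'   truncated at 3 sd); 0 = monodisperse.
#' @param seed RNG seed (initial positions and radii).
#' @param diameter mean particle diameter in nm used to scale the output.
#' @param phi_start initial packing fraction of the growth schedule.
#' @param dphi initial growth step in packing fraction.
#' @param e_window energy-per-particle window `(lo, hi)` accepted as
#'   just-jammed; the force tolerance and window sizes are in the reduced
#'   units of the harmonic model (unit overlap energy scale).
#' @param ftol FIRE force-convergence tolerance (box units).
#' @param max_fire maximum FIRE iterations per quench.
#' @param max_outer maximum growth/bisection steps.
#' @return A [sphere_assembly()] with rattler labels and metadata fields
#'   `phi`, `mean_contacts` (non-rattlers, zero gap), `n_rattlers`, `seed`.
#'   Failure to converge raises a condition of class
#'   `diamondpack_jam_error` carrying the last state in `$state`.
#' @export
generate_jammed_packing <- function(n, polydispersity = 0, seed = 1,
                                    diameter = 210,
                                    phi_start = 0.55, dphi = 0.01,
                                    e_window = c(1e-8, 1e-7), ftol = 1e-8,
                                    max_fire = 200000L, max_outer = 300L) {
  if (n < 4) stopf("n must be >= 4")
  if (polydispersity < 0) stopf("polydispersity must be >= 0")
  init <- with_seed(seed, {
    rel <- 1 + polydispersity * pmin(pmax(rnorm(n), -3), 3)
    rel <- rel / mean(rel)
    list(pos = matrix(runif(3 * n), n, 3), rel = rel)
  })
  res <- cpp_jam(init$pos, init$rel, phi_start, dphi,
                 e_window[1], e_window[2], ftol,
                 as.integer(max_fire), as.integer(max_outer))
  if (!isTRUE(res$converged)) {
    cond <- errorCondition(
      sprintf(paste("jamming protocol failed to converge (phi = %.4f,",
                    "energy/particle = %.3g); the request may be below the",
                    "jamming density or the iteration budget too small"),
              res$phi, res$energy_per_particle),
      class = c("diamondpack_jam_error", "error"), state = res)
    stop(cond)
  }
  # scale to physical units: mean diameter -> `diameter` nm
  scale <- diameter / (2 * mean(res$radii))
  pos <- res$pos * scale
  rad <- res$radii * scale
  box <- rep(scale, 3)
  a <- sphere_assembly(pos, rad, box, periodic = c(TRUE, TRUE, TRUE))
  # contacts at force balance: pairs within summed radii (zero gap)
  g <- contact_graph(a, gap_tol = 0)
  rat <- find_rattlers(g)
  deg_bb <- backbone_degrees(g, rat)
  a$labels <- as.integer(rat)
  a$meta <- list(phi = res$phi,
                 mean_contacts = mean(deg_bb),
                 n_rattlers = sum(rat),
                 energy_per_particle = res$energy_per_particle,
                 fire_iterations = res$fire_iterations,
                 seed = seed, polydispersity = polydispersity)
  a
}

# iterative rattler pruning: drop particles with < 4 contacts, recount
find_rattlers <- function(g) {
  n <- g$n
  active <- rep(TRUE, n)
  repeat {
    keep_edge <- active[g$edges[, 1]] & active[g$edges[, 2]]
    deg <- tabulate(c(g$edges[keep_edge, , drop = FALSE]), nbins = n)
    drop <- active & deg < 4
    if (!any(drop)) break
    active[drop] <- FALSE
  }
  !active
}

# contact count among backbone (non-rattler) particles only
backbone_degrees <- function(g, rattler) {
  keep <- !rattler
  e <- g$edges[keep[g$edges[, 1]] & keep[g$edges[, 2]], , drop = FALSE]
  deg <- tabulate(c(e), nbins = g$n)
  deg[keep]
}
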