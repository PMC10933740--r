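#' Voxelize a sphere assembly
#'
#' Binary occupancy on a regular grid: a voxel is occupied iff its centre
#' lies inside any sphere (periodic axes wrap). The grid packing fraction
#' converges to the analytic one as the pitch shrinks.
#'
#' @param a a [sphere_assembly()].
#' @param pitch voxel edge, nm (default 15, the tomography slice thickness).
#' @param origin grid corner, nm.
#' @param max_voxels memory guard; exceeding it errors with advice to use a
#'   larger pitch.
#' @return A [voxel_volume()].
#' @export
voxelize <- function(a, pitch = 15, origin = c(0, 0, 0), max_voxels = 2.5e8) {
  if (pitch <= 0) stopf("pitch must be > 0")
  dims <- pmax(as.integer(ceiling((a$box - origin) / pitch)), 1L)
  if (prod(as.numeric(dims)) > max_voxels)
    stopf("grid of %d x %d x %d voxels exceeds the budget; increase pitch",
          dims[1], dims[2], dims[3])
  g <- cpp_voxelize(a$positions, a$radii, origin, dims, pitch, a$box / pitch,
                    a$periodic)
  # cpp_voxelize wraps in voxel units when periodic: pass box in voxels
  voxel_volume(array(g, dims), pitch, origin)
}

#' Degradation specification for the tomogram emulator
#'
#' Emulates the damage chain of ion-beam tomography on resin-infiltrated
#' samples: per-particle isotropic shrinkage (10-20 percent linearly in the
#' experiment), smooth random surface deformation, and uncorrelated voxel
#' noise.
#'
#' @param shrink_factor linear scale factor in (0, 1].
#' @param deform_amplitude surface distortion amplitude, nm.
#' @param deform_correlation correlation length of the deformation field, nm.
#' @param noise_rate voxel flip probability, `[0, 0.2]`.
#' @param seed RNG seed.
#' @return An object of class `degradation_spec`.
#' @export
degradation_spec <- function(shrink_factor = 0.83, deform_amplitude = 10,
                             deform_correlation = 30, noise_rate = 0.002,
                             seed = 1) {
  if (shrink_factor <= 0 || shrink_factor > 1)
    stopf("shrink_factor must be in (0, 1]")
  if (noise_rate < 0 || noise_rate > 0.2) stopf("noise_rate must be in [0, 0.2]")
  if (deform_amplitude < 0) stopf("deform_amplitude must be >= 0")
  structure(list(shrink_factor = shrink_factor,
                 deform_amplitude = deform_amplitude,
                 deform_correlation = deform_correlation,
                 noise_rate = noise_rate, seed = seed),
            class = "degradation_spec")
}

#' Degrade a voxel volume like a beam-damaged tomogram
#'
#' Applies, in order: isotropic sample contraction by the linear
#' `shrink_factor` (the whole grid is resampled at the same pitch, so
#' particle sizes *and* spacings contract together, exactly the effect the
#' downstream 1.2x voxel-volume rescale is meant to compensate); smooth
#' random per-particle surface deformation (the surface is carved where a
#' correlated Gaussian random field exceeds the local distance transform);
#' and salt-and-pepper voxel noise. Deterministic given the spec seed.
#' `shrink_factor = 1` with zero deformation and noise is the identity.
#'
#' @param vol a binary [voxel_volume()].
#' @param spec a [degradation_spec()].
#' @return The degraded [voxel_volume()] (fewer voxels per axis after
#'   contraction).
#' @export
degrade <- function(vol, spec = degradation_spec()) {
  g <- array(as.integer(vol$grid > 0), dim(vol$grid))
  dims <- dim(g)
  s <- spec$shrink_factor
  if (s < 1) {
    nd <- pmax(1L, as.integer(round(dims * s)))
    idx <- lapply(1:3, function(ax)
      pmin(dims[ax], pmax(1L, as.integer(ceiling((seq_len(nd[ax]) - 0.5) / s)))))
    g <- g[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    dims <- nd
  }
  if (spec$deform_amplitude > 0) {
    edt <- sqrt(cpp_edt(as.integer(g), dims))   # interior distance, voxels
    field <- cpp_noise_field(dims, spec$deform_correlation / vol$voxel_pitch,
                             spec$seed + 1)
    amp <- spec$deform_amplitude / vol$voxel_pitch
    # carve the surface where the field pushes inward; EDT >= 1 on the
    # foreground, so only positive excursions bite (no net shrink)
    g <- array(as.integer(g > 0 & edt > 0.5 + amp * field), dims)
  }
  if (spec$noise_rate > 0) {
    flip <- with_seed(spec$seed + 2, runif(length(g)) < spec$noise_rate)
    g[flip] <- 1L - g[flip]
    dim(g) <- dims
  }
  voxel_volume(g, vol$voxel_pitch, vol$origin)
}

# typical blob radius in voxels: median peak height of the interior EDT
estimate_blob_radius <- function(edt, dims) {
  sm <- cpp_blur3(edt, dims, 1)
  mx <- cpp_local_maxima(sm, as.integer(edt > 0), dims, 1.5)
  if (!length(mx)) return(max(edt))
  median(edt[mx])
}

#' Extract spheres from a voxel volume
#'
#' The segmentation chain of tomographic particle analysis: Euclidean
#' distance transform of the foreground, Gaussian smoothing (sd =
#' `marker_sd_factor` x expected radius), local maxima as watershed markers
#' (maxima closer than `merge_factor` x expected diameter are merged,
#' keeping the deeper one), marker-controlled watershed on the smoothed
#' distance map, then per-label centroids and equivalent-volume radii
#' `r = (3V / 4 pi)^(1/3)`. An empty volume yields an empty assembly (not an
#' error); an all-occupied grid yields a single grid-spanning particle.
#'
#' @param vol a binary or labelled [voxel_volume()] (labels are binarized;
#'   extraction assigns fresh labels).
#' @param expected_radius expected particle radius, nm; estimated from the
#'   distance transform when `NULL`.
#' @param marker_sd_factor smoothing scale as a fraction of the expected
#'   radius.
#' @param merge_factor marker merge distance as a fraction of the expected
#'   diameter.
#' @param min_volume_factor labels smaller than this fraction of the expected
#'   sphere volume are discarded as noise fragments.
#' @return A [sphere_assembly()] with labels 1..K, walled box `dims * pitch`;
#'   metadata records the marker parameters.
#' @export
extract_spheres <- function(vol, expected_radius = NULL,
                            marker_sd_factor = 0.25, merge_factor = 0.7,
                            min_volume_factor = 0.1) {
  dims <- dim(vol$grid)
  pitch <- vol$voxel_pitch
  mask <- as.integer(vol$grid > 0)
  box <- dims * pitch
  empty_assembly <- function() {
    a <- structure(list(positions = matrix(0, 0, 3), radii = numeric(0),
                        box = box, periodic = c(FALSE, FALSE, FALSE),
                        orientations = NULL, labels = integer(0),
                        meta = list(note = "empty volume")),
                   class = "sphere_assembly")
    a
  }
  if (!any(mask > 0)) return(empty_assembly())
  if (all(mask > 0)) {
    V <- prod(dims) * pitch^3
    return(sphere_assembly(matrix(box / 2, 1, 3), (3 * V / (4 * pi))^(1 / 3),
                           box, periodic = c(FALSE, FALSE, FALSE),
                           labels = 1L,
                           meta = list(note = "all-occupied grid")))
  }
  edt <- sqrt(cpp_edt(mask, dims))
  r_vox <- if (is.null(expected_radius)) estimate_blob_radius(edt, dims)
           else expected_radius / pitch
  sm <- cpp_blur3(edt, dims, max(marker_sd_factor * r_vox, 0.5))
  mx <- cpp_local_maxima(sm, mask, dims, 0.35 * r_vox)
  if (!length(mx)) mx <- which.max(sm)
  # merge maxima closer than merge_factor * diameter, keep the deeper one
  coord <- arrayInd(mx, dims)
  ord <- order(sm[mx], decreasing = TRUE)
  keep <- logical(length(mx))
  mind2 <- (merge_factor * 2 * r_vox)^2
  kept_xyz <- matrix(0, 0, 3)
  for (k in ord) {
    x <- coord[k, ]
    if (nrow(kept_xyz) == 0 ||
        min(rowSums(sweep(kept_xyz, 2, x)^2)) > mind2) {
      keep[k] <- TRUE
      kept_xyz <- rbind(kept_xyz, x)
    }
  }
  mx <- mx[keep]
  markers <- integer(length(mask))
  markers[mx] <- seq_along(mx)
  lab <- cpp_watershed(sm, markers, mask, dims)
  K <- length(mx)
  idx <- which(lab > 0)
  ci <- arrayInd(idx, dims)
  labv <- lab[idx]
  counts <- tabulate(labv, nbins = K)
  sums <- rowsum(ci + 0.0, labv)
  grp <- as.integer(rownames(sums))
  pos <- matrix(0, K, 3)
  pos[grp, ] <- sums / counts[grp]
  pos <- sweep((pos - 0.5) * pitch, 2, vol$origin, "+")
  radii <- (3 * counts * pitch^3 / (4 * pi))^(1 / 3)
  ok <- counts > min_volume_factor * (4 / 3) * pi * r_vox^3
  if (!any(ok)) ok <- counts > 0
  sphere_assembly(pos[ok, , drop = FALSE], radii[ok], box,
                  periodic = c(FALSE, FALSE, FALSE),
                  labels = seq_len(sum(ok)),
                  meta = list(expected_radius_vox = r_vox,
                              marker_sd_factor = marker_sd_factor,
                              merge_factor = merge_factor,
                              n_markers = K))
}

#' Rescale an assembly isotropically
#'
#' Positions, radii and box are multiplied by `factor`; the packing fraction
#' and (with the gap scaled alike) the contact statistics are invariant.
#' This is the correction that compensates the 20 percent beam-induced
#' shrinkage of tomograms before statistics are taken.
#'
#' @param a a [sphere_assembly()].
#' @param factor scale factor (> 0).
#' @return The rescaled [sphere_assembly()].
#' @export
rescale_assembly <- function(a, factor) {
  if (factor <= 0) stopf("factor must be > 0")
  a$positions <- a$positions * factor
  a$radii <- a$radii * factor
  a$box <- a$box * factor
  a$meta$rescaled <- factor
  a
}

#' Replace extracted particles by ideal spheres of one diameter
#'
#' Centres are preserved and every radius is set to `target_diameter / 2`,
#' the idealization applied to deformed tomogram particles before optical or
#' contact analysis. An overlap report (pair count and maximum overlap
#' depth, nm) is attached as `attr(, "overlap_report")`.
#'
#' @param a a [sphere_assembly()].
#' @param target_diameter nm (> 0).
#' @return The regularized [sphere_assembly()].
#' @export
regularize_spheres <- function(a, target_diameter) {
  if (target_diameter <= 0) stopf("target_diameter must be > 0")
  out <- a
  out$radii <- rep(target_diameter / 2, nrow(a$positions))
  g <- contact_graph(out, gap_tol = 0)
  depth <- 0
  if (nrow(g$edges) > 0) {
    d <- sqrt(rowSums(min_image(
      out$positions[g$edges[, 2], , drop = FALSE] -
        out$positions[g$edges[, 1], , drop = FALSE], out$box, out$periodic)^2))
    depth <- max(target_diameter - d)
  }
  out$meta$regularized <- target_diameter
  attr(out, "overlap_report") <- list(n_overlaps = nrow(g$edges),
                                      max_depth = depth)
  out
}
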