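# Shared fixtures and independent oracles for the test suite.

# random sequential-addition assembly with guaranteed minimum separation
rsa_assembly <- function(n, box, min_sep, radius, periodic = c(TRUE, TRUE, TRUE),
                         seed = 1, max_tries = 20000) {
  set.seed(seed)
  pos <- matrix(NA_real_, n, 3)
  placed <- 0
  tries <- 0
  while (placed < n && tries < max_tries) {
    tries <- tries + 1
    cand <- runif(3) * box
    ok <- TRUE
    if (placed > 0) {
      d <- sweep(pos[seq_len(placed), , drop = FALSE], 2, cand)
      for (ax in 1:3)
        if (periodic[ax]) d[, ax] <- d[, ax] - box[ax] * round(d[, ax] / box[ax])
      ok <- min(rowSums(d^2)) >= min_sep^2
    }
    if (ok) {
      placed <- placed + 1
      pos[placed, ] <- cand
    }
  }
  stopifnot(placed == n)
  sphere_assembly(pos, radius, box, periodic)
}

random_unit_quats <- function(n, seed = 1) {
  set.seed(seed)
  q <- matrix(rnorm(4 * n), n, 4)
  q / sqrt(rowSums(q^2))
}

# all-pairs brute-force contact graph (independent of the cell-list path)
brute_contact_degrees <- function(a, gap) {
  n <- nrow(a$positions)
  deg <- integer(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- a$positions[j, ] - a$positions[i, ]
    for (ax in 1:3)
      if (a$periodic[ax]) d[ax] <- d[ax] - a$box[ax] * round(d[ax] / a$box[ax])
    if (sqrt(sum(d^2)) <= a$radii[i] + a$radii[j] + gap) {
      deg[i] <- deg[i] + 1L
      deg[j] <- deg[j] + 1L
    }
  }
  deg
}

# --- independent spherical-harmonic oracle: explicit closed forms ----------
# Hard-coded Y_lm for l = 4 and l = 6 (m >= 0) from the standard tables;
# negative m via Y_{l,-m} = (-1)^m Conj(Y_{l,m}). No code shared with the
# package implementation (which uses Legendre recurrences).
ylm_table <- function(l, m, theta, phi) {
  ct <- cos(theta)
  st <- sin(theta)
  mm <- abs(m)
  val <- if (l == 0 && mm == 0) {
    0.5 * sqrt(1 / pi) + 0 * ct
  } else if (l == 4) {
    switch(mm + 1,
      (3 / 16) * sqrt(1 / pi) * (35 * ct^4 - 30 * ct^2 + 3),
      (-3 / 8) * sqrt(5 / pi) * st * (7 * ct^3 - 3 * ct),
      (3 / 8) * sqrt(5 / (2 * pi)) * st^2 * (7 * ct^2 - 1),
      (-3 / 8) * sqrt(35 / pi) * st^3 * ct,
      (3 / 16) * sqrt(35 / (2 * pi)) * st^4)
  } else if (l == 6) {
    switch(mm + 1,
      (1 / 32) * sqrt(13 / pi) * (231 * ct^6 - 315 * ct^4 + 105 * ct^2 - 5),
      (-1 / 16) * sqrt(273 / (2 * pi)) * st * (33 * ct^5 - 30 * ct^3 + 5 * ct),
      (1 / 64) * sqrt(1365 / pi) * st^2 * (33 * ct^4 - 18 * ct^2 + 1),
      (-1 / 32) * sqrt(1365 / pi) * st^3 * (11 * ct^3 - 3 * ct),
      (3 / 32) * sqrt(91 / (2 * pi)) * st^4 * (11 * ct^2 - 1),
      (-3 / 32) * sqrt(1001 / pi) * st^5 * ct,
      (1 / 64) * sqrt(3003 / pi) * st^6)
  } else stop("oracle only covers l in {0, 4, 6}")
  y <- val * exp(1i * mm * phi)
  if (m < 0) y <- (-1)^mm * Conj(y)
  y
}

# direct brute-force q_l of one particle from explicit bond vectors
oracle_ql <- function(bonds, l) {
  u <- bonds / sqrt(rowSums(bonds^2))
  theta <- acos(pmin(1, pmax(-1, u[, 3])))
  phi <- atan2(u[, 2], u[, 1])
  s <- 0
  for (m in -l:l) {
    qlm <- mean(ylm_table(l, m, theta, phi))
    s <- s + Mod(qlm)^2
  }
  sqrt(4 * pi / (2 * l + 1) * s)
}

# quaternion that rotates unit vector `from` onto unit vector `to`
quat_between <- function(from, to) {
  from <- from / sqrt(sum(from^2))
  to <- to / sqrt(sum(to^2))
  c_ <- sum(from * to)
  if (c_ > 1 - 1e-12) return(c(1, 0, 0, 0))
  if (c_ < -1 + 1e-12) {
    ax <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- ax - sum(ax * from) * from
    ax <- ax / sqrt(sum(ax^2))
    return(c(0, ax))
  }
  ax <- c(from[2] * to[3] - from[3] * to[2],
          from[3] * to[1] - from[1] * to[3],
          from[1] * to[2] - from[2] * to[1])
  ax <- ax / sqrt(sum(ax^2))
  th <- acos(c_)
  c(cos(th / 2), sin(th / 2) * ax)
}

# rotation matrix from an axis-angle, for rotational-invariance checks
rotmat <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

tetra_axes <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
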