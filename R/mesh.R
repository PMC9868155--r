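#' Build a triangulated tube surface from an area profile
#'
#' Sweeps an elliptical (or circular) cross-section along the z axis with
#' the area prescribed by the profile at every grid plane, producing a
#' watertight open-ended tube mesh in mm. Cross-section *shape* is a
#' modelling choice; only area enters the downstream pressure-loss
#' equations. Ring vertices lie on the exact ellipse, so the polygonal
#' section underestimates the smooth area by the factor
#' `n_theta/(2*pi) * sin(2*pi/n_theta)` -- about 0.16% at `n_theta = 64`,
#' halving with each doubling of the angular resolution, which is the
#' mesh-refinement convergence handle of the slicer.
#'
#' @param profile an [make_area_profile()] result.
#' @param spec the originating [airway_spec()] (supplies cross-section
#'   shape, aspect and `n_theta`).
#' @return An object of class `airway_mesh`: list with `vertices` (n x 3
#'   matrix, mm) and `faces` (m x 3 integer matrix, 1-based,
#'   counter-clockwise seen from outside).
#' @export
make_surface_mesh <- function(profile, spec) {
  stopifnot(inherits(profile, "area_profile"), inherits(spec, "airway_spec"))
  if (any(profile$area_mm2 <= 0)) {
    stop("degenerate (zero-area) cross-section in profile", call. = FALSE)
  }
  nt <- spec$n_theta
  theta <- 2 * pi * (seq_len(nt) - 1L) / nt
  nz <- length(profile$z_mm)
  asp <- spec$aspect
  verts <- matrix(0, nrow = nz * nt, ncol = 3L)
  for (i in seq_len(nz)) {
    A <- profile$area_mm2[i]
    ry <- sqrt(A / (pi * asp))
    rx <- ry * asp
    rows <- (i - 1L) * nt + seq_len(nt)
    verts[rows, 1L] <- rx * cos(theta)
    verts[rows, 2L] <- ry * sin(theta)
    verts[rows, 3L] <- profile$z_mm[i]
  }
  # two triangles per quad between consecutive rings
  faces <- matrix(0L, nrow = 2L * nt * (nz - 1L), ncol = 3L)
  k <- 0L
  for (i in seq_len(nz - 1L)) {
    a <- (i - 1L) * nt + seq_len(nt)           # upper ring
    b <- i * nt + seq_len(nt)                  # lower ring
    a2 <- a[c(seq_len(nt)[-1L], 1L)]
    b2 <- b[c(seq_len(nt)[-1L], 1L)]
    faces[k + seq_len(nt), ] <- cbind(a, b, b2)
    faces[k + nt + seq_len(nt), ] <- cbind(a, b2, a2)
    k <- k + 2L * nt
  }
  structure(list(vertices = verts, faces = faces), class = "airway_mesh")
}

#' @export
print.airway_mesh <- function(x, ...) {
  cat("Triangulated airway surface:",
      nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  zr <- range(x$vertices[, 3L])
  cat(sprintf("  z range %.2f to %.2f mm\n", zr[1L], zr[2L]))
  invisible(x)
}

#' Apply bounded random displacement to mesh vertices
#'
#' Displaces each vertex radially (in the xy cross-sectional plane, away
#' from the local section centroid at x = y = 0) by a uniform random
#' offset bounded by `amplitude`. Used to build robustness fixtures for the
#' slicer. `amplitude = 0` returns the input unchanged; the same `seed`
#' always gives the same mesh.
#'
#' @param mesh an `airway_mesh`.
#' @param amplitude_mm maximum radial displacement, mm (>= 0).
#' @param seed integer RNG seed.
#' @return A perturbed `airway_mesh`.
#' @export
perturb_mesh <- function(mesh, amplitude_mm, seed = 1L) {
  stopifnot(inherits(mesh, "airway_mesh"))
  stopifnot_scalar(amplitude_mm, "amplitude_mm", nonneg = TRUE)
  if (amplitude_mm == 0) return(mesh)
  v <- mesh$vertices
  r <- sqrt(v[, 1L]^2 + v[, 2L]^2)
  if (amplitude_mm >= min(r)) {
    warning("perturbation amplitude is large relative to the lumen radius; ",
            "self-intersection cannot be ruled out")
  }
  off <- with_seed(seed, stats::runif(nrow(v), -amplitude_mm, amplitude_mm))
  scale <- ifelse(r > 0, (r + off) / r, 1)
  v[, 1L] <- v[, 1L] * scale
  v[, 2L] <- v[, 2L] * scale
  structure(list(vertices = v, faces = mesh$faces), class = "airway_mesh")
}
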