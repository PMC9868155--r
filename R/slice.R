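# Cross-sectional plane stack: mesh slicing, plane_Amin, regions,
# subsegments, morphometry.

#' Slice an airway surface mesh into a descending plane stack
#'
#' Intersects the mesh with planes perpendicular to the z axis, descending
#' from `top_z` to `bottom_z` in steps of `spacing_mm` (plane index
#' increases downstream, i.e. with decreasing z). The cross-sectional area
#' at each plane is the sum of the areas of all closed intersection
#' contours (a bifid or non-convex lumen may intersect a plane in several
#' loops; their areas are summed, because only total area enters the
#' pressure-loss relations).
#'
#' Planes that coincide with mesh vertices are nudged along z by a
#' negligible offset (1e-6 of the spacing) for robustness; an empty
#' intersection at any requested plane is an error naming the z, since a
#' discontinuous lumen invalidates the whole stack.
#'
#' @param mesh an `airway_mesh` (mm).
#' @param top_z,bottom_z axial extent, mm, `top_z > bottom_z`.
#' @param spacing_mm plane spacing, mm (default 0.5).
#' @return A `plane_sections` data.frame with columns `index` (1-based,
#'   contiguous), `z_mm`, `area_mm2`, `n_loops` and `region` (NA until
#'   [assign_regions()] is called).
#' @export
slice_airway <- function(mesh, top_z, bottom_z, spacing_mm = 0.5) {
  stopifnot(inherits(mesh, "airway_mesh"))
  stopifnot_scalar(spacing_mm, "spacing_mm", positive = TRUE)
  if (top_z <= bottom_z) stop("'top_z' must exceed 'bottom_z'", call. = FALSE)
  n <- as.integer(round((top_z - bottom_z) / spacing_mm)) + 1L
  zs <- top_z - (seq_len(n) - 1L) * spacing_mm

  v <- mesh$vertices
  f <- mesh$faces
  tz <- cbind(v[f[, 1L], 3L], v[f[, 2L], 3L], v[f[, 3L], 3L])
  tri_zmin <- pmin(tz[, 1L], tz[, 2L], tz[, 3L])
  tri_zmax <- pmax(tz[, 1L], tz[, 2L], tz[, 3L])
  mesh_zmin <- min(tri_zmin)
  mesh_zmax <- max(tri_zmax)
  eps <- spacing_mm * 1e-6

  area <- numeric(n)
  nloops <- integer(n)
  for (i in seq_len(n)) {
    z0 <- zs[i]
    # nudge away from exact vertex hits, toward the mesh interior
    if (z0 - eps <= mesh_zmin) z0 <- z0 + eps else z0 <- z0 - eps
    res <- plane_section_area(v, f, tri_zmin, tri_zmax, z0)
    if (res$n_loops == 0L) {
      stop(sprintf(
        "empty mesh intersection at z = %.3f mm: lumen is discontinuous or plane range exceeds the mesh",
        zs[i]), call. = FALSE)
    }
    area[i] <- res$area
    nloops[i] <- res$n_loops
  }
  structure(
    data.frame(index = seq_len(n), z_mm = zs, area_mm2 = area,
               n_loops = nloops,
               region = rep(NA_character_, n),
               stringsAsFactors = FALSE),
    class = c("plane_sections", "data.frame")
  )
}

# Intersect the triangle soup with the plane z = z0 and return the summed
# absolute area of the closed contours plus their count. Intersection
# segments are chained into loops by matching endpoints on a 1e-6 mm grid;
# loop area is the planar shoelace formula.
plane_section_area <- function(v, f, tri_zmin, tri_zmax, z0) {
  hit <- which(tri_zmin < z0 & tri_zmax > z0)
  if (length(hit) == 0L) return(list(area = 0, n_loops = 0L))
  p1 <- v[f[hit, 1L], , drop = FALSE]
  p2 <- v[f[hit, 2L], , drop = FALSE]
  p3 <- v[f[hit, 3L], , drop = FALSE]
  d1 <- p1[, 3L] - z0
  d2 <- p2[, 3L] - z0
  d3 <- p3[, 3L] - z0

  cross_edge <- function(pa, pb, da, db) {
    t <- da / (da - db)
    cbind(pa[, 1L] + t * (pb[, 1L] - pa[, 1L]),
          pa[, 2L] + t * (pb[, 2L] - pa[, 2L]))
  }
  nh <- length(hit)
  e1 <- matrix(NA_real_, nh, 2L)
  e2 <- matrix(NA_real_, nh, 2L)
  e3 <- matrix(NA_real_, nh, 2L)
  m12 <- d1 * d2 < 0
  m23 <- d2 * d3 < 0
  m31 <- d3 * d1 < 0
  if (any(m12)) e1[m12, ] <- cross_edge(p1[m12, , drop = FALSE],
                                        p2[m12, , drop = FALSE],
                                        d1[m12], d2[m12])
  if (any(m23)) e2[m23, ] <- cross_edge(p2[m23, , drop = FALSE],
                                        p3[m23, , drop = FALSE],
                                        d2[m23], d3[m23])
  if (any(m31)) e3[m31, ] <- cross_edge(p3[m31, , drop = FALSE],
                                        p1[m31, , drop = FALSE],
                                        d3[m31], d1[m31])
  # identify intersection points by the mesh edge they lie on: two
  # triangles sharing an edge produce the same key exactly, independent of
  # floating-point details of the interpolated point
  edge_key <- function(pa, pb) {
    sa <- sprintf("%.17g,%.17g,%.17g", pa[, 1L], pa[, 2L], pa[, 3L])
    sb <- sprintf("%.17g,%.17g,%.17g", pb[, 1L], pb[, 2L], pb[, 3L])
    ifelse(sa < sb, paste(sa, sb), paste(sb, sa))
  }
  k12 <- edge_key(p1, p2)
  k23 <- edge_key(p2, p3)
  k31 <- edge_key(p3, p1)
  # each strictly-crossing triangle cuts exactly two of its three edges
  two <- (m12 + m23 + m31) == 2L
  seg_a <- ifelse(cbind(m12, m12), e1, e2)[two, , drop = FALSE]
  seg_b <- ifelse(cbind(m12 & m23, m12 & m23), e2, e3)[two, , drop = FALSE]
  ka <- ifelse(m12, k12, k23)[two]
  kb <- ifelse(m12 & m23, k23, k31)[two]
  ns <- nrow(seg_a)
  if (ns < 3L) return(list(area = 0, n_loops = 0L))
  # endpoint -> segment adjacency (each key should occur on two segments)
  keys <- c(ka, kb)
  seg_id <- rep(seq_len(ns), 2L)
  uk <- unique(keys)
  slot <- match(keys, uk)
  adj <- vector("list", length(uk))
  for (i in seq_along(keys)) adj[[slot[i]]] <- c(adj[[slot[i]]], seg_id[i])

  used <- logical(ns)
  total <- 0
  n_loops <- 0L
  for (s0 in seq_len(ns)) {
    if (used[s0]) next
    loop_x <- numeric(0)
    loop_y <- numeric(0)
    cur <- s0
    at_a <- TRUE                       # entering `cur` at its `a` endpoint
    repeat {
      used[cur] <- TRUE
      if (at_a) {
        loop_x <- c(loop_x, seg_a[cur, 1L])
        loop_y <- c(loop_y, seg_a[cur, 2L])
        nxt_key <- kb[cur]
      } else {
        loop_x <- c(loop_x, seg_b[cur, 1L])
        loop_y <- c(loop_y, seg_b[cur, 2L])
        nxt_key <- ka[cur]
      }
      cand <- adj[[match(nxt_key, uk)]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) break
      cur <- cand[1L]
      at_a <- identical(ka[cur], nxt_key)
    }
    m <- length(loop_x)
    if (m >= 3L) {
      j <- c(seq_len(m)[-1L], 1L)
      total <- total + abs(sum(loop_x * loop_y[j] - loop_x[j] * loop_y) / 2)
      n_loops <- n_loops + 1L
    }
  }
  list(area = total, n_loops = n_loops)
}

#' Locate the minimum-area plane (plane_Amin) within a region
#'
#' Returns the index of the plane with the globally smallest area within
#' the given region. Ties (a flat constricted plateau) break to the first,
#' most upstream, minimal plane. A region whose areas are all equal has no
#' constriction (a degenerate cylinder) and raises an error, because a
#' plane_Amin must be smaller than at least one neighbour.
#'
#' @param sections a `plane_sections` data.frame.
#' @param region `NULL` (whole stack) or one of `"velopharynx"`,
#'   `"oropharynx"` (requires [assign_regions()] first).
#' @return The plane `index` (1-based, in stack numbering) of plane_Amin.
#' @export
find_plane_amin <- function(sections, region = NULL) {
  stopifnot(is.data.frame(sections), nrow(sections) >= 1L)
  sub <- sections
  if (!is.null(region)) {
    sub <- sections[!is.na(sections$region) & sections$region == region, ]
    if (nrow(sub) == 0L) stop("region '", region, "' is empty", call. = FALSE)
  }
  a <- sub$area_mm2
  if (diff(range(a)) <= max(a) * 1e-12) {
    stop("no constriction: all cross-sectional areas in the region are equal",
         call. = FALSE)
  }
  sub$index[which.min(a)]
}

#' Assign velopharyngeal/oropharyngeal region labels
#'
#' Planes 1..`dividing_index` (down to the soft-palate tip, inclusive) are
#' labelled `velopharynx`; planes below it `oropharynx`. The dividing plane
#' is an anatomical landmark that cannot be inferred from the bare mesh and
#' must be supplied.
#'
#' @param sections a `plane_sections` data.frame.
#' @param dividing_index plane index of the soft-palate tip; must satisfy
#'   `1 < dividing_index < n_planes`.
#' @return `sections` with the `region` column filled.
#' @export
assign_regions <- function(sections, dividing_index) {
  n <- nrow(sections)
  if (!is.numeric(dividing_index) || length(dividing_index) != 1L ||
      dividing_index <= 1 || dividing_index >= n) {
    stop("'dividing_index' must lie strictly between plane 1 and plane ", n,
         call. = FALSE)
  }
  sections$region <- ifelse(sections$index <= dividing_index,
                            "velopharynx", "oropharynx")
  sections
}

#' Plane-to-plane area ratio series
#'
#' `ratio[N] = A[N] / A[N+1]` for N = 1..n-1: the local taper of the lumen
#' (> 1 where the lumen narrows downstream).
#'
#' @param sections a `plane_sections` data.frame (>= 2 planes).
#' @return Numeric vector of length `n - 1`.
#' @seealso [area_ratio_to_amin()] for the ratio referenced to plane_Amin.
#' @export
area_ratio_series <- function(sections) {
  a <- sections$area_mm2
  if (length(a) < 2L) stop("need at least two planes", call. = FALSE)
  a[-length(a)] / a[-1L]
}

#' Area ratio of every plane to plane_Amin
#'
#' `A[N] / A[amin]` for every plane: >= 1 everywhere, 1 at plane_Amin.
#'
#' @param sections a `plane_sections` data.frame.
#' @param amin_index plane index of plane_Amin (default: located on the
#'   whole stack).
#' @return Numeric vector of length `n`.
#' @export
area_ratio_to_amin <- function(sections, amin_index = NULL) {
  if (is.null(amin_index)) amin_index <- find_plane_amin(sections)
  sections$area_mm2 / sections$area_mm2[sections$index == amin_index]
}

#' Build inter-plane subsegments with lateral wall areas
#'
#' Subsegment N is the lumen slab bounded above by plane N and below by
#' plane N+1, together with the lateral wall band between the two planes.
#' The band wall area is the exact area of the mesh triangles clipped to
#' the z slab.
#'
#' @param sections a `plane_sections` data.frame (>= 2 planes).
#' @param mesh optional `airway_mesh`; when supplied, the clipped wall band
#'   area is computed, otherwise `wall_area_mm2` is the circular-equivalent
#'   estimate (mean perimeter x slant-corrected height).
#' @return data.frame with columns `index`, `upper_plane`, `lower_plane`,
#'   `z_upper_mm`, `z_lower_mm`, `wall_area_mm2`.
#' @export
build_subsegments <- function(sections, mesh = NULL) {
  n <- nrow(sections)
  if (n < 2L) stop("need at least two planes", call. = FALSE)
  idx <- seq_len(n - 1L)
  z_up <- sections$z_mm[idx]
  z_lo <- sections$z_mm[idx + 1L]
  if (!is.null(mesh)) {
    wall <- mesh_band_areas(mesh, z_up, z_lo)
  } else {
    # circular-equivalent perimeter of the mean area, times the band height
    r_up <- sqrt(sections$area_mm2[idx] / pi)
    r_lo <- sqrt(sections$area_mm2[idx + 1L] / pi)
    dz <- z_up - z_lo
    slant <- sqrt(dz^2 + (r_up - r_lo)^2)
    wall <- pi * (r_up + r_lo) * slant
  }
  data.frame(index = idx, upper_plane = idx, lower_plane = idx + 1L,
             z_upper_mm = z_up, z_lower_mm = z_lo, wall_area_mm2 = wall)
}

# Exact area of mesh triangles clipped to each z slab [z_lo, z_up].
mesh_band_areas <- function(mesh, z_up, z_lo) {
  v <- mesh$vertices
  f <- mesh$faces
  tz <- cbind(v[f[, 1L], 3L], v[f[, 2L], 3L], v[f[, 3L], 3L])
  tri_zmin <- pmin(tz[, 1L], tz[, 2L], tz[, 3L])
  tri_zmax <- pmax(tz[, 1L], tz[, 2L], tz[, 3L])
  vapply(seq_along(z_up), function(i) {
    hit <- which(tri_zmax > z_lo[i] & tri_zmin < z_up[i])
    if (length(hit) == 0L) return(0)
    s <- 0
    for (t in hit) {
      poly <- rbind(v[f[t, 1L], ], v[f[t, 2L], ], v[f[t, 3L], ])
      poly <- clip_polygon_halfspace(poly, z_lo[i], above = TRUE)
      if (nrow(poly) >= 3L) poly <- clip_polygon_halfspace(poly, z_up[i],
                                                           above = FALSE)
      if (nrow(poly) >= 3L) s <- s + polygon_area_3d(poly)
    }
    s
  }, numeric(1L))
}

# Sutherland-Hodgman clip of a planar 3D polygon against z >= z0
# (above = TRUE) or z <= z0.
clip_polygon_halfspace <- function(poly, z0, above = TRUE) {
  n <- nrow(poly)
  keep <- if (above) poly[, 3L] >= z0 else poly[, 3L] <= z0
  out <- matrix(numeric(0), ncol = 3L)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (keep[i]) out <- rbind(out, poly[i, ])
    if (keep[i] != keep[j]) {
      t <- (z0 - poly[i, 3L]) / (poly[j, 3L] - poly[i, 3L])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

# Area of a planar polygon in 3D (Newell's formula).
polygon_area_3d <- function(poly) {
  n <- nrow(poly)
  j <- c(seq_len(n)[-1L], 1L)
  cx <- sum(poly[, 2L] * poly[j, 3L] - poly[j, 2L] * poly[, 3L])
  cy <- sum(poly[, 3L] * poly[j, 1L] - poly[j, 3L] * poly[, 1L])
  cz <- sum(poly[, 1L] * poly[j, 2L] - poly[j, 1L] * poly[, 2L])
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

#' Summarize stack morphometry
#'
#' Produces the standard per-region morphometry summary: segment length
#' (`(n_planes - 1) * spacing`, in cm), plane count, dividing plane, and
#' the plane_Amin index and area (cm^2) for each region. A region without a
#' constriction (all areas equal) is flagged rather than failing.
#'
#' @param sections a `plane_sections` data.frame with regions assigned.
#' @return A list of class `morphometry_report`, serializable with
#'   [jsonlite::toJSON()].
#' @export
morphometry_report <- function(sections) {
  n <- nrow(sections)
  if (any(is.na(sections$region))) {
    stop("regions are not assigned; call assign_regions() first",
         call. = FALSE)
  }
  spacing <- abs(stats::median(diff(sections$z_mm)))
  dividing <- max(sections$index[sections$region == "velopharynx"])
  per_region <- lapply(c("velopharynx", "oropharynx"), function(reg) {
    res <- tryCatch(find_plane_amin(sections, reg), error = function(e) NULL)
    if (is.null(res)) {
      list(region = reg, amin_index = NA_integer_, amin_area_cm2 = NA_real_,
           no_constriction = TRUE)
    } else {
      list(region = reg, amin_index = res,
           amin_area_cm2 = sections$area_mm2[sections$index == res] / 100,
           no_constriction = FALSE)
    }
  })
  names(per_region) <- c("velopharynx", "oropharynx")
  structure(
    list(segment_length_cm = (n - 1L) * spacing / 10,
         n_planes = n,
         dividing_plane_index = dividing,
         regions = per_region),
    class = "morphometry_report"
  )
}

#' @export
print.morphometry_report <- function(x, ...) {
  cat(sprintf("Pharyngeal segment: %.2f cm, %d planes, dividing plane %d\n",
              x$segment_length_cm, x$n_planes, x$dividing_plane_index))
  for (reg in x$regions) {
    if (isTRUE(reg$no_constriction)) {
      cat(sprintf("  %-12s no constriction\n", reg$region))
    } else {
      cat(sprintf("  %-12s plane_Amin at plane %d, area %.4f cm^2\n",
                  reg$region, reg$amin_index, reg$amin_area_cm2))
    }
  }
  invisible(x)
}
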