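# Post-processing of sampled flow fields: mass-flow-weighted plane
# averages, dynamic/total/relative total pressure, wall-shear aggregation,
# subsegmental loss coefficient and resistance (square law), and the
# frictional-vs-interior pressure-loss decomposition.

#' Mass-flow-weighted plane average
#'
#' `sum(phi * rho * |u.n| * a) / sum(rho * |u.n| * a)`, the standard
#' post-processor convention for averaging a field over a cross-sectional
#' plane: each sample is weighted by the magnitude of its mass flux through
#' the plane (`a` = sample area weight, `n` = bulk flow direction).
#'
#' @param phi numeric vector of field samples.
#' @param velocity n x 3 matrix of sample velocities, m/s.
#' @param area_weight sample area weights (any consistent unit).
#' @param rho gas density, kg/m^3 (cancels for constant density; kept for
#'   the general form).
#' @param flow_direction unit 3-vector of the bulk flow direction.
#' @return The weighted average (scalar).
#' @export
mass_flow_average <- function(phi, velocity, area_weight, rho = 1.204,
                              flow_direction = c(0, 0, -1)) {
  velocity <- matrix(velocity, ncol = 3L)
  if (length(phi) != nrow(velocity) || length(phi) != length(area_weight)) {
    stop("'phi', 'velocity' and 'area_weight' must have matching lengths",
         call. = FALSE)
  }
  nvec <- flow_direction / sqrt(sum(flow_direction^2))
  w <- rho * abs(velocity %*% nvec) * area_weight
  tot <- sum(w)
  if (tot <= 0) {
    stop("zero total mass flux through the plane: average undefined",
         call. = FALSE)
  }
  sum(phi * w) / tot
}

#' Dynamic pressure
#'
#' `Pv = 1/2 rho v^2` (always >= 0).
#'
#' @param v velocity magnitude, m/s (vectorized).
#' @param rho gas density, kg/m^3.
#' @return Dynamic pressure, Pa.
#' @export
dynamic_pressure <- function(v, rho = 1.204) 0.5 * rho * v^2

#' Total pressure
#'
#' `Pt = Ps + Pv`; identically the "gap" between the static-pressure curve
#' and the negated dynamic-pressure curve.
#'
#' @param ps static pressure, Pa (gauge; negative during inspiration).
#' @param pv dynamic pressure, Pa.
#' @return Total pressure, Pa.
#' @export
total_pressure <- function(ps, pv) ps + pv

#' Relative total pressure Pt' referenced to plane I
#'
#' Subtracts the first element (plane I) from the whole series, removing
#' the pressure already lost upstream of the segment so only losses within
#' the region of interest remain. The first element of the result is
#' exactly 0.
#'
#' @param pt numeric vector of total pressures, plane I first.
#' @return Vector of the same length.
#' @export
relative_total_pressure <- function(pt) {
  if (length(pt) < 1L) stop("empty total-pressure series", call. = FALSE)
  pt - pt[1L]
}

#' Area-weighted mean wall shear stress of a subsegment band
#'
#' @param wss wall-shear magnitudes of the patches, Pa.
#' @param patch_area patch areas (any consistent unit).
#' @return Mean wall shear, Pa.
#' @export
subsegment_wss <- function(wss, patch_area) {
  if (length(wss) == 0L || sum(patch_area) <= 0) {
    stop("subsegment has no wall area", call. = FALSE)
  }
  sum(wss * patch_area) / sum(patch_area)
}

#' Subsegmental resistance and loss coefficient (square law)
#'
#' The square law `dPt = R V^2` with `V = v (A_N + A_{N+1})/2` the
#' volumetric flow rate expressed through the mean cross-section gives
#' `R = (Pt_N - Pt_{N+1}) / (v_N (A_N + A_{N+1})/2)^2` (units Pa s^2 m^-6),
#' and the dimensionless loss coefficient `K = dPt / Pv_N`. `v_N` is the
#' mass-flow-weighted velocity magnitude at the upper plane.
#'
#' @param pt_upper,pt_lower total pressure at planes N and N+1, Pa.
#' @param v_upper velocity at plane N, m/s (> 0).
#' @param area_upper_m2,area_lower_m2 areas of planes N and N+1, m^2.
#' @param rho gas density, kg/m^3.
#' @return List with `dpt_pa`, `K`, `R_pa_s2_m6`, and `flagged_negative`
#'   (`TRUE` when dPt < 0, i.e. apparent total-pressure gain).
#' @examples
#' subsegment_resistance(-10, -14, 5, 1e-4, 1e-4)$R_pa_s2_m6  # 1.6e7
#' @export
subsegment_resistance <- function(pt_upper, pt_lower, v_upper,
                                  area_upper_m2, area_lower_m2,
                                  rho = 1.204) {
  if (any(v_upper <= 0)) stop("'v_upper' must be > 0", call. = FALSE)
  if (any(area_upper_m2 <= 0 | area_lower_m2 <= 0)) {
    stop("areas must be > 0", call. = FALSE)
  }
  dpt <- pt_upper - pt_lower
  V <- v_upper * (area_upper_m2 + area_lower_m2) / 2
  pv <- dynamic_pressure(v_upper, rho)
  list(dpt_pa = dpt, K = dpt / pv, R_pa_s2_m6 = dpt / V^2,
       flagged_negative = dpt < 0)
}

#' Split a subsegment's total-pressure loss into frictional and interior parts
#'
#' The frictional (wall) part is estimated as the wall dissipation power
#' per unit flow, `wss_mean * wall_area * v_mean / Q`: exact in the
#' laminar Poiseuille limit, where the whole loss is wall shear work. The
#' interior part (separation, recirculation, turbulent dissipation in the
#' bulk) is the remainder `dpt - frictional`; it may come out negative when
#' the wall estimate overshoots, and is then reported as a diagnostic, not
#' clamped.
#'
#' @param dpt_pa subsegment total-pressure drop, Pa.
#' @param wss_mean_pa area-weighted mean wall shear, Pa.
#' @param wall_area_m2 lateral wall area, m^2.
#' @param v_mean_ms mean velocity at the upper plane, m/s.
#' @param Q_m3s volumetric flow rate, m^3/s (> 0).
#' @return List with `frictional_pa` and `interior_pa`
#'   (`frictional + interior == dpt` exactly).
#' @export
loss_decomposition <- function(dpt_pa, wss_mean_pa, wall_area_m2,
                               v_mean_ms, Q_m3s) {
  if (any(Q_m3s <= 0)) stop("'Q_m3s' must be > 0", call. = FALSE)
  frictional <- wss_mean_pa * wall_area_m2 * v_mean_ms / Q_m3s
  list(frictional_pa = frictional, interior_pa = dpt_pa - frictional)
}

#' Post-process a sampled flow field over the plane stack
#'
#' Applies the full post-processing chain to a `flow_field_samples` object:
#' per-plane mass-flow-weighted averages of static pressure, velocity
#' magnitude and TKE; dynamic, total and relative total pressure; and
#' per-subsegment total-pressure drop, loss coefficient K, square-law
#' resistance R, mean wall shear, and the frictional/interior loss split.
#'
#' @param field a [make_flow_field()] result (or anything with the same
#'   `planes`/`walls` schema, `flow_direction`, `rho` and `Q_lpm`).
#' @param sections optional `plane_sections` data.frame giving plane areas;
#'   defaults to the areas implied by the field's sample weights.
#' @return List of class `airway_postproc` with `planes` (data.frame:
#'   `index`, `z_mm`, `area_mm2`, `ps_pa`, `v_ms`, `tke_m2s2`, `pv_pa`,
#'   `pt_pa`, `pt_prime_pa`) and `subsegments` (data.frame: `index`,
#'   `dpt_pa`, `K`, `R_pa_s2_m6`, `wss_mean_pa`, `wall_area_mm2`,
#'   `frictional_pa`, `interior_pa`, `flagged_negative`).
#' @export
postprocess_field <- function(field, sections = NULL) {
  pl <- field$planes
  idx <- sort(unique(pl$plane_index))
  rho <- field$rho
  nvec <- field$flow_direction

  per_plane <- lapply(idx, function(i) {
    s <- pl[pl$plane_index == i, ]
    vel <- cbind(s$ux_ms, s$uy_ms, s$uz_ms)
    vmag <- sqrt(rowSums(vel^2))
    data.frame(
      index = i, z_mm = s$z_mm[1L],
      area_mm2 = sum(s$area_weight_mm2),
      ps_pa = mass_flow_average(s$ps_pa, vel, s$area_weight_mm2, rho, nvec),
      v_ms = mass_flow_average(vmag, vel, s$area_weight_mm2, rho, nvec),
      tke_m2s2 = mass_flow_average(s$tke_m2s2, vel, s$area_weight_mm2, rho,
                                   nvec)
    )
  })
  planes <- do.call(rbind, per_plane)
  if (!is.null(sections)) {
    planes$area_mm2 <- sections$area_mm2[match(planes$index, sections$index)]
  }
  planes$pv_pa <- dynamic_pressure(planes$v_ms, rho)
  planes$pt_pa <- total_pressure(planes$ps_pa, planes$pv_pa)
  planes$pt_prime_pa <- relative_total_pressure(planes$pt_pa)

  n <- nrow(planes)
  iu <- seq_len(n - 1L)
  Q <- lpm_to_m3s(field$Q_lpm)
  wss_mean <- vapply(iu, function(i) {
    w <- field$walls[field$walls$subseg_index == i, ]
    if (nrow(w) == 0L) return(NA_real_)
    subsegment_wss(w$wss_pa, w$patch_area_mm2)
  }, numeric(1L))
  wall_area_mm2 <- vapply(iu, function(i) {
    sum(field$walls$patch_area_mm2[field$walls$subseg_index == i])
  }, numeric(1L))

  res <- subsegment_resistance(planes$pt_pa[iu], planes$pt_pa[iu + 1L],
                               planes$v_ms[iu],
                               mm2_to_m2(planes$area_mm2[iu]),
                               mm2_to_m2(planes$area_mm2[iu + 1L]),
                               rho)
  dec <- loss_decomposition(res$dpt_pa, wss_mean,
                            mm2_to_m2(wall_area_mm2),
                            planes$v_ms[iu], Q)
  subseg <- data.frame(
    index = iu, dpt_pa = res$dpt_pa, K = res$K,
    R_pa_s2_m6 = res$R_pa_s2_m6, wss_mean_pa = wss_mean,
    wall_area_mm2 = wall_area_mm2,
    frictional_pa = dec$frictional_pa, interior_pa = dec$interior_pa,
    flagged_negative = res$flagged_negative
  )
  structure(list(planes = planes, subsegments = subseg, rho = rho,
                 Q_lpm = field$Q_lpm),
            class = "airway_postproc")
}

#' @export
print.airway_postproc <- function(x, ...) {
  n <- nrow(x$planes)
  cat("Post-processed plane stack:", n, "planes, Q =", x$Q_lpm, "L/min\n")
  cat(sprintf("  total Pt' drop %.3f Pa; frictional %.3f Pa, interior %.3f Pa\n",
              -x$planes$pt_prime_pa[n],
              sum(x$subsegments$frictional_pa, na.rm = TRUE),
              sum(x$subsegments$interior_pa, na.rm = TRUE)))
  invisible(x)
}
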