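# Synthetic jet/recirculation flow fields sampled on the plane stack.

#' Default jet-core area fraction along the airway
#'
#' The jet core fills the whole lumen (`beta = 1`) from plane I down
#' through the constriction (plane_Amin and any constricted plateau), then
#' narrows linearly with distance into the downstream expansion to 0.6 at
#' the bottom plane: downstream of the constriction the high-velocity jet
#' occupies the posterior core while an anterior recirculation region
#' develops.
#'
#' @param profile an `area_profile`.
#' @return Numeric vector of per-plane core fractions in (0, 1].
#' @export
default_jet_core_fraction <- function(profile) {
  n <- length(profile$z_mm)
  t_mm <- (seq_len(n) - 1L) * profile$spacing_mm
  i_amin <- profile$landmarks$amin
  a_min <- profile$area_mm2[i_amin]
  # end of the constricted region: last plane (at/after amin) within 5% of
  # the minimum area
  past <- which(t_mm > t_mm[i_amin] & profile$area_mm2 > 1.05 * a_min)
  i_end <- if (length(past)) min(past) - 1L else n
  beta <- rep(1, n)
  if (i_end < n) {
    u <- (t_mm[(i_end + 1L):n] - t_mm[i_end]) / (t_mm[n] - t_mm[i_end])
    beta[(i_end + 1L):n] <- 1 - 0.4 * u
  }
  beta
}

#' Generate discrete flow-field samples on the plane stack
#'
#' Builds per-plane velocity/static-pressure/TKE samples and per-subsegment
#' wall-shear samples with the structure the pressure-loss analysis
#' assumes: a forward jet core of area fraction `beta` per plane, the
#' remaining (anterior) area carrying reversed flow at `recirc_strength`
#' times the core speed, speeds scaled so the net volumetric flux through
#' every plane equals `Q_lpm` exactly. Pressures and wall shear come from
#' the quasi-1D solver ([solve_quasi1d()]): the static-pressure samples are
#' set so that each plane's mass-flow-weighted *total* pressure equals the
#' solver's -- the solver owns the loss budget, while the jet structure
#' redistributes it between static and dynamic pressure (for a uniform
#' field, `beta = 1`, the static pressures are exactly the solver's). TKE
#' peaks at the core/recirculation interface where the shear layer sits.
#'
#' Sampling uses an equal-area polar grid whose radial boundaries include
#' the core/recirculation interface exactly, so the reversed-flow area
#' fraction is exactly `1 - beta`. The grid is offset toward the posterior
#' (-y) wall to mimic the posterior position of the pharyngeal jet; sample
#' coordinates are carried in the output but only area weights and
#' velocities enter any computed statistic.
#'
#' @param profile an [make_area_profile()] result.
#' @param Q_lpm volumetric flow rate, L/min (default 18).
#' @param jet_core_fraction per-plane numeric vector of core area fractions
#'   in (0, 1], or `NULL` for [default_jet_core_fraction()].
#' @param recirc_strength reversed-flow speed as a fraction of the core
#'   speed, in `[0, 1)`.
#' @param tke_model `"shear"` (interface-peaked) or `"none"`.
#' @param fluid a [fluid_properties()].
#' @param cfg a [solver_config()]; its `Q_lpm` is overridden by `Q_lpm`.
#' @param n_r,n_sector radial and angular sampling resolution per plane.
#' @param n_wall_patches wall patches per subsegment.
#' @param wss_noise relative amplitude of uniform noise on wall-shear
#'   samples (0 = exact solver values).
#' @param seed integer seed (wall-shear noise).
#' @return List of class `flow_field_samples` with `planes` (data.frame:
#'   `plane_index`, `z_mm`, `x_mm`, `y_mm`, `area_weight_mm2`, `ux_ms`,
#'   `uy_ms`, `uz_ms`, `ps_pa`, `tke_m2s2`), `walls` (data.frame:
#'   `subseg_index`, `patch_area_mm2`, `wss_pa`), `flow_direction` (unit
#'   vector, bulk inspiratory direction), `rho`, `Q_lpm`, and the solver
#'   `solution` used for pressures.
#' @export
make_flow_field <- function(profile,
                            Q_lpm = 18,
                            jet_core_fraction = NULL,
                            recirc_strength = 0.2,
                            tke_model = c("shear", "none"),
                            fluid = fluid_properties(),
                            cfg = solver_config(),
                            n_r = 8L, n_sector = 12L,
                            n_wall_patches = 8L,
                            wss_noise = 0,
                            seed = 1L) {
  stopifnot(inherits(profile, "area_profile"))
  tke_model <- match.arg(tke_model)
  if (recirc_strength < 0 || recirc_strength >= 1) {
    stop("'recirc_strength' must lie in [0, 1)", call. = FALSE)
  }
  n <- length(profile$z_mm)
  beta <- if (is.null(jet_core_fraction)) {
    default_jet_core_fraction(profile)
  } else {
    rep_len(as.numeric(jet_core_fraction), n)
  }
  if (any(beta <= 0 | beta > 1)) {
    stop("'jet_core_fraction' must lie in (0, 1]", call. = FALSE)
  }
  gamma <- recirc_strength
  denom <- beta - (1 - beta) * gamma
  if (any(denom <= 1e-9)) {
    stop("flux normalization impossible: jet core fraction too small for ",
         "the requested recirculation strength (non-positive net flux)",
         call. = FALSE)
  }
  cfg$Q_lpm <- Q_lpm
  sol <- solve_quasi1d(profile, fluid, cfg)
  Q <- lpm_to_m3s(Q_lpm)

  plane_list <- vector("list", n)
  for (i in seq_len(n)) {
    A_mm2 <- profile$area_mm2[i]
    A <- mm2_to_m2(A_mm2)
    R <- sqrt(A_mm2 / pi)
    # equal-area radial boundaries, with the interface radius inserted
    s <- seq(0, 1, length.out = n_r + 1L)
    if (beta[i] < 1) s <- sort(unique(c(s, beta[i])))
    nr <- length(s) - 1L
    s_lo <- rep(s[-length(s)], each = n_sector)
    s_hi <- rep(s[-1L], each = n_sector)
    th <- rep(2 * pi * (seq_len(n_sector) - 0.5) / n_sector, times = nr)
    cell_area <- A_mm2 * (s_hi - s_lo) / n_sector
    r_mid <- R * sqrt((s_lo + s_hi) / 2)
    s_mid <- (s_lo + s_hi) / 2
    forward <- s_mid < beta[i] | beta[i] == 1
    u_core <- Q / (A * denom[i])
    # z decreases downstream: forward axial velocity is negative
    uz <- ifelse(forward, -u_core, gamma * u_core)
    # mass-flow-weighted velocity magnitude of this discrete profile; the
    # static pressure is anchored so that ps + rho*v_mfa^2/2 = solver Pt
    b <- beta[i]
    v_mfa <- u_core * (b + (1 - b) * gamma^2) / (b + (1 - b) * gamma)
    ps_i <- sol$planes$pt_pa[i] - 0.5 * fluid$rho * v_mfa^2
    # offset the sampling frame toward the posterior (-y) wall
    y_off <- -(R - R * sqrt(beta[i])) * 0.5
    tke <- if (tke_model == "shear") {
      k_bg <- 1.5 * (0.05 * u_core)^2
      if (beta[i] < 1) {
        du <- u_core * (1 + gamma)
        r_if <- R * sqrt(beta[i])
        k_bg + 0.1 * du^2 * exp(-((r_mid - r_if) / (0.1 * R))^2)
      } else {
        rep(k_bg, length(r_mid))
      }
    } else {
      rep(0, length(r_mid))
    }
    plane_list[[i]] <- data.frame(
      plane_index = i, z_mm = profile$z_mm[i],
      x_mm = r_mid * cos(th), y_mm = r_mid * sin(th) + y_off,
      area_weight_mm2 = cell_area,
      ux_ms = 0, uy_ms = 0, uz_ms = uz,
      ps_pa = ps_i, tke_m2s2 = tke
    )
  }
  planes <- do.call(rbind, plane_list)

  sub <- sol$subsegments
  nw <- nrow(sub) * n_wall_patches
  noise <- if (wss_noise > 0) {
    with_seed(seed, stats::runif(nw, -wss_noise, wss_noise))
  } else {
    rep(0, nw)
  }
  walls <- data.frame(
    subseg_index = rep(sub$index, each = n_wall_patches),
    patch_area_mm2 = rep(sub$wall_area_mm2 / n_wall_patches,
                         each = n_wall_patches),
    wss_pa = rep(sub$tau_wall_pa, each = n_wall_patches) * (1 + noise)
  )

  structure(
    list(planes = planes, walls = walls,
         flow_direction = c(0, 0, -1), rho = fluid$rho, Q_lpm = Q_lpm,
         solution = sol),
    class = "flow_field_samples"
  )
}

#' @export
print.flow_field_samples <- function(x, ...) {
  cat("Flow-field samples:", length(unique(x$planes$plane_index)),
      "planes,", nrow(x$walls), "wall patches, Q =", x$Q_lpm, "L/min\n")
  invisible(x)
}
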