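# Quasi-1D extended Bernoulli solver: total-pressure marching with Darcy
# friction and Borda-Carnot expansion losses over an axial area profile.

#' Gas properties
#'
#' Defaults are air at roughly 20 degrees C.
#'
#' @param rho density, kg/m^3.
#' @param mu dynamic viscosity, Pa s.
#' @return list of class `fluid_properties`.
#' @export
fluid_properties <- function(rho = 1.204, mu = 1.81e-5) {
  stopifnot_scalar(rho, "rho", positive = TRUE)
  stopifnot_scalar(mu, "mu", positive = TRUE)
  structure(list(rho = rho, mu = mu), class = "fluid_properties")
}

#' Quasi-1D solver configuration
#'
#' @param Q_lpm inspiratory volumetric flow rate, L/min (18 by default, the
#'   fixed rate all analyses in this package assume).
#' @param inlet_total_pressure_pa total-pressure datum at plane I, Pa. Kept
#'   at 0 so that the relative total pressure Pt' referenced to plane I has
#'   its datum built in and upstream (nasal) losses never enter.
#' @param friction_model `"blended"` (laminar 64/Re below Re = 2000,
#'   Blasius 0.316 Re^-0.25 above 4000, linear blend between -- the
#'   pharyngeal constriction sits in this transitional band),
#'   `"laminar"`, `"blasius"`, or `"none"` (exact lossless Bernoulli).
#' @param expansion_loss `"borda_carnot"` or `"none"`.
#' @param contraction_loss_coeff loss coefficient applied to the downstream
#'   dynamic pressure on contractions (0 = ideal acceleration).
#' @return list of class `solver_config`.
#' @export
solver_config <- function(Q_lpm = 18,
                          inlet_total_pressure_pa = 0,
                          friction_model = c("blended", "laminar",
                                             "blasius", "none"),
                          expansion_loss = c("borda_carnot", "none"),
                          contraction_loss_coeff = 0) {
  stopifnot_scalar(Q_lpm, "Q_lpm", positive = TRUE)
  stopifnot_scalar(contraction_loss_coeff, "contraction_loss_coeff",
                   nonneg = TRUE)
  structure(
    list(Q_lpm = Q_lpm,
         inlet_total_pressure_pa = inlet_total_pressure_pa,
         friction_model = match.arg(friction_model),
         expansion_loss = match.arg(expansion_loss),
         contraction_loss_coeff = contraction_loss_coeff),
    class = "solver_config"
  )
}

#' Darcy friction factor
#'
#' Laminar `f = 64/Re` for `Re <= 2000`; Blasius `f = 0.316 Re^-0.25` for
#' `Re >= 4000`; linear interpolation between the two endpoint values in
#' the transitional band (continuous at both ends).
#'
#' @param Re Reynolds number (> 0), vectorized.
#' @param model `"blended"`, `"laminar"`, `"blasius"` or `"none"`.
#' @return Friction factor(s).
#' @export
darcy_friction <- function(Re, model = "blended") {
  if (model == "none") return(rep(0, length(Re)))
  if (any(!is.finite(Re) | Re <= 0)) {
    stop("'Re' must be positive and finite", call. = FALSE)
  }
  switch(model,
    laminar = 64 / Re,
    blasius = 0.316 * Re^(-0.25),
    blended = {
      f_lo <- 64 / 2000
      f_hi <- 0.316 * 4000^(-0.25)
      ifelse(Re <= 2000, 64 / Re,
             ifelse(Re >= 4000, 0.316 * Re^(-0.25),
                    f_lo + (Re - 2000) / 2000 * (f_hi - f_lo)))
    },
    stop("unknown friction model '", model, "'", call. = FALSE)
  )
}

#' Circular-equivalent Reynolds number of a duct cross-section
#'
#' Uses the circular-equivalent hydraulic diameter `D_h = 2 sqrt(A/pi)` and
#' the bulk velocity `v = Q/A`.
#'
#' @param Q_lpm volumetric flow rate, L/min (>= 0).
#' @param area_mm2 cross-sectional area, mm^2 (> 0). Vectorized.
#' @param fluid a [fluid_properties()].
#' @return Reynolds number(s); 0 when `Q_lpm = 0`.
#' @examples
#' reynolds_number(18, 54.43)  # approx. 3.05e3 at the narrowest plane_Amin
#' @export
reynolds_number <- function(Q_lpm, area_mm2, fluid = fluid_properties()) {
  if (any(area_mm2 <= 0)) stop("'area_mm2' must be > 0", call. = FALSE)
  if (Q_lpm < 0) stop("'Q_lpm' must be >= 0", call. = FALSE)
  A <- mm2_to_m2(area_mm2)
  v <- lpm_to_m3s(Q_lpm) / A
  dh <- 2 * sqrt(A / pi)
  fluid$rho * v * dh / fluid$mu
}

#' Borda-Carnot total-pressure loss at an area expansion
#'
#' `dPt = 1/2 rho v_up^2 (1 - A_up/A_down)^2`: the irreversible
#' total-pressure loss of a sudden expansion, the model's stand-in for
#' separation/recirculation ("interior") loss. Zero when the areas are
#' equal, and zero on contractions (no expansion loss). Approaches the full
#' upstream dynamic pressure as `A_down -> Inf`.
#'
#' @param A_up,A_down areas up/downstream (any consistent unit), vectorized.
#' @param v_up upstream bulk velocity, m/s.
#' @param rho gas density, kg/m^3.
#' @return Pressure loss, Pa (>= 0).
#' @export
borda_carnot_loss <- function(A_up, A_down, v_up, rho = 1.204) {
  if (any(A_up <= 0 | A_down <= 0)) stop("areas must be > 0", call. = FALSE)
  ifelse(A_down >= A_up, 0.5 * rho * v_up^2 * (1 - A_up / A_down)^2, 0)
}

#' Solve the quasi-1D pressure march over an area profile
#'
#' Marches the total pressure downstream from the plane-I datum:
#' `Pt[N+1] = Pt[N] - dPt_friction[N] - dPt_expansion[N]`, with the bulk
#' velocity `v[N] = Q/A[N]`, static pressure `Ps[N] = Pt[N] - Pv[N]`
#' (so `Pt = Ps + Pv` holds identically), Darcy friction loss
#' `f (dz/D_h) (rho v^2/2)` evaluated at the upstream plane of each
#' subsegment, wall shear `tau_w = (f/8) rho v^2`, and Borda-Carnot loss on
#' expansions. All loss terms are non-negative, so Pt never increases
#' downstream.
#'
#' @param profile an [make_area_profile()] result (or any `area_profile`).
#' @param fluid a [fluid_properties()].
#' @param cfg a [solver_config()].
#' @return List of class `pressure_profile` with `planes` (data.frame:
#'   `index`, `z_mm`, `area_mm2`, `v_ms`, `ps_pa`, `pv_pa`, `pt_pa`,
#'   `pt_prime_pa`) and `subsegments` (data.frame: `index`, `Re`,
#'   `f_darcy`, `tau_wall_pa`, `dpt_friction_pa`, `dpt_expansion_pa`,
#'   `wall_area_mm2`).
#' @export
solve_quasi1d <- function(profile,
                          fluid = fluid_properties(),
                          cfg = solver_config()) {
  stopifnot(inherits(profile, "area_profile"))
  n <- length(profile$z_mm)
  A <- mm2_to_m2(profile$area_mm2)
  Q <- lpm_to_m3s(cfg$Q_lpm)
  v <- Q / A
  dh <- 2 * sqrt(A / pi)
  Re <- fluid$rho * v * dh / fluid$mu
  f <- darcy_friction(Re, cfg$friction_model)
  tau <- f / 8 * fluid$rho * v^2

  dz <- mm_to_m(abs(diff(profile$z_mm)))
  iu <- seq_len(n - 1L)
  dpt_fric <- f[iu] * (dz / dh[iu]) * 0.5 * fluid$rho * v[iu]^2
  dpt_exp <- if (cfg$expansion_loss == "borda_carnot") {
    borda_carnot_loss(A[iu], A[iu + 1L], v[iu], fluid$rho)
  } else {
    rep(0, n - 1L)
  }
  if (cfg$contraction_loss_coeff > 0) {
    contr <- A[iu + 1L] < A[iu]
    dpt_exp[contr] <- dpt_exp[contr] +
      cfg$contraction_loss_coeff * 0.5 * fluid$rho * v[iu + 1L][contr]^2
  }
  pt <- cfg$inlet_total_pressure_pa - cumsum(c(0, dpt_fric + dpt_exp))
  pv <- 0.5 * fluid$rho * v^2
  ps <- pt - pv

  # circular-equivalent wall band area, for the frictional-loss bookkeeping
  perim <- pi * (dh[iu] + dh[iu + 1L]) / 2
  wall_area <- perim * dz * MM2_PER_M2

  structure(
    list(planes = data.frame(index = seq_len(n), z_mm = profile$z_mm,
                             area_mm2 = profile$area_mm2,
                             v_ms = v, ps_pa = ps, pv_pa = pv, pt_pa = pt,
                             pt_prime_pa = pt - pt[1L]),
         subsegments = data.frame(index = iu, Re = Re[iu], f_darcy = f[iu],
                                  tau_wall_pa = tau[iu],
                                  dpt_friction_pa = dpt_fric,
                                  dpt_expansion_pa = dpt_exp,
                                  wall_area_mm2 = wall_area),
         fluid = fluid, config = cfg),
    class = "pressure_profile"
  )
}

#' @export
print.pressure_profile <- function(x, ...) {
  n <- nrow(x$planes)
  cat("Quasi-1D pressure solution:", n, "planes at Q =",
      x$config$Q_lpm, "L/min\n")
  cat(sprintf("  total Pt' drop %.3f Pa (friction %.3f, expansion %.3f)\n",
              -x$planes$pt_prime_pa[n],
              sum(x$subsegments$dpt_friction_pa),
              sum(x$subsegments$dpt_expansion_pa)))
  invisible(x)
}
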