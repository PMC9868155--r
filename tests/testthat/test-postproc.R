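# Mass-flow-weighted averages, pressure algebra, resistance, loss split.

test_that("mass-flow average weights samples by their mass flux", {
  # constant field: any velocities
  v <- cbind(0, 0, -runif(5, 1, 3))
  expect_equal(mass_flow_average(rep(7, 5), v, runif(5, 1, 2)), 7)
  # hand-evaluated two-sample case: weights 1 and 3, values 0 and 1
  v2 <- cbind(c(0, 0), c(0, 0), c(-1, -3))
  expect_equal(mass_flow_average(c(0, 1), v2, c(1, 1), rho = 1), 0.75)
  # all flow tangential to the plane: undefined
  v3 <- cbind(c(1, 2), c(0, 1), c(0, 0))
  expect_error(mass_flow_average(c(0, 1), v3, c(1, 1)), "zero total mass flux")
})

test_that("pressure algebra follows its defining identities", {
  expect_equal(dynamic_pressure(0), 0)
  expect_equal(dynamic_pressure(10, rho = 1.2), 60)
  expect_equal(total_pressure(-100, 60), -40)
  expect_equal(relative_total_pressure(c(-5, -20, -45)), c(0, -15, -40))
  expect_equal(relative_total_pressure(rep(-3, 4)), rep(0, 4))
  set.seed(1)
  ps <- rnorm(20, -30, 10)
  pv <- dynamic_pressure(runif(20, 0, 8))
  # Pt via the sum equals Ps - (-Pv) identically
  expect_identical(total_pressure(ps, pv), ps - (-pv))
  pt <- total_pressure(ps, pv)
  expect_identical(relative_total_pressure(pt)[1L], 0)
})

test_that("subsegment wall shear is the area-weighted patch mean", {
  expect_equal(subsegment_wss(rep(0.5, 4), rep(2, 4)), 0.5)
  expect_equal(subsegment_wss(c(1, 0), c(1, 3)), 0.25)
  expect_error(subsegment_wss(numeric(0), numeric(0)), "no wall area")
})

test_that("square-law resistance matches direct evaluation and round-trips K", {
  res <- subsegment_resistance(-10, -14, 5, 1e-4, 1e-4)
  expect_equal(res$R_pa_s2_m6, 4 / (5e-4)^2)
  expect_equal(res$dpt_pa, 4)
  expect_false(res$flagged_negative)
  z <- subsegment_resistance(-10, -10, 5, 1e-4, 1e-4)
  expect_equal(z$R_pa_s2_m6, 0)
  expect_equal(z$K, 0)
  # Eq 6-9 consistency on random records: dPt = K Pv = R (v Abar)^2
  set.seed(7)
  for (i in 1:20) {
    v <- runif(1, 1, 10)
    a1 <- runif(1, 3e-5, 3e-4)
    a2 <- runif(1, 3e-5, 3e-4)
    dpt <- runif(1, -2, 6)
    r <- subsegment_resistance(0, -dpt, v, a1, a2, rho = 1.204)
    pv <- dynamic_pressure(v, 1.204)
    expect_equal(r$K * pv, dpt, tolerance = 1e-12)
    expect_equal(r$R_pa_s2_m6 * (v * (a1 + a2) / 2)^2, dpt,
                 tolerance = 1e-12)
    expect_identical(r$flagged_negative, dpt < 0)
  }
})

test_that("loss decomposition conserves the drop and is exact for Poiseuille flow", {
  # no wall shear: the whole drop is interior loss
  d0 <- loss_decomposition(2.5, 0, 1e-3, 4, 3e-4)
  expect_equal(d0$frictional_pa, 0)
  expect_equal(d0$interior_pa, 2.5)
  # laminar tube: wall dissipation accounts for the entire drop
  cfg <- solver_config(friction_model = "laminar", expansion_loss = "none")
  prof <- cylinder_profile(5, 50)
  fld <- make_flow_field(prof, jet_core_fraction = 1, cfg = cfg)
  post <- postprocess_field(fld)
  tot_d <- sum(post$subsegments$dpt_pa)
  tot_f <- sum(post$subsegments$frictional_pa)
  expect_equal(tot_f / tot_d, 1, tolerance = 0.02)
  expect_equal(post$subsegments$frictional_pa + post$subsegments$interior_pa,
               post$subsegments$dpt_pa, tolerance = 1e-15)
  # mean WSS against the Hagen-Poiseuille closed form
  tau_hp <- 4 * fluid_properties()$mu * (18 / 6e4) / (pi * 0.005^3)
  expect_equal(mean(post$subsegments$wss_mean_pa), tau_hp, tolerance = 0.01)
})

test_that("post-processing reproduces the solver pressures on uniform fields", {
  for (tpl in c("FTP1_MC", "FTP4_MO")) {
    prof <- make_area_profile(airway_spec(tpl))
    sol <- solve_quasi1d(prof)
    fld <- make_flow_field(prof, jet_core_fraction = 1)
    post <- postprocess_field(fld)
    expect_equal(post$planes$ps_pa, sol$planes$ps_pa, tolerance = 5e-3,
                 info = tpl)
    expect_equal(post$planes$pv_pa, sol$planes$pv_pa, tolerance = 5e-3,
                 info = tpl)
    expect_equal(post$planes$pt_pa, sol$planes$pt_pa, tolerance = 5e-3,
                 info = tpl)
    expect_identical(post$planes$pt_prime_pa[1L], 0)
  }
})

test_that("interior loss dominates downstream of a rapid expansion", {
  # FTP1 mouth-closed pattern: tight constriction then rapid expansion
  prof <- make_area_profile(airway_spec("FTP1_MC"))
  fld <- make_flow_field(prof)
  post <- postprocess_field(fld)
  i_amin <- prof$landmarks$amin
  up <- post$subsegments$index < i_amin
  share_up <- sum(post$subsegments$interior_pa[up]) /
    sum(post$subsegments$dpt_pa[up])
  share_dn <- sum(post$subsegments$interior_pa[!up]) /
    sum(post$subsegments$dpt_pa[!up])
  expect_gt(share_dn, share_up)
})
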