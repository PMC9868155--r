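# Quasi-1D extended Bernoulli solver.

test_that("friction factor laws and transitional blending are continuous", {
  expect_equal(darcy_friction(1000, "laminar"), 0.064)
  expect_equal(darcy_friction(10000, "blasius"), 0.316 * 10000^(-0.25))
  eps <- 1e-9
  expect_equal(darcy_friction(2000 - eps, "blended"),
               darcy_friction(2000, "blended"), tolerance = 1e-12)
  expect_equal(darcy_friction(4000 + eps, "blended"),
               darcy_friction(4000, "blended"), tolerance = 1e-12)
  expect_true(all(darcy_friction(c(100, 3000, 50000), "none") == 0))
  expect_error(darcy_friction(-5, "laminar"), "positive")
})

test_that("Reynolds number uses the circular-equivalent hydraulic diameter", {
  fluid <- fluid_properties()
  # independent closed form: Re = rho * (Q/A) * 2 sqrt(A/pi) / mu
  A <- 54.43e-6
  Q <- 18 / 6e4
  re_oracle <- fluid$rho * (Q / A) * 2 * sqrt(A / pi) / fluid$mu
  expect_equal(reynolds_number(18, 54.43), re_oracle, tolerance = 1e-12)
  expect_equal(reynolds_number(18, 2 * 54.43) / reynolds_number(18, 54.43),
               1 / sqrt(2), tolerance = 1e-12)
  expect_equal(reynolds_number(0, 54.43), 0)
  expect_error(reynolds_number(18, -1), "area")
})

test_that("Borda-Carnot loss matches its closed form and limits", {
  expect_equal(borda_carnot_loss(100, 100, 5), 0)
  expect_equal(borda_carnot_loss(100, Inf, 5, rho = 1.2),
               0.5 * 1.2 * 25)
  expect_equal(borda_carnot_loss(50, 100, 5, rho = 1.2), 3.75)
  # contraction: no expansion loss
  expect_equal(borda_carnot_loss(100, 50, 5), 0)
})

test_that("lossless solve reduces to Bernoulli: flat Ps in a tube, Pt identically zero", {
  cfg <- solver_config(friction_model = "none", expansion_loss = "none")
  sol <- solve_quasi1d(cylinder_profile(), cfg = cfg)
  expect_true(all(abs(sol$planes$pt_pa) < 1e-12))
  expect_lt(diff(range(sol$planes$ps_pa)), 1e-12)
  # converging-diverging: Ps minimum exactly at the constriction, full recovery
  prof <- make_area_profile(hourglass_spec(rel = 0.5, expansion = 250))
  solb <- solve_quasi1d(prof, cfg = cfg)
  expect_true(all(abs(solb$planes$pt_prime_pa) < 1e-12))
  expect_identical(which.min(solb$planes$ps_pa), prof$landmarks$amin)
  expect_equal(solb$planes$ps_pa[1L], solb$planes$ps_pa[length(prof$z_mm)],
               tolerance = 1e-12)
})

test_that("laminar straight tube reproduces Hagen-Poiseuille drop and wall shear", {
  r <- 0.005
  L <- 0.05
  Q <- 18 / 6e4
  fluid <- fluid_properties()
  dp_hp <- 8 * fluid$mu * L * Q / (pi * r^4)
  tau_hp <- 4 * fluid$mu * Q / (pi * r^3)
  sol <- solve_quasi1d(cylinder_profile(5, 50),
                       cfg = solver_config(friction_model = "laminar"))
  n <- nrow(sol$planes)
  expect_equal(sol$planes$pt_pa[1L] - sol$planes$pt_pa[n], dp_hp,
               tolerance = 0.01)
  expect_equal(mean(sol$subsegments$tau_wall_pa), tau_hp, tolerance = 0.01)
})

test_that("total pressure never increases downstream and Pt = Ps + Pv holds", {
  for (tpl in all_templates) {
    sol <- solve_quasi1d(make_area_profile(airway_spec(tpl)))
    expect_true(all(diff(sol$planes$pt_pa) <= 1e-15), info = tpl)
    expect_equal(sol$planes$pt_pa, sol$planes$ps_pa + sol$planes$pv_pa,
                 tolerance = 1e-15, info = tpl)
    expect_true(all(sol$subsegments$dpt_friction_pa >= 0), info = tpl)
    expect_true(all(sol$subsegments$dpt_expansion_pa >= 0), info = tpl)
  }
})

test_that("total loss grows as the constriction narrows or its plateau lengthens", {
  drop_of <- function(amin, plateau) {
    prof <- make_area_profile(hourglass_spec(length_mm = 50, amin = amin,
                                             rel = 0.4, plateau = plateau))
    sol <- solve_quasi1d(prof)
    -sol$planes$pt_prime_pa[nrow(sol$planes)]
  }
  drops_amin <- vapply(c(60, 90, 120, 150), drop_of, numeric(1L),
                       plateau = 5)
  expect_true(all(diff(drops_amin) < 0))
  drops_plat <- vapply(c(0, 5, 10, 15), function(p) drop_of(80, p),
                       numeric(1L))
  expect_true(all(diff(drops_plat) > 0))
})
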