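# End-to-end pipeline orchestration and file outputs.

test_that("template end-to-end run recovers the configured plane_Amin area", {
  out <- withr::local_tempdir()
  cfg <- run_config(template = "FTP4_MO", seed = 3L)
  res <- run_report(cfg, out)
  expect_true(all(file.exists(res$files)))
  morpho <- jsonlite::read_json(res$files[["morphometry"]])
  expect_equal(morpho$regions$velopharynx$amin_area_cm2, 0.5443,
               tolerance = 0.02)
  expect_identical(morpho$n_planes, 103L)
  expect_identical(morpho$dividing_plane_index, 53L)
  # subsegment table carries level labels
  sub <- utils::read.csv(res$files[["subsegments"]])
  expect_true(all(sub$level %in% 1:3))
})

test_that("identical config and seed give byte-identical outputs", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  run_report(run_config(template = "FTP2_MO", seed = 11L), out1)
  run_report(run_config(template = "FTP2_MO", seed = 11L), out2)
  for (f in c("morphometry.json", "planes.csv", "subsegments.csv",
              "levels.json")) {
    a <- readBin(file.path(out1, f), "raw", file.size(file.path(out1, f)))
    b <- readBin(file.path(out2, f), "raw", file.size(file.path(out2, f)))
    expect_identical(a, b, info = f)
  }
})

test_that("derived columns of the written tables recompute exactly", {
  out <- withr::local_tempdir()
  res <- run_report(run_config(template = "FTP3_MC", seed = 2L), out)
  pl <- utils::read.csv(res$files[["planes"]])
  rho <- 1.204
  expect_equal(pl$pv_pa, 0.5 * rho * pl$v_ms^2, tolerance = 1e-9)
  expect_equal(pl$pt_pa, pl$ps_pa + pl$pv_pa, tolerance = 1e-9)
  expect_equal(pl$pt_prime_pa, pl$pt_pa - pl$pt_pa[1L], tolerance = 1e-9)
  sub <- utils::read.csv(res$files[["subsegments"]])
  n <- nrow(pl)
  dpt <- pl$pt_pa[-n] - pl$pt_pa[-1L]
  expect_equal(sub$dpt_pa, dpt, tolerance = 1e-9)
  vbar <- pl$v_ms[-n]
  abar <- (pl$area_mm2[-n] + pl$area_mm2[-1L]) / 2 / 1e6
  expect_equal(sub$R_pa_s2_m6, dpt / (vbar * abar)^2, tolerance = 1e-6)
  expect_equal(sub$frictional_pa + sub$interior_pa, sub$dpt_pa,
               tolerance = 1e-9)
})

test_that("an external mesh needs an explicit dividing-plane landmark", {
  expect_error(run_config(mesh_path = "somewhere.stl"),
               "dividing_index")
  # and a failing stage is reported by name
  cfg <- run_config(mesh_path = "no-such-file.stl", dividing_index = 5L)
  expect_error(run_report(cfg), "read-mesh")
})

test_that("a YAML config round-trips through the pipeline", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("template: FTP4_MC",
               "Q_lpm: 18",
               "seed: 9",
               "theta_exp: 1.6",
               "fluid:",
               "  rho: 1.204",
               "  mu: 1.81e-5",
               "solver:",
               "  friction_model: blended",
               "  expansion_loss: borda_carnot"), f)
  cfg <- read_run_config(f)
  expect_identical(cfg$seed, 9L)
  expect_equal(cfg$theta_exp, 1.6)
  res <- run_report(cfg)
  expect_identical(res$morphometry$n_planes, 91L)
})

test_that("external STL meshes run through the same pipeline", {
  stl <- withr::local_tempfile(fileext = ".stl")
  spec <- hourglass_spec(length_mm = 20, rel = 0.5)
  write_stl(make_surface_mesh(make_area_profile(spec), spec), stl)
  cfg <- run_config(mesh_path = stl, dividing_index = 25L)
  res <- run_report(cfg)
  expect_identical(res$morphometry$n_planes, 41L)
  expect_equal(res$morphometry$regions$velopharynx$amin_area_cm2, 1,
               tolerance = 0.02)
})
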