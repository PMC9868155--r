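# Plane stack slicing, plane_Amin, regions, subsegments, morphometry.

test_that("a disjoint bifid lumen sums its loop areas", {
  # two parallel tubes of 30 and 20 mm^2, far apart in x
  m1 <- make_surface_mesh(cylinder_profile(sqrt(30 / pi), 10), mesh_spec(48L))
  m2 <- make_surface_mesh(cylinder_profile(sqrt(20 / pi), 10), mesh_spec(48L))
  m2$vertices[, 1L] <- m2$vertices[, 1L] + 20
  mesh <- structure(list(vertices = rbind(m1$vertices, m2$vertices),
                         faces = rbind(m1$faces,
                                       m2$faces + nrow(m1$vertices))),
                    class = "airway_mesh")
  sec <- slice_airway(mesh, 10, 0, 0.5)
  expect_true(all(sec$n_loops == 2L))
  expect_true(all(abs(sec$area_mm2 / 50 - 1) < 0.01))
})

test_that("an out-of-range plane reports the offending z", {
  mesh <- cylinder_mesh(length_mm = 10)
  expect_error(slice_airway(mesh, 12, 0, 0.5), "z = 12")
  expect_error(slice_airway(mesh, 10, 10, 0.5), "top_z")
})

test_that("plane_Amin is the first minimal plane and needs a real constriction", {
  sec <- data.frame(index = 1:5, z_mm = 5:1,
                    area_mm2 = c(5, 4, 3, 4, 5), region = NA)
  expect_identical(find_plane_amin(sec), 3L)
  sec$area_mm2 <- c(5, 3, 3, 3, 5)
  expect_identical(find_plane_amin(sec), 2L)
  sec$area_mm2 <- rep(4, 5)
  expect_error(find_plane_amin(sec), "no constriction")
})

test_that("region assignment partitions the stack once at the dividing plane", {
  sec <- data.frame(index = 1:10, z_mm = 10:1, area_mm2 = rep(10, 10),
                    region = NA)
  out <- assign_regions(sec, 4L)
  expect_identical(sum(out$region == "velopharynx"), 4L)
  expect_identical(sum(out$region == "oropharynx"), 6L)
  expect_identical(sum(diff(out$region == "velopharynx") != 0), 1L)
  expect_error(assign_regions(sec, 10L), "dividing_index")
  expect_error(assign_regions(sec, 1L), "dividing_index")
})

test_that("regional plane_Amin search is restricted to the region", {
  spec <- airway_spec("FTP4_MO")
  prof <- make_area_profile(spec)
  mesh <- make_surface_mesh(prof, spec)
  sec <- assign_regions(slice_airway(mesh, max(prof$z_mm), min(prof$z_mm)),
                        53L)
  oro <- find_plane_amin(sec, "oropharynx")
  expect_gte(oro, 54L)
  velo <- find_plane_amin(sec, "velopharynx")
  expect_identical(velo, 41L)
})

test_that("area ratio series follows the printed plane-N-over-plane-N+1 form", {
  sec <- data.frame(index = 1:3, z_mm = 3:1, area_mm2 = c(100, 100, 100))
  expect_equal(area_ratio_series(sec), c(1, 1))
  sec$area_mm2 <- c(100, 50, 25)
  expect_equal(area_ratio_series(sec), c(2, 2))
  # narrowing limb of an hourglass: all ratios above 1 upstream of amin
  prof <- make_area_profile(hourglass_spec(rel = 0.5))
  secp <- data.frame(index = seq_along(prof$z_mm), z_mm = prof$z_mm,
                     area_mm2 = prof$area_mm2)
  r <- area_ratio_series(secp)
  expect_true(all(r[seq_len(prof$landmarks$amin - 1L)] >= 1))
  # and the ratio-to-amin variant is 1 at the minimum, >= 1 elsewhere
  ra <- area_ratio_to_amin(secp)
  expect_equal(ra[prof$landmarks$amin], 1)
  expect_true(all(ra >= 1))
})

test_that("subsegments pair consecutive planes and carry the band wall area", {
  mesh <- cylinder_mesh(r_mm = 5, length_mm = 50)
  sec <- slice_airway(mesh, 50, 0, 0.5)
  sub <- build_subsegments(sec, mesh)
  expect_equal(nrow(sub), nrow(sec) - 1L)
  expect_identical(sub$upper_plane, sub$index)
  expect_identical(sub$lower_plane, sub$index + 1L)
  expect_true(all(abs(sub$wall_area_mm2 / (2 * pi * 5 * 0.5) - 1) < 0.02))
  # profile-based fallback agrees with the mesh band for a cylinder
  sub2 <- build_subsegments(sec)
  expect_true(all(abs(sub2$wall_area_mm2 / sub$wall_area_mm2 - 1) < 0.02))
})

test_that("morphometry reports length, regions and constriction flags", {
  spec <- airway_spec("FTP4_MO")
  prof <- make_area_profile(spec)
  mesh <- make_surface_mesh(prof, spec)
  sec <- assign_regions(slice_airway(mesh, max(prof$z_mm), min(prof$z_mm)),
                        53L)
  rep <- morphometry_report(sec)
  expect_equal(rep$segment_length_cm, 5.10, tolerance = 1e-8)
  expect_identical(rep$n_planes, 103L)
  expect_identical(rep$dividing_plane_index, 53L)
  expect_equal(rep$regions$velopharynx$amin_area_cm2, 0.5443,
               tolerance = 0.02)
  # degenerate cylinder: flagged, not an error
  csec <- assign_regions(slice_airway(cylinder_mesh(length_mm = 10), 10, 0),
                         10L)
  crep <- morphometry_report(csec)
  expect_true(crep$regions$velopharynx$no_constriction)
  expect_error(morphometry_report(slice_airway(cylinder_mesh(length_mm = 10),
                                               10, 0)),
               "assign_regions")
})
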