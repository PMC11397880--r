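test_that("projected distance ratio matches the closed form and rejects the horizon", {
  expect_equal(projected_distance_ratio(chi_deg = 0), 1)
  expect_equal(projected_distance_ratio(chi_deg = 45), sqrt(2), tolerance = 1e-12)
  # tilt/fov convenience form evaluates at tilt - fov/2
  expect_equal(projected_distance_ratio(tilt_deg = 45, fov_deg = 30),
               1 / cos(30 * pi / 180), tolerance = 1e-12)
  expect_equal(round(projected_distance_ratio(tilt_deg = 45, fov_deg = 30), 5),
               1.15470)
  expect_error(projected_distance_ratio(chi_deg = 90), "unbounded")
  # strictly increasing on [0, 90) and 1 at 0
  grid <- seq(0, 89, by = 0.5)
  r <- projected_distance_ratio(chi_deg = grid)
  expect_true(all(diff(r) > 0))
  expect_equal(r[1], 1)
})

test_that("ground footprint: nadir symmetry, swath formula, and width/ratio cross-check", {
  cam <- camera_model(640, 512, focal_length_mm = 9, vfov_deg = 30,
                      pixel_pitch_um = 9 * 2 * tan(15 * pi / 180) / 512 * 1e3)
  fl0 <- flight_config(40, 2, tilt_from_nadir_deg = 0)
  fp0 <- ground_footprint(cam, fl0)
  expect_equal(fp0$d_near_m, -fp0$d_far_m, tolerance = 1e-9)
  expect_equal(fp0$d_mid_m, 0)
  expect_equal(fp0$d_nadir_swath_m, 2 * 40 * tan(15 * pi / 180), tolerance = 1e-12)
  expect_equal(round(fp0$d_nadir_swath_m, 3), 21.436)

  fl45 <- flight_config(40, 2, tilt_from_nadir_deg = 45)
  fp45 <- ground_footprint(cam, fl45)
  expect_true(fp45$d_near_m <= fp45$d_mid_m && fp45$d_mid_m <= fp45$d_far_m)
  expect_true(fp45$w_near_m < fp45$w_mid_m && fp45$w_mid_m < fp45$w_far_m)
  # near-edge width at tilt 45 over mid width at nadir equals the projection ratio
  expect_equal(fp45$w_near_m / fp0$w_mid_m,
               projected_distance_ratio(tilt_deg = 45, fov_deg = cam$vfov_deg),
               tolerance = 1e-9)
  # heights are measured above the detection surface
  fl_can <- flight_config(65, 2, tilt_from_nadir_deg = 0, canopy_height_m = 25)
  expect_equal(ground_footprint(cam, fl_can)$d_nadir_swath_m,
               fp0$d_nadir_swath_m, tolerance = 1e-12)
  expect_error(ground_footprint(cam, flight_config(40, 2, 80)), "unbounded")
})

test_that("GSD is linear in distance with the pinhole scale", {
  cam <- study_camera()
  expect_equal(ground_sample_distance(cam, 15), 15 * 12e-6 / 9e-3, tolerance = 1e-12)
  expect_equal(ground_sample_distance(cam, 15), 0.02)
  d <- c(1, 7.3, 40)
  expect_equal(ground_sample_distance(cam, 2 * d),
               2 * ground_sample_distance(cam, d), tolerance = 1e-12)
  expect_error(ground_sample_distance(cam, 0))
})

test_that("area excess between heights is quadratic in the height ratio", {
  expect_equal(area_excess_between_heights(40, 40), 0)
  expect_equal(area_excess_between_heights(40, 50), 56.25, tolerance = 1e-12)
  expect_equal(area_excess_between_heights(10, 20), 300)
  expect_error(area_excess_between_heights(50, 40))
})

test_that("masking rules reproduce the survey dialect and the exact-area variants", {
  am <- mask_spec_for_angle(10, 56)
  expect_equal(am$bottom$left_frac, 0.05)
  expect_equal(am$bottom$right_frac, 0.05)
  expect_equal(am$top$left_frac, 0.28)
  expect_equal(am$rule, "survey")
  z <- mask_spec_for_angle(0, 0)
  expect_equal(z$bottom$left_frac, 0)
  expect_equal(z$top$right_frac, 0)
  am_x <- mask_spec_for_angle(10, 56, rule = "exact")
  expect_equal(am_x$bottom$left_frac, (1 - 1 / 1.10) / 2, tolerance = 1e-12)
  expect_equal(round(100 * am_x$bottom$left_frac, 3), 4.545)

  hm <- mask_spec_for_height(55.2)
  expect_equal(hm$left_frac, 0.138)
  expect_equal(unlist(hm[c("left_frac", "right_frac", "top_frac", "bottom_frac")]),
               rep(0.138, 4), ignore_attr = TRUE)
  expect_equal(mask_spec_for_height(0)$top_frac, 0)
  hx <- mask_spec_for_height(56.25, rule = "exact")
  expect_equal(hx$left_frac, 0.10, tolerance = 1e-12)
  expect_error(mask_spec_for_angle(-1, 0))
  expect_error(mask_spec_for_height(-5))
})

test_that("exact-area height masks restore area parity to 1e-9", {
  for (excess in c(5, 21, 56.25, 120)) {
    m <- mask_spec_for_height(excess, rule = "exact")
    area_kept <- (1 - m$left_frac - m$right_frac) * (1 - m$top_frac - m$bottom_frac)
    expect_equal(area_kept * (1 + excess / 100), 1, tolerance = 1e-9)
  }
})

test_that("detection-distance limit inverts the GSD pixel-size rule", {
  cam <- study_camera()
  d <- max_detection_distance(0.5, 10, cam)
  expect_equal(d, 37.5)
  # defining property: the body spans exactly min_pixels at the limit
  expect_equal(0.5 / ground_sample_distance(cam, d), 10, tolerance = 1e-12)
  expect_equal(max_detection_distance(0.5, 20, cam), d / 2)

  expect_equal(max_flight_height_agl(57, canopy_height_m = 25), 82)
  expect_equal(max_flight_height_agl(12.3), 12.3)
  expect_equal(round(max_flight_height_agl(57, 25, 45), 1), 65.3)
  expect_error(max_flight_height_agl(57, 25, 90))
})

test_that("camera model derives FOV from specs and flags inconsistencies", {
  cam <- study_camera()
  expect_equal(cam$hfov_deg, 2 * atan(640 * 12e-3 / (2 * 9)) * 180 / pi)
  expect_true(cam$vfov_deg < cam$hfov_deg)
  expect_error(camera_model(640, 512, 9, hfov_deg = 60), "inconsistent")
  expect_silent(camera_model(640, 512, 9, hfov_deg = cam$hfov_deg + 0.4))
  expect_error(camera_model(-640, 512, 9))
  expect_error(flight_config(40, 2, 0, canopy_height_m = 45),
               "must exceed canopy")
})

test_that("geometry report covers the height x tilt grid", {
  rep <- geometry_report(study_camera(), c(40, 50), c(0, 45), canopy_height_m = 25)
  expect_equal(nrow(rep), 4)
  expect_true(all(rep$gsd_mid_m_per_px > 0))
  # oblique mid-line GSD exceeds the nadir GSD at the same height
  expect_true(all(rep$gsd_mid_m_per_px[rep$tilt_deg == 45] >
                    rep$gsd_mid_m_per_px[rep$tilt_deg == 0]))
})
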