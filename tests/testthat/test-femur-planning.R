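test_that("anterior cortex line reproduces a straight cortex", {
  f <- generate_femur(femur_params(dfb = 0))
  a <- fit_anterior_cortex_line(f)
  # the straight shaft cortex is vertical at x = outer radius
  expect_equal(abs(a$direction[2]), 1, tolerance = 1e-9)
  expect_gt(a$direction[2], 0)  # oriented proximally
  expect_equal(a$anchor[1], 14, tolerance = 1e-6)
  # bowed bone: the fit stays within the two segment directions
  fb <- fixture_femur(6)
  ab <- fit_anterior_cortex_line(fb)
  tilt <- signed_angle(vline(), ab)
  expect_gt(tilt, -6 - 0.1)
  expect_lt(tilt, 0.1)
})

test_that("IM guide line sits at the flange angle and on the posterior canal wall", {
  f <- fixture_femur()
  for (nm in c("J2BCS", "Physica")) {
    imp <- implant_library()[[nm]]
    a <- fit_anterior_cortex_line(f)
    b <- construct_im_guide_line(f, imp)
    expect_equal(signed_angle(a, b), imp$anterior_flange_angle,
                 tolerance = 1e-9)
    # tangency: touches the wall, wall entirely on its posterior side
    wall <- f$canal_posterior_wall
    d <- apply(unclass(wall), 1, function(p) point_line_distance(p, b))
    expect_equal(min(d), 0, tolerance = 1e-9)
    expect_equal(b$anchor, unname(brute_support_vertex(wall, b$direction, "right")),
                 tolerance = 1e-9)
  }
})

test_that("FED adds exactly the rod radius to the notch-roof distance", {
  # manufactured case: guide line passes exactly through the notch roof
  groove <- polycurve(rbind(c(20, -8), c(-20, -8)))
  fake <- list(groove_curve = groove, notch_roof = c(6, -8))
  through <- directed_line(pnt(6, -8), c(0, 1))
  res <- compute_fed(fake, through, implant_library()$J2BCS)
  expect_equal(res$notch_distance_a, 0, tolerance = 1e-12)
  expect_equal(res$fed, 4)
  # a = 5 -> fed = 9 for the 8 mm rod
  res5 <- compute_fed(fake, directed_line(pnt(11, -8), c(0, 1)),
                      implant_library()$U2)
  expect_equal(res5$notch_distance_a, 5, tolerance = 1e-12)
  expect_equal(res5$fed, 9)
  # transfer value is rounded, stored value is not
  expect_equal(res5$fed_rounded, 9)
  off <- compute_fed(fake, directed_line(pnt(11.4, -8), c(0, 1)),
                     implant_library()$U2)
  expect_equal(off$fed_rounded, round(off$fed))
  expect_false(isTRUE(all.equal(off$fed, off$fed_rounded)))
  # a line missing the groove is a planning error
  expect_error(compute_fed(fake, directed_line(pnt(500, 0), c(0, 1)),
                           implant_library()$U2),
               "planning error")
})

test_that("the femoral reference line is the symmetry axis of a straight bone", {
  f <- generate_femur(femur_params(dfb = 0))
  lc <- femur_reference_line(f)
  expect_equal(abs(lc$direction[2]), 1, tolerance = 1e-9)
  expect_equal(lc$anchor[1], 0, tolerance = 1e-6)
  # bowed-bone oracle: midpoints of the explicit chords at 70 and 110 mm
  fb <- fixture_femur(6)
  lcb <- femur_reference_line(fb)
  m7 <- cortical_midpoint(point_at_curve_distance(fb$posterior_cortex,
                                                  fb$blumensaat_posterior, 70),
                          fb$anterior_cortex, c(0, 1))
  expect_equal(point_line_distance(m7, lcb), 0, tolerance = 1e-9)
})

test_that("preop gamma is zero for coincident lines, signed for flexion", {
  l <- vline()
  expect_equal(preop_gamma(l, l), 0)
  flexed <- rotate_line(l, pnt(0, 0), 3.2)
  expect_equal(preop_gamma(flexed, l), 3.2, tolerance = 1e-9)
  # mirroring flexion to extension flips the sign
  extended <- rotate_line(l, pnt(0, 0), -3.2)
  expect_equal(preop_gamma(extended, l), -3.2, tolerance = 1e-9)
})

test_that("plan_femur composes the constructions and respects its invariants", {
  f <- fixture_femur(4.4)
  for (nm in names(implant_library())) {
    p <- plan_femur(f, nm)
    imp <- implant_library()[[nm]]
    expect_equal(p$fed, p$notch_distance_a + imp$im_rod_diameter / 2)
    expect_gte(p$fed, imp$im_rod_diameter / 2)
    expect_gte(p$fed, 0)
    expect_lte(p$fed, 20)
  }
  # rigid-motion invariance of (gamma, fed)
  set.seed(45)
  rm_ <- random_rigid()
  f2 <- rigid_transform(f, rm_$angle, rm_$shift)
  p1 <- plan_femur(f, "Exult"); p2 <- plan_femur(f2, "Exult")
  expect_equal(p2$preop_gamma, p1$preop_gamma, tolerance = 1e-9)
  expect_equal(p2$fed, p1$fed, tolerance = 1e-9)
})

test_that("gamma grows with the flange angle and FED with anterior bowing", {
  f <- fixture_femur(4.4)
  g3 <- plan_femur(f, "J2BCS")$preop_gamma   # 3 deg flange
  g5 <- plan_femur(f, "Physica")$preop_gamma # 5 deg flange
  expect_gte(g5, g3)
  for (nm in c("J2BCS", "Physica")) {
    feds <- vapply(c(0, 2, 4, 6, 8, 9.5), function(d)
      plan_femur(generate_femur(femur_params(dfb = d)), nm)$fed, numeric(1))
    expect_true(all(diff(feds) >= -1e-9))
  }
})
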