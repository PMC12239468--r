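test_that("signed_angle handles identity, boundary and rotation cases", {
  v <- vline()
  expect_equal(signed_angle(v, v), 0)
  # perpendicularity is the fold boundary, assigned to +90
  expect_equal(signed_angle(v, hline()), 90)
  expect_equal(signed_angle(hline(), v), 90)
  # rotation-matrix oracle: rotating the direction by +a gives +a
  for (a in c(-89, -45, -3, 0.5, 3, 30, 89.9)) {
    b <- directed_line(pnt(2, -1), as.numeric(rot2(a) %*% c(0, 1)))
    expect_equal(signed_angle(v, b), a, tolerance = 1e-9)
  }
})

test_that("signed_angle is antisymmetric and rigid-motion invariant", {
  set.seed(41)
  for (i in 1:25) {
    a <- directed_line(runif(2, -50, 50), runif(2, -1, 1))
    b <- directed_line(runif(2, -50, 50), runif(2, -1, 1))
    ang <- signed_angle(a, b)
    if (abs(ang) < 89.9) {
      expect_equal(signed_angle(b, a), -ang, tolerance = 1e-9)
    }
    rm_ <- random_rigid()
    a2 <- rotate_line(a, pnt(0, 0), rm_$angle)
    b2 <- rotate_line(b, pnt(0, 0), rm_$angle)
    expect_equal(signed_angle(a2, b2), ang, tolerance = 1e-9)
  }
})

test_that("point_line_distance matches trivial cases and a sampling oracle", {
  l <- vline(3)
  expect_equal(point_line_distance(pnt(3, 77), l), 0)
  expect_equal(point_line_distance(pnt(4, 0), l), 1)
  set.seed(42)
  for (i in 1:10) {
    p <- runif(2, -30, 30)
    l2 <- directed_line(runif(2, -30, 30), runif(2, -1, 1))
    expect_equal(point_line_distance(p, l2),
                 brute_point_line_distance(p, l2), tolerance = 1e-4)
  }
})

test_that("rotate_line composes with signed_angle and is involutive at 180", {
  l <- directed_line(pnt(5, 5), c(0.6, 0.8))
  expect_equal(rotate_line(l, pnt(0, 0), 0)$direction, l$direction)
  r2 <- rotate_line(rotate_line(l, pnt(1, 2), 90), pnt(1, 2), 90)
  expect_equal(r2$direction, -l$direction, tolerance = 1e-12)
  expect_equal(signed_angle(l, rotate_line(l, pnt(-3, 9), 3)), 3,
               tolerance = 1e-9)
})

test_that("tangent_line_of_direction agrees with exhaustive vertex search", {
  quad <- polycurve(rbind(c(0, 0), c(10, 1), c(11, 12), c(-1, 10), c(0, 0.5)))
  for (side in c("right", "left")) {
    tl <- tangent_line_of_direction(quad, c(0, 1), side)
    expect_equal(tl$anchor, unname(brute_support_vertex(quad, c(0, 1), side)),
                 tolerance = 1e-12)
  }
  # all points lie in one closed half-plane of the returned line
  set.seed(43)
  for (i in 1:20) {
    npts <- sample(5:60, 1)
    curve <- polycurve(cbind(cumsum(runif(npts, 0.1, 3)),
                             rnorm(npts, sd = 5)))
    d <- as.numeric(rot2(runif(1, -180, 180)) %*% c(0, 1))
    tl <- tangent_line_of_direction(curve, d, "right")
    n <- c(d[2], -d[1])
    s <- unclass(curve) %*% n - sum(tl$anchor * n)
    expect_true(all(s <= 1e-9))
    expect_equal(tl$anchor, unname(brute_support_vertex(curve, d, "right")),
                 tolerance = 1e-12)
  }
})

test_that("tangent line of a parallel segment is the segment's own line", {
  seg <- polycurve(rbind(c(2, 0), c(2, 10)))
  tl <- tangent_line_of_direction(seg, c(0, 1), "right")
  expect_equal(point_line_distance(pnt(2, 5), tl), 0, tolerance = 1e-12)
  # translation of the curve translates the tangent with it
  seg2 <- polycurve(rbind(c(9, -4), c(9, 6)))
  tl2 <- tangent_line_of_direction(seg2, c(0, 1), "right")
  expect_equal(tl2$anchor[1] - tl$anchor[1], 7)
})

test_that("point_at_curve_distance walks arc length, with a cumulative oracle", {
  straight <- polycurve(rbind(c(0, 0), c(0, 200)))
  expect_equal(point_at_curve_distance(straight, pnt(0, 0), 0), c(0, 0))
  expect_equal(point_at_curve_distance(straight, pnt(0, 0), 70), c(0, 70))
  # bent polyline: 3-4-5 triangle leg then vertical; oracle by hand
  bent <- polycurve(rbind(c(0, 0), c(3, 4), c(3, 10)))
  expect_equal(point_at_curve_distance(bent, pnt(0, 0), 5), c(3, 4))
  expect_equal(point_at_curve_distance(bent, pnt(0, 0), 7), c(3, 6))
  expect_equal(point_at_curve_distance(bent, pnt(0, 0), 2.5),
               c(1.5, 2), tolerance = 1e-12)
  expect_error(point_at_curve_distance(bent, pnt(0, 0), 50),
               "insufficient contour coverage")
})

test_that("cortical_midpoint bisects parallel cortices and a bowed chord oracle", {
  far <- polycurve(rbind(c(30, -10), c(30, 110)))
  expect_equal(cortical_midpoint(pnt(0, 50), far, c(0, 1)), c(15, 50))
  # bowed opposite contour: chord at 45 deg local axis, oracle solved by hand:
  # chord through (0,0) perpendicular to (1,1)/sqrt(2) is the line y = -x;
  # opposite segment from (5,-1) to (5,-9) is hit at (5,-5)
  opp <- polycurve(rbind(c(5, -1), c(5, -9)))
  expect_equal(cortical_midpoint(pnt(0, 0), opp, c(1, 1)), c(2.5, -2.5),
               tolerance = 1e-12)
  expect_error(cortical_midpoint(pnt(0, 0), polycurve(rbind(c(5, 5), c(9, 9))),
                                 c(0, 1)),
               "contour coverage")
})

test_that("distances scale linearly and angles are scale invariant", {
  a <- directed_line(pnt(1, 1), c(1, 3))
  b <- directed_line(pnt(0, -2), c(-1, 4))
  p <- pnt(7, -3)
  k <- 3.7
  a_s <- directed_line(k * a$anchor, a$direction)
  b_s <- directed_line(k * b$anchor, b$direction)
  expect_equal(point_line_distance(k * p, a_s), k * point_line_distance(p, a))
  expect_equal(signed_angle(a_s, b_s), signed_angle(a, b))
})
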