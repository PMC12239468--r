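make_case <- function(dfb = 4.4, implant = "J2BCS",
                      error_model = zero_error_model()) {
  f <- fixture_femur(dfb)
  t <- fixture_tibia()
  fp <- plan_femur(f, implant)
  tp <- plan_tibia(t, implant)
  list(f = f, t = t, fp = fp, tp = tp,
       ex = execute_plan(fp, tp, error_model))
}

test_that("exact execution reproduces the plan (plus the slope-guide extra)", {
  cs <- make_case(implant = "J2BCS")
  expect_identical(cs$ex$achieved_femoral$direction, cs$fp$line_b$direction)
  cr <- case_result(cs$f, cs$t, cs$fp, cs$tp, cs$ex)
  expect_identical(cr$postop_gamma, cr$preop_gamma)
  expect_equal(cr$postop_delta - cr$preop_delta, 3, tolerance = 1e-9)
  expect_equal(cr$gamma_diff, 0)
  expect_equal(cr$delta_diff, 0, tolerance = 1e-9)
  expect_true(cr$gamma_within && cr$delta_within)
  expect_false(cr$notching)
})

test_that("a pure bias shifts the postoperative gamma by exactly the bias", {
  cs <- make_case(error_model = execution_error_model(gamma_bias = 1.2,
                                                      gamma_sd = 0,
                                                      delta_bias = 0,
                                                      delta_sd = 0))
  qg <- postop_gamma(cs$f, cs$ex$achieved_femoral)
  expect_equal(qg - cs$fp$preop_gamma, 1.2, tolerance = 1e-9)
})

test_that("an injected known rotation is recovered by the postoperative angles", {
  cs <- make_case(implant = "U2")
  ach <- rotate_line(cs$fp$line_b, cs$fp$entry_point, -2.7)
  expect_equal(postop_gamma(cs$f, ach) - cs$fp$preop_gamma, -2.7,
               tolerance = 1e-9)
  acht <- rotate_line(cs$tp$em_line, cs$tp$em_line$anchor, 1.5)
  d <- corrected_differences(cs$fp$preop_gamma, postop_gamma(cs$f, ach),
                             cs$tp$preop_delta, postop_delta(cs$t, acht), "U2")
  expect_equal(d$delta_diff, 1.5, tolerance = 1e-9)
})

test_that("slope-guide corrections depend on the implant's stem configuration", {
  for (nm in names(implant_library())) {
    cs <- make_case(implant = nm)
    cr <- case_result(cs$f, cs$t, cs$fp, cs$tp, cs$ex)
    extra <- if (nm %in% c("J2BCS", "Exult")) 3 else 0
    expect_equal(cr$postop_delta - cr$preop_delta, extra, tolerance = 1e-9)
    expect_equal(cr$delta_diff, 0, tolerance = 1e-9)
    # the uncorrected difference exceeds the corrected one by exactly the extra
    expect_equal((cr$postop_delta - cr$preop_delta) - cr$delta_diff, extra,
                 tolerance = 1e-9)
  }
  expect_error(corrected_differences(0, 0, 0, 0, "NotAnImplant"),
               "unknown implant")
})

test_that("execution error sampling is reproducible under a seed", {
  cs <- make_case()
  em <- execution_error_model()
  set.seed(77); e1 <- execute_plan(cs$fp, cs$tp, em)
  set.seed(77); e2 <- execute_plan(cs$fp, cs$tp, em)
  expect_identical(e1$gamma_error, e2$gamma_error)
  expect_identical(e1$achieved_femoral$direction, e2$achieved_femoral$direction)
})

test_that("target classification uses the closed +/-2 degree interval", {
  expect_true(within_target(0))
  expect_true(within_target(2.0))
  expect_true(within_target(-2.0))
  expect_false(within_target(2.01))
  expect_false(within_target(7.2))  # the largest observed outlier is outside
})

test_that("notching is absent on exact execution and appears under extreme flexion", {
  # across the documented anatomy range
  for (d in c(-0.7, 0, 4.4, 9.5)) {
    for (nm in c("J2BCS", "Physica")) {
      f <- generate_femur(femur_params(dfb = d))
      fp <- plan_femur(f, nm)
      expect_false(detect_notching(f, fp$line_b, nm))
    }
  }
  # forcing the achieved axis far into flexion on a highly bowed bone drives
  # the anterior cut under the cortex
  f <- generate_femur(femur_params(dfb = 9))
  fp <- plan_femur(f, "J2BCS")
  forced <- rotate_line(fp$line_b, fp$entry_point, 25)
  expect_true(detect_notching(f, forced, "J2BCS"))
  # the flag is rigid-motion invariant
  set.seed(48)
  rm_ <- random_rigid()
  f2 <- rigid_transform(f, rm_$angle, rm_$shift)
  fp2 <- plan_femur(f2, "J2BCS")
  forced2 <- rotate_line(fp2$line_b, fp2$entry_point, 25)
  expect_false(detect_notching(f2, fp2$line_b, "J2BCS"))
  expect_true(detect_notching(f2, forced2, "J2BCS"))
})

test_that("accuracy does not increase with execution-error spread", {
  f <- fixture_femur(); t <- fixture_tibia()
  fp <- plan_femur(f, "U2"); tp <- plan_tibia(t, "U2")
  acc <- vapply(c(0.5, 1.5, 3), function(s) {
    set.seed(49)
    diffs <- replicate(150, {
      ex <- execute_plan(fp, tp, execution_error_model(gamma_bias = 1,
                                                       gamma_sd = s,
                                                       delta_sd = 0))
      postop_gamma(f, ex$achieved_femoral) - fp$preop_gamma
    })
    mean(abs(diffs) <= 2)
  }, numeric(1))
  expect_true(all(diff(acc) <= 0.05))  # non-increasing up to Monte-Carlo noise
})
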