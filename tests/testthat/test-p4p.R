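test_that("cycle evaluation applies the improve-or-absolute rule", {
  target <- performance_target("fbd", increment = 5, absolute = 85)
  # averaging 86% against an absolute threshold of 85%: achieved
  res <- evaluate_cycle(rep(86, 6), 1, target, previous = 86)
  expect_true(res$achieved)
  expect_equal(res$average, 86)
  # both branches fail: 44 < 40 + 5 and 44 < 85
  res <- evaluate_cycle(rep(44, 6), 1, target, previous = 40)
  expect_false(res$achieved)
  # relative branch succeeds: 46 >= 40 + 5
  res <- evaluate_cycle(rep(46, 6), 1, target, previous = 40)
  expect_true(res$achieved)
  # previous defaults to the preceding cycle's average
  series <- c(rep(40, 6), rep(46, 6))
  expect_true(evaluate_cycle(series, 2, target)$achieved)
  expect_error(evaluate_cycle(rep(40, 6), 1, target), "baseline")
  # incomplete cycles defer evaluation
  expect_error(evaluate_cycle(rep(40, 8), 2, target, previous = 40),
               "incomplete")
})

test_that("payment amounts sum over achieved indicators", {
  expect_equal(payment_amount(c(ipt2 = FALSE, fbd = FALSE), 100), 0)
  expect_equal(payment_amount(c(ipt2 = TRUE, fbd = TRUE), 100), 200)
  expect_equal(payment_amount(c(ipt2 = TRUE, fbd = TRUE), 100,
                              enabled = FALSE), 0)
})

test_that("disbursement splits exactly by the staff share", {
  res <- disburse(200, 0.75)
  expect_equal(res$staff, 150)
  expect_equal(res$operations, 50)
  res <- disburse(200, 0.10)
  expect_equal(res$staff, 20)
  expect_equal(res$operations, 180)
  expect_equal(disburse(0, 0.75), list(staff = 0, operations = 0))
  # staff + operations always equals the amount, exactly
  for (amt in c(1, 37.5, 200, 1234.56))
    for (s in c(0.1, 0.25, 0.5, 0.75, 0.9)) {
      d <- disburse(amt, s)
      expect_identical(d$staff + d$operations, amt)
    }
})

test_that("payment calendars follow the planned and the observed schedules", {
  expect_identical(payment_calendar("on_time", 54),
                   as.integer(c(9, 15, 21, 27, 33, 39, 45, 51)))
  expect_identical(payment_calendar("actual_delayed", 54),
                   as.integer(c(13, 18, 22, 27, 34, 42)))
  expect_identical(payment_calendar("on_time", 8), integer())
  expect_identical(payment_calendar("actual_delayed", 8), integer())
})

test_that("months overdue track the oldest earned-but-unpaid cycle", {
  pay <- payment_calendar("actual_delayed", 54)
  # cycle 1 (ends 6, due 9, paid 13): overdue 1..3 in months 10..12
  expect_equal(months_overdue(10, 6, pay), 1L)
  expect_equal(months_overdue(12, 6, pay), 3L)
  expect_equal(months_overdue(13, 6, pay), 0L)  # the month-13 payment clears it
  expect_equal(months_overdue(14, 6, pay), 0L)
  # nothing earned: never overdue
  expect_equal(months_overdue(20, integer(), pay), 0L)
  # cycle 7 (ends 42, due 45) is never paid under the actual schedule
  expect_equal(months_overdue(49, c(6, 42), pay), 4L)
  expect_equal(months_overdue(54, c(6, 42), pay), 9L)
})

test_that("under the delayed schedule the post-42 gap reaches the severe regime", {
  cfg <- default_cfg()
  cfg$p4p$schedule <- "actual_delayed"
  traj <- run_p4p(cfg)
  overdue <- trajectory_value(traj, "p4p_overdue")
  expect_gte(max(overdue[43:54]), cfg$facility$severe_delay)
})

test_that("the liability stock conserves earned and paid amounts", {
  for (mode in c("on_time", "actual_delayed")) {
    cfg <- default_cfg()
    cfg$p4p$schedule <- mode
    traj <- run_p4p(cfg)
    expect_conserved(traj, "p4p_liability", "p4p_accrual", "p4p_payment")
    # every staff + operations split reassembles the payment exactly
    expect_equal(trajectory_value(traj, "staff_incentive") +
                   trajectory_value(traj, "operations_payment"),
                 trajectory_value(traj, "p4p_payment_due"))
  }
})

test_that("disabling P4P reproduces the control trajectory bitwise", {
  c1 <- control_cfg()
  c2 <- control_cfg()
  c2$p4p$staff_share <- 0.10          # intervention knobs are inert when off
  c2$p4p$schedule <- "actual_delayed"
  t1 <- run_p4p(c1)
  t2 <- run_p4p(c2)
  expect_identical(unclass(t1)[, colnames(t1)], unclass(t2)[, colnames(t1)])
  # and no payment events exist at all
  expect_true(all(trajectory_value(t1, "p4p_payment_due") == 0))
  expect_true(all(trajectory_value(t1, "p4p_earned") == 0))
})
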