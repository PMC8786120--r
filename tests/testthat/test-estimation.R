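test_that("annual waste formula evaluates in tonnes and is linear in rates", {
  # pure inpatient: 365 * 100 beds * 1.0 * 1 kg = 36,500 kg = 36.5 t
  expect_equal(annual_waste(100, 1, 0, m = 1, s = 0), 36.5)
  # Hubei 2019 row: inpatient + outpatient components
  q19 <- annual_waste(403300, 0.923, 3.54e8, m = 0.5, s = 0.04)
  expect_equal(q19, (365 * 403300 * 0.923 * 0.5 + 3.54e8 * 0.04) / 1000)
  expect_equal(q19, 82094.877, tolerance = 1e-6)
  # doubling both rates doubles the total for any record
  expect_equal(annual_waste(4e5, 0.9, 3e8, m = 1.0, s = 0.08),
               2 * annual_waste(4e5, 0.9, 3e8, m = 0.5, s = 0.04))
  # term isolation: the two components add up
  expect_equal(annual_waste(4e5, 0.9, 3e8, m = 0.5, s = 0.04),
               annual_waste(4e5, 0.9, 3e8, m = 0.5, s = 0) +
                 3e8 * 0.04 / 1000)
})

test_that("annual waste rejects invalid inputs", {
  expect_error(annual_waste(0, 0.9, 1e6), "beds")
  expect_error(annual_waste(100, 0, 1e6), "utilization")
  expect_error(annual_waste(100, 1.25, 1e6), "utilization")
  expect_error(annual_waste(100, 0.9, -1), "visits")
  expect_error(annual_waste(100, 0.9, 1e6, m = -0.1), "m and s")
})

test_that("month weights are visit shares summing to one", {
  uni <- month_weights(monthly_series(2019, 1:12, rep(5, 12)))
  expect_equal(uni$w, rep(1 / 12, 12))
  skew <- month_weights(monthly_series(2019, 1:12, c(2, rep(1, 11))))
  expect_equal(skew$w[1], 2 / 13)
  expect_equal(sum(skew$w), 1)
  # degenerate mass in one month is allowed (weights may be zero)
  one <- month_weights(monthly_series(2019, 1:12, c(rep(0, 5), 10, rep(0, 6))))
  expect_equal(one$w[6], 1)
  expect_error(month_weights(monthly_series(2019, 1:11, rep(1, 11))), "12 months")
  expect_error(month_weights(monthly_series(2019, 1:12, rep(0, 12))), "> 0")
})

test_that("monthly disaggregation conserves the annual total", {
  w <- month_weights(monthly_series(2018, 1:12, rep(100, 12)))
  expect_equal(monthly_waste(1200, w)$value, rep(100, 12))
  expect_equal(monthly_waste(0, w)$value, rep(0, 12))
  prof <- default_seasonality()
  mw <- monthly_waste(82095, unclass(prof), year = 2019)
  expect_equal(sum(mw$value), 82095, tolerance = 1e-12)
  expect_equal(which.min(mw$value), 2L)  # February trough
  expect_equal(which.max(mw$value), 3L)  # March peak
})

test_that("window allocation is pro rata by true calendar days", {
  s <- monthly_series(2020, 1:4, c(310, 290, 310, 300))
  # full-month window returns the month value unchanged
  feb <- allocate_window(s, date_window("2020-02-01", "2020-02-29"))
  expect_equal(attr(feb, "total"), 290)
  expect_equal(feb$month_days, 29L)  # 2020 is a leap year
  # 10 of 30 days -> one third
  apr <- allocate_window(s, date_window("2020-04-01", "2020-04-10"))
  expect_equal(attr(apr, "total"), 100)
  # windows outside coverage fail
  expect_error(allocate_window(s, date_window("2019-12-31", "2020-01-05")),
               "coverage")
  expect_error(allocate_window(s, date_window("2020-04-20", "2020-05-02")),
               "coverage")
})

test_that("window allocation agrees with a per-day brute-force oracle", {
  set.seed(401)
  # Jul 2019 .. Dec 2020
  s <- monthly_series(rep(c(2019, 2020), c(6, 12)), c(7:12, 1:12),
                      stats::runif(18, 50, 400))
  first <- as.Date("2019-07-01"); last <- as.Date("2020-12-31")
  all_days <- seq(first, last, by = "1 day")
  for (k in 1:200) {
    d <- sort(sample(all_days, 2, replace = TRUE))
    w <- date_window(d[1], d[2])
    expect_equal(attr(allocate_window(s, w), "total"), allocate_by_day(s, w),
                 tolerance = 1e-9)
  }
})

test_that("window allocation is additive over adjacent disjoint windows", {
  set.seed(402)
  s <- monthly_series(2020, 1:12, stats::runif(12, 100, 800))
  for (k in 1:50) {
    d <- sort(sample(seq(as.Date("2020-01-01"), as.Date("2020-12-31"), "1 day"),
                     3, replace = FALSE))
    total_union <- attr(allocate_window(s, date_window(d[1], d[3])), "total")
    left <- attr(allocate_window(s, date_window(d[1], d[2])), "total")
    right <- attr(allocate_window(s, date_window(d[2] + 1, d[3])), "total")
    expect_equal(left + right, total_union, tolerance = 1e-9)
  }
})

test_that("monthly series validates its invariants", {
  expect_error(monthly_series(2020, c(1, 3), c(1, 2)), "contiguous")
  expect_error(monthly_series(2020, 1:2, c(1, -2)), ">= 0")
  expect_error(monthly_series(2020, 13, 1), "1..12")
  # year boundary is contiguous
  s <- monthly_series(rep(c(2019, 2020), c(2, 2)), c(11, 12, 1, 2), 1:4)
  expect_s3_class(s, "mw_monthly")
})
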