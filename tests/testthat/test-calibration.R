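test_that("horizon truncation recodes late events and nests across horizons", {
  r <- survival_records(c(1, 2, 3), c(12, 8, 10.5), c(TRUE, TRUE, FALSE))
  t10 <- truncate_at_horizon(r, 10)
  expect_equal(t10$time, c(10, 8, 10))
  expect_identical(t10$event, c(FALSE, TRUE, FALSE))
  # events at nested horizons are nested
  set.seed(2)
  r2 <- random_records(200)
  e5 <- truncate_at_horizon(r2, 2)$event
  e10 <- truncate_at_horizon(r2, 4)$event
  expect_true(all(!e5 | e10))
  expect_lte(sum(e5), sum(e10))
  # cohort frames are truncated consistently
  co <- small_cohort(n = 60, seed = 5)
  tc <- truncate_at_horizon(co, 5)
  expect_true(all(tc$time <= 5))
  expect_true(all(is.na(tc$ad_subtype[tc$event == "censored"])))
  expect_error(truncate_at_horizon(r, 0), "horizon")
})

test_that("kaplan_meier matches the hand product-limit calculation", {
  r <- survival_records(c(0, 0, 0), c(1, 2, 3), c(TRUE, FALSE, TRUE))
  # at t=3: (1 - 1/3) * (1 - 1/1) = 0
  expect_equal(as.numeric(km_survival(r, 3)), 0, tolerance = 1e-12)
  expect_equal(as.numeric(km_survival(r, 1.5)), 2 / 3, tolerance = 1e-12)
  # no events: survival 1 everywhere
  r0 <- survival_records(c(0, 0), c(1, 2), c(FALSE, FALSE))
  expect_identical(as.numeric(km_survival(r0, 2)), 1)
  expect_true(attr(km_survival(r0, 5), "extrapolated"))
  # nonincreasing in t
  set.seed(3)
  r1 <- random_records(100)
  ts <- seq(0.1, 4, by = 0.3)
  s <- vapply(ts, function(t) as.numeric(km_survival(r1, t)), 0)
  expect_true(all(diff(s) <= 1e-12))
})

test_that("incidence_rate is events per 1000 person-years", {
  r <- survival_records(c(0, 0), c(40, 60), c(TRUE, TRUE))
  expect_identical(incidence_rate(r), 20)
  r0 <- survival_records(c(0, 0), c(40, 60), c(FALSE, FALSE))
  expect_identical(incidence_rate(r0), 0)
  # the emulated validation sample: 867 events over 75,581 person-years
  n <- 6667
  times <- rep(75581 / n, n)
  ev <- c(rep(TRUE, 867), rep(FALSE, n - 867))
  expect_equal(incidence_rate(survival_records(rep(0, n), times, ev)),
               1000 * 867 / 75581, tolerance = 1e-12)
  expect_equal(round(incidence_rate(survival_records(rep(0, n), times, ev)), 1),
               11.5)
})

test_that("calibration recovers slope 1 / intercept 0 for self-consistent predictions", {
  set.seed(10)
  n <- 20000
  p <- plogis(rnorm(n, -2, 1.2))
  y <- runif(n) < p
  # events somewhere inside the horizon, non-events at the horizon
  rec <- survival_records(p, ifelse(y, runif(n, 0.1, 9.9), 10), y)
  cal <- calibration_intercept_slope(p, rec, 10)
  expect_lt(abs(cal$slope - 1), 0.05)
  expect_lt(abs(cal$intercept), 0.05)
  expect_identical(cal$n_used, as.integer(n))
  expect_identical(nrow(cal$bins), 10L)
  expect_true(all(cal$bins$observed >= 0 & cal$bins$observed <= 1))
})

test_that("doubling the odds shifts the intercept by -log 2 and not the slope", {
  set.seed(12)
  n <- 4000
  p <- plogis(rnorm(n, -1.5, 1))
  y <- runif(n) < p
  rec <- survival_records(p, ifelse(y, 5, 10), y)
  cal1 <- calibration_intercept_slope(p, rec, 10)
  p2 <- plogis(qlogis(p) + log(2))
  cal2 <- calibration_intercept_slope(p2, rec, 10)
  expect_equal(cal2$slope, cal1$slope, tolerance = 1e-6)
  expect_equal(cal2$intercept, cal1$intercept - log(2), tolerance = 1e-6)
})

test_that("participants censored before the horizon are excluded from the binary fit", {
  p <- c(0.2, 0.4, 0.6, 0.3)
  rec <- survival_records(p, c(3, 10, 7, 10), c(FALSE, FALSE, TRUE, TRUE))
  cal <- calibration_intercept_slope(p, rec, 10)
  expect_identical(cal$n_used, 3L)
  expect_identical(cal$n_excluded, 1L)
})

test_that("degenerate calibration inputs are errors", {
  rec <- survival_records(c(0.2, 0.4), c(10, 10), c(FALSE, FALSE))
  expect_error(calibration_intercept_slope(c(0.2, 0.4), rec, 10), "identical")
  rec2 <- survival_records(c(0.3, 0.3), c(5, 10), c(TRUE, FALSE))
  expect_error(calibration_intercept_slope(c(0.3, 0.3), rec2, 10), "constant")
  expect_error(calibration_intercept_slope(c(0, 0.5), rec2, 10), "inside")
})

test_that("logistic recalibration matches the observed proportion exactly", {
  set.seed(14)
  n <- 3000
  p <- plogis(rnorm(n, -2.5, 0.8))
  y <- runif(n) < plogis(qlogis(p) + log(2)) # outcomes at doubled odds
  rec <- survival_records(p, ifelse(y, 5, 10), y)
  r <- recalibrate_logistic(p, rec, 10)
  expect_equal(mean(r$predictions), mean(y), tolerance = 1e-10)
  # small risks: odds doubling is approximately a log-2 shift
  expect_lt(abs(r$delta - log(2)), 0.15)
  # already-calibrated predictions need no shift
  y2 <- runif(n) < p
  rec2 <- survival_records(p, ifelse(y2, 5, 10), y2)
  r2 <- recalibrate_logistic(p, rec2, 10)
  expect_lt(abs(r2$delta), 0.2)
})

test_that("Cox recalibration reduces to the KM event probability at a constant LP", {
  set.seed(15)
  r <- random_records(300)
  rc <- recalibrate_cox(rep(1.7, 300), r, 3)
  s <- as.numeric(km_survival(truncate_at_horizon(r, 3), 3))
  expect_equal(unique(rc$risk), 1 - s, tolerance = 1e-12)
  # strictly increasing in the linear predictor
  lp <- rnorm(300)
  rc2 <- recalibrate_cox(lp, r, 3)
  expect_true(all(diff(rc2$risk[order(lp)]) > 0))
})
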