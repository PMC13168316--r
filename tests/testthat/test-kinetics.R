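# Cell-specific rate estimators on constructed time courses with
# closed-form expected values.

make_course <- function(day, vcd, ...) {
  culture_time_course(day = day, vcd = vcd, ...)
}

test_that("specific growth rate recovers exponential generating rates", {
  cc <- make_course(0:3, c(1, 2, 4, 8))
  mu <- specific_growth_rate(cc)
  expect_equal(mu$mu, rep(log(2), 3))

  cc <- make_course(0:2, c(4, 4, 2))
  mu <- specific_growth_rate(cc)
  expect_equal(mu$mu, c(0, -log(2)))

  # exactly exponential VCD returns the generating rate at every interval
  r <- 0.43
  cc <- make_course(0:8, 0.7 * exp(r * (0:8)))
  expect_equal(specific_growth_rate(cc)$mu, rep(r, 8))

  # nonpositive VCD flags the interval as missing, not an error
  cc <- make_course(0:2, c(2, 0, 4))
  expect_equal(is.na(specific_growth_rate(cc)$mu), c(TRUE, TRUE))
})

test_that("trapezoid IVCD is exact for affine VCD and nonnegative", {
  cc <- make_course(0:1, c(2, 4))
  expect_equal(incremental_ivcd(cc)$ivcd, 3)

  cc <- make_course(c(0, 2.5), c(3, 3))
  expect_equal(incremental_ivcd(cc)$ivcd, 7.5)

  # linear ramp: cumulative trapezoid equals the analytic integral
  a <- 1.2; b <- 0.8
  t <- seq(0, 10, by = 0.5)
  cc <- make_course(t, a + b * t)
  cum <- cumulative_ivcd(cc)
  analytic <- a * t + b * t^2 / 2
  expect_equal(cum$ivcd_sum, analytic, tolerance = 1e-12)

  expect_error(incremental_ivcd(make_course(0, 1)), "at least 2")
})

test_that("rate estimates are invariant to a constant time offset", {
  t <- 0:6
  vcd <- 0.8 * exp(0.5 * t)
  lac <- 2 + 0.9 * t
  for (off in c(0, 3.5)) {
    cc <- make_course(t + off, vcd, lactate = lac)
    if (off == 0) {
      base_mu <- specific_growth_rate(cc)$mu
      base_ql <- specific_lactate_rate(cc)$q_lac
    } else {
      expect_equal(specific_growth_rate(cc)$mu, base_mu)
      expect_equal(specific_lactate_rate(cc)$q_lac, base_ql)
    }
  }
})

test_that("lactate rate converts mM over IVCD with sign symmetry", {
  # flat VCD 1 over 2 days -> delta IVCD = 2; delta LAC +-2 mM
  cc <- make_course(c(0, 2), c(1, 1), lactate = c(0, 2))
  expect_equal(specific_lactate_rate(cc)$q_lac, 1)
  cc <- make_course(c(0, 2), c(1, 1), lactate = c(2, 0))
  expect_equal(specific_lactate_rate(cc)$q_lac, -1)
  cc <- make_course(c(0, 2), c(1, 1), lactate = c(2, 2))
  expect_equal(specific_lactate_rate(cc)$q_lac, 0)

  # delta LAC +2 mM over delta IVCD = 1 -> 2 pmol/cell/d
  cc <- make_course(c(0, 2), c(0.5, 0.5), lactate = c(1, 3))
  expect_equal(specific_lactate_rate(cc)$q_lac, 2)
})

test_that("productivity handles dilution-negative deltas and the average", {
  # delta P = 100 mg/L over delta IVCD = 10 -> 10 pg/cell/d
  cc <- make_course(0:1, c(10, 10), titer = c(0, 100))
  qp <- specific_productivity(cc)
  expect_equal(qp$intervals$q_p, 10)

  # feed dilution: negative delta allowed, no error
  cc <- make_course(0:2, c(10, 10, 10), titer = c(100, 90, 130))
  qp <- specific_productivity(cc)
  expect_equal(qp$intervals$q_p, c(-1, 4))

  # process average over days 3-11
  t <- 0:11
  cc <- make_course(t, rep(5, 12), titer = 20 * t)
  qp <- specific_productivity(cc)
  expect_equal(qp$average, (20 * 11 - 20 * 3) / (5 * 8))
})

test_that("q_GLC regression matches the normal-equations oracle per window", {
  feeds <- data.frame(day = c(3, 5), feed_pct_vv = 0,
                      glucose_target_g_l = NA, gal_plus = FALSE)
  # flat VCD 2 -> ivcd_sum = 2t; exactly linear glucose in ivcd_sum
  t <- 0:7
  glc <- 8 - 0.25 * (2 * t)
  cc <- make_course(t, rep(2, 8), glucose = glc, feed_events = feeds)
  qg <- specific_glucose_rate(cc, use_postfeed = FALSE)
  expect_equal(qg$q_glc, rep(0.25, 2))
  expect_equal(qg$rss, rep(0, 2), tolerance = 1e-12)
  expect_equal(qg$q_glc_pg, rep(250, 2))

  # constant glucose -> zero rate
  cc <- make_course(t, rep(2, 8), glucose = rep(5, 8), feed_events = feeds)
  qg <- specific_glucose_rate(cc, use_postfeed = FALSE)
  expect_equal(qg$q_glc, rep(0, 2))

  # noisy window: 3 points, compare against closed-form least squares
  x <- c(2, 4, 6); y <- c(7.9, 7.2, 6.1)
  slope_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  feeds1 <- data.frame(day = 0, feed_pct_vv = 0,
                       glucose_target_g_l = NA, gal_plus = FALSE)
  cc <- make_course(0:3, rep(2, 4), glucose = c(8.5, y),
                    feed_events = feeds1)
  qg <- specific_glucose_rate(cc, use_postfeed = FALSE)
  expect_equal(qg$slope, slope_hand)

  # half-open windows: the pre-feed sample on a feed day belongs to the
  # previous window
  expect_equal(qg$n_points, 3L)
})

test_that("windows with too few points are skipped with a warning", {
  feeds <- data.frame(day = c(3, 4), feed_pct_vv = 0,
                      glucose_target_g_l = NA, gal_plus = FALSE)
  cc <- make_course(0:5, rep(2, 6), glucose = rep(4, 6),
                    feed_events = feeds)
  warns <- capture_warnings(qg <- specific_glucose_rate(cc,
                                                        use_postfeed = FALSE))
  expect_match(warns, "fewer than 2", all = TRUE)
  expect_true(length(warns) >= 1)
})

test_that("time courses round-trip through CSV and tidy rates assemble", {
  feeds <- data.frame(strategy = "STD", day = 3, feed_pct_vv = 5,
                      glucose_target_g_l = 8, gal_plus = FALSE)
  df <- data.frame(
    replicate = "r1", strategy = "STD", day = 0:5,
    vcd_1e6_per_ml = exp(0.4 * (0:5)), viability_pct = 98,
    diameter_um = 13.5, glucose_g_l = 8 - 0.5 * (0:5),
    lactate_mm = c(0, 1, 2, 3, 2, 1), titer_mg_l = 30 * (0:5), ph = 7.2
  )
  tc_path <- withr::local_tempfile(fileext = ".csv")
  feed_path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, tc_path, row.names = FALSE)
  utils::write.csv(feeds, feed_path, row.names = FALSE)
  courses <- read_time_courses(tc_path, feed_path)
  expect_length(courses, 1)
  rates <- compute_rates(courses[[1]])
  expect_true(all(c("mu", "ivcd", "ivcd_sum", "q_p", "q_lac") %in%
                    rates$quantity))
  expect_equal(rates$value[rates$quantity == "mu"], rep(0.4, 5))
})
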