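test_that("equal-count binning pools the configured statistic", {
  rec <- data.frame(total_gfp = c(10, 20, 30, 40),
                    d = c(1, 100, 9, 16))
  cv <- build_drc(rec, "d", n_min = 2, pooling = "gmean")
  expect_equal(cv$value, c(10, 12))     # sqrt(1*100), sqrt(9*16)
  expect_equal(cv$n, c(2L, 2L))
  expect_true(all(diff(cv$expression) > 0))
  # median pooling
  rec2 <- data.frame(total_gfp = 1:6, d = c(1, 2, 3, 5, 5, 5))
  cv2 <- build_drc(rec2, "d", n_min = 3, pooling = "median")
  expect_equal(cv2$value[1], 2)
  # shortfall errors informatively
  expect_error(build_drc(rec, "d", n_min = 3), "too few")
})

test_that("bins remain in expression order with uneven record counts", {
  set.seed(2)
  rec <- data.frame(total_gfp = 10^runif(107, 3, 7), d = rlnorm(107))
  cv <- build_drc(rec, "d", n_min = 10, pooling = "gmean")
  expect_equal(sum(cv$n), 107)
  expect_true(all(cv$n >= 10))
  expect_true(!is.unsorted(cv$expression))
})

test_that("RoV reproduces hand-computed window variances", {
  rov <- rov_series(c(1, 2, 3, 10, 20, 30), N = 2, log = FALSE)
  # i = 3: var(10,20) / var(1,2) = 50 / 0.5
  expect_equal(rov$rov[rov$index == 3], 100, tolerance = 1e-12)
  # symmetric windows with identical multisets -> 1
  rov2 <- rov_series(c(5, 7, 9, 5, 7, 9, 5), N = 3, log = FALSE)
  expect_equal(rov2$rov, 1, tolerance = 1e-12)
  # constant trailing window -> flagged undefined, not Inf
  rov3 <- rov_series(c(4, 4, 3, 9, 1), N = 2, log = FALSE)
  expect_true(is.na(rov3$rov[1]))
  expect_error(rov_series(1:5, N = 3), "too short")
  expect_error(rov_series(c(1, -1, 2, 3, 4, 5, 6), N = 3, log = TRUE),
               "positive")
})

test_that("RoV matches the direct-summation oracle on random series", {
  set.seed(1234)
  for (i in 1:1000) {
    d <- rlnorm(50, meanlog = runif(1, 0, 3), sdlog = runif(1, 0.1, 1))
    N <- sample(2:6, 1)
    got <- rov_series(d, N = N)$rov
    want <- rov_oracle(d, N)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("reversing a series swaps the RoV windows", {
  set.seed(77)
  for (i in 1:50) {
    d <- rlnorm(30)
    N <- sample(2:5, 1)
    fwd <- rov_series(d, N = N)$rov
    rev_ <- rov_series(rev(d), N = N)$rov
    expect_equal(fwd, 1 / rev(rev_), tolerance = 1e-10)
  }
})

test_that("scaling a descriptor leaves log-scale RoV unchanged", {
  set.seed(31)
  d <- rlnorm(30, 2, 0.5)
  r1 <- rov_series(d, N = 3)$rov
  r2 <- rov_series(7.3 * d, N = 3)$rov
  expect_equal(r1, r2, tolerance = 1e-12)
  # geometric-mean bins scale linearly with the descriptor
  rec <- data.frame(total_gfp = 10^runif(60, 3, 6), d = rlnorm(60))
  c1 <- build_drc(rec, "d", n_min = 10, pooling = "gmean")
  rec$d <- rec$d * 5
  c2 <- build_drc(rec, "d", n_min = 10, pooling = "gmean")
  expect_equal(c2$value, 5 * c1$value, tolerance = 1e-12)
})

test_that("threshold detection finds breakpoints and ignores clean trends", {
  tf <- list(baseline = 100, plateau = 10000, t1 = 1e4, t2 = 1e6)
  set.seed(5)
  cv <- synthetic_curve(tf, n_bins = 40, lo = 1e2, hi = 1e8, noise_cv = 0.05)
  cd <- detect_thresholds(rov_series(cv), cv)
  expect_equal(nrow(cd), 2)
  expect_equal(cd$type, c("lower", "upper"))
  expect_lt(abs(log10(cd$expression[1] / 1e4)), 0.5)
  expect_lt(abs(log10(cd$expression[2] / 1e6)), 0.5)
  # monotone noise-free log-linear curve: constant RoV, no candidates
  expr <- 10^seq(2, 8, length.out = 30)
  clean <- structure(
    data.frame(expression = expr, value = expr^0.5, lo = expr^0.5,
               hi = expr^0.5, n = 100L),
    class = c("DoseResponseCurve", "data.frame"))
  cdc <- detect_thresholds(rov_series(clean), clean)
  expect_equal(nrow(cdc), 0)
  # single breakpoint (baseline -> rise, no plateau): one candidate
  set.seed(6)
  cv1 <- synthetic_curve(list(baseline = 100, plateau = 10000, t1 = 1e5,
                              t2 = 1e9), n_bins = 40, lo = 1e2, hi = 1e8,
                         noise_cv = 0.05)
  cd1 <- detect_thresholds(rov_series(cv1), cv1)
  expect_equal(nrow(cd1), 1)
  expect_equal(cd1$type, "lower")
  expect_lt(abs(log10(cd1$expression / 1e5)), 0.5)
})

test_that("global thresholds pool candidates geometrically", {
  one <- data.frame(expression = c(1e3, 1e5),
                    type = c("lower", "upper"))
  expect_equal(unname(global_thresholds(one)), c(1e3, 1e5))
  two <- list(data.frame(expression = c(1e2, 1e6), type = c("lower", "upper")),
              data.frame(expression = c(1e4, 1e6), type = c("lower", "upper")))
  expect_equal(unname(global_thresholds(two)[1]), 1e3)
  expect_error(global_thresholds(data.frame(expression = 1e3,
                                            type = "lower")), "upper")
  crossed <- data.frame(expression = c(1e5, 1e3), type = c("lower", "upper"))
  expect_error(global_thresholds(crossed), "crossed")
})

test_that("regime assignment uses half-open intervals", {
  rec <- data.frame(total_gfp = c(10, 99.9999, 100, 500, 1000, 5000))
  out <- assign_regimes(rec, 100, 1000)
  expect_equal(as.character(out$regime),
               c("no_effect", "no_effect", "dose_response", "dose_response",
                 "saturation", "saturation"))
  expect_equal(unname(as.integer(attr(out, "counts"))), c(2L, 2L, 2L))
  all_low <- assign_regimes(data.frame(total_gfp = 1:10), 100, 1000)
  expect_true(all(all_low$regime == "no_effect"))
})
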