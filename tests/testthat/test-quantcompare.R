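test_that("paired response regression is exact on exact data", {
  fit <- fit_paired_response(1:5, 2 * (1:5))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, 1)
  expect_error(fit_paired_response(rep(3, 5), 1:5), "degenerate")
  expect_error(fit_paired_response(1:2, 1:2), "at least 3")
})

test_that("paired regression is scale-equivariant in y", {
  set.seed(42)
  x <- runif(20, 1, 10)
  y <- 1.7 * x + 0.4 + rnorm(20, 0, 0.2)
  f1 <- fit_paired_response(x, y)
  f2 <- fit_paired_response(x, 100 * y)
  expect_equal(f2$slope, 100 * f1$slope)
  expect_equal(f2$intercept, 100 * f1$intercept)
  expect_equal(f2$r_squared, f1$r_squared)
})

test_that("relative standard deviation matches hand computation", {
  expect_equal(relative_sd(c(10, 10, 10)), 0)
  expect_equal(relative_sd(c(9, 10, 11)), 10)  # sd 1, mean 10
  expect_error(relative_sd(5), "at least 2")
  expect_error(relative_sd(c(-1, 1)), "mean response is zero")
})

test_that("LOD follows 3.3 sigma over slope and its homogeneities", {
  ser <- calibration_series("butanal", "SIFT", c(1, 2, 3, 4),
                            c(10, 20, 30, 40), ppbv_per_unit = 2)
  expect_equal(lod_from_calibration(ser, 0), 0)
  l1 <- lod_from_calibration(ser, 1.5)
  expect_equal(l1, 3.3 * 1.5 / 10 * 2)  # hand computation
  expect_equal(lod_from_calibration(ser, 3), 2 * l1)
  # strictly decreasing in slope
  steeper <- calibration_series("butanal", "SIFT", c(1, 2, 3, 4),
                                c(20, 40, 60, 80), ppbv_per_unit = 2)
  expect_lt(lod_from_calibration(steeper, 1.5), l1)
  flat <- calibration_series("x", "SIFT", 1:3, c(3, 2, 1))
  expect_error(lod_from_calibration(flat, 1), "positive")
})

test_that("class composition normalises per sample and summarises cohort", {
  one <- data.frame(sample = "S1",
                    chem_class = c("ketone", "aldehyde", "acid", "phenol",
                                   "alcohol"),
                    area = c(77, 10, 9, 3, 1))
  prof <- class_composition(one)
  expect_equal(sort(prof$per_sample$percent, decreasing = TRUE),
               c(77, 10, 9, 3, 1))
  expect_equal(sum(prof$per_sample$percent), 100)
  expect_identical(prof$cohort$chem_class[1L], "ketone")

  solo <- class_composition(data.frame(sample = "S1", chem_class = "acid",
                                       area = 5))
  expect_equal(solo$per_sample$percent, 100)

  set.seed(7)
  many <- data.frame(sample = rep(sprintf("S%d", 1:20), each = 5),
                     chem_class = rep(c("a", "b", "c", "d", "e"), 20),
                     area = runif(100, 0, 50))
  sums <- tapply(class_composition(many)$per_sample$percent,
                 class_composition(many)$per_sample$sample, sum)
  expect_true(all(abs(sums - 100) < 1e-9))

  expect_error(class_composition(data.frame(sample = "S1",
                                            chem_class = "a", area = 0)),
               "undefined")
  # tier column restricts to confirmed/probable annotations
  tiered <- data.frame(sample = "S1", chem_class = c("a", "b"),
                       area = c(10, 90),
                       tier = c("confirmed", "rejected"))
  expect_equal(class_composition(tiered)$per_sample$percent, 100)
})
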