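lib <- example_library()

test_that("simulation is a pure function of config and seed", {
  cfg <- sim_config()
  a <- simulate_platform_peaks(lib, "EI", cfg, seed = 101)
  b <- simulate_platform_peaks(lib, "EI", cfg, seed = 101)
  expect_identical(a, b)
  c1 <- simulate_cohort(10, cfg, seed = 5)
  c2 <- simulate_cohort(10, cfg, seed = 5)
  expect_identical(c1, c2)
})

test_that("noiseless generation emits exactly the predicted m/z", {
  quiet <- sim_config(noise_cv = 0, decoy_rate = 0, mz_jitter_sd = 0,
                      ri_jitter_sd = 0)
  tab <- simulate_platform_peaks(list(lib[["acetic acid"]]), "SIFT_H3O",
                                 quiet, seed = 1)
  expect_setequal(tab$mz, c(61, 79, 97))
  tab_ei <- simulate_platform_peaks(list(lib[["heptanal"]]), "EI",
                                    quiet, seed = 1)
  # suppressed molecular ion is not emitted
  expect_setequal(tab_ei$mz, c(43, 44))
  expect_equal(unique(tab_ei$ri), 944)
})

test_that("noiseless generation plus annotation is lossless", {
  quiet <- sim_config(noise_cv = 0, decoy_rate = 0, mz_jitter_sd = 0,
                      ri_jitter_sd = 0)
  bench <- recovery_benchmark(lib, config = quiet, seed = 2)
  expect_equal(bench$top1_rate, 1)
  expect_true(all(bench$results$tier == "confirmed"))
})

test_that("calibration simulation recovers the truth", {
  loadings <- seq(50, 1000, length.out = 8)  # vapour-volume style schedule
  exact <- simulate_calibration_series(3e15, 2e6, loadings,
                                       sim_config(noise_cv = 0), seed = 1)
  fit <- fit_paired_response(exact$A$response, exact$B$response)
  expect_equal(fit$slope, 3e15)
  # recovery is exact up to double-precision round-off at ~1e18 magnitudes
  expect_equal(fit$intercept, 2e6, tolerance = 1e-3)
  expect_equal(fit$r_squared, 1)

  noisy <- simulate_calibration_series(3e15, 0, loadings, sim_config(),
                                       seed = 8)
  nf <- fit_paired_response(noisy$A$response, noisy$B$response)
  expect_lt(abs(nf$slope - 3e15) / 3e15, 0.1)
})

test_that("replicate noise reproduces the configured CV", {
  cfg <- sim_config()  # 9% noise
  set.seed(12)
  rsds <- replicate(300, {
    s <- simulate_calibration_series(1, 0, c(100, 100, 100), cfg)
    relative_sd(s$B$response)
  })
  expect_lt(abs(mean(rsds) - 9), 1.5)
})

test_that("cohort composition centres on the configured medians", {
  exact <- sim_config(composition_concentration = Inf)
  one <- simulate_cohort(1, exact, seed = 4)
  prof <- class_composition(one)
  expect_equal(prof$per_sample$percent[
    prof$per_sample$chem_class == "ketone"], 77, tolerance = 1e-6)

  coh <- simulate_cohort(200, sim_config(), seed = 21)
  med <- class_composition(coh)$cohort
  expect_lt(abs(med$median[med$chem_class == "ketone"] - 77), 3)
})

test_that("grouped simulated features carry decoys and truth labels", {
  cfg <- sim_config()
  tabs <- list(EI = simulate_platform_peaks(lib, "EI", cfg, seed = 31),
               SIFT_NO = simulate_platform_peaks(lib, "SIFT_NO", cfg,
                                                 seed = 32))
  groups <- group_simulated_peaks(tabs)
  expect_setequal(names(groups), vapply(lib, `[[`, character(1L), "name"))
  g <- groups[["propanal"]]
  expect_s3_class(g$peaks$EI, "peak_table")
  expect_false(is.na(g$observed_ri))
  expect_true(is.na(attr(g$peaks$SIFT_NO, "platform") == "SIFT_NO") ||
              attr(g$peaks$SIFT_NO, "platform") == "SIFT_NO")
})
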