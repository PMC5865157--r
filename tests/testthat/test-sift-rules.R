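test_that("precursor hydrate series match the instrument values", {
  expect_identical(precursor_series("H3O+"), c(19L, 37L, 55L, 73L))
  expect_identical(precursor_series("NO+"), c(30L, 48L, 66L))
  expect_identical(max(precursor_series("H3O+")) -
                     min(precursor_series("H3O+")), 54L)
  expect_true(all(diff(precursor_series("H3O+")) == 18L))
  expect_true(all(diff(precursor_series("NO+")) == 18L))
  expect_error(precursor_series("O2+"), "supported: H3O\\+, NO\\+")
})

test_that("H3O+ channels: protonation, hydrates, alcohol dehydration", {
  expect_setequal(predict_sift_products(fx_acetic, "H3O+")$mz,
                  c(61L, 79L, 97L))
  # hydrate series arithmetic with difference 18 starting at M+1
  for (cand in list(fx_acetic, fx_phenol, fx_butanol)) {
    p <- predict_sift_products(cand, "H3O+")
    hyd <- sort(p$mz[p$transform %in% c("M+H", "M+H+nH2O")])
    expect_equal(hyd[1L], cand$molecular_mass + 1L)
    expect_true(all(diff(hyd) == 18L))
  }
  et <- predict_sift_products(fx_ethanol, "H3O+")
  expect_true(any(et$channel == "dehydration" & et$mz == 29L))
  # ketones and aldehydes: plain protonation
  expect_identical(predict_sift_products(fx_acetone, "H3O+")$mz, 59L)
  expect_identical(predict_sift_products(fx_propanal, "H3O+")$mz, 59L)
})

test_that("NO+ channels: electron transfer, adduct, hydride abstraction", {
  ph <- predict_sift_products(fx_phenol, "NO+")
  expect_identical(ph$mz[ph$intensity_class == "base"], 94L)
  expect_identical(ph$channel[ph$intensity_class == "base"],
                   "electron transfer")

  hep <- predict_sift_products(fx_heptanal, "NO+")
  expect_identical(hep$mz, 113L)
  expect_identical(hep$channel, "hydride abstraction")

  but <- predict_sift_products(fx_butanoic, "NO+")
  expect_identical(but$mz, 118L)  # M + 30 nitrosonium adduct
  expect_true(attr(but, "dissociative_ionisation"))
  # only acids carry the dissociative flag
  expect_false(attr(predict_sift_products(fx_acetone, "NO+"),
                    "dissociative_ionisation"))
})

test_that("channel predictions depend only on class and precursor", {
  # same class and carbon count, different name/RI: identical channels
  a <- compound_record("x", "C4H8O2", "acid", reference_ri = 800)
  b <- compound_record("y", "C4H8O2", "acid")
  pa <- predict_sift_products(a, "NO+")
  pb <- predict_sift_products(b, "NO+")
  expect_identical(pa[, c("transform", "mz", "intensity_class")],
                   pb[, c("transform", "mz", "intensity_class")])
})

test_that("kinetic entries validate branching fractions", {
  expect_s3_class(kinetic_entry("propanal", "NO+", 2.4e-9, c(57L), 1),
                  "kinetic_entry")
  expect_error(kinetic_entry("x", "NO+", -1, 57L, 1), "positive")
  expect_error(kinetic_entry("x", "NO+", 2e-9, c(57L, 87L), c(0.6, 0.6)),
               "sum to 1")
})

test_that("MIM quantitation follows first-order flow-tube kinetics", {
  # arithmetic oracle: ratio 7.5e-4 / (3e-9 cm3/s * 10 ms * 2.5e16 cm-3)
  # = 1e-9 mixing ratio = 1 ppbv, computed by hand
  expect_equal(quantify_mim(600, 8e5, k = 3e-9, reaction_time = 0.01,
                            number_density = 2.5e16), 1)
  base <- quantify_mim(600, 8e5, 3e-9, 0.01, 2.5e16)
  expect_equal(quantify_mim(1200, 8e5, 3e-9, 0.01, 2.5e16), 2 * base)
  expect_equal(quantify_mim(600, 4e5, 3e-9, 0.01, 2.5e16), 2 * base)
  expect_equal(quantify_mim(0, 8e5, 3e-9, 0.01, 2.5e16), 0)
  expect_error(quantify_mim(600, 0, 3e-9, 0.01, 2.5e16),
               "undefined at zero")
})
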