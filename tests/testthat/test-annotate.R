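ladder <- data.frame(carbon = 5:20,
                     rt = 4 + 2.2 * (5:20) + 0.05 * (5:20)^2)

test_that("retention index interpolates linearly on the alkane ladder", {
  expect_equal(compute_ri(ladder$rt[1L], ladder), 500)
  # midpoint between C12 and C13 -> 1250
  mid <- mean(ladder$rt[ladder$carbon %in% c(12, 13)])
  expect_equal(compute_ri(mid, ladder), 1250)
  # arithmetic oracle: hand-placed analyte 30% of the way from C7 to C8
  rt7 <- ladder$rt[ladder$carbon == 7]
  rt8 <- ladder$rt[ladder$carbon == 8]
  expect_equal(compute_ri(rt7 + 0.3 * (rt8 - rt7), ladder), 730)
  expect_error(compute_ri(ladder$rt[1L] - 1, ladder),
               "refusing to extrapolate")
  expect_error(compute_ri(max(ladder$rt) + 1, ladder),
               "refusing to extrapolate")
})

test_that("library-score gate is strict at the 800 boundary", {
  expect_true(library_gate(750, 820))
  expect_false(library_gate(800, 800))
  expect_false(library_gate(1000, 1000))
  expect_error(library_gate(-5, 900), "\\[0, 1000\\]")
  expect_error(library_gate(500, 1200), "\\[0, 1000\\]")
})

test_that("ion matching supports, and refuses to support, correctly", {
  preds <- predict_ei_ions(fx_propanal)
  ev <- match_ions(preds, peak_table(c(29.1, 150), c(100, 5),
                                     platform = "EI"))
  expect_true(ev$matched)
  expect_equal(ev$matched_ions$predicted_mz, 29)

  empty <- match_ions(preds, peak_table(numeric(0), numeric(0),
                                        platform = "EI"))
  expect_false(empty$matched)
  expect_identical(nrow(empty$matched_ions), 0L)

  # decoy control: every peak shifted +5 m/z matches nothing
  shifted <- match_ions(preds, peak_table(preds$mz + 5, rep(50, nrow(preds)),
                                          platform = "EI"))
  expect_false(shifted$matched)

  expect_error(
    match_ions(preds, peak_table(29, 100, platform = "PCI")),
    "platform")
})

test_that("acetic acid outranks ammonium acetate on the worked peak group", {
  res <- screen_candidates(acetic_peak_group(),
                           list(fx_acetic, fx_ammonium_acetate))
  expect_identical(res$candidate[1L], "acetic acid")
  expect_identical(res$tier[res$candidate == "ammonium acetate"],
                   "rejected")
  # the ammonium-acetate protonated molecule (77 + 1) matches nothing
  expect_identical(fx_ammonium_acetate$molecular_mass, 77L)
})

test_that("propanal reaches tier confirmed with RI plus three platforms", {
  peaks <- list(
    EI = peak_table(c(58, 29), c(60, 100), platform = "EI"),
    PCI = peak_table(59, 100, platform = "PCI"),
    SIFT_NO = peak_table(57, 100, platform = "SIFT_NO"))
  res <- screen_candidates(peaks, list(fx_propanal, fx_acetone),
                           observed_ri = 489)
  expect_identical(res$candidate[1L], "propanal")
  expect_identical(res$tier[1L], "confirmed")
})

test_that("SIFT-indistinguishable isomers are ambiguous until RI resolves", {
  sift_peaks <- list(
    SIFT_H3O = peak_table(c(123, 141, 159), c(100, 50, 30),
                          platform = "SIFT_H3O"))
  cands <- list(fx_ethylphenol2, fx_ethylphenol4)
  res <- screen_candidates(sift_peaks, cands)
  expect_true(all(res$tier == "tentative"))
  expect_setequal(res$ambiguity_set, c("2-ethylphenol", "4-ethylphenol"))

  resolved <- screen_candidates(sift_peaks, cands, observed_ri = 1286)
  r2 <- resolved[resolved$candidate == "2-ethylphenol", ]
  r4 <- resolved[resolved$candidate == "4-ethylphenol", ]
  expect_identical(r2$tier, "probable")  # RI + one platform
  expect_true(r2$ri_match)
  expect_false(r4$ri_match)
  expect_identical(resolved$ambiguity_set, c("", ""))
  expect_identical(resolved$candidate[1L], "2-ethylphenol")
})

test_that("tier is monotone in matched platforms", {
  tiers <- c(rejected = 0, tentative = 1, probable = 2, confirmed = 3)
  all_peaks <- list(
    EI = peak_table(c(58, 29), c(60, 100), platform = "EI"),
    PCI = peak_table(59, 100, platform = "PCI"),
    SIFT_NO = peak_table(57, 100, platform = "SIFT_NO"))
  for (ri in list(NA_real_, 489)) {
    prev <- -Inf
    for (k in 1:3) {
      res <- screen_candidates(all_peaks[seq_len(k)], list(fx_propanal),
                               observed_ri = ri)
      now <- tiers[[res$tier[1L]]]
      expect_gte(now, prev)
      prev <- now
    }
  }
})

test_that("screening is invariant under candidate permutation", {
  cands <- unname(example_library())
  peaks <- acetic_peak_group()
  a <- screen_candidates(peaks, cands, observed_ri = 675)
  set.seed(3)
  b <- screen_candidates(peaks, sample(cands), observed_ri = 675)
  strip <- function(x) {
    data.frame(unclass(x)[names(x)], stringsAsFactors = FALSE,
               check.names = FALSE)
  }
  expect_identical(strip(a), strip(b))
  expect_identical(a$candidate[1L], "acetic acid")
})

test_that("a fully contradicted candidate never outranks a partial match", {
  peaks <- acetic_peak_group()
  res <- screen_candidates(peaks, list(fx_acetic, fx_heptanal,
                                       fx_ammonium_acetate))
  idx <- match(c("acetic acid", "ammonium acetate"), res$candidate)
  expect_true(idx[1L] < idx[2L])
  expect_identical(res$tier[res$candidate == "heptanal"], "rejected")
})
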