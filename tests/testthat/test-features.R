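test_that("lesion-type proportions are ratios over demyelinating lesions only", {
  p <- lesion_type_proportions(2, 2, 4, 2)
  expect_equal(unname(p[1, ]), c(0.2, 0.2, 0.4, 0.2))
  expect_equal(unname(lesion_type_proportions(0, 0, 5, 0)[1, ]), c(0, 0, 1, 0))
  expect_equal(unname(lesion_type_proportions(3, 1, 1, 0)[1, ]), c(0.6, 0.2, 0.2, 0))
  expect_warning(p0 <- lesion_type_proportions(0, 0, 0, 0), "zero")
  expect_true(all(is.na(p0)))
  # defined rows always sum to 1
  set.seed(1)
  cnt <- matrix(rpois(40, 3), 10, 4)
  cnt[1, ] <- cnt[1, ] + 1
  p <- suppressWarnings(lesion_type_proportions(cnt[, 1], cnt[, 2], cnt[, 3], cnt[, 4]))
  sums <- rowSums(p)
  expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-12))
})

test_that("brainstem loads exclude reactive sites and distinguish 0 from missing", {
  expect_equal(lesion_load(1, 2, 1, 0), 4)
  expect_equal(lesion_load(0, 0, 0, 0), 0)
  expect_equal(lesion_load(2, 2, 2, 2), 8)
  expect_true(is.na(lesion_load(NA, NA, NA, NA)))
  expect_equal(reactive_site_load(3), 3)
  expect_equal(reactive_site_load(0), 0)
  expect_true(is.na(reactive_site_load(NA)))
  # load + reactive load equals the total brainstem anomaly count
  set.seed(2)
  bs <- matrix(rpois(50, 2), 10, 5)
  expect_equal(lesion_load(bs[, 2], bs[, 3], bs[, 4], bs[, 5]) + reactive_site_load(bs[, 1]),
               rowSums(bs))
})

test_that("cortical lesion rate is per cortex-containing block, undefined at 0 blocks", {
  expect_equal(cortical_lesion_rate(6, 4), 1.5)
  expect_equal(cortical_lesion_rate(0, 3), 0)
  expect_true(is.na(cortical_lesion_rate(2, 0)))
})

test_that("activation score averages per-lesion morphology scores and is bounded", {
  expect_equal(activation_score(1, 1, 1), 0.5)
  expect_equal(activation_score(0, 0, 4), 1)
  expect_equal(activation_score(2, 0, 1), 1 / 3)
  expect_true(is.na(activation_score(0, 0, 0)))
  set.seed(3)
  cnt <- matrix(rpois(30, 2) + 1, 10, 3)
  a <- activation_score(cnt[, 1], cnt[, 2], cnt[, 3])
  expect_true(all(a >= 0 & a <= 1))
  # invariant to how lesions are ordered: only counts matter, and swapping
  # ramified/foamy reflects the score around 1/2
  expect_equal(activation_score(cnt[, 3], cnt[, 2], cnt[, 1]), 1 - a)
})

test_that("presence binarization is any-block-positive with missing for no data", {
  expect_true(binarize_presence(c(FALSE, FALSE, TRUE)))
  expect_false(binarize_presence(c(FALSE, FALSE)))
  expect_true(is.na(binarize_presence(logical(0))))
  expect_true(is.na(binarize_presence(c(NA, NA))))
})

test_that("symptom load is observations per disease-year and scales with duration", {
  expect_equal(symptom_load(30, 20), 1.5)
  expect_equal(symptom_load(0, 7), 0)
  expect_equal(symptom_load(7, 14), 0.5)
  expect_true(is.na(symptom_load(3, 0)))
  expect_equal(symptom_load(12, 8), 2 * symptom_load(12, 16))
})

test_that("median domain onset uses the even-count midpoint", {
  expect_equal(median_domain_onset(30), 30)
  expect_equal(median_domain_onset(c(20, 30, 50)), 30)
  expect_equal(median_domain_onset(c(20, 40)), 30)
  expect_true(is.na(median_domain_onset(numeric(0))))
})

test_that("grey-matter proportions are defined only with at least one cortical lesion", {
  expect_equal(unname(grey_matter_proportions(2, 1, 1)[1, ]), c(0.5, 0.25, 0.25))
  expect_equal(unname(grey_matter_proportions(0, 0, 3)[1, ]), c(0, 0, 1))
  expect_true(all(is.na(grey_matter_proportions(0, 0, 0))))
})

test_that("derive_features assembles the 13-variable input table from raw records", {
  rec <- data.frame(
    donor_id = c("a", "b", "c"),
    bs_reactive = c(3, 0, NA), bs_active = c(1, 0, NA), bs_mixed = c(2, 0, NA),
    bs_inactive = c(1, 0, NA), bs_remyelinated = c(0, 0, NA),
    wm_active = c(2, 3, 1), wm_mixed = c(2, 1, 1), wm_inactive = c(4, 1, 2),
    wm_remyelinated = c(2, 0, 1),
    mg_ramified = c(1, 2, 0), mg_ameboid = c(1, 0, 1), mg_foamy = c(1, 1, 1),
    cortical_blocks = c(4, 0, 3), cortical_lesions = c(6, 0, 0),
    cuff_present = c(TRUE, FALSE, TRUE), nodule_present = c(FALSE, FALSE, TRUE)
  )
  ft <- derive_features(rec)
  expect_equal(ncol(ft), 14)  # donor_id + 13 variables
  expect_equal(ft$lesion_load, c(4, 0, NA))
  expect_equal(ft$reactive_site_load, c(3, 0, NA))
  expect_equal(ft$cortical_lesion_rate, c(1.5, NA, 0))
  expect_equal(ft$activation_score, c(0.5, 1 / 3, 0.75))
  expect_s3_class(ft$cuff, "factor")
  # CLR columns sum to zero per donor within each block
  expect_true(all(abs(rowSums(ft[, paste0("wm_clr_", c("active", "mixed",
    "inactive", "remyelinated"))])) < 1e-10))
  expect_true(all(abs(rowSums(ft[, paste0("mg_clr_", c("ramified", "ameboid",
    "foamy"))])) < 1e-10))
})
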