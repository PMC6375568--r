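test_that("Du Bois BSA matches the direct formula and scales as a power law", {
  expect_equal(compute_bsa(180, 80), 0.007184 * 180^0.725 * 80^0.425)
  expect_equal(compute_bsa(180, 160) / compute_bsa(180, 80), 2^0.425)
  expect_gt(compute_bsa(167, 64), 1.6)
  expect_lt(compute_bsa(167, 64), 1.9)
  expect_error(compute_bsa(-170, 60), "positive")
})

test_that("BSA indexing divides and round-trips", {
  expect_equal(index_to_bsa(200, 2), 100)
  expect_equal(index_to_bsa(42.5, 1), 42.5)
  # indexed value times BSA recovers the raw volume
  expect_equal(index_to_bsa(75.8 * 1.94, 1.94), 75.8)
  expect_error(index_to_bsa(10, 0), "bsa")
})

fake_wall <- function(max_edwt, ratio) {
  structure(list(max_edwt = max_edwt, min_edwt = max_edwt / ratio,
                 max_min_ratio = ratio, slice_of_max = 1L, status = "ok"),
            class = "edwt_result")
}
fake_vol <- function(method, lvedv, lvm, tpm = NA_real_) {
  structure(list(method = method, LVEDV = lvedv, LVESV = lvedv / 2,
                 LVSV = lvedv / 2, LVEF = 50, LVM = lvm, TPM = tpm),
            class = "lv_volumetrics")
}

test_that("sport indices are the defining exact ratios", {
  si <- compute_sport_indices(fake_wall(14, 1.5),
                              vol_cq = fake_vol("CQ", 200, 150),
                              vol_tq = fake_vol("TQ", 180, 170, tpm = 30),
                              bsa = 2)
  expect_equal(si$edwt_lvedvi_cq, 14 / 100)
  expect_equal(si$lvm_lvedv_cq, 0.75)
  expect_equal(si$edwt_lvedvi_tq, 14 / 90)
  expect_equal(si$lvm_lvedv_tq, 170 / 180)
  expect_equal(si$tpm_pct, 100 * 30 / 170)
  # TPM% and the compact share sum to exactly 100
  expect_equal(si$tpm_pct + 100 * (170 - 30) / 170, 100)
})

test_that("TPM percentage demands the threshold-based result", {
  expect_error(compute_sport_indices(fake_wall(14, 1.5),
                                     vol_cq = fake_vol("CQ", 200, 150),
                                     bsa = 2, tpm = TRUE), "TQ")
  expect_error(compute_sport_indices(fake_wall(14, 1.5), bsa = 2),
               "quantification result")
})

test_that("index computation is unit-coherent", {
  si_ml <- compute_sport_indices(fake_wall(14, 1.5),
                                 vol_cq = fake_vol("CQ", 200, 150), bsa = 2)
  # converting volume to mm^3 and back leaves the index unchanged
  v_mm3 <- fake_vol("CQ", 200 * 1000 / 1000, 150)
  si_rt <- compute_sport_indices(fake_wall(14, 1.5), vol_cq = v_mm3, bsa = 2)
  expect_equal(si_ml$edwt_lvedvi_cq, si_rt$edwt_lvedvi_cq)
})

test_that("classification is strict at the cut-off and monotone", {
  rules <- reference_cutoff_rules()
  mk <- function(v) list(edwt_lvedvi_cq = v, edwt_lvedvi_tq = 0.1,
                         lvm_lvedv_cq = 0.5, lvm_lvedv_tq = 1.0,
                         maxmin_edwt = 1.5, max_edwt = 12)
  above <- classify_subject(mk(0.15), rules)$labels
  expect_equal(above$label[above$index == "edwt_lvedvi_cq"], "HCM-range")
  at <- classify_subject(mk(0.14), rules)$labels
  expect_equal(at$label[at$index == "edwt_lvedvi_cq"], "athlete-range")
  # monotone: raising one index never flips a label back to athlete-range
  lab <- function(v) classify_subject(mk(v), rules)$labels$label[1L]
  v <- seq(0.05, 0.4, by = 0.01)
  hcm <- vapply(v, function(x) lab(x) == "HCM-range", logical(1))
  expect_true(all(diff(hcm) >= 0))
})

test_that("grey zone bounds are inclusive 13-16 mm", {
  g <- function(e) classify_subject(
    list(max_edwt = e, maxmin_edwt = 1, edwt_lvedvi_cq = 0.1,
         edwt_lvedvi_tq = 0.1, lvm_lvedv_cq = 0.5, lvm_lvedv_tq = 1))$grey_zone
  expect_true(g(13.0))
  expect_true(g(16.0))
  expect_false(g(12.9))
  expect_false(g(16.1))
})

test_that("unknown rule indices are rejected", {
  expect_error(classify_subject(list(edwt_lvedvi_cq = 0.2),
                                cutoff_rules("not_an_index", 1)),
               "unknown index")
})
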