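test_that("slice summation handles single, empty and cylindrical inputs", {
  expect_equal(slice_summation_volume(1000, 8), 8)
  expect_equal(slice_summation_volume(numeric(0), 8), 0)
  expect_equal(slice_summation_volume(rep(pi * 25^2, 10), 8), 157.0796,
               tolerance = 1e-6)
  expect_equal(slice_summation_volume(1000, 8, slice_gap = 2), 10)
  expect_error(slice_summation_volume(-1, 8), "areas")
})

test_that("CQ recovers the closed-form annulus mass and handles no contraction", {
  ph <- generate_phantom(phantom_spec(
    n_slices = 10L, endo_radius_ed = 25, endo_radius_es = 18, wall_base = 10,
    in_plane_spacing = 1, supersampling_factor = 2))
  v <- cq_quantify(ph$stack, ph$contours, density = 1.05)
  expect_equal(v$LVM, pi * (35^2 - 25^2) * 80 * 1.05 / 1000,
               tolerance = 0.005)
  # identical phases: no stroke volume
  frozen <- ph$contours
  frozen$ES <- frozen$ED
  v0 <- cq_quantify(ph$stack, frozen)
  expect_equal(v0$LVSV, 0)
  expect_equal(v0$LVEF, 0)
  # missing endocardial contour is a method requirement
  broken <- ph$contours
  broken$ED[[2L]]$endo <- NULL
  expect_error(cq_quantify(ph$stack, broken), "endocardial contour")
})

test_that("class intensity estimation finds the two levels", {
  img <- matrix(200, 20, 20)
  mask <- matrix(FALSE, 20, 20)
  mask[4:16, 4:16] <- TRUE
  img[6:12, 6:12] <- 1000
  est <- estimate_class_intensities(img, mask)
  expect_false(est$degenerate)
  expect_equal(est$blood, 1000)
  expect_equal(est$muscle, 200)

  set.seed(1)
  noisy <- img + matrix(rnorm(400, sd = 30), 20, 20)
  est2 <- estimate_class_intensities(noisy, mask)
  expect_lt(abs(est2$blood - 1000), 3 * 30 / sqrt(49))
  expect_lt(abs(est2$muscle - 200), 3 * 30 / sqrt(sum(mask) - 49))

  flat <- matrix(500, 20, 20)
  expect_true(estimate_class_intensities(flat, mask)$degenerate)
})

test_that("threshold labelmap matches the phantom geometry when noiseless", {
  # supersampling 1 leaves pure two-level voxels: labels must equal the
  # geometric classes voxel-for-voxel
  sp <- quick_spec(supersampling_factor = 1L, in_plane_spacing = 1,
                   trabecular_fraction = 0.2, n_papillary = 2)
  ph <- generate_phantom(sp)
  lm <- threshold_labelmap(ph$stack$phases$ED, ph$contours$ED, 1)
  g <- sp$grid_size
  pos <- (seq_len(g) - 0.5) - g / 2
  x <- matrix(pos, g, g); y <- matrix(pos, g, g, byrow = TRUE)
  r <- sqrt(x^2 + y^2)
  # skip voxel centers closer to the endo circle than the polygon chord error
  clear <- abs(r - sp$endo_radius_ed) > 0.05
  for (s in seq_len(sp$n_slices)) {
    img <- ph$stack$phases$ED[, , s]
    lab <- lm$labels[[s]]
    in_mask <- lab > 0L
    # in-mask blood voxels are exactly the blood-intensity voxels
    expect_identical(lab[in_mask] == 1L,
                     img[in_mask] == sp$blood_intensity)
    # muscle inside the cavity boundary is TPM, outside it is compact wall
    musc <- in_mask & lab != 1L & clear
    expect_identical(lab[musc] == 3L, r[musc] < sp$endo_radius_ed)
  }
})

test_that("threshold fraction 1 labels every in-mask voxel muscle", {
  sp <- quick_spec(supersampling_factor = 1L)
  ph <- generate_phantom(sp)
  lm <- threshold_labelmap(ph$stack$phases$ED, ph$contours$ED,
                           sp$in_plane_spacing, threshold_fraction = 1)
  expect_equal(lm$counts[["cavity_blood"]], 0)
  expect_error(threshold_labelmap(ph$stack$phases$ED, ph$contours$ED,
                                  sp$in_plane_spacing, 0), "threshold")
})

test_that("labelmap equals exhaustive per-voxel classification", {
  # random intensities, arbitrary threshold fractions
  set.seed(20)
  for (f in c(0.3, 0.5, 0.8)) {
    img <- array(runif(24 * 24 * 3, 0, 1000), dim = c(24, 24, 3))
    contours <- lapply(1:3, function(s)
      list(endo = circle_poly(6, center = c(12, 12)),
           epi = circle_poly(10, center = c(12, 12))))
    lm <- threshold_labelmap(img, contours, 1, f)
    pos <- seq_len(24) - 0.5
    for (s in 1:3) {
      est <- lm$estimates[[s]]
      cut <- est$muscle + f * (est$blood - est$muscle)
      ref <- matrix(0L, 24, 24)
      for (i in 1:24) for (j in 1:24) {
        d <- sqrt((pos[i] - 12)^2 + (pos[j] - 12)^2)
        if (d < 10) {
          if (img[i, j, s] > cut) ref[i, j] <- 1L
          else ref[i, j] <- if (d < 6) 3L else 2L
        }
      }
      expect_identical(lm$labels[[s]], ref)
    }
  }
})

test_that("labelmap partition conserves the in-mask voxel count", {
  sp <- quick_spec(trabecular_fraction = 0.15, n_papillary = 2,
                   noise_sigma = 20)
  ph <- generate_phantom(sp)
  for (phs in c("ED", "ES")) {
    lm <- threshold_labelmap(ph$stack$phases[[phs]], ph$contours[[phs]],
                             sp$in_plane_spacing)
    for (s in seq_len(sp$n_slices)) {
      masks <- cmrsport:::contour_masks(ph$contours[[phs]][[s]],
                                        dim(ph$stack$phases[[phs]])[1:2],
                                        sp$in_plane_spacing)
      expect_identical(sum(lm$labels[[s]] > 0L), sum(masks$epi))
    }
  }
})

test_that("TQ recovers phantom truth and TPM-free phantoms match CQ", {
  sp <- phantom_spec(n_slices = 6L, endo_radius_ed = 25, endo_radius_es = 18,
                     wall_base = 10, trabecular_fraction = 0.15,
                     n_papillary = 2, in_plane_spacing = 1,
                     supersampling_factor = 4)
  ph <- generate_phantom(sp)
  v <- tq_quantify(ph$stack, ph$contours)
  truth_lvm <- (ph$truth$compact_myo_volume + ph$truth$tpm_volume) * 1.05
  expect_equal(v$LVM, truth_lvm, tolerance = 0.02)
  expect_equal(v$LVEDV, ph$truth$cavity_volume_ed, tolerance = 0.02)
  expect_equal(v$TPM, ph$truth$tpm_volume * 1.05, tolerance = 0.05)

  bare <- generate_phantom(quick_spec(in_plane_spacing = 1,
                                      supersampling_factor = 4))
  vb <- tq_quantify(bare$stack, bare$contours)
  cb <- cq_quantify(bare$stack, bare$contours)
  expect_equal(vb$TPM, 0)
  expect_equal(vb$LVM, cb$LVM, tolerance = 0.02)
})

test_that("method ordering holds on TPM-containing phantoms", {
  ph <- generate_phantom(quick_spec(trabecular_fraction = 0.2,
                                    n_papillary = 2, noise_sigma = 15))
  tq <- tq_quantify(ph$stack, ph$contours)
  cq <- cq_quantify(ph$stack, ph$contours)
  expect_lt(tq$LVEDV, cq$LVEDV)
  expect_gt(tq$LVM, cq$LVM)
  expect_gt(tq$LVEF, cq$LVEF)
})
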