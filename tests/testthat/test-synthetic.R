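test_that("generate_parcellation produces the requested label structure", {
  cfg <- synthetic_config(seed = 1)
  p <- generate_parcellation(cfg)
  expect_equal(nrow(p$labels), 41)  # 2 x 20 + 1 midline
  for (sd in c("left", "right"))
    expect_equal(sum(p$labels$side == sd &
                       connremod:::label_has_group(p$labels, "insular")), 6)
  # every label has a contiguous nonempty patch with >= 8 voxels
  counts <- table(p$volume[p$volume != 0])
  expect_setequal(as.integer(names(counts)), p$labels$id)
  expect_true(all(counts >= 8))
  # full-scale analogue: 124 per side + brainstem = 249 labels
  big <- generate_parcellation(synthetic_config(regions_per_hemisphere = 124,
                                                volume_shape = c(40, 40, 40)))
  expect_equal(nrow(big$labels), 249)
  # sizing error when the grid cannot host the labels
  expect_error(generate_parcellation(
    synthetic_config(regions_per_hemisphere = 124, volume_shape = c(8, 8, 8))),
    "too small")
})

test_that("homotopic naming pairs left and right labels", {
  p <- generate_parcellation(synthetic_config())
  perm <- connremod:::canonical_side_perm(p$labels)
  expect_equal(perm[perm], seq_along(perm))  # involution
  expect_equal(p$labels$side[perm[p$labels$side == "left"]],
               rep("right", 20))
  expect_equal(perm[p$labels$side == "midline"],
               which(p$labels$side == "midline"))
})

test_that("generate_cohort is deterministic and respects its contracts", {
  cfg <- synthetic_config(n_subjects = 4, seed = 11)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1, g2)  # bit-identical under the same seed
  ch <- g1$cohort
  expect_equal(length(ch$subjects), 4)
  for (s in ch$subjects) {
    for (tp in c("t0", "t1", "t2")) {
      m <- s$matrices[[tp]]
      expect_equal(m, t(m))
      expect_true(all(m >= 0))
      expect_true(all(diag(m) == 0))
    }
    # support consistency: structural zeros never gain weight
    z <- s$matrices$t0 == 0
    expect_true(all(s$matrices$t1[z] == 0))
    expect_true(all(s$matrices$t2[z] == 0))
  }
  # focus sides: round(frac_left * n) left-sided
  expect_equal(sum(vapply(ch$subjects, `[[`, "", "focus_side") == "left"),
               round(0.4 * 4))
})

test_that("null configuration yields identical timepoints and empty truth", {
  cfg <- synthetic_config(n_subjects = 3, noise_log_sd = 0,
                          effect_decrease_ipsi = 1,
                          effect_increase_contra = 1,
                          effect_increase_periresection = 1, seed = 2)
  gen <- generate_cohort(cfg)
  expect_equal(nrow(gen$ground_truth), 0)  # factor 1.0 is not an effect
  for (s in gen$cohort$subjects) {
    expect_equal(s$matrices$t0, s$matrices$t1)
    expect_equal(s$matrices$t1, s$matrices$t2)
  }
})

test_that("ground truth is closed under the generated support", {
  gen <- generate_cohort(synthetic_config(n_subjects = 3, seed = 5))
  gt <- gen$ground_truth
  expect_true(all(gt$interval %in% c("early", "late")))
  expect_true(all(gt$label_i < gt$label_j))
  canon <- canonical_matrices(gen$cohort)
  for (k in seq_len(nrow(gt)))  # planted edges exist at t0 in every subject
    for (m in canon)
      expect_gt(m$t0[gt$label_i[k], gt$label_j[k]], 0)
  # planted factors match direction
  expect_true(all(gt$factor[gt$direction == "decrease"] < 1))
  expect_true(all(gt$factor[gt$direction == "increase"] > 1))
})

test_that("frac_structural_zeros = 0 gives full off-diagonal support", {
  gen <- generate_cohort(synthetic_config(n_subjects = 2,
                                          frac_structural_zeros = 0,
                                          seed = 3))
  m0 <- gen$cohort$subjects[[1]]$matrices$t0
  expect_true(all(m0[upper.tri(m0)] > 0))
})

test_that("resection masks are tailored, overlapping and focus-sided", {
  cfg <- synthetic_config(seed = 4)
  p <- generate_parcellation(cfg)
  d <- cfg$volume_shape
  halfx <- floor(d[1] / 2)
  mR <- generate_resection_masks(cfg, p, 1, "right")
  expect_true(all(mR$t1 %in% 0:1) && all(mR$t2 %in% 0:1))
  expect_false(identical(mR$t1, mR$t2))
  expect_gt(sum(mR$t1 * mR$t2), 0)  # overlap
  # union absorbs both masks
  u <- merge_masks(mR$t1, mR$t2)
  expect_true(all(u >= mR$t1) && all(u >= mR$t2))
  # right-focus masks live on the right x-half
  expect_true(all(which(mR$t1 == 1, arr.ind = TRUE)[, 1] > d[1] - halfx))
  mL <- generate_resection_masks(cfg, p, 2, "left")
  expect_true(all(which(mL$t1 == 1, arr.ind = TRUE)[, 1] <= halfx))
  # masks differ between subjects
  mR2 <- generate_resection_masks(cfg, p, 3, "right")
  expect_false(identical(mR$t1, mR2$t1) && identical(mR$t2, mR2$t2))
})

test_that("generate_streamlines reproduces its source matrix through build", {
  cfg <- synthetic_config(seed = 6)
  p <- generate_parcellation(cfg)
  gen <- generate_cohort(cfg)
  target <- gen$cohort$subjects[[1]]$matrices$t0
  str <- generate_streamlines(cfg, p, matrix = target)
  rebuilt <- build_matrix(str, p$labels)
  expect_equal(rebuilt, target, tolerance = 1e-12)
  # endpoints carry their declared labels
  d <- dim(p$volume)
  la <- p$volume[cbind(str$ax, str$ay, str$az)]
  lb <- p$volume[cbind(str$bx, str$by, str$bz)]
  expect_equal(la, str$label_a)
  expect_equal(lb, str$label_b)
  expect_true(all(str$length > 0) && all(str$contribution >= 0))
  # empty matrix -> empty set -> zero matrix downstream
  empty <- generate_streamlines(cfg, p, matrix = target * 0)
  expect_equal(nrow(empty), 0)
  expect_true(all(build_matrix(empty, p$labels) == 0))
})

test_that("synthetic_config validates its invariants", {
  expect_error(synthetic_config(frac_structural_zeros = 1.2), "proportions")
  expect_error(synthetic_config(effect_decrease_ipsi = 0), "factors")
  expect_error(synthetic_config(n_insular_subregions = 30), "insular")
})
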