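test_that("threshold extremes and monotonicity behave as a mask should", {
  img <- fixture_single_mito()$image
  full <- segment_cristae(img, segmentation_config(threshold = 0))
  expect_equal(full$mask, full$prob > 0)
  empty <- segment_cristae(img, segmentation_config(threshold = 1))
  expect_false(any(empty$mask))

  thr <- c(0.1, 0.3, 0.5, 0.8)
  sizes <- vapply(thr, function(t) {
    sum(segment_cristae(img, segmentation_config(threshold = t))$mask)
  }, 1)
  expect_true(all(diff(sizes) <= 0))

  zero <- mito_image(matrix(0, 64, 64), 20)
  expect_false(any(segment_cristae(zero)$mask))
})

test_that("segmentation is deterministic and reproduces structure (Dice)", {
  fx <- fixture_single_mito()
  again <- segment_cristae(fx$image)
  expect_identical(again$mask, fx$seg$mask)

  truth <- resolution_truth_mask(render_density(fx$scene, "IM"))
  expect_gte(dice_coef(fx$seg$mask, truth), 0.8)
})

test_that("closing merges cristae into one mitochondrion per component", {
  # one tubule's cristae -> one label; distant tubules stay separate
  mk <- matrix(FALSE, 200, 120)
  for (cx in seq(20, 80, by = 4)) mk[cx, 40:70] <- TRUE     # comb A
  for (cx in seq(120, 180, by = 4)) mk[cx, 40:70] <- TRUE   # comb B, > 2r away
  lab <- segment_mitochondria(mk, segmentation_config(), 20)
  expect_equal(max(lab), 2L)
  # closing is extensive: every label covers at least its cristae pixels
  for (l in 1:2) {
    expect_gte(sum(lab == l), sum(mk & lab == l))
  }
  expect_true(all(sort(unique(as.vector(lab))) == 0:2))

  empty <- segment_mitochondria(matrix(FALSE, 30, 30))
  expect_equal(max(empty), 0L)
})

test_that("nucleoid detection finds isolated nucleoids with sub-pixel accuracy", {
  p <- scene_params(n_components = 4, field_um = c(10, 10),
                    tubule_length_um = c(4, 6), branch_prob_per_um = 0,
                    min_separation_um = 1.2)
  sc <- generate_network(p, seed = 6)
  sc <- sample_nucleoids(sc, nucleoid_placement(occupancy = 1, per_um = 0,
                                                radius_nm = 180), seed = 8)
  dna <- simulate_acquisition(render_density(sc, "mtDNA"),
                              acquisition_settings(I_dep = 0,
                                                   photon_budget = 300),
                              seed = 12)
  nuc <- detect_nucleoids(dna)
  m <- match_detections(cbind(sc$nucleoids$x, sc$nucleoids$y), nuc)
  expect_equal(nrow(nuc), nrow(sc$nucleoids))
  expect_equal(m$recall, 1)
  expect_lt(stats::median(m$errors), 0.02)  # < 1 pixel

  empty <- mito_image(matrix(0, 64, 64), 20, "mtDNA")
  expect_equal(nrow(detect_nucleoids(empty)), 0L)
})

test_that("nucleoids outside any mitochondrion get owner label 0", {
  fx <- fixture_single_mito()
  sc <- fx$scene
  sc$nucleoids <- data.frame(
    x = c(sc$tubules[[1]]$path[30, 1], 4.5),
    y = c(sc$tubules[[1]]$path[30, 2], 0.4),
    kind = "density", landmark_kind = NA, r_um = 0.18)
  dna <- simulate_acquisition(render_density(sc, "mtDNA"),
                              acquisition_settings(I_dep = 0,
                                                   photon_budget = 300),
                              seed = 2)
  nuc <- detect_nucleoids(dna, mito_labels = fx$labels)
  expect_equal(nrow(nuc), 2L)
  expect_setequal(nuc$mito_label, c(0L, 1L))
})

test_that("the pixel classifier matches the ridge mode's contract", {
  skip_if_not_installed("ranger")
  fx <- fixture_single_mito()
  truth <- resolution_truth_mask(render_density(fx$scene, "IM"))
  cfg <- segmentation_config(method = "pixel-classifier", threshold = 0.5)
  expect_error(segment_cristae(fx$image, cfg), "labels or a model")
  model <- train_cristae_classifier(fx$image, truth, cfg, seed = 3)
  seg <- segment_cristae(fx$image, cfg, model = model)
  expect_true(all(seg$prob >= 0 & seg$prob <= 1))
  expect_gte(dice_coef(seg$mask, truth), 0.8)
  # deterministic for a fixed trained model
  seg2 <- segment_cristae(fx$image, cfg, model = model)
  expect_identical(seg$mask, seg2$mask)
})
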