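test_that("skeletons of canonical shapes have the right landmarks and length", {
  # straight bar: 100 px at 20 nm -> 2.0 um, 2 tips, no branch points
  bar <- matrix(0L, 160, 60)
  bar[31:130, 29:31] <- 1L
  sk <- skeletonize_component(bar, 1, 20)
  expect_equal(sk$length_um, 2.0, tolerance = 0.05)
  expect_equal(nrow(sk$tips), 2L)
  expect_equal(nrow(sk$branch_points), 0L)

  # Y shape: 3 tips, 1 branch point
  y <- matrix(0L, 120, 120)
  y[20:60, 59:61] <- 1L
  y[60:100, 59:61] <- 1L
  for (k in 0:40) y[60 + k, 61 + round(k * 0.8) + (-1:1)] <- 1L
  sky <- skeletonize_component(y, 1, 20)
  expect_equal(nrow(sky$tips), 3L)
  expect_equal(nrow(sky$branch_points), 1L)

  # ring: closed loop, no tips, no branch points
  th <- seq(0, 2 * pi, length.out = 400)
  ring <- matrix(0L, 100, 100)
  for (r in seq(28, 32, by = 0.5)) {
    ring[cbind(round(50 + r * cos(th)), round(50 + r * sin(th)))] <- 1L
  }
  skr <- skeletonize_component(ring, 1, 20)
  expect_equal(nrow(skr$tips), 0L)
  expect_equal(nrow(skr$branch_points), 0L)
  expect_gt(skr$length_um, 2 * pi * 30 * 0.02 * 0.8)

  expect_error(skeletonize_component(bar, 7), "not present")
})

test_that("the three-class rule is total, exclusive and matches its wording", {
  expect_identical(classify_mitochondrion(6.0, 10), "III")  # length branch
  expect_identical(classify_mitochondrion(1.0, 3), "I")
  expect_identical(classify_mitochondrion(3.0, 4), "II")
  expect_identical(classify_mitochondrion(1.0, 13), "III")  # count branch

  # boundary grid: ties at 2.5/6 fall to II, III strictly > 5 / > 12
  lens <- c(0, 1, 2.4999, 2.5, 3, 5, 5.0001, 8)
  cnts <- c(0L, 5L, 6L, 9L, 12L, 13L, 25L)
  for (L in lens) for (C in cnts) {
    cls <- classify_mitochondrion(L, C)
    expect_true(cls %in% c("I", "II", "III"))
    if (L > 5 || C > 12) {
      expect_identical(cls, "III")
    } else if (L >= 2.5 || C >= 6) {
      expect_identical(cls, "II")
    } else {
      expect_identical(cls, "I")
    }
  }
  expect_error(classify_mitochondrion(-1, 3), "non-negative")
  expect_error(classification_rule(L_low = 5, L_high = 2), "L_low")
})

test_that("cristae counting partitions components between mitochondria", {
  fx <- fixture_single_mito()
  n <- count_cristae(1, fx$seg$mask, fx$labels)
  expect_equal(n, fx$scene$components$n_cristae[1])

  expect_equal(count_cristae(1, matrix(FALSE, 50, 50),
                             matrix(1L, 50, 50)), 0L)

  # two mitochondria sharing no cristae: counts sum to the total
  pop <- data.frame(length_um = c(3, 4), n_cristae = c(6, 9),
                    class = c("II", "II"))
  sc <- scene_from_population(pop, diameter_nm = c(450, 500), seed = 2)
  img <- simulate_acquisition(render_density(sc, "IM"),
                              acquisition_settings(photon_budget = 300),
                              seed = 5)
  seg <- segment_cristae(img)
  lab <- segment_mitochondria(seg$mask)
  expect_equal(max(lab), 2L)
  total <- sum(vapply(1:2, function(l) {
    count_cristae(l, seg$mask, lab)
  }, 1L))
  expect_lte(abs(total - 15L), 1L)
})

test_that("rendered tubules recover their true length within 5%", {
  pop <- data.frame(length_um = c(2.2, 4, 7), n_cristae = c(4, 10, 20),
                    class = c("I", "II", "III"))
  sc <- scene_from_population(pop, seed = 1)
  img <- simulate_acquisition(render_density(sc, "IM"),
                              acquisition_settings(photon_budget = 300),
                              seed = 2)
  seg <- segment_cristae(img)
  lab <- segment_mitochondria(seg$mask)
  mm <- measure_mitochondria(lab, seg$mask)
  meas <- sort(mm$records$length_um)
  expect_equal(meas, sort(pop$length_um), tolerance = 0.05)
  expect_identical(sort(mm$records$class), sort(pop$class))
})

test_that("population summaries are proportion-correct and order-invariant", {
  rec <- data.frame(length_um = c(1, 1.2, 0.9), n_cristae = c(2, 3, 4),
                    class = "I")
  s <- summarize_population(rec)
  expect_equal(unname(s$proportions), c(1, 0, 0))

  rec2 <- data.frame(length_um = runif(30, 0.5, 8),
                     n_cristae = sample(0:20, 30, TRUE))
  rec2$class <- vapply(seq_len(30), function(i) {
    classify_mitochondrion(rec2$length_um[i], rec2$n_cristae[i])
  }, "")
  p1 <- summarize_population(rec2)$proportions
  p2 <- summarize_population(rec2[sample(30), ])$proportions
  expect_identical(p1, p2)
  expect_equal(sum(p1), 1)
  expect_error(summarize_population(rec2[0, ]), "summarize")
})
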