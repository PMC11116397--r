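test_that("nearest distances are Euclidean minima, isometry-invariant", {
  lm <- data.frame(x_um = 0, y_um = 0)
  nc <- data.frame(x_um = c(3, 6), y_um = c(4, 8))
  expect_equal(nearest_distances(lm, nc), 5)

  lm2 <- data.frame(x_um = c(1, 2), y_um = c(1, 1))
  nc2 <- data.frame(x_um = 1, y_um = 1)
  expect_equal(nearest_distances(lm2, nc2), c(0, 1))

  shift <- function(d, dx, dy) data.frame(x_um = d$x_um + dx,
                                          y_um = d$y_um + dy)
  expect_equal(nearest_distances(shift(lm2, 5, -3), shift(nc2, 5, -3)),
               nearest_distances(lm2, nc2))
  expect_error(nearest_distances(lm, nc[0, ]), "no reference")
})

test_that("fraction below cutoff is strict and monotone in the cutoff", {
  d <- c(0, 0.1, 0.6, 0.9)
  expect_equal(fraction_below(rep(0, 5), 0.6), 1)
  expect_equal(fraction_below(d, 0.6), 0.5)     # strict: 0.6 not counted
  expect_equal(fraction_below(d, 0.05), 0.25)
  cuts <- seq(0.05, 1.2, by = 0.05)
  f <- vapply(cuts, function(ct) fraction_below(d, ct), 1)
  expect_true(all(diff(f) >= 0))
  expect_error(fraction_below(numeric(0)), "no distances")
})

test_that("exponential MLE recovers the rate and scales correctly", {
  d <- rep(0.5, 20)
  expect_equal(fit_exponential(d)$lambda, 2)

  withr::with_seed(3, x <- rexp(1e4, 2))
  f <- fit_exponential(x, seed = 1)
  expect_equal(f$lambda, 2, tolerance = 0.025)
  expect_true(f$ci[1] < 2 && 2 < f$ci[2])
  expect_gt(f$ks_p, 0.01)
  # scale equivariance
  f3 <- fit_exponential(3 * x, seed = 1)
  expect_equal(f3$lambda, f$lambda / 3, tolerance = 1e-12)
  # bootstrap is seeded
  expect_identical(fit_exponential(x, seed = 7)$ci,
                   fit_exponential(x, seed = 7)$ci)
  expect_error(fit_exponential(rep(0, 20)), "zero")
  expect_error(fit_exponential(c(1, 2)), "n >= 10")
})

test_that("rate recovery is unbiased within 2% across replicates", {
  lam_hat <- vapply(1:100, function(s) {
    withr::with_seed(1000 + s, 1 / mean(rexp(1e4, 2)))
  }, 1)
  expect_lt(abs(mean(lam_hat) - 2) / 2, 0.02)
})

test_that("area ratios are per-mitochondrion, linear, and skip bad records", {
  rec <- data.frame(label = 1:3,
                    mito_area_um2 = c(2, 4, 3),
                    cristae_area_um2 = c(1, 2, 1.5),
                    nucleoid_area_um2 = c(0.5, 0, 0.6))
  ar <- area_ratios(rec)
  expect_equal(ar$ratios$ratio_mito, c(0.25, 0, 0.2))
  dbl <- rec
  dbl$nucleoid_area_um2 <- 2 * dbl$nucleoid_area_um2
  expect_equal(area_ratios(dbl)$ratios$ratio_mito, 2 * ar$ratios$ratio_mito)

  bad <- rbind(rec, data.frame(label = 4, mito_area_um2 = 0,
                               cristae_area_um2 = 0, nucleoid_area_um2 = 1))
  expect_warning(ar2 <- area_ratios(bad), "skipped")
  expect_equal(ar2$n_skipped, 1L)
  expect_equal(nrow(ar2$ratios), 3L)

  # invariant under relabeling
  perm <- rec[c(3, 1, 2), ]
  expect_equal(sort(area_ratios(perm)$ratios$ratio_mito),
               sort(ar$ratios$ratio_mito))
})

test_that("group comparison uses Mann-Whitney with documented edge cases", {
  u <- compare_groups(c(1, 2), c(3, 4))
  expect_equal(unname(u$statistic), 0)

  same <- compare_groups(rep(1, 5), rep(1, 7))
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)

  withr::with_seed(2, a <- runif(50))
  sep <- compare_groups(a, a + 10)
  expect_lt(sep$p_value, 1e-10)

  ks <- compare_groups(a, a + 10, stats_config(test = "ks"))
  expect_identical(ks$test, "ks")
  expect_lt(ks$p_value, 1e-10)
  expect_error(compare_groups(numeric(0), 1), "non-empty")
})

test_that("the report bundles distances, fits, ratios and proportions", {
  withr::with_seed(9, {
    lmk <- data.frame(kind = rep(c("tip", "branch"), c(30, 12)),
                      x_um = runif(42, 0, 10), y_um = runif(42, 0, 10))
    nuc <- data.frame(x_um = runif(60, 0, 10), y_um = runif(60, 0, 10))
  })
  rec <- data.frame(label = 1:4, length_um = c(1, 3, 6, 2),
                    n_cristae = c(2, 7, 15, 3),
                    class = c("I", "II", "III", "I"),
                    mito_area_um2 = c(1, 2, 4, 1),
                    cristae_area_um2 = c(0.4, 1, 2, 0.5),
                    nucleoid_area_um2 = c(0.2, 0.5, 1, 0))
  rep <- spatial_stats_report(lmk, nuc, rec)
  expect_setequal(names(rep$landmark_stats), c("tip", "branch"))
  for (s in rep$landmark_stats) {
    expect_true(s$fraction_below >= 0 && s$fraction_below <= 1)
  }
  expect_gt(rep$landmark_stats$tip$lambda, 0)
  expect_equal(sum(rep$class_proportions), 1)
})
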