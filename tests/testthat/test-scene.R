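test_that("network generation is deterministic and honours its parameters", {
  p <- scene_params(n_components = 3, field_um = c(8, 8))
  a <- generate_network(p, seed = 11)
  b <- generate_network(p, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, generate_network(p, seed = 12)))

  nb <- generate_network(scene_params(n_components = 3, field_um = c(8, 8),
                                      branch_prob_per_um = 0), seed = 5)
  expect_equal(nrow(nb$branch_points), 0)
  expect_equal(length(nb$tubules), 3L)
})

test_that("cristae are placed at the configured spacing", {
  p <- scene_params(n_components = 1, field_um = c(10, 10),
                    tubule_length_um = c(3.5, 3.5), branch_prob_per_um = 0)
  sc <- generate_network(p, seed = 7)
  # centreline of 3.5 um at 70 nm spacing
  expect_equal(nrow(sc$cristae), floor(3500 / 70))
  # rendered crista count equals the scene's true count
  expect_equal(sc$components$n_cristae, nrow(sc$cristae))
  # every crista segment lies within its tubule envelope
  for (k in seq_len(nrow(sc$cristae))) {
    tb <- sc$tubules[[sc$cristae$tubule[k]]]
    rp <- mitosted:::resample_path(tb$path, 0.02)
    d0 <- min(sqrt((rp[, "x"] - sc$cristae$x0[k])^2 +
                     (rp[, "y"] - sc$cristae$y0[k])^2))
    d1 <- min(sqrt((rp[, "x"] - sc$cristae$x1[k])^2 +
                     (rp[, "y"] - sc$cristae$y1[k])^2))
    expect_lt(max(d0, d1), tb$radius_um + 1e-6)
  }
})

test_that("scene parameter validation rejects impossible geometry", {
  expect_error(scene_params(field_um = c(0.3, 0.3)), "too small")
  expect_error(scene_params(cristae_spacing_nm = 15,
                            cristae_thickness_nm = 20), "spacing")
  expect_error(nucleoid_placement(occupancy = 1.4), "occupancy")
  expect_error(nucleoid_placement(lambda_per_um = -1), "lambda")
})

test_that("full landmark occupancy puts a nucleoid on every tip", {
  sc <- generate_network(scene_params(n_components = 2, field_um = c(8, 8)),
                         seed = 3)
  sc <- sample_nucleoids(sc, nucleoid_placement(occupancy = 1, per_um = 0),
                         seed = 9)
  d <- nearest_distances(data.frame(x_um = sc$tips$x, y_um = sc$tips$y),
                         data.frame(x_um = sc$nucleoids$x,
                                    y_um = sc$nucleoids$y))
  expect_true(all(d < 1e-9))
  # occupancy model at the default rate
  expect_true(all(sc$nucleoids$kind == "landmark"))
})

test_that("landmark nearest distances follow the exponential law", {
  lam <- -log(0.35) / 0.6
  pl <- nucleoid_placement(occupancy = 0, lambda_per_um = lam, per_um = 0)
  p <- scene_params(n_components = 40, field_um = c(40, 40),
                    branch_prob_per_um = 0, tubule_length_um = c(6, 9),
                    min_separation_um = 1.5, cristae_spacing_nm = 400)
  dall <- c()
  for (s in 1:4) {
    sc <- generate_network(p, seed = s)
    sc <- sample_nucleoids(sc, pl, seed = 100 + s)
    lmk <- sc$tips
    dall <- c(dall, nearest_distances(
      data.frame(x_um = lmk$x, y_um = lmk$y),
      data.frame(x_um = sc$nucleoids$x, y_um = sc$nucleoids$y)))
  }
  # closed form: 1 - exp(-lambda * 0.6) = 0.65
  expect_equal(fraction_below(dall, 0.6), 0.65, tolerance = 0.06)
  ks <- suppressWarnings(ks.test(dall, "pexp", rate = lam))
  expect_gt(ks$p.value, 0.01)
})

test_that("density rendering is linear, mass-correct and warns on aliasing", {
  sc <- generate_network(scene_params(n_components = 1, field_um = c(6, 6)),
                         seed = 2)
  empty <- sc
  empty$tubules <- list()
  empty$cristae <- empty$cristae[0, ]
  empty$tips <- empty$tips[0, ]
  expect_true(all(render_density(empty, "IM") == 0))

  # a single nucleoid's mass is proportional to pi r^2
  nuc_scene <- empty
  nuc_scene$nucleoids <- data.frame(x = 3, y = 3, kind = "density",
                                    landmark_kind = NA, r_um = 0.3)
  m1 <- render_density(nuc_scene, "mtDNA")
  px_area <- (20 / 1000)^2
  expect_equal(sum(m1 > 0) * px_area, pi * 0.3^2, tolerance = 0.05)

  nuc_scene$params$amplitude <- 2
  m2 <- render_density(nuc_scene, "mtDNA")
  expect_equal(unclass(m2), 2 * unclass(m1), ignore_attr = TRUE)

  expect_warning(render_density(sc, "IM", pixel_size_nm = 100), "aliased")
})

test_that("morphology population sampler respects the requested mixture", {
  all_one <- sample_morphology_population(c(1, 0, 0), 200, seed = 5)
  expect_true(all(all_one$class == "I"))
  expect_true(all(all_one$length_um < 2.5 & all_one$n_cristae < 6))

  mix <- c(0.157, 0.169, 0.674)
  pop <- sample_morphology_population(mix, 4000, seed = 8)
  props <- as.numeric(table(factor(pop$class, c("I", "II", "III")))) / 4000
  expect_true(all(abs(props - mix) < 3 * sqrt(mix * (1 - mix) / 4000) + 0.01))
  # labels always consistent with the rule
  relab <- vapply(seq_len(nrow(pop)), function(i) {
    classify_mitochondrion(pop$length_um[i], pop$n_cristae[i])
  }, "")
  expect_identical(relab, pop$class)

  expect_error(sample_morphology_population(c(0, 0, 0), 10), "fractions")
  expect_error(sample_morphology_population(c(0.5, 0.2, 0.2), 10), "sum to 1")
})

test_that("scene truth serializes to JSON", {
  sc <- fixture_network()$scene
  f <- withr::local_tempfile(fileext = ".json")
  write_scene_json(sc, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(nrow(back$components), nrow(sc$components))
  expect_equal(back$components$length_um, sc$components$length_um,
               tolerance = 1e-9)
})
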