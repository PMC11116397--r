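# shared fixtures, built once per test run and memoized

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# a small default network scene plus its rendered/acquired IM channel
fixture_network <- function() {
  memo("network", function() {
    p <- scene_params(n_components = 3, field_um = c(8, 8))
    sc <- generate_network(p, seed = 2)
    dens <- render_density(sc, "IM")
    img <- simulate_acquisition(dens, acquisition_settings(photon_budget = 300),
                                seed = 4)
    list(params = p, scene = sc, density = dens, image = img)
  })
}

# one straight mitochondrion with known cristae, segmented
fixture_single_mito <- function() {
  memo("single", function() {
    pop <- data.frame(length_um = 4, n_cristae = 10, class = "II")
    sc <- scene_from_population(pop, diameter_nm = c(450, 450), seed = 3)
    img <- simulate_acquisition(render_density(sc, "IM"),
                                acquisition_settings(photon_budget = 300),
                                seed = 3)
    seg <- segment_cristae(img)
    labels <- segment_mitochondria(seg$mask)
    list(scene = sc, image = img, seg = seg, labels = labels)
  })
}

# truth mask for segmentation quality: geometric support dilated to the
# resolution footprint (half the effective PSF FWHM on each side)
resolution_truth_mask <- function(density, fwhm_nm = 40) {
  supp <- mitosted:::img_matrix(density) > 0
  r_px <- max(1L, round(fwhm_nm / 2 / pixel_size_nm(density)))
  m <- EBImage::dilate(matrix(as.numeric(supp), nrow(supp), ncol(supp)),
                       EBImage::makeBrush(2L * r_px + 1L, "disc"))
  m > 0
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# greedy matching of detections to truth within a tolerance radius
match_detections <- function(truth_xy, det, tol_um = 0.3) {
  used <- rep(FALSE, nrow(det))
  tp <- 0L
  errs <- c()
  for (i in seq_len(nrow(truth_xy))) {
    d <- sqrt((det$x_um - truth_xy[i, 1])^2 + (det$y_um - truth_xy[i, 2])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] < tol_um) {
      tp <- tp + 1L
      used[j] <- TRUE
      errs <- c(errs, d[j])
    }
  }
  list(tp = tp, precision = tp / max(nrow(det), 1L),
       recall = tp / max(nrow(truth_xy), 1L), errors = errs)
}
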