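#' Segmentation configuration
#'
#' @param method `"ridge-threshold"` (deterministic Hessian ridge filter,
#'   default) or `"pixel-classifier"` (random-forest on a filter bank,
#'   needs training labels or a trained model).
#' @param threshold probability threshold in \[0, 1\]; pixels with response
#'   strictly above it enter the mask.
#' @param scales_nm filter-bank scales (Gaussian sigma, nm).
#' @param closing_radius_nm disk radius for the morphological closing that
#'   merges cristae into whole mitochondria; default 70 nm, the cristae
#'   spacing.
#' @param nucleoid_sigma_nm Gaussian smoothing sigma for the mtDNA channel.
#' @param nucleoid_min_area_um2 minimum accepted nucleoid area.
#' @param nucleoid_threshold `"halfmax"` (per-blob half-maximum refinement
#'   of an Otsu prefilter; approximately deconvolves the confocal blur for
#'   area measurement) or `"otsu"`.
#' @param background_window_um rolling-median background window (mtDNA
#'   channel), larger than any nucleoid.
#' @param max_crista_len_um upper bound on a single crista's extent; longer
#'   thin components are treated as boundary membrane when counting.
#' @param min_mito_area_um2 labelled components smaller than this are
#'   dropped as segmentation specks.
#' @param watershed split merged nucleoid blobs by local-maxima watershed.
#' @return a `segmentation_config` list.
#' @export
segmentation_config <- function(method = c("ridge-threshold",
                                           "pixel-classifier"),
                                threshold = 0.3,
                                scales_nm = c(30, 50),
                                closing_radius_nm = 70,
                                nucleoid_sigma_nm = 60,
                                nucleoid_min_area_um2 = 0.01,
                                nucleoid_threshold = c("halfmax", "otsu"),
                                background_window_um = 2,
                                max_crista_len_um = 1.2,
                                min_mito_area_um2 = 0.05,
                                watershed = FALSE) {
  method <- match.arg(method)
  nucleoid_threshold <- match.arg(nucleoid_threshold)
  if (threshold < 0 || threshold > 1) {
    stop("threshold must be in [0, 1]", call. = FALSE)
  }
  if (any(scales_nm <= 0)) stop("scales must be positive", call. = FALSE)
  structure(list(method = method, threshold = threshold,
                 scales_nm = scales_nm,
                 closing_radius_nm = closing_radius_nm,
                 nucleoid_sigma_nm = nucleoid_sigma_nm,
                 nucleoid_min_area_um2 = nucleoid_min_area_um2,
                 nucleoid_threshold = nucleoid_threshold,
                 background_window_um = background_window_um,
                 max_crista_len_um = max_crista_len_um,
                 min_mito_area_um2 = min_mito_area_um2,
                 watershed = watershed),
            class = "segmentation_config")
}

gaussian_deriv_kernels <- function(sigma_px) {
  w <- max(2L, ceiling(3 * sigma_px))
  x <- -w:w
  g <- exp(-x^2 / (2 * sigma_px^2))
  g <- g / sum(g)
  g1 <- -x / sigma_px^2 * g     # d/dx of the Gaussian
  g2 <- (x^2 / sigma_px^2 - 1) / sigma_px^2 * g
  list(g = g, g1 = g1, g2 = g2)
}

sep_filter <- function(m, kx, ky) {
  EBImage::filter2(m, outer(kx, ky), boundary = "circular")
}

hessian_features <- function(m, sigma_px) {
  k <- gaussian_deriv_kernels(sigma_px)
  gxx <- sep_filter(m, k$g2, k$g)
  gyy <- sep_filter(m, k$g, k$g2)
  gxy <- sep_filter(m, k$g1, k$g1)
  tr <- gxx + gyy
  disc <- sqrt(pmax((gxx - gyy)^2 + 4 * gxy^2, 0))
  list(smooth = sep_filter(m, k$g, k$g),
       gradmag = sqrt(sep_filter(m, k$g1, k$g)^2 +
                        sep_filter(m, k$g, k$g1)^2),
       lam_lo = (tr - disc) / 2,   # most negative on bright ridges
       lam_hi = (tr + disc) / 2)
}

#' Ridge-filter response map for curvilinear (cristae-like) structures
#'
#' Scale-normalized negative Hessian eigenvalue response, maximized over
#' scales and normalized to \[0, 1\].
#'
#' @param img a `mito_image`.
#' @param scales_nm Gaussian scales (nm).
#' @return matrix in \[0, 1\].
#' @export
ridge_response <- function(img, scales_nm = c(30, 50)) {
  m <- img_matrix(img)
  px <- pixel_size_nm(img)
  resp <- matrix(0, nrow(m), ncol(m))
  for (s in scales_nm) {
    sigma_px <- max(s / px, 0.5)
    f <- hessian_features(m, sigma_px)
    r <- pmax(-f$lam_lo, 0) * sigma_px^2
    resp <- pmax(resp, r)
  }
  mx <- max(resp)
  if (mx > 0) resp / mx else resp
}

#' Train a pixel classifier for cristae segmentation
#'
#' Random forest on a filter bank (Gaussian smooth, gradient magnitude and
#' both Hessian eigenvalues at each configured scale), trained on a labelled
#' image. Fills the same contract as an interactively trained
#' pixel-classification tool: probability image in, threshold out.
#'
#' @param img a `mito_image`.
#' @param labels integer/logical matrix, same size: 1 = cristae, 0 =
#'   background.
#' @param cfg a [segmentation_config()].
#' @param n_per_class training pixels sampled per class.
#' @param seed integer seed.
#' @return a `cristae_classifier` object.
#' @export
train_cristae_classifier <- function(img, labels, cfg = segmentation_config(),
                                     n_per_class = 3000, seed = 1L) {
  if (!requireNamespace("ranger", quietly = TRUE)) {
    stop("pixel-classifier mode needs the 'ranger' package", call. = FALSE)
  }
  feats <- classifier_features(img, cfg$scales_nm)
  y <- as.integer(as.vector(labels) > 0)
  withr::with_seed(seed, {
    idx1 <- which(y == 1); idx0 <- which(y == 0)
    idx <- c(sample(idx1, min(n_per_class, length(idx1))),
             sample(idx0, min(n_per_class, length(idx0))))
    df <- as.data.frame(feats[idx, , drop = FALSE])
    df$y <- factor(y[idx], levels = c(0, 1))
    rf <- ranger::ranger(y ~ ., data = df, probability = TRUE,
                         num.trees = 100, seed = seed)
  })
  structure(list(model = rf, scales_nm = cfg$scales_nm),
            class = "cristae_classifier")
}

classifier_features <- function(img, scales_nm) {
  m <- img_matrix(img)
  px <- pixel_size_nm(img)
  cols <- list()
  for (s in scales_nm) {
    f <- hessian_features(m, max(s / px, 0.5))
    cols[[paste0("sm", s)]] <- as.vector(f$smooth)
    cols[[paste0("gm", s)]] <- as.vector(f$gradmag)
    cols[[paste0("l1_", s)]] <- as.vector(f$lam_lo)
    cols[[paste0("l2_", s)]] <- as.vector(f$lam_hi)
  }
  do.call(cbind, cols)
}

#' Segment cristae in an inner-membrane image
#'
#' Produces a probability map and its thresholded binary mask. The
#' deterministic ridge-threshold mode needs no training; the
#' pixel-classifier mode requires either training `labels` or a fitted
#' `model`.
#'
#' @param img IM-channel `mito_image`.
#' @param cfg a [segmentation_config()].
#' @param labels optional training labels (matrix) for pixel-classifier
#'   mode.
#' @param model optional `cristae_classifier`.
#' @return list with `prob` (matrix in \[0,1\]) and `mask` (logical matrix);
#'   pixels strictly above the threshold are foreground.
#' @export
segment_cristae <- function(img, cfg = segmentation_config(), labels = NULL,
                            model = NULL) {
  stopifnot(inherits(img, "mito_image"))
  if (cfg$method == "ridge-threshold") {
    prob <- ridge_response(img, cfg$scales_nm)
  } else {
    if (is.null(model)) {
      if (is.null(labels)) {
        stop("pixel-classifier mode needs training labels or a model",
             call. = FALSE)
      }
      model <- train_cristae_classifier(img, labels, cfg)
    }
    feats <- as.data.frame(classifier_features(img, model$scales_nm))
    pred <- predict(model$model, data = feats)$predictions
    prob <- matrix(pred[, "1"], nrow(img), ncol(img))
  }
  list(prob = prob, mask = prob > cfg$threshold)
}

disc_brush <- function(radius_px) {
  size <- 2L * max(1L, round(radius_px)) + 1L
  EBImage::makeBrush(size, shape = "disc")
}

#' Merge a cristae mask into labelled whole mitochondria
#'
#' Morphological closing with a disk of the configured radius, hole
#' filling, and 8-connected component labelling.
#'
#' @param mask logical cristae mask.
#' @param cfg a [segmentation_config()].
#' @param pixel_size_nm pixel size (nm).
#' @return integer label matrix (0 background, labels contiguous from 1).
#' @export
segment_mitochondria <- function(mask, cfg = segmentation_config(),
                                 pixel_size_nm = 20) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (!any(m > 0)) return(matrix(0L, nrow(mask), ncol(mask)))
  r_px <- cfg$closing_radius_nm / pixel_size_nm
  closed <- EBImage::closing(m, disc_brush(r_px))
  filled <- EBImage::fillHull(closed)
  lab <- matrix(as.integer(EBImage::bwlabel(filled)), nrow(mask), ncol(mask))
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    min_px <- cfg$min_mito_area_um2 / (pixel_size_nm / 1000)^2
    keep <- which(sizes >= min_px)
    relab <- integer(max(lab))
    relab[keep] <- seq_along(keep)
    lab[lab > 0] <- relab[lab[lab > 0]]
  }
  lab
}

block_median_background <- function(m, block_px) {
  nx <- nrow(m); ny <- ncol(m)
  bx <- max(1L, ceiling(nx / block_px))
  by <- max(1L, ceiling(ny / block_px))
  gx <- pmin(((seq_len(nx) - 1L) %/% block_px) + 1L, bx)
  gy <- pmin(((seq_len(ny) - 1L) %/% block_px) + 1L, by)
  med <- tapply(as.vector(m), list(gx[row(m)], gy[col(m)]), median)
  med <- matrix(as.numeric(med), bx, by)
  # bilinear upsample of the coarse median grid
  cx <- (seq_len(bx) - 0.5) * block_px
  cy <- (seq_len(by) - 0.5) * block_px
  xi <- pmin(pmax(seq_len(nx), min(cx)), max(cx))
  yi <- pmin(pmax(seq_len(ny), min(cy)), max(cy))
  fx <- approx(cx, seq_len(bx), xout = xi, rule = 2, ties = "ordered")$y
  fy <- approx(cy, seq_len(by), xout = yi, rule = 2, ties = "ordered")$y
  bilinear_at(med, rep(fx, times = ny), rep(fy, each = nx)) |>
    matrix(nx, ny)
}

#' Detect mtDNA nucleoids in a confocal channel
#'
#' Gaussian smoothing, rolling-median background subtraction, Otsu
#' thresholding and connected-component analysis; blob areas are refined at
#' each blob's half-maximum by default. Components below the minimum area
#' are discarded.
#'
#' @param img mtDNA-channel `mito_image`.
#' @param cfg a [segmentation_config()].
#' @param mito_labels optional integer label matrix from
#'   [segment_mitochondria()]; the owning label is read at each centroid
#'   (0 when outside every mitochondrion).
#' @return data frame (id, x_um, y_um, area_um2, mito_label).
#' @export
detect_nucleoids <- function(img, cfg = segmentation_config(),
                             mito_labels = NULL) {
  stopifnot(inherits(img, "mito_image"))
  m <- img_matrix(img)
  px <- pixel_size_nm(img)
  empty <- data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0), mito_label = integer(0))
  if (max(m) <= 0) return(empty)
  if (mean(m == max(m)) >= 0.001) {
    warning("possible saturation: >= 0.1% of pixels at the maximum")
  }
  sm <- blur_gaussian(m, cfg$nucleoid_sigma_nm / px)
  bg <- block_median_background(sm, max(4L, round(cfg$background_window_um *
                                                    1000 / px / 2)))
  fg <- pmax(sm - bg, 0)
  if (max(fg) <= 0) return(empty)
  thr <- EBImage::otsu(fg / max(fg), range = c(0, 1)) * max(fg)
  mask <- fg > thr
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(m), ncol(m)))
  if (cfg$watershed) {
    dist <- EBImage::distmap(mask)
    lab <- EBImage::watershed(dist * (lab > 0), tolerance = 1)
  }
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  nlab <- max(lab)
  if (nlab == 0) return(empty)
  out <- vector("list", nlab)
  id <- 0L
  for (l in seq_len(nlab)) {
    sel <- which(lab == l)
    vmax <- max(fg[sel])
    sel_area <- if (cfg$nucleoid_threshold == "halfmax") {
      sel[fg[sel] > vmax / 2]
    } else sel
    area <- length(sel_area) * (px / 1000)^2
    if (area < cfg$nucleoid_min_area_um2) next
    wts <- fg[sel]
    ij <- arrayInd(sel, dim(m))
    cx <- sum(ij[, 1] * wts) / sum(wts)
    cy <- sum(ij[, 2] * wts) / sum(wts)
    owner <- 0L
    if (!is.null(mito_labels)) {
      owner <- mito_labels[round(cx), round(cy)]
    }
    id <- id + 1L
    out[[id]] <- data.frame(id = id, x_um = (cx - 0.5) * px / 1000,
                            y_um = (cy - 0.5) * px / 1000,
                            area_um2 = area, mito_label = as.integer(owner))
  }
  if (id == 0L) return(empty)
  do.call(rbind, out[seq_len(id)])
}
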