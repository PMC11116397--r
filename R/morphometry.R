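#' Three-class morphology rule thresholds
#'
#' Mitochondria shorter than `L_low` with fewer than `C_low` cristae are
#' Class I; those longer than `L_high` or with more than `C_high` cristae
#' are Class III; everything else (length in \[L_low, L_high\] or count in
#' \[C_low, C_high\], ties included) is Class II.
#'
#' @param L_low,L_high length thresholds (um), default 2.5 and 5.
#' @param C_low,C_high cristae-count thresholds, default 6 and 12.
#' @return a `classification_rule` list.
#' @export
classification_rule <- function(L_low = 2.5, L_high = 5, C_low = 6,
                                C_high = 12) {
  if (!(L_low < L_high) || !(C_low < C_high)) {
    stop("need L_low < L_high and C_low < C_high", call. = FALSE)
  }
  structure(list(L_low = L_low, L_high = L_high, C_low = C_low,
                 C_high = C_high), class = "classification_rule")
}

#' Classify a mitochondrion by length and cristae count
#'
#' Class III conditions (length > L_high OR count > C_high) are tested
#' first, then Class II (length >= L_low OR count >= C_low), else Class I.
#' The III-first precedence resolves the overlap of the "or" clauses: a
#' short organelle with many cristae is Class III. Total over
#' \[0, Inf) x \{0, 1, ...\}.
#'
#' @param length_um skeleton length (um), >= 0.
#' @param n_cristae cristae count, >= 0.
#' @param rule a [classification_rule()].
#' @return `"I"`, `"II"` or `"III"`.
#' @export
classify_mitochondrion <- function(length_um, n_cristae,
                                   rule = classification_rule()) {
  if (length_um < 0 || n_cristae < 0) {
    stop("length and cristae count must be non-negative", call. = FALSE)
  }
  if (length_um > rule$L_high || n_cristae > rule$C_high) return("III")
  if (length_um >= rule$L_low || n_cristae >= rule$C_low) return("II")
  "I"
}

# distance from a skeleton tip to the mask boundary along the outward
# skeleton direction; 0 when the direction cannot be established
tip_extension <- function(skl, mask, tip, depth = 5L) {
  # walk back along the skeleton up to `depth` steps to get a direction
  cur <- matrix(tip, 1)
  seen <- sprintf("%d_%d", tip[1], tip[2])
  back <- tip
  for (d in seq_len(depth)) {
    nxt <- NULL
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      i <- back[1] + di; j <- back[2] + dj
      if (i < 1 || j < 1 || i > nrow(skl) || j > ncol(skl)) next
      key <- sprintf("%d_%d", i, j)
      if (skl[i, j] && !(key %in% seen)) { nxt <- c(i, j); seen <- c(seen, key) }
    }
    if (is.null(nxt)) break
    back <- nxt
  }
  v <- tip - back
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) return(0)
  v <- v / nv
  s <- 0
  repeat {
    s <- s + 0.5
    i <- round(tip[1] + v[1] * s); j <- round(tip[2] + v[2] * s)
    if (i < 1 || j < 1 || i > nrow(mask) || j > ncol(mask) ||
        mask[i, j] == 0) {
      return(s - 0.5)
    }
    if (s > max(dim(mask))) return(0)
  }
}

cluster_points <- function(pts, radius) {
  # greedy merge of points within `radius` into single landmarks
  if (nrow(pts) == 0) return(pts)
  centres <- pts[1, , drop = FALSE]
  members <- list(1L)
  if (nrow(pts) > 1) {
    for (i in 2:nrow(pts)) {
      d <- sqrt((centres[, 1] - pts[i, 1])^2 + (centres[, 2] - pts[i, 2])^2)
      j <- which(d <= radius)[1]
      if (is.na(j)) {
        centres <- rbind(centres, pts[i, , drop = FALSE])
        members[[length(members) + 1L]] <- i
      } else {
        members[[j]] <- c(members[[j]], i)
        centres[j, ] <- colMeans(pts[members[[j]], , drop = FALSE])
      }
    }
  }
  centres
}

#' Skeletonize one labelled mitochondrion
#'
#' Topology-preserving (Guo-Hall) thinning of the component, landmark
#' extraction and geodesic length. Length counts 4-neighbour steps as 1 and
#' diagonal steps as sqrt(2) pixel sizes, skipping diagonals shortcut by an
#' existing 4-path; with `extend_tips` (default) each tip adds the distance
#' from the tip to the component boundary along the local skeleton
#' direction, so the length matches the full tubule length rather than
#' stopping where thinning retracts from the rounded ends.
#'
#' @param labels integer label matrix.
#' @param label which component.
#' @param pixel_size_nm pixel size (nm).
#' @param merge_radius_px branch-point pixels closer than this merge into
#'   one landmark.
#' @param extend_tips add the distance-map value at each tip to the length.
#' @return list with `length_um`, `tips` (data frame x_um, y_um),
#'   `branch_points` (data frame), and the `skeleton` logical matrix.
#' @export
skeletonize_component <- function(labels, label, pixel_size_nm = 20,
                                  merge_radius_px = 3, extend_tips = TRUE) {
  sel <- labels == label
  if (!any(sel)) stop("label ", label, " not present", call. = FALSE)
  px_um <- pixel_size_nm / 1000
  ij <- which(sel, arr.ind = TRUE)
  x0 <- max(1L, min(ij[, 1]) - 2L); x1 <- min(nrow(labels), max(ij[, 1]) + 2L)
  y0 <- max(1L, min(ij[, 2]) - 2L); y1 <- min(ncol(labels), max(ij[, 2]) + 2L)
  mask <- matrix(0L, x1 - x0 + 1L, y1 - y0 + 1L)
  mask[cbind(ij[, 1] - x0 + 1L, ij[, 2] - y0 + 1L)] <- 1L
  sk <- .thin_guo_hall(mask)
  nb <- .skel_neighbour_count(sk)
  skl <- sk == 1L
  tips_px <- which(skl & nb == 1L, arr.ind = TRUE)
  if (sum(skl) == 1L) tips_px <- which(skl, arr.ind = TRUE)
  branch_px <- which(skl & nb >= 3L, arr.ind = TRUE)
  # geodesic length from adjacency counts
  shift_and <- function(m, di, dj) {
    nr <- nrow(m); nc <- ncol(m)
    a <- m[max(1, 1 + di):min(nr, nr + di), max(1, 1 + dj):min(nc, nc + dj),
           drop = FALSE]
    b <- m[max(1, 1 - di):min(nr, nr - di), max(1, 1 - dj):min(nc, nc - dj),
           drop = FALSE]
    a & b
  }
  n_e <- sum(shift_and(skl, 1, 0))
  n_s <- sum(shift_and(skl, 0, 1))
  # diagonal pairs not shortcut through a shared 4-neighbour
  diag_kept <- function(di, dj) {
    pr <- which(skl, arr.ind = TRUE)
    q1 <- cbind(pr[, 1] + di, pr[, 2] + dj)
    ok <- q1[, 1] >= 1 & q1[, 1] <= nrow(skl) & q1[, 2] >= 1 &
      q1[, 2] <= ncol(skl)
    pr <- pr[ok, , drop = FALSE]; q1 <- q1[ok, , drop = FALSE]
    pair <- skl[q1]
    if (!any(pair)) return(0L)
    pr <- pr[pair, , drop = FALSE]; q1 <- q1[pair, , drop = FALSE]
    at <- function(i, j) {
      ok <- i >= 1 & i <= nrow(skl) & j >= 1 & j <= ncol(skl)
      v <- rep(FALSE, length(i)); v[ok] <- skl[cbind(i[ok], j[ok])]; v
    }
    common <- at(pr[, 1] + di, pr[, 2]) | at(pr[, 1], pr[, 2] + dj)
    sum(!common)
  }
  n_d <- diag_kept(1, 1) + diag_kept(1, -1)
  length_px <- n_e + n_s + sqrt(2) * n_d
  if (extend_tips && nrow(tips_px)) {
    for (ti in seq_len(nrow(tips_px))) {
      length_px <- length_px + tip_extension(skl, mask, tips_px[ti, ])
    }
  }
  to_um <- function(pts) {
    if (!nrow(pts)) {
      return(data.frame(x_um = numeric(0), y_um = numeric(0)))
    }
    data.frame(x_um = (pts[, 1] + x0 - 1L - 0.5) * px_um,
               y_um = (pts[, 2] + y0 - 1L - 0.5) * px_um)
  }
  branch_lm <- cluster_points(branch_px, merge_radius_px)
  list(length_um = length_px * px_um,
       tips = to_um(tips_px),
       branch_points = to_um(branch_lm),
       skeleton = skl, offset = c(x0, y0))
}

crista_components <- function(cristae_mask, pixel_size_nm,
                              max_crista_len_um = 1.2) {
  lab <- EBImage::bwlabel(matrix(as.numeric(cristae_mask),
                                 nrow(cristae_mask), ncol(cristae_mask)))
  lab <- matrix(as.integer(lab), nrow(cristae_mask), ncol(cristae_mask))
  n <- max(lab)
  if (n == 0) {
    return(data.frame(comp = integer(0), x = numeric(0), y = numeric(0),
                      area_px = integer(0), is_crista = logical(0)))
  }
  px_um <- pixel_size_nm / 1000
  filled <- matrix(as.integer(EBImage::fillHull(lab)), nrow(lab), ncol(lab))
  out <- data.frame(comp = seq_len(n), x = NA_real_, y = NA_real_,
                    area_px = NA_integer_, is_crista = NA)
  for (l in seq_len(n)) {
    sel <- which(lab == l)
    ij <- arrayInd(sel, dim(lab))
    out$x[l] <- mean(ij[, 1]); out$y[l] <- mean(ij[, 2])
    out$area_px[l] <- length(sel)
    extent <- max(diff(range(ij[, 1])), diff(range(ij[, 2]))) * px_um
    fill_ratio <- sum(filled == l) / length(sel)
    # boundary membrane shows up as a ring (fills) or a long open contour
    out$is_crista[l] <- fill_ratio <= 1.25 && extent <= max_crista_len_um
  }
  out
}

#' Count cristae inside one mitochondrion
#'
#' Connected components of the cristae mask whose centroid falls inside the
#' given label. Ring-like or over-long thin components are treated as
#' boundary membrane, not cristae.
#'
#' @param label mitochondrion label.
#' @param cristae_mask logical cristae mask.
#' @param labels integer label matrix (same geometry).
#' @param pixel_size_nm pixel size (nm).
#' @param cfg a [segmentation_config()] (for `max_crista_len_um`).
#' @return integer count.
#' @export
count_cristae <- function(label, cristae_mask, labels, pixel_size_nm = 20,
                          cfg = segmentation_config()) {
  cc <- crista_components(cristae_mask, pixel_size_nm,
                          cfg$max_crista_len_um)
  if (!nrow(cc)) return(0L)
  inside <- labels[cbind(pmin(pmax(round(cc$x), 1), nrow(labels)),
                         pmin(pmax(round(cc$y), 1), ncol(labels)))] == label
  sum(inside & cc$is_crista)
}

#' Per-mitochondrion records from a segmented image pair
#'
#' Combines skeleton morphometry, cristae counts, class labels, areas and
#' nucleoid ownership into one record per labelled mitochondrion.
#'
#' @param labels integer mitochondrion label matrix.
#' @param cristae_mask logical cristae mask.
#' @param nucleoids data frame from [detect_nucleoids()] (may be `NULL`).
#' @param pixel_size_nm pixel size (nm).
#' @param rule a [classification_rule()].
#' @param cfg a [segmentation_config()].
#' @param boundary_correction_nm the labelled region extends to the outer
#'   edge of the segmented membrane band, but the organelle boundary is the
#'   band midline; areas are counted after eroding the region by this
#'   half-band width (default 25 nm: membrane half-thickness plus filter
#'   response spread).
#' @return list with `records` (data frame: label, length_um, n_cristae,
#'   class, mito_area_um2, cristae_area_um2, nucleoid_area_um2) and
#'   `landmarks` (data frame: label, kind, x_um, y_um).
#' @export
measure_mitochondria <- function(labels, cristae_mask, nucleoids = NULL,
                                 pixel_size_nm = 20,
                                 rule = classification_rule(),
                                 cfg = segmentation_config(),
                                 boundary_correction_nm = 25) {
  n <- max(labels)
  px_um2 <- (pixel_size_nm / 1000)^2
  recs <- vector("list", n)
  lms <- vector("list", n)
  er_px <- round(boundary_correction_nm / pixel_size_nm)
  interior <- if (er_px > 0) {
    EBImage::erode(matrix(as.numeric(labels > 0), nrow(labels),
                          ncol(labels)),
                   EBImage::makeBrush(2L * er_px + 1L, "disc")) > 0
  } else labels > 0
  cc <- crista_components(cristae_mask, pixel_size_nm, cfg$max_crista_len_um)
  for (l in seq_len(n)) {
    sk <- skeletonize_component(labels, l, pixel_size_nm)
    inside <- if (nrow(cc)) {
      labels[cbind(pmin(pmax(round(cc$x), 1), nrow(labels)),
                   pmin(pmax(round(cc$y), 1), ncol(labels)))] == l
    } else logical(0)
    n_cr <- sum(inside & cc$is_crista)
    mito_area <- sum(labels == l & interior) * px_um2
    cristae_area <- sum(cristae_mask & labels == l) * px_um2
    nuc_area <- if (!is.null(nucleoids) && nrow(nucleoids)) {
      sum(nucleoids$area_um2[nucleoids$mito_label == l])
    } else 0
    recs[[l]] <- data.frame(
      label = l, length_um = sk$length_um, n_cristae = n_cr,
      class = classify_mitochondrion(sk$length_um, n_cr, rule),
      mito_area_um2 = mito_area, cristae_area_um2 = cristae_area,
      nucleoid_area_um2 = nuc_area)
    lm <- rbind(
      if (nrow(sk$tips)) cbind(label = l, kind = "tip", sk$tips),
      if (nrow(sk$branch_points)) cbind(label = l, kind = "branch",
                                        sk$branch_points))
    lms[[l]] <- lm
  }
  lms <- lms[!vapply(lms, is.null, TRUE)]
  list(records = do.call(rbind, recs),
       landmarks = if (length(lms)) do.call(rbind, lms) else
         data.frame(label = integer(0), kind = character(0),
                    x_um = numeric(0), y_um = numeric(0)))
}

#' Class proportions and scatter table of a population
#'
#' @param records data frame with `length_um`, `n_cristae`, `class`.
#' @return list with `proportions` (named I/II/III, summing to 1) and
#'   `scatter` (length, count, class per record).
#' @export
summarize_population <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    stop("no mitochondria to summarize", call. = FALSE)
  }
  tab <- table(factor(records$class, levels = c("I", "II", "III")))
  props <- setNames(as.numeric(tab) / nrow(records), c("I", "II", "III"))
  list(proportions = props,
       scatter = records[, c("length_um", "n_cristae", "class")])
}
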