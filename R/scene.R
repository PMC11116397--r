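#' Parameters of a synthetic mitochondrial scene
#'
#' Defaults follow the geometry of mammalian mitochondria as seen by STED:
#' tubules 200-700 nm in diameter with transverse cristae spaced about
#' 70 nm apart.
#'
#' @param field_um field size, c(width, height) in micrometres.
#' @param diameter_nm tubule diameter range (nm).
#' @param cristae_spacing_nm spacing between consecutive cristae (nm).
#' @param cristae_thickness_nm thickness of a crista stroke (nm).
#' @param membrane_thickness_nm thickness of the boundary-membrane stroke (nm).
#' @param n_components number of network components.
#' @param branch_prob_per_um probability of grafting a branch per micrometre
#'   of trunk.
#' @param amplitude fluorophore density amplitude per structure (a.u.).
#' @param tubule_length_um trunk length range (micrometres).
#' @param cristae_span_frac upper bound on the fraction of the tubule
#'   radius spanned by a crista on each side of the centreline.
#' @param cristae_gap_nm clear gap kept between a crista end and the
#'   boundary membrane (crista half-span = min(span_frac * r, r - gap));
#'   keeps cristae resolvable from the membrane at the imaging resolution.
#' @param step_um centreline step used when growing tubules (micrometres).
#' @param curvature_sd standard deviation of the heading increment per
#'   sqrt(micrometre); caps tubule curvature.
#' @param min_separation_um clearance kept between the envelopes of
#'   different network components (tubules are regrown, up to a retry cap,
#'   when they would come closer).
#' @return a `scene_params` list.
#' @export
scene_params <- function(field_um = c(10, 10),
                         diameter_nm = c(200, 700),
                         cristae_spacing_nm = 70,
                         cristae_thickness_nm = 20,
                         membrane_thickness_nm = 30,
                         n_components = 5,
                         branch_prob_per_um = 0.15,
                         amplitude = 1,
                         tubule_length_um = c(3, 8),
                         cristae_span_frac = 0.7,
                         cristae_gap_nm = 90,
                         step_um = 0.05,
                         curvature_sd = 0.6,
                         min_separation_um = 0.3) {
  p <- list(field_um = as.numeric(field_um),
            diameter_nm = as.numeric(diameter_nm),
            cristae_spacing_nm = cristae_spacing_nm,
            cristae_thickness_nm = cristae_thickness_nm,
            membrane_thickness_nm = membrane_thickness_nm,
            n_components = as.integer(n_components),
            branch_prob_per_um = branch_prob_per_um,
            amplitude = amplitude,
            tubule_length_um = as.numeric(tubule_length_um),
            cristae_span_frac = cristae_span_frac,
            cristae_gap_nm = cristae_gap_nm,
            step_um = step_um,
            curvature_sd = curvature_sd,
            min_separation_um = min_separation_um)
  validate_scene_params(p)
  class(p) <- "scene_params"
  p
}

validate_scene_params <- function(p) {
  if (any(p$field_um <= 0)) stop("field size must be positive", call. = FALSE)
  if (p$diameter_nm[1] <= 0 || diff(p$diameter_nm) < 0) {
    stop("diameter range must be positive and increasing", call. = FALSE)
  }
  if (p$diameter_nm[2] / 1000 >= min(p$field_um)) {
    stop("field too small to host one tubule of minimum diameter",
         call. = FALSE)
  }
  if (min(p$field_um) < p$diameter_nm[1] / 1000 + 0.5) {
    stop("field too small to host one tubule of minimum diameter",
         call. = FALSE)
  }
  if (!(p$cristae_spacing_nm > p$cristae_thickness_nm) ||
      p$cristae_thickness_nm <= 0) {
    stop("need cristae spacing > cristae thickness > 0", call. = FALSE)
  }
  invisible(p)
}

#' Nucleoid placement model
#'
#' Landmarks (tips and branch points) are occupied independently with the
#' stated probability; each unoccupied landmark receives a nucleoid whose
#' nearest distance along the tubule follows an exponential law. Additional
#' nucleoids are scattered along the tubules at a Poisson rate per
#' micrometre.
#'
#' The default occupancy (0.677) and exponential rate
#' (-log(0.35)/0.6 = 1.7497 per micrometre, i.e. 65.0% of nearest distances
#' below 0.6 um) match the landmark statistics reported for healthy COS7
#' mitochondria.
#'
#' @param occupancy probability that a landmark carries a nucleoid.
#' @param lambda_per_um exponential rate of the landmark nearest-distance
#'   law (1/um).
#' @param radius_nm nucleoid disk radius (nm).
#' @param per_um expected extra nucleoids per micrometre of tubule.
#' @param target_area_ratio if not `NULL`, the nucleoid radius is solved so
#'   that total nucleoid area / total mitochondrial area equals this value
#'   (the control default is 0.291).
#' @return a `nucleoid_placement` list.
#' @export
nucleoid_placement <- function(occupancy = 0.677,
                               lambda_per_um = -log(0.35) / 0.6,
                               radius_nm = 195,
                               per_um = 0.5,
                               target_area_ratio = NULL) {
  if (occupancy < 0 || occupancy > 1) {
    stop("occupancy must be in [0, 1]", call. = FALSE)
  }
  if (lambda_per_um <= 0) stop("lambda must be > 0", call. = FALSE)
  structure(list(occupancy = occupancy, lambda_per_um = lambda_per_um,
                 radius_nm = radius_nm, per_um = per_um,
                 target_area_ratio = target_area_ratio),
            class = "nucleoid_placement")
}

# ---- polyline helpers -------------------------------------------------------

path_cumlen <- function(path) {
  d <- sqrt(diff(path[, 1])^2 + diff(path[, 2])^2)
  c(0, cumsum(d))
}

# resample a polyline at arclength step; returns matrix with x, y and unit
# tangents
resample_path <- function(path, step_um) {
  cl <- path_cumlen(path)
  L <- cl[length(cl)]
  if (L <= 0) {
    return(cbind(x = path[1, 1], y = path[1, 2], tx = 1, ty = 0, s = 0))
  }
  s <- unique(c(seq(0, L, by = step_um), L))
  x <- approx(cl, path[, 1], xout = s, ties = "ordered")$y
  y <- approx(cl, path[, 2], xout = s, ties = "ordered")$y
  tx <- c(diff(x), tail(diff(x), 1))
  ty <- c(diff(y), tail(diff(y), 1))
  nrm <- sqrt(tx^2 + ty^2)
  nrm[nrm == 0] <- 1
  cbind(x = x, y = y, tx = tx / nrm, ty = ty / nrm, s = s)
}

grow_polyline <- function(start, heading, length_um, step_um, curvature_sd,
                          field_um, margin, avoid_r = 0) {
  n_steps <- max(1L, ceiling(length_um / step_um))
  pts <- matrix(NA_real_, n_steps + 1L, 2L)
  pts[1, ] <- start
  th <- heading
  centre <- field_um / 2
  lag <- max(3L, ceiling(avoid_r / step_um) + 2L)
  for (k in seq_len(n_steps)) {
    th <- th + rnorm(1, 0, curvature_sd * sqrt(step_um))
    nxt <- pts[k, ] + step_um * c(cos(th), sin(th))
    if (nxt[1] < margin || nxt[1] > field_um[1] - margin ||
        nxt[2] < margin || nxt[2] > field_um[2] - margin) {
      th <- atan2(centre[2] - pts[k, 2], centre[1] - pts[k, 1]) +
        rnorm(1, 0, 0.2)
      nxt <- pts[k, ] + step_um * c(cos(th), sin(th))
    }
    # steer away from the tubule's own earlier path (self-crossings would
    # not be resolvable as a single tubule)
    if (avoid_r > 0 && k > lag) {
      old <- pts[1:(k - lag), , drop = FALSE]
      too_close <- function(p) {
        min((old[, 1] - p[1])^2 + (old[, 2] - p[2])^2) < avoid_r^2
      }
      if (too_close(nxt)) {
        for (dth in c(0.5, -0.5, 1, -1, 1.5, -1.5, 2, -2)) {
          cand <- pts[k, ] + step_um * c(cos(th + dth), sin(th + dth))
          if (!too_close(cand) && cand[1] > margin &&
              cand[1] < field_um[1] - margin && cand[2] > margin &&
              cand[2] < field_um[2] - margin) {
            th <- th + dth; nxt <- cand; break
          }
        }
      }
    }
    pts[k + 1L, ] <- nxt
  }
  pts
}

crista_half_span <- function(radius_um, span_frac, gap_nm) {
  max(min(span_frac * radius_um, radius_um - gap_nm / 1000), 0.03)
}

cristae_for_tubule <- function(path, radius_um, spacing_um, half_span_um) {
  rp <- resample_path(path, spacing_um / 4)
  L <- max(rp[, "s"])
  n <- floor(L / spacing_um + 1e-9)
  if (n < 1) {
    return(data.frame(x0 = numeric(0), y0 = numeric(0),
                      x1 = numeric(0), y1 = numeric(0)))
  }
  s_k <- (seq_len(n) - 0.5) * spacing_um
  x <- approx(rp[, "s"], rp[, "x"], xout = s_k, ties = "ordered")$y
  y <- approx(rp[, "s"], rp[, "y"], xout = s_k, ties = "ordered")$y
  tx <- approx(rp[, "s"], rp[, "tx"], xout = s_k, ties = "ordered")$y
  ty <- approx(rp[, "s"], rp[, "ty"], xout = s_k, ties = "ordered")$y
  nrm <- sqrt(tx^2 + ty^2); nrm[nrm == 0] <- 1
  nx <- -ty / nrm; ny <- tx / nrm
  h <- half_span_um
  data.frame(x0 = x - h * nx, y0 = y - h * ny,
             x1 = x + h * nx, y1 = y + h * ny)
}

# ---- network generation -----------------------------------------------------

#' Generate a synthetic mitochondrial network
#'
#' Grows curvature-capped random-walk tubules, grafts side branches at a
#' Poisson rate along each trunk, and places transverse cristae at the
#' configured spacing, perpendicular to the local centreline. Deterministic
#' for a given seed.
#'
#' @param params a [scene_params()] object.
#' @param seed integer seed.
#' @return a `mito_scene` with tubules, cristae, tips, branch points and
#'   per-component truth (length, cristae count, morphology class).
#' @export
generate_network <- function(params, seed = 1L) {
  validate_scene_params(params)
  withr::with_seed(seed, {
    tubules <- list()
    tips <- list()
    branches <- list()
    margin <- params$diameter_nm[2] / 2000 + 0.2
    occupied <- NULL   # x, y, radius, component of accepted tubule samples
    clearance_of <- function(path, radius, exclude_comp = NA) {
      occ <- occupied
      if (!is.null(occ) && !is.na(exclude_comp)) {
        occ <- occ[occ[, 4] != exclude_comp, , drop = FALSE]
      }
      if (is.null(occ) || nrow(occ) == 0) return(Inf)
      rp <- resample_path(path, 0.1)
      # only occupied points near the candidate's bounding box can matter
      pad <- radius + max(occ[, 3]) + 2 * params$min_separation_um + 0.2
      near <- occ[, 1] >= min(rp[, "x"]) - pad &
        occ[, 1] <= max(rp[, "x"]) + pad &
        occ[, 2] >= min(rp[, "y"]) - pad &
        occ[, 2] <= max(rp[, "y"]) + pad
      if (!any(near)) return(Inf)
      occ <- occ[near, , drop = FALSE]
      d2 <- outer(rp[, "x"], occ[, 1], "-")^2 +
        outer(rp[, "y"], occ[, 2], "-")^2
      min(sqrt(d2) - matrix(occ[, 3], nrow(rp), nrow(occ),
                            byrow = TRUE)) - radius
    }
    remember <- function(path, radius, comp) {
      rp <- resample_path(path, 0.1)
      occupied <<- rbind(occupied,
                         cbind(rp[, "x"], rp[, "y"], radius, comp))
    }
    for (comp in seq_len(params$n_components)) {
      radius <- runif(1, params$diameter_nm[1], params$diameter_nm[2]) / 2000
      L <- runif(1, params$tubule_length_um[1], params$tubule_length_um[2])
      trunk <- NULL
      best_clear <- -Inf
      for (try in 1:25) {
        start <- c(runif(1, margin, params$field_um[1] - margin),
                   runif(1, margin, params$field_um[2] - margin))
        heading <- runif(1, 0, 2 * pi)
        cand <- grow_polyline(start, heading, L, params$step_um,
                              params$curvature_sd, params$field_um, margin,
                              avoid_r = 2 * radius + 0.15)
        cl <- clearance_of(cand, radius)
        if (cl > best_clear) { trunk <- cand; best_clear <- cl }
        if (cl >= params$min_separation_um) break
      }
      remember(trunk, radius, comp)
      tubules[[length(tubules) + 1L]] <-
        list(component = comp, path = trunk, radius_um = radius,
             graft = NA_integer_)
      trunk_idx <- length(tubules)
      tips[[length(tips) + 1L]] <-
        data.frame(x = c(trunk[1, 1], trunk[nrow(trunk), 1]),
                   y = c(trunk[1, 2], trunk[nrow(trunk), 2]),
                   component = comp, tubule = trunk_idx,
                   end = c("start", "end"))
      # branch grafting along the trunk
      p_step <- params$branch_prob_per_um * params$step_um
      for (k in 2:(nrow(trunk) - 1L)) {
        if (runif(1) < p_step) {
          gpt <- trunk[k, ]
          th0 <- atan2(trunk[k + 1L, 2] - trunk[k - 1L, 2],
                       trunk[k + 1L, 1] - trunk[k - 1L, 1])
          th <- th0 + sample(c(-1, 1), 1) * runif(1, pi / 3, pi / 2)
          bl <- runif(1, 0.25, 0.6) * L
          br <- radius * runif(1, 0.8, 1)
          bp <- best_bp <- grow_polyline(gpt, th, bl, params$step_um,
                                         params$curvature_sd,
                                         params$field_um, margin,
                                         avoid_r = 2 * br + 0.15)
          best_clear <- clearance_of(bp, br, exclude_comp = comp)
          for (try in 1:10) {
            if (best_clear >= params$min_separation_um) break
            th2 <- th0 + sample(c(-1, 1), 1) * runif(1, pi / 3, pi / 2)
            bp <- grow_polyline(gpt, th2, bl, params$step_um,
                                params$curvature_sd, params$field_um,
                                margin, avoid_r = 2 * br + 0.15)
            cl <- clearance_of(bp, br, exclude_comp = comp)
            if (cl > best_clear) { best_bp <- bp; best_clear <- cl }
          }
          bp <- best_bp
          remember(bp, br, comp)
          tubules[[length(tubules) + 1L]] <-
            list(component = comp, path = bp,
                 radius_um = br,
                 graft = trunk_idx)
          branches[[length(branches) + 1L]] <-
            data.frame(x = gpt[1], y = gpt[2], component = comp,
                       tubule = length(tubules))
          tips[[length(tips) + 1L]] <-
            data.frame(x = bp[nrow(bp), 1], y = bp[nrow(bp), 2],
                       component = comp, tubule = length(tubules),
                       end = "end")
        }
      }
    }
    build_scene(params, tubules, do.call(rbind, tips),
                if (length(branches)) do.call(rbind, branches) else
                  data.frame(x = numeric(0), y = numeric(0),
                             component = integer(0), tubule = integer(0)))
  })
}

build_scene <- function(params, tubules, tips, branch_points) {
  spacing <- params$cristae_spacing_nm / 1000
  cr <- lapply(seq_along(tubules), function(i) {
    t <- tubules[[i]]
    d <- cristae_for_tubule(t$path, t$radius_um, spacing,
                            crista_half_span(t$radius_um,
                                             params$cristae_span_frac,
                                             params$cristae_gap_nm))
    if (nrow(d)) { d$component <- t$component; d$tubule <- i }
    d
  })
  cr <- cr[vapply(cr, nrow, 1L) > 0]
  cristae <- if (length(cr)) do.call(rbind, cr) else
    data.frame(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
               y1 = numeric(0), component = integer(0), tubule = integer(0))
  comp_ids <- sort(unique(vapply(tubules, `[[`, 1L, "component")))
  lens <- vapply(tubules, function(t) max(path_cumlen(t$path)), 1)
  tub_comp <- vapply(tubules, `[[`, 1L, "component")
  # organelle length = centreline length plus the rounded end cap at every
  # free tip (full end-to-end extent, the quantity a length trace measures)
  cap_len <- vapply(comp_ids, function(cid) {
    tt <- tips[tips$component == cid, , drop = FALSE]
    if (!nrow(tt)) return(0)
    sum(vapply(tt$tubule, function(i) tubules[[i]]$radius_um, 1))
  }, 1)
  comps <- data.frame(
    component = comp_ids,
    length_um = vapply(comp_ids, function(cid) {
      sum(lens[tub_comp == cid])
    }, 1) + cap_len,
    n_cristae = vapply(comp_ids, function(cid) {
      sum(cristae$component == cid)
    }, 1))
  comps$class <- vapply(seq_len(nrow(comps)), function(i) {
    classify_mitochondrion(comps$length_um[i], comps$n_cristae[i])
  }, "")
  structure(list(params = params, field_um = params$field_um,
                 tubules = tubules, cristae = cristae, tips = tips,
                 branch_points = branch_points, components = comps,
                 nucleoids = NULL),
            class = "mito_scene")
}

#' @export
print.mito_scene <- function(x, ...) {
  cat(sprintf(paste0("<mito_scene> %.1f x %.1f um, %d components, ",
                     "%d tubules, %d cristae, %d tips, %d branch points, ",
                     "%d nucleoids\n"),
              x$field_um[1], x$field_um[2], nrow(x$components),
              length(x$tubules), nrow(x$cristae), nrow(x$tips),
              nrow(x$branch_points),
              if (is.null(x$nucleoids)) 0L else nrow(x$nucleoids)))
  invisible(x)
}

scene_landmarks <- function(scene) {
  t <- scene$tips
  b <- scene$branch_points
  rbind(data.frame(x = t$x, y = t$y, component = t$component,
                   tubule = t$tubule, kind = "tip",
                   end = t$end, stringsAsFactors = FALSE),
        if (nrow(b)) data.frame(x = b$x, y = b$y, component = b$component,
                                tubule = b$tubule, kind = "branch",
                                end = "graft", stringsAsFactors = FALSE))
}

scene_mito_area_um2 <- function(scene) {
  sum(vapply(scene$tubules, function(t) {
    max(path_cumlen(t$path)) * 2 * t$radius_um
  }, 1))
}

# first point along a tubule path whose straight-line distance from the
# landmark reaches d; paths are walked from the landmark inwards
point_at_euclidean <- function(path, from_end, d, step_um = 0.01) {
  rp <- resample_path(path, step_um)
  if (from_end == "end") rp <- rp[rev(seq_len(nrow(rp))), , drop = FALSE]
  dist <- sqrt((rp[, "x"] - rp[1, "x"])^2 + (rp[, "y"] - rp[1, "y"])^2)
  k <- which(dist >= d)[1]
  if (is.na(k)) {
    k <- which.max(dist)
    return(list(x = rp[k, "x"], y = rp[k, "y"], truncated = TRUE))
  }
  if (k == 1L) return(list(x = rp[1, "x"], y = rp[1, "y"], truncated = FALSE))
  # refine between the bracketing samples so the distance is exact
  t <- (d - dist[k - 1]) / max(dist[k] - dist[k - 1], 1e-12)
  list(x = rp[k - 1, "x"] + t * (rp[k, "x"] - rp[k - 1, "x"]),
       y = rp[k - 1, "y"] + t * (rp[k, "y"] - rp[k - 1, "y"]),
       truncated = FALSE)
}

#' Place mtDNA nucleoids in a scene
#'
#' See [nucleoid_placement()] for the model. Landmark nucleoids sit exactly
#' on their landmark; exponential-law nucleoids sit on the centreline of the
#' landmark's tubule at the drawn Euclidean distance; density nucleoids are
#' uniform in arc length over all tubules. Centres always lie on tubule
#' centrelines, hence inside the envelopes.
#'
#' @param scene a `mito_scene`.
#' @param placement a [nucleoid_placement()].
#' @param seed integer seed.
#' @return the scene with a `nucleoids` data frame (x, y, r_um, kind).
#' @export
sample_nucleoids <- function(scene, placement = nucleoid_placement(),
                             seed = 1L) {
  stopifnot(inherits(scene, "mito_scene"))
  if (!length(scene$tubules)) stop("scene has no tubules", call. = FALSE)
  lm <- scene_landmarks(scene)
  comp_len <- scene$components$length_um
  if (1 / placement$lambda_per_um > max(comp_len)) {
    warning("exponential mean exceeds every tubule length; ",
            "distances will be truncated")
  }
  withr::with_seed(seed, {
    out <- list()
    n_trunc <- 0L
    if (nrow(lm)) {
      occ <- runif(nrow(lm)) < placement$occupancy
      for (i in seq_len(nrow(lm))) {
        if (occ[i]) {
          out[[length(out) + 1L]] <-
            data.frame(x = lm$x[i], y = lm$y[i], kind = "landmark",
                       landmark_kind = lm$kind[i])
        } else {
          d <- rexp(1, placement$lambda_per_um)
          tb <- scene$tubules[[lm$tubule[i]]]
          from <- if (lm$kind[i] == "branch") "start" else
            if (lm$end[i] == "start") "start" else "end"
          p <- point_at_euclidean(tb$path, from, d)
          if (p$truncated) n_trunc <- n_trunc + 1L
          out[[length(out) + 1L]] <-
            data.frame(x = p$x, y = p$y, kind = "exp",
                       landmark_kind = lm$kind[i])
        }
      }
    }
    if (placement$per_um > 0) {
      lens <- vapply(scene$tubules, function(t) max(path_cumlen(t$path)), 1)
      n_extra <- rpois(1, placement$per_um * sum(lens))
      if (n_extra > 0) {
        which_tub <- sample.int(length(lens), n_extra, replace = TRUE,
                                prob = lens)
        for (j in seq_len(n_extra)) {
          tb <- scene$tubules[[which_tub[j]]]
          rp <- resample_path(tb$path, 0.02)
          s <- runif(1, 0, max(rp[, "s"]))
          x <- approx(rp[, "s"], rp[, "x"], xout = s, ties = "ordered")$y
          y <- approx(rp[, "s"], rp[, "y"], xout = s, ties = "ordered")$y
          out[[length(out) + 1L]] <-
            data.frame(x = x, y = y, kind = "density",
                       landmark_kind = NA_character_)
        }
      }
    }
    if (n_trunc > 0.02 * max(1L, nrow(lm))) {
      warning(sprintf("%d nearest-distance draws truncated by tubule extent",
                      n_trunc))
    }
    nuc <- if (length(out)) do.call(rbind, out) else
      data.frame(x = numeric(0), y = numeric(0), kind = character(0),
                 landmark_kind = character(0))
    r <- placement$radius_nm / 1000
    if (!is.null(placement$target_area_ratio) && nrow(nuc)) {
      area <- scene_mito_area_um2(scene)
      target <- placement$target_area_ratio * area
      r <- sqrt(target / (nrow(nuc) * pi))
      # overlapping disks cover less than the sum of their areas; iterate
      # the radius against the rasterized union so the covered area hits
      # the target
      grid_px <- 0.02
      for (it in 1:4) {
        M <- matrix(0, ceiling(scene$field_um[1] / grid_px),
                    ceiling(scene$field_um[2] / grid_px))
        M <- paint_points(M, nuc$x, nuc$y, r, grid_px, 1)
        covered <- sum(M > 0) * grid_px^2
        r <- r * sqrt(target / max(covered, 1e-9))
      }
    }
    nuc$r_um <- rep(r, nrow(nuc))
    scene$nucleoids <- nuc
    scene$placement <- placement
    scene
  })
}

# ---- rasterization ----------------------------------------------------------

paint_points <- function(M, xs, ys, radius_um, px_um, value) {
  if (!length(xs)) return(M)
  r_px <- radius_um / px_um
  w <- max(0L, ceiling(r_px - 0.5))
  offs <- expand.grid(di = -w:w, dj = -w:w)
  keep <- sqrt(offs$di^2 + offs$dj^2) <= max(r_px, 0.5) + 1e-9
  offs <- offs[keep, , drop = FALSE]
  i0 <- round(xs / px_um + 0.5)
  j0 <- round(ys / px_um + 0.5)
  nx <- nrow(M); ny <- ncol(M)
  ii <- rep(i0, each = nrow(offs)) + rep(offs$di, length(i0))
  jj <- rep(j0, each = nrow(offs)) + rep(offs$dj, length(j0))
  ok <- ii >= 1 & ii <= nx & jj >= 1 & jj <= ny
  idx <- cbind(ii[ok], jj[ok])
  M[idx] <- pmax(M[idx], value)
  M
}

paint_stroke <- function(M, pts, thickness_um, px_um, value) {
  paint_points(M, pts[, 1], pts[, 2], thickness_um / 2, px_um, value)
}

segment_points <- function(x0, y0, x1, y1, step_um) {
  L <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  n <- max(2L, ceiling(L / step_um) + 1L)
  cbind(seq(x0, x1, length.out = n), seq(y0, y1, length.out = n))
}

cap_points <- function(centre, radius_um, heading, step_um) {
  # semicircular end cap opening away from `heading`
  arc <- seq(heading + pi / 2, heading + 3 * pi / 2, length.out =
               max(4L, ceiling(pi * radius_um / step_um)))
  cbind(centre[1] + radius_um * cos(arc), centre[2] + radius_um * sin(arc))
}

#' Render a continuous fluorophore-density map for one channel
#'
#' The IM channel paints the boundary membrane (offset curves with end caps
#' at free tips) and all crista segments; the mtDNA channel paints nucleoid
#' disks. Structures are painted at the scene amplitude, so doubling the
#' amplitude scales the map exactly.
#'
#' @param scene a `mito_scene`.
#' @param channel `"IM"` or `"mtDNA"`.
#' @param pixel_size_nm raster pixel size (nm); default 20 so a 40 nm PSF is
#'   Nyquist sampled.
#' @return a `mito_image` density map (arbitrary units, not photon counts).
#' @export
render_density <- function(scene, channel = c("IM", "mtDNA"),
                           pixel_size_nm = 20) {
  channel <- match.arg(channel)
  stopifnot(inherits(scene, "mito_scene"))
  if (pixel_size_nm <= 0) stop("pixel size must be > 0", call. = FALSE)
  if (channel == "IM" && pixel_size_nm > scene$params$cristae_spacing_nm) {
    warning("pixel size exceeds cristae spacing: ground truth is aliased")
  }
  px <- pixel_size_nm / 1000
  nx <- max(1L, round(scene$field_um[1] / px))
  ny <- max(1L, round(scene$field_um[2] / px))
  M <- matrix(0, nx, ny)
  amp <- scene$params$amplitude
  step <- px / 2
  if (channel == "IM") {
    memb_t <- scene$params$membrane_thickness_nm / 1000
    cris_t <- scene$params$cristae_thickness_nm / 1000
    free_tips <- scene$tips
    for (i in seq_along(scene$tubules)) {
      tb <- scene$tubules[[i]]
      rp <- resample_path(tb$path, step)
      nxv <- -rp[, "ty"]; nyv <- rp[, "tx"]
      left <- cbind(rp[, "x"] + tb$radius_um * nxv,
                    rp[, "y"] + tb$radius_um * nyv)
      right <- cbind(rp[, "x"] - tb$radius_um * nxv,
                     rp[, "y"] - tb$radius_um * nyv)
      M <- paint_stroke(M, left, memb_t, px, amp)
      M <- paint_stroke(M, right, memb_t, px, amp)
      ft <- free_tips[free_tips$tubule == i, , drop = FALSE]
      for (k in seq_len(nrow(ft))) {
        if (ft$end[k] == "start") {
          ctr <- tb$path[1, ]; hd <- atan2(rp[2, "y"] - rp[1, "y"],
                                           rp[2, "x"] - rp[1, "x"])
        } else {
          n <- nrow(rp)
          ctr <- tb$path[nrow(tb$path), ]
          hd <- atan2(rp[n, "y"] - rp[n - 1, "y"],
                      rp[n, "x"] - rp[n - 1, "x"]) + pi
        }
        M <- paint_stroke(M, cap_points(ctr, tb$radius_um, hd, step),
                          memb_t, px, amp)
      }
    }
    cr <- scene$cristae
    for (k in seq_len(nrow(cr))) {
      pts <- segment_points(cr$x0[k], cr$y0[k], cr$x1[k], cr$y1[k], step)
      M <- paint_stroke(M, pts, cris_t, px, amp)
    }
  } else {
    nuc <- scene$nucleoids
    if (!is.null(nuc) && nrow(nuc)) {
      for (k in seq_len(nrow(nuc))) {
        M <- paint_points(M, nuc$x[k], nuc$y[k], nuc$r_um[k], px, amp)
      }
    }
  }
  mito_image(M, pixel_size_nm, channel)
}

# ---- morphology populations -------------------------------------------------

in_class_region <- function(length_um, n_cristae, cls,
                            rule = classification_rule()) {
  classify_mitochondrion(length_um, n_cristae, rule) == cls
}

#' Sample a mitochondrial morphology population
#'
#' Draws (length, cristae count) pairs whose true class labels follow the
#' requested Class I/II/III mixture. Lengths come from a lognormal base
#' distribution; counts are drawn conditionally on length (about one crista
#' per 0.35 um plus noise) and the pair is rejection-sampled into the
#' requested class region.
#'
#' @param mixture numeric of length 3, class fractions summing to 1.
#' @param n number of mitochondria.
#' @param seed integer seed.
#' @param rule a [classification_rule()].
#' @return data frame with `length_um`, `n_cristae`, `class`.
#' @export
sample_morphology_population <- function(mixture, n, seed = 1L,
                                         rule = classification_rule()) {
  if (length(mixture) != 3L || any(mixture < 0) || sum(mixture) == 0) {
    stop("mixture must be 3 non-negative fractions, not all zero",
         call. = FALSE)
  }
  if (abs(sum(mixture) - 1) > 1e-6) {
    stop("mixture fractions must sum to 1", call. = FALSE)
  }
  classes <- c("I", "II", "III")
  withr::with_seed(seed, {
    want <- sample(classes, n, replace = TRUE, prob = mixture)
    len <- num <- numeric(n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in 1:300) {
        L <- rlnorm(1, log(3), 0.7)
        if (L < 0.5 || L > 12) next
        C <- max(0L, as.integer(round(L / 0.35 + rnorm(1, 0, 2))))
        if (in_class_region(L, C, want[i], rule)) {
          ok <- TRUE; break
        }
      }
      if (!ok) {
        # direct draw inside the canonical box of the wanted class
        if (want[i] == "I") {
          L <- runif(1, 0.7, 2.3); C <- sample(0:5, 1)
        } else if (want[i] == "II") {
          L <- runif(1, 2.6, 4.9)
          C <- min(12L, max(0L, as.integer(round(L / 0.35))))
        } else {
          L <- runif(1, 5.3, 9); C <- as.integer(round(L / 0.35))
        }
      }
      len[i] <- L; num[i] <- C
    }
    data.frame(length_um = len, n_cristae = as.integer(num),
               class = vapply(seq_len(n), function(i) {
                 classify_mitochondrion(len[i], num[i], rule)
               }, ""))
  })
}

#' Lay out a morphology population as a renderable scene
#'
#' Each (length, cristae count) record becomes one straight tubule in a grid
#' cell, with exactly the requested number of evenly spaced transverse
#' cristae. Rows are separated widely enough that segmentation cannot merge
#' neighbours.
#'
#' @param pop data frame from [sample_morphology_population()].
#' @param diameter_nm tubule diameter range (nm).
#' @param params optional [scene_params()] supplying stroke thicknesses and
#'   amplitude.
#' @param seed integer seed (diameters only).
#' @return a `mito_scene`.
#' @export
scene_from_population <- function(pop, diameter_nm = c(300, 500),
                                  params = NULL, seed = 1L) {
  n <- nrow(pop)
  stopifnot(n >= 1)
  cell_w <- max(pop$length_um) + 1.4
  cell_h <- 1.6
  ncols <- max(1L, round(sqrt(n * cell_h / cell_w)))
  nrows <- ceiling(n / ncols)
  field <- c(ncols * cell_w + 0.4, nrows * cell_h + 0.4)
  withr::with_seed(seed, {
    radii <- runif(n, diameter_nm[1], diameter_nm[2]) / 2000
  })
  base <- if (is.null(params)) scene_params(field_um = field) else params
  base$field_um <- field
  base$n_components <- n
  tubules <- vector("list", n)
  tips <- vector("list", n)
  cristae <- vector("list", n)
  for (i in seq_len(n)) {
    col <- (i - 1L) %% ncols
    row <- (i - 1L) %/% ncols
    x0 <- 0.4 + col * cell_w
    y0 <- 0.4 + cell_h / 2 + row * cell_h
    # requested length is the full organelle extent; the centreline is
    # shorter by one cap radius at each end
    L <- max(pop$length_um[i] - 2 * radii[i], 0.2)
    x0 <- x0 + radii[i]
    path <- cbind(seq(x0, x0 + L, length.out = max(2L, ceiling(L / 0.05))),
                  y0)
    tubules[[i]] <- list(component = i, path = path, radius_um = radii[i],
                         graft = NA_integer_)
    tips[[i]] <- data.frame(x = c(x0, x0 + L), y = y0, component = i,
                            tubule = i, end = c("start", "end"))
    C <- pop$n_cristae[i]
    if (C > 0) {
      sx <- x0 + (seq_len(C) - 0.5) * L / C
      h <- crista_half_span(radii[i], base$cristae_span_frac,
                            base$cristae_gap_nm)
      cristae[[i]] <- data.frame(x0 = sx, y0 = y0 - h, x1 = sx, y1 = y0 + h,
                                 component = i, tubule = i)
    }
  }
  cristae <- cristae[!vapply(cristae, is.null, TRUE)]
  comps <- data.frame(component = seq_len(n), length_um = pop$length_um,
                      n_cristae = pop$n_cristae)
  comps$class <- vapply(seq_len(n), function(i) {
    classify_mitochondrion(comps$length_um[i], comps$n_cristae[i])
  }, "")
  structure(list(params = base, field_um = field, tubules = tubules,
                 cristae = if (length(cristae)) do.call(rbind, cristae) else
                   data.frame(x0 = numeric(0), y0 = numeric(0),
                              x1 = numeric(0), y1 = numeric(0),
                              component = integer(0), tubule = integer(0)),
                 tips = do.call(rbind, tips),
                 branch_points = data.frame(x = numeric(0), y = numeric(0),
                                            component = integer(0),
                                            tubule = integer(0)),
                 components = comps, nucleoids = NULL),
            class = "mito_scene")
}

#' Serialize a scene's vector truth to JSON
#' @param scene a `mito_scene`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scene_json <- function(scene, path) {
  obj <- list(field_um = scene$field_um,
              tubules = lapply(scene$tubules, function(t) {
                list(component = t$component, radius_um = t$radius_um,
                     path = unname(as.matrix(t$path)))
              }),
              cristae = scene$cristae, tips = scene$tips,
              branch_points = scene$branch_points,
              components = scene$components,
              nucleoids = scene$nucleoids)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
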