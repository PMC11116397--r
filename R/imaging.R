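#' Fraction of fluorescence remaining under depletion
#'
#' The depletion law is F(I) = F0 / (1 + I/Is), the unique simple law that
#' both drops to 50% at I = Is (the operational definition of the
#' saturation power) and is consistent with the resolution scaling
#' d0 / sqrt(1 + I/Is).
#'
#' @param I depletion power (mW), >= 0. Vectorised.
#' @param Is saturation power (mW), > 0.
#' @return fraction of fluorescence remaining, in (0, 1].
#' @export
depletion_efficiency <- function(I, Is) {
  if (!is.numeric(Is) || Is <= 0) stop("Is must be > 0", call. = FALSE)
  if (any(I < 0)) stop("depletion power must be >= 0", call. = FALSE)
  1 / (1 + I / Is)
}

#' Effective STED PSF width
#'
#' d_eff = d0 / sqrt(1 + I_dep/Is): equal to the diffraction-limited width
#' at zero depletion power and strictly decreasing in depletion power.
#'
#' @param d0 diffraction-limited PSF FWHM (nm).
#' @param I_dep depletion power (mW), >= 0.
#' @param Is saturation power (mW), > 0.
#' @return effective FWHM (nm).
#' @export
effective_fwhm <- function(d0, I_dep, Is) {
  if (d0 <= 0 || Is <= 0 || any(I_dep < 0)) {
    stop("need d0 > 0, Is > 0, I_dep >= 0", call. = FALSE)
  }
  d0 / sqrt(1 + I_dep / Is)
}

#' Resolution-enhancement factor sqrt(1 + I_dep/Is)
#' @inheritParams effective_fwhm
#' @return fold improvement over the diffraction limit.
#' @export
resolution_enhancement <- function(I_dep, Is) {
  effective_fwhm(1, 0, Is) / effective_fwhm(1, I_dep, Is)
}

#' Acquisition settings for simulated imaging
#'
#' @param I_dep depletion power (mW); 0 gives confocal resolution.
#' @param d0 diffraction-limited PSF FWHM (nm), default 250.
#' @param photon_budget expected photons at the brightest pixel.
#' @param background constant background level (photons).
#' @param read_noise_sd Gaussian read-noise standard deviation (counts).
#' @param pixel_size_nm pixel size (nm).
#' @param shot_noise apply Poisson noise (disable for noise-free expected
#'   images).
#' @return an `acquisition_settings` list.
#' @export
acquisition_settings <- function(I_dep = 34.7, d0 = 250,
                                 photon_budget = 150, background = 2,
                                 read_noise_sd = 1, pixel_size_nm = 20,
                                 shot_noise = TRUE) {
  if (I_dep < 0 || d0 <= 0 || pixel_size_nm <= 0) {
    stop("need I_dep >= 0, d0 > 0, pixel size > 0", call. = FALSE)
  }
  structure(list(I_dep = I_dep, d0 = d0, photon_budget = photon_budget,
                 background = background, read_noise_sd = read_noise_sd,
                 pixel_size_nm = pixel_size_nm, shot_noise = shot_noise),
            class = "acquisition_settings")
}

gaussian_kernel <- function(sigma_px) {
  w <- max(1L, ceiling(3 * sigma_px))
  x <- -w:w
  k <- exp(-x^2 / (2 * sigma_px^2))
  k2 <- outer(k, k)
  k2 / sum(k2)
}

blur_gaussian <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  EBImage::filter2(m, gaussian_kernel(sigma_px), boundary = "circular")
}

#' Simulate STED/confocal acquisition of a density map
#'
#' Convolves the density with an isotropic Gaussian PSF at the effective
#' FWHM, scales to the photon budget, and applies Poisson shot noise, a
#' constant background and Gaussian read noise (clipped at zero).
#' Deterministic for a given seed.
#'
#' @param density a `mito_image` density map.
#' @param settings an [acquisition_settings()].
#' @param Is saturation power of the dye (mW).
#' @param seed integer seed.
#' @return a `mito_image` of photon counts.
#' @export
simulate_acquisition <- function(density, settings, Is = 0.864, seed = 1L) {
  stopifnot(inherits(density, "mito_image"))
  m <- img_matrix(density)
  if (any(!is.finite(m))) stop("density must be finite", call. = FALSE)
  px <- pixel_size_nm(density)
  fwhm <- effective_fwhm(settings$d0, settings$I_dep, Is)
  if (fwhm < px) warning("effective PSF FWHM below pixel size: under-sampled")
  sigma_px <- fwhm / (2 * sqrt(2 * log(2))) / px
  blurred <- blur_gaussian(m, sigma_px)
  mx <- max(blurred)
  scaled <- if (mx > 0) blurred / mx * settings$photon_budget else blurred
  lambda <- pmax(scaled + settings$background, 0)
  withr::with_seed(seed, {
    counts <- if (settings$shot_noise) {
      rpois(length(lambda), lambda)
    } else {
      lambda
    }
    if (settings$read_noise_sd > 0 && settings$shot_noise) {
      counts <- counts + rnorm(length(lambda), 0, settings$read_noise_sd)
    }
  })
  out <- matrix(pmax(counts, 0), nrow(m), ncol(m))
  mito_image(out, px, attr(density, "channel"))
}

#' Simulate a depletion-power series for saturation measurement
#'
#' The excitation-on series follows F0 * 1/(1 + I/Is) plus a depletion-only
#' (secondary excitation) component linear in the depletion power; the
#' excitation-off series contains only that component. Noise is i.i.d.
#' multiplicative per point.
#'
#' @param Is true saturation power (mW).
#' @param powers depletion powers (mW), ascending, starting at 0.
#' @param noise relative noise level (e.g. 0.02 for 2%).
#' @param seed integer seed.
#' @param F0 fluorescence at zero depletion (a.u.).
#' @param secondary_per_mw depletion-only signal per mW of depletion power,
#'   as a fraction of F0.
#' @return a `saturation_series` data frame (power_mW, on_mean, off_mean).
#' @export
simulate_depletion_series <- function(Is, powers = seq(0, 40, length.out = 12),
                                      noise = 0.02, seed = 1L, F0 = 1,
                                      secondary_per_mw = 0.005) {
  if (powers[1] != 0 || any(diff(powers) <= 0)) {
    stop("powers must start at 0 and be strictly increasing", call. = FALSE)
  }
  sec <- F0 * secondary_per_mw * powers
  on_true <- F0 * depletion_efficiency(powers, Is) + sec
  withr::with_seed(seed, {
    on <- on_true * (1 + rnorm(length(powers), 0, noise))
    off <- sec * (1 + rnorm(length(powers), 0, noise))
  })
  structure(data.frame(power_mW = powers, on_mean = on, off_mean = off),
            class = c("saturation_series", "data.frame"))
}

#' Estimate the saturation power from a depletion series
#'
#' Subtracts the depletion-only series from the excitation-on series,
#' clips negatives, normalizes by the zero-power value and fits
#' 1/(1 + I/Is) by least squares; the fitted Is is the depletion power at
#' which fluorescence drops to 50%. If the model fit fails, the monotone
#' interpolation crossing of 0.5 is returned instead.
#'
#' @param series a data frame with columns `power_mW`, `on_mean`,
#'   `off_mean` (at least 5 powers spanning the 50% point).
#' @return list with `Is_mW`, `se`, `ci` (95%), `method`.
#' @export
fit_saturation_power <- function(series) {
  stopifnot(all(c("power_mW", "on_mean", "off_mean") %in% names(series)))
  if (nrow(series) < 5) stop("need at least 5 powers", call. = FALSE)
  I <- series$power_mW
  y <- pmax(series$on_mean - series$off_mean, 0)
  if (y[1] <= 0) {
    stop("series is all zero after on - off subtraction", call. = FALSE)
  }
  norm <- y / y[1]
  if (min(norm) > 0.5) {
    stop("series does not reach saturation: curve never crosses 50%",
         call. = FALSE)
  }
  k <- which(norm <= 0.5)[1]
  Is0 <- if (k == 1) I[2] / 2 else {
    I[k - 1] + (0.5 - norm[k - 1]) * (I[k] - I[k - 1]) /
      (norm[k] - norm[k - 1])
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(norm ~ 1 / (1 + I / Is),
                      start = list(Is = max(Is0, 1e-6)),
                      lower = 1e-9, control = minpack.lm::nls.lm.control(
                        maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(Is_mW = Is0, se = NA_real_, ci = c(NA_real_, NA_real_),
                method = "interpolation"))
  }
  est <- unname(coef(fit)["Is"])
  se <- tryCatch(unname(summary(fit)$coefficients["Is", "Std. Error"]),
                 error = function(e) NA_real_)
  list(Is_mW = est, se = se,
       ci = c(est - 1.96 * se, est + 1.96 * se), method = "model_fit")
}

# ---- resolution estimation --------------------------------------------------

tukey_window <- function(n, alpha = 0.25) {
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / alpha - 2 / alpha + 1)))
  w
}

#' Fourier ring correlation resolution of an image pair
#'
#' Both frames are apodized (Tukey window), Fourier transformed and
#' correlated per one-pixel-wide frequency ring; the curve is smoothed by a
#' 3-ring moving average and the resolution is the inverse of the first
#' frequency at which it falls below 1/7.
#'
#' @param imgA,imgB two `mito_image` frames of the same scene with
#'   independent noise.
#' @param threshold FRC threshold, default 1/7.
#' @return list with `resolution_nm`, `limited` (`TRUE` when the curve never
#'   crosses and only the Nyquist bound 2 x pixel size can be reported),
#'   `no_signal` (`TRUE` when the images do not correlate at any ring — no
#'   resolution estimate exists and `resolution_nm` is `NA`), and the `frc`
#'   curve (spatial frequency in 1/nm vs correlation).
#' @export
estimate_frc_resolution <- function(imgA, imgB, threshold = 1 / 7) {
  stopifnot(inherits(imgA, "mito_image"), inherits(imgB, "mito_image"))
  if (!identical(dim(imgA), dim(imgB))) {
    stop("images must have identical dimensions", call. = FALSE)
  }
  px <- pixel_size_nm(imgA)
  if (!isTRUE(all.equal(px, pixel_size_nm(imgB)))) {
    stop("images must share a pixel size", call. = FALSE)
  }
  n <- min(dim(imgA))
  n <- n - n %% 2L
  a <- img_matrix(imgA)[1:n, 1:n]
  b <- img_matrix(imgB)[1:n, 1:n]
  w <- tukey_window(n)
  W <- outer(w, w)
  FA <- fft((a - mean(a)) * W)
  FB <- fft((b - mean(b)) * W)
  f <- c(0:(n / 2), (n / 2 - 1):1) / n   # cycles per pixel, length n
  ring <- round(sqrt(outer(f^2, f^2, "+")) * n)
  kmax <- n %/% 2L
  num <- rowsum(as.vector(Re(FA * Conj(FB))), as.vector(ring))
  d1 <- rowsum(as.vector(Mod(FA)^2), as.vector(ring))
  d2 <- rowsum(as.vector(Mod(FB)^2), as.vector(ring))
  k <- as.integer(rownames(num))
  keep <- k >= 1 & k <= kmax
  k <- k[keep]
  frc <- as.vector(num[keep] / sqrt(d1[keep] * d2[keep]))
  frc[!is.finite(frc)] <- 0
  sm <- stats::filter(frc, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- frc[is.na(sm)]
  freq_nm <- k / (n * px)
  curve <- data.frame(freq_per_nm = freq_nm, frc = as.numeric(sm))
  if (sm[1] < threshold) {
    return(list(resolution_nm = NA_real_, limited = FALSE, no_signal = TRUE,
                frc = curve))
  }
  below <- which(sm < threshold)
  if (!length(below)) {
    return(list(resolution_nm = 2 * px, limited = TRUE, no_signal = FALSE,
                frc = curve))
  }
  kc <- below[1]
  # linear interpolation of the crossing between ring kc-1 and kc
  f0 <- freq_nm[kc - 1]; f1 <- freq_nm[kc]
  y0 <- sm[kc - 1]; y1 <- sm[kc]
  fc <- f0 + (threshold - y0) / (y1 - y0) * (f1 - f0)
  list(resolution_nm = 1 / fc, limited = FALSE, no_signal = FALSE,
       frc = curve)
}

bilinear_at <- function(m, xi, yi) {
  # xi, yi in pixel units where pixel centre i is at coordinate i
  nx <- nrow(m); ny <- ncol(m)
  x0 <- pmin(pmax(floor(xi), 1L), nx - 1L)
  y0 <- pmin(pmax(floor(yi), 1L), ny - 1L)
  dx <- xi - x0; dy <- yi - y0
  m[cbind(x0, y0)] * (1 - dx) * (1 - dy) +
    m[cbind(x0 + 1L, y0)] * dx * (1 - dy) +
    m[cbind(x0, y0 + 1L)] * (1 - dx) * dy +
    m[cbind(x0 + 1L, y0 + 1L)] * dx * dy
}

#' Measure FWHM of an intensity profile along a line
#'
#' Samples a bilinear-interpolated profile between two points, fits a
#' Gaussian plus constant offset by least squares and reports
#' FWHM = 2 sqrt(2 log 2) sigma.
#'
#' @param img a `mito_image`.
#' @param p0,p1 line endpoints, c(x, y) in micrometres.
#' @param oversample profile samples per pixel.
#' @param width_um averaging width perpendicular to the line (0 for a
#'   single-pixel profile); averaging along a structure suppresses shot
#'   noise in the profile.
#' @return list with `fwhm_nm`, `sigma_nm`, `profile` data frame.
#' @export
measure_fwhm_profile <- function(img, p0, p1, oversample = 2,
                                 width_um = 0) {
  stopifnot(inherits(img, "mito_image"))
  px <- pixel_size_nm(img)
  m <- img_matrix(img)
  L_um <- sqrt(sum((p1 - p0)^2))
  n <- max(8L, ceiling(L_um * 1000 / px * oversample))
  t <- seq(0, 1, length.out = n)
  xs <- (p0[1] + t * (p1[1] - p0[1])) * 1000 / px + 0.5
  ys <- (p0[2] + t * (p1[2] - p0[2])) * 1000 / px + 0.5
  # axis-aligned lines sample exactly at pixel centres so interpolation
  # cannot widen the profile
  if (abs(p1[2] - p0[2]) < 1e-9) {
    xs <- seq(round(xs[1]), round(xs[n]))
    ys <- rep(round(ys[1]), length(xs))
    t <- seq(0, 1, length.out = length(xs))
    n <- length(xs)
  } else if (abs(p1[1] - p0[1]) < 1e-9) {
    ys <- seq(round(ys[1]), round(ys[n]))
    xs <- rep(round(xs[1]), length(ys))
    t <- seq(0, 1, length.out = length(ys))
    n <- length(ys)
  }
  if (any(xs < 1 | xs > nrow(m) | ys < 1 | ys > ncol(m))) {
    stop("line extends outside the image", call. = FALSE)
  }
  u <- (p1 - p0) / sqrt(sum((p1 - p0)^2))
  w_off <- if (width_um > 0) {
    k <- floor(width_um * 1000 / px / 2)
    (-k):k
  } else 0L
  v <- rowMeans(vapply(w_off, function(o) {
    xi <- xs - o * u[2]
    yi <- ys + o * u[1]
    xi <- pmin(pmax(xi, 1), nrow(m))
    yi <- pmin(pmax(yi, 1), ncol(m))
    bilinear_at(m, xi, yi)
  }, numeric(length(xs))))
  s_nm <- sqrt((xs - xs[1])^2 + (ys - ys[1])^2) * px
  if (max(v) - min(v) < 1e-9 * max(abs(v), 1)) {
    stop("flat profile: no peak to fit", call. = FALSE)
  }
  mu0 <- s_nm[which.max(v)]
  b0 <- min(v)
  a0 <- max(v) - b0
  sig0 <- max(diff(range(s_nm)) / 10, px / 2)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ b + a * exp(-(s_nm - mu)^2 / (2 * sig^2)),
                      start = list(b = b0, a = a0, mu = mu0, sig = sig0),
                      lower = c(-Inf, 0, min(s_nm), px / 10),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    stop("Gaussian profile fit did not converge (peak amplitude ",
         signif(a0, 3), ", range ", signif(diff(range(s_nm)), 4), " nm)",
         call. = FALSE)
  }
  sig <- unname(coef(fit)["sig"])
  list(fwhm_nm = 2 * sqrt(2 * log(2)) * sig, sigma_nm = sig,
       profile = data.frame(s_nm = s_nm, value = v))
}
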