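#' Spatial-statistics configuration
#'
#' @param cutoff_um distance cutoff for the below-threshold fraction
#'   (default 0.6).
#' @param bin_width_um histogram bin width.
#' @param test group-comparison test: `"mann-whitney"` or `"ks"`.
#' @param alpha significance level.
#' @return a `stats_config` list.
#' @export
stats_config <- function(cutoff_um = 0.6, bin_width_um = 0.2,
                         test = c("mann-whitney", "ks"), alpha = 0.05) {
  test <- match.arg(test)
  if (cutoff_um <= 0 || bin_width_um <= 0) {
    stop("cutoff and bin width must be positive", call. = FALSE)
  }
  structure(list(cutoff_um = cutoff_um, bin_width_um = bin_width_um,
                 test = test, alpha = alpha), class = "stats_config")
}

#' Nearest-nucleoid distance for each landmark
#'
#' Minimum 2D Euclidean distance from each landmark (tip, branch point or
#' externally supplied site such as a fusion event) to any nucleoid
#' centroid.
#'
#' @param landmarks data frame with `x_um`, `y_um` (or `x`, `y`).
#' @param nucleoids data frame with `x_um`, `y_um` (or `x`, `y`).
#' @return numeric vector of distances (um), one per landmark.
#' @export
nearest_distances <- function(landmarks, nucleoids) {
  get_xy <- function(d) {
    if (all(c("x_um", "y_um") %in% names(d))) {
      cbind(d$x_um, d$y_um)
    } else if (all(c("x", "y") %in% names(d))) {
      cbind(d$x, d$y)
    } else stop("need x/y columns", call. = FALSE)
  }
  lm <- get_xy(landmarks)
  if (is.null(nucleoids) || nrow(nucleoids) == 0) {
    stop("no reference points: empty nucleoid set", call. = FALSE)
  }
  if (nrow(lm) == 0) stop("no landmarks", call. = FALSE)
  nc <- get_xy(nucleoids)
  vapply(seq_len(nrow(lm)), function(i) {
    sqrt(min((nc[, 1] - lm[i, 1])^2 + (nc[, 2] - lm[i, 2])^2))
  }, 1)
}

#' Fraction of distances strictly below a cutoff
#' @param distances numeric vector (um).
#' @param cutoff_um cutoff (um).
#' @return fraction in \[0, 1\].
#' @export
fraction_below <- function(distances, cutoff_um = 0.6) {
  if (!length(distances)) stop("no distances", call. = FALSE)
  mean(distances < cutoff_um)
}

#' Fit an exponential law to nearest distances
#'
#' Maximum-likelihood rate (1/mean), a seeded 95% percentile-bootstrap
#' confidence interval, and a one-sample Kolmogorov-Smirnov statistic
#' against the fitted law.
#'
#' @param distances numeric vector (um), n >= 10, all >= 0.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed for the bootstrap.
#' @return list with `lambda`, `ci`, `ks_stat`, `ks_p`.
#' @export
fit_exponential <- function(distances, n_boot = 1000, seed = 1L) {
  if (length(distances) < 10) stop("need n >= 10 distances", call. = FALSE)
  if (any(distances < 0)) stop("distances must be >= 0", call. = FALSE)
  if (all(distances == 0)) {
    stop("all distances are zero: rate is unbounded", call. = FALSE)
  }
  lambda <- 1 / mean(distances)
  boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      1 / mean(sample(distances, replace = TRUE))
    }, 1)
  })
  ks <- suppressWarnings(ks.test(distances, "pexp", rate = lambda))
  list(lambda = lambda,
       ci = unname(quantile(boot, c(0.025, 0.975))),
       ks_stat = unname(ks$statistic), ks_p = ks$p.value)
}

#' Per-mitochondrion nucleoid area ratios
#'
#' Computes nucleoid/mitochondrion and nucleoid/cristae area ratios per
#' record, then averages within groups. Records with a zero denominator are
#' skipped with a warning and reported in the skip count.
#'
#' @param records data frame from [measure_mitochondria()].
#' @param group optional grouping vector (defaults to one group).
#' @param cfg a [stats_config()] (histogram bin width).
#' @return list with `ratios` (per-record data frame), `group_means`,
#'   `histogram`, `n_skipped`.
#' @export
area_ratios <- function(records, group = NULL, cfg = stats_config()) {
  if (is.null(group)) group <- rep("all", nrow(records))
  ok_mito <- records$mito_area_um2 > 0
  ok_cris <- records$cristae_area_um2 > 0
  n_skip <- sum(!ok_mito)
  if (n_skip > 0) {
    warning(n_skip, " record(s) skipped: zero mitochondrial area")
  }
  ratios <- data.frame(
    label = records$label[ok_mito],
    group = group[ok_mito],
    ratio_mito = records$nucleoid_area_um2[ok_mito] /
      records$mito_area_um2[ok_mito],
    ratio_cristae = ifelse(ok_cris[ok_mito],
                           records$nucleoid_area_um2[ok_mito] /
                             pmax(records$cristae_area_um2[ok_mito],
                                  .Machine$double.eps),
                           NA_real_))
  gm <- aggregate(cbind(ratio_mito, ratio_cristae) ~ group, data = ratios,
                  FUN = function(x) mean(x, na.rm = TRUE), na.action = NULL)
  breaks <- seq(0, max(ratios$ratio_mito, cfg$bin_width_um) +
                  cfg$bin_width_um, by = cfg$bin_width_um)
  h <- hist(ratios$ratio_mito, breaks = breaks, plot = FALSE)
  list(ratios = ratios, group_means = gm,
       histogram = data.frame(mid = h$mids, count = h$counts),
       n_skipped = n_skip)
}

#' Compare two groups of ratios or distances
#'
#' Two-sided Mann-Whitney U by default (exact for n <= 20 per group, else
#' normal approximation with tie correction); Kolmogorov-Smirnov via
#' config. Identical constant samples return p = 1 with a degenerate flag.
#'
#' @param a,b numeric vectors.
#' @param cfg a [stats_config()].
#' @return list with `statistic`, `p_value`, `test`, `degenerate`.
#' @export
compare_groups <- function(a, b, cfg = stats_config()) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty",
                                     call. = FALSE)
  if (length(unique(c(a, b))) == 1L) {
    return(list(statistic = NA_real_, p_value = 1, test = cfg$test,
                degenerate = TRUE))
  }
  if (cfg$test == "mann-whitney") {
    exact <- max(length(a), length(b)) <= 20 &&
      !any(duplicated(c(a, b)))
    w <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
    list(statistic = unname(w$statistic), p_value = w$p.value,
         test = "mann-whitney", degenerate = FALSE)
  } else {
    k <- suppressWarnings(ks.test(a, b))
    list(statistic = unname(k$statistic), p_value = k$p.value,
         test = "ks", degenerate = FALSE)
  }
}

#' Full spatial-statistics report
#'
#' Nearest distances per landmark kind, below-cutoff fractions, the fitted
#' exponential rate, and per-mitochondrion area ratios.
#'
#' @param landmarks data frame with `kind`, `x_um`, `y_um`.
#' @param nucleoids data frame from [detect_nucleoids()].
#' @param records data frame from [measure_mitochondria()] (optional).
#' @param cfg a [stats_config()].
#' @param seed bootstrap seed.
#' @return a `spatial_stats_report` list.
#' @export
spatial_stats_report <- function(landmarks, nucleoids, records = NULL,
                                 cfg = stats_config(), seed = 1L) {
  kinds <- unique(landmarks$kind)
  per_kind <- lapply(kinds, function(k) {
    d <- nearest_distances(landmarks[landmarks$kind == k, , drop = FALSE],
                           nucleoids)
    fit <- if (length(d) >= 10 && any(d > 0)) {
      fit_exponential(d, seed = seed)
    } else NULL
    list(kind = k, distances = d,
         fraction_below = fraction_below(d, cfg$cutoff_um),
         lambda = if (is.null(fit)) NA_real_ else fit$lambda,
         lambda_ci = if (is.null(fit)) c(NA_real_, NA_real_) else fit$ci,
         ks_p = if (is.null(fit)) NA_real_ else fit$ks_p)
  })
  names(per_kind) <- kinds
  ar <- if (!is.null(records) && nrow(records)) area_ratios(records,
                                                            cfg = cfg)
  cls <- if (!is.null(records) && nrow(records)) {
    summarize_population(records)$proportions
  }
  structure(list(landmark_stats = per_kind, area_ratios = ar,
                 class_proportions = cls, config = cfg),
            class = "spatial_stats_report")
}
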