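#' Pipeline configuration
#'
#' Bundles every stage configuration with a global seed and output
#' directory. All lengths are in the units named by the key (nm or um).
#'
#' @param scene a [scene_params()].
#' @param placement a [nucleoid_placement()].
#' @param acquisition_im [acquisition_settings()] for the IM (STED) channel.
#' @param acquisition_mtdna [acquisition_settings()] for the mtDNA
#'   (confocal) channel; `I_dep = 0`.
#' @param Is dye saturation power (mW).
#' @param segmentation a [segmentation_config()].
#' @param rule a [classification_rule()].
#' @param stats a [stats_config()].
#' @param seed global seed; every random stage derives its seed from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(scene = scene_params(),
                            placement = nucleoid_placement(),
                            acquisition_im = acquisition_settings(),
                            acquisition_mtdna =
                              acquisition_settings(I_dep = 0),
                            Is = 0.864,
                            segmentation = segmentation_config(),
                            rule = classification_rule(),
                            stats = stats_config(),
                            seed = 1L) {
  structure(list(scene = scene, placement = placement,
                 acquisition_im = acquisition_im,
                 acquisition_mtdna = acquisition_mtdna, Is = Is,
                 segmentation = segmentation, rule = rule, stats = stats,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: `scene`, `placement`, `acquisition_im`,
#' `acquisition_mtdna`, `Is`, `segmentation`, `rule`, `stats`, `seed`; each
#' section takes the arguments of the corresponding constructor, which
#' validates it.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(fun, args) do.call(fun, if (is.null(args)) list() else
    args)
  pipeline_config(
    scene = build(scene_params, y$scene),
    placement = build(nucleoid_placement, y$placement),
    acquisition_im = build(acquisition_settings, y$acquisition_im),
    acquisition_mtdna = build(acquisition_settings,
                              if (is.null(y$acquisition_mtdna))
                                list(I_dep = 0) else y$acquisition_mtdna),
    Is = if (is.null(y$Is)) 0.864 else y$Is,
    segmentation = build(segmentation_config, y$segmentation),
    rule = build(classification_rule, y$rule),
    stats = build(stats_config, y$stats),
    seed = if (is.null(y$seed)) 1L else y$seed)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(f))
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage,
                  paste(names(c(...)), unlist(c(...)), sep = "=",
                        collapse = " ")))
}

#' Run the full synthetic pipeline
#'
#' Executes simulate -> acquire -> segment -> morphometry -> spatial stats
#' in order and writes all stage outputs plus a run manifest to `out_dir`.
#' In real-image mode (both `im_image` and `mtdna_image` supplied) the
#' first two stages are skipped.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing); `NULL` keeps
#'   results in memory only.
#' @param im_image,mtdna_image optional `mito_image` inputs (real-image
#'   mode).
#' @return list with `scene` (synthetic mode), `images`, `segmentation`,
#'   `records`, `landmarks`, `nucleoids`, `report`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         im_image = NULL, mtdna_image = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  files <- character(0)
  scene <- NULL
  synthetic <- is.null(im_image) || is.null(mtdna_image)
  if (synthetic) {
    scene <- generate_network(config$scene, seed = config$seed)
    scene <- sample_nucleoids(scene, config$placement,
                              seed = config$seed + 1L)
    stage_log("simulate", c(components = nrow(scene$components),
                            cristae = nrow(scene$cristae),
                            nucleoids = nrow(scene$nucleoids)))
    px <- config$acquisition_im$pixel_size_nm
    dens_im <- render_density(scene, "IM", px)
    dens_dna <- render_density(scene, "mtDNA", px)
    im_image <- simulate_acquisition(dens_im, config$acquisition_im,
                                     Is = config$Is,
                                     seed = config$seed + 2L)
    mtdna_image <- simulate_acquisition(dens_dna, config$acquisition_mtdna,
                                        Is = config$Is,
                                        seed = config$seed + 3L)
    stage_log("acquire", c(px_nm = px,
                           fwhm_nm = round(effective_fwhm(
                             config$acquisition_im$d0,
                             config$acquisition_im$I_dep, config$Is), 1)))
  }
  seg <- segment_cristae(im_image, config$segmentation)
  labels <- segment_mitochondria(seg$mask, config$segmentation,
                                 pixel_size_nm(im_image))
  nucleoids <- detect_nucleoids(mtdna_image, config$segmentation, labels)
  stage_log("segment", c(mitochondria = max(labels),
                         nucleoids = nrow(nucleoids)))
  if (max(labels) == 0) {
    stop("pipeline: no mitochondria segmented", call. = FALSE)
  }
  mm <- measure_mitochondria(labels, seg$mask, nucleoids,
                             pixel_size_nm(im_image), config$rule,
                             config$segmentation)
  stage_log("morphometry", c(records = nrow(mm$records),
                             landmarks = nrow(mm$landmarks)))
  report <- spatial_stats_report(mm$landmarks, nucleoids, mm$records,
                                 config$stats, seed = config$seed + 4L)
  stage_log("stats", c(kinds = length(report$landmark_stats)))
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   package_version =
                     as.character(utils::packageVersion("mitosted")),
                   synthetic = synthetic,
                   started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
                   finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  result <- list(scene = scene,
                 images = list(IM = im_image, mtDNA = mtdna_image),
                 segmentation = list(prob = seg$prob, mask = seg$mask,
                                     labels = labels),
                 records = mm$records, landmarks = mm$landmarks,
                 nucleoids = nucleoids, report = report,
                 manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(name, writer) {
      p <- file.path(out_dir, name)
      writer(p)
      files <<- c(files, name)
    }
    if (!is.null(scene)) {
      wr("scene.json", function(p) write_scene_json(scene, p))
    }
    wr("im.tif", function(p) write_image(im_image, p))
    wr("mtdna.tif", function(p) write_image(mtdna_image, p))
    wr("cristae_mask.tif", function(p) {
      write_image(mito_image(matrix(as.numeric(seg$mask), nrow(seg$mask),
                                    ncol(seg$mask)),
                             pixel_size_nm(im_image), "mask"), p)
    })
    wr("mito_labels.tif", function(p) {
      write_image(mito_image(labels + 0, pixel_size_nm(im_image),
                             "labels"), p)
    })
    wr("records.csv", function(p) write.csv(mm$records, p,
                                            row.names = FALSE))
    wr("landmarks.csv", function(p) write.csv(mm$landmarks, p,
                                              row.names = FALSE))
    wr("nucleoids.csv", function(p) write.csv(nucleoids, p,
                                              row.names = FALSE))
    wr("report.json", function(p) {
      slim <- list(
        fractions_below = lapply(report$landmark_stats, function(s) {
          s$fraction_below
        }),
        lambda = lapply(report$landmark_stats, function(s) s$lambda),
        class_proportions = report$class_proportions,
        area_ratio_means = if (!is.null(report$area_ratios)) {
          report$area_ratios$group_means
        })
      jsonlite::write_json(slim, p, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
    })
    manifest$files <- files
    result$manifest <- manifest
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}
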