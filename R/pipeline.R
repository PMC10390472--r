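#' Pipeline configuration
#'
#' A validated bundle of per-stage parameter blocks plus a global seed. Every
#' parameter has a default; physical parameters carry their unit in the name
#' (`_um`, `_nm`, `_px`), which is the package's unit convention -- quantities
#' without a unit suffix are counts or ratios. The configuration serializes
#' losslessly to YAML.
#'
#' Supported stages: `fiber_phantom` (generate and save a network phantom
#' image), `pore_size` (run [pore_size_pipeline()] on the stage input), and
#' `fiber_width` (automatic transects + [fiber_width_report()]).
#'
#' @param seed global integer seed, fanned out per stage via [child_seed()].
#' @param stages named list of stage parameter blocks (may be empty). Unknown
#'   stage names or parameters are schema errors.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, stages = list()) {
  defaults <- list(
    fiber_phantom = list(field_um = c(102.4, 102.4), pixel_size_um = 0.1,
                         gap_rate_per_um = 1 / 3, sigma_nm = 150,
                         modality = "confocal", noise = TRUE),
    pore_size = list(bandpass_small_px = 0.5, bandpass_large_px = 40,
                     rollingball_radius_px = 50,
                     threshold_method = "phansalkar", window_px = 15,
                     min_gaps = 100),
    fiber_width = list(n_transects = 30, length_um = NA_real_)
  )
  if (is.null(names(stages)) && length(stages) > 0)
    stop("`stages` must be a named list")
  bad <- setdiff(names(stages), names(defaults))
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  merged <- lapply(names(stages), function(s) {
    extra <- setdiff(names(stages[[s]]), names(defaults[[s]]))
    if (length(extra))
      stop(sprintf("unknown parameter(s) in stage '%s': %s", s,
                   paste(extra, collapse = ", ")))
    utils::modifyList(defaults[[s]], stages[[s]])
  })
  names(merged) <- names(stages)
  structure(list(seed = as.integer(seed), stages = merged),
            class = "pipeline_config")
}

#' Serialize / deserialize a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  pipeline_config(seed = x$seed, stages = x$stages)
}

#' Run the configured stages and write a manifest
#'
#' Executes the requested stages in dependency order (`fiber_phantom` feeds
#' `pore_size` and `fiber_width`), writes each stage's outputs under
#' `out_dir`, and returns a manifest of outputs with MD5 hashes, so that a
#' fixed configuration and seed reproduce identical files.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return data frame manifest `stage, file, md5` (zero rows for an empty
#'   stage list), with the config attached as attribute.
#' @export
run_pipeline <- function(config, out_dir = tempfile("pipeline")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(stage = character(0), file = character(0),
                         md5 = character(0))
  add <- function(stage, file) {
    manifest <<- rbind(manifest,
                       data.frame(stage = stage, file = file,
                                  md5 = unname(tools::md5sum(file))))
  }
  image <- NULL
  st <- config$stages
  order <- intersect(c("fiber_phantom", "pore_size", "fiber_width"), names(st))
  for (s in order) {
    p <- st[[s]]
    if (s == "fiber_phantom") {
      ph <- fiber_network_phantom(field_um = p$field_um,
                                  pixel_size = p$pixel_size_um,
                                  gap_rate = p$gap_rate_per_um,
                                  sigma_nm = p$sigma_nm,
                                  seed = child_seed(config$seed, s))
      image <- generate_fiber_image(ph, modality = p$modality,
                                    noise = p$noise,
                                    seed = child_seed(config$seed, "render"))
      f <- file.path(out_dir, "phantom.tif")
      write_image(image, f); add(s, f); add(s, paste0(f, ".json"))
      ft <- file.path(out_dir, "phantom_truth.json")
      jsonlite::write_json(list(gap_rate_per_um = ph$gap_rate,
                                sigma_nm = ph$sigma_nm,
                                n_fibers = nrow(ph$fibers),
                                seed = ph$seed),
                           ft, auto_unbox = TRUE, digits = NA)
      add(s, ft)
    } else if (s == "pore_size") {
      if (is.null(image)) stop("pore_size stage requires a fiber_phantom stage")
      cfg <- pore_config(bandpass_small_px = p$bandpass_small_px,
                         bandpass_large_px = p$bandpass_large_px,
                         rollingball_radius_px = p$rollingball_radius_px,
                         threshold_method = p$threshold_method,
                         window_px = p$window_px, min_gaps = p$min_gaps)
      fit <- pore_size_pipeline(image, cfg)
      f <- file.path(out_dir, "pore_size.json")
      jsonlite::write_json(list(lambda_per_um = fit$lambda,
                                pore_size_um = fit$pore_size,
                                n_gaps = fit$n_gaps,
                                ks_statistic = fit$ks_statistic),
                           f, auto_unbox = TRUE, digits = NA)
      add(s, f)
      fg <- file.path(out_dir, "gaps_um.csv")
      utils::write.csv(data.frame(gap_um = fit$gaps), fg, row.names = FALSE)
      add(s, fg)
    } else if (s == "fiber_width") {
      if (is.null(image)) stop("fiber_width stage requires a fiber_phantom stage")
      len <- if (is.na(p$length_um)) NULL else p$length_um
      rois <- auto_transects(image, p$n_transects, length_um = len,
                             seed = child_seed(config$seed, s))
      rep <- fiber_width_report(image, rois)
      f <- file.path(out_dir, "fiber_width.json")
      jsonlite::write_json(list(mean_fwhm_um = rep$mean_fwhm,
                                sd_fwhm_um = rep$sd_fwhm,
                                n_accepted = rep$n_accepted,
                                n_rejected = rep$n_rejected),
                           f, auto_unbox = TRUE, digits = NA)
      add(s, f)
    }
  }
  attr(manifest, "config") <- config
  manifest
}
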