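# Readers/writers and the pipeline runner. Images travel as multi-page TIFF
# (one page per channel) with a JSON sidecar carrying the pixel size,
# channel names and intensity scale; tables as CSV with documented column
# orders; configs and manifests as YAML/JSON.

#' Write an ImageField as multi-page TIFF plus JSON sidecar
#'
#' One TIFF page per channel, 32 bits per sample, intensities scaled to
#' [0, 1]; the scale factor, pixel size, field id and channel names go into
#' the sidecar so that \code{\link{readImageField}} restores the field.
#'
#' @param field an \linkS4class{ImageField}.
#' @param path TIFF output path.
#' @param sidecarPath JSON sidecar path (default \code{paste0(path, ".json")}).
#' @return Invisibly, the sidecar path.
#' @export
writeImageField <- function(field, path, sidecarPath = paste0(path, ".json")) {
  mx <- max(vapply(field@channels, max, numeric(1)), 1e-12)
  tiff::writeTIFF(lapply(field@channels, function(m) m / mx), path,
                  bits.per.sample = 32L)
  meta <- list(field_id = field@fieldId,
               pixel_size_um = field@pixelSize,
               channels = as.list(names(field@channels)),
               intensity_scale = mx)
  jsonlite::write_json(meta, sidecarPath, auto_unbox = TRUE, digits = NA)
  invisible(sidecarPath)
}

#' Read an ImageField from multi-page TIFF plus JSON sidecar
#'
#' The sidecar must provide \code{pixel_size_um} and one channel name per
#' TIFF page; a count mismatch or missing pixel size is an error (pixel size
#' is never silently assumed at analysis time).
#'
#' @param path TIFF path.
#' @param sidecarPath JSON sidecar path.
#' @return An \linkS4class{ImageField}.
#' @export
readImageField <- function(path, sidecarPath = paste0(path, ".json")) {
  if (!file.exists(sidecarPath))
    stop("sidecar not found: ", sidecarPath)
  meta <- jsonlite::read_json(sidecarPath, simplifyVector = TRUE)
  if (is.null(meta$pixel_size_um))
    stop("sidecar lacks pixel_size_um; pixel size is mandatory metadata")
  pages <- tiff::readTIFF(path, all = TRUE)
  chn <- unlist(meta$channels)
  if (length(chn) != length(pages))
    stop(sprintf("sidecar lists %d channels but TIFF has %d pages",
                 length(chn), length(pages)))
  d <- dim(pages[[1]])
  for (i in seq_along(pages))
    if (!identical(dim(pages[[i]]), d))
      stop("TIFF page ", i, " differs in shape from page 1")
  scale <- meta$intensity_scale %||% 1
  channels <- lapply(pages, function(m) m * scale)
  names(channels) <- chn
  ImageField(channels, meta$pixel_size_um,
             fieldId = meta$field_id %||% "field")
}

#' Write a PunctaSet as CSV
#'
#' Stable column order: field_id, channel, id, centroid_x_um, centroid_y_um,
#' area_um2, diameter_um.
#'
#' @param puncta a \linkS4class{PunctaSet}.
#' @param path output CSV path.
#' @return Invisibly, the data.frame written.
#' @importFrom utils write.csv
#' @export
writePunctaCSV <- function(puncta, path) {
  st <- punctaTable(puncta)
  df <- data.frame(field_id = puncta@fieldId, channel = puncta@channel,
                   id = st$id,
                   centroid_x_um = st$centroid_x_um,
                   centroid_y_um = st$centroid_y_um,
                   area_um2 = st$area_um2, diameter_um = st$diameter_um)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read a long behavior CSV with reserved baseline time labels
#'
#' Expected columns: \code{animal_id}, \code{time_h}, \code{threshold_g}
#' plus optional grouping columns. \code{time_h} entries \code{"preCCI"} and
#' \code{"predrug"} are baseline rows; they are folded into
#' \code{e_precci_g} / \code{e_predrug_g} columns on the remaining
#' (numeric-time) rows, the format the %MPE functions expect.
#'
#' @param path CSV path.
#' @return Long behavior data.frame (see \code{\link{mpeTable}}).
#' @importFrom utils read.csv
#' @export
readBehaviorTable <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "time_h", "threshold_g")
  if (!all(need %in% names(raw)))
    stop("behavior CSV must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(raw, raw$animal_id), function(a) {
    pre <- a$threshold_g[a$time_h == "preCCI"]
    prd <- a$threshold_g[a$time_h == "predrug"]
    if (length(pre) != 1 || length(prd) != 1)
      stop("animal ", a$animal_id[1],
           " must have exactly one preCCI and one predrug row")
    rest <- a[!a$time_h %in% c("preCCI", "predrug"), ]
    rest$time_h <- as.numeric(rest$time_h)
    rest$e_precci_g <- pre
    rest$e_predrug_g <- prd
    rest
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

validateRunConfig <- function(config) {
  num0 <- function(x) !is.null(x) && (!is.numeric(x) || x < 0)
  for (key in c("dilation_um", "overlap_threshold", "min_diameter_um",
                "max_diameter_um", "expansion_um"))
    if (num0(config[[key]]))
      stop("config parameter '", key, "' must be a non-negative number")
  if (!is.null(config$overlap_threshold) &&
      (config$overlap_threshold <= 0 || config$overlap_threshold > 1))
    stop("config parameter 'overlap_threshold' must lie in (0, 1]")
  invisible(config)
}

#' Run a seeded simulate-detect-filter-colocalize pipeline
#'
#' Executes the full puncta workflow on one synthetic field and writes all
#' artifacts plus a manifest into \code{outDir}: the field (TIFF + sidecar),
#' the ground truth CSV, one puncta CSV per channel, the colocalization
#' result JSON, and \code{manifest.json} with the config echo, seed,
#' package version, per-stage record counts and md5 checksums of every
#' artifact. Identical config and seed give identical checksums. Invalid
#' parameters (e.g. a negative dilation) are rejected before any compute.
#'
#' @param config named list (or path to a YAML file) with optional entries:
#'   \code{seed}, \code{sim} (arguments to \code{\link{punctaSimParams}}),
#'   \code{threshold_method}, \code{min_diameter_um}, \code{max_diameter_um},
#'   \code{dilation_um}, \code{overlap_threshold}.
#' @param outDir output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @importFrom utils write.csv packageVersion
#' @importFrom tools md5sum
#' @export
runPipeline <- function(config = list(), outDir) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  validateRunConfig(config)
  seed <- as.integer(config$seed %||% 1L)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  simArgs <- config$sim %||% list()
  simArgs$seed <- seed
  if (!is.null(simArgs$fieldSizeUm)) simArgs$fieldSizeUm <-
    as.numeric(simArgs$fieldSizeUm)
  params <- do.call(punctaSimParams, simArgs)
  sim <- simulatePunctaField(params)

  tifPath <- file.path(outDir, "field.tif")
  writeImageField(sim$field, tifPath)
  truthPath <- file.path(outDir, "truth.csv")
  write.csv(sim$truth, truthPath, row.names = FALSE)

  method <- config$threshold_method %||% "otsu"
  counts <- list()
  punctaPaths <- character(0)
  sets <- list()
  for (ch in channelNames(sim$field)) {
    ps <- detectPuncta(sim$field, ch, method,
                       fixedValue = config$fixed_threshold)
    ps <- filterBySize(ps,
                       config$min_diameter_um %||% 0.2,
                       config$max_diameter_um %||% 3.0)
    sets[[ch]] <- ps
    p <- file.path(outDir, paste0("puncta_", ch, ".csv"))
    writePunctaCSV(ps, p)
    punctaPaths <- c(punctaPaths, p)
    counts[[paste0("puncta_", ch)]] <- nPuncta(ps)
  }

  chn <- channelNames(sim$field)
  res <- colocalize(sets[[chn[2]]], sets[[chn[1]]],
                    overlapThreshold = config$overlap_threshold %||% 0.5,
                    dilationUm = config$dilation_um %||% 0.1,
                    roi = fullFieldROI(sim$field))
  colocPath <- file.path(outDir, "colocal.json")
  jsonlite::write_json(list(
    field_id = res@fieldId,
    reference_channel = res@referenceChannel,
    other_channel = res@otherChannel,
    dilation_um = res@dilationUm,
    overlap_threshold = res@overlapThreshold,
    n_reference = res@nReference,
    n_colocalized = res@nColocalized,
    colocalized_fraction = res@colocalizedFraction,
    colocalized_density_per_um2 = res@colocalizedDensity,
    reference_density_per_um2 = res@referenceDensity,
    roi = res@roiLabel), colocPath, auto_unbox = TRUE, digits = NA)
  counts$truth_objects <- nrow(sim$truth)
  counts$colocalized <- res@nColocalized

  artifacts <- c(tifPath, paste0(tifPath, ".json"), truthPath,
                 punctaPaths, colocPath)
  manifest <- list(
    package_version = as.character(packageVersion("spincolocal")),
    seed = seed,
    config = config,
    counts = counts,
    checksums = as.list(md5sum(artifacts)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
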