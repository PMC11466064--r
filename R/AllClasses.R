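#' @import methods
NULL

#' ImageField: a multichannel 2D fluorescence image with physical pixel size
#'
#' The unit of all image analysis in this package. Channels are named 2D
#' intensity matrices of equal shape; rows are y, columns are x. Physical
#' coordinates are 0-based pixel indices times \code{pixelSize} (micrometers
#' per pixel).
#'
#' @slot fieldId character identifier of the field.
#' @slot channels named list of numeric matrices, all the same dimension,
#'   finite and non-negative.
#' @slot pixelSize physical pixel size in micrometers per pixel (> 0).
#' @export
setClass("ImageField",
  representation(fieldId = "character", channels = "list",
                 pixelSize = "numeric"))

setValidity("ImageField", function(object) {
  ch <- object@channels
  if (length(ch) == 0L) return("at least one channel is required")
  if (is.null(names(ch)) || any(!nzchar(names(ch))) || anyDuplicated(names(ch)))
    return("channels must have unique non-empty names")
  if (!all(vapply(ch, is.matrix, logical(1))))
    return("all channels must be matrices")
  d <- dim(ch[[1]])
  for (nm in names(ch)) {
    m <- ch[[nm]]
    if (!identical(dim(m), d))
      return(sprintf("channel '%s' differs in shape", nm))
    if (!all(is.finite(m)) || any(m < 0))
      return(sprintf("channel '%s' has non-finite or negative intensities", nm))
  }
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("pixelSize must be a single positive number (um/pixel)")
  TRUE
})

#' Construct an ImageField
#'
#' @param channels named list of numeric intensity matrices (equal shape).
#' @param pixelSize micrometers per pixel.
#' @param fieldId identifier string.
#' @return An \linkS4class{ImageField}.
#' @examples
#' f <- ImageField(list(a2 = matrix(0, 64, 64)), pixelSize = 0.15)
#' @export
ImageField <- function(channels, pixelSize, fieldId = "field") {
  new("ImageField", fieldId = fieldId, channels = channels,
      pixelSize = as.numeric(pixelSize))
}

#' ROIMask: a binary region-of-interest aligned to an ImageField
#'
#' Typical labels in dorsal horn work are \code{"superficial_dorsal_horn"}
#' and \code{"deep_dorsal_horn"}; any custom label is allowed. Area in
#' square micrometers is derived from the pixel count.
#'
#' @slot label character region label.
#' @slot mask logical matrix, same shape as the field it belongs to.
#' @slot pixelSize micrometers per pixel of the parent field.
#' @export
setClass("ROIMask",
  representation(label = "character", mask = "matrix", pixelSize = "numeric"))

setValidity("ROIMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be a logical matrix")
  if (!any(object@mask)) return("ROI has zero area")
  if (object@pixelSize <= 0) return("pixelSize must be positive")
  TRUE
})

#' Construct an ROIMask
#'
#' @param mask logical matrix (TRUE = inside the region).
#' @param pixelSize micrometers per pixel.
#' @param label region label.
#' @export
ROIMask <- function(mask, pixelSize, label = "custom") {
  new("ROIMask", label = label, mask = mask, pixelSize = as.numeric(pixelSize))
}

#' Full-field ROI covering an entire ImageField
#' @param field an \linkS4class{ImageField}.
#' @param label region label.
#' @export
fullFieldROI <- function(field, label = "full_field") {
  d <- dim(field@channels[[1]])
  ROIMask(matrix(TRUE, d[1], d[2]), field@pixelSize, label)
}

#' Rectangular ROI given physical bounds in micrometers
#'
#' Bounds are inclusive on pixel centers: a pixel with 0-based index (i, j)
#' lies at (j * pixelSize, i * pixelSize).
#'
#' @param field an \linkS4class{ImageField}.
#' @param xlim,ylim numeric length-2 bounds in micrometers.
#' @param label region label.
#' @export
rectROI <- function(field, xlim, ylim, label = "custom") {
  d <- dim(field@channels[[1]])
  px <- field@pixelSize
  y <- (seq_len(d[1]) - 1) * px
  x <- (seq_len(d[2]) - 1) * px
  mask <- outer(y >= ylim[1] & y <= ylim[2], x >= xlim[1] & x <= xlim[2], "&")
  ROIMask(mask, px, label)
}

#' PunctaSet: labeled fluorescent objects from one channel of one field
#'
#' Each punctum is a connected (8-connectivity) set of pixels with derived
#' physical measurements: area (pixel count times squared pixel size) and
#' equivalent circular diameter \eqn{2\sqrt{A/\pi}}. After morphological
#' dilation (see \code{\link{dilatePuncta}}) pixel sets of distinct puncta
#' may overlap; freshly detected sets are pairwise disjoint.
#'
#' @slot fieldId,channel provenance of the objects.
#' @slot dim integer field dimensions (rows, cols).
#' @slot pixelSize micrometers per pixel.
#' @slot pixels list of integer matrices (row, col), one per punctum, 1-based.
#' @slot stats data.frame with columns id, area_um2, diameter_um,
#'   centroid_x_um, centroid_y_um.
#' @slot provenance list recording the threshold method, its value, any
#'   dilation applied, and warning flags.
#' @export
setClass("PunctaSet",
  representation(fieldId = "character", channel = "character",
                 dim = "integer", pixelSize = "numeric",
                 pixels = "list", stats = "data.frame",
                 provenance = "list"))

setValidity("PunctaSet", function(object) {
  if (length(object@pixels) != nrow(object@stats))
    return("pixels and stats disagree in length")
  if (anyDuplicated(object@stats$id)) return("punctum ids must be unique")
  if (object@pixelSize <= 0) return("pixelSize must be positive")
  for (p in object@pixels) {
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) == 0L)
      return("each pixel set must be a non-empty 2-column matrix")
    if (anyDuplicated((p[, 2] - 1) * object@dim[1] + p[, 1]))
      return("duplicate pixels within a punctum")
  }
  TRUE
})

#' ColocalizationResult: object-based colocalization of two puncta channels
#'
#' A reference punctum is colocalized when, after dilating both channels,
#' the fraction of its own (dilated) pixels shared with the union of
#' other-channel puncta strictly exceeds \code{overlapThreshold}.
#'
#' @slot fieldId field identifier.
#' @slot referenceChannel,otherChannel channel names.
#' @slot dilationUm dilation radius applied to both channels (um).
#' @slot overlapThreshold overlap fraction that must be exceeded.
#' @slot nReference,nColocalized counts (within the ROI when one was given).
#' @slot overlapFractions per-reference-punctum covered fraction.
#' @slot colocalized logical per reference punctum.
#' @slot inROI logical per reference punctum (all TRUE without an ROI).
#' @slot colocalizedFraction nColocalized / nReference (NA when nReference 0).
#' @slot colocalizedDensity colocalized count per um^2 of ROI (NA without ROI).
#' @slot referenceDensity reference count per um^2 of ROI (NA without ROI).
#' @slot roiLabel label of the ROI used, or NA.
#' @slot flags character vector of condition flags (e.g. "empty_reference").
#' @export
setClass("ColocalizationResult",
  representation(fieldId = "character",
                 referenceChannel = "character", otherChannel = "character",
                 dilationUm = "numeric", overlapThreshold = "numeric",
                 nReference = "integer", nColocalized = "integer",
                 overlapFractions = "numeric", colocalized = "logical",
                 inROI = "logical",
                 colocalizedFraction = "numeric",
                 colocalizedDensity = "numeric",
                 referenceDensity = "numeric",
                 roiLabel = "character", flags = "character"))

setValidity("ColocalizationResult", function(object) {
  if (object@nColocalized > object@nReference)
    return("nColocalized exceeds nReference")
  f <- object@colocalizedFraction
  if (!is.na(f) && (f < 0 || f > 1))
    return("colocalizedFraction outside [0, 1]")
  TRUE
})

#' GroupComparison: two-group summary with percent reduction and t test
#'
#' @slot measure name of the compared measure.
#' @slot groups labels of the control and test group.
#' @slot means,sems,n group means, standard errors of the mean, sizes.
#' @slot percentReduction 100 (control - test) / control, one decimal.
#' @slot tStatistic,df,pValue unpaired two-sided t test (pooled variance).
#' @slot flags e.g. "degenerate" when the test is undefined.
#' @export
setClass("GroupComparison",
  representation(measure = "character", groups = "character",
                 means = "numeric", sems = "numeric", n = "integer",
                 percentReduction = "numeric",
                 tStatistic = "numeric", df = "numeric", pValue = "numeric",
                 flags = "character"))

#' HillFit: fitted Hill concentration-response parameters
#'
#' Model: response = baseline + Emax * c^nH / (c^nH + EC50^nH), with the
#' baseline optionally fixed to zero. Estimates are obtained by nonlinear
#' least squares with EC50 parameterized on the log10 scale.
#'
#' @slot estimates named numeric: ec50 (um), hill, emax, baseline.
#' @slot se standard errors for the same parameters (NA if unavailable).
#' @slot fixedBaseline logical, was the baseline fixed to zero.
#' @slot converged logical convergence flag.
#' @slot rss residual sum of squares.
#' @slot nObs number of fitted points.
#' @slot message diagnostic text for non-converged fits.
#' @export
setClass("HillFit",
  representation(estimates = "numeric", se = "numeric",
                 fixedBaseline = "logical", converged = "logical",
                 rss = "numeric", nObs = "integer", message = "character"))

setValidity("HillFit", function(object) {
  est <- object@estimates
  need <- c("ec50", "hill", "emax", "baseline")
  if (!all(need %in% names(est))) return("estimates must name ec50, hill, emax, baseline")
  if (object@converged && (est[["ec50"]] <= 0 || est[["hill"]] <= 0))
    return("converged fit must have positive ec50 and hill")
  TRUE
})
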