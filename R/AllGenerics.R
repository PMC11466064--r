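# Accessor generics. Slot access from user code is discouraged; these are
# the supported surface.

#' @rdname accessors
#' @param object an object of one of the package classes.
#' @export
setGeneric("fieldId", function(object) standardGeneric("fieldId"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @param channel channel name.
#' @export
setGeneric("channelData", function(object, channel) standardGeneric("channelData"))
#' @rdname accessors
#' @export
setGeneric("areaUm2", function(object) standardGeneric("areaUm2"))
#' @rdname accessors
#' @export
setGeneric("nPuncta", function(object) standardGeneric("nPuncta"))
#' @rdname accessors
#' @export
setGeneric("punctaTable", function(object) standardGeneric("punctaTable"))
#' @rdname accessors
#' @export
setGeneric("pixelSets", function(object) standardGeneric("pixelSets"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("colocalizedFraction", function(object) standardGeneric("colocalizedFraction"))
#' @rdname accessors
#' @export
setGeneric("isColocalized", function(object) standardGeneric("isColocalized"))
#' @rdname accessors
#' @export
setGeneric("overlapFractions", function(object) standardGeneric("overlapFractions"))
#' @rdname accessors
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))

#' Accessors for spincolocal classes
#'
#' Small read-only accessors: \code{fieldId}, \code{pixelSize},
#' \code{channelNames}/\code{channelData} (ImageField), \code{areaUm2}
#' (ROIMask), \code{nPuncta}/\code{punctaTable}/\code{pixelSets}/
#' \code{provenance} (PunctaSet), \code{colocalizedFraction}/
#' \code{isColocalized}/\code{overlapFractions} (ColocalizationResult),
#' \code{converged} (HillFit).
#'
#' @name accessors
NULL

#' @rdname accessors
setMethod("fieldId", "ImageField", function(object) object@fieldId)
#' @rdname accessors
setMethod("fieldId", "PunctaSet", function(object) object@fieldId)
#' @rdname accessors
setMethod("pixelSize", "ImageField", function(object) object@pixelSize)
#' @rdname accessors
setMethod("pixelSize", "PunctaSet", function(object) object@pixelSize)
#' @rdname accessors
setMethod("pixelSize", "ROIMask", function(object) object@pixelSize)
#' @rdname accessors
setMethod("channelNames", "ImageField", function(object) names(object@channels))
#' @rdname accessors
setMethod("channelData", "ImageField", function(object, channel) {
  if (!channel %in% names(object@channels))
    stop("no channel named '", channel, "'")
  object@channels[[channel]]
})
#' @rdname accessors
setMethod("areaUm2", "ROIMask", function(object)
  sum(object@mask) * object@pixelSize^2)
#' @rdname accessors
setMethod("nPuncta", "PunctaSet", function(object) length(object@pixels))
#' @rdname accessors
setMethod("punctaTable", "PunctaSet", function(object) object@stats)
#' @rdname accessors
setMethod("pixelSets", "PunctaSet", function(object) object@pixels)
#' @rdname accessors
setMethod("provenance", "PunctaSet", function(object) object@provenance)
#' @rdname accessors
setMethod("colocalizedFraction", "ColocalizationResult",
  function(object) object@colocalizedFraction)
#' @rdname accessors
setMethod("isColocalized", "ColocalizationResult",
  function(object) object@colocalized)
#' @rdname accessors
setMethod("overlapFractions", "ColocalizationResult",
  function(object) object@overlapFractions)
#' @rdname accessors
setMethod("converged", "HillFit", function(object) object@converged)

#' @describeIn accessors fitted parameters of a Hill fit
#' @param object a \linkS4class{HillFit}.
#' @importFrom stats coef
#' @export
setMethod("coef", "HillFit", function(object) object@estimates)

setMethod("show", "ImageField", function(object) {
  d <- dim(object@channels[[1]])
  cat(sprintf("ImageField '%s': %d x %d px (%.1f x %.1f um), %.4g um/px\n",
              object@fieldId, d[1], d[2],
              d[1] * object@pixelSize, d[2] * object@pixelSize,
              object@pixelSize))
  cat("channels:", paste(names(object@channels), collapse = ", "), "\n")
})

setMethod("show", "ROIMask", function(object) {
  cat(sprintf("ROIMask '%s': %.1f um^2 (%d px)\n",
              object@label, areaUm2(object), sum(object@mask)))
})

setMethod("show", "PunctaSet", function(object) {
  cat(sprintf("PunctaSet: %d puncta, channel '%s', field '%s'\n",
              nPuncta(object), object@channel, object@fieldId))
  pv <- object@provenance
  if (!is.null(pv$method))
    cat(sprintf("  threshold: %s (%.4g)\n", pv$method,
                if (is.null(pv$threshold)) NA_real_ else pv$threshold))
  if (!is.null(pv$dilated_um) && pv$dilated_um > 0)
    cat(sprintf("  dilated by %.3g um\n", pv$dilated_um))
  if (isTRUE(pv$size_filtered))
    cat(sprintf("  size filter: [%.3g, %.3g] um\n",
                pv$min_diameter_um, pv$max_diameter_um))
  if (nPuncta(object) > 0) {
    cat(sprintf("  diameter (um): median %.3g, range [%.3g, %.3g]\n",
                stats::median(object@stats$diameter_um),
                min(object@stats$diameter_um), max(object@stats$diameter_um)))
  }
})

setMethod("show", "ColocalizationResult", function(object) {
  cat(sprintf("ColocalizationResult: %s vs %s (field '%s')\n",
              object@referenceChannel, object@otherChannel, object@fieldId))
  cat(sprintf("  dilation %.3g um, overlap > %.2g\n",
              object@dilationUm, object@overlapThreshold))
  cat(sprintf("  %d / %d reference puncta colocalized (fraction %.3f)\n",
              object@nColocalized, object@nReference,
              object@colocalizedFraction))
  if (!is.na(object@colocalizedDensity))
    cat(sprintf("  ROI '%s': colocalized density %.4g /um^2 (reference %.4g)\n",
                object@roiLabel, object@colocalizedDensity,
                object@referenceDensity))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison of %s\n", object@measure))
  for (i in 1:2)
    cat(sprintf("  %s: mean %.4g +/- %.3g SEM (n = %d)\n",
                object@groups[i], object@means[i], object@sems[i], object@n[i]))
  cat(sprintf("  percent reduction: %.1f%%\n", object@percentReduction))
  if (is.na(object@pValue)) {
    cat("  t test undefined (", paste(object@flags, collapse = ", "), ")\n")
  } else {
    cat(sprintf("  unpaired t test: t = %.3g, df = %g, p = %.3g\n",
                object@tStatistic, object@df, object@pValue))
  }
})

setMethod("show", "HillFit", function(object) {
  e <- object@estimates; s <- object@se
  cat("HillFit", if (object@fixedBaseline) "(baseline fixed to 0)" else "", "\n")
  for (p in c("ec50", "hill", "emax", "baseline")) {
    if (p == "baseline" && object@fixedBaseline) next
    cat(sprintf("  %-8s %.6g", p, e[[p]]))
    if (is.finite(s[[p]])) cat(sprintf("  (SE %.3g)", s[[p]]))
    cat("\n")
  }
  cat(sprintf("  %s, RSS %.4g, n = %d\n",
              if (object@converged) "converged" else
                paste("NOT converged:", object@message),
              object@rss, object@nObs))
})
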