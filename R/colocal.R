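# Object-based colocalization: dilation of both channels followed by the
# >50% area-overlap rule, with colocalized-cluster densities per ROI and
# the percent-reduction group statistic.

# Integer offsets of a rasterized disk of the given radius (in pixels).
diskOffsets <- function(radiusPx) {
  d <- ceiling(radiusPx)
  g <- expand.grid(dr = -d:d, dc = -d:d)
  g <- g[g$dr^2 + g$dc^2 <= radiusPx^2 + 1e-9, , drop = FALSE]
  as.matrix(g)
}

# Dilate one pixel set by the offset stencil, clipping to the field bounds.
dilatePixelSet <- function(pix, offsets, nr, nc) {
  rr <- outer(pix[, 1], offsets[, 1], "+")
  cc <- outer(pix[, 2], offsets[, 2], "+")
  keep <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  lin <- unique((cc[keep] - 1L) * nr + rr[keep])
  cbind(row = (lin - 1L) %% nr + 1L, col = (lin - 1L) %/% nr + 1L)
}

#' Morphologically dilate every punctum by a physical radius
#'
#' Each punctum's pixel set is dilated by a disk of radius
#' \code{dilationUm}. The default 0.1 um is the standard enlargement that
#' prevents edge exclusions in object-based colocalization. When the radius
#' is positive but smaller than one pixel it is rounded up to one pixel, so
#' a nonzero dilation always has an effect. Dilated puncta may overlap each
#' other; ids and order are preserved.
#'
#' @param puncta a \linkS4class{PunctaSet}.
#' @param dilationUm dilation radius in micrometers (>= 0; 0 is identity).
#' @return A \linkS4class{PunctaSet} with dilated pixel sets and updated
#'   area/diameter statistics; \code{provenance(x)$dilated_um} records the
#'   total dilation applied.
#' @export
dilatePuncta <- function(puncta, dilationUm = 0.1) {
  stopifnot(dilationUm >= 0)
  if (dilationUm == 0 || nPuncta(puncta) == 0) {
    prov <- puncta@provenance
    prov$dilated_um <- (prov$dilated_um %||% 0) + dilationUm
    puncta@provenance <- prov
    return(puncta)
  }
  rPx <- dilationUm / puncta@pixelSize
  if (rPx < 1) rPx <- 1
  offs <- diskOffsets(rPx)
  nr <- puncta@dim[1]; nc <- puncta@dim[2]
  pixels <- lapply(puncta@pixels, dilatePixelSet, offsets = offs,
                   nr = nr, nc = nc)
  prov <- puncta@provenance
  prov$dilated_um <- (prov$dilated_um %||% 0) + dilationUm
  new("PunctaSet", fieldId = puncta@fieldId, channel = puncta@channel,
      dim = puncta@dim, pixelSize = puncta@pixelSize,
      pixels = pixels,
      stats = punctaStats(pixels, puncta@pixelSize, ids = puncta@stats$id),
      provenance = prov)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Object-based colocalization between two puncta channels
#'
#' Both channels are dilated by \code{dilationUm}. A reference punctum is
#' colocalized when the fraction of its own (dilated) pixels shared with the
#' union of all other-channel (dilated) puncta strictly exceeds
#' \code{overlapThreshold}; each reference punctum is counted at most once
#' no matter how many partners it touches, and a punctum straddling two
#' partners sums its covered pixels. Overlap is measured relative to the
#' reference punctum's area (the documented convention); the operation is
#' therefore asymmetric in its arguments, and both directions can be
#' computed by swapping them.
#'
#' When an ROI is supplied, counts and densities are restricted to reference
#' puncta whose pre-dilation centroid lies inside it (other-channel puncta
#' outside the ROI still count as overlap partners).
#'
#' An empty reference set yields a result with \code{nReference = 0}, an
#' undefined (NA) colocalized fraction and the flag \code{"empty_reference"}.
#'
#' @param reference,other \linkS4class{PunctaSet}s from the same field.
#' @param overlapThreshold overlap fraction that must be exceeded (in (0, 1]).
#' @param dilationUm dilation radius applied to both channels (um).
#' @param roi optional \linkS4class{ROIMask} for densities.
#' @return A \linkS4class{ColocalizationResult}.
#' @examples
#' sim <- simulatePunctaField(punctaSimParams(trueColocFraction = 0.5, seed = 2))
#' a2 <- filterBySize(detectPuncta(sim$field, "a2"))
#' geph <- filterBySize(detectPuncta(sim$field, "geph"))
#' colocalize(a2, geph, roi = fullFieldROI(sim$field))
#' @export
colocalize <- function(reference, other, overlapThreshold = 0.5,
                       dilationUm = 0.1, roi = NULL) {
  stopifnot(overlapThreshold > 0, overlapThreshold <= 1, dilationUm >= 0)
  if (!identical(reference@dim, other@dim) ||
      reference@pixelSize != other@pixelSize)
    stop("reference and other puncta must come from the same field geometry")
  flags <- character(0)

  refD <- dilatePuncta(reference, dilationUm)
  othD <- dilatePuncta(other, dilationUm)
  nr <- reference@dim[1]; nc <- reference@dim[2]

  unionMask <- matrix(FALSE, nr, nc)
  for (p in othD@pixels) unionMask[p] <- TRUE

  nRef <- nPuncta(reference)
  fracs <- numeric(nRef)
  for (i in seq_len(nRef)) {
    p <- refD@pixels[[i]]
    fracs[i] <- sum(unionMask[p]) / nrow(p)
  }
  coloc <- fracs > overlapThreshold

  inROI <- rep(TRUE, nRef)
  roiLabel <- NA_character_
  colocDens <- NA_real_; refDens <- NA_real_
  if (!is.null(roi)) {
    if (!identical(as.integer(reference@dim), as.integer(dim(roi@mask))))
      stop("ROI mask shape does not match the puncta field")
    inROI <- centroidInROI(reference, roi)
    a <- areaUm2(roi)
    colocDens <- sum(coloc & inROI) / a
    refDens <- sum(inROI) / a
    roiLabel <- roi@label
  }

  nReference <- sum(inROI)
  nColocalized <- sum(coloc & inROI)
  if (nReference == 0) flags <- c(flags, "empty_reference")

  new("ColocalizationResult",
      fieldId = reference@fieldId,
      referenceChannel = reference@channel, otherChannel = other@channel,
      dilationUm = dilationUm, overlapThreshold = overlapThreshold,
      nReference = as.integer(nReference),
      nColocalized = as.integer(nColocalized),
      overlapFractions = fracs, colocalized = coloc, inROI = inROI,
      colocalizedFraction = if (nReference > 0) nColocalized / nReference
                            else NA_real_,
      colocalizedDensity = colocDens, referenceDensity = refDens,
      roiLabel = roiLabel, flags = flags)
}

#' Percent reduction of a mean measure relative to control
#'
#' \eqn{100 (control - test) / control}, rounded to one decimal (the
#' presentation convention for cluster-density reductions). Negative values
#' indicate an increase and are reported as negative reductions.
#'
#' @param controlMean,testMean group means; \code{controlMean} must be > 0.
#' @param digits decimals to round to (default 1); \code{NA} for no rounding.
#' @return Percent reduction.
#' @examples
#' percentReduction(0.23, 0.005)  # 97.8
#' @export
percentReduction <- function(controlMean, testMean, digits = 1) {
  if (!is.finite(controlMean) || controlMean <= 0)
    stop("controlMean must be a positive number")
  out <- 100 * (controlMean - testMean) / controlMean
  if (is.na(digits)) out else round(out, digits)
}

#' Compare a measure between two groups of sections or animals
#'
#' Returns group means, standard errors of the mean, the percent reduction
#' of the test mean relative to the control mean, and an unpaired two-sided
#' t test (pooled variance). When both groups have zero variance and equal
#' means the test is undefined and flagged rather than raised as an error.
#'
#' @param control,test numeric vectors of per-section (or per-animal) values,
#'   at least 2 each.
#' @param measure name of the compared measure.
#' @param labels length-2 character group labels (control first).
#' @return A \linkS4class{GroupComparison}.
#' @importFrom stats t.test sd var
#' @export
compareGroups <- function(control, test, measure = "density_per_um2",
                          labels = c("control", "test")) {
  stopifnot(length(control) >= 2, length(test) >= 2)
  means <- c(mean(control), mean(test))
  sems <- c(sd(control) / sqrt(length(control)),
            sd(test) / sqrt(length(test)))
  flags <- character(0)
  tt <- tryCatch(t.test(control, test, var.equal = TRUE),
                 error = function(e) NULL)
  if (is.null(tt)) {
    flags <- c(flags, if (means[1] == means[2]) "degenerate" else "zero_variance")
    tstat <- NA_real_; df <- NA_real_; p <- NA_real_
  } else {
    tstat <- unname(tt$statistic); df <- unname(tt$parameter)
    p <- tt$p.value
  }
  pr <- if (means[1] > 0) percentReduction(means[1], means[2]) else NA_real_
  if (is.na(pr)) flags <- c(flags, "control_mean_not_positive")
  new("GroupComparison", measure = measure, groups = labels,
      means = means, sems = sems,
      n = c(length(control), length(test)),
      percentReduction = pr,
      tStatistic = tstat, df = df, pValue = p, flags = flags)
}

#' Bonferroni correction for a declared number of tests
#'
#' Multiplies each p value by \code{nTests} and caps at 1 (via
#' \code{\link[stats]{p.adjust}}).
#'
#' @param p numeric vector of raw p values.
#' @param nTests declared number of tests (>= length(p)).
#' @importFrom stats p.adjust
#' @export
adjustBonferroni <- function(p, nTests = length(p)) {
  p.adjust(p, method = "bonferroni", n = nTests)
}
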