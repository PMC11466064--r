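# Puncta detection: thresholding + 8-connected labeling + physical size
# measurements. The size filter and density computations live here too.

# 8-connected labeling. EBImage::bwlabel is 4-connected; diagonally adjacent
# 4-components are merged with a union-find pass to match the particle-
# analysis convention used throughout the package.
label8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  n <- max(lab)
  if (n == 0) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- NULL
  if (nr > 1 && nc > 1) {
    pairs <- rbind(
      cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
      cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1])))   # up-right
    pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  if (!is.null(pairs) && nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n), find, numeric(1))
  newid <- match(root, sort(unique(root)))
  lab[lab > 0] <- newid[lab[lab > 0]]
  lab
}

# Triangle threshold on a 256-bin histogram: line from the histogram peak to
# the far end of the longer tail; threshold at maximal perpendicular distance.
triangleThreshold <- function(x, levels = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(NA_real_)
  brk <- seq(rng[1], rng[2], length.out = levels + 1L)
  counts <- tabulate(findInterval(x, brk, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = levels)
  peak <- which.max(counts)
  lo <- which(counts > 0)[1]
  hi <- rev(which(counts > 0))[1]
  # pick the longer tail (the side with more dynamic range past the peak)
  if ((hi - peak) >= (peak - lo)) { a <- peak; b <- hi } else { a <- peak; b <- lo }
  if (a == b) return(mean(rng))
  idx <- seq(a, b)
  # distance from (i, counts[i]) to the line (a, counts[a]) -- (b, counts[b])
  dx <- b - a; dy <- counts[b] - counts[a]
  dist <- abs(dy * (idx - a) - dx * (counts[idx] - counts[a])) /
    sqrt(dx^2 + dy^2)
  t_bin <- idx[which.max(dist)]
  (brk[t_bin] + brk[t_bin + 1L]) / 2
}

thresholdValue <- function(img, method, fixedValue = NULL) {
  switch(method,
    otsu = {
      rng <- range(img)
      EBImage::otsu(EBImage::Image(img), range = rng, levels = 256L)
    },
    triangle = triangleThreshold(img),
    fixed = {
      if (is.null(fixedValue) || !is.finite(fixedValue))
        stop("threshold method 'fixed' requires a finite fixedValue")
      fixedValue
    },
    stop("unknown threshold method '", method, "'"))
}

# Build a PunctaSet from a label matrix.
punctaFromLabels <- function(lab, fieldId, channel, pixelSize, provenance) {
  n <- max(lab)
  pixels <- vector("list", n)
  if (n > 0) {
    idx <- which(lab > 0)
    rr <- (idx - 1L) %% nrow(lab) + 1L
    cc <- (idx - 1L) %/% nrow(lab) + 1L
    ids <- lab[idx]
    ord <- order(ids)
    sp <- split(ord, ids[ord])
    for (i in seq_len(n))
      pixels[[i]] <- cbind(row = rr[sp[[i]]], col = cc[sp[[i]]])
  }
  stats <- punctaStats(pixels, pixelSize)
  new("PunctaSet", fieldId = fieldId, channel = channel,
      dim = dim(lab), pixelSize = pixelSize,
      pixels = pixels, stats = stats, provenance = provenance)
}

punctaStats <- function(pixels, pixelSize, ids = seq_along(pixels)) {
  n <- length(pixels)
  area <- vapply(pixels, nrow, integer(1)) * pixelSize^2
  data.frame(
    id = as.integer(ids),
    area_um2 = as.numeric(area),
    diameter_um = 2 * sqrt(as.numeric(area) / pi),
    # physical coordinates: 0-based pixel index * pixel size
    centroid_x_um = vapply(pixels, function(p) mean(p[, 2] - 1), numeric(1)) * pixelSize,
    centroid_y_um = vapply(pixels, function(p) mean(p[, 1] - 1), numeric(1)) * pixelSize
  )[seq_len(n), , drop = FALSE]
}

#' Detect fluorescent puncta in one channel
#'
#' Thresholds the channel (intensity strictly above the threshold is
#' foreground) and labels connected components under 8-connectivity. No size
#' filtering is applied here; see \code{\link{filterBySize}}. The threshold
#' method and value are recorded in the result's provenance.
#'
#' A constant channel cannot support a data-driven threshold; in that case an
#' empty set is returned with the provenance flag \code{"constant_image"}
#' rather than an error.
#'
#' @param field an \linkS4class{ImageField}.
#' @param channel channel name.
#' @param method one of \code{"otsu"} (default), \code{"triangle"},
#'   \code{"fixed"}.
#' @param fixedValue threshold value when \code{method = "fixed"}.
#' @return A \linkS4class{PunctaSet}.
#' @examples
#' sim <- simulatePunctaField(punctaSimParams(seed = 1))
#' ps <- detectPuncta(sim$field, "a2")
#' nPuncta(ps)
#' @export
detectPuncta <- function(field, channel, method = c("otsu", "triangle", "fixed"),
                         fixedValue = NULL) {
  method <- match.arg(method)
  img <- channelData(field, channel)
  if (diff(range(img)) == 0 && method != "fixed") {
    prov <- list(method = method, threshold = NA_real_, dilated_um = 0,
                 flags = "constant_image")
    return(punctaFromLabels(matrix(0L, nrow(img), ncol(img)),
                            field@fieldId, channel, field@pixelSize, prov))
  }
  thr <- thresholdValue(img, method, fixedValue)
  mask <- img > thr
  lab <- label8(mask)
  prov <- list(method = method, threshold = as.numeric(thr), dilated_um = 0,
               flags = character(0))
  punctaFromLabels(lab, field@fieldId, channel, field@pixelSize, prov)
}

#' Filter puncta by equivalent circular diameter
#'
#' Retains puncta whose equivalent diameter lies in the inclusive interval
#' \code{[minDiameterUm, maxDiameterUm]}; the defaults exclude objects
#' strictly below 0.2 um and strictly above 3 um in diameter, the standard
#' size cutoff for immunohistochemical cluster analysis. Order and ids are
#' preserved; the operation is idempotent.
#'
#' @param puncta a \linkS4class{PunctaSet}.
#' @param minDiameterUm,maxDiameterUm retention bounds in micrometers.
#' @return A filtered \linkS4class{PunctaSet}.
#' @export
filterBySize <- function(puncta, minDiameterUm = 0.2, maxDiameterUm = 3.0) {
  stopifnot(minDiameterUm > 0, maxDiameterUm > minDiameterUm)
  d <- puncta@stats$diameter_um
  keep <- d >= minDiameterUm & d <= maxDiameterUm
  prov <- puncta@provenance
  prov$size_filtered <- TRUE
  prov$min_diameter_um <- minDiameterUm
  prov$max_diameter_um <- maxDiameterUm
  new("PunctaSet", fieldId = puncta@fieldId, channel = puncta@channel,
      dim = puncta@dim, pixelSize = puncta@pixelSize,
      pixels = puncta@pixels[keep],
      stats = puncta@stats[keep, , drop = FALSE],
      provenance = prov)
}

# Which puncta have their centroid inside the ROI (pixel whose center is
# nearest the centroid).
centroidInROI <- function(puncta, roi) {
  if (nPuncta(puncta) == 0) return(logical(0))
  px <- puncta@pixelSize
  st <- puncta@stats
  rr <- pmin(pmax(round(st$centroid_y_um / px) + 1, 1), nrow(roi@mask))
  cc <- pmin(pmax(round(st$centroid_x_um / px) + 1, 1), ncol(roi@mask))
  roi@mask[cbind(rr, cc)]
}

#' Cluster density of puncta within a region of interest
#'
#' Counts puncta whose centroid lies inside the ROI (centroid-in-ROI rule,
#' which avoids double counting across region boundaries) and divides by the
#' ROI area in square micrometers.
#'
#' @param puncta a \linkS4class{PunctaSet}.
#' @param roi an \linkS4class{ROIMask} aligned to the same field.
#' @return Density in puncta per square micrometer.
#' @export
clusterDensity <- function(puncta, roi) {
  if (!identical(as.integer(puncta@dim), as.integer(dim(roi@mask))))
    stop("ROI mask shape does not match the puncta field")
  a <- areaUm2(roi)
  if (a <= 0) stop("ROI has zero area")
  sum(centroidInROI(puncta, roi)) / a
}
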