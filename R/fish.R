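# RNAscope-style cell calling: nucleus segmentation, nuclear-area expansion,
# per-cell dot counting with the >=3-dot positivity rule, and coexpression
# tabulation stratified by region.

#' Segment nuclei from the nuclear-stain channel
#'
#' Thresholds the nuclear channel, labels 8-connected components and drops
#' components below a minimum area (debris). Touching nuclei are merged into
#' one component by plain labeling; this is the documented behavior (no
#' watershed splitting), so synthetic fields keep nuclei disjoint.
#'
#' @param field an \linkS4class{ImageField}.
#' @param nuclearChannel channel name of the nuclear stain (e.g. DAPI).
#' @param method threshold method, as in \code{\link{detectPuncta}}.
#' @param fixedValue threshold when \code{method = "fixed"}.
#' @param minAreaUm2 minimum nucleus area in square micrometers.
#' @return A \linkS4class{PunctaSet} whose objects are nuclei.
#' @export
segmentNuclei <- function(field, nuclearChannel,
                          method = c("otsu", "triangle", "fixed"),
                          fixedValue = NULL, minAreaUm2 = 10) {
  method <- match.arg(method)
  ps <- detectPuncta(field, nuclearChannel, method, fixedValue)
  keep <- ps@stats$area_um2 >= minAreaUm2
  new("PunctaSet", fieldId = ps@fieldId, channel = ps@channel,
      dim = ps@dim, pixelSize = ps@pixelSize,
      pixels = ps@pixels[keep],
      stats = ps@stats[keep, , drop = FALSE],
      provenance = c(ps@provenance, list(min_area_um2 = minAreaUm2)))
}

#' Expand a nucleus pixel set by a physical radius
#'
#' Morphological dilation of a single pixel set by a disk of radius
#' \code{expansionUm} (default 2 um, the standard cytoplasmic margin for
#' transcript-dot counting), clipped to the field bounds.
#'
#' @param nucleus integer matrix of (row, col) pixel coordinates, 1-based.
#' @param expansionUm expansion radius in micrometers (>= 0; 0 is identity).
#' @param pixelSizeUm micrometers per pixel.
#' @param dim integer field dimensions (rows, cols).
#' @return Expanded pixel set, same format as the input.
#' @export
expandNucleus <- function(nucleus, expansionUm = 2.0, pixelSizeUm, dim) {
  stopifnot(expansionUm >= 0, pixelSizeUm > 0)
  if (expansionUm == 0) return(nucleus)
  rPx <- expansionUm / pixelSizeUm
  if (rPx < 1) rPx <- 1
  dilatePixelSet(nucleus, diskOffsets(rPx), dim[1], dim[2])
}

#' Is a cell positive for a marker given its dot count?
#'
#' The positivity rule: a cell is positive when at least \code{minPuncta}
#' (default 3) marker dots fall within its expanded nuclear area.
#'
#' @param nDots integer vector of per-cell dot counts.
#' @param minPuncta minimum dot count for positivity.
#' @return Logical vector.
#' @export
callPositive <- function(nDots, minPuncta = 3L) {
  stopifnot(minPuncta >= 1)
  nDots >= minPuncta
}

#' Count marker dots per cell within expanded nuclear areas
#'
#' Dots are assigned by the centroid-in-area rule. A dot falling inside the
#' overlapping expanded areas of several cells is assigned to the cell whose
#' nucleus centroid is nearest (ties go to the lower cell id); a dot outside
#' every expanded area is unassigned.
#'
#' @param nuclei a \linkS4class{PunctaSet} of nuclei (see
#'   \code{\link{segmentNuclei}}).
#' @param dots a \linkS4class{PunctaSet} of marker dots, detected without any
#'   size filter (transcript dots are below the immunohistochemical size
#'   cutoff).
#' @param expansionUm expansion radius in micrometers.
#' @return Integer vector of dot counts, one per nucleus.
#' @export
countDotsPerCell <- function(nuclei, dots, expansionUm = 2.0) {
  nCells <- nPuncta(nuclei)
  counts <- integer(nCells)
  if (nCells == 0 || nPuncta(dots) == 0) return(counts)
  px <- nuclei@pixelSize
  nr <- nuclei@dim[1]; nc <- nuclei@dim[2]
  # ownership map: for every pixel, the owning cell id (contested pixels go
  # to the nearest nucleus centroid, tie -> lower id)
  owner <- matrix(0L, nr, nc)
  bestD2 <- matrix(Inf, nr, nc)
  cx <- nuclei@stats$centroid_x_um / px  # 0-based pixel units
  cy <- nuclei@stats$centroid_y_um / px
  for (i in seq_len(nCells)) {
    exp_i <- expandNucleus(nuclei@pixels[[i]], expansionUm, px,
                           c(nr, nc))
    d2 <- (exp_i[, 1] - 1 - cy[i])^2 + (exp_i[, 2] - 1 - cx[i])^2
    lin <- (exp_i[, 2] - 1L) * nr + exp_i[, 1]
    take <- d2 < bestD2[lin]   # strict: ties keep the earlier (lower) id
    owner[lin[take]] <- i
    bestD2[lin[take]] <- d2[take]
  }
  st <- dots@stats
  rr <- pmin(pmax(round(st$centroid_y_um / px) + 1, 1), nr)
  cc <- pmin(pmax(round(st$centroid_x_um / px) + 1, 1), nc)
  own <- owner[cbind(rr, cc)]
  tab <- tabulate(own[own > 0], nbins = nCells)
  as.integer(tab)
}

#' Call cells for a panel of markers on one field
#'
#' Runs nucleus segmentation (unless a \code{nuclei} set is supplied),
#' detects dots on every marker channel without a size filter, counts dots
#' per cell within the expanded nuclear area and applies the positivity
#' rule. Cells are assigned to regions by their nucleus centroid.
#'
#' @param field an \linkS4class{ImageField}.
#' @param nuclearChannel name of the nuclear-stain channel.
#' @param markerChannels character vector of marker channel names.
#' @param regions optional list of \linkS4class{ROIMask}s; a cell's region is
#'   the label of the first ROI containing its nucleus centroid (cells in no
#'   ROI get region \code{NA}).
#' @param expansionUm nuclear expansion radius (um).
#' @param minPuncta positivity threshold (dots).
#' @param nuclei optional pre-segmented nuclei \linkS4class{PunctaSet}.
#' @param ... passed to \code{\link{segmentNuclei}}.
#' @return A data.frame of cell calls: \code{cell_id}, \code{region},
#'   \code{centroid_x_um}, \code{centroid_y_um}, then per marker
#'   \code{n_<marker>} (count) and \code{pos_<marker>} (logical).
#' @export
callCells <- function(field, nuclearChannel, markerChannels, regions = NULL,
                      expansionUm = 2.0, minPuncta = 3L, nuclei = NULL, ...) {
  if (is.null(nuclei)) nuclei <- segmentNuclei(field, nuclearChannel, ...)
  nCells <- nPuncta(nuclei)
  st <- punctaTable(nuclei)
  region <- rep(NA_character_, nCells)
  if (!is.null(regions)) {
    for (roi in regions) {
      inside <- centroidInROI(nuclei, roi)
      region[is.na(region) & inside] <- roi@label
    }
  }
  out <- data.frame(cell_id = st$id, region = region,
                    centroid_x_um = st$centroid_x_um,
                    centroid_y_um = st$centroid_y_um)
  for (mk in markerChannels) {
    dots <- detectPuncta(field, mk)
    n <- countDotsPerCell(nuclei, dots, expansionUm)
    out[[paste0("n_", mk)]] <- n
    out[[paste0("pos_", mk)]] <- callPositive(n, minPuncta)
  }
  out
}

#' Coexpression fractions per region
#'
#' For each requested (region, conditioning marker, target marker) triple,
#' computes the fraction of cells positive for the conditioning marker that
#' are also positive for the target marker. With a \code{section} column in
#' \code{calls}, per-section fractions are summarized as mean and SD across
#' sections. A zero denominator yields an NA fraction with a flag rather
#' than an error.
#'
#' @param calls data.frame of cell calls (see \code{\link{callCells}}); must
#'   contain \code{region} and \code{pos_<marker>} columns, optionally
#'   \code{section}.
#' @param spec data.frame with columns \code{region}, \code{conditioning},
#'   \code{target}. Use region \code{"all"} to pool regions.
#' @return A data.frame with columns region, conditioning, target,
#'   n_double_positive, n_conditioning, fraction, and (when sections are
#'   present) section_mean and section_sd, plus a logical
#'   \code{undefined} flag.
#' @importFrom stats sd
#' @export
coexpressionFractions <- function(calls, spec) {
  stopifnot(all(c("region", "conditioning", "target") %in% names(spec)))
  hasSection <- "section" %in% names(calls)
  res <- vector("list", nrow(spec))
  for (i in seq_len(nrow(spec))) {
    rg <- spec$region[i]; cm <- spec$conditioning[i]; tm <- spec$target[i]
    colC <- paste0("pos_", cm); colT <- paste0("pos_", tm)
    if (!all(c(colC, colT) %in% names(calls)))
      stop("calls lack positivity columns for markers '", cm, "'/'", tm, "'")
    sub <- if (identical(rg, "all")) calls else calls[!is.na(calls$region) &
                                                      calls$region == rg, ]
    den <- sum(sub[[colC]])
    num <- sum(sub[[colC]] & sub[[colT]])
    frac <- if (den > 0) num / den else NA_real_
    row <- data.frame(region = rg, conditioning = cm, target = tm,
                      n_double_positive = num, n_conditioning = den,
                      fraction = frac, undefined = den == 0)
    if (hasSection) {
      bySec <- vapply(split(sub, sub$section), function(s) {
        d <- sum(s[[colC]])
        if (d > 0) sum(s[[colC]] & s[[colT]]) / d else NA_real_
      }, numeric(1))
      bySec <- bySec[!is.na(bySec)]
      row$section_mean <- if (length(bySec)) mean(bySec) else NA_real_
      row$section_sd <- if (length(bySec) > 1) sd(bySec) else NA_real_
    }
    res[[i]] <- row
  }
  do.call(rbind, res)
}
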