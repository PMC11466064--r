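# Seeded synthetic-data generators with carried ground truth. These emulate
# the statistical structure of the study data: two-channel puncta fields
# with a controllable true colocalization fraction, multiplex-FISH fields of
# nuclei with per-marker expression probabilities and per-fluorophore
# background dot rates, Hill-shaped dose-response tables, and CCI-like
# behavioral cohorts.

defaultChannelSpec <- function(density_per_um2 = 0.15, diameter_mean_um = 0.6,
                               diameter_sd_um = 0.1, peak_intensity = 1,
                               background_level = 0.1, noise_sd = 0.02) {
  list(density_per_um2 = density_per_um2, diameter_mean_um = diameter_mean_um,
       diameter_sd_um = diameter_sd_um, peak_intensity = peak_intensity,
       background_level = background_level, noise_sd = noise_sd)
}

#' Parameters for the two-channel puncta field simulator
#'
#' Defaults emulate confocal imaging of inhibitory-synapse markers in the
#' dorsal horn: 0.15 um pixels (typical 40x confocal sampling), an 80 x 80
#' um field, puncta of mean diameter 0.6 um (SD 0.1) so the truth survives
#' the 0.2-3 um size filter, densities of the order of the measured cluster
#' densities (0.15/um^2, below the generator's 20% within-channel overlap
#' guard), and a true colocalization fraction of 0.5.
#'
#' @param fieldSizeUm numeric length-2, field width and height (um).
#' @param pixelSizeUm micrometers per pixel.
#' @param channels named list of exactly two channel specs (see the fields
#'   of \code{defaultChannelSpec}): the first is the scaffold/"other"
#'   channel, the second the reference channel whose objects may be placed
#'   concentric with first-channel objects.
#' @param trueColocFraction fraction of second-channel objects placed
#'   concentric with (and the same nominal diameter as) a first-channel
#'   object.
#' @param seed integer seed.
#' @return A validated list of class \code{"PunctaSimParams"}.
#' @export
punctaSimParams <- function(fieldSizeUm = c(80, 80), pixelSizeUm = 0.15,
                            channels = list(geph = defaultChannelSpec(),
                                            a2 = defaultChannelSpec()),
                            trueColocFraction = 0.5, seed = 1L) {
  p <- list(fieldSizeUm = fieldSizeUm, pixelSizeUm = pixelSizeUm,
            channels = channels, trueColocFraction = trueColocFraction,
            seed = as.integer(seed))
  class(p) <- "PunctaSimParams"
  validatePunctaSimParams(p)
  p
}

validatePunctaSimParams <- function(p) {
  stopifnot(length(p$fieldSizeUm) == 2, all(p$fieldSizeUm > 0),
            p$pixelSizeUm > 0,
            length(p$channels) == 2, !is.null(names(p$channels)),
            p$trueColocFraction >= 0, p$trueColocFraction <= 1)
  dimsPx <- floor(p$fieldSizeUm / p$pixelSizeUm)
  if (any(dimsPx < 64))
    stop("field must be at least 64 x 64 pixels")
  for (nm in names(p$channels)) {
    ch <- p$channels[[nm]]
    if (ch$density_per_um2 < 0) stop("densities must be >= 0")
    if (ch$diameter_mean_um <= 0 || ch$diameter_sd_um < 0)
      stop("diameter parameters must be positive")
    if (ch$noise_sd < 0 || ch$background_level < 0)
      stop("noise and background must be >= 0")
    # reject densities at which within-channel object overlap would corrupt
    # the ground truth: P(overlap) = 1 - exp(-density * pi * d^2) > 0.2
    pOv <- 1 - exp(-ch$density_per_um2 * pi * ch$diameter_mean_um^2)
    if (pOv > 0.2)
      stop(sprintf(
        "channel '%s': expected object overlap %.0f%% exceeds 20%% (unusable truth)",
        nm, 100 * pOv))
  }
  invisible(p)
}

# Add a Gaussian-profile spot (FWHM = diameter) to an image, in place.
renderSpot <- function(img, xUm, yUm, diameterUm, peak, pixelSize) {
  sigma <- diameterUm / (2 * sqrt(2 * log(2))) / pixelSize  # px
  xPx <- xUm / pixelSize; yPx <- yUm / pixelSize            # 0-based
  d <- ceiling(4 * sigma)
  r0 <- max(1, floor(yPx) + 1 - d); r1 <- min(nrow(img), floor(yPx) + 1 + d)
  c0 <- max(1, floor(xPx) + 1 - d); c1 <- min(ncol(img), floor(xPx) + 1 + d)
  if (r0 > r1 || c0 > c1) return(img)
  ry <- (r0:r1) - 1 - yPx
  cx <- (c0:c1) - 1 - xPx
  img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] +
    peak * exp(-outer(ry^2, cx^2, "+") / (2 * sigma^2))
  img
}

subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483647)
}

#' Simulate a two-channel puncta field with ground truth
#'
#' Object counts per channel are Poisson with mean density x area; centers
#' are uniform over the field, except that a \code{trueColocFraction} share
#' of second-channel objects is placed concentric with a randomly chosen
#' first-channel object, sharing its nominal diameter (a colocalized pair
#' represents one synaptic structure imaged in two channels). Each object is
#' rendered as an isotropic 2D Gaussian spot whose FWHM equals its nominal
#' diameter, on a constant background with additive Gaussian noise.
#' Identical parameters and seed give bit-identical output; each channel
#' draws from its own deterministic sub-stream.
#'
#' @param params a \code{\link{punctaSimParams}} object.
#' @return list with \code{field} (an \linkS4class{ImageField}),
#'   \code{truth} (data.frame: channel, x_um, y_um, diameter_um,
#'   is_colocalized) and \code{params}.
#' @importFrom stats rpois runif rnorm
#' @export
simulatePunctaField <- function(params) {
  validatePunctaSimParams(params)
  px <- params$pixelSizeUm
  nc <- as.integer(floor(params$fieldSizeUm[1] / px))  # width  -> columns
  nr <- as.integer(floor(params$fieldSizeUm[2] / px))  # height -> rows
  area <- (nc * px) * (nr * px)
  chNames <- names(params$channels)
  truthList <- list()
  channels <- list()

  # channel 1 objects
  set.seed(subSeed(params$seed, 1))
  ch1 <- params$channels[[1]]
  n1 <- rpois(1, ch1$density_per_um2 * area)
  x1 <- runif(n1, 0, nc * px); y1 <- runif(n1, 0, nr * px)
  d1 <- pmax(rnorm(n1, ch1$diameter_mean_um, ch1$diameter_sd_um), 0.05)

  # channel 2 objects: a trueColocFraction share concentric with channel 1
  set.seed(subSeed(params$seed, 2))
  ch2 <- params$channels[[2]]
  n2 <- rpois(1, ch2$density_per_um2 * area)
  nColoc <- round(params$trueColocFraction * n2)
  if (nColoc > 0 && n1 == 0)
    stop("cannot place colocalized objects: first channel is empty")
  partner <- if (nColoc > 0)
    sample(n1, nColoc, replace = nColoc > n1) else integer(0)
  nFree <- n2 - nColoc
  x2 <- c(x1[partner], runif(nFree, 0, nc * px))
  y2 <- c(y1[partner], runif(nFree, 0, nr * px))
  d2 <- c(d1[partner], pmax(rnorm(nFree, ch2$diameter_mean_um,
                                  ch2$diameter_sd_um), 0.05))
  isColoc2 <- c(rep(TRUE, nColoc), rep(FALSE, nFree))
  ch1Coloc <- seq_len(n1) %in% partner

  xs <- list(x1, x2); ys <- list(y1, y2); ds <- list(d1, d2)
  colocs <- list(ch1Coloc, isColoc2)
  for (k in 1:2) {
    spec <- params$channels[[k]]
    set.seed(subSeed(params$seed, 10 + k))  # rendering noise sub-stream
    img <- matrix(spec$background_level, nr, nc)
    nk <- length(xs[[k]])
    for (i in seq_len(nk))
      img <- renderSpot(img, xs[[k]][i], ys[[k]][i], ds[[k]][i],
                        spec$peak_intensity, px)
    if (spec$noise_sd > 0)
      img <- img + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    img[img < 0] <- 0
    channels[[chNames[k]]] <- img
    truthList[[k]] <- if (nk > 0) data.frame(
      channel = chNames[k], x_um = xs[[k]], y_um = ys[[k]],
      diameter_um = ds[[k]], is_colocalized = colocs[[k]]) else NULL
  }
  truth <- do.call(rbind, truthList)
  if (is.null(truth))
    truth <- data.frame(channel = character(0), x_um = numeric(0),
                        y_um = numeric(0), diameter_um = numeric(0),
                        is_colocalized = logical(0))
  field <- ImageField(channels, px,
                      fieldId = sprintf("sim_puncta_seed%d", params$seed))
  list(field = field, truth = truth, params = params)
}

#' Parameters for the multiplex-FISH field simulator
#'
#' Defaults emulate transcript-dot fields of dorsal horn tissue: disjoint
#' disk nuclei of 4 um radius, per-marker Bernoulli expression, Poisson dot
#' counts (mean 15) placed inside the expanded nuclear area for positive
#' cells, and a small per-fluorophore uniform background dot rate chosen so
#' that the expected background count per expanded area stays below one dot
#' (different fluorophores show different background levels; the positivity
#' rule, not background subtraction, absorbs it).
#'
#' @param nCells number of cells.
#' @param fieldSizeUm field width and height in micrometers.
#' @param pixelSizeUm micrometers per pixel.
#' @param nucleusRadiusUm nucleus radius (um).
#' @param expressionProbability named numeric vector, marker -> probability
#'   a cell expresses it (in [0, 1]).
#' @param dotsPerPositiveCell Poisson mean of dots in a positive cell.
#' @param backgroundDotsPerUm2 per-fluorophore uniform background dot rate.
#' @param dotDiameterUm rendered dot FWHM (um).
#' @param nucleusIntensity,dotPeakIntensity,backgroundLevel,noiseSd rendering
#'   parameters.
#' @param regionLabels optional character vector of length \code{nCells}
#'   naming each cell's region; by default cells in the upper half of the
#'   field are labeled \code{"superficial_dorsal_horn"} and the rest
#'   \code{"deep_dorsal_horn"}.
#' @param seed integer seed.
#' @return A validated list of class \code{"FishSimParams"}.
#' @export
fishSimParams <- function(nCells = 40, fieldSizeUm = c(100, 100),
                          pixelSizeUm = 0.25, nucleusRadiusUm = 4,
                          expressionProbability = c(gabrg1 = 0.44,
                                                    slc32a1 = 0.6),
                          dotsPerPositiveCell = 15,
                          backgroundDotsPerUm2 = 0.004,
                          dotDiameterUm = 0.5,
                          nucleusIntensity = 1, dotPeakIntensity = 1,
                          backgroundLevel = 0.05, noiseSd = 0.01,
                          regionLabels = NULL, seed = 1L) {
  p <- list(nCells = as.integer(nCells), fieldSizeUm = fieldSizeUm,
            pixelSizeUm = pixelSizeUm, nucleusRadiusUm = nucleusRadiusUm,
            expressionProbability = expressionProbability,
            dotsPerPositiveCell = dotsPerPositiveCell,
            backgroundDotsPerUm2 = backgroundDotsPerUm2,
            dotDiameterUm = dotDiameterUm,
            nucleusIntensity = nucleusIntensity,
            dotPeakIntensity = dotPeakIntensity,
            backgroundLevel = backgroundLevel, noiseSd = noiseSd,
            regionLabels = regionLabels, seed = as.integer(seed))
  class(p) <- "FishSimParams"
  validateFishSimParams(p)
  p
}

validateFishSimParams <- function(p) {
  stopifnot(p$nCells >= 0, all(p$fieldSizeUm > 0), p$pixelSizeUm > 0,
            p$nucleusRadiusUm > 0, p$dotsPerPositiveCell >= 0,
            p$backgroundDotsPerUm2 >= 0)
  ep <- p$expressionProbability
  if (length(ep) == 0 || is.null(names(ep)))
    stop("expressionProbability must be a named vector")
  if (any(ep < 0 | ep > 1)) stop("expression probabilities must lie in [0, 1]")
  if (!is.null(p$regionLabels) && length(p$regionLabels) != p$nCells)
    stop("regionLabels must have one entry per cell")
  # nucleus packing feasibility: reject configurations that force overlap.
  # Each placed nucleus excludes a disk of radius (2r + margin)/2 around its
  # center; random sequential placement jams near 55% coverage of that
  # exclusion area, so stay below 45%.
  area <- prod(p$fieldSizeUm)
  rExcl <- (2 * p$nucleusRadiusUm + 2.5) / 2
  if (p$nCells * pi * rExcl^2 > 0.45 * area)
    stop("nucleus packing too dense: cells would be forced to overlap")
  invisible(p)
}

#' Simulate a multiplex-FISH field with ground truth
#'
#' Places disjoint disk nuclei (rejection sampling with a safety margin),
#' draws per-cell marker positivity from the expression probabilities, and
#' for each positive cell places a Poisson number of transcript dots inside
#' the expanded nuclear area; background dots are uniform over the field at
#' the per-fluorophore rate. Channels: one nuclear stain (\code{"dapi"})
#' plus one dot channel per marker. Identical parameters and seed give
#' bit-identical output.
#'
#' @param params a \code{\link{fishSimParams}} object.
#' @return list with \code{field} (\linkS4class{ImageField}), \code{truth}
#'   (data.frame: cell_id, x_um, y_um, radius_um, region, and one logical
#'   \code{pos_<marker>} column per marker) and \code{params}.
#' @importFrom stats rbinom rpois runif rnorm
#' @export
simulateFishField <- function(params) {
  validateFishSimParams(params)
  px <- params$pixelSizeUm
  nc <- as.integer(floor(params$fieldSizeUm[1] / px))
  nr <- as.integer(floor(params$fieldSizeUm[2] / px))
  W <- nc * px; H <- nr * px
  r <- params$nucleusRadiusUm
  n <- params$nCells

  set.seed(subSeed(params$seed, 1))
  # nucleus centers: pairwise distance >= 2r + 2.5 um, fully inside field
  margin <- r + 0.5
  cx <- numeric(0); cy <- numeric(0)
  tries <- 0L; maxTries <- 400L * max(n, 1L)
  while (length(cx) < n) {
    if (tries >= maxTries)
      stop("could not place disjoint nuclei; packing too dense")
    tries <- tries + 1L
    x <- runif(1, margin, W - margin); y <- runif(1, margin, H - margin)
    if (length(cx) == 0 ||
        all((cx - x)^2 + (cy - y)^2 >= (2 * r + 2.5)^2)) {
      cx <- c(cx, x); cy <- c(cy, y)
    }
  }
  region <- params$regionLabels
  if (is.null(region))
    region <- ifelse(cy < H / 2, "superficial_dorsal_horn",
                     "deep_dorsal_horn")

  markers <- names(params$expressionProbability)
  truth <- data.frame(cell_id = seq_len(n), x_um = cx, y_um = cy,
                      radius_um = rep(r, n), region = region)

  # nuclear channel: filled disks
  xPx <- (seq_len(nc) - 1) * px; yPx <- (seq_len(nr) - 1) * px
  dapi <- matrix(params$backgroundLevel, nr, nc)
  for (i in seq_len(n)) {
    rIdx <- which(abs(yPx - cy[i]) <= r); cIdx <- which(abs(xPx - cx[i]) <= r)
    d2 <- outer((yPx[rIdx] - cy[i])^2, (xPx[cIdx] - cx[i])^2, "+")
    blk <- dapi[rIdx, cIdx, drop = FALSE]
    blk[d2 <= r^2] <- params$backgroundLevel + params$nucleusIntensity
    dapi[rIdx, cIdx] <- blk
  }
  channels <- list(dapi = dapi)

  for (k in seq_along(markers)) {
    mk <- markers[k]
    set.seed(subSeed(params$seed, 100 + k))
    pos <- if (n > 0) rbinom(n, 1, params$expressionProbability[[mk]]) == 1
           else logical(0)
    img <- matrix(params$backgroundLevel, nr, nc)
    # cell-associated dots, uniform in a disk comfortably inside the
    # 2 um-expanded nuclear area
    rDot <- r + 1.5
    for (i in which(pos)) {
      nd <- rpois(1, params$dotsPerPositiveCell)
      if (nd > 0) {
        ang <- runif(nd, 0, 2 * pi); rad <- rDot * sqrt(runif(nd))
        dx <- pmin(pmax(cx[i] + rad * cos(ang), 0), W - px)
        dy <- pmin(pmax(cy[i] + rad * sin(ang), 0), H - px)
        for (j in seq_len(nd))
          img <- renderSpot(img, dx[j], dy[j], params$dotDiameterUm,
                            params$dotPeakIntensity, px)
      }
    }
    nBg <- rpois(1, params$backgroundDotsPerUm2 * W * H)
    if (nBg > 0) {
      bx <- runif(nBg, 0, W - px); by <- runif(nBg, 0, H - px)
      for (j in seq_len(nBg))
        img <- renderSpot(img, bx[j], by[j], params$dotDiameterUm,
                          params$dotPeakIntensity, px)
    }
    if (params$noiseSd > 0)
      img <- img + matrix(rnorm(nr * nc, 0, params$noiseSd), nr, nc)
    img[img < 0] <- 0
    channels[[mk]] <- img
    truth[[paste0("pos_", mk)]] <- pos
  }

  field <- ImageField(channels, px,
                      fieldId = sprintf("sim_fish_seed%d", params$seed))
  list(field = field, truth = truth, params = params)
}

#' Simulate a Hill-shaped concentration-response table
#'
#' Responses are the Hill equation at the true parameters plus additive
#' Gaussian noise.
#'
#' @param ec50,hill,emax,baseline true Hill parameters.
#' @param concentrations positive concentrations (um), sorted ascending.
#' @param noiseSd Gaussian noise SD in response units.
#' @param replicates replicate measurements per concentration.
#' @param seed integer seed (NULL leaves the RNG stream untouched when
#'   \code{noiseSd = 0}).
#' @return data.frame with columns concentration_uM, response, replicate_id.
#' @importFrom stats rnorm
#' @export
simulateDoseResponse <- function(ec50, hill, emax, concentrations,
                                 noiseSd = 0, replicates = 1L,
                                 baseline = 0, seed = NULL) {
  stopifnot(all(is.finite(concentrations)), all(concentrations > 0),
            !is.unsorted(concentrations), noiseSd >= 0, replicates >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  conc <- rep(concentrations, times = replicates)
  repId <- rep(seq_len(replicates), each = length(concentrations))
  mu <- hillResponse(conc, ec50, hill, emax, baseline)
  resp <- if (noiseSd > 0) mu + rnorm(length(mu), 0, noiseSd) else mu
  data.frame(concentration_uM = conc, response = resp, replicate_id = repId)
}

#' Simulate a CCI-like behavioral cohort
#'
#' Per animal: a pre-injury threshold around \code{baselineG}, a post-injury
#' (pre-drug) threshold reduced by \code{cciDropFraction}, and post-drug
#' thresholds whose expected percent maximal possible effect equals
#' \code{drugEffectMpe} at the peak window (time points up to 1 h) and
#' decays exponentially afterwards (time constant 1.5 h). With zero noise
#' the window-mean percent MPE is exactly \code{100 * drugEffectMpe}.
#'
#' @param n animals in the cohort.
#' @param baselineG mean pre-injury withdrawal threshold (grams).
#' @param cciDropFraction fractional threshold drop after injury (in [0, 1]).
#' @param drugEffectMpe peak drug effect as a fraction of the maximal
#'   possible effect (in [0, 1]).
#' @param timepointsH post-drug measurement times (hours).
#' @param noiseSdG Gaussian measurement noise, grams.
#' @param group group label attached to every row.
#' @param seed integer seed.
#' @return Long data.frame: animal_id, group, time_h, threshold_g,
#'   e_precci_g, e_predrug_g.
#' @importFrom stats rnorm
#' @export
simulateBehaviorCohort <- function(n = 7, baselineG = 5.5,
                                   cciDropFraction = 0.6,
                                   drugEffectMpe = 0.7,
                                   timepointsH = c(0.5, 1, 2, 3, 4),
                                   noiseSdG = 0.3, group = "treated",
                                   seed = 1L) {
  stopifnot(n >= 1, baselineG > 0,
            cciDropFraction >= 0, cciDropFraction <= 1,
            drugEffectMpe >= 0, drugEffectMpe <= 1, noiseSdG >= 0)
  set.seed(as.integer(seed))
  profile <- ifelse(timepointsH <= 1, 1, exp(-(timepointsH - 1) / 1.5))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ePre <- baselineG + if (noiseSdG > 0) rnorm(1, 0, noiseSdG) else 0
    ePre <- max(ePre, 0.5)
    ePredrug <- ePre * (1 - cciDropFraction)
    mu <- ePredrug + drugEffectMpe * profile * (ePre - ePredrug)
    thr <- mu + if (noiseSdG > 0) rnorm(length(mu), 0, noiseSdG) else 0
    rows[[i]] <- data.frame(
      animal_id = sprintf("%s_%02d", group, i), group = group,
      time_h = timepointsH, threshold_g = pmax(thr, 0.01),
      e_precci_g = ePre, e_predrug_g = ePredrug)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
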