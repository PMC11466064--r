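# Independent brute-force oracles and small constructors used across tests.
# The oracles deliberately share no code with the package implementation:
# labeling is done by breadth-first search, dilation by a full-grid
# Euclidean distance scan, and colocalization by per-pixel counting.

# Brute-force 8-connected labeling by BFS over the mask.
oracleLabel8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (mask[r, c] && lab[r, c] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(r, c)); lab[r, c] <- nxt
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (dr in -1:1) for (dc in -1:1) {
          rr <- p[1] + dr; cc <- p[2] + dc
          if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
              mask[rr, cc] && lab[rr, cc] == 0L) {
            lab[rr, cc] <- nxt
            queue[[length(queue) + 1L]] <- c(rr, cc)
          }
        }
      }
    }
  }
  lab
}

# Partition of a label matrix as a canonical set of pixel-index sets,
# invariant to label numbering.
labelPartition <- function(lab) {
  idx <- which(lab > 0)
  parts <- unname(lapply(split(idx, lab[idx]), sort))
  parts[order(vapply(parts, min, numeric(1)))]
}

# Effective dilation radius in pixels: radius below one pixel rounds up.
oracleRadiusPx <- function(dilationUm, pixelSizeUm) {
  if (dilationUm == 0) return(0)
  r <- dilationUm / pixelSizeUm
  if (r < 1) 1 else r
}

# All grid pixels within Euclidean distance radiusPx of the pixel set,
# computed by a full-grid scan.
oracleDilate <- function(pix, radiusPx, nr, nc) {
  if (radiusPx == 0) return(pix[order(pix[, 2], pix[, 1]), , drop = FALSE])
  grid <- cbind(rep(seq_len(nr), nc), rep(seq_len(nc), each = nr))
  d2 <- matrix(Inf, nrow(grid), 1)
  for (k in seq_len(nrow(pix))) {
    dk <- (grid[, 1] - pix[k, 1])^2 + (grid[, 2] - pix[k, 2])^2
    d2 <- pmin(d2, dk)
  }
  keep <- d2 <= radiusPx^2 + 1e-9
  grid[keep, , drop = FALSE]
}

# Per-pixel brute-force colocalization: returns per-reference-punctum
# overlap fractions and decisions.
oracleColocalize <- function(reference, other, overlapThreshold = 0.5,
                             dilationUm = 0.1) {
  px <- pixelSize(reference)
  nr <- reference@dim[1]; nc <- reference@dim[2]
  r <- oracleRadiusPx(dilationUm, px)
  unionMask <- matrix(FALSE, nr, nc)
  for (p in pixelSets(other)) {
    d <- oracleDilate(p, r, nr, nc)
    unionMask[d] <- TRUE
  }
  fr <- vapply(pixelSets(reference), function(p) {
    d <- oracleDilate(p, r, nr, nc)
    sum(unionMask[d]) / nrow(d)
  }, numeric(1))
  list(fractions = fr, colocalized = fr > overlapThreshold)
}

# Construct a PunctaSet directly from a list of pixel matrices.
makePunctaSet <- function(pixelList, dims, pixelSizeUm = 0.1,
                          channel = "ch", fieldId = "constructed") {
  new("PunctaSet", fieldId = fieldId, channel = channel,
      dim = as.integer(dims), pixelSize = pixelSizeUm,
      pixels = lapply(pixelList, function(p) {
        p <- as.matrix(p); storage.mode(p) <- "integer"
        colnames(p) <- c("row", "col"); p
      }),
      stats = spincolocal:::punctaStats(
        lapply(pixelList, function(p) { p <- as.matrix(p); p }),
        pixelSizeUm),
      provenance = list(method = "constructed", dilated_um = 0))
}

# Roughly circular blob of nPix pixels centered at (row, col).
blobPixels <- function(center, nPix, dims) {
  grid <- cbind(rep(seq_len(dims[1]), dims[2]),
                rep(seq_len(dims[2]), each = dims[1]))
  d2 <- (grid[, 1] - center[1])^2 + (grid[, 2] - center[2])^2
  grid[order(d2)[seq_len(nPix)], , drop = FALSE]
}

# Rectangular block of pixels.
blockPixels <- function(rows, cols) {
  cbind(rep(rows, times = length(cols)), rep(cols, each = length(rows)))
}

# Noise-free field with Gaussian spots at given positions (um).
spotField <- function(xUm, yUm, diameterUm, dims, pixelSizeUm = 0.1,
                      peak = 1, background = 0.1, channel = "ch") {
  img <- matrix(background, dims[1], dims[2])
  for (i in seq_along(xUm))
    img <- spincolocal:::renderSpot(img, xUm[i], yUm[i],
                                    if (length(diameterUm) > 1)
                                      diameterUm[i] else diameterUm,
                                    peak, pixelSizeUm)
  f <- list(img); names(f) <- channel
  ImageField(f, pixelSizeUm, fieldId = "spots")
}

# Constructed FISH fixture: four nuclei (radius 3 um) whose 2 um-expanded
# areas contain exactly 0, 2, 3 and 20 marker dots. Dots are laid out on
# rings with >= 1.2 um spacing so each renders as a separate punctum.
makeFishFixture <- function(pixelSizeUm = 0.2) {
  px <- pixelSizeUm
  dims <- c(300L, 300L)
  centersX <- c(12, 12, 48, 48); centersY <- c(12, 48, 12, 48)
  dapi <- matrix(0.05, dims[1], dims[2])
  xs <- (seq_len(dims[2]) - 1) * px; ys <- (seq_len(dims[1]) - 1) * px
  for (i in 1:4) {
    dd <- outer((ys - centersY[i])^2, (xs - centersX[i])^2, "+")
    dapi[dd <= 9] <- 1
  }
  marker <- matrix(0.02, dims[1], dims[2])
  ringDots <- function(cx, cy, n) {
    if (n == 0) return(NULL)
    perRing <- c(8, 12)  # radii 2.2 and 4.2 um
    radii <- c(2.2, 4.2)
    out <- NULL
    left <- n
    for (k in 1:2) {
      m <- min(left, perRing[k])
      if (m == 0) break
      ang <- seq(0, 2 * pi, length.out = m + 1)[-1] + 0.1 * k
      out <- rbind(out, cbind(cx + radii[k] * cos(ang),
                              cy + radii[k] * sin(ang)))
      left <- left - m
    }
    out
  }
  nDots <- c(0, 2, 3, 20)
  for (i in 1:4) {
    d <- ringDots(centersX[i], centersY[i], nDots[i])
    if (!is.null(d))
      for (j in seq_len(nrow(d)))
        marker <- spincolocal:::renderSpot(marker, d[j, 1], d[j, 2],
                                           0.5, 1, px)
  }
  list(field = ImageField(list(dapi = dapi, g1 = marker), px),
       centersX = centersX, centersY = centersY, nDots = nDots)
}

# Two-channel simulation parameters used by the recovery tests: dilute,
# noise-free fields whose spot diameters sit comfortably inside the size
# filter, so that detection is near-perfect and chance overlap stays small.
recoveryChannels <- function(density = 0.05, noise = 0) {
  dc <- spincolocal:::defaultChannelSpec
  list(geph = dc(density, 0.5, 0.05, noise_sd = noise),
       a2 = dc(density, 0.5, 0.05, noise_sd = noise))
}
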