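test_that("nuclear expansion matches disk geometry and contains the nucleus", {
  px <- 0.1
  dims <- c(200L, 200L)
  # disk nucleus of radius 5 um centered at pixel (100, 100)
  grid <- cbind(rep(1:200, 200), rep(1:200, each = 200))
  d2 <- (grid[, 1] - 100)^2 + (grid[, 2] - 100)^2
  nucleus <- grid[d2 <= (5 / px)^2, , drop = FALSE]

  # expansion 0 is the identity
  expect_identical(expandNucleus(nucleus, 0, px, dims), nucleus)

  exp2 <- expandNucleus(nucleus, 2, px, dims)
  # contains the nucleus
  key <- function(p) paste(p[, 1], p[, 2])
  expect_true(all(key(nucleus) %in% key(exp2)))
  expect_gt(nrow(exp2), nrow(nucleus))
  # area ratio approximates (7/5)^2 = 49/25
  expect_lt(abs(nrow(exp2) / nrow(nucleus) - 49 / 25), 0.05)
  # matches the brute-force disk dilation oracle
  want <- oracleDilate(nucleus, 2 / px, dims[1], dims[2])
  expect_setequal(key(exp2), key(want))
})

test_that("positivity needs at least the minimum dot count and is monotone", {
  expect_identical(callPositive(c(0L, 2L, 3L, 20L)), c(FALSE, FALSE, TRUE, TRUE))
  counts <- 0:10
  for (m in 1:6) {
    pm <- callPositive(counts, m)
    pm1 <- callPositive(counts, m + 1)
    expect_true(all(pm1 <= pm))  # raising the threshold never adds positives
  }
})

test_that("cells with 0, 2, 3 and 20 dots in their expanded areas call negative, negative, positive, positive", {
  fx <- makeFishFixture()
  nuclei <- segmentNuclei(fx$field, "dapi")
  expect_equal(nPuncta(nuclei), 4)
  dots <- detectPuncta(fx$field, "g1")
  expect_equal(nPuncta(dots), sum(fx$nDots))
  counts <- countDotsPerCell(nuclei, dots, expansionUm = 2)
  # order cells to match construction via centroids
  st <- punctaTable(nuclei)
  ord <- order(round(st$centroid_x_um / 10), round(st$centroid_y_um / 10))
  expect_equal(counts[ord], fx$nDots)
  expect_identical(callPositive(counts[ord]), c(FALSE, FALSE, TRUE, TRUE))
})

test_that("contested dots go to the nearer nucleus centroid, ties to the lower id", {
  px <- 0.5
  dims <- c(60L, 60L)
  dapi <- matrix(0, dims[1], dims[2])
  # two 3x3 nuclei centered at columns 10 and 20, same row band
  dapi[14:16, 9:11] <- 1
  dapi[14:16, 19:21] <- 1
  marker <- matrix(0, dims[1], dims[2])
  # one dot nearer nucleus 1, placed inside both expanded areas
  marker <- spincolocal:::renderSpot(marker, (13 - 1) * px, (15 - 1) * px,
                                     0.8, 1, px)
  field <- ImageField(list(dapi = dapi, g1 = marker), px)
  nuclei <- segmentNuclei(field, "dapi", minAreaUm2 = 1)
  expect_equal(nPuncta(nuclei), 2)
  counts <- countDotsPerCell(nuclei, detectPuncta(field, "g1"),
                             expansionUm = 3)
  st <- punctaTable(nuclei)
  nearer <- which.min(abs(st$centroid_x_um - (13 - 1) * px))
  expect_equal(counts[nearer], 1L)
  expect_equal(sum(counts), 1L)

  # exact tie: dot equidistant from both centroids -> lower cell id
  marker2 <- matrix(0, dims[1], dims[2])
  marker2 <- spincolocal:::renderSpot(marker2, (15 - 1) * px, (15 - 1) * px,
                                      0.8, 1, px)
  field2 <- ImageField(list(dapi = dapi, g1 = marker2), px)
  nuclei2 <- segmentNuclei(field2, "dapi", minAreaUm2 = 1)
  counts2 <- countDotsPerCell(nuclei2, detectPuncta(field2, "g1"),
                              expansionUm = 3)
  expect_equal(counts2, c(1L, 0L))
})

test_that("segmented nuclei match the generating disks (Jaccard >= 0.9)", {
  sim <- simulateFishField(fishSimParams(nCells = 30, seed = 17))
  nuclei <- segmentNuclei(sim$field, "dapi")
  expect_equal(nPuncta(nuclei), 30)
  px <- pixelSize(sim$field)
  d <- nuclei@dim
  st <- punctaTable(nuclei)
  for (i in seq_len(nPuncta(nuclei))) {
    j <- which.min((sim$truth$x_um - st$centroid_x_um[i])^2 +
                   (sim$truth$y_um - st$centroid_y_um[i])^2)
    # rasterize the true disk
    pix <- pixelSets(nuclei)[[i]]
    rows <- (seq_len(d[1]) - 1) * px; cols <- (seq_len(d[2]) - 1) * px
    rIdx <- which(abs(rows - sim$truth$y_um[j]) <= 4)
    cIdx <- which(abs(cols - sim$truth$x_um[j]) <= 4)
    dd <- outer((rows[rIdx] - sim$truth$y_um[j])^2,
                (cols[cIdx] - sim$truth$x_um[j])^2, "+")
    truthPix <- cbind(rep(rIdx, ncol(dd))[as.vector(dd) <= 16],
                      rep(cIdx, each = nrow(dd))[as.vector(dd) <= 16])
    key <- function(p) paste(p[, 1], p[, 2])
    inter <- length(intersect(key(pix), key(truthPix)))
    uni <- length(union(key(pix), key(truthPix)))
    expect_gte(inter / uni, 0.9)
  }
})

test_that("touching disks merge into one component, as the oracle predicts", {
  px <- 0.5
  dapi <- matrix(0, 40, 40)
  dapi[10:14, 10:14] <- 1
  dapi[10:14, 15:19] <- 1  # touching blocks
  field <- ImageField(list(dapi = dapi), px)
  nuclei <- segmentNuclei(field, "dapi", minAreaUm2 = 1)
  expect_equal(nPuncta(nuclei), 1)
  expect_equal(max(oracleLabel8(dapi > 0.5)), 1)
})

test_that("coexpression fractions are exact on constructed calls and recover simulated rates", {
  calls <- data.frame(
    cell_id = 1:6,
    region = rep(c("superficial_dorsal_horn", "deep_dorsal_horn"), each = 3),
    pos_g1 = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    pos_vgat = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  spec <- data.frame(region = c("superficial_dorsal_horn", "all",
                                "deep_dorsal_horn"),
                     conditioning = c("vgat", "vgat", "g1"),
                     target = c("g1", "g1", "vgat"))
  tab <- coexpressionFractions(calls, spec)
  expect_equal(tab$fraction[1], 2 / 3)
  expect_equal(tab$fraction[2], 0.5)
  expect_true(is.na(tab$fraction[3]))   # zero denominator flagged
  expect_true(tab$undefined[3])
  expect_true(all(tab$n_double_positive <= tab$n_conditioning))

  # relabeling cell ids leaves fractions unchanged
  calls2 <- calls; calls2$cell_id <- rev(calls2$cell_id)
  expect_equal(coexpressionFractions(calls2, spec)$fraction, tab$fraction)

  # simulated conditional expression: P(target | conditioning) = 0.44
  set.seed(88)
  n <- 500
  cond <- rep(TRUE, n)
  targ <- runif(n) < 0.44
  big <- data.frame(cell_id = 1:n, region = "superficial_dorsal_horn",
                    pos_vgat = cond, pos_g1 = targ)
  got <- coexpressionFractions(big,
    data.frame(region = "superficial_dorsal_horn",
               conditioning = "vgat", target = "g1"))
  expect_lt(abs(got$fraction - 0.44), 0.05)
})

test_that("end-to-end positivity calls reach 95% sensitivity and specificity", {
  tp <- 0; fn <- 0; tn <- 0; fp <- 0
  for (s in 1:2) {
    sim <- simulateFishField(fishSimParams(seed = 40 + s))
    calls <- callCells(sim$field, "dapi", names(sim$params$expressionProbability))
    tr <- sim$truth
    m <- vapply(seq_len(nrow(calls)), function(i)
      which.min((tr$x_um - calls$centroid_x_um[i])^2 +
                (tr$y_um - calls$centroid_y_um[i])^2), integer(1))
    for (mk in names(sim$params$expressionProbability)) {
      pred <- calls[[paste0("pos_", mk)]]
      tru <- tr[[paste0("pos_", mk)]][m]
      tp <- tp + sum(pred & tru); fn <- fn + sum(!pred & tru)
      tn <- tn + sum(!pred & !tru); fp <- fp + sum(pred & !tru)
    }
  }
  expect_gte(tp / (tp + fn), 0.95)
  expect_gte(tn / (tn + fp), 0.95)
})
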