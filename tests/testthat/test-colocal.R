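test_that("dilation by zero is the identity and a sub-pixel radius rounds up", {
  px <- 0.1
  dims <- c(20, 20)
  ps <- makePunctaSet(list(cbind(10L, 10L)), dims, px)
  d0 <- dilatePuncta(ps, 0)
  expect_identical(pixelSets(d0), pixelSets(ps))

  # 1-pixel punctum, pixel 0.1 um, dilation 0.1 um -> radius-1 disk, 5 px
  d1 <- dilatePuncta(ps, 0.1)
  got <- pixelSets(d1)[[1]]
  expect_equal(nrow(got), 5)
  want <- oracleDilate(cbind(10L, 10L), oracleRadiusPx(0.1, px), 20, 20)
  expect_setequal(paste(got[, 1], got[, 2]), paste(want[, 1], want[, 2]))

  # dilation below one pixel still grows the set
  dHalf <- dilatePuncta(ps, 0.04)
  expect_equal(nrow(pixelSets(dHalf)[[1]]), 5)
})

test_that("dilation matches the disk-rasterization oracle and never shrinks", {
  sim <- simulatePunctaField(punctaSimParams(seed = 12))
  ps <- filterBySize(detectPuncta(sim$field, "a2"))
  for (dil in c(0.1, 0.3)) {
    dl <- dilatePuncta(ps, dil)
    expect_identical(punctaTable(dl)$id, punctaTable(ps)$id)
    expect_true(all(punctaTable(dl)$area_um2 >= punctaTable(ps)$area_um2))
    r <- oracleRadiusPx(dil, pixelSize(ps))
    for (i in sample(nPuncta(ps), min(5, nPuncta(ps)))) {
      want <- oracleDilate(pixelSets(ps)[[i]], r, ps@dim[1], ps@dim[2])
      got <- pixelSets(dl)[[i]]
      expect_setequal(paste(got[, 1], got[, 2]), paste(want[, 1], want[, 2]))
    }
  }
})

test_that("overlap fractions follow the strict >50% pixel-count rule", {
  px <- 0.1
  dims <- c(40, 40)
  ref <- makePunctaSet(list(blockPixels(10:14, 10:14)), dims, px,
                       channel = "a2")
  # other channel covers 15 of the 25 reference pixels: 0.60 -> colocalized
  oth15 <- makePunctaSet(list(blockPixels(10:14, 10:12)), dims, px,
                         channel = "geph")
  r15 <- colocalize(ref, oth15, overlapThreshold = 0.5, dilationUm = 0)
  expect_equal(overlapFractions(r15), 0.6)
  expect_true(isColocalized(r15))
  expect_equal(colocalizedFraction(r15), 1)

  # 12 of 25 pixels: 0.48 -> not colocalized
  oth12 <- makePunctaSet(list(blockPixels(10:13, 10:12)), dims, px,
                         channel = "geph")
  r12 <- colocalize(ref, oth12, overlapThreshold = 0.5, dilationUm = 0)
  expect_equal(overlapFractions(r12), 0.48)
  expect_false(isColocalized(r12))

  # exactly 50% is NOT colocalized (strict inequality): 24-px reference,
  # 12 px covered
  ref24 <- makePunctaSet(list(blockPixels(20:23, 20:25)), dims, px,
                         channel = "a2")
  othHalf <- makePunctaSet(list(blockPixels(20:23, 20:22)), dims, px,
                           channel = "geph")
  rHalf <- colocalize(ref24, othHalf, overlapThreshold = 0.5, dilationUm = 0)
  expect_equal(overlapFractions(rHalf), 0.5)
  expect_false(isColocalized(rHalf))

  # a reference punctum straddling two partners sums its covered pixels
  oth2 <- makePunctaSet(list(blockPixels(10:14, 10:11),
                             blockPixels(10:14, 13:14)), dims, px,
                        channel = "geph")
  r2 <- colocalize(ref, oth2, overlapThreshold = 0.5, dilationUm = 0)
  expect_equal(overlapFractions(r2), 0.8)
  expect_equal(r2@nColocalized, 1L)
})

test_that("identical sets fully colocalize; distant sets do not", {
  sim <- simulatePunctaField(punctaSimParams(seed = 14))
  ps <- filterBySize(detectPuncta(sim$field, "a2"))
  self <- colocalize(ps, ps)
  expect_equal(colocalizedFraction(self), 1)

  px <- 0.1; dims <- c(60, 60)
  a <- makePunctaSet(list(blockPixels(5:8, 5:8)), dims, px)
  b <- makePunctaSet(list(blockPixels(40:43, 40:43)), dims, px)
  expect_equal(colocalizedFraction(colocalize(a, b, dilationUm = 0.1)), 0)
})

test_that("empty reference gives a flagged undefined fraction, not an error", {
  px <- 0.1; dims <- c(30, 30)
  empty <- makePunctaSet(list(), dims, px)
  oth <- makePunctaSet(list(cbind(5L, 5L)), dims, px)
  r <- colocalize(empty, oth)
  expect_equal(r@nReference, 0L)
  expect_true(is.na(colocalizedFraction(r)))
  expect_true("empty_reference" %in% r@flags)
})

test_that("colocalized count is monotone in dilation and overlap threshold", {
  sim <- simulatePunctaField(punctaSimParams(trueColocFraction = 0.4, seed = 16))
  a2 <- filterBySize(detectPuncta(sim$field, "a2"))
  geph <- filterBySize(detectPuncta(sim$field, "geph"))
  nByDil <- vapply(c(0, 0.1, 0.2, 0.4), function(d)
    colocalize(a2, geph, dilationUm = d)@nColocalized, integer(1))
  expect_true(all(diff(nByDil) >= 0))
  nByThr <- vapply(c(0.25, 0.5, 0.75, 0.95), function(t)
    colocalize(a2, geph, overlapThreshold = t)@nColocalized, integer(1))
  expect_true(all(diff(nByThr) <= 0))
})

test_that("colocalization is asymmetric exactly as the pixel oracle computes", {
  px <- 0.1; dims <- c(40, 40)
  big <- makePunctaSet(list(blockPixels(10:19, 10:19)), dims, px,
                       channel = "big")
  small <- makePunctaSet(list(blockPixels(12:14, 12:14)), dims, px,
                         channel = "small")
  ab <- colocalize(big, small, dilationUm = 0)
  ba <- colocalize(small, big, dilationUm = 0)
  expect_false(isColocalized(ab))   # 9/100 covered
  expect_true(isColocalized(ba))    # fully covered
  oAB <- oracleColocalize(big, small, dilationUm = 0)
  oBA <- oracleColocalize(small, big, dilationUm = 0)
  expect_equal(overlapFractions(ab), oAB$fractions)
  expect_equal(overlapFractions(ba), oBA$fractions)
})

test_that("implementation agrees with the per-pixel oracle on random fields", {
  for (s in 1:5) {
    p <- punctaSimParams(fieldSizeUm = c(19.2, 19.2), pixelSizeUm = 0.15,
                         channels = recoveryChannels(noise = 0.02),
                         trueColocFraction = runif(1), seed = 700 + s)
    sim <- simulatePunctaField(p)
    a2 <- filterBySize(detectPuncta(sim$field, "a2"))
    geph <- filterBySize(detectPuncta(sim$field, "geph"))
    res <- colocalize(a2, geph)
    ora <- oracleColocalize(a2, geph)
    expect_equal(overlapFractions(res), ora$fractions)
    expect_identical(isColocalized(res), ora$colocalized)
  }
})

test_that("percent reduction reproduces printed worked examples and edge cases", {
  expect_equal(percentReduction(0.23, 0.005), 97.8)
  expect_equal(percentReduction(0.46, 0.18), 60.9)
  expect_equal(percentReduction(1, 1), 0)
  expect_equal(percentReduction(0.2, 0.3), -50)  # increase: negative reduction
  expect_error(percentReduction(0, 0.1), "positive")
  expect_error(percentReduction(-1, 0.1), "positive")
  expect_equal(percentReduction(3, 1, digits = NA), 200 / 3)
})

test_that("group comparison returns means, SEM, reduction and a t test", {
  g <- compareGroups(c(2, 4, 6), c(1, 2, 3), labels = c("fl", "ko"))
  expect_equal(g@means, c(4, 2))
  expect_equal(g@sems, c(2 / sqrt(3), sd(c(1, 2, 3)) / sqrt(3)))
  expect_equal(g@percentReduction, 50)
  ref <- t.test(c(2, 4, 6), c(1, 2, 3), var.equal = TRUE)
  expect_equal(g@pValue, ref$p.value)

  deg <- compareGroups(c(1, 1, 1), c(1, 1, 1))
  expect_equal(deg@percentReduction, 0)
  expect_true(is.na(deg@pValue))
  expect_true("degenerate" %in% deg@flags)
})

test_that("group comparison recovers a simulated 50% density reduction", {
  hits <- 0
  ok <- 0
  for (s in 1:100) {
    set.seed(4000 + s)
    ctl <- rnorm(10, 0.6, 0.02)
    tst <- rnorm(10, 0.3, 0.02)
    g <- compareGroups(ctl, tst)
    if (abs(g@percentReduction - 50) <= 5) ok <- ok + 1
    if (!is.na(g@pValue) && g@pValue < 0.001) hits <- hits + 1
  }
  expect_gte(ok, 95)
  expect_gte(hits, 95)
})
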