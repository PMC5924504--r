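test_that("PC1 association scale behaves on collinear and independent inputs", {
  # perfectly correlated (after log) variables: PC1 explains everything
  b <- c(1, 2, 4, 8, 16)
  pc <- humanAssociationPC1(b, b)
  expect_equal(pc$varianceExplained, 1, tolerance = 1e-12)
  expect_equal(sum(pc$scores), 0, tolerance = 1e-9)
  # orientation: larger densities get larger scores
  expect_gt(cor(pc$scores, b), 0.9)

  set.seed(61)
  t2 <- exp(rnorm(4000)); b2 <- exp(rnorm(4000))
  pc2 <- humanAssociationPC1(t2, b2, eps = 0)
  expect_equal(pc2$varianceExplained, 0.5, tolerance = 0.03)

  expect_error(humanAssociationPC1(rep(2, 5), rep(3, 5)), "zero variance")
  expect_error(humanAssociationPC1(1:2, 1:2), "at least 3")
})

test_that("PC1 scores are invariant to affine rescaling of the raw inputs", {
  set.seed(62)
  t0 <- exp(rnorm(9)); b0 <- exp(rnorm(9))
  pcA <- humanAssociationPC1(t0, b0, eps = 0)
  # multiplicative rescaling shifts the log, and standardization removes it
  pcB <- humanAssociationPC1(t0 * 37, b0 * 0.04, eps = 0)
  expect_equal(pcA$scores, pcB$scores, tolerance = 1e-9)
})

test_that("resource densities recover published values on single-habitat ranges", {
  # a 1-ha home range entirely inside closed riparian habitat
  ud <- gaussianUD(sd = 18, nCells = 100, lim = 4)
  iso <- volumeIsopleth(ud, 95)
  hab <- list(list(
    polygon = data.frame(x = c(-500, 500, 500, -500),
                         y = c(-500, -500, 500, 500)),
    habitat_class = "riparian", canopy = "closed"))
  ls <- methods::new("LandscapeBundle",
                     land = list(), buildings = matrix(numeric(0), ncol = 2),
                     trees = matrix(numeric(0), ncol = 2), habitats = hab,
                     refuse = matrix(numeric(0), ncol = 2),
                     bedNights = data.frame(x = numeric(0), y = numeric(0),
                                            bed_nights = numeric(0)))
  rd <- resourceDensities(iso, ls, "dry")
  areaM2 <- areaHa(iso) * 1e4
  expect_equal(rd$macrofauna_count, 288 * areaM2)
  expect_equal(rd$macrofauna_density_m2, 288)
  expect_equal(resourceDensities(iso, ls, "wet")$macrofauna_density_m2, 549)
  expect_equal(rd$building_count, 0)       # apoanthropic: zero buildings
  expect_equal(rd$building_density_ha, 0)
  # densities recompute from counts and areas exactly
  expect_equal(rd$macrofauna_density_m2, rd$macrofauna_count / areaM2)

  # a range split between two habitats gets the area-weighted mean density
  hab2 <- list(
    list(polygon = data.frame(x = c(-500, 0, 0, -500),
                              y = c(-500, -500, 500, 500)),
         habitat_class = "riparian", canopy = "closed"),
    list(polygon = data.frame(x = c(0, 500, 500, 0),
                              y = c(-500, -500, 500, 500)),
         habitat_class = "riparian", canopy = "open"))
  ls2 <- ls; ls2@habitats <- hab2
  rd2 <- resourceDensities(iso, ls2, "dry")
  w <- rd2$habitat_areas_m2 / sum(rd2$habitat_areas_m2)
  expect_equal(rd2$macrofauna_density_m2,
               unname(w["riparian_closed"] * 288 + w["riparian_open"] * 143))
  # a symmetric Gaussian splits close to 50:50
  expect_equal(unname(w["riparian_closed"]), 0.5, tolerance = 0.05)

  # a building inside the range is counted, with density count/area
  ls3 <- ls
  ls3@buildings <- rbind(c(0, 0), c(5000, 5000))  # one inside, one far away
  rd3 <- resourceDensities(iso, ls3, "dry")
  expect_equal(rd3$building_count, 1)
  expect_equal(rd3$building_density_ha, 1 / areaHa(iso))

  # unknown habitat class is a configuration error
  ls4 <- ls
  ls4@habitats[[1]]$habitat_class <- "dunes"
  expect_error(resourceDensities(iso, ls4, "dry"), "dunes")
})

test_that("patch dispersion equals hand-computed and brute-force values", {
  expect_equal(meanNearestNeighbour(cbind(c(0, 1, 3), 0)), 4 / 3)
  grid3 <- as.matrix(expand.grid(x = 0:2, y = 0:2))
  expect_equal(meanNearestNeighbour(grid3), 1)
  expect_message(v <- meanNearestNeighbour(cbind(1, 1)), "fewer than 2")
  expect_true(is.na(v))
  set.seed(71)
  pts <- matrix(runif(200) * 100, ncol = 2)
  brute <- mean(vapply(seq_len(100), function(i) {
    min(sqrt((pts[-i, 1] - pts[i, 1])^2 + (pts[-i, 2] - pts[i, 2])^2))
  }, 0))
  expect_equal(meanNearestNeighbour(pts), brute)
})

test_that("fold change follows the study convention", {
  expect_equal(foldChange(106, 1146), 9.81, tolerance = 0.001)
  expect_equal(foldChange(143, 94), -0.34, tolerance = 0.01)
  expect_equal(foldChange(212, 526), 1.48, tolerance = 0.005)
  expect_equal(foldChange(288, 549), 0.9, tolerance = 0.01)
  expect_equal(foldChange(140, 296), 1.11, tolerance = 0.005)
  expect_equal(foldChange(347, 513), 0.5, tolerance = 0.05)
  expect_equal(foldChange(7, 7), 0)
  expect_error(foldChange(0, 5), "before")
})

test_that("group sizes use monthly modes and seasonal medians", {
  jan <- as.Date("2009-01-10") + c(0, 5, 10)
  counts <- data.frame(date = jan, count = c(12, 12, 13))
  gs <- groupSizeSummaries(counts)
  expect_equal(gs$monthly$mode, 12)

  counts2 <- data.frame(
    date = c(rep(as.Date("2009-01-15"), 2), rep(as.Date("2009-02-15"), 2),
             rep(as.Date("2009-03-15"), 2)),
    count = c(12, 12, 14, 14, 16, 16))
  gs2 <- groupSizeSummaries(counts2)
  expect_equal(sort(gs2$monthly$mode), c(12, 14, 16))
  expect_equal(unname(gs2$seasonal[["wet"]]), 14)

  counts3 <- data.frame(date = rep(as.Date("2009-01-15"), 4),
                        count = c(12, 12, 13, 13))
  expect_message(gs3 <- groupSizeSummaries(counts3), "tie")
  expect_equal(gs3$monthly$mode, 12)

  # opportunistic groups: median of raw counts
  counts4 <- data.frame(date = as.Date("2009-06-15") + 0:4,
                        count = c(4, 9, 10, 11, 50))
  gs4 <- groupSizeSummaries(counts4, opportunistic = TRUE)
  expect_equal(unname(gs4$seasonal[["dry"]]), 10)
})

test_that("fecal organic matter medians summarise per group and season", {
  s <- data.frame(group_id = "G1", om = c(80, 85, 90))
  expect_equal(fecalOMIndex(s)$om_median, 85)
  s1 <- data.frame(group_id = "G2", om = 88)
  expect_equal(fecalOMIndex(s1)$om_median, 88)
  s2 <- data.frame(group_id = rep(c("A", "B"), each = 4),
                   season = rep(c("wet", "dry"), 4),
                   om = c(70, 60, 72, 62, 90, 80, 92, 82))
  idx <- fecalOMIndex(s2)
  expect_equal(idx$om_median[idx$group_id == "A" & idx$season == "wet"], 71)
  expect_equal(idx$om_median[idx$group_id == "B" & idx$season == "dry"], 81)
  expect_equal(idx$om_median[idx$group_id == "A" & idx$season == "overall"],
               66)
})
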