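test_that("resistance surface is an elementwise cost lookup", {
  g1 <- categoryGrid(matrix(1, 3, 3), 5)
  expect_true(all(gridValues(buildResistance(g1)) == 1))
  g9 <- categoryGrid(matrix(9, 3, 3), 5)
  expect_true(all(gridValues(buildResistance(g9)) == 1000))
  gm <- categoryGrid(matrix(c(1, 4, 8, 9), 2, 2), 5)
  expect_equal(gridValues(buildResistance(gm)),
               matrix(c(1, 25, 50, 1000), 2, 2))
  expect_error(buildResistance(gm, cv = c("1" = 1)),
               class = "volescape_cv_error")
})

test_that("uniform surface: corner-to-corner path runs the diagonal at cost 4*sqrt(2)", {
  res <- resistanceGrid(matrix(1, 5, 5), 1)
  p <- leastCostPath(res, c(1, 1), c(5, 5))
  expect_equal(p$cost, 4 * sqrt(2), tolerance = 1e-12)
  expect_equal(p$cells[, "row"], 1:5, ignore_attr = TRUE)
  expect_equal(p$cells[, "col"], 1:5, ignore_attr = TRUE)
})

test_that("src = dst gives a single-cell path of zero cost", {
  res <- resistanceGrid(matrix(1, 4, 4), 2)
  p <- leastCostPath(res, c(2, 3), c(2, 3))
  expect_equal(nrow(p$cells), 1)
  expect_equal(p$cost, 0)
  expect_equal(effectiveDistance(p), 0)
})

test_that("path threads the single gap in a high-cost wall, at the oracle cost", {
  cv <- matrix(1, 7, 7)
  cv[, 4] <- 1000
  cv[4, 4] <- 1        # gap
  res <- resistanceGrid(cv, 10)
  p <- leastCostPath(res, c(1, 1), c(7, 7))
  expect_true(any(p$cells[, 1] == 4 & p$cells[, 2] == 4))
  expect_equal(p$cost, dijkstraOracle(cv, 10, c(1, 1), c(7, 7)),
               tolerance = 1e-9)
})

test_that("least-cost cost equals the brute-force Dijkstra oracle on random grids", {
  set.seed(99)
  for (case in 1:60) {
    nr <- sample(3:9, 1); nc <- sample(3:9, 1)
    cv <- matrix(sample(c(1, 25, 50, 1000), nr * nc, TRUE), nr, nc)
    res <- resistanceGrid(cv, 5)
    src <- c(sample(nr, 1), sample(nc, 1))
    dst <- c(sample(nr, 1), sample(nc, 1))
    p <- leastCostPath(res, src, dst)
    expect_equal(p$cost, dijkstraOracle(cv, 5, src, dst), tolerance = 1e-9)
  }
})

test_that("raising a cost value never lowers any accumulated cost", {
  set.seed(7)
  cv <- matrix(sample(c(1, 25, 50), 36, TRUE), 6, 6)
  res1 <- resistanceGrid(cv, 5)
  cv2 <- cv; cv2[cv2 == 25] <- 400
  res2 <- resistanceGrid(cv2, 5)
  for (k in 1:10) {
    src <- c(sample(6, 1), sample(6, 1)); dst <- c(sample(6, 1), sample(6, 1))
    expect_gte(leastCostPath(res2, src, dst)$cost + 1e-9,
               leastCostPath(res1, src, dst)$cost)
  }
})

test_that("effective distance sums step lengths, with optional DEM correction", {
  p <- structure(list(cells = cbind(row = rep(1, 5), col = 1:5),
                      cost = 0, cellSize = 5), class = "lcpPath")
  expect_equal(effectiveDistance(p), 20)
  dem <- elevationGrid(matrix(rep(seq(0, 20, by = 5), each = 1), 1, 5), 5)
  expect_equal(effectiveDistance(p, dem), 4 * sqrt(50), tolerance = 1e-12)
  flat <- elevationGrid(matrix(3, 1, 5), 5)
  expect_equal(effectiveDistance(p, flat), 20)
  small <- elevationGrid(matrix(0, 1, 2), 5)
  expect_error(effectiveDistance(p, small), class = "volescape_dem_error")
})

test_that("resistance distance: patch runs in km times cost value", {
  # 3 km through meadow: 3.0
  cells <- cbind(row = rep(1, 7), col = 1:7)
  p <- structure(list(cells = cells, cost = 0, cellSize = 500),
                 class = "lcpPath")
  g <- categoryGrid(matrix(1, 1, 7), 500)
  expect_equal(resistanceDistance(p, g), 3)
  # 1 km meadow then 0.2 km annual crop: 1 + 5 = 6
  cells2 <- cbind(row = rep(1, 7), col = 1:7)
  p2 <- structure(list(cells = cells2, cost = 0, cellSize = 200),
                  class = "lcpPath")
  cats <- matrix(c(rep(1, 6), 4), 1, 7)
  g2 <- categoryGrid(cats, 200)
  # runs: meadow gets 5 full steps + half of the boundary step = 1.1 km,
  # crop gets the remaining 0.1 km
  expect_equal(resistanceDistance(p2, g2), 1.1 * 1 + 0.1 * 25)
})

test_that("run segmentation equals the per-cell length x cost sum", {
  set.seed(12)
  for (case in 1:20) {
    nr <- 8; nc <- 8
    cats <- matrix(sample(c(1, 4, 8, 9), nr * nc, TRUE), nr, nc)
    g <- categoryGrid(cats, 50)
    res <- buildResistance(g)
    p <- leastCostPath(res, c(sample(nr, 1), sample(nc, 1)),
                       c(sample(nr, 1), sample(nc, 1)))
    if (nrow(p$cells) < 2) next
    steps <- c(0, 50 * ifelse(rowSums(abs(diff(p$cells))) == 2, sqrt(2), 1))
    cellLen <- (steps + c(steps[-1], 0)) / 2
    cvMap <- defaultCostValues()
    oracle <- sum(cellLen / 1000 *
                  cvMap[as.character(cats[p$cells])])
    expect_equal(resistanceDistance(p, g), unname(oracle), tolerance = 1e-9)
  }
})

test_that("Euclidean matrix reproduces distances from the printed coordinates", {
  demes <- table1Demes()
  eu <- euclideanMatrix(demes)
  expect_equal(eu[9, 10], sqrt(925^2 + 529^2) / 1000, tolerance = 1e-6)
  expect_equal(eu[1, 10], 20.299, tolerance = 1e-3)
  same <- data.frame(name = c("a", "b"), easting = c(5, 5),
                     northing = c(9, 9))
  expect_equal(euclideanMatrix(same)[1, 2], 0)
})

test_that("lens suitability: all-suitable and all-unsuitable limits, oracle stripes", {
  big <- categoryGrid(matrix(1, 100, 100), 50)
  expect_equal(suitabilityIndex(c(1000, 2500), c(3000, 2500), big), 0.5)
  water <- categoryGrid(matrix(9, 100, 100), 50)
  expect_equal(suitabilityIndex(c(1000, 2500), c(3000, 2500), water), 0)

  # striped grid: compare against an explicit point-in-lens count
  stripes <- categoryGrid(matrix(rep(c(1, 9), length.out = 100), 100, 100,
                                 byrow = TRUE), 50)
  A <- c(1200, 2600); B <- c(3300, 2100)
  d <- sqrt(sum((A - B)^2))
  got <- suitabilityIndex(A, B, stripes)
  ctr <- expand.grid(row = 1:100, col = 1:100)
  ex <- (ctr$col - 0.5) * 50
  ny <- (100 - ctr$row + 0.5) * 50
  inLens <- ((ex - A[1])^2 + (ny - A[2])^2 <= d^2) &
            ((ex - B[1])^2 + (ny - B[2])^2 <= d^2)
  suit <- gridValues(stripes)[cbind(ctr$row, ctr$col)] == 1
  expect_equal(got, (sum(inLens & suit) / sum(inLens)) / (d / 1000),
               tolerance = 1e-9)
  expect_true(got >= 0 && got <= 1 / (d / 1000))
})

test_that("distance bundle: octile bound on uniform land, resistance >= euclidean", {
  uni <- categoryGrid(matrix(1, 60, 60), 50)
  demes <- data.frame(name = c("a", "b", "c"),
                      easting = c(300, 2600, 1300),
                      northing = c(400, 2500, 2300))
  b <- distanceBundle(demes, uni)
  eu <- distanceMatrix(b, "euclidean"); eff <- distanceMatrix(b, "effective")
  up <- upper.tri(eu)
  # 8-neighbour lattice elongation is at most ~8.3% plus snapping slack
  expect_true(all(eff[up] <= 1.083 * eu[up] + 2 * 50 / 1000))
  expect_true(all(distanceMatrix(b, "resistance")[up] >= eu[up] - 0.15))
  expect_equal(diag(eff), rep(0, 3), ignore_attr = TRUE)
  expect_true(all(is.na(diag(distanceMatrix(b, "suitability")))))
})

test_that("ASCII grid round-trips through write and read", {
  g <- categoryGrid(matrix(sample(1:9, 30, TRUE), 5, 6), 25,
                    origin = c(1000, 2000))
  f <- withr::local_tempfile(fileext = ".asc")
  writeAsciiGrid(g, f)
  g2 <- readAsciiGrid(f)
  expect_equal(gridValues(g2), gridValues(g), ignore_attr = TRUE)
  expect_equal(cellSize(g2), 25)
  expect_equal(gridOrigin(g2), c(1000, 2000))
  dem <- elevationGrid(matrix(runif(30, 0, 300), 5, 6), 25)
  f2 <- withr::local_tempfile(fileext = ".asc")
  writeAsciiGrid(dem, f2)
  d2 <- readAsciiGrid(f2, "elevation")
  expect_equal(gridValues(d2), gridValues(dem), tolerance = 1e-6,
               ignore_attr = TRUE)
})
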