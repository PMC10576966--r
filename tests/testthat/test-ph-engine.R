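# Persistence engines: closed forms, oracle equivalence, invariances.

test_that("a single point yields one essential dim-0 bar and nothing else", {
  b <- bars(vrBarcodes(pointCloud(matrix(c(0, 0, 0), 1)), rf = 5))
  expect_equal(nrow(b), 1)
  expect_equal(b$dim, 0)
  expect_false(is.finite(b$death))
  expect_error(vrBarcodes(pointCloud(matrix(0, 0, 3)), 5), "empty")
})

test_that("unit square VR barcode matches the closed form", {
  bc <- vrBarcodes(unitSquare(), rf = 3, maxHomDim = 2)
  b <- bars(bc)
  d0 <- b[b$dim == 0 & is.finite(b$death), ]
  expect_equal(sort(d0$death), c(1, 1, 1))
  expect_equal(sum(b$dim == 0 & !is.finite(b$death)), 1)
  d1 <- b[b$dim == 1, ]
  expect_equal(nrow(d1), 1)
  expect_equal(d1$birth, 1)
  expect_equal(d1$death, sqrt(2))
  expect_equal(sum(b$dim == 2), 0)
})

test_that("equilateral triangle has no finite dim-1 VR bar", {
  b <- bars(vrBarcodes(equilateralTriangle(), rf = 3, maxHomDim = 2))
  expect_equal(sort(b$death[b$dim == 0 & is.finite(b$death)]), c(1, 1))
  expect_equal(sum(b$dim == 1), 0)  # born and filled at the same value
})

test_that("two-point closed form holds for the brute-force oracle", {
  cl <- pointCloud(rbind(c(0, 0, 0), c(0, 0, 2.5)))
  b <- bars(bruteForceVR(cl))
  expect_equal(b$death[is.finite(b$death)], 2.5)
  expect_equal(sum(!is.finite(b$death)), 1)
  bc <- bars(bruteForceCech(cl))
  expect_equal(bc$death[is.finite(bc$death)], 1.25)  # half the distance
})

test_that("alpha barcode of the unit square matches the closed form", {
  b <- bars(alphaBarcodes(unitSquare()))
  d1 <- b[b$dim == 1, ]
  expect_equal(nrow(d1), 1)
  expect_equal(d1$birth, 0.5, tolerance = 1e-4)
  expect_equal(d1$death, sqrt(2) / 2, tolerance = 1e-4)
  expect_equal(sum(b$dim == 2), 0)
})

test_that("collinear clouds have contractible alpha complexes", {
  cl3 <- pointCloud(rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0)))
  b <- bars(alphaBarcodes(cl3))
  expect_equal(sum(b$dim > 0), 0)
  expect_equal(sort(b$death[b$dim == 0 & is.finite(b$death)]),
               c(0.5, 1))  # half the consecutive gaps
  # more points on a line, unsorted input
  cl6 <- pointCloud(cbind(c(4, 0, 2.2, 9, 6.1, 1), 0, 0))
  b6 <- bars(alphaBarcodes(cl6))
  expect_equal(sum(b6$dim > 0), 0)
  gaps <- diff(sort(c(4, 0, 2.2, 9, 6.1, 1))) / 2
  expect_equal(sort(b6$death[is.finite(b6$death)]), sort(gaps),
               tolerance = 1e-9)
})

test_that("obtuse triangle: alpha equals the Cech oracle (min-ball rule)", {
  cl <- pointCloud(rbind(c(0, 0, 0), c(4, 0, 0), c(1, 0.5, 0)))
  expect_same_diagram(alphaBarcodes(cl), bruteForceCech(cl), tol = 1e-5)
})

test_that("elementFilter restricts by element and preserves order", {
  cl <- pointCloud(diag(3), c("C", "N", "C"))
  expect_equal(nrow(coords(elementFilter(cl, "C"))), 2)
  expect_equal(nrow(coords(elementFilter(cl, "P"))), 0)
  g <- pointCloud(matrix(rnorm(12), 4), c("N", "C", "C", "O"))
  expect_equal(elements(elementFilter(g, c("C", "N"))), c("N", "C", "C"))
})

test_that("VR engine matches the brute-force oracle on random clouds", {
  for (seed in 1:15) {
    n <- 4 + seed %% 5
    cl <- randCloud(n, seed)
    expect_same_diagram(vrBarcodes(cl, rf = 10, maxHomDim = 2),
                        bruteForceVR(cl, rf = 10, maxHomDim = 2))
  }
})

test_that("alpha engine matches the brute-force Cech oracle", {
  for (seed in 101:115) {
    n <- 4 + seed %% 5
    cl <- randCloud(n, seed)
    expect_same_diagram(alphaBarcodes(cl), bruteForceCech(cl),
                        tol = 1e-6)
  }
})

test_that("barcodes are scale-equivariant and rigid-motion invariant", {
  cl <- randCloud(7, 77)
  s <- 2.37
  for (fn in list(function(c_) vrBarcodes(c_, rf = 50),
                  alphaBarcodes)) {
    b1 <- bars(fn(cl))
    b2 <- bars(fn(pointCloud(coords(cl) * s)))
    fin <- is.finite(b1$death)
    expect_equal(b2$birth, b1$birth * s, tolerance = 1e-9)
    expect_equal(b2$death[fin], b1$death[fin] * s, tolerance = 1e-9)
  }
  # random rotation + translation
  set.seed(8)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  moved <- pointCloud(sweep(coords(cl) %*% R, 2, c(5, -3, 2), "+"))
  for (fn in list(function(c_) vrBarcodes(c_, rf = 50),
                  alphaBarcodes)) {
    b1 <- bars(fn(cl)); b2 <- bars(fn(moved))
    fin <- is.finite(b1$death)
    expect_equal(b2$birth, b1$birth, tolerance = 1e-9)
    expect_equal(b2$death[fin], b1$death[fin], tolerance = 1e-9)
  }
})

test_that("dim-0 structure: n bars total, finite deaths = MST weights", {
  for (seed in 21:26) {
    n <- 10 + seed
    cl <- randCloud(n, seed, scale = 5)
    b <- bars(vrBarcodes(cl, rf = 50, maxHomDim = 0))
    d0 <- b[b$dim == 0, ]
    expect_equal(nrow(d0), n)
    expect_equal(sum(!is.finite(d0$death)), 1)
    expect_equal(sort(d0$death[is.finite(d0$death)]),
                 mstWeights(coords(cl)), tolerance = 1e-9)
  }
})

test_that("bars alive at r_f are right-censored and flagged", {
  bc <- vrBarcodes(unitSquare(), rf = 1.2, maxHomDim = 2)
  b <- bars(bc)
  d1 <- b[b$dim == 1, ]
  expect_equal(nrow(d1), 1)
  expect_equal(d1$death, 1.2)   # the loop would die at sqrt(2) > rf
  expect_true(d1$censored)
  # components never censored: still one essential bar
  expect_equal(sum(b$dim == 0 & !is.finite(b$death)), 1)
})

test_that("barcode CSV export/import round trips including inf", {
  bc <- vrBarcodes(unitSquare(), rf = 3, maxHomDim = 2)
  f <- tempfile(fileext = ".csv")
  exportBarcode(bc, f)
  expect_true(any(grepl("inf", readLines(f))))
  bc2 <- importBarcode(f, complex = "vr", rf = 3)
  expect_equal(bars(bc2)$birth, bars(bc)$birth, tolerance = 1e-9)
  expect_equal(bars(bc2)$death, bars(bc)$death, tolerance = 1e-9)
})
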