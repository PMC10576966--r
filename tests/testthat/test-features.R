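# Barcode vectorization and the four feature blocks.

mkBarcode <- function(dims, births, deaths) {
  b <- data.frame(dim = as.integer(dims), birth = births, death = deaths,
                  censored = logical(length(dims)))
  b <- b[order(b$dim, b$birth, b$death), ]
  rownames(b) <- NULL
  new("Barcode", bars = b, complex = "vr", rf = 10, maxHomDim = 2L)
}

test_that("binCounts uses half-open death-time bins", {
  empty <- mkBarcode(integer(0), numeric(0), numeric(0))
  expect_equal(binCounts(empty, c(0.5, 1, 1.5), 0), c(0L, 0L))
  sq <- vrBarcodes(unitSquare(), rf = 3)
  expect_equal(binCounts(sq, c(0.5, 1.0, 1.5), 0), c(3L, 0L))  # 1.0 in (0.5,1]
  expect_length(binCounts(sq, c(1.2, 1.3, 1.4, 1.5, 1.6, 2.0), 0), 5)
  # birth binning option
  expect_equal(binCounts(sq, c(0.5, 1.5), 1, quantity = "birth"), 1L)
})

test_that("barcodeStats returns the 15 statistics in fixed order", {
  bc <- mkBarcode(c(1, 1), c(1, 1), c(2, 4))
  expect_equal(barcodeStats(bc, 1),
               c(1, 1, 1, 2, 0,  4, 2, 3, 6, 1,  3, 1, 2, 4, 1))
  expect_equal(barcodeStats(bc, 2), rep(0, 15))
  one <- mkBarcode(1, 0.5, 0.70711)
  s <- barcodeStats(one, 1)
  expect_equal(s[c(5, 10, 15)], rep(0, 3))        # sd of n = 1
  expect_equal(s[4], 0.5)                          # sum = the single value
  expect_equal(s[9], 0.70711)
})

test_that("tf1 matches hand-derived values on a square of side 1.4", {
  v <- tf1(unitSquare(1.4))
  expect_length(v, 48)
  expect_true(all(is.finite(v)))
  d0bins <- v[1:5]
  expect_equal(unname(d0bins), c(0, 3, 0, 0, 0))   # three deaths at 1.4
  d1bins <- v[6:10]
  expect_equal(unname(d1bins), c(1, 0, 0, 0, 0))   # death 1.4*sqrt(2)=1.98
  expect_equal(unname(v[11:13]), c(0, 0, 0))       # no dim-2 bars
  expect_equal(unname(v["tf1_d0_bl_2nd"]), 1.4)
  expect_equal(unname(v["tf1_d0_bl_3rd"]), 1.4)
  expect_equal(unname(v["tf1_d0_bl_sum"]), 4.2)
  expect_equal(unname(v["tf1_d0_bl_mean"]), 1.4)
  expect_equal(unname(v["tf1_d1_longest_onset"]), 1.4)
  expect_equal(unname(v["tf1_d1_bl_max"]), 1.4 * sqrt(2) - 1.4)
})

test_that("tf1 of a single atom is all zeros", {
  v <- tf1(pointCloud(matrix(c(1, 2, 3), 1)))
  expect_equal(unname(v), rep(0, 48))
  expect_error(tf1(pointCloud(matrix(0, 0, 3))), "empty")
})

test_that("tf2 matches the alpha closed form on the unit square", {
  v <- tf2(unitSquare())
  expect_length(v, 30)
  expect_equal(unname(v[1:5]), c(0.5, 0.5, 0.5, 0.5, 0),
               tolerance = 1e-4)                      # dim-1 BT stats
  expect_equal(unname(v[6:9]), rep(sqrt(2) / 2, 4), tolerance = 1e-4)
  expect_equal(unname(v[11:14]), rep(sqrt(2) / 2 - 0.5, 4),
               tolerance = 1e-3)
  expect_equal(unname(v[16:30]), rep(0, 15))          # no dim-2 bars
  vc <- tf2(pointCloud(cbind(c(0, 1.5, 3, 4.1), 0, 0)))
  expect_equal(unname(vc), rep(0, 30))                # collinear cloud
})

test_that("tf3 encodes each residue's covalent fingerprint", {
  s <- synthStructure("GKG", conformation = "extended")
  w <- extractWindow("GKG", 2)
  v <- tf3(s, w)
  expect_length(v, 240)
  # offsets -1 and +1 are glycines: MST deaths {1.23, 1.46, 1.52}
  gly <- c(1, 1, 4, 1.23 + 1.46 + 1.52, 0, 0)
  expect_equal(unname(v[(19 * 6 + 1):(20 * 6)]), gly, tolerance = 1e-6)
  expect_equal(unname(v[(20 * 6 + 1):(21 * 6)]), gly, tolerance = 1e-6)
  # all other offsets are X
  expect_equal(unname(v[-(115:126)]), rep(0, 228))
})

test_that("tf3 of an isolated lysine window is all zeros", {
  s <- synthStructure("K", conformation = "extended")
  v <- tf3(s, extractWindow("K", 1))
  expect_equal(unname(v), rep(0, 240))
})

test_that("tf3 per-residue 0-bar count equals the heavy-atom count", {
  fx <- demoStructureWindow(seed = 31)
  v <- tf3(fx$structure, fx$window)
  offs <- c(-20:-1, 1:20)
  n0 <- v[seq(3, 240, by = 6)]
  for (i in seq_along(offs)) {
    rn <- fx$window@center + offs[i]
    expected <- if (rn < 1 || rn > nchar(proteinSequence(fx$structure)))
      0 else nrow(residueHeavyAtoms(fx$structure, rn))
    expect_equal(unname(n0[i]), expected)
  }
})

test_that("tf4 counts nitrogen components of the local region", {
  s <- synthStructure("GGKGG", conformation = "extended")
  v <- tf4(s, extractWindow("GGKGG", 3))
  expect_length(v, 38)
  # 5 backbone N (incl. the lysine NZ = 6 N atoms) spaced < 10 apart:
  # finite 0-bars = atoms - 1 component
  cl <- windowPointCloud(s, 3, 2)
  nN <- sum(elements(cl) == "N")
  expect_equal(unname(v[38]), nN - 1)
  # carbon-only block reacts to the C sub-cloud only
  expect_true(any(v[20:22] > 0))
})

test_that("featurize is the concatenation of the four blocks", {
  fx <- demoStructureWindow(seed = 12)
  v <- featurize(fx$structure, fx$window)
  expect_length(v, 356)
  expect_true(all(is.finite(v)))
  cloud <- windowPointCloud(fx$structure, fx$window@center, 20L)
  expect_equal(unname(v),
               unname(c(tf1(cloud), tf2(cloud),
                        tf3(fx$structure, fx$window),
                        tf4(fx$structure, fx$window))))
})

test_that("featurize is invariant under rigid motion and atom order", {
  fx <- demoStructureWindow(seed = 13, noiseSd = 0.03)
  v <- featurize(fx$structure, fx$window)
  set.seed(99)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  s2 <- fx$structure
  xyz <- as.matrix(atoms(s2)[c("x", "y", "z")]) %*% R
  s2@atoms$x <- xyz[, 1] + 11
  s2@atoms$y <- xyz[, 2] - 4
  s2@atoms$z <- xyz[, 3] + 0.5
  expect_equal(featurize(s2, fx$window), v, tolerance = 1e-6)
  # permute atom rows within the file
  s3 <- fx$structure
  set.seed(100)
  s3@atoms <- s3@atoms[sample(nrow(s3@atoms)), ]
  expect_equal(featurize(s3, fx$window), v, tolerance = 1e-9)
})

test_that("feature names are stable and block-partitioned", {
  fn <- topoFeatureNames()
  expect_equal(nrow(fn), 356)
  expect_equal(as.vector(table(fn$block)[c("tf1", "tf2", "tf3", "tf4")]),
               c(48L, 30L, 240L, 38L))
  expect_equal(fn$id[1], "f_0001")
  expect_equal(fn$id[356], "f_0356")
  expect_false(anyDuplicated(fn$name) > 0)
})

test_that("featurizeSet builds an annotated SummarizedExperiment", {
  ds <- synthDataset(2, 2, seed = 3, noiseSd = 0.02)
  se <- featurizeSet(ds$structures, ds$windows)
  expect_s4_class(se, "SummarizedExperiment")
  expect_equal(dim(se), c(356L, 4L))
  expect_equal(SummarizedExperiment::colData(se)$label,
               c("positive", "positive", "negative", "negative"))
  expect_true(all(is.finite(SummarizedExperiment::assay(se))))
  f <- tempfile(fileext = ".tsv")
  writeFeatureMatrix(se, f)
  tab <- read.delim(f, check.names = FALSE)
  expect_equal(dim(tab), c(4L, 359L))
  expect_true(file.exists(paste0(f, ".names.json")))
})
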