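# Shared fixtures and small utilities, all built in code.

unitSquare <- function(side = 1) {
  pointCloud(rbind(c(0, 0, 0), c(side, 0, 0), c(side, side, 0),
                   c(0, side, 0)))
}

equilateralTriangle <- function(side = 1) {
  pointCloud(rbind(c(0, 0, 0), c(side, 0, 0),
                   c(side / 2, side * sqrt(3) / 2, 0)))
}

randCloud <- function(n, seed, scale = 3) {
  set.seed(seed)
  pointCloud(matrix(runif(3 * n, 0, scale), ncol = 3))
}

# minimum-spanning-tree edge weights (Prim), independent of the PH engine
mstWeights <- function(X) {
  D <- as.matrix(dist(X))
  n <- nrow(D)
  inTree <- c(TRUE, rep(FALSE, n - 1))
  w <- numeric(0)
  while (sum(inTree) < n) {
    sub <- D[inTree, !inTree, drop = FALSE]
    w <- c(w, min(sub))
    j <- which(!inTree)[which(sub == min(sub), arr.ind = TRUE)[1, 2]]
    inTree[j] <- TRUE
  }
  sort(w)
}

# sorted finite bars of one dimension as a plain matrix, for diagram
# comparison
finiteDiagram <- function(barcode, d) {
  b <- bars(barcode)
  b <- b[b$dim == d & is.finite(b$death), c("birth", "death")]
  as.matrix(b[order(b$birth, b$death), , drop = FALSE])
}

expect_same_diagram <- function(a, b, tol = 1e-8) {
  for (d in 0:2) {
    da <- finiteDiagram(a, d)
    db <- finiteDiagram(b, d)
    expect_equal(nrow(da), nrow(db),
                 info = paste("finite bar count, dim", d))
    if (nrow(da) > 0)
      expect_lt(max(abs(da - db)), tol)
    ia <- sum(bars(a)$dim == d & !is.finite(bars(a)$death))
    ib <- sum(bars(b)$dim == d & !is.finite(bars(b)$death))
    expect_equal(ia, ib, info = paste("essential bar count, dim", d))
  }
}

# a tiny structure + matching window for feature tests
demoStructureWindow <- function(seq = NULL, conformation = "compact",
                                noiseSd = 0, seed = 5) {
  if (is.null(seq)) {
    set.seed(seed)
    s <- sample(c("A", "G", "S", "L", "V", "T", "E", "R"), 41,
                replace = TRUE)
    s[21] <- "K"
    seq <- paste(s, collapse = "")
  }
  structure <- synthStructure(seq, conformation, noiseSd = noiseSd,
                              seed = seed)
  pos <- as.integer(regexpr("K", seq))
  list(structure = structure, window = extractWindow(seq, pos))
}
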