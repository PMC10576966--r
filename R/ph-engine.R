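# Persistence barcodes of element-labelled point clouds.
#
# Production paths: the compiled Vietoris-Rips clique filtration and the
# compiled Delaunay/Alpha filtration. The pure-R brute-force oracles live in
# oracles.R and share only the bar post-processing below, so the two routes
# stay independent up to the common bookkeeping (censoring, zero-length
# discard, ordering).

#' Construct a PointCloud
#'
#' @param coords numeric matrix (n x 3) of coordinates in Angstrom.
#' @param elements chemical symbols, one per row; defaults to carbon.
#' @return a \linkS4class{PointCloud}.
#' @export
pointCloud <- function(coords, elements = NULL) {
  coords <- as.matrix(coords)
  if (is.null(elements)) elements <- rep("C", nrow(coords))
  new("PointCloud", coords = coords, elements = as.character(elements))
}

#' Element-specific sub-cloud
#'
#' Restricts a cloud to atoms of the given element(s), preserving order.
#' This is the element-specific persistent homology (ESPH) device: carbon-
#' only clouds expose hydrophobic packing, nitrogen-only clouds the
#' hydrogen-bonding skeleton.
#'
#' @param cloud a \linkS4class{PointCloud}.
#' @param elements character vector of symbols to keep, e.g. \code{"C"}.
#' @return a \linkS4class{PointCloud}.
#' @export
elementFilter <- function(cloud, elements) {
  keep <- cloud@elements %in% elements
  new("PointCloud", coords = cloud@coords[keep, , drop = FALSE],
      elements = cloud@elements[keep])
}

# Shared bar post-processing: right-censor unpaired positive-dimensional
# bars at rf, discard zero-length pairs (relative tolerance so that the
# mutually-cancelling huge circumradii of near-degenerate Alpha slivers
# cannot leak through), and order bars by (dim, birth, death).
.makeBarcode <- function(pairs, complex, rf, maxHomDim) {
  b <- data.frame(dim = as.integer(pairs[, 1]), birth = pairs[, 2],
                  death = pairs[, 3])
  b$censored <- FALSE
  if (is.finite(rf)) {
    cens <- b$dim > 0 & !is.finite(b$death)
    b$death[cens] <- rf
    b$censored[cens] <- TRUE
  }
  keep <- b$death > b$birth + 1e-5 * pmax(1, abs(b$birth))
  b <- b[keep, , drop = FALSE]
  b <- b[order(b$dim, b$birth, b$death), , drop = FALSE]
  rownames(b) <- NULL
  new("Barcode", bars = b, complex = complex, rf = rf,
      maxHomDim = as.integer(maxHomDim))
}

#' Vietoris-Rips persistence barcode
#'
#' Computes the persistence barcode of the Vietoris-Rips clique filtration
#' of a point cloud, on the pairwise-distance scale: a simplex enters the
#' filtration when its largest pairwise distance reaches the filtration
#' value. Simplices are enumerated up to dimension \code{maxHomDim + 1} and
#' capped at \code{rf}; classes of positive dimension still alive at
#' \code{rf} are right-censored to death \code{rf} and flagged. The final
#' complex keeps one essential (infinite) dim-0 bar per connected
#' component.
#'
#' @param cloud a \linkS4class{PointCloud}.
#' @param rf ending filtration value in Angstrom.
#' @param maxHomDim largest homology dimension (0, 1 or 2).
#' @return a \linkS4class{Barcode}.
#' @examples
#' sq <- pointCloud(rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0)))
#' bars(vrBarcodes(sq, rf = 3))
#' @export
vrBarcodes <- function(cloud, rf = 7, maxHomDim = 2) {
  if (nrow(cloud@coords) == 0) stop("empty point cloud")
  stopifnot(rf > 0)
  pairs <- cpp_vr_pairs(cloud@coords, rf, as.integer(maxHomDim))
  .makeBarcode(pairs, "vr", rf, maxHomDim)
}

#' Alpha-complex persistence barcode
#'
#' Computes the persistence barcode of the Alpha filtration (the nerve of
#' Voronoi-restricted balls, a subcomplex of the Delaunay triangulation) on
#' the ball-radius scale in Angstrom. The Delaunay complex is finite, so no
#' filtration cap is needed. Inputs with degenerate geometry (collinear or
#' coplanar quadruples) are perturbed by a deterministic jitter of
#' \code{jitterSd} Angstrom before triangulation — far below any feature
#' bin width; fully collinear clouds are triangulated as a path along the
#' line.
#'
#' @param cloud a \linkS4class{PointCloud}.
#' @param maxHomDim largest homology dimension (0, 1 or 2).
#' @param jitterSd scale of the degeneracy-breaking perturbation.
#' @return a \linkS4class{Barcode}.
#' @examples
#' sq <- pointCloud(rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0)))
#' bars(alphaBarcodes(sq))  # one dim-1 bar (0.5, sqrt(2)/2)
#' @export
alphaBarcodes <- function(cloud, maxHomDim = 2, jitterSd = 1e-6) {
  X <- cloud@coords
  if (nrow(X) == 0) stop("empty point cloud")
  if (nrow(X) >= 2) {
    # exactly collinear clouds: the Delaunay complex is the path along the
    # line; components merge at half the consecutive gaps, nothing else
    ctr <- sweep(X, 2, colMeans(X))
    sv <- svd(ctr, nu = 0, nv = 0)$d
    if (sv[1] == 0 || all(sv[-1] <= 1e-12 * sv[1])) {
      t <- sort(as.vector(ctr %*% svd(ctr, nv = 3)$v[, 1]))
      pairs <- cbind(0, 0, c(diff(t) / 2, Inf))
      return(.makeBarcode(pairs, "alpha", NA_real_, maxHomDim))
    }
  }
  res <- cpp_alpha_pairs(X, as.integer(maxHomDim))
  attempt <- 0
  while (res$degenerate && attempt < 3) {
    attempt <- attempt + 1
    jit <- .withLocalSeed(20230 + attempt, {
      matrix(rnorm(length(X), sd = jitterSd * 10^(attempt - 1)),
             nrow = nrow(X))
    })
    res <- cpp_alpha_pairs(X + jit, as.integer(maxHomDim))
  }
  if (res$degenerate)
    stop("Alpha triangulation failed on degenerate input")
  pairs <- res$pairs
  pairs[, 2:3] <- sqrt(pairs[, 2:3])  # squared radius -> radius, Angstrom
  .makeBarcode(pairs, "alpha", NA_real_, maxHomDim)
}

# evaluate expr under a fixed RNG state without disturbing the caller's
.withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Export a barcode as CSV
#'
#' Header \code{dim,birth,death}; infinite deaths are written as
#' \code{inf}.
#'
#' @param barcode a \linkS4class{Barcode}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
exportBarcode <- function(barcode, path) {
  b <- barcode@bars
  d <- ifelse(is.finite(b$death), format(b$death, digits = 12), "inf")
  writeLines(c("dim,birth,death",
               paste(b$dim, format(b$birth, digits = 12), d, sep = ",")),
             path)
  invisible(path)
}

#' Import a barcode CSV written by \code{exportBarcode}
#'
#' @param path input path.
#' @param complex filtration tag to record.
#' @param rf filtration cap to record (\code{NA} if none).
#' @param maxHomDim largest homology dimension recorded.
#' @return a \linkS4class{Barcode}.
#' @export
importBarcode <- function(path, complex = "vr", rf = NA_real_,
                          maxHomDim = 2) {
  d <- read.table(path, header = TRUE, sep = ",",
                  stringsAsFactors = FALSE)
  death <- suppressWarnings(as.numeric(ifelse(d$death == "inf", Inf,
                                              d$death)))
  b <- data.frame(dim = as.integer(d$dim), birth = as.numeric(d$birth),
                  death = death, censored = FALSE)
  b <- b[order(b$dim, b$birth, b$death), , drop = FALSE]
  rownames(b) <- NULL
  new("Barcode", bars = b, complex = complex, rf = rf,
      maxHomDim = as.integer(maxHomDim))
}
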