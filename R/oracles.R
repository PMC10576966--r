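# Brute-force persistence oracles.
#
# Deliberately naive pure-R realizations of the same homology computations
# as the compiled engines: enumerate every candidate simplex, sort the
# filtration, reduce the full boundary matrix over GF(2). They exist to
# cross-check the production paths on small clouds and are capped
# accordingly.

# boundary-matrix reduction over GF(2) on an explicit filtration
# simp: list of integer vertex vectors (sorted); value, dim: parallel
.reduceFiltration <- function(simp, value, dim, maxHomDim) {
  m <- length(simp)
  ord <- order(value, dim, vapply(simp, function(v)
    paste(sprintf("%06d", v), collapse = ""), ""))
  simp <- simp[ord]; value <- value[ord]; dim <- dim[ord]
  key <- vapply(simp, function(v) paste(v, collapse = "."), "")
  pos <- seq_len(m)
  names(pos) <- key

  cols <- vector("list", m)
  for (j in seq_len(m)) {
    if (dim[j] == 0) { cols[[j]] <- integer(0); next }
    v <- simp[[j]]
    f <- vapply(seq_along(v), function(drop)
      pos[[paste(v[-drop], collapse = ".")]], 1L)
    cols[[j]] <- sort(f)
  }

  low_of <- integer(m)  # pivot row -> column, 0 = none
  is_death <- logical(m)
  killed <- logical(m)
  pairs <- matrix(0L, 0, 2)
  for (j in seq_len(m)) {
    col <- cols[[j]]
    while (length(col) > 0) {
      lw <- col[length(col)]
      k <- low_of[lw]
      if (k == 0) break
      col <- sort(c(setdiff(col, cols[[k]]), setdiff(cols[[k]], col)))
    }
    cols[[j]] <- col
    if (length(col) > 0) {
      lw <- col[length(col)]
      low_of[lw] <- j
      pairs <- rbind(pairs, c(lw, j))
      is_death[j] <- TRUE
      killed[lw] <- TRUE
    }
  }
  out <- NULL
  if (nrow(pairs) > 0)
    out <- cbind(dim[pairs[, 1]], value[pairs[, 1]], value[pairs[, 2]])
  ess <- which(!is_death & !killed & dim <= maxHomDim)
  if (length(ess) > 0)
    out <- rbind(out, cbind(dim[ess], value[ess], Inf))
  keep <- out[, 1] <= maxHomDim
  out[keep, , drop = FALSE]
}

.allSubsets <- function(n, maxSize) {
  out <- list()
  for (k in seq_len(min(maxSize, n)))
    out <- c(out, utils::combn(n, k, simplify = FALSE))
  out
}

#' Brute-force Vietoris-Rips persistence (test oracle)
#'
#' Enumerates every subset of up to 4 points, assigns the largest pairwise
#' distance as filtration value, and reduces the full boundary matrix over
#' GF(2). Capped at 10 points; this is the reference implementation the
#' production engine is validated against, not a production path.
#'
#' @param cloud a \linkS4class{PointCloud} with at most 10 points.
#' @param rf ending filtration value (simplices above it are omitted and
#'   surviving classes censored, as in \code{\link{vrBarcodes}}).
#' @param maxHomDim largest homology dimension (0, 1 or 2).
#' @return a \linkS4class{Barcode}.
#' @export
bruteForceVR <- function(cloud, rf = Inf, maxHomDim = 2) {
  X <- cloud@coords
  n <- nrow(X)
  if (n == 0) stop("empty point cloud")
  if (n > 10) stop("brute-force VR oracle is capped at 10 points")
  D <- as.matrix(dist(X))
  subs <- .allSubsets(n, maxHomDim + 2)
  val <- vapply(subs, function(s)
    if (length(s) == 1) 0 else max(D[s, s]), 1.0)
  keep <- val <= rf
  pairs <- .reduceFiltration(subs[keep], val[keep],
                             vapply(subs[keep], length, 1L) - 1L, maxHomDim)
  .makeBarcode(pairs, "vr-bruteforce", rf, maxHomDim)
}

# radius of the minimum enclosing ball of <= 5 points (support enumeration)
.minBallRadius <- function(P) {
  n <- nrow(P)
  if (n == 1) return(0)
  best <- Inf
  sub <- .allSubsets(n, min(n, 4))
  for (s in sub) {
    if (length(s) < 2) next
    cs <- .circumsphere(P[s, , drop = FALSE])
    if (!is.finite(cs$r2)) next
    d2 <- colSums((t(P) - cs$center)^2)
    if (all(d2 <= cs$r2 * (1 + 1e-9) + 1e-12) && cs$r2 < best)
      best <- cs$r2
  }
  sqrt(best)
}

# smallest sphere through all rows of P within their affine hull
.circumsphere <- function(P) {
  B <- sweep(P[-1, , drop = FALSE], 2, P[1, ])
  G <- B %*% t(B)
  w <- tryCatch(solve(2 * G, rowSums(B^2)),
                error = function(e) NULL)
  if (is.null(w)) return(list(center = P[1, ], r2 = Inf))
  off <- drop(t(B) %*% w)
  list(center = P[1, ] + off, r2 = sum(off^2))
}

#' Brute-force Cech persistence (Alpha-complex test oracle)
#'
#' Enumerates every subset of up to 4 points with the radius of its minimum
#' enclosing ball as filtration value (the Cech rule: a simplex enters when
#' its vertices fit in a common ball). The Cech and Alpha filtrations have
#' identical persistence diagrams, so this oracle validates
#' \code{\link{alphaBarcodes}}. Capped at 8 points.
#'
#' @param cloud a \linkS4class{PointCloud} with at most 8 points.
#' @param maxHomDim largest homology dimension (0, 1 or 2).
#' @return a \linkS4class{Barcode}.
#' @export
bruteForceCech <- function(cloud, maxHomDim = 2) {
  X <- cloud@coords
  n <- nrow(X)
  if (n == 0) stop("empty point cloud")
  if (n > 8) stop("brute-force Cech oracle is capped at 8 points")
  subs <- .allSubsets(n, maxHomDim + 2)
  val <- vapply(subs, function(s)
    .minBallRadius(X[s, , drop = FALSE]), 1.0)
  pairs <- .reduceFiltration(subs, val,
                             vapply(subs, length, 1L) - 1L, maxHomDim)
  .makeBarcode(pairs, "cech", NA_real_, maxHomDim)
}
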