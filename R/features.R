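# Vectorization of persistence barcodes into the four topological feature
# blocks (48 + 30 + 240 + 38 = 356 features per peptide window).
#
# Conventions used throughout:
#  * all bins are half-open (lo, hi] and count bars by DEATH time;
#  * statistics and bar-length sums use finite bars only (the essential
#    dim-0 bar is excluded; censored bars count as dying at r_f);
#  * the standard deviation is population-style (divide by n), so a single
#    bar contributes 0;
#  * an empty bar set yields zeros.

# finite bars of one dimension, as a data.frame
.finiteBars <- function(barcode, d) {
  b <- barcode@bars
  b[b$dim == d & is.finite(b$death), , drop = FALSE]
}

#' Count bars by death time in half-open bins
#'
#' The binning approach (BA): the number of finite bars of the given
#' dimension whose death time (or birth time) falls in each half-open bin
#' \code{(edges[i], edges[i+1]]}.
#'
#' @param barcode a \linkS4class{Barcode}.
#' @param edges strictly increasing bin edges in Angstrom (length >= 2).
#' @param dim homology dimension of the bars to count.
#' @param quantity \code{"death"} (default) or \code{"birth"}.
#' @return integer vector of length \code{length(edges) - 1}.
#' @export
binCounts <- function(barcode, edges, dim = 0, quantity = c("death",
                                                            "birth")) {
  quantity <- match.arg(quantity)
  stopifnot(length(edges) >= 2, all(diff(edges) > 0))
  b <- .finiteBars(barcode, dim)
  x <- b[[quantity]]
  vapply(seq_len(length(edges) - 1), function(i)
    sum(x > edges[i] & x <= edges[i + 1]), 1L)
}

.popSd <- function(x) if (length(x) == 0) 0 else
  sqrt(mean((x - mean(x))^2))

.fiveStats <- function(x) {
  if (length(x) == 0) return(rep(0, 5))
  c(max(x), min(x), mean(x), sum(x), .popSd(x))
}

#' Barcode statistics of one dimension
#'
#' The barcode-statistics (BS) vectorization: maximum, minimum, mean,
#' summation and (population) standard deviation of the birth times, death
#' times and bar lengths of the finite bars of a dimension — 15 values in
#' that fixed order. No bars yield 15 zeros.
#'
#' @param barcode a \linkS4class{Barcode}.
#' @param dim homology dimension.
#' @return numeric vector of length 15.
#' @export
barcodeStats <- function(barcode, dim = 1) {
  b <- .finiteBars(barcode, dim)
  c(.fiveStats(b$birth), .fiveStats(b$death),
    .fiveStats(b$death - b$birth))
}

# bar lengths ranked longest-first; ties broken by earlier birth, then
# original order
.rankedLengths <- function(b) {
  if (nrow(b) == 0) return(numeric(0))
  len <- b$death - b$birth
  len[order(-len, b$birth, seq_len(nrow(b)))]
}

.TF1_D0_EDGES <- c(1.2, 1.3, 1.4, 1.5, 1.6, 2.0)
.TF1_D1_EDGES <- c(1.5, 2.7, 3.5, 4.5, 5, 6.7)
.TF1_D2_EDGES <- c(2.4, 2.9, 5.5, 6.7)
.TF3_EDGES <- c(1.25, 1.5, 1.75)
.TF4_ALL_EDGES <- seq(1.2, 1.6, by = 0.1)
.TF4_C_EDGES <- seq(1.5, 3.0, by = 0.5)
.RF_WINDOW <- 7
.RF_RESIDUE <- 6
.RF_LOCAL <- 7
.RF_LOCAL_N <- 12

#' TF1: whole-window Vietoris-Rips features (48 values)
#'
#' VR barcode of the full window cloud (dims 0-2, r_f = 7 Angstrom), then:
#' dim-0 death counts over bins with edges 1.2-2.0 (5), dim-1 death counts
#' over 1.5-6.7 (5), dim-2 death counts over 2.4-6.7 (3), the second and
#' third longest dim-0 bar lengths (2), the sum and mean of dim-0 bar
#' lengths (2), the birth of the longest dim-1 bar (1), and the barcode
#' statistics of dims 1 and 2 (15 + 15).
#'
#' @param windowCloud \linkS4class{PointCloud} of the 41-residue window.
#' @return named numeric vector of length 48.
#' @export
tf1 <- function(windowCloud) {
  bc <- vrBarcodes(windowCloud, rf = .RF_WINDOW, maxHomDim = 2)
  b0 <- .finiteBars(bc, 0)
  b1 <- .finiteBars(bc, 1)
  len0 <- .rankedLengths(b0)
  second <- if (length(len0) >= 2) len0[2] else 0
  third <- if (length(len0) >= 3) len0[3] else 0
  onset <- if (nrow(b1) == 0) 0 else {
    len1 <- b1$death - b1$birth
    b1$birth[order(-len1, b1$birth, seq_len(nrow(b1)))][1]
  }
  out <- c(binCounts(bc, .TF1_D0_EDGES, 0),
           binCounts(bc, .TF1_D1_EDGES, 1),
           binCounts(bc, .TF1_D2_EDGES, 2),
           second, third,
           sum(b0$death - b0$birth),
           if (nrow(b0) == 0) 0 else mean(b0$death - b0$birth),
           onset,
           barcodeStats(bc, 1), barcodeStats(bc, 2))
  names(out) <- .tf1Names()
  out
}

#' TF2: whole-window Alpha-complex features (30 values)
#'
#' Barcode statistics of the dim-1 and dim-2 bars of the Alpha filtration
#' of the window cloud (15 + 15 values). Alpha bars capture cycles and
#' voids of the molecular body at the ball-radius scale.
#'
#' @param windowCloud \linkS4class{PointCloud} of the 41-residue window.
#' @return named numeric vector of length 30.
#' @export
tf2 <- function(windowCloud) {
  bc <- alphaBarcodes(windowCloud, maxHomDim = 2)
  out <- c(barcodeStats(bc, 1), barcodeStats(bc, 2))
  names(out) <- .tf2Names()
  out
}

#' TF3: per-residue Vietoris-Rips features (240 values)
#'
#' For each of the 40 flanking residues of the window, in order (offsets
#' -20..-1 then +1..+20 from the central lysine), the VR barcode of that
#' residue's own heavy atoms (r_f = 6 Angstrom) yields six values: dim-0
#' death counts in (1.25, 1.5] and (1.5, 1.75] (the covalent-bond bins
#' that fingerprint the residue type), the total number of 0-bars (finite
#' plus essential, i.e. the heavy-atom count), and the bar-length sums of
#' dims 0, 1 and 2. Offsets outside the sequence are the dummy code X and
#' contribute six zeros.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param window a \linkS4class{PeptideWindow} mapping onto it.
#' @return named numeric vector of length 240.
#' @export
tf3 <- function(structure, window) {
  center <- window@center
  L <- nchar(structure@sequence)
  if (center < 1 || center > L ||
      substr(structure@sequence, center, center) != "K")
    stop("window center does not map to a lysine of the structure")
  out <- numeric(0)
  for (off in c(-20:-1, 1:20)) {
    rn <- center + off
    if (rn < 1 || rn > L) { out <- c(out, rep(0, 6)); next }
    a <- residueHeavyAtoms(structure, rn)
    if (nrow(a) == 0)
      stop("structure has no atoms for residue ", rn,
           " inside the window")
    cl <- pointCloud(as.matrix(a[c("x", "y", "z")]), a$element)
    bc <- vrBarcodes(cl, rf = .RF_RESIDUE, maxHomDim = 2)
    b <- bc@bars
    n0 <- sum(b$dim == 0) # finite + essential = atom count
    sums <- vapply(0:2, function(d) {
      fb <- .finiteBars(bc, d)
      sum(fb$death - fb$birth)
    }, 1.0)
    out <- c(out, binCounts(bc, .TF3_EDGES, 0), n0, sums)
  }
  names(out) <- .tf3Names()
  out
}

#' TF4: local-region Vietoris-Rips features (38 values)
#'
#' The local region is the five-residue fragment center-2 .. center+2.
#' Three VR analyses: (a) all heavy atoms — dim-0 death counts over four
#' 0.1-Angstrom bins spanning (1.2, 1.6] plus the dim-1 barcode statistics
#' (4 + 15); (b) the carbon-only sub-cloud (ESPH C) — dim-0 death counts
#' over three 0.5-Angstrom bins spanning (1.5, 3.0] plus the dim-1 barcode
#' statistics (3 + 15); (c) the nitrogen-only sub-cloud (ESPH N) — the
#' number of finite 0-bars dying below 10 Angstrom (1).
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param window a \linkS4class{PeptideWindow} mapping onto it.
#' @return named numeric vector of length 38.
#' @export
tf4 <- function(structure, window) {
  cloud <- windowPointCloud(structure, window@center, flank = 2L)
  bcAll <- vrBarcodes(cloud, rf = .RF_LOCAL, maxHomDim = 1)
  a <- c(binCounts(bcAll, .TF4_ALL_EDGES, 0), barcodeStats(bcAll, 1))
  cC <- elementFilter(cloud, "C")
  b <- if (nrow(cC@coords) == 0) rep(0, 18) else {
    bcC <- vrBarcodes(cC, rf = .RF_LOCAL, maxHomDim = 1)
    c(binCounts(bcC, .TF4_C_EDGES, 0), barcodeStats(bcC, 1))
  }
  cN <- elementFilter(cloud, "N")
  cc <- if (nrow(cN@coords) == 0) 0 else {
    bcN <- vrBarcodes(cN, rf = .RF_LOCAL_N, maxHomDim = 0)
    f0 <- .finiteBars(bcN, 0)
    sum(f0$death < 10)
  }
  out <- c(a, b, cc)
  names(out) <- .tf4Names()
  out
}

.statNames <- function(prefix) {
  stats <- c("max", "min", "mean", "sum", "sd")
  qty <- c("bt", "dt", "bl")
  paste0(prefix, rep(qty, each = 5), "_", rep(stats, 3))
}

.binNames <- function(prefix, edges) {
  paste0(prefix, "(", edges[-length(edges)], ",", edges[-1], "]")
}

.tf1Names <- function() c(
  .binNames("tf1_d0_death_", .TF1_D0_EDGES),
  .binNames("tf1_d1_death_", .TF1_D1_EDGES),
  .binNames("tf1_d2_death_", .TF1_D2_EDGES),
  "tf1_d0_bl_2nd", "tf1_d0_bl_3rd", "tf1_d0_bl_sum", "tf1_d0_bl_mean",
  "tf1_d1_longest_onset",
  .statNames("tf1_d1_"), .statNames("tf1_d2_"))

.tf2Names <- function() c(.statNames("tf2_d1_"), .statNames("tf2_d2_"))

.tf3Names <- function() {
  offs <- c(-20:-1, 1:20)
  unlist(lapply(offs, function(o) {
    p <- sprintf("tf3_res%+d_", o)
    c(.binNames(paste0(p, "d0_death_"), .TF3_EDGES),
      paste0(p, c("n0bars", "d0_bl_sum", "d1_bl_sum", "d2_bl_sum")))
  }))
}

.tf4Names <- function() c(
  .binNames("tf4_all_d0_death_", .TF4_ALL_EDGES),
  .statNames("tf4_all_d1_"),
  .binNames("tf4_C_d0_death_", .TF4_C_EDGES),
  .statNames("tf4_C_d1_"),
  "tf4_N_n0bars_lt10")

#' Feature index table
#'
#' Stable identifiers (\code{f_0001} .. \code{f_0356}), block membership
#' and human-readable names of the 356 topological features.
#'
#' @return data.frame with columns \code{index}, \code{id}, \code{block},
#'   \code{name}.
#' @export
topoFeatureNames <- function() {
  nm <- c(.tf1Names(), .tf2Names(), .tf3Names(), .tf4Names())
  data.frame(index = seq_along(nm),
             id = sprintf("f_%04d", seq_along(nm)),
             block = rep(c("tf1", "tf2", "tf3", "tf4"),
                         times = c(48, 30, 240, 38)),
             name = nm, stringsAsFactors = FALSE)
}

#' Featurize one window: the 356-entry topological vector
#'
#' Concatenation of the TF1 (48), TF2 (30), TF3 (240) and TF4 (38) blocks.
#' Deterministic and invariant under rigid motion of the structure and
#' under atom reordering within the input file.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param window a \linkS4class{PeptideWindow} mapping onto it.
#' @return named numeric vector of length 356.
#' @export
featurize <- function(structure, window) {
  cloud <- windowPointCloud(structure, window@center, flank = 20L)
  c(tf1(cloud), tf2(cloud), tf3(structure, window),
    tf4(structure, window))
}

#' Featurize a WindowSet into a SummarizedExperiment
#'
#' Rows are the 356 features (with block annotation in \code{rowData});
#' columns are windows, with \code{proteinId}, \code{center} and
#' \code{label} in \code{colData}.
#'
#' @param structures named list of \linkS4class{ProteinStructure}s, keyed
#'   by protein id.
#' @param windowsSet a \linkS4class{WindowSet}.
#' @param verbose print progress every 25 windows.
#' @return a \code{SummarizedExperiment} with assay \code{"topo"}.
#' @export
featurizeSet <- function(structures, windowsSet, verbose = FALSE) {
  w <- windowsSet@windows
  fn <- topoFeatureNames()
  mat <- matrix(NA_real_, nrow = nrow(fn), ncol = nrow(w))
  for (i in seq_len(nrow(w))) {
    s <- structures[[w$proteinId[i]]]
    if (is.null(s)) stop("no structure for protein ", w$proteinId[i])
    pw <- new("PeptideWindow", proteinId = w$proteinId[i],
              center = as.integer(w$center[i]), peptide = w$peptide[i],
              label = w$label[i])
    mat[, i] <- featurize(s, pw)
    if (verbose && i %% 25 == 0)
      message("featurized ", i, "/", nrow(w), " windows")
  }
  rownames(mat) <- fn$id
  colnames(mat) <- paste0(w$proteinId, ":K", w$center)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(topo = mat),
    rowData = S4Vectors::DataFrame(block = fn$block, name = fn$name),
    colData = S4Vectors::DataFrame(proteinId = w$proteinId,
                                   center = w$center, label = w$label))
}

#' Write a feature matrix as TSV plus a JSON name map
#'
#' One row per window: \code{protein_id}, \code{position}, \code{label},
#' then \code{f_0001} .. \code{f_0356}; a sidecar \code{<path>.names.json}
#' maps feature ids to blocks and readable names.
#'
#' @param se the \code{SummarizedExperiment} from
#'   \code{\link{featurizeSet}}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureMatrix <- function(se, path) {
  mat <- t(SummarizedExperiment::assay(se, "topo"))
  cd <- SummarizedExperiment::colData(se)
  df <- data.frame(protein_id = cd$proteinId, position = cd$center,
                   label = cd$label, mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  fn <- topoFeatureNames()
  jsonlite::write_json(
    stats::setNames(lapply(seq_len(nrow(fn)), function(i)
      list(block = fn$block[i], name = fn$name[i])), fn$id),
    paste0(path, ".names.json"), auto_unbox = TRUE)
  invisible(path)
}
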