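#' @import methods
NULL

#' ProteinStructure: a parsed single-chain protein structure
#'
#' Holds the amino-acid sequence and an ordered table of atoms with element
#' labels and 1-based residue numbering. Residue numbers index directly into
#' the sequence, matching the convention of AlphaFold models where residue i
#' of the model is residue i of the UniProt sequence. Positions of the
#' sequence for which the file provides no atoms are recorded as \code{X}.
#'
#' @slot proteinId single identifier string.
#' @slot sequence one-letter amino-acid sequence (may contain \code{X} at
#'   positions with no resolved residue).
#' @slot atoms data.frame with columns \code{element}, \code{atomName},
#'   \code{residueNumber}, \code{residueName}, \code{x}, \code{y}, \code{z}
#'   (coordinates in Angstrom).
#' @exportClass ProteinStructure
setClass("ProteinStructure",
  representation(proteinId = "character", sequence = "character",
                 atoms = "data.frame"))

setValidity("ProteinStructure", function(object) {
  a <- object@atoms
  need <- c("element", "atomName", "residueNumber", "residueName",
            "x", "y", "z")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns", paste(need, collapse = ", ")))
  if (length(object@sequence) != 1L || length(object@proteinId) != 1L)
    return("proteinId and sequence must be single strings")
  if (nrow(a) > 0) {
    if (!all(is.finite(c(a$x, a$y, a$z))))
      return("atom coordinates must be finite")
    L <- nchar(object@sequence)
    if (any(a$residueNumber < 1L) || any(a$residueNumber > L))
      return("residue numbers must lie in [1, length(sequence)]")
    chr <- strsplit(object@sequence, "")[[1]]
    got <- vapply(split(a$residueName, a$residueNumber),
                  function(r) r[[1]], "")
    one <- .aa3to1(got)
    at <- as.integer(names(got))
    bad <- one != chr[at] & one != "X"
    if (any(bad))
      return(paste0("residue name/sequence mismatch at position ",
                    at[which(bad)[1]]))
  }
  TRUE
})

#' PointCloud: element-labelled 3D coordinates
#'
#' @slot coords numeric matrix with 3 columns (Angstrom).
#' @slot elements chemical symbols, one per point.
#' @exportClass PointCloud
setClass("PointCloud",
  representation(coords = "matrix", elements = "character"))

setValidity("PointCloud", function(object) {
  if (ncol(object@coords) != 3) return("coords must have 3 columns")
  if (nrow(object@coords) != length(object@elements))
    return("coords and elements lengths differ")
  if (nrow(object@coords) > 0 && !all(is.finite(object@coords)))
    return("coordinates must be finite")
  TRUE
})

#' Barcode: a persistence barcode
#'
#' The multiset of (dimension, birth, death) intervals of a filtration.
#' \code{death} is \code{Inf} for essential classes (components alive at the
#' end of the filtration); for Vietoris-Rips runs truncated at \code{rf},
#' higher-dimensional classes still alive at \code{rf} are right-censored to
#' death \code{rf} and flagged in \code{censored}. Zero-length pairs are
#' discarded at construction.
#'
#' @slot bars data.frame with columns \code{dim}, \code{birth}, \code{death},
#'   \code{censored}.
#' @slot complex filtration tag: \code{"vr"}, \code{"alpha"}, \code{"cech"},
#'   \code{"vr-bruteforce"}.
#' @slot rf ending filtration value in Angstrom (\code{NA} when the
#'   filtration needs no cap, as for Alpha).
#' @slot maxHomDim largest homology dimension computed.
#' @exportClass Barcode
setClass("Barcode",
  representation(bars = "data.frame", complex = "character", rf = "numeric",
                 maxHomDim = "integer"))

setValidity("Barcode", function(object) {
  b <- object@bars
  if (!all(c("dim", "birth", "death", "censored") %in% names(b)))
    return("bars must have columns dim, birth, death, censored")
  if (nrow(b) > 0) {
    if (any(b$death <= b$birth))
      return("every bar must satisfy death > birth")
    if (any(b$birth < 0)) return("births must be >= 0")
    if (any(b$dim == 0 & b$birth != 0)) return("dim-0 births must be 0")
  }
  TRUE
})

#' PeptideWindow: a 41-residue lysine-centered peptide
#'
#' @slot proteinId protein identifier.
#' @slot center 1-based sequence position of the central lysine.
#' @slot peptide 41-character string over the 20 amino acids plus the dummy
#'   code \code{X} used to pad past the sequence termini.
#' @slot label \code{"positive"}, \code{"negative"} or \code{"unlabeled"}.
#' @exportClass PeptideWindow
setClass("PeptideWindow",
  representation(proteinId = "character", center = "integer",
                 peptide = "character", label = "character"))

setValidity("PeptideWindow", function(object) {
  p <- object@peptide
  if (nchar(p) != 41L) return("peptide must have 41 characters")
  if (substr(p, 21L, 21L) != "K")
    return("the 21st character must be the central lysine K")
  inner <- sub("^X*", "", sub("X*$", "", p))
  if (grepl("X", inner))
    return("dummy code X may appear only as a prefix and/or suffix")
  if (!object@label %in% c("positive", "negative", "unlabeled"))
    return("label must be positive, negative or unlabeled")
  TRUE
})

#' WindowSet: an ordered collection of labelled peptide windows
#'
#' @slot windows data.frame with columns \code{proteinId}, \code{center},
#'   \code{peptide}, \code{label}.
#' @slot provenance free-text tag naming the source dataset.
#' @exportClass WindowSet
setClass("WindowSet",
  representation(windows = "data.frame", provenance = "character"))

setValidity("WindowSet", function(object) {
  w <- object@windows
  if (!all(c("proteinId", "center", "peptide", "label") %in% names(w)))
    return("windows must have columns proteinId, center, peptide, label")
  if (anyDuplicated(w[c("proteinId", "center")]))
    return("duplicate (proteinId, center) pairs")
  if (nrow(w) > 0) {
    if (any(nchar(w$peptide) != 41L)) return("all peptides must be 41-mers")
    if (any(substr(w$peptide, 21L, 21L) != "K"))
      return("all peptides must have K at position 21")
  }
  TRUE
})

#' FScoreRanking: per-feature F-scores with the induced ordering
#'
#' @slot scores non-negative F-score per feature.
#' @slot order permutation of feature indices sorting the scores
#'   non-increasingly (ties broken by ascending index).
#' @exportClass FScoreRanking
setClass("FScoreRanking",
  representation(scores = "numeric", order = "integer"))

#' ModelConfig: classifier kind and hyperparameters
#'
#' Defaults follow the published protocol: 500 boosting rounds for the
#' gradient boosting classifier, 370 trees with square-root feature
#' subsampling and out-of-bag scoring for the random forest, and an RBF
#' support-vector classifier with kernel width 1/d and probability outputs.
#'
#' @slot kind \code{"gbc"}, \code{"rfc"} or \code{"svc"}.
#' @slot nEstimators ensemble size (ignored by \code{svc}).
#' @slot seed integer seed used when fitting.
#' @exportClass ModelConfig
setClass("ModelConfig",
  representation(kind = "character", nEstimators = "numeric",
                 seed = "numeric"))

#' EvalReport: confusion counts and summary metrics of one evaluation
#'
#' @slot tp,tn,fp,fn confusion counts.
#' @slot sp,sn,acc,mcc,auc specificity, sensitivity, accuracy, Matthews
#'   correlation coefficient and ROC AUC.
#' @slot folds per-fold (or per-repeat) breakdown, one row each.
#' @exportClass EvalReport
setClass("EvalReport",
  representation(tp = "numeric", tn = "numeric", fp = "numeric",
                 fn = "numeric", sp = "numeric", sn = "numeric",
                 acc = "numeric", mcc = "numeric", auc = "numeric",
                 folds = "data.frame"))

setValidity("EvalReport", function(object) {
  if (object@tp + object@tn + object@fp + object@fn <= 0)
    return("confusion counts must sum to a positive total")
  ok01 <- function(x) length(x) == 1 && x >= 0 && x <= 1
  if (!ok01(object@sp) || !ok01(object@sn) || !ok01(object@acc) ||
      !ok01(object@auc))
    return("sp, sn, acc, auc must lie in [0, 1]")
  if (object@mcc < -1 || object@mcc > 1) return("mcc must lie in [-1, 1]")
  TRUE
})
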