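#' @rdname ProteinStructure-class
#' @param object,x a \linkS4class{ProteinStructure}
#' @export
setGeneric("proteinId", function(x) standardGeneric("proteinId"))

#' @rdname ProteinStructure-class
#' @export
setGeneric("proteinSequence",
           function(x) standardGeneric("proteinSequence"))

#' @rdname ProteinStructure-class
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname PointCloud-class
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname PointCloud-class
#' @export
setGeneric("elements", function(x) standardGeneric("elements"))

#' @rdname Barcode-class
#' @export
setGeneric("bars", function(x) standardGeneric("bars"))

#' @rdname WindowSet-class
#' @export
setGeneric("sampleWindows", function(x) standardGeneric("sampleWindows"))

#' @rdname EvalReport-class
#' @export
setGeneric("metrics", function(x) standardGeneric("metrics"))

#' @export
#' @rdname ProteinStructure-class
setMethod("proteinId", "ProteinStructure", function(x) x@proteinId)

#' @export
#' @rdname ProteinStructure-class
setMethod("proteinSequence", "ProteinStructure", function(x) x@sequence)

#' @export
#' @rdname ProteinStructure-class
setMethod("atoms", "ProteinStructure", function(x) x@atoms)

#' @export
#' @rdname PointCloud-class
#' @param x a \linkS4class{PointCloud}
setMethod("coords", "PointCloud", function(x) x@coords)

#' @export
#' @rdname PointCloud-class
setMethod("elements", "PointCloud", function(x) x@elements)

#' @export
#' @rdname Barcode-class
#' @param x a \linkS4class{Barcode}
setMethod("bars", "Barcode", function(x) x@bars)

#' @export
#' @rdname WindowSet-class
#' @param x a \linkS4class{WindowSet}
setMethod("sampleWindows", "WindowSet", function(x) x@windows)

#' @export
#' @rdname EvalReport-class
#' @param x an \linkS4class{EvalReport}
setMethod("metrics", "EvalReport", function(x)
  c(sp = x@sp, sn = x@sn, acc = x@acc, mcc = x@mcc, auc = x@auc))

setMethod("show", "ProteinStructure", function(object) {
  cat("ProteinStructure", object@proteinId, "\n")
  cat(" ", nchar(object@sequence), "residues,", nrow(object@atoms),
      "atoms\n")
})

setMethod("show", "PointCloud", function(object) {
  cat("PointCloud with", nrow(object@coords), "points;",
      "elements:", paste(names(table(object@elements)), collapse = " "),
      "\n")
})

setMethod("show", "Barcode", function(object) {
  b <- object@bars
  cat("Barcode (", object@complex, " filtration)\n", sep = "")
  for (d in 0:object@maxHomDim)
    cat("  dim ", d, ": ", sum(b$dim == d & is.finite(b$death)),
        " finite + ", sum(b$dim == d & !is.finite(b$death)),
        " essential bars\n", sep = "")
})

setMethod("show", "WindowSet", function(object) {
  w <- object@windows
  cat("WindowSet [", object@provenance, "]: ", nrow(w), " windows (",
      sum(w$label == "positive"), " positive, ",
      sum(w$label == "negative"), " negative)\n", sep = "")
})

setMethod("show", "PeptideWindow", function(object) {
  cat("PeptideWindow ", object@proteinId, ":K", object@center, " [",
      object@label, "]\n  ", object@peptide, "\n", sep = "")
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport: tp=", object@tp, " tn=", object@tn, " fp=", object@fp,
      " fn=", object@fn, "\n", sep = "")
  m <- metrics(object)
  cat(" ", paste(sprintf("%s=%.4f", names(m), m), collapse = "  "), "\n")
})

setMethod("show", "FScoreRanking", function(object) {
  cat("FScoreRanking over", length(object@scores), "features; top:",
      paste(utils::head(object@order, 5), collapse = ", "), "\n")
})
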