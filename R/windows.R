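# Lysine-centered peptide windows: extraction, redundancy removal and the
# mapping from windows to heavy-atom point clouds.

.FLANK <- 20L
.WINLEN <- 41L

#' Extract a 41-residue lysine-centered window
#'
#' The window consists of the central lysine plus 20 residues on either
#' side; positions running past the sequence termini are padded with the
#' dummy code \code{X}.
#'
#' @param sequence amino-acid string.
#' @param position 1-based position of the central lysine (must be
#'   \code{K}).
#' @param proteinId identifier stored with the window.
#' @param label \code{"positive"}, \code{"negative"} or \code{"unlabeled"}.
#' @return a \linkS4class{PeptideWindow}.
#' @examples
#' extractWindow("ACDEFGHIKLMNPQRSTVWY", 9)
#' @export
extractWindow <- function(sequence, position, proteinId = "protein",
                          label = "unlabeled") {
  L <- nchar(sequence)
  if (position < 1 || position > L)
    stop("position out of range")
  if (substr(sequence, position, position) != "K")
    stop("residue at position ", position, " is ",
         substr(sequence, position, position), ", not K")
  idx <- (position - .FLANK):(position + .FLANK)
  chars <- ifelse(idx < 1 | idx > L, "X",
                  substring(sequence, idx, idx))
  new("PeptideWindow", proteinId = proteinId, center = as.integer(position),
      peptide = paste(chars, collapse = ""), label = label)
}

.peptideOf <- function(w) if (is(w, "PeptideWindow")) w@peptide else w

#' Positionwise identity of two peptide windows
#'
#' The fraction of the 41 aligned positions at which the two peptides carry
#' the same character. Windows are pre-aligned by their central lysine, so
#' no alignment is performed; the dummy code \code{X} matches only itself.
#'
#' @param a,b \linkS4class{PeptideWindow}s or 41-character strings.
#' @return identity fraction in [0, 1].
#' @export
pairwiseIdentity <- function(a, b) {
  pa <- .peptideOf(a); pb <- .peptideOf(b)
  if (nchar(pa) != .WINLEN || nchar(pb) != .WINLEN)
    stop("windows must be 41-mers")
  mean(strsplit(pa, "")[[1]] == strsplit(pb, "")[[1]])
}

#' Assemble a WindowSet
#'
#' @param windows list of \linkS4class{PeptideWindow}s, or a data.frame with
#'   columns \code{proteinId}, \code{center}, \code{peptide}, \code{label}.
#' @param provenance source tag.
#' @return a \linkS4class{WindowSet}.
#' @export
windowSet <- function(windows, provenance = "unspecified") {
  if (is.data.frame(windows)) {
    df <- windows
  } else {
    df <- data.frame(
      proteinId = vapply(windows, function(w) w@proteinId, ""),
      center = vapply(windows, function(w) w@center, 1L),
      peptide = vapply(windows, function(w) w@peptide, ""),
      label = vapply(windows, function(w) w@label, ""),
      stringsAsFactors = FALSE)
  }
  rownames(df) <- NULL
  new("WindowSet", windows = df, provenance = provenance)
}

#' Remove redundant windows at a sequence-identity threshold
#'
#' Positive and negative windows are pooled, ordered by
#' (\code{proteinId}, \code{center}), and passed through a greedy keep-first
#' filter: a window survives iff its positionwise identity with every
#' already-kept window is at most \code{threshold}. Labels are retained, so
#' the survivors split back into their classes afterwards. With the default
#' 0.40 threshold, any pair sharing more than 40% of its 41 positions keeps
#' only its first member.
#'
#' @param samples a \linkS4class{WindowSet}.
#' @param threshold identity threshold in (0, 1).
#' @return the filtered \linkS4class{WindowSet}.
#' @export
redundancyFilter <- function(samples, threshold = 0.40) {
  stopifnot(threshold > 0, threshold < 1)
  w <- samples@windows
  if (nrow(w) <= 1) return(samples)
  w <- w[order(w$proteinId, w$center), , drop = FALSE]
  pep <- do.call(rbind, strsplit(w$peptide, ""))
  keep <- integer(0)
  for (i in seq_len(nrow(w))) {
    if (length(keep) == 0) { keep <- i; next }
    ident <- rowMeans(sweep(pep[keep, , drop = FALSE], 2, pep[i, ], "=="))
    if (all(ident <= threshold)) keep <- c(keep, i)
  }
  out <- w[keep, , drop = FALSE]
  rownames(out) <- NULL
  new("WindowSet", windows = out, provenance = samples@provenance)
}

#' Heavy-atom point cloud of a window region
#'
#' Collects the heavy atoms of the residues \code{center - flank} ..
#' \code{center + flank} of a structure. Window positions outside
#' \code{[1, L]} are the dummy code \code{X} and contribute no atoms.
#' Residues inside the range that the structure does not resolve are an
#' error rather than a silent gap.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param center 1-based position of the central lysine.
#' @param flank number of residues on each side (20 for the whole window, 2
#'   for the local region).
#' @return a \linkS4class{PointCloud}.
#' @export
windowPointCloud <- function(structure, center, flank = 20L) {
  L <- nchar(structure@sequence)
  if (center < 1 || center > L) stop("center out of range")
  if (substr(structure@sequence, center, center) != "K")
    stop("residue ", center, " of ", structure@proteinId, " is not a lysine")
  rng <- max(1L, center - flank):min(L, center + flank)
  a <- heavyAtoms(structure)
  a <- a[a$residueNumber %in% rng, , drop = FALSE]
  missing <- setdiff(rng, unique(a$residueNumber))
  if (length(missing) > 0)
    stop("structure ", structure@proteinId,
         " has no atoms for residue(s) ", paste(missing, collapse = ", "),
         " inside the requested window")
  new("PointCloud", coords = as.matrix(a[c("x", "y", "z")]),
      elements = a$element)
}

#' Build labelled windows from sequences and a site table
#'
#' Positive windows are extracted at every annotated lysine; negative
#' windows at every other lysine of the same proteins (the standard
#' construction for site predictors). Proteins in the site table without a
#' sequence are an error.
#'
#' @param sequences named character vector (or anything coercible with
#'   \code{as.character}, e.g. an \code{AAStringSet}) of protein sequences.
#' @param sites data.frame with columns \code{protein_id}, \code{position}
#'   and optionally \code{label} (\code{1}/\code{positive} marks a
#'   sumoylation site). If \code{label} is absent all rows are positives.
#' @param negatives \code{"auto"} to enumerate non-annotated lysines as
#'   negatives, \code{"none"} to keep only the table's rows.
#' @param provenance source tag for the resulting set.
#' @return a \linkS4class{WindowSet}.
#' @export
buildWindows <- function(sequences, sites, negatives = c("auto", "none"),
                         provenance = "sites") {
  negatives <- match.arg(negatives)
  seqs <- toupper(as.character(sequences))
  names(seqs) <- names(sequences)
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("sequences must be named by protein id")
  if (!all(c("protein_id", "position") %in% names(sites)))
    stop("sites must have columns protein_id and position")
  lab <- if ("label" %in% names(sites))
    ifelse(sites$label %in% c(1, "1", "positive", "TRUE"), "positive",
           "negative")
  else rep("positive", nrow(sites))
  miss <- setdiff(unique(sites$protein_id), names(seqs))
  if (length(miss) > 0)
    stop("no sequence for protein(s): ", paste(miss, collapse = ", "))
  out <- list()
  for (i in seq_len(nrow(sites)))
    out[[length(out) + 1]] <- extractWindow(
      seqs[[sites$protein_id[i]]], sites$position[i],
      proteinId = sites$protein_id[i], label = lab[i])
  if (negatives == "auto") {
    pos <- paste(sites$protein_id, sites$position)
    for (pid in unique(sites$protein_id)) {
      ks <- which(strsplit(seqs[[pid]], "")[[1]] == "K")
      ks <- ks[!(paste(pid, ks) %in% pos)]
      for (p in ks)
        out[[length(out) + 1]] <- extractWindow(
          seqs[[pid]], p, proteinId = pid, label = "negative")
    }
  }
  windowSet(out, provenance = provenance)
}

#' Read a site-annotation table
#'
#' Tab-separated with header \code{protein_id  position  label}.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readSiteTable <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a WindowSet as a TSV sample table
#'
#' Columns \code{protein_id}, \code{position}, \code{peptide},
#' \code{label}.
#'
#' @param samples a \linkS4class{WindowSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSampleSet <- function(samples, path) {
  w <- samples@windows
  write.table(
    data.frame(protein_id = w$proteinId, position = w$center,
               peptide = w$peptide, label = w$label),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
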