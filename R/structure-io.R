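# Reading and writing protein structures and sequences.

.aa3to1 <- function(resid) {
  suppressWarnings(out <- bio3d::aa321(resid))
  out[is.na(out)] <- "X"
  out
}

.aa1to3 <- function(one) {
  suppressWarnings(out <- bio3d::aa123(one))
  out[is.na(out)] <- "UNK"
  out
}

.STANDARD_AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                   "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                   "THR", "TRP", "TYR", "VAL")

#' Read a protein structure from a PDB or mmCIF file
#'
#' Parses the first model of a single-chain structure file into a
#' \linkS4class{ProteinStructure}. All ATOM records are kept, hydrogens
#' included (use \code{\link{heavyAtoms}} to drop them). Residue numbering is
#' taken from the file; for AlphaFold models (\code{AF-<id>-F1-model_vN})
#' this matches UniProt positions 1..L, and the UniProt accession is used as
#' the protein id. Alternate locations are resolved by keeping the
#' highest-occupancy copy (ties: first). HETATM records are skipped with a
#' warning. Files with more than one chain are an error naming the chains:
#' the caller must extract the chain of interest first.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"pdb"} or
#'   \code{"mmcif"}.
#' @return a \linkS4class{ProteinStructure}.
#' @examples
#' s <- synthStructure("ACDKG", conformation = "extended")
#' f <- tempfile(fileext = ".pdb")
#' writeStructure(s, f)
#' readStructure(f)
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path, verbose = FALSE,
                                           rm.alt = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- parsed$atom
  if (nrow(at) == 0) stop("no atom records in ", path)

  chains <- unique(at$chain[!is.na(at$chain)])
  if (length(chains) > 1)
    stop("multi-chain file (chains: ", paste(chains, collapse = ", "),
         "); extract a single chain before reading")

  het <- at$type == "HETATM"
  if (any(het)) {
    warning("skipping ", sum(het), " HETATM record(s) in ", basename(path))
    at <- at[!het, , drop = FALSE]
  }
  if (nrow(at) == 0) stop("no ATOM records in ", path)

  # alternate locations: keep the highest-occupancy copy, ties -> first
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    occ <- at$o
    occ[is.na(occ)] <- 1
    key <- paste(at$resno, at$elety)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(i) {
      i[which.max(occ[i])]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }

  if (any(at$resno < 1))
    stop("residue numbers below 1 are not supported")
  L <- max(at$resno)
  seqc <- rep("X", L)
  first <- !duplicated(at$resno)
  seqc[at$resno[first]] <- .aa3to1(at$resid[first])

  elesy <- at$elesy
  if (is.null(elesy) || all(is.na(elesy)))
    elesy <- substr(gsub("[0-9]", "", at$elety), 1, 1)
  elesy <- toupper(trimws(elesy))

  id <- sub("\\.(pdb|cif|mmcif)(\\.gz)?$", "", basename(path),
            ignore.case = TRUE)
  m <- regmatches(id, regexec("^AF-([A-Z0-9]+)-F[0-9]+-model", id))[[1]]
  if (length(m) == 2) id <- m[2]

  new("ProteinStructure", proteinId = id,
      sequence = paste(seqc, collapse = ""),
      atoms = data.frame(element = elesy, atomName = trimws(at$elety),
                         residueNumber = as.integer(at$resno),
                         residueName = at$resid,
                         x = at$x, y = at$y, z = at$z,
                         stringsAsFactors = FALSE))
}

#' Write a structure as a normalized PDB file
#'
#' Emits plain ATOM records (single chain A, 3-decimal coordinates in
#' Angstrom), suitable as a fixture for \code{\link{readStructure}}.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeStructure <- function(structure, path) {
  a <- structure@atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[c("x", "y", "z")]))),
                   resno = a$residueNumber, resid = a$residueName,
                   eleno = seq_len(nrow(a)), elety = a$atomName,
                   chain = rep("A", nrow(a)), o = rep(1, nrow(a)),
                   b = rep(0, nrow(a)), elesy = a$element)
  invisible(path)
}

#' Heavy atoms of a structure
#'
#' Returns the atom table with hydrogens removed (element \code{H} or
#' \code{D}), preserving the original order. Hydrogens are excluded from all
#' persistence analyses: they only add short redundant bars.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @return data.frame of atom records.
#' @export
heavyAtoms <- function(structure) {
  a <- structure@atoms
  a[!(a$element %in% c("H", "D")), , drop = FALSE]
}

#' Heavy atoms of one residue
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param residueNumber 1-based residue position.
#' @return data.frame of that residue's heavy-atom records.
#' @export
residueHeavyAtoms <- function(structure, residueNumber) {
  L <- nchar(structure@sequence)
  if (length(residueNumber) != 1 || residueNumber < 1 || residueNumber > L)
    stop("residueNumber must lie in [1, ", L, "]")
  a <- heavyAtoms(structure)
  a[a$residueNumber == residueNumber, , drop = FALSE]
}

.FASTA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                     "X", "U", "B", "Z")

#' Read a FASTA file of protein sequences
#'
#' Record ids are the first whitespace-delimited token after \code{>};
#' sequences are uppercased. Characters outside the 20 amino acids plus
#' \code{X}, \code{U}, \code{B}, \code{Z} raise an error naming the
#' offenders.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
readFasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"),
                        function(x) x[1], "")
  bad <- lapply(strsplit(seqs, ""), function(ch) setdiff(ch, .FASTA_ALPHABET))
  off <- unique(unlist(bad))
  if (length(off) > 0)
    stop("invalid sequence character(s): ", paste(off, collapse = ", "))
  seqs
}
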