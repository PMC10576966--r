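# Deterministic synthetic peptide structures.
#
# Residues are placed along an idealized backbone trace (consecutive CA-CA
# distance exactly 3.8 Angstrom; "compact" = helical turn of 100 degrees
# per residue, "extended" = straight strand) and dressed with the real
# heavy-atom composition of each residue type at idealized bond lengths:
# N-CA 1.46, CA-C 1.52, C-O 1.23, C-N(next) ~1.33, side-chain bonds
# 1.43-1.55 depending on the element. Side chains grow as zigzag chains —
# atom counts and bond scales are faithful, ring closures are not. The
# point is a fully controllable test bed whose class signal (compact vs
# extended) is conformational, mirroring the structural nature of
# sumoylation-site context, while every bonded distance stays inside the
# 1.2-1.6 Angstrom range probed by the dim-0 feature bins.

# real side-chain heavy atoms (name = element initial + position code)
.SIDE_CHAINS <- list(
  A = c(CB = "C"),
  R = c(CB = "C", CG = "C", CD = "C", NE = "N", CZ = "C", NH1 = "N",
        NH2 = "N"),
  N = c(CB = "C", CG = "C", OD1 = "O", ND2 = "N"),
  D = c(CB = "C", CG = "C", OD1 = "O", OD2 = "O"),
  C = c(CB = "C", SG = "S"),
  Q = c(CB = "C", CG = "C", CD = "C", OE1 = "O", NE2 = "N"),
  E = c(CB = "C", CG = "C", CD = "C", OE1 = "O", OE2 = "O"),
  G = character(0),
  H = c(CB = "C", CG = "C", ND1 = "N", CD2 = "C", CE1 = "C", NE2 = "N"),
  I = c(CB = "C", CG1 = "C", CG2 = "C", CD1 = "C"),
  L = c(CB = "C", CG = "C", CD1 = "C", CD2 = "C"),
  K = c(CB = "C", CG = "C", CD = "C", CE = "C", NZ = "N"),
  M = c(CB = "C", CG = "C", SD = "S", CE = "C"),
  F = c(CB = "C", CG = "C", CD1 = "C", CD2 = "C", CE1 = "C", CE2 = "C",
        CZ = "C"),
  P = c(CB = "C", CG = "C", CD = "C"),
  S = c(CB = "C", OG = "O"),
  T = c(CB = "C", OG1 = "O", CG2 = "C"),
  W = c(CB = "C", CG = "C", CD1 = "C", CD2 = "C", NE1 = "N", CE2 = "C",
        CE3 = "C", CZ2 = "C", CZ3 = "C", CH2 = "C"),
  Y = c(CB = "C", CG = "C", CD1 = "C", CD2 = "C", CE1 = "C", CE2 = "C",
        CZ = "C", OH = "O"),
  V = c(CB = "C", CG1 = "C", CG2 = "C"))

# backbone placement constants (Angstrom); chosen so that with a 3.8 CA-CA
# step the peptide-bond C-N(next) distance comes out at 1.33
.CA_C_PAR <- 1.52 * cos(33.2 * pi / 180)
.CA_C_PERP <- 1.52 * sin(33.2 * pi / 180)
.N_CA_PERP <- .CA_C_PERP
.N_CA_PAR <- sqrt(1.46^2 - .N_CA_PERP^2)
.SIDE_BOND <- c(C = 1.53, N = 1.47, O = 1.43, S = 1.55)

.normalize <- function(v) v / sqrt(sum(v^2))

#' Generate a synthetic peptide structure
#'
#' Deterministic for a given specification: the same arguments always
#' return the identical structure.
#'
#' @param sequence amino-acid string (the 20 standard letters).
#' @param conformation \code{"compact"} (helical trace) or
#'   \code{"extended"} (straight trace).
#' @param noiseSd standard deviation of seeded Gaussian coordinate noise,
#'   Angstrom.
#' @param seed noise seed.
#' @param proteinId identifier for the result.
#' @return a \linkS4class{ProteinStructure}.
#' @examples
#' synthStructure("GAKSV", conformation = "compact")
#' @export
synthStructure <- function(sequence, conformation = c("compact",
                                                      "extended"),
                           noiseSd = 0, seed = 1, proteinId = "synth") {
  conformation <- match.arg(conformation)
  stopifnot(noiseSd >= 0)
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(chars, names(.SIDE_CHAINS))
  if (length(bad) > 0)
    stop("invalid residue letter(s): ", paste(bad, collapse = ", "))
  L <- length(chars)

  # CA trace with exact 3.8 steps
  if (conformation == "compact") {
    theta <- 100 * pi / 180
    rise <- 1.5
    R <- sqrt(3.8^2 - rise^2) / (2 * sin(theta / 2))
    i <- seq_len(L) - 1
    ca <- cbind(R * cos(i * theta), R * sin(i * theta), rise * i)
    radial <- cbind(cos(i * theta), sin(i * theta), 0 * i)
  } else {
    ca <- cbind(3.8 * (seq_len(L) - 1), 0, 0)
    radial <- cbind(0, rep(1, L), 0)
  }

  # per-segment orthonormal frames (u along chain, w sideways, v = u x w)
  u <- matrix(0, L, 3); w <- matrix(0, L, 3); v <- matrix(0, L, 3)
  for (i in seq_len(L)) {
    ui <- if (i < L) .normalize(ca[i + 1, ] - ca[i, ])
          else if (L > 1) u[L - 1, ] else c(1, 0, 0)
    wi <- .normalize(radial[i, ] - sum(radial[i, ] * ui) * ui)
    u[i, ] <- ui; w[i, ] <- wi
    v[i, ] <- c(ui[2] * wi[3] - ui[3] * wi[2],
                ui[3] * wi[1] - ui[1] * wi[3],
                ui[1] * wi[2] - ui[2] * wi[1])
  }

  name <- character(0); elem <- character(0); resno <- integer(0)
  xyz <- matrix(0, 0, 3)
  put <- function(nm, el, rn, p) {
    name <<- c(name, nm); elem <<- c(elem, el)
    resno <<- c(resno, rn); xyz <<- rbind(xyz, p)
  }
  for (i in seq_len(L)) {
    fp <- if (i > 1) i - 1 else i # frame of the preceding segment
    put("N", "N", i, ca[i, ] - .N_CA_PAR * u[fp, ] + .N_CA_PERP * w[fp, ])
    put("CA", "C", i, ca[i, ])
    cpos <- ca[i, ] + .CA_C_PAR * u[i, ] + .CA_C_PERP * w[i, ]
    put("C", "C", i, cpos)
    put("O", "O", i, cpos + 1.23 * v[i, ])
    side <- .SIDE_CHAINS[[chars[i]]]
    prev <- ca[i, ]
    for (k in seq_along(side)) {
      dirk <- .normalize(cos(40 * pi / 180) * w[i, ] +
                         (-1)^k * sin(40 * pi / 180) * v[i, ])
      prev <- prev + .SIDE_BOND[[side[[k]]]] * dirk
      put(names(side)[k], side[[k]], i, prev)
    }
  }
  if (noiseSd > 0)
    xyz <- xyz + .withLocalSeed(seed, matrix(rnorm(length(xyz),
                                                   sd = noiseSd),
                                             nrow = nrow(xyz)))
  new("ProteinStructure", proteinId = proteinId,
      sequence = paste(chars, collapse = ""),
      atoms = data.frame(element = elem, atomName = name,
                         residueNumber = resno,
                         residueName = .aa1to3(chars[resno]),
                         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                         stringsAsFactors = FALSE))
}

#' Generate a labelled synthetic dataset
#'
#' \code{nPos} windows cut from compact-conformation structures (label
#' positive) and \code{nNeg} from extended ones (label negative), each a
#' 41-residue peptide with a central lysine and seeded random flanking
#' sequence — so the classes differ in geometry, not residue composition.
#'
#' @param nPos,nNeg class sizes.
#' @param seed master seed (drives sequences, per-structure noise seeds).
#' @param noiseSd coordinate noise, Angstrom.
#' @return list with \code{windows} (a \linkS4class{WindowSet}) and
#'   \code{structures} (named list of \linkS4class{ProteinStructure}s).
#' @export
synthDataset <- function(nPos, nNeg, seed = 1, noiseSd = 0.05) {
  stopifnot(nPos >= 1, nNeg >= 1)
  n <- nPos + nNeg
  aa <- names(.SIDE_CHAINS)
  plan <- .withLocalSeed(seed, {
    data.frame(
      pid = c(sprintf("SP%04d", seq_len(nPos)),
              sprintf("SN%04d", seq_len(nNeg))),
      conf = rep(c("compact", "extended"), c(nPos, nNeg)),
      label = rep(c("positive", "negative"), c(nPos, nNeg)),
      sseed = sample.int(2^30, n),
      seq = vapply(seq_len(n), function(i) {
        s <- sample(aa, 41, replace = TRUE)
        s[21] <- "K"
        paste(s, collapse = "")
      }, ""), stringsAsFactors = FALSE)
  })
  structures <- list()
  wins <- vector("list", n)
  for (i in seq_len(n)) {
    structures[[plan$pid[i]]] <- synthStructure(
      plan$seq[i], plan$conf[i], noiseSd = noiseSd, seed = plan$sseed[i],
      proteinId = plan$pid[i])
    wins[[i]] <- extractWindow(plan$seq[i], 21, proteinId = plan$pid[i],
                               label = plan$label[i])
  }
  list(windows = windowSet(wins, provenance = sprintf(
         "synthetic compact/extended n=%d+%d noise=%g seed=%d",
         nPos, nNeg, noiseSd, seed)),
       structures = structures)
}

#' Write a miniature synthetic dataset to disk
#'
#' Emits one PDB per structure, a \code{sites.tsv} annotation table and a
#' \code{sequences.fasta}, i.e. the full external-input layout the reading
#' functions consume.
#'
#' @param dir output directory (created if needed).
#' @param nPos,nNeg,seed,noiseSd passed to \code{\link{synthDataset}}.
#' @return invisible list with element \code{dir} and the generated file
#'   paths.
#' @export
simulateDataset <- function(dir, nPos = 5, nNeg = 5, seed = 1,
                            noiseSd = 0.05) {
  ds <- synthDataset(nPos, nNeg, seed = seed, noiseSd = noiseSd)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdb <- character(0)
  for (s in ds$structures)
    pdb <- c(pdb, writeStructure(s, file.path(dir, paste0(proteinId(s),
                                                          ".pdb"))))
  w <- sampleWindows(ds$windows)
  sites <- file.path(dir, "sites.tsv")
  write.table(data.frame(protein_id = w$proteinId, position = w$center,
                         label = ifelse(w$label == "positive", 1, 0)),
              sites, sep = "\t", quote = FALSE, row.names = FALSE)
  fasta <- file.path(dir, "sequences.fasta")
  writeLines(paste0(">", w$proteinId, "\n",
                    vapply(ds$structures[w$proteinId], proteinSequence,
                           "")), fasta)
  invisible(list(dir = dir, pdb = pdb, sites = sites, fasta = fasta))
}
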