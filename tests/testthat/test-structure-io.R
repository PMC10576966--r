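# Structure and sequence I/O.

pdbLine <- function(serial, name, alt, resn, chain, resno, x, y, z, occ,
                    elem, record = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, alt, resn, chain, resno, x, y, z, occ, 0,
          elem)
}

test_that("empty or unparsable files raise a parse error", {
  f <- tempfile(fileext = ".pdb")
  file.create(f)
  expect_error(readStructure(f), "parse|atom")
  expect_error(readStructure(tempfile()), "not found")
})

test_that("write-then-read round trip preserves atoms and coordinates", {
  s <- synthStructure("ACDKGWKLMV", conformation = "compact")
  f <- tempfile(fileext = ".pdb")
  writeStructure(s, f)
  s2 <- readStructure(f)
  expect_equal(nrow(atoms(s2)), nrow(atoms(s)))
  expect_equal(atoms(s2)$element, atoms(s)$element)
  expect_equal(atoms(s2)$residueNumber, atoms(s)$residueNumber)
  # PDB stores 3 decimals
  expect_lt(max(abs(as.matrix(atoms(s2)[c("x", "y", "z")]) -
                    as.matrix(atoms(s)[c("x", "y", "z")]))), 1e-3)
  expect_equal(proteinSequence(s2), proteinSequence(s))
})

test_that("AlphaFold-style filenames yield the UniProt accession as id", {
  s <- synthStructure("GAKAG", conformation = "extended")
  d <- tempfile()
  dir.create(d)
  f <- file.path(d, "AF-O00429-F1-model_v4.pdb")
  writeStructure(s, f)
  expect_equal(proteinId(readStructure(f)), "O00429")
})

test_that("hydrogens are retained by the reader and dropped by heavyAtoms", {
  lines <- c(
    pdbLine(1, "N", " ", "GLY", "A", 1, 0, 0, 0, 1, "N"),
    pdbLine(2, "CA", " ", "GLY", "A", 1, 1.46, 0, 0, 1, "C"),
    pdbLine(3, "C", " ", "GLY", "A", 1, 1.46, 1.52, 0, 1, "C"),
    pdbLine(4, "O", " ", "GLY", "A", 1, 1.46, 1.52, 1.23, 1, "O"),
    pdbLine(5, "H", " ", "GLY", "A", 1, -0.5, 0.5, 0, 1, "H"),
    pdbLine(6, "HA2", " ", "GLY", "A", 1, 1.2, -0.9, 0, 1, "H"),
    pdbLine(7, "HA3", " ", "GLY", "A", 1, 1.2, 0.4, 0.9, 1, "H"),
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  s <- readStructure(f)
  expect_equal(nrow(atoms(s)), 7)            # H kept on read
  h <- heavyAtoms(s)
  expect_equal(h$atomName, c("N", "CA", "C", "O"))
  # idempotent
  s2 <- s
  s2@atoms <- h
  expect_equal(heavyAtoms(s2), h)
})

test_that("multi-chain files are an error naming the chains", {
  lines <- c(
    pdbLine(1, "CA", " ", "GLY", "A", 1, 0, 0, 0, 1, "C"),
    pdbLine(2, "CA", " ", "GLY", "B", 1, 5, 0, 0, 1, "C"),
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  expect_error(readStructure(f), "A.*B|multi-chain")
})

test_that("alternate locations keep the highest occupancy copy", {
  lines <- c(
    pdbLine(1, "CA", "A", "GLY", "A", 1, 0, 0, 0, 0.4, "C"),
    pdbLine(2, "CA", "B", "GLY", "A", 1, 9, 9, 9, 0.6, "C"),
    pdbLine(3, "C", " ", "GLY", "A", 1, 1.52, 0, 0, 1, "C"),
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  s <- readStructure(f)
  expect_equal(nrow(atoms(s)), 2)
  expect_equal(atoms(s)$x[atoms(s)$atomName == "CA"], 9)
})

test_that("HETATM records are skipped with a warning", {
  lines <- c(
    pdbLine(1, "CA", " ", "GLY", "A", 1, 0, 0, 0, 1, "C"),
    pdbLine(2, "O", " ", "HOH", "A", 2, 8, 8, 8, 1, "O",
            record = "HETATM"),
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  expect_warning(s <- readStructure(f), "HETATM")
  expect_equal(nrow(atoms(s)), 1)
})

test_that("residueHeavyAtoms counts real residue compositions", {
  s <- synthStructure("ACDKGWKLMV", conformation = "compact")
  expect_equal(nrow(residueHeavyAtoms(s, 6)), 14)  # tryptophan
  expect_equal(nrow(residueHeavyAtoms(s, 4)), 9)   # lysine
  expect_equal(nrow(residueHeavyAtoms(s, 5)), 4)   # glycine backbone only
  expect_error(residueHeavyAtoms(s, 0), "\\[1")
  expect_error(residueHeavyAtoms(s, 11), "\\[1")
})

test_that("mmCIF files with the standard atom_site layout are readable", {
  s <- synthStructure("GAKAG", conformation = "extended")
  a <- atoms(s)
  f <- tempfile(fileext = ".cif")
  cols <- c("group_PDB", "id", "type_symbol", "label_atom_id",
            "label_alt_id", "label_comp_id", "label_asym_id",
            "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
            "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
            "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
            "auth_comp_id", "auth_asym_id", "auth_atom_id",
            "pdbx_PDB_model_num")
  writeLines(c(
    "data_synth", "loop_", paste0("_atom_site.", cols),
    sprintf(
      "ATOM %d %s %s . %s A 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s A %s 1",
      seq_len(nrow(a)), a$element, a$atomName, a$residueName,
      a$residueNumber, a$x, a$y, a$z, a$residueNumber, a$residueName,
      a$atomName)), f)
  s2 <- readStructure(f, format = "mmcif")
  expect_equal(proteinSequence(s2), "GAKAG")
  expect_equal(atoms(s2)$atomName, a$atomName)
  expect_equal(atoms(s2)$element, a$element)
  expect_lt(max(abs(atoms(s2)$x - a$x)), 1e-3)
})

test_that("readFasta parses ids, uppercases and validates the alphabet", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">a some description", "ACDK", ">b", "mkvl"), f)
  seqs <- readFasta(f)
  expect_equal(names(seqs), c("a", "b"))
  expect_equal(unname(seqs), c("ACDK", "MKVL"))
  writeLines(c(">bad", "ACOKJ"), f)
  expect_error(readFasta(f), "O")
})
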