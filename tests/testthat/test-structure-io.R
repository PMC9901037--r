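test_that("write/read round trip preserves the atom table", {
  m <- makeGappedStructure(20, list())
  f <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(m, f)
  m2 <- readStructure(f)
  a <- atoms(m); b <- atoms(m2)
  expect_equal(nrow(b), nrow(a))
  expect_equal(b$chain, a$chain)
  expect_equal(b$resno, a$resno)
  expect_equal(b$elety, a$elety)
  # coordinates at the format's printed precision
  expect_equal(b$x, round(a$x, 3))
  expect_equal(b$y, round(a$y, 3))
  expect_equal(b$z, round(a$z, 3))
  # 12 atoms in 3 residues survive as 12 atoms in 3 residues
  m3 <- StructureModel(atoms(m)[atoms(m)$resno %in% 1:3, ])
  expect_equal(nrow(atoms(m3)), 12)
  expect_equal(length(unique(atoms(m3)$resno)), 3)
})

test_that("unreadable and empty inputs give explicit errors", {
  expect_error(readStructure(tempfile()), "not found")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER    junk", "END"), f)
  expect_error(readStructure(f), "no polymer atoms|cannot parse")
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA AALA A   2       9.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA BALA A   2       7.000   0.000   0.000  0.50  0.00           C",
    "END"), f)
  m <- readStructure(f)
  a <- atoms(m)
  expect_equal(nrow(a), 2)
  expect_equal(a$x[a$resno == 1], 5.0)  # occupancy 0.6 wins
  expect_equal(a$x[a$resno == 2], 9.0)  # tie broken by altloc order (A)
})

test_that("mmCIF files read through the same contract", {
  f <- withr::local_tempfile(fileext = ".cif")
  hdr <- paste0("_atom_site.",
                c("group_PDB", "id", "type_symbol", "label_atom_id",
                  "label_alt_id", "label_comp_id", "label_asym_id",
                  "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                  "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                  "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                  "auth_comp_id", "auth_asym_id", "auth_atom_id",
                  "pdbx_PDB_model_num"))
  rows <- sprintf(
    "ATOM %d C CA . ALA A 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d ALA A CA 1",
    1:3, 1:3, c(1, 4, 7), c(2, 5, 8), c(3, 6, 9), 1:3)
  writeLines(c("data_test", "loop_", hdr, rows), f)
  m <- readStructure(f)
  a <- atoms(m)
  expect_equal(nrow(a), 3)
  expect_equal(a$resno, 1:3)
  expect_equal(a$x, c(1, 4, 7))
  expect_equal(a$elety, rep("CA", 3))
})

test_that("unmodeled-region detection finds engineered gaps", {
  m <- makeGappedStructure(180, list(c(42, 59)))
  r <- detectUnmodeledRegions(m, "A")
  expect_equal(nrow(r), 1)
  expect_equal(r$first, 42)
  expect_equal(r$last, 59)
  expect_equal(r$length, 18)

  m6 <- makeGappedStructure(180, list(c(54, 59)))
  r6 <- detectUnmodeledRegions(m6, "A")
  expect_equal(r6$length, 6)

  full <- makeGappedStructure(180, list())
  expect_equal(nrow(detectUnmodeledRegions(full, "A")), 0)

  expect_error(detectUnmodeledRegions(full, "Z"), "not present")
})

test_that("gap lengths sum to sequence length minus modeled count", {
  for (miss in list(list(c(5, 9)), list(c(2, 3), c(40, 80)),
                    list(c(1, 4), c(100, 100), c(170, 180)))) {
    m <- makeGappedStructure(180, miss)
    r <- detectUnmodeledRegions(m, "A")
    nModeled <- length(unique(atoms(m)$resno))
    expect_equal(sum(r$length), 180 - nModeled)
  }
})

test_that("detection survives gaps spanning the sequence-record termini", {
  m <- makeGappedStructure(60, list(c(1, 3), c(58, 60)))
  r <- detectUnmodeledRegions(m, "A")
  expect_equal(r$first, c(1, 58))
  expect_equal(r$length, c(3, 3))
})

test_that("detection is invariant to atom-record permutation", {
  m <- makeGappedStructure(100, list(c(30, 35), c(70, 71)))
  set.seed(5)
  shuffled <- StructureModel(atoms(m)[sample(nrow(atoms(m))), ],
                             chainSeq = chainSequences(m))
  expect_equal(detectUnmodeledRegions(shuffled, "A"),
               detectUnmodeledRegions(m, "A"))
})

test_that("SEQRES records survive a write/read cycle", {
  m <- makeGappedStructure(40, list(c(10, 12)))
  f <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(m, f)
  m2 <- readStructure(f)
  expect_equal(detectUnmodeledRegions(m2, "A")$length, 3)
})

test_that("peptide positions resolve through the disulfide anchor", {
  m <- makeComplexFixture()
  map <- resolvePeptidePositions(m, "C", "A")
  expect_equal(positionResno(map, "P7"), 7)
  expect_equal(positionResno(map, "P1"), 1)  # P1 is the chain's first residue
  expect_equal(unname(positionLabels(map)[["P8"]]), 8)

  # extension residues: renumber the same peptide starting at 3 and add
  # two N-terminal extension residues
  a <- atoms(m)
  pep <- a$chain == "C"
  a$resno[pep] <- a$resno[pep] + 2L
  ext <- data.frame(chain = "C", resno = 1:2, resid = "ARG", elety = "CA",
                    x = c(20, 24), y = 0, z = 0, occ = 1,
                    stringsAsFactors = FALSE)
  m2 <- StructureModel(rbind(a, ext))
  map2 <- resolvePeptidePositions(m2, "C", "A")
  expect_equal(positionResno(map2, "P1"), 3)
  expect_equal(positionResno(map2, "P-1"), 2)
  expect_equal(positionResno(map2, "P-2"), 1)
})

test_that("missing disulfide partner gives a mapping error", {
  m <- makeComplexFixture()
  a <- atoms(m)
  noCys <- StructureModel(a[!(a$chain == "C" & a$elety == "SG"), ])
  expect_error(resolvePeptidePositions(noCys, "C", "A"), "manually")
  # Cys present but too far
  far <- a
  far$y[far$chain == "C" & far$elety == "SG"] <- 50
  expect_error(resolvePeptidePositions(StructureModel(far), "C", "A"),
               "within 2.5")
})

test_that("selection strings resolve deterministically", {
  m <- makeComplexFixture()
  i1 <- parseSelection(m, "A:1-90:CA")
  expect_equal(length(i1), 90)
  expect_equal(i1, selectAtoms(m, chain = "A", resno = 1:90, elety = "CA"))
  expect_equal(length(parseSelection(m, "C:*:*")),
               sum(atoms(m)$chain == "C"))
  expect_equal(length(parseSelection(m, "A:52:CD1")), 1)
  expect_error(parseSelection(m, "A:1-90"), "CHAIN:RES:ATOM")
})
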