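# Structure/sequence I/O and the entry/entity/instance projection.

test_that("mmCIF round-trip preserves atoms, residues and modeled flags", {
  m <- build_ideal_chain(data.frame(element = "helix", length = 20),
                         strrep("A", 20), entry_id = "RT01")
  path <- withr::local_tempfile(fileext = ".cif")
  write_structure(m, path)
  back <- read_structure(path)
  expect_equal(back$entry_id, "RT01")
  expect_length(back$chains, 1)
  expect_equal(nrow(back$chains[[1]]$atoms), nrow(m$chains[[1]]$atoms))
  expect_equal(back$chains[[1]]$residues$modeled, m$chains[[1]]$residues$modeled)
  expect_equal(sum(back$chains[[1]]$residues$modeled), 20)
  # coordinates survive at the 3-decimal precision of the format
  expect_equal(as.matrix(back$chains[[1]]$atoms[, c("x", "y", "z")]),
               as.matrix(m$chains[[1]]$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("unmodeled residues are bookkept from the entity sequence", {
  m <- build_ideal_chain(data.frame(element = "helix", length = 100),
                         strrep("A", 100), entry_id = "GAP1")
  inst <- m$chains[[1]]
  drop <- c(1:9, 91:100)
  inst$residues$modeled[drop] <- FALSE
  inst$atoms <- inst$atoms[!(inst$atoms$seq_pos %in% drop), ]
  m$chains[[1]] <- inst
  path <- withr::local_tempfile(fileext = ".cif")
  write_structure(m, path)
  back <- read_structure(path)
  res <- back$chains[[1]]$residues
  expect_equal(sum(res$modeled), 81)
  expect_equal(sum(!res$modeled), 19)
  expect_equal(res$seq_pos[!res$modeled], drop)
})

test_that("computed-model B-factors become per-residue confidence", {
  m <- build_ideal_chain(data.frame(element = "helix", length = 20),
                         strrep("A", 20), entry_id = "CSM1",
                         provenance = "computed")
  conf <- round(seq(0, 100, length.out = 20), 2)
  m$chains[[1]]$residues$confidence <- conf
  path <- withr::local_tempfile(fileext = ".cif")
  write_structure(m, path)
  back <- read_structure(path)
  expect_equal(back$provenance, "computed")
  expect_equal(back$chains[[1]]$residues$confidence, conf)
  # experimental read of the same coordinates has no confidence
  m2 <- m; m2$provenance <- "experimental"
  m2$chains[[1]]$residues$confidence <- NA_real_
  path2 <- withr::local_tempfile(fileext = ".cif")
  write_structure(m2, path2)
  expect_true(all(is.na(read_structure(path2)$chains[[1]]$residues$confidence)))
})

test_that("homodimers give one entity with two instances; heterodimers two", {
  res <- data.frame(seq_pos = 1:3, aa = c("A", "C", "D"), modeled = FALSE,
                    confidence = NA_real_)
  mk <- function(chain, uid) polymer_instance(chain, uid, res)
  homo <- structure_model("HOMO", list(mk("A", "HOMO_1"), mk("B", "HOMO_1")))
  ents <- extract_entities(homo)
  expect_length(ents, 1)
  expect_equal(ents[[1]]$entity_uid, "HOMO_1")
  res2 <- data.frame(seq_pos = 1:3, aa = c("A", "C", "E"), modeled = FALSE,
                     confidence = NA_real_)
  hetero <- structure_model("HET", list(mk("A", "HET_1"),
                                        polymer_instance("B", "HET_2", res2)))
  expect_length(extract_entities(hetero), 2)
  # idempotence
  expect_identical(extract_entities(homo), extract_entities(homo))
})

test_that("sidecar metadata merges by uid and unknown rows warn", {
  m <- build_ideal_chain(data.frame(element = "helix", length = 10),
                         strrep("A", 10), entry_id = "SC01")
  meta <- data.frame(entity_uid = c("SC01_1", "NOPE_9"),
                     accession = c("P12345", "P0"),
                     organism = c("Homo sapiens", "x"),
                     release_date = c("2020-01-01", ""),
                     deposition_group_id = c("", ""),
                     provenance = c("", ""), stringsAsFactors = FALSE)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write.table(meta, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(clean <- read_entity_sidecar(tsv, known_uids = "SC01_1"),
                 "unknown entity_uid")
  ents <- extract_entities(m, clean)
  expect_equal(ents[["SC01_1"]]$accession, "P12345")
  expect_equal(ents[["SC01_1"]]$organism, "Homo sapiens")
  expect_null(ents[["SC01_1"]]$deposition_group_id)
  # no sidecar: optional fields unset
  bare <- extract_entities(m)
  expect_null(bare[["SC01_1"]]$accession)
})

test_that("FASTA round-trips on ids and sequences, including 'X'", {
  ents <- tiny_entities(c(A_1 = "ACDEFG", B_1 = "ACDXFG", C_1 = "WYV"))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(ents, path)
  back <- read_fasta(path)
  expect_length(back, 3)
  expect_equal(names(back), c("A_1", "B_1", "C_1"))
  expect_equal(unname(back["B_1"]), "ACDXFG")
  expect_error(write_fasta(list(), tempfile()), "no entities")
})

test_that("legacy PDB parsing renumbers insertion codes sequentially", {
  pdb_lines <- c(
    "ATOM      1  CA  ALA A   1      11.000   6.000  -6.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2      14.000   6.000  -6.000  1.00  0.00           C",
    "ATOM      3  CA  SER A   2A     17.000   6.000  -6.000  1.00  0.00           C",
    "ATOM      4  CA  VAL A   3      20.000   6.000  -6.000  1.00  0.00           C",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb_lines, path)
  suppressMessages(m <- read_structure(path, format = "pdb"))
  res <- m$chains[[1]]$residues
  expect_equal(res$seq_pos, 1:4)
  expect_equal(res$aa, c("A", "G", "S", "V"))
  expect_true(all(res$modeled))
})

test_that("domain annotations are validated against the sequence", {
  expect_error(polymer_entity("U_1", "U", "ACDEF",
                              domain_annotations = data.frame(
                                source = "PFAM", domain_id = "PF1",
                                begin = 2, end = 9)),
               "begin <= end <= sequence length")
  expect_error(polymer_entity("U_1", "U", "ACDEF",
                              domain_annotations = data.frame(
                                source = "BAD", domain_id = "D",
                                begin = 1, end = 2)),
               "domain sources")
})

test_that("invalid residue tables are rejected", {
  expect_error(polymer_instance("A", "U_1",
                                data.frame(seq_pos = c(1, 1, 2),
                                           aa = "A", modeled = FALSE,
                                           confidence = NA_real_)),
               "strictly increasing")
  res <- data.frame(seq_pos = 1:2, aa = "A", modeled = c(TRUE, FALSE),
                    confidence = NA_real_)
  expect_error(polymer_instance("A", "U_1", res,
                                atoms = data.frame(seq_pos = 2,
                                                   atom_name = "CA",
                                                   element = "C",
                                                   x = 0, y = 0, z = 0)),
               "unmodeled residues cannot carry atoms")
  expect_error(structure_model("E", list(), provenance = "experimental"),
               "at least one chain")
  res3 <- data.frame(seq_pos = 1, aa = "A", modeled = FALSE,
                     confidence = 130)
  expect_error(polymer_instance("A", "U_1", res3), "\\[0, 100\\]")
})

test_that("water and amino acids cannot be ligands", {
  res <- data.frame(seq_pos = 1, aa = "A", modeled = FALSE,
                    confidence = NA_real_)
  inst <- polymer_instance("A", "U_1", res)
  bad <- data.frame(comp_id = "HOH", chain_id = "L", atom_name = "O",
                    element = "O", x = 0, y = 0, z = 0)
  expect_error(structure_model("E", list(inst), ligands = bad),
               "cannot be ligands")
})
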