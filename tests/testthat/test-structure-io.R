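test_that("parsing is lossless and format-agnostic for a minimal structure", {
  fp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(minimal_pdb_lines(), fp)
  atoms <- read_structure(fp)
  expect_equal(nrow(atoms), 2)
  expect_equal(length(unique(atoms$chain_id)), 1)
  expect_equal(atoms$x, c(1, 2))
  expect_equal(atoms$atom_name, c("N", "CA"))
  expect_true(all(atoms$is_polymer))

  fc <- withr::local_tempfile(fileext = ".cif")
  writeLines(minimal_cif_lines(), fc)
  cif <- read_structure(fc)
  expect_equal(nrow(cif), nrow(atoms))
  expect_equal(cif[, c("x", "y", "z")], atoms[, c("x", "y", "z")],
               ignore_attr = TRUE)
  expect_equal(cif$atom_name, atoms$atom_name)
})

test_that("write/read round trip preserves names and coordinates to PDB precision", {
  toy <- toy_labeled_structure()
  fp <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(toy, fp)
  back <- read_structure(fp)
  expect_equal(nrow(back), nrow(toy))
  expect_equal(back$atom_name, toy$atom_name)
  expect_equal(back$residue_number, toy$residue_number)
  expect_equal(as.matrix(back[, c("x", "y", "z")]),
               as.matrix(toy[, c("x", "y", "z")]), tolerance = 1e-3)
})

test_that("unreadable and unknown-format inputs raise named errors", {
  expect_error(read_structure(tempfile(fileext = ".pdb")), "not found")
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines("junk", f)
  expect_error(read_structure(f), "format")
})

test_that("extract_bilins finds residues by code, assigns hosts, survives chain shuffling", {
  toy <- toy_labeled_structure()
  bil <- extract_bilins(toy)
  expect_equal(nrow(bil), 3)
  expect_equal(sort(bil$chain_id), c("U", "V", "W"))
  # each bilin sits next to its own decoy chain
  expect_equal(bil$host_chain_id[match(c("U", "V", "W"), bil$chain_id)],
               c("A", "B", "C"))
  expect_equal(vapply(bil$atoms, nrow, integer(1)), rep(20L, 3))

  # invariance to atom/chain order in the file
  shuffled <- toy[rev(seq_len(nrow(toy))), ]
  bil2 <- extract_bilins(shuffled)
  expect_equal(dplyr::arrange(bil2, chain_id)[, c("chain_id", "host_chain_id", "n_atoms")],
               dplyr::arrange(bil, chain_id)[, c("chain_id", "host_chain_id", "n_atoms")])

  # zero matches: empty with a warning
  expect_warning(none <- extract_bilins(toy, residue_codes = "ZZZ"),
                 "no residues")
  expect_equal(nrow(none), 0)
})

test_that("arginine-contact signature indexes the bottom-trimer b82 bilins", {
  toy <- toy_labeled_structure()
  bil <- extract_bilins(toy)
  lab <- assign_bilin_labels(bil, toy, linker_chains = c(CpcL = "L"), cutoff = 4)
  # the bilin with no arginine contact is index 2; the one touched by the
  # highest-numbered arginines is index 1
  expect_equal(lab$monomer_index[lab$chain_id == "V"], 2L)
  expect_equal(lab$monomer_index[lab$chain_id == "U"], 1L)
  expect_equal(lab$monomer_index[lab$chain_id == "W"], 3L)
  expect_setequal(lab$label, c("1I-b82-1", "1I-b82-2", "1I-b82-3"))

  # deterministic given the same model and cutoff
  lab2 <- assign_bilin_labels(bil, toy, linker_chains = c(CpcL = "L"), cutoff = 4)
  expect_identical(lab$label, lab2$label)

  # single bilin: label assigned without a signature test
  one <- as_bilin_table(make_tetrapyrrole(10, 10, 10))
  one$label <- NULL
  lone <- assign_bilin_labels(one, make_tetrapyrrole(10, 10, 10))
  expect_equal(nrow(lone), 1)
  expect_match(lone$label, "^1I-")
})

test_that("ambiguous arginine signatures are reported, not silently broken", {
  toy <- toy_labeled_structure()
  # remove every arginine: two or more bilins share the zero signature
  toy_noargs <- toy[toy$residue_name != "ARG", ]
  bil <- extract_bilins(toy_noargs)
  # all three share a zero-contact signature: chain-order indices retained
  lab <- assign_bilin_labels(bil, toy_noargs, linker_chains = c(CpcL = "L"))
  expect_equal(sort(lab$monomer_index), 1:3)
  # two bilins with arginine contacts from the same max residue number
  toy_amb <- toy
  toy_amb$residue_number[toy_amb$residue_name == "ARG" &
                           toy_amb$residue_number %in% c(181, 169)] <- 150L
  toy_amb$residue_number[toy_amb$residue_name == "ARG" &
                           toy_amb$residue_number %in% c(112, 178)] <- 150L
  toy_amb$residue_number[toy_amb$residue_name == "ARG" &
                           toy_amb$residue_number %in% c(16, 163)] <- 150L
  bil_amb <- extract_bilins(toy_amb)
  expect_error(assign_bilin_labels(bil_amb, toy_amb, linker_chains = c(CpcL = "L")),
               "ambiguous")
})

test_that("bilin inventory TSV carries the expected columns", {
  toy <- toy_labeled_structure()
  bil <- assign_bilin_labels(extract_bilins(toy), toy,
                             linker_chains = c(CpcL = "L"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_bilin_inventory(bil, f)
  tab <- utils::read.delim(f)
  expect_equal(nrow(tab), 3)
  expect_true(all(c("label", "residue_name", "chain_id", "host_chain_id",
                    "n_atoms") %in% names(tab)))
})
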