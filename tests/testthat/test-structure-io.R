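test_that("contiguous chains are read with a full register", {
  xyz <- cbind(0, 0, c(0, 3.8, 7.6))
  p <- write_toy_pdb(1:3, xyz)
  ch <- read_chain(p, "A")
  expect_equal(chain_length(ch), 3L)
  expect_true(all(ch$residues$present))
  expect_equal(ch$residues$resno, 1:3)
  expect_equal(ch$residues$z, c(0, 3.8, 7.6))
})

test_that("author-numbering gaps insert absent placeholder positions", {
  xyz <- cbind(0, 0, c(0, 3.8, 7.6))
  p <- write_toy_pdb(c(1, 2, 5), xyz)
  ch <- read_chain(p, "A")
  expect_equal(chain_length(ch), 5L)
  expect_equal(ch$residues$present, c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(ch$residues$resno, 1:5)
})

test_that("a residue lacking a C-alpha becomes an absent register position", {
  # residue 2 exists in the file but has no CA record
  xyz <- rbind(c(0, 0, 0), c(0, 0, 3.8), c(0, 0, 7.6))
  path <- write_toy_pdb(c(1, 2, 3), xyz, elety = c("CA", "CB", "CA"))
  ch <- read_chain(path, "A")
  expect_equal(chain_length(ch), 3L)
  expect_equal(ch$residues$present, c(TRUE, FALSE, TRUE))
})

test_that("missing files, unknown chains and empty chains raise errors", {
  expect_error(read_chain(tempfile(), "A"), "file not found")
  p <- write_toy_pdb(1:3, cbind(0, 0, c(0, 3.8, 7.6)))
  expect_error(read_chain(p, "Z"), "chain not found")
  p2 <- write_toy_pdb(1:3, cbind(0, 0, c(0, 3.8, 7.6)),
                      elety = rep("CB", 3))
  expect_error(read_chain(p2, "A"), "empty chain")
})

test_that("mmCIF files are read with the same register rules as PDB", {
  cif <- c(
    "data_test", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 C CA . ALA A 1 1 ? 0.000 0.000 0.000 1.00 0.00 ? 1 ALA A CA 1",
    "ATOM 2 C CA . GLY A 1 2 ? 0.000 0.000 3.800 1.00 0.00 ? 2 GLY A CA 1",
    "ATOM 3 C CA . SER A 1 3 ? 0.000 0.000 7.600 1.00 0.00 ? 5 SER A CA 1",
    "#")
  path <- tempfile(fileext = ".cif")
  writeLines(cif, path)
  ch <- suppressWarnings(read_chain(path, "A"))
  expect_equal(chain_length(ch), 5L)          # author numbers 1,2,5
  expect_equal(ch$residues$present, c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(ch$residues$resid[c(1, 2, 5)], c("ALA", "GLY", "SER"))
  expect_equal(ch$residues$z[5], 7.6)
})

test_that("label files in pair and per-line formats align to the register", {
  p <- write_toy_pdb(c(1, 2, 5), cbind(0, 0, c(0, 3.8, 7.6)))
  ch <- read_chain(p, "A")
  lab <- tempfile()
  writeLines(c("1\t1", "2\t1", "5\t1"), lab)
  expect_equal(read_labels(lab, ch), c(1L, 1L, 4L, 4L, 1L))
  writeLines(c("3", "3", "0", "0", "3"), lab)
  expect_equal(read_labels(lab, ch), c(3L, 3L, 4L, 4L, 3L))
  # comma-delimited pairs
  writeLines(c("1,2", "2,2", "5,0"), lab)
  expect_equal(read_labels(lab, ch), c(2L, 2L, 4L, 4L, 0L))
})

test_that("illegal label values and misaligned label files are rejected", {
  p <- write_toy_pdb(1:3, cbind(0, 0, c(0, 3.8, 7.6)))
  ch <- read_chain(p, "A")
  lab <- tempfile()
  writeLines(c("1\t7", "2\t0", "3\t0"), lab)
  expect_error(read_labels(lab, ch), "label value")
  writeLines(c("1\t0", "2\t0"), lab)                 # residue 3 uncovered
  expect_error(read_labels(lab, ch), "label alignment")
  writeLines(c("0", "0"), lab)                       # wrong per-line length
  expect_error(read_labels(lab, ch), "label alignment")
  writeLines(c("1\t0", "2\t0", "9\t0"), lab)         # outside register
  expect_error(read_labels(lab, ch), "label alignment")
})

test_that("writing and re-reading a chain preserves the register and coordinates", {
  g <- solenoid_geometry(1, n_repeats = 3, jitter_sd = 0.3, seed = 7)
  cm <- make_composite(15, g, 15, seed = 2, gap = TRUE)
  path <- tempfile(fileext = ".pdb")
  write_chain_pdb(cm$chain, path)
  ch2 <- read_chain(path, "A")
  expect_equal(chain_length(ch2), chain_length(cm$chain))
  expect_equal(ch2$residues$resno, cm$chain$residues$resno)
  expect_equal(ch2$residues$present, cm$chain$residues$present)
  expect_equal(ch2$residues$resid[ch2$residues$present],
               cm$chain$residues$resid[cm$chain$residues$present])
  expect_lt(max(abs(ch2$residues$x - cm$chain$residues$x), na.rm = TRUE), 1e-3)
  expect_lt(max(abs(ch2$residues$z - cm$chain$residues$z), na.rm = TRUE), 1e-3)
  # gap insertion is idempotent: write/read again reproduces absences
  path2 <- tempfile(fileext = ".pdb")
  write_chain_pdb(ch2, path2)
  ch3 <- read_chain(path2, "A")
  expect_equal(ch3$residues$present, ch2$residues$present)
})
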