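# Helpers to build small in-memory structures -------------------------------

toy_121 <- function() make_toy_complex(toy_complex_spec(n_residues = 120, seed = 7))

pdb_atom_line <- function(serial, name, alt, resname, chain, resno,
                          x, y, z, occ, element) {
  sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resname, chain, resno, x, y, z, occ, 0, element)
}

test_that("a written complex re-splits into the same protein and ligand", {
  toy <- toy_121()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_complex(toy$protein, toy$ligand, f)
  ents <- read_structure(f)
  roles <- vapply(ents, function(e) e$role, character(1))
  expect_setequal(roles, c("protein", "ligand"))
  prot <- ents[[which(roles == "protein")]]
  lig <- ents[[which(roles == "ligand")]]
  expect_identical(nrow(prot$atoms), nrow(toy$protein$atoms))
  expect_identical(nrow(lig$atoms), nrow(toy$ligand$atoms))
  expect_lt(max(abs(as.matrix(prot$atoms[, c("x", "y", "z")]) -
                    as.matrix(toy$protein$atoms[, c("x", "y", "z")]))), 6e-4)
  expect_identical(unique(lig$atoms$resname), "LIG")
  expect_identical(unique(lig$atoms$record), "HETATM")
  expect_identical(prot$atoms$resname, toy$protein$atoms$resname)
})

test_that("solvent and common additives are excluded by default", {
  toy <- toy_121()
  hoh <- toy$ligand
  hoh$atoms$resname <- "HOH"
  f <- withr::local_tempfile(fileext = ".pdb")
  write_complex(toy$protein, hoh, f)
  ents <- read_structure(f)
  expect_length(ents, 1L)
  expect_identical(ents[[1]]$role, "protein")
  # but kept when the exclusion list is overridden
  ents2 <- read_structure(f, exclude = character(0))
  expect_length(ents2, 2L)
})

test_that("multi-model files honor the model argument and bounds", {
  toy <- toy_121()
  xyz <- as.matrix(toy$protein$atoms[, c("x", "y", "z")])
  sets <- lapply(1:5, function(k) xyz + k)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_fixture(toy$protein, sets, f)
  s1 <- read_structure(f, model = 1)[[1]]
  s5 <- read_structure(f, model = 5)[[1]]
  off1 <- as.matrix(s1$atoms[, c("x", "y", "z")]) - xyz
  off5 <- as.matrix(s5$atoms[, c("x", "y", "z")]) - xyz
  expect_equal(mean(off1), 1, tolerance = 1e-3)
  expect_equal(mean(off5), 5, tolerance = 1e-3)
  expect_error(read_structure(f, model = 6), "model")
  expect_error(read_structure(f, model = 0), "model")
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  lines <- c(
    pdb_atom_line(1, "CA", "A", "ALA", "A", 1, 0, 0, 0, 0.40, "C"),
    pdb_atom_line(2, "CA", "B", "ALA", "A", 1, 1, 1, 1, 0.60, "C"),
    pdb_atom_line(3, "CA", " ", "GLY", "A", 2, 5, 0, 0, 1.00, "C"),
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  st <- read_structure(f)[[1]]
  expect_identical(nrow(st$atoms), 2L)
  expect_equal(st$atoms$x[st$atoms$resno == 1], 1)  # conformer B won
})

test_that("structures beyond 9999 atoms round-trip at PDB precision", {
  set.seed(1)
  nres <- 2700L
  n <- nres * 4L
  df <- data.frame(
    name = rep(c("N", "CA", "C", "O"), nres),
    element = rep(c("N", "C", "C", "O"), nres),
    resname = "GLY", chain = "A",
    resno = rep(seq_len(nres), each = 4), insert = "", alt = "", occ = 1,
    x = runif(n, -50, 50), y = runif(n, -50, 50), z = runif(n, -50, 50),
    record = "ATOM", serial = seq_len(n), stringsAsFactors = FALSE)
  big <- zpocket:::new_structure(zpocket:::finalize_atoms(df), "protein")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(big, f)
  b2 <- read_structure(f)[[1]]
  expect_identical(nrow(b2$atoms), n)
  expect_gt(max(b2$atoms$serial), 9999)
  expect_lt(max(abs(as.matrix(b2$atoms[, c("x", "y", "z")]) -
                    as.matrix(df[, c("x", "y", "z")]))), 6e-4)
})

test_that("reader fails loudly on missing or unusable input", {
  expect_error(read_structure(file.path(tempdir(), "no-such-file.pdb")),
               "no such file")
  toy <- toy_121()
  empty <- toy$protein
  empty$atoms <- empty$atoms[0, , drop = FALSE]
  expect_error(write_structure(empty, withr::local_tempfile()), "empty")
})
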