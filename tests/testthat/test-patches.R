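# A hand-built straight-chain protein with one ligand atom: residue i has
# its Ca at x = 3 (i - 1), the ligand atom sits at the origin. Distances to
# the ligand are therefore exactly 0, 3, 6, 9, ... Angstrom.
chain_protein <- function(n = 8) {
  df <- data.frame(
    name = "CA", element = "C", resname = "GLY", chain = "A",
    resno = seq_len(n), insert = "", alt = "", occ = 1,
    x = 3 * (seq_len(n) - 1), y = 0, z = 0,
    record = "ATOM", serial = seq_len(n), stringsAsFactors = FALSE)
  zpocket:::new_structure(zpocket:::finalize_atoms(df), "protein")
}

point_ligand <- function() {
  df <- data.frame(
    name = "C1", element = "C", resname = "LIG", chain = "L",
    resno = 1L, insert = "", alt = "", occ = 1, x = 0, y = 0, z = 0,
    record = "HETATM", serial = 1L, stringsAsFactors = FALSE)
  zpocket:::new_structure(zpocket:::finalize_atoms(df), "ligand")
}

test_that("the binding-site cutoff is strictly less-than", {
  bs <- define_binding_site(chain_protein(), point_ligand(), cutoff = 6)
  # residues at 0 and 3 A qualify; the residue at exactly 6 A does not
  expect_setequal(bs$residues, c("A:1:", "A:2:"))
  expect_identical(bs$kind, "BS")
  bs7 <- define_binding_site(chain_protein(), point_ligand(), cutoff = 6.001)
  expect_setequal(bs7$residues, c("A:1:", "A:2:", "A:3:"))
})

test_that("residue-centered sets collect residues within the radius", {
  prot <- chain_protein()
  rs <- residue_centered_set(prot, "A:3:", radius = 6)
  # centers at 0, 3, 6, 9, 12, ...: strictly within 6 A of x = 6 are x = 3..9
  expect_setequal(rs$residues, c("A:2:", "A:3:", "A:4:"))
  rs2 <- residue_centered_set(prot, "A:3:", radius = 6.001)
  expect_setequal(rs2$residues, c("A:1:", "A:2:", "A:3:", "A:4:", "A:5:"))
  expect_identical(rs$center_residue, "A:3:")
  expect_error(residue_centered_set(prot, "A:99:"), "no alpha carbon")
})

test_that("decoys are size-matched and exclude the binding site center", {
  toy <- make_toy_complex(toy_complex_spec(n_residues = 150, seed = 11))
  dec <- generate_decoys(toy$protein, toy$bs)
  expect_gt(length(dec), 10)
  expect_true(all(vapply(dec, function(d) d$kind, character(1)) == "BSD"))
  centers <- vapply(dec, function(d) d$center_residue, character(1))
  expect_length(intersect(centers, toy$bs$residues), 0L)
  Rstar <- attr(dec, "radius")
  expect_true(Rstar >= 6 && Rstar <= 20)
  # the chosen radius minimizes the size gap on the recorded curve
  curve <- attr(dec, "size_curve")
  gaps <- abs(curve$mean_size - length(toy$bs$residues))
  expect_equal(curve$radius[which.min(gaps)], Rstar)
})

test_that("the surface-exposure filter prunes decoy centers", {
  toy <- make_toy_complex(toy_complex_spec(n_residues = 150, seed = 11))
  cloud <- build_surface(toy$protein, point_density = 1, seed = 1)
  all_dec <- generate_decoys(toy$protein, toy$bs)
  exp_dec <- generate_decoys(toy$protein, toy$bs, cloud = cloud)
  exposed <- unique(cloud$points$residue)
  expect_true(all(vapply(exp_dec, function(d) d$center_residue,
                         character(1)) %in% exposed))
  expect_lte(length(exp_dec), length(all_dec))
})

test_that("cut_patch keeps exactly the points of the requested residues", {
  toy <- make_toy_complex(toy_complex_spec(n_residues = 120, seed = 7))
  cloud <- build_surface(toy$protein, point_density = 1, seed = 2)
  rs <- residue_centered_set(toy$protein, toy$bs$residues[1], radius = 9,
                             kind = "residue_centered")
  p <- cut_patch(cloud, rs)
  expect_s3_class(p, "zp_patch")
  expect_setequal(unique(p$cloud$points$residue),
                  intersect(rs$residues, unique(cloud$points$residue)))
  expect_identical(nrow(p$cloud$points),
                   sum(cloud$points$residue %in% rs$residues))
  # a residue set with no surface points is an error, not an empty patch
  empty <- zpocket:::new_residue_set("Z:999:", kind = "residue_centered")
  expect_error(cut_patch(cloud, empty), "empty patch")
})
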