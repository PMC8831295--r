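test_that("the toy generator is a deterministic function of its spec", {
  s <- toy_complex_spec(n_residues = 130, seed = 21, noise_sd = 0.2)
  t1 <- make_toy_complex(s)
  t2 <- make_toy_complex(s)
  expect_identical(t1$protein$atoms, t2$protein$atoms)
  expect_identical(t1$ligand$atoms, t2$ligand$atoms)
  expect_identical(t1$bs$residues, t2$bs$residues)
})

test_that("generated complexes respect the carve contract", {
  spec <- toy_complex_spec(n_residues = 150, seed = 5)   # noise 0
  toy <- make_toy_complex(spec)
  lig <- as.matrix(toy$ligand$atoms[, c("x", "y", "z")])
  prot <- toy$protein$atoms
  dmin <- vapply(seq_len(nrow(prot)), function(i) {
    sqrt(min((lig[, 1] - prot$x[i])^2 + (lig[, 2] - prot$y[i])^2 +
             (lig[, 3] - prot$z[i])^2))
  }, numeric(1))
  expect_true(all(dmin >= vdw_radius(prot$element) + 1.7 + spec$contact_gap))
  expect_gte(nrow(toy$ligand$atoms), 12)
  expect_identical(unique(toy$ligand$atoms$record), "HETATM")
  expect_s3_class(toy$bs, "zp_residue_set")
  expect_gt(length(toy$bs$residues), 0)
})

test_that("zero complementarity yields a detached ligand and no ground truth", {
  spec <- toy_complex_spec(seed = 4, complementarity = 0)
  toy <- make_toy_complex(spec)
  expect_null(toy$bs)
  lig_center <- colMeans(as.matrix(toy$ligand$atoms[, c("x", "y", "z")]))
  expect_gt(sqrt(sum(lig_center^2)), 2 * spec$protein_radius)
})

test_that("random rotations are proper and distance-preserving", {
  for (s in 1:5) {
    R <- random_rotation(seed = s)
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
  p1 <- make_shape("dumbbell", n_points = 500, seed = 1)
  p2 <- rotate_cloud(p1, seed = 9)
  i <- sample.int(nrow(p1), 50)
  expect_equal(as.numeric(dist(p1[i, ])), as.numeric(dist(p2[i, ])),
               tolerance = 1e-9)
  # rotating a surface cloud keeps its normals unit length
  toy <- make_toy_complex(toy_complex_spec(n_residues = 120, seed = 7))
  cl <- build_surface(toy$protein, point_density = 1, seed = 2)
  cl2 <- rotate_cloud(cl, seed = 9)
  expect_equal(sqrt(cl2$points$nx^2 + cl2$points$ny^2 + cl2$points$nz^2),
               rep(1, nrow(cl2$points)), tolerance = 1e-9)
})

test_that("the shape library produces five distinguishable shapes", {
  shapes <- c("ellipsoid", "dumbbell", "torus", "blob", "helix")
  ds <- lapply(shapes, function(s)
    zernike_descriptor(make_shape(s, n_points = 2000, seed = 1),
                       grid_side = 32))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_gt(manhattan_distance(ds[[i]], ds[[j]]), 0.5)
  }
  expect_error(make_shape("cube"), "arg")
})

test_that("descriptor distance to the ligand tracks pocket proximity", {
  # at full complementarity and zero noise the carved pocket is the region
  # whose local shape matches the ligand: over all residue-centered patches
  # the Manhattan distance correlates with the center's distance to the
  # ligand (rank correlation well above chance on every tested seed)
  for (s in 1:2) {
    toy <- make_toy_complex(toy_complex_spec(seed = s))
    cloud <- build_surface(toy$protein, point_density = 3, seed = s)
    ligd <- zernike_descriptor(build_surface(toy$ligand, point_density = 3,
                                             seed = s), grid_side = 32)
    ca <- zpocket:::ca_table(toy$protein)
    lc <- colMeans(as.matrix(toy$ligand$atoms[, c("x", "y", "z")]))
    prox <- numeric(0); dst <- numeric(0)
    for (i in seq_len(nrow(ca))) {
      rs <- residue_centered_set(toy$protein, ca$residue[i], radius = 9)
      p <- tryCatch(cut_patch(cloud, rs), error = function(e) NULL)
      if (is.null(p)) next
      prox <- c(prox, sqrt(sum((as.numeric(ca[i, c("x", "y", "z")]) - lc)^2)))
      dst <- c(dst, manhattan_distance(
        zernike_descriptor(p, grid_side = 32), ligd))
    }
    expect_gt(length(dst), 100)
    expect_gt(cor(prox, dst, method = "spearman"), 0.25)
  }
})

test_that("infeasible toy geometries are rejected", {
  expect_error(make_toy_complex(
    toy_complex_spec(ligand_radius = 8, protein_radius = 10)), "infeasible")
})
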