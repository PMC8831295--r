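# Approximate natural amino-acid composition used to name toy residues so
# that frequency analyses are exercisable on synthetic sites.
default_aa_composition <- function() {
  c(ALA = 8.3, ARG = 5.5, ASN = 4.1, ASP = 5.5, CYS = 1.4, GLN = 3.9,
    GLU = 6.8, GLY = 7.1, HIS = 2.3, ILE = 5.9, LEU = 9.7, LYS = 5.8,
    MET = 2.4, PHE = 3.9, PRO = 4.7, SER = 6.6, THR = 5.4, TRP = 1.1,
    TYR = 2.9, VAL = 6.9) / 100
}

#' Specification of a synthetic carved-pocket complex
#'
#' Collects the parameters of the toy protein-ligand generator. The output
#' of [make_toy_complex()] is a deterministic function of the spec
#' (including its seed), and the `complementarity` parameter monotonically
#' controls the expected ligand-pocket descriptor distance: at 1 the ligand
#' is carved deeply into the protein body and the pocket wraps it; at 0 the
#' ligand is placed far from the protein and no ground truth exists.
#'
#' @param n_residues target number of pseudo-residues packed into the
#'   protein ball (default 280; the packing stops early if fewer fit).
#' @param pocket_depth how far below the protein radius the ligand center
#'   sits at complementarity 1, in Angstrom (default 2).
#' @param ligand_radius nominal ligand sphere radius in Angstrom (default 3).
#' @param complementarity scalar in `[0, 1]` (default 1).
#' @param noise_sd Gaussian coordinate jitter applied to every atom, in
#'   Angstrom (default 0).
#' @param seed integer seed; identical specs regenerate bit-identically.
#' @param protein_radius radius of the protein atom ball in Angstrom
#'   (default 10.5).
#' @param contact_gap carve clearance between ligand and pocket wall
#'   (default 0.5 A).
#' @param aa_composition sampling weights for residue names.
#' @return a `zp_toy_spec` list.
#' @export
toy_complex_spec <- function(n_residues = 280, pocket_depth = 2,
                             ligand_radius = 3, complementarity = 1,
                             noise_sd = 0, seed = 1,
                             protein_radius = 10.5, contact_gap = 0.5,
                             aa_composition = default_aa_composition()) {
  stopifnot(n_residues >= 8, pocket_depth > 0, ligand_radius > 0,
            complementarity >= 0, complementarity <= 1, noise_sd >= 0)
  structure(list(n_residues = n_residues, pocket_depth = pocket_depth,
                 ligand_radius = ligand_radius,
                 complementarity = complementarity, noise_sd = noise_sd,
                 seed = as.integer(seed), protein_radius = protein_radius,
                 contact_gap = contact_gap, aa_composition = aa_composition),
            class = "zp_toy_spec")
}

#' Generate a synthetic protein-ligand complex with a carved pocket
#'
#' The pseudo-protein is a ball of Ca-only residues packed quasi-uniformly
#' (minimum-spacing thinning of a random sample), so that every surface
#' region is backed by residues whose Ca sits right at the surface — the
#' attribution structure the binding-site rule relies on. The ligand is an
#' atom blob filling a sphere placed at a depth controlled by
#' `complementarity`, and the pocket is carved by removing protein atoms
#' that intersect the ligand dilated by the contact gap, so the pocket wall
#' is geometrically complementary to the ligand. Ground-truth binding-site
#' residues (6 A Ca rule) are recorded.
#'
#' @param spec a `zp_toy_spec` from [toy_complex_spec()].
#' @return list with `protein` and `ligand` (`zp_structure`s), `bs` (the
#'   ground-truth `zp_residue_set`, or `NULL` at complementarity 0) and
#'   `spec`.
#' @export
make_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "zp_toy_spec"))
  a <- spec$protein_radius
  if (2 * spec$ligand_radius > a) {
    stop("infeasible geometry: ligand larger than protein")
  }
  set.seed(spec$seed)

  # quasi-uniform packing of Ca positions in the ball, min spacing 2.6 A
  spacing <- 2.6
  cand <- matrix(stats::runif(3 * 40 * spec$n_residues, -a, a), ncol = 3)
  cand <- cand[rowSums(cand^2) <= a^2, , drop = FALSE]
  acc <- matrix(0, spec$n_residues, 3)
  n_acc <- 0L
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (n_acc > 0L) {
      d2 <- (acc[seq_len(n_acc), 1] - p[1])^2 +
            (acc[seq_len(n_acc), 2] - p[2])^2 +
            (acc[seq_len(n_acc), 3] - p[3])^2
      if (min(d2) < spacing^2) next
    }
    n_acc <- n_acc + 1L
    acc[n_acc, ] <- p
    if (n_acc == spec$n_residues) break
  }
  ca <- acc[seq_len(n_acc), , drop = FALSE]
  resnames <- sample(names(spec$aa_composition), n_acc,
                     replace = TRUE, prob = spec$aa_composition)
  prot <- data.frame(
    name = "CA", element = "C", resname = resnames, chain = "A",
    resno = seq_len(n_acc), insert = "", alt = "", occ = 1,
    x = ca[, 1], y = ca[, 2], z = ca[, 3],
    record = "ATOM", stringsAsFactors = FALSE
  )

  # ligand blob
  cdir <- stats::rnorm(3); cdir <- cdir / sqrt(sum(cdir^2))
  cl <- spec$complementarity
  center_r <- if (cl > 0) {
    a + spec$ligand_radius - cl * (spec$pocket_depth + spec$ligand_radius)
  } else 3 * a
  lcenter <- cdir * center_r
  b <- max(0.8, spec$ligand_radius - 1.7)   # atom-center radius so SES ~ ligand_radius
  n_lig <- max(12L, ceiling(4 / 3 * pi * b^3 / 1.5))
  lpos <- matrix(0, 0, 3)
  while (nrow(lpos) < n_lig - 1L) {
    cand <- matrix(stats::runif(3 * 2 * n_lig, -b, b), ncol = 3)
    cand <- cand[rowSums(cand^2) <= b^2, , drop = FALSE]
    lpos <- rbind(lpos, cand)
  }
  lpos <- rbind(c(0, 0, 0), lpos[seq_len(n_lig - 1L), , drop = FALSE])
  lpos <- sweep(lpos, 2L, lcenter, `+`)
  lig <- data.frame(
    name = paste0("C", seq_len(n_lig)),
    element = "C", resname = "LIG", chain = "L", resno = 1L,
    insert = "", alt = "", occ = 1,
    x = lpos[, 1], y = lpos[, 2], z = lpos[, 3],
    record = "HETATM", stringsAsFactors = FALSE
  )

  # carve: remove protein atoms intersecting the dilated ligand blob
  if (cl > 0) {
    rvp <- vdw_radius(prot$element)
    pmat <- as.matrix(prot[, c("x", "y", "z")])
    dmin <- apply(pmat, 1L, function(q) {
      sqrt(min((lpos[, 1] - q[1])^2 + (lpos[, 2] - q[2])^2 +
               (lpos[, 3] - q[3])^2))
    })
    prot <- prot[dmin >= rvp + 1.7 + spec$contact_gap, , drop = FALSE]
    if (nrow(prot) == 0L) stop("carve removed every protein atom")
  }

  if (spec$noise_sd > 0) {
    prot[, c("x", "y", "z")] <- prot[, c("x", "y", "z")] +
      matrix(stats::rnorm(3 * nrow(prot), 0, spec$noise_sd), ncol = 3)
    lig[, c("x", "y", "z")] <- lig[, c("x", "y", "z")] +
      matrix(stats::rnorm(3 * nrow(lig), 0, spec$noise_sd), ncol = 3)
  }

  prot$serial <- seq_len(nrow(prot))
  lig$serial <- nrow(prot) + seq_len(nrow(lig))
  protein <- new_structure(finalize_atoms(prot), "protein")
  ligand <- new_structure(finalize_atoms(lig), "ligand")

  bs <- if (cl > 0) define_binding_site(protein, ligand) else NULL
  list(protein = protein, ligand = ligand, bs = bs, spec = spec)
}

#' Random rotation matrix
#'
#' A proper rotation (det = +1) drawn uniformly (Haar) via QR decomposition
#' of a Gaussian matrix.
#'
#' @param seed optional integer seed.
#' @return 3x3 orthonormal matrix.
#' @export
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

check_rotation <- function(R) {
  if (!is.matrix(R) || any(dim(R) != 3) ||
      max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9) {
    stop("rotation must be a 3x3 orthonormal matrix with det +1")
  }
  invisible(R)
}

#' Rigidly rotate a structure, cloud or coordinate matrix about its centroid
#'
#' @param x a `zp_structure`, `zp_cloud`, or numeric matrix with 3 columns.
#' @param rotation 3x3 proper rotation matrix; if `NULL`, a random rotation
#'   drawn with `seed`.
#' @param seed seed for the random rotation.
#' @return object of the same type with rotated coordinates (and rotated
#'   normals for clouds).
#' @export
rotate_cloud <- function(x, rotation = NULL, seed = NULL) {
  if (is.null(rotation)) rotation <- random_rotation(seed)
  check_rotation(rotation)
  rot_about_centroid <- function(m) {
    ctr <- colMeans(m)
    sweep(sweep(m, 2L, ctr) %*% t(rotation), 2L, ctr, `+`)
  }
  if (is.matrix(x)) return(rot_about_centroid(x))
  if (inherits(x, "zp_structure")) {
    m <- rot_about_centroid(atom_coords(x))
    x$atoms$x <- m[, 1]; x$atoms$y <- m[, 2]; x$atoms$z <- m[, 3]
    return(x)
  }
  if (inherits(x, "zp_cloud")) {
    m <- rot_about_centroid(cloud_coords(x))
    x$points$x <- m[, 1]; x$points$y <- m[, 2]; x$points$z <- m[, 3]
    if (all(c("nx", "ny", "nz") %in% names(x$points)) &&
        !anyNA(x$points$nx)) {
      nm <- as.matrix(x$points[, c("nx", "ny", "nz")]) %*% t(rotation)
      x$points$nx <- nm[, 1]; x$points$ny <- nm[, 2]; x$points$nz <- nm[, 3]
    }
    return(x)
  }
  stop("cannot rotate object of class ", paste(class(x), collapse = "/"))
}

#' Synthetic voxelizable test shapes
#'
#' Deterministic point-cloud samples of simple closed surfaces (ellipsoid,
#' dumbbell, torus, bumpy sphere, helix tube) used by the rotation-invariance
#' validation suite.
#'
#' @param name one of `"ellipsoid"`, `"dumbbell"`, `"torus"`, `"blob"`,
#'   `"helix"`.
#' @param n_points approximate number of points (default 4000).
#' @param seed integer seed.
#' @return numeric matrix with 3 columns (Angstrom-scale coordinates).
#' @export
make_shape <- function(name = c("ellipsoid", "dumbbell", "torus", "blob",
                                "helix"),
                       n_points = 4000, seed = 1) {
  name <- match.arg(name)
  set.seed(seed)
  u <- fibonacci_sphere(n_points)
  switch(name,
    ellipsoid = u %*% diag(c(9, 6, 4)),
    dumbbell = {
      half <- n_points %/% 2
      rbind(sweep(u[seq_len(half), ] * 4, 2L, c(-4.5, 0, 0), `+`),
            sweep(u[-seq_len(half), ] * 3, 2L, c(4.5, 0, 0), `+`))
    },
    torus = {
      t1 <- stats::runif(n_points, 0, 2 * pi)
      t2 <- stats::runif(n_points, 0, 2 * pi)
      Rr <- 6; rr <- 2
      cbind((Rr + rr * cos(t2)) * cos(t1), (Rr + rr * cos(t2)) * sin(t1),
            rr * sin(t2))
    },
    blob = {
      r <- 6 * (1 + 0.25 * sin(3 * atan2(u[, 2], u[, 1])) *
                  cos(2 * acos(pmin(1, pmax(-1, u[, 3])))))
      u * r
    },
    helix = {
      t1 <- seq(0, 4 * pi, length.out = n_points)
      ring <- stats::runif(n_points, 0, 2 * pi)
      cx <- 5 * cos(t1); cy <- 5 * sin(t1); cz <- seq(-6, 6, length.out = n_points)
      cbind(cx + 1.2 * cos(ring), cy + 1.2 * sin(ring), cz)
    })
}

#' Write a DMS-dialect surface fixture
#'
#' Emits one atom-center line (`type A`) per atom contributing points and one
#' surface-point line (`type SR0`) per cloud point, in the dialect
#' [read_dms()] parses: `resname resno atomname x y z type [area nx ny nz]`.
#' Coordinates are written with 3 decimals (round-trip equality holds at
#' that precision).
#'
#' @param cloud an attributed `zp_cloud` whose `atom_ref`s are valid indices
#'   into its structure.
#' @param path output path.
#' @export
write_dms_fixture <- function(cloud, path) {
  stopifnot(inherits(cloud, "zp_cloud"))
  atoms <- cloud$structure$atoms
  if (any(cloud$points$atom_ref < 1 | cloud$points$atom_ref > nrow(atoms))) {
    stop("cloud contains unresolvable atom references")
  }
  ai <- sort(unique(cloud$points$atom_ref))
  atom_lines <- sprintf("%-4s %4d %-4s %9.3f %9.3f %9.3f A",
                        atoms$resname[ai], atoms$resno[ai], atoms$name[ai],
                        atoms$x[ai], atoms$y[ai], atoms$z[ai])
  p <- cloud$points
  has_nrm <- all(c("nx", "ny", "nz") %in% names(p)) && !anyNA(p$nx)
  pt_lines <- if (has_nrm) {
    sprintf("%-4s %4d %-4s %9.3f %9.3f %9.3f SR0 0.333 %6.3f %6.3f %6.3f",
            atoms$resname[p$atom_ref], atoms$resno[p$atom_ref],
            atoms$name[p$atom_ref], p$x, p$y, p$z, p$nx, p$ny, p$nz)
  } else {
    sprintf("%-4s %4d %-4s %9.3f %9.3f %9.3f SR0",
            atoms$resname[p$atom_ref], atoms$resno[p$atom_ref],
            atoms$name[p$atom_ref], p$x, p$y, p$z)
  }
  writeLines(c(atom_lines, pt_lines), path)
  invisible(path)
}

#' Write a multi-model PDB fixture
#'
#' Wraps one MODEL/ENDMDL block per coordinate set around the atoms of a
#' structure; used to build conformer-ensemble fixtures for the reader.
#'
#' @param x a `zp_structure` supplying the atom table.
#' @param coord_sets list of N x 3 coordinate matrices, one per model.
#' @param path output path.
#' @export
write_multimodel_fixture <- function(x, coord_sets, path) {
  stopifnot(inherits(x, "zp_structure"), length(coord_sets) >= 1)
  con <- file(path, "w")
  on.exit(close(con))
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  for (i in seq_along(coord_sets)) {
    m <- coord_sets[[i]]
    stopifnot(nrow(m) == nrow(x$atoms))
    xi <- x
    xi$atoms$x <- m[, 1]; xi$atoms$y <- m[, 2]; xi$atoms$z <- m[, 3]
    write_structure(xi, tmp)
    body <- readLines(tmp)
    body <- body[grepl("^(ATOM|HETATM|TER)", body)]
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(body, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
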