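new_residue_set <- function(residues, kind = c("BS", "BSD", "residue_centered"),
                            center = NA_character_) {
  kind <- match.arg(kind)
  residues <- unique(residues)
  if (length(residues) == 0L) stop("residue set must be non-empty")
  if (!is.na(center) && !(center %in% residues)) {
    stop("center residue must belong to the set")
  }
  structure(list(residues = residues, center_residue = center, kind = kind),
            class = "zp_residue_set")
}

#' @export
print.zp_residue_set <- function(x, ...) {
  cat(sprintf("<zp_residue_set> kind=%s, %d residues%s\n", x$kind,
              length(x$residues),
              if (is.na(x$center_residue)) "" else
                paste0(", centered on ", x$center_residue)))
  invisible(x)
}

#' Define the binding site of a ligand on a protein
#'
#' A residue belongs to the binding site (BS) when its alpha carbon lies at
#' a distance strictly less than `cutoff` from at least one ligand atom
#' (all ligand atoms are considered, hydrogens included when present).
#'
#' @param protein a `zp_structure` with role "protein" (must have Ca atoms).
#' @param ligand a `zp_structure` with the ligand atoms.
#' @param cutoff distance cutoff in Angstrom (default 6, strict "less than").
#' @return a `zp_residue_set` of kind `"BS"`.
#' @export
define_binding_site <- function(protein, ligand, cutoff = 6) {
  stopifnot(inherits(protein, "zp_structure"), inherits(ligand, "zp_structure"),
            cutoff > 0)
  ca <- ca_table(protein)
  if (nrow(ca) == 0L) stop("protein has no alpha carbons")
  lig <- atom_coords(ligand)
  cxyz <- as.matrix(ca[, c("x", "y", "z")])
  dmin <- apply(cxyz, 1L, function(p) {
    sqrt(min((lig[, 1] - p[1])^2 + (lig[, 2] - p[2])^2 + (lig[, 3] - p[3])^2))
  })
  hit <- dmin < cutoff
  if (!any(hit)) {
    stop("empty binding site: no Ca within ", cutoff, " A of any ligand atom")
  }
  new_residue_set(ca$residue[hit], kind = "BS")
}

#' Residue-centered spherical region
#'
#' All residues whose Ca lies strictly closer than `radius` to the Ca of the
#' center residue (the center is always included).
#'
#' @param protein a `zp_structure`.
#' @param center residue key (`"chain:resno:insert"`) of the center residue;
#'   must have a Ca.
#' @param radius sphere radius in Angstrom (default 9).
#' @param kind stored kind label (default "residue_centered"; [generate_decoys()]
#'   uses "BSD").
#' @return a `zp_residue_set`.
#' @export
residue_centered_set <- function(protein, center, radius = 9,
                                 kind = "residue_centered") {
  stopifnot(inherits(protein, "zp_structure"), radius > 0)
  ca <- ca_table(protein)
  i <- match(center, ca$residue)
  if (is.na(i)) stop("center residue ", center, " has no alpha carbon")
  d <- sqrt((ca$x - ca$x[i])^2 + (ca$y - ca$y[i])^2 + (ca$z - ca$z[i])^2)
  new_residue_set(ca$residue[d < radius], kind = kind, center = center)
}

#' Generate size-matched binding-site decoys
#'
#' Builds residue-centered regions at every candidate Ca for each probe
#' radius R on a grid (default 6 to 20 A in 1 A steps), picks the radius R*
#' whose mean region size is closest to the true binding-site size (ties go
#' to the smaller radius), and returns the regions at R* as decoys (kind
#' `"BSD"`). Decoys centered on a binding-site residue are excluded by
#' default. When a surface cloud is supplied, only surface-exposed residues
#' (contributing at least one surface point) are used as centers; buried
#' residues would yield empty patches.
#'
#' @param protein a `zp_structure`.
#' @param binding_site the true BS `zp_residue_set` to size-match against.
#' @param r_min,r_max,r_step radius grid in Angstrom (defaults 6, 20, 1).
#' @param cloud optional `zp_cloud` used for the surface-exposure filter.
#' @param keep_overlapping if `TRUE`, keep decoys centered inside the BS
#'   (the literal random-region reading).
#' @return list of `zp_residue_set` decoys, with attributes `radius` (R*)
#'   and `mean_size`.
#' @export
generate_decoys <- function(protein, binding_site, r_min = 6, r_max = 20,
                            r_step = 1, cloud = NULL,
                            keep_overlapping = FALSE) {
  stopifnot(inherits(protein, "zp_structure"),
            inherits(binding_site, "zp_residue_set"))
  ca <- ca_table(protein)
  centers <- ca$residue
  if (!is.null(cloud)) {
    exposed <- unique(cloud$points$residue)
    centers <- centers[centers %in% exposed]
  }
  if (!keep_overlapping) {
    centers <- centers[!(centers %in% binding_site$residues)]
  }
  if (length(centers) == 0L) stop("no candidate decoy centers available")

  cxyz <- as.matrix(ca[, c("x", "y", "z")])
  rownames(cxyz) <- ca$residue
  D <- as.matrix(dist(cxyz))
  radii <- seq(r_min, r_max, by = r_step)
  target <- length(binding_site$residues)
  mean_size <- vapply(radii, function(R) {
    mean(colSums(D[, centers, drop = FALSE] < R))
  }, numeric(1))
  best <- which.min(abs(mean_size - target))   # which.min takes the first: smaller R on ties
  Rstar <- radii[best]

  decoys <- lapply(centers, function(cc) {
    new_residue_set(ca$residue[D[, cc] < Rstar], kind = "BSD", center = cc)
  })
  attr(decoys, "radius") <- Rstar
  attr(decoys, "mean_size") <- mean_size[best]
  attr(decoys, "size_curve") <- data.frame(radius = radii, mean_size = mean_size)
  decoys
}

#' Cut the surface patch belonging to a residue set
#'
#' Subsets a surface point cloud to the points attributed to residues of the
#' set.
#'
#' @param cloud a `zp_cloud`.
#' @param residue_set a `zp_residue_set`.
#' @return a `zp_patch`: list with `residue_set`, `cloud` (the subset) and
#'   `descriptor` (NULL until computed).
#' @export
cut_patch <- function(cloud, residue_set) {
  stopifnot(inherits(cloud, "zp_cloud"), inherits(residue_set, "zp_residue_set"))
  sel <- cloud$points$residue %in% residue_set$residues
  if (!any(sel)) stop("empty patch: no surface point maps into the residue set")
  sub <- new_cloud(cloud$points[sel, , drop = FALSE], cloud$source,
                   cloud$structure)
  structure(list(residue_set = residue_set, cloud = sub, descriptor = NULL),
            class = "zp_patch")
}

#' @export
print.zp_patch <- function(x, ...) {
  cat(sprintf("<zp_patch> kind=%s, %d residues, %d surface points\n",
              x$residue_set$kind, length(x$residue_set$residues),
              nrow(x$cloud$points)))
  invisible(x)
}
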