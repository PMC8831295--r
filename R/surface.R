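#' van der Waals radius lookup
#'
#' Standard element radii used by the internal surface builder. Unknown
#' elements fall back to the carbon radius (1.7 A) with a warning.
#' @param element character vector of element symbols.
#' @return numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  tab <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, H = 1.2, P = 1.8)
  e <- toupper(element)
  r <- unname(tab[e])
  if (anyNA(r)) {
    warning("unknown element(s) ", paste(unique(e[is.na(r)]), collapse = ", "),
            ": using default vdW radius 1.7 A")
    r[is.na(r)] <- 1.7
  }
  r
}

new_cloud <- function(points, source, structure) {
  stopifnot(is.data.frame(points))
  if (nrow(points) == 0L) stop("surface point cloud must be non-empty")
  structure(list(points = points, source = source, structure = structure),
            class = "zp_cloud")
}

#' @export
print.zp_cloud <- function(x, ...) {
  cat(sprintf("<zp_cloud> %d surface points (%s), %d residues\n",
              nrow(x$points), x$source, length(unique(x$points$residue))))
  invisible(x)
}

cloud_coords <- function(cloud) as.matrix(cloud$points[, c("x", "y", "z")])

# Deterministic, near-uniform directions on the unit sphere.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

# Per-atom local frames built from equivariant geometric cues (direction to
# the structure centroid and to the nearest neighbouring atom), so that
# rotating the input structure rotates the sampled surface rigidly.
local_frames <- function(xyz) {
  n <- nrow(xyz)
  ctr <- colMeans(xyz)
  frames <- vector("list", n)
  if (n > 1L) {
    d2 <- as.matrix(dist(xyz))
    diag(d2) <- Inf
    nn <- apply(d2, 1L, which.min)
  }
  for (i in seq_len(n)) {
    u <- xyz[i, ] - ctr
    if (sqrt(sum(u^2)) < 1e-8) u <- c(0, 0, 1) else u <- u / sqrt(sum(u^2))
    v <- if (n > 1L) xyz[nn[i], ] - xyz[i, ] else c(1, 0, 0)
    w <- v - sum(v * u) * u
    if (sqrt(sum(w^2)) < 1e-8) {
      # collinear fallback: any perpendicular (not equivariant, degenerate case)
      v <- diag(3)[, which.min(abs(u))]
      w <- v - sum(v * u) * u
    }
    w <- w / sqrt(sum(w^2))
    frames[[i]] <- cbind(u, w, c(u[2] * w[3] - u[3] * w[2],
                                 u[3] * w[1] - u[1] * w[3],
                                 u[1] * w[2] - u[2] * w[1]))
  }
  frames
}

#' Build a solvent-excluded-surface point sample
#'
#' Approximates the molecular (solvent-excluded) surface: sample points on
#' per-atom spheres of radius vdW + probe, discard points strictly inside any
#' other atom's inflated sphere, then retract each surviving point by the
#' probe radius towards its generating atom. Each point is attributed to the
#' atom (and hence residue) that generated it. Sampling directions live in
#' per-atom frames derived from the structure geometry, so the construction
#' is equivariant: rotating the structure rotates the cloud (same seed).
#'
#' @param x a `zp_structure`.
#' @param probe_radius probe sphere radius in Angstrom (default 1.4, water).
#' @param point_density target sampling density in points per square Angstrom
#'   of solvent-accessible sphere area (default 3).
#' @param seed integer seed controlling a global twist of the sampling
#'   lattice; the same seed gives bit-identical output.
#' @return a `zp_cloud`.
#' @export
build_surface <- function(x, probe_radius = 1.4, point_density = 3, seed = 1L) {
  stopifnot(inherits(x, "zp_structure"), probe_radius > 0, point_density > 0)
  xyz <- atom_coords(x)
  n <- nrow(xyz)
  rv <- vdw_radius(x$atoms$element)
  R <- rv + probe_radius

  # seeded twist applied inside every local frame (determinism contract);
  # the caller's RNG state is left untouched
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  ang <- stats::runif(1, 0, 2 * pi)
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  twist <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)

  frames <- local_frames(xyz)
  # neighbour lists: only atoms whose inflated spheres can contain candidates
  d <- as.matrix(dist(xyz))
  pts <- vector("list", n)
  for (i in seq_len(n)) {
    m <- max(8L, ceiling(point_density * 4 * pi * R[i]^2))
    dirs <- fibonacci_sphere(m) %*% t(twist) %*% t(frames[[i]])
    cand <- sweep(dirs * R[i], 2L, xyz[i, ], `+`)
    nb <- which(d[i, ] < R[i] + R & seq_len(n) != i)
    keep <- rep(TRUE, m)
    for (j in nb) {
      dj2 <- (cand[, 1] - xyz[j, 1])^2 + (cand[, 2] - xyz[j, 2])^2 +
             (cand[, 3] - xyz[j, 3])^2
      keep <- keep & dj2 >= (R[j] - 1e-9)^2
    }
    if (!any(keep)) next
    dirs <- dirs[keep, , drop = FALSE]
    q <- sweep(dirs * rv[i], 2L, xyz[i, ], `+`)  # retracted by probe
    pts[[i]] <- data.frame(
      x = q[, 1], y = q[, 2], z = q[, 3],
      nx = dirs[, 1], ny = dirs[, 2], nz = dirs[, 3],
      atom_ref = i,
      residue = x$atoms$residue[i],
      resname = x$atoms$resname[i],
      stringsAsFactors = FALSE
    )
  }
  pts <- do.call(rbind, pts)
  if (is.null(pts) || nrow(pts) == 0L) stop("structure produced no surface points")
  rownames(pts) <- NULL
  new_cloud(pts, "internal", x)
}

#' Read a DMS-style molecular surface file
#'
#' Parses surface-point lines of the DMS text dialect: whitespace-separated
#' `resname resno atomname x y z type [area nx ny nz]`. Lines whose type
#' field starts with `A` describe atom centers and are skipped; types
#' starting with `S` are surface points. Each point is resolved to an atom of
#' `structure` by (residue number, atom name).
#'
#' @param path path to a DMS file.
#' @param structure the `zp_structure` the surface belongs to.
#' @param strict if `TRUE` (default) an unresolvable atom reference is an
#'   error (reported with its line number); if `FALSE` the line is dropped
#'   with a warning.
#' @return a `zp_cloud` with `source = "dms_file"`.
#' @export
read_dms <- function(path, structure, strict = TRUE) {
  stopifnot(inherits(structure, "zp_structure"))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  key <- paste(structure$atoms$resno, structure$atoms$name)
  rows <- vector("list", length(lines))
  bad <- integer(0)
  for (k in seq_along(lines)) {
    f <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    if (length(f) < 7) next
    type <- f[7]
    if (startsWith(type, "A")) next
    if (!startsWith(type, "S")) next
    idx <- match(paste(as.integer(f[2]), f[3]), key)
    if (is.na(idx)) {
      bad <- c(bad, k)
      next
    }
    nrm <- if (length(f) >= 11) as.numeric(f[9:11]) else c(NA_real_, NA_real_, NA_real_)
    rows[[k]] <- data.frame(
      x = as.numeric(f[4]), y = as.numeric(f[5]), z = as.numeric(f[6]),
      nx = nrm[1], ny = nrm[2], nz = nrm[3],
      atom_ref = idx,
      residue = structure$atoms$residue[idx],
      resname = structure$atoms$resname[idx],
      stringsAsFactors = FALSE
    )
  }
  if (length(bad) > 0L) {
    msg <- paste0("unresolvable atom reference on line(s) ",
                  paste(bad, collapse = ", "), " of ", path)
    if (strict) stop(msg) else warning(msg, " (dropped)")
  }
  pts <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(pts) || nrow(pts) == 0L) stop("no surface points parsed from ", path)
  rownames(pts) <- NULL
  new_cloud(pts, "dms_file", structure)
}
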