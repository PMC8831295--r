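#' Manhattan distance between two Zernike descriptors
#'
#' `sum_i |a_i - b_i|`. Low distance means high shape complementarity: two
#' perfectly fitting surfaces share their descriptors.
#'
#' @param a,b `zp_descriptor` objects (or bare numeric vectors) of equal
#'   length.
#' @return non-negative scalar.
#' @export
manhattan_distance <- function(a, b) {
  va <- if (inherits(a, "zp_descriptor")) a$values else as.numeric(a)
  vb <- if (inherits(b, "zp_descriptor")) b$values else as.numeric(b)
  if (length(va) != length(vb)) {
    stop("descriptor length mismatch: ", length(va), " vs ", length(vb))
  }
  sum(abs(va - vb))
}

#' Z-score normalization of patch-ligand distances
#'
#' Standardizes each distance against the mean and the population standard
#' deviation (divide by N) of all patch-ligand distances of the complex:
#' `Z_i = (x_i - mu(x)) / sigma(x)`. BS and decoy rows are normalized
#' together.
#'
#' @param distances data.frame with columns `patch_id`, `kind` (one of BS,
#'   BSD, residue_centered) and `distance`; at least 2 rows with distinct
#'   distances.
#' @param ligand_id identifier recorded in the result.
#' @return a `zp_complementarity` table: the input plus a `zscore` column
#'   (mean 0, population sd 1).
#' @export
zscore_table <- function(distances, ligand_id = "ligand") {
  stopifnot(is.data.frame(distances),
            all(c("patch_id", "kind", "distance") %in% names(distances)))
  x <- distances$distance
  if (length(x) < 2L) stop("need at least 2 distances")
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))   # population sd
  if (sigma == 0) stop("zero variance: all distances identical")
  out <- distances
  out$zscore <- (x - mu) / sigma
  attr(out, "ligand_id") <- ligand_id
  attr(out, "sd_convention") <- "population"
  class(out) <- c("zp_complementarity", class(out))
  out
}

#' Best-matching pocket for a ligand
#'
#' Scans a list of described patches and returns the one with the smallest
#' Manhattan distance to the ligand descriptor. Exact ties are broken by
#' patch order and flagged.
#'
#' @param ligand a `zp_descriptor` of the ligand.
#' @param patches named list of `zp_descriptor`s (or of `zp_patch` objects
#'   carrying a `descriptor`).
#' @return list with `patch_id`, `distance`, `distances` (all of them) and
#'   `tie` flag.
#' @export
best_pocket <- function(ligand, patches) {
  if (length(patches) == 0L) stop("empty patch list")
  descs <- lapply(patches, function(p) {
    if (inherits(p, "zp_patch")) {
      if (is.null(p$descriptor)) stop("patch carries no descriptor")
      p$descriptor
    } else p
  })
  ids <- names(patches)
  if (is.null(ids)) ids <- as.character(seq_along(patches))
  d <- vapply(descs, manhattan_distance, numeric(1), b = ligand)
  i <- which.min(d)
  tie <- sum(d == d[i]) > 1L
  if (tie) warning("tied best-pocket distances; returning the first by id order")
  list(patch_id = ids[i], distance = unname(d[i]),
       distances = setNames(unname(d), ids), tie = tie)
}

#' Empirical association threshold from background distances
#'
#' The lower empirical quantile of a background (decoy-ligand) distance
#' distribution: a candidate distance below it has probability below
#' `quantile` of belonging to the non-association distribution. Uses the
#' type-1 empirical quantile (smallest order statistic with index
#' `ceiling(q * N)`; no interpolation). The threshold is always recomputed
#' from the supplied background, never assumed.
#'
#' @param background_distances numeric vector (>= 20 values).
#' @param quantile lower-tail fraction (default 0.05).
#' @return scalar threshold.
#' @export
association_threshold <- function(background_distances, quantile = 0.05) {
  x <- as.numeric(background_distances)
  if (length(x) < 20L) stop("need at least 20 background distances")
  if (quantile <= 0 || quantile > 1) stop("quantile must be in (0, 1]")
  sort(x)[ceiling(quantile * length(x))]
}

#' Call a ligand-receptor association
#'
#' Positive when the best-pocket distance is strictly below the threshold
#' and, if a per-residue quality table is supplied, the mean quality of the
#' pocket residues is at most the supplied first-quartile bound (lower
#' quality score = better prediction, as for per-residue model confidence
#' scores).
#'
#' @param candidate result of [best_pocket()], or a list with `patch_id` and
#'   `distance`.
#' @param threshold association threshold (> 0), e.g. from
#'   [association_threshold()].
#' @param patch_residues residue keys of the best patch (required when a
#'   quality gate is used).
#' @param quality_scores optional named numeric vector of per-residue quality
#'   scores; must cover every patch residue.
#' @param quality_quartile_bound optional scalar; the gate passes when the
#'   mean patch quality is <= this bound.
#' @param ligand_id,receptor_id identifiers recorded in the call.
#' @return a `zp_association`: list with `ligand_id`, `receptor_id`,
#'   `best_patch_id`, `distance`, `threshold_used`, `quality_gate_passed`
#'   and `positive`.
#' @export
call_association <- function(candidate, threshold, patch_residues = NULL,
                             quality_scores = NULL,
                             quality_quartile_bound = NULL,
                             ligand_id = "ligand", receptor_id = "receptor") {
  stopifnot(threshold > 0)
  gate <- TRUE
  if (!is.null(quality_scores) && !is.null(quality_quartile_bound)) {
    if (is.null(patch_residues)) stop("patch_residues required for the quality gate")
    miss <- setdiff(patch_residues, names(quality_scores))
    if (length(miss) > 0L) {
      stop("quality table missing residue(s): ", paste(miss, collapse = ", "))
    }
    gate <- mean(quality_scores[patch_residues]) <= quality_quartile_bound
  }
  structure(list(
    ligand_id = ligand_id, receptor_id = receptor_id,
    best_patch_id = candidate$patch_id, distance = candidate$distance,
    threshold_used = threshold, quality_gate_passed = gate,
    positive = candidate$distance < threshold && gate
  ), class = "zp_association")
}

#' @export
print.zp_association <- function(x, ...) {
  cat(sprintf("<zp_association> %s ~ %s: patch %s, distance %.4g vs threshold %.4g -> %s\n",
              x$ligand_id, x$receptor_id, x$best_patch_id, x$distance,
              x$threshold_used,
              if (x$positive) "ASSOCIATED" else "not associated"))
  invisible(x)
}
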