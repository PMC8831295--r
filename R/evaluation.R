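#' ROC curve and AUC for binding-site discrimination
#'
#' Labels the true binding sites positive and the decoys negative and uses a
#' score (the Zernike descriptor distance to the cognate ligand) as the
#' discriminant. By convention a LOW distance indicates a positive, which is
#' handled by negating scores internally. The AUC is computed from the
#' Mann-Whitney rank statistic with tie correction; the stored curve is a
#' full threshold sweep whose trapezoidal integral equals the rank AUC.
#'
#' @param labels logical (or 0/1) vector; `TRUE` = positive (true BS).
#' @param scores numeric vector of the same length.
#' @param positive_is_low if `TRUE` (default) small scores indicate
#'   positives.
#' @return a `zp_roc`: list with `fpr`, `tpr`, `thresholds`, `auc`, `n_pos`,
#'   `n_neg`.
#' @export
roc_auc <- function(labels, scores, positive_is_low = TRUE) {
  lab <- as.logical(labels)
  stopifnot(length(lab) == length(scores))
  if (!any(lab) || all(lab)) stop("both classes must be present")
  s <- if (positive_is_low) -scores else scores
  n1 <- sum(lab); n0 <- sum(!lab)
  r <- rank(s)                                 # midranks handle ties
  auc <- (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- sort(unique(s), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(s[lab] >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(s[!lab] >= t), numeric(1))
  fpr <- c(0, fp / n0, 1)
  tpr <- c(0, tp / n1, 1)
  structure(list(fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, if (positive_is_low) -thr else thr, -Inf),
                 auc = auc, n_pos = n1, n_neg = n0),
            class = "zp_roc")
}

#' @export
print.zp_roc <- function(x, ...) {
  cat(sprintf("<zp_roc> AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

descriptor_values <- function(x) {
  if (inherits(x, "zp_descriptor")) x$values else as.numeric(x)
}

#' Specific similarity between two index-aligned patch sets
#'
#' Mean Manhattan distance over corresponding patch pairs (patch i of the
#' experimental structure against patch i of the model, both centered on the
#' same residue): `S_s = (1/N) sum_i dist(E_i, M_i)`.
#'
#' @param pairsA,pairsB equal-length, index-aligned lists of
#'   `zp_descriptor`s.
#' @return scalar mean distance.
#' @export
specific_similarity <- function(pairsA, pairsB) {
  if (length(pairsA) != length(pairsB)) stop("patch lists differ in length")
  if (length(pairsA) == 0L) stop("empty patch lists")
  mean(mapply(manhattan_distance, pairsA, pairsB))
}

#' Non-specific similarity between two patch sets
#'
#' Mean Manhattan distance over all ordered non-corresponding pairs:
#' `S_ns = (1/(N(N-1))) sum_{i != j} dist(E_i, M_j)`. Note that
#' dist(E_i, M_j) and dist(E_j, M_i) differ in general, hence the ordered
#' enumeration.
#'
#' @inheritParams specific_similarity
#' @return scalar mean distance.
#' @export
nonspecific_similarity <- function(pairsA, pairsB) {
  N <- length(pairsA)
  if (N != length(pairsB)) stop("patch lists differ in length")
  if (N < 2L) stop("need at least 2 patches")
  tot <- 0
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i != j) tot <- tot + manhattan_distance(pairsA[[i]], pairsB[[j]])
  }
  tot / (N * (N - 1))
}

#' Zernike sensitivity of a model against its experimental structure
#'
#' S_Z = S_ns - S_s: positive when corresponding surface regions of the two
#' structures are preferentially matched, i.e. the shape description
#' recognizes the same region on model and experiment. Also reports a
#' per-patch z-score of each specific distance against that patch's own
#' distance distribution to all model patches (negative = the matching
#' region is closer than typical).
#'
#' @inheritParams specific_similarity
#' @return a `zp_similarity`: list with `s_specific`, `s_nonspecific`,
#'   `sensitivity` and `patch_zscores`.
#' @export
zernike_sensitivity <- function(pairsA, pairsB) {
  s_s <- specific_similarity(pairsA, pairsB)
  s_ns <- nonspecific_similarity(pairsA, pairsB)
  N <- length(pairsA)
  zs <- vapply(seq_len(N), function(i) {
    di <- vapply(seq_len(N), function(j)
      manhattan_distance(pairsA[[i]], pairsB[[j]]), numeric(1))
    mu <- mean(di); sg <- sqrt(mean((di - mu)^2))
    if (sg == 0) 0 else (di[i] - mu) / sg
  }, numeric(1))
  structure(list(s_specific = s_s, s_nonspecific = s_ns,
                 sensitivity = s_ns - s_s, patch_zscores = zs),
            class = "zp_similarity")
}

#' @export
print.zp_similarity <- function(x, ...) {
  cat(sprintf("<zp_similarity> S_s = %.4g, S_ns = %.4g, S_Z = %.4g\n",
              x$s_specific, x$s_nonspecific, x$sensitivity))
  invisible(x)
}

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

#' Amino-acid frequencies of binding regions
#'
#' Counts residue occurrences over a collection of sites and normalizes to
#' fractions summing to 1. Unknown residue codes are pooled under `"other"`
#' with a warning.
#'
#' @param sites a list whose elements are either character vectors of
#'   3-letter residue codes or `zp_residue_set`s (in which case `structure`
#'   must be supplied to resolve residue names).
#' @param structure optional `zp_structure` used to map residue keys of
#'   `zp_residue_set`s to residue names.
#' @return named numeric vector over the 20 amino acids (plus `"other"` when
#'   present), summing to 1.
#' @export
residue_frequencies <- function(sites, structure = NULL) {
  if (length(sites) == 0L) stop("empty site list")
  codes <- unlist(lapply(sites, function(s) {
    if (inherits(s, "zp_residue_set")) {
      if (is.null(structure)) stop("structure required to resolve residue names")
      a <- structure$atoms
      a$resname[match(s$residues, a$residue)]
    } else as.character(s)
  }))
  codes <- toupper(codes)
  unknown <- !(codes %in% AA3)
  if (any(unknown)) {
    warning(sum(unknown), " residue code(s) outside the 20 amino acids, counted as 'other'")
    codes[unknown] <- "other"
  }
  tab <- table(factor(codes, levels = c(AA3, if (any(unknown)) "other")))
  out <- as.numeric(tab) / sum(tab)
  names(out) <- names(tab)
  out
}

#' Quartile stratification of per-complex z-scores
#'
#' Assigns each complex to a quartile of the empirical z-score distribution:
#' quartile 1 holds the most negative (best classified) complexes, quartile
#' 4 the worst. Boundaries are type-1 empirical quantiles; values tied with
#' a boundary go to the lower quartile.
#'
#' @param zscores numeric vector (length >= 4).
#' @return integer labels 1-4.
#' @export
quartile_stratify <- function(zscores) {
  x <- as.numeric(zscores)
  if (length(x) < 4L) stop("need at least 4 complexes")
  qs <- vapply(c(0.25, 0.5, 0.75), function(q) sort(x)[ceiling(q * length(x))],
               numeric(1))
  1L + (x > qs[1]) + (x > qs[2]) + (x > qs[3])
}

#' Carved-pocket benchmark: BS-vs-decoy discrimination on synthetic complexes
#'
#' Generates seeded toy protein-ligand complexes with [make_toy_complex()],
#' builds their surfaces, defines the true binding site (6 A rule) and
#' size-matched decoys, describes every patch and the ligand with Zernike
#' invariants, scores complementarity by Manhattan distance and normalizes
#' per complex with the z-score. Pooled raw distances feed a BS-vs-BSD ROC.
#'
#' @param n_complexes number of seeded complexes (default 50).
#' @param seed master seed; per-complex seeds are derived from it.
#' @param complementarity,noise_sd generator settings (defaults 1.0 and 0.3 A,
#'   the benchmark study condition).
#' @param n_decoys decoys scored per complex (default 8, subsampled from the
#'   full decoy set).
#' @param grid_side,order descriptor resolution (defaults 32 and 10).
#' @param point_density surface sampling density (default 3 points/A^2).
#' @return list with `table` (one row per patch: complex, patch_id, kind,
#'   distance, zscore), `roc` (a `zp_roc` on pooled distances),
#'   `frac_bs_z_negative` and `bs_zscores`.
#' @export
run_pocket_benchmark <- function(n_complexes = 50, seed = 1,
                                 complementarity = 1.0, noise_sd = 0.3,
                                 n_decoys = 8, grid_side = 32, order = 10,
                                 point_density = 3) {
  set.seed(seed)
  seeds <- sample.int(1e8, n_complexes)
  rows <- vector("list", n_complexes)
  for (k in seq_len(n_complexes)) {
    tc <- make_toy_complex(toy_complex_spec(
      complementarity = complementarity, noise_sd = noise_sd,
      seed = seeds[k]))
    prot_cloud <- build_surface(tc$protein, point_density = point_density,
                                seed = seeds[k])
    lig_cloud <- build_surface(tc$ligand, point_density = point_density,
                               seed = seeds[k])
    bs <- define_binding_site(tc$protein, tc$ligand)
    decoys <- generate_decoys(tc$protein, bs, cloud = prot_cloud)
    if (length(decoys) > n_decoys) {
      set.seed(seeds[k])
      decoys <- decoys[sort(sample.int(length(decoys), n_decoys))]
    }
    lig_desc <- zernike_descriptor(lig_cloud, order = order,
                                   grid_side = grid_side)
    sets <- c(list(bs), decoys)
    ids <- c("BS", paste0("BSD_", vapply(decoys, function(d) d$center_residue,
                                         character(1))))
    dist_k <- vapply(sets, function(s) {
      p <- cut_patch(prot_cloud, s)
      manhattan_distance(zernike_descriptor(p, order = order,
                                            grid_side = grid_side), lig_desc)
    }, numeric(1))
    tab <- zscore_table(data.frame(
      patch_id = ids,
      kind = c("BS", rep("BSD", length(decoys))),
      distance = dist_k, stringsAsFactors = FALSE
    ), ligand_id = sprintf("toy_%d", k))
    tab$complex <- k
    rows[[k]] <- as.data.frame(tab)
  }
  table <- do.call(rbind, rows)
  roc <- roc_auc(table$kind == "BS", table$distance, positive_is_low = TRUE)
  bs_z <- table$zscore[table$kind == "BS"]
  list(table = table, roc = roc,
       frac_bs_z_negative = mean(bs_z < 0), bs_zscores = bs_z)
}

#' Mean ligand-BS distance as a function of generator complementarity
#'
#' Runs the toy generator across complementarity levels and seeds and
#' reports the mean BS-patch-to-ligand descriptor distance per level. The
#' generator contract is that this curve is non-increasing in the
#' complementarity parameter.
#'
#' @param levels complementarity levels (default 0.25, 0.5, 0.75, 1).
#' @param n_seeds seeds per level (default 20).
#' @param seed master seed.
#' @param noise_sd generator noise (default 0).
#' @param grid_side,order,point_density descriptor and surface settings.
#' @return data.frame with columns `complementarity` and `mean_distance`.
#' @export
complementarity_sweep <- function(levels = c(0.25, 0.5, 0.75, 1),
                                  n_seeds = 20, seed = 1, noise_sd = 0,
                                  grid_side = 32, order = 10,
                                  point_density = 3) {
  set.seed(seed)
  seeds <- sample.int(1e8, n_seeds)
  means <- vapply(levels, function(cl) {
    d <- vapply(seeds, function(sk) {
      tc <- make_toy_complex(toy_complex_spec(
        complementarity = cl, noise_sd = noise_sd, seed = sk))
      prot_cloud <- build_surface(tc$protein, point_density = point_density,
                                  seed = sk)
      lig_cloud <- build_surface(tc$ligand, point_density = point_density,
                                 seed = sk)
      bs <- define_binding_site(tc$protein, tc$ligand)
      p <- cut_patch(prot_cloud, bs)
      manhattan_distance(
        zernike_descriptor(p, order = order, grid_side = grid_side),
        zernike_descriptor(lig_cloud, order = order, grid_side = grid_side))
    }, numeric(1))
    mean(d)
  }, numeric(1))
  data.frame(complementarity = levels, mean_distance = means)
}
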