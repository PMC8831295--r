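#' @importFrom stats sd quantile rnorm runif setNames aggregate cor
#' @importFrom utils head read.table write.table
NULL

# Canonical residue key: "chain:resno:insert". Used everywhere a residue_id
# is needed (patch attribution, residue sets, ground-truth tables).
residue_key <- function(chain, resno, insert = "") {
  insert[is.na(insert)] <- ""
  chain[is.na(chain)] <- ""
  paste(chain, resno, insert, sep = ":")
}

#' Default exclusion list for waters and common crystallization additives
#'
#' Residue names dropped by [read_structure()] when partitioning a PDB file
#' into protein and ligand entities.
#' @export
default_exclusions <- function() {
  c("HOH", "DOD", "NA", "CL", "SO4", "GOL", "PEG", "EDO")
}

new_structure <- function(atoms, role = c("protein", "ligand"), model_index = 1L) {
  role <- match.arg(role)
  stopifnot(is.data.frame(atoms))
  if (nrow(atoms) == 0L) stop("structure must contain at least one atom")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("atom coordinates must be finite")
  }
  atoms$residue <- residue_key(atoms$chain, atoms$resno, atoms$insert)
  structure(
    list(atoms = atoms, role = role, model_index = as.integer(model_index)),
    class = "zp_structure"
  )
}

#' @export
print.zp_structure <- function(x, ...) {
  cat(sprintf(
    "<zp_structure> role=%s  %d atoms, %d residues (model %d)\n",
    x$role, nrow(x$atoms), length(unique(x$atoms$residue)), x$model_index
  ))
  invisible(x)
}

infer_element <- function(elesy, name) {
  ele <- toupper(trimws(elesy))
  bad <- is.na(ele) | ele == ""
  if (any(bad)) {
    # fall back on the atom name: strip digits, take leading letters
    guess <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", trimws(name[bad]))))
    two <- c("CL", "BR", "NA", "MG", "ZN", "FE", "MN", "CA", "SE")
    guess <- ifelse(substr(guess, 1, 2) %in% two, substr(guess, 1, 2),
                    substr(guess, 1, 1))
    ele[bad] <- guess
  }
  ele[is.na(ele) | ele == ""] <- "C"
  ele
}

atoms_from_bio3d <- function(pdb, xyz) {
  a <- pdb$atom
  n <- nrow(a)
  xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  data.frame(
    serial  = as.integer(a$eleno),
    name    = trimws(a$elety),
    element = infer_element(a$elesy, a$elety),
    resname = trimws(a$resid),
    chain   = ifelse(is.na(a$chain), "", a$chain),
    resno   = as.integer(a$resno),
    insert  = ifelse(is.na(a$insert), "", a$insert),
    alt     = ifelse(is.na(a$alt), "", a$alt),
    occ     = ifelse(is.na(a$o), 1, a$o),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    record  = a$type,
    stringsAsFactors = FALSE
  )
}

# Altloc resolution: keep the highest-occupancy conformer of each
# (residue, atom name); ties broken by altloc letter order.
resolve_altloc <- function(atoms) {
  if (all(atoms$alt == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name, sep = "|")
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    o <- atoms$occ[idx]
    idx[order(-o, atoms$alt[idx])][1L]
  }), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

finalize_atoms <- function(atoms) {
  atoms$is_ca <- atoms$name == "CA" & atoms$record == "ATOM"
  atoms$is_heavy <- toupper(atoms$element) != "H"
  atoms
}

#' Read a PDB file and partition it into protein and ligand entities
#'
#' Polymer chains (ATOM records) are merged into a single protein structure;
#' each HETATM group with a distinct (chain, residue number, residue name)
#' identity becomes a separate ligand structure. Waters and common
#' crystallization additives are dropped (see [default_exclusions()]).
#' Alternate locations are resolved to the highest-occupancy conformer.
#'
#' @param path path to a PDB file.
#' @param model 1-based model index for multi-model files (default 1, the
#'   first MODEL block).
#' @param exclude character vector of HETATM residue names to discard.
#' @return A list of `zp_structure` objects: the protein first (if any ATOM
#'   records are present), then one entry per ligand.
#' @export
read_structure <- function(path, model = 1L, exclude = default_exclusions()) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("could not parse PDB file '", path, "': ",
                             conditionMessage(e))
  )
  n_models <- nrow(pdb$xyz)
  if (is.null(n_models)) n_models <- 1L
  if (model < 1L || model > n_models) {
    stop(sprintf("model %d requested but file has %d model(s)", model, n_models))
  }
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model, ] else as.numeric(pdb$xyz)
  atoms <- atoms_from_bio3d(pdb, xyz)
  atoms <- atoms[!(atoms$record == "HETATM" & atoms$resname %in% exclude), ,
                 drop = FALSE]
  atoms <- resolve_altloc(atoms)
  atoms <- finalize_atoms(atoms)
  if (nrow(atoms) == 0L) stop("no atoms left in model ", model)

  out <- list()
  prot <- atoms[atoms$record == "ATOM", , drop = FALSE]
  if (nrow(prot) > 0L) {
    out <- c(out, list(new_structure(prot, "protein", model)))
  }
  het <- atoms[atoms$record == "HETATM", , drop = FALSE]
  if (nrow(het) > 0L) {
    grp <- paste(het$chain, het$resno, het$resname, sep = ":")
    for (g in unique(grp)) {
      out <- c(out, list(new_structure(het[grp == g, , drop = FALSE],
                                       "ligand", model)))
    }
  }
  if (length(out) == 0L) stop("model ", model, " contains no usable entities")
  out
}

#' Write a structure back to PDB format
#'
#' Round-trips through [read_structure()] preserving atom count, names,
#' residue identities and coordinates at PDB precision (3 decimals). Serial
#' numbers above 99999 are written as given and the fixed-width field widens
#' (bio3d dialect).
#'
#' @param x a `zp_structure`.
#' @param path output path.
#' @export
write_structure <- function(x, path) {
  stopifnot(inherits(x, "zp_structure"))
  a <- x$atoms
  if (nrow(a) == 0L) stop("refusing to write an empty structure")
  ok <- tryCatch({
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
      type = if (x$role == "protein") rep("ATOM", nrow(a)) else rep("HETATM", nrow(a)),
      resno = a$resno, resid = a$resname, eleno = a$serial,
      elety = a$name, chain = ifelse(a$chain == "", " ", a$chain),
      insert = ifelse(a$insert == "", "", a$insert),
      o = a$occ, b = rep(0, nrow(a)), elesy = a$element
    )
    TRUE
  }, error = function(e) stop("could not write '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}

#' Write a protein and its ligand(s) into one PDB file
#'
#' Concatenates the ATOM records of the protein with the HETATM records of
#' each ligand, so that [read_structure()] re-splits the file into the same
#' entities.
#'
#' @param protein a `zp_structure` with role `"protein"`.
#' @param ligands a single `zp_structure` or a list of them.
#' @param path output path.
#' @export
write_complex <- function(protein, ligands, path) {
  stopifnot(inherits(protein, "zp_structure"))
  if (inherits(ligands, "zp_structure")) ligands <- list(ligands)
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  keep_records <- function(f) {
    lines <- readLines(f)
    lines[grepl("^(ATOM|HETATM|TER)", lines)]
  }
  write_structure(protein, tmp)
  out <- keep_records(tmp)
  for (lg in ligands) {
    stopifnot(inherits(lg, "zp_structure"))
    write_structure(lg, tmp)
    out <- c(out, keep_records(tmp))
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

# Ca coordinate table: one row per residue that has an alpha carbon.
ca_table <- function(x) {
  stopifnot(inherits(x, "zp_structure"))
  ca <- x$atoms[x$atoms$is_ca, , drop = FALSE]
  ca[!duplicated(ca$residue), c("residue", "resname", "x", "y", "z"),
     drop = FALSE]
}

atom_coords <- function(x) as.matrix(x$atoms[, c("x", "y", "z")])
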