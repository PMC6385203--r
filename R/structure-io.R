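#' Atomic structures, docking poses and pose ensembles
#'
#' `structure3d()` wraps an atom table into the container used throughout the
#' package for receptor structures. `docking_pose()` wraps a peptide
#' conformation plus its docking score, and `pose_ensemble()` collects scored
#' poses of one peptide docked to one rigid receptor, sorted best (most
#' negative affinity) first.
#'
#' The atom table has one row per atom with columns `serial`, `name`,
#' `element`, `res_name`, `res_seq`, `ins`, `chain`, `x`, `y`, `z`
#' (coordinates in Angstrom). Insertion codes are kept in `ins` and appended
#' to the residue key where residues are compared; residue numbering is taken
#' from the file unmodified.
#'
#' @param atoms data.frame with the columns listed above.
#' @param id character identifier for the structure.
#' @param score docking affinity in kcal/mol (more negative = better).
#' @param pose_id character identifier for the pose.
#' @param peptide_name peptide the ensemble belongs to (e.g. `"FRRFa"`).
#' @param poses list of `docking_pose` objects.
#' @param receptor_id identifier of the common rigid receptor frame.
#' @return An object of class `structure3d`, `docking_pose` or
#'   `pose_ensemble` respectively.
#' @examples
#' at <- data.frame(serial = 1L, name = "CA", element = "C",
#'                  res_name = "GLY", res_seq = 1L, ins = "", chain = "A",
#'                  x = 0, y = 0, z = 0)
#' s <- structure3d(at, id = "toy")
#' @export
structure3d <- function(atoms, id = "structure") {
  atoms <- validate_atoms(atoms)
  if (anyDuplicated(atoms$serial))
    stop("atom serial numbers must be unique within a model")
  obj <- list(atoms = atoms, chains = sort(unique(atoms$chain)), id = id)
  class(obj) <- "structure3d"
  obj
}

#' @rdname structure3d
#' @export
docking_pose <- function(atoms, score, pose_id = "pose") {
  atoms <- validate_atoms(atoms)
  if (nrow(atoms) < 1L) stop("a pose must contain at least one atom")
  if (!is.finite(score)) stop("pose score must be finite")
  obj <- list(atoms = atoms, score = as.numeric(score),
              pose_id = as.character(pose_id))
  class(obj) <- "docking_pose"
  obj
}

#' @rdname structure3d
#' @export
pose_ensemble <- function(peptide_name, poses, receptor_id = "receptor") {
  stopifnot(is.list(poses))
  if (length(poses) == 0L) stop("pose ensemble must contain at least one pose")
  ok <- vapply(poses, inherits, logical(1), what = "docking_pose")
  if (!all(ok)) stop("all elements of `poses` must be docking_pose objects")
  scores <- vapply(poses, `[[`, numeric(1), "score")
  poses <- poses[order(scores)]  # stable: ties keep input order
  obj <- list(peptide_name = peptide_name, poses = poses,
              receptor_id = receptor_id)
  class(obj) <- "pose_ensemble"
  obj
}

validate_atoms <- function(atoms) {
  need <- c("serial", "name", "element", "res_name", "res_seq", "chain",
            "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (!"ins" %in% names(atoms)) atoms$ins <- ""
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("atom coordinates must be finite")
  if (any(!nzchar(atoms$element))) stop("atom element symbols must be non-empty")
  atoms$serial <- as.integer(atoms$serial)
  atoms$res_seq <- as.integer(atoms$res_seq)
  rownames(atoms) <- NULL
  atoms
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("<structure3d> %s: %d atoms, chains %s\n", x$id,
              nrow(x$atoms), paste(x$chains, collapse = "")))
  invisible(x)
}

#' @export
print.docking_pose <- function(x, ...) {
  cat(sprintf("<docking_pose> %s: %d atoms, score %.2f kcal/mol\n",
              x$pose_id, nrow(x$atoms), x$score))
  invisible(x)
}

#' @export
print.pose_ensemble <- function(x, ...) {
  sc <- ensemble_scores(x)
  cat(sprintf("<pose_ensemble> %s on %s: %d poses, scores %.2f .. %.2f\n",
              x$peptide_name, x$receptor_id, length(x$poses),
              min(sc), max(sc)))
  invisible(x)
}

#' Docking scores of an ensemble, best first
#' @param ensemble a `pose_ensemble`.
#' @return numeric vector of affinities (kcal/mol), ascending.
#' @export
ensemble_scores <- function(ensemble) {
  vapply(ensemble$poses, `[[`, numeric(1), "score")
}

# ---- PDB parsing ----------------------------------------------------------

# Fixed-column parse of ATOM/HETATM records. Keeps the first alternate
# location per (chain, res, insertion, atom name); element from columns
# 77-78 with an atom-name fallback.
parse_pdb_atoms <- function(lines) {
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  if (length(lines) == 0L) return(NULL)
  lines <- formatC(lines, width = 80, flag = "-")
  trim <- function(x) gsub("^\\s+|\\s+$", "", x)
  at <- data.frame(
    serial   = suppressWarnings(as.integer(substr(lines, 7, 11))),
    name     = trim(substr(lines, 13, 16)),
    altloc   = trim(substr(lines, 17, 17)),
    res_name = trim(substr(lines, 18, 20)),
    chain    = trim(substr(lines, 22, 22)),
    res_seq  = suppressWarnings(as.integer(substr(lines, 23, 26))),
    ins      = trim(substr(lines, 27, 27)),
    x        = as.numeric(substr(lines, 31, 38)),
    y        = as.numeric(substr(lines, 39, 46)),
    z        = as.numeric(substr(lines, 47, 54)),
    element  = trim(substr(lines, 77, 78)),
    stringsAsFactors = FALSE
  )
  # element fallback: first alphabetic character of the atom name
  noel <- !nzchar(at$element)
  if (any(noel)) {
    guess <- toupper(sub("^[0-9']*([A-Za-z]).*$", "\\1", at$name[noel]))
    at$element[noel] <- guess
  }
  at$element <- toupper(at$element)
  # first altloc per atom site
  key <- paste(at$chain, at$res_seq, at$ins, at$name, sep = "|")
  at <- at[!duplicated(key), ]
  at$altloc <- NULL
  rownames(at) <- NULL
  at
}

#' Read a receptor structure from a PDB file
#'
#' Parses fixed-column `ATOM`/`HETATM` records in file order. Hydrogens are
#' retained if present (heavy-atom-only algorithms ignore them downstream);
#' only the first alternate location of an atom is kept and insertion codes
#' are preserved. If the file contains multiple `MODEL` blocks only the first
#' model is read.
#'
#' @param path path to a PDB-format file.
#' @param id identifier for the returned structure; default basename of path.
#' @return a [structure3d] object.
#' @export
read_structure <- function(path, id = NULL) {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  lines <- readLines(path, warn = FALSE)
  # restrict to the first MODEL if the file is multi-model
  m0 <- grep("^MODEL", lines)
  if (length(m0) >= 1L) {
    e0 <- grep("^ENDMDL", lines)
    end <- if (length(e0)) e0[1] else length(lines)
    lines <- lines[seq(m0[1], end)]
  }
  at <- parse_pdb_atoms(lines)
  if (is.null(at)) stop("no ATOM/HETATM records found in ", path)
  structure3d(at, id = if (is.null(id)) basename(path) else id)
}

#' Read a docking pose ensemble
#'
#' Supports two dialects of multi-conformation docking output:
#' \describe{
#'   \item{multi-MODEL PDB}{`MODEL`/`ENDMDL` blocks with one score line per
#'     model, `REMARK VINA RESULT: <affinity> ...`.}
#'   \item{AutoDock-style result text}{`MODEL`/`ENDMDL` blocks whose score is
#'     carried on `USER` lines, e.g.
#'     `USER  Estimated Free Energy of Binding = -7.0 kcal/mol`, or a
#'     `USER`-tagged `VINA RESULT`/`Score:` line. This covers the
#'     AutoDock-family ".dock4" result layout, which is parsed from its
#'     MODEL-delimited conformations rather than from a documented schema.}
#' }
#' Poses are returned sorted best-score-first regardless of file order.
#'
#' @param path path to the pose file.
#' @param peptide_name name of the docked peptide.
#' @param receptor_id identifier of the receptor frame the poses share.
#' @return a [pose_ensemble] object.
#' @export
read_pose_ensemble <- function(path, peptide_name,
                               receptor_id = "receptor") {
  if (!file.exists(path)) stop("cannot read pose file: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) {
    # single unscored block is not a valid ensemble
    stop("no MODEL records (no poses) found in ", path)
  }
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  poses <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    blk <- lines[starts[k]:ends[k]]
    mnum <- suppressWarnings(as.integer(sub("^MODEL\\s+", "", blk[1])))
    if (is.na(mnum)) mnum <- k
    score <- parse_pose_score(blk)
    if (is.na(score))
      stop("pose ", mnum, " in ", basename(path),
           " has no parseable score line")
    at <- parse_pdb_atoms(blk)
    if (is.null(at))
      stop("pose ", mnum, " in ", basename(path), " contains no atoms")
    poses[[k]] <- docking_pose(at, score,
                               pose_id = sprintf("%s_%03d", peptide_name, mnum))
  }
  pose_ensemble(peptide_name, poses, receptor_id = receptor_id)
}

parse_pose_score <- function(block_lines) {
  sc_line <- grep("^REMARK\\s+VINA\\s+RESULT", block_lines, value = TRUE)
  if (length(sc_line) == 0L)
    sc_line <- grep("^USER.*(Estimated Free Energy of Binding|VINA RESULT|Score)",
                    block_lines, value = TRUE, ignore.case = TRUE)
  if (length(sc_line) == 0L) return(NA_real_)
  stripped <- sub("^[A-Z]+\\s+[A-Za-z ]*", "", sc_line[1])
  num <- regmatches(stripped, regexpr("-?[0-9]+\\.?[0-9]*", stripped))
  if (length(num) == 0L)
    num <- regmatches(sc_line[1], regexpr("-?[0-9]+\\.?[0-9]*", sc_line[1]))
  if (length(num) == 0L) return(NA_real_)
  as.numeric(num[1])
}

# ---- PDB writing ----------------------------------------------------------

format_pdb_atom <- function(at) {
  name <- ifelse(nchar(at$name) < 4 & !grepl("^[0-9]", at$name),
                 paste0(" ", at$name), at$name)
  sprintf("ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          at$serial %% 100000L, substr(name, 1, 4), at$res_name,
          substr(at$chain, 1, 1), at$res_seq %% 10000L,
          ifelse(nzchar(at$ins), at$ins, " "),
          at$x, at$y, at$z, at$element)
}

#' Write structures and pose ensembles as PDB
#'
#' `write_structure()` writes one structure; `write_pose_ensemble()` writes a
#' multi-MODEL PDB with one `REMARK VINA RESULT` score line per model, the
#' same dialect [read_pose_ensemble] consumes, so written files round-trip.
#'
#' @param x a [structure3d] or [pose_ensemble].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  stopifnot(inherits(x, "structure3d"))
  writeLines(c(format_pdb_atom(x$atoms), "END"), path)
  invisible(path)
}

#' @rdname write_structure
#' @export
write_pose_ensemble <- function(x, path) {
  stopifnot(inherits(x, "pose_ensemble"))
  out <- character(0)
  for (k in seq_along(x$poses)) {
    p <- x$poses[[k]]
    out <- c(out,
             sprintf("MODEL %8d", k),
             sprintf("REMARK VINA RESULT: %8.3f      0.000      0.000", p$score),
             format_pdb_atom(p$atoms),
             "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

# ---- search boxes ---------------------------------------------------------

#' Generate docking search boxes centered on residue alpha-carbons
#'
#' Builds one cubic search box per requested (chain, residue), centered on
#' that residue's C-alpha. Used to tile the whole ectodomain of a trimeric
#' channel with overlapping boxes (e.g. 4 residues x 3 chains = 12 boxes of
#' side 35 Angstrom).
#'
#' @param structure a [structure3d].
#' @param residue_ids data.frame with columns `chain`, `res_seq` and
#'   optionally `res_name` (checked when present).
#' @param side cube side length in Angstrom (default 35).
#' @return data.frame with one row per box: `label`, `chain`, `res_seq`,
#'   `res_name`, `cx`, `cy`, `cz`, `side`.
#' @export
make_search_boxes <- function(structure, residue_ids, side = 35) {
  stopifnot(inherits(structure, "structure3d"))
  if (!is.data.frame(residue_ids))
    residue_ids <- as.data.frame(residue_ids)
  if (side <= 0) stop("box side length must be positive")
  at <- structure$atoms
  out <- vector("list", nrow(residue_ids))
  for (i in seq_len(nrow(residue_ids))) {
    ch <- residue_ids$chain[i]
    rs <- residue_ids$res_seq[i]
    sel <- at$chain == ch & at$res_seq == rs & at$name == "CA"
    if (!any(sel))
      stop(sprintf("residue %s%d has no CA atom in structure %s",
                   ch, rs, structure$id))
    rn <- at$res_name[which(sel)[1]]
    if (!is.null(residue_ids$res_name) && !is.na(residue_ids$res_name[i]) &&
        nzchar(residue_ids$res_name[i]) && residue_ids$res_name[i] != rn)
      stop(sprintf("residue %s%d is %s in the structure, not %s",
                   ch, rs, rn, residue_ids$res_name[i]))
    j <- which(sel)[1]
    out[[i]] <- data.frame(label = sprintf("%s%d_%s", ch, rs, rn),
                           chain = ch, res_seq = rs, res_name = rn,
                           cx = at$x[j], cy = at$y[j], cz = at$z[j],
                           side = side, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
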