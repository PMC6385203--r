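#' Consensus-selection parameters
#'
#' Parameters of the cross-peptide pose-selection procedure: poses of the
#' short peptide within `energy_window` kcal/mol of its best docking score
#' are kept, and retained only if the RMSD over the nine heavy atoms of the
#' Arg-Phe-amide (RFa) moiety to some pose of the longer peptide is strictly
#' below `rmsd_cutoff`.
#'
#' @param energy_window kcal/mol, > 0 (default 1.0).
#' @param rmsd_cutoff Angstrom, > 0 (default 1.0); strict inequality.
#' @return list of class `consensus_params`.
#' @export
consensus_params <- function(energy_window = 1.0, rmsd_cutoff = 1.0) {
  if (energy_window <= 0 || rmsd_cutoff <= 0)
    stop("energy_window and rmsd_cutoff must be positive")
  structure(list(energy_window = energy_window, rmsd_cutoff = rmsd_cutoff),
            class = "consensus_params")
}

# canonical atom order of the RFa frame
RFA_FRAME_ATOMS <- c("ARG N", "ARG CA", "ARG CG", "ARG CZ",
                     "PHE N", "PHE CA", "PHE CG", "PHE CZ", "NH2 N")

# accepted names for the C-terminal amide nitrogen (builder-dependent)
AMIDE_N_ALIASES <- c("NT", "NXT", "NH2")

#' Extract the Arg-Phe-amide (RFa) frame of a peptide pose
#'
#' RFamide peptides share a C-terminal Arg-Phe-NH2 motif. Pose similarity is
#' measured over nine heavy atoms of that moiety: backbone N and C-alpha plus
#' side-chain CG and CZ of the C-terminal-most Arg and Phe, and the
#' C-terminal amide nitrogen. The amide nitrogen may be named `NT`, `NXT` or
#' `NH2` (an `NH2` atom of an Arg side chain is never taken); atoms are
#' returned in a fixed canonical order so that correspondence is positional.
#'
#' @param pose a [docking_pose] of a peptide carrying the RFa motif.
#' @return 9 x 3 numeric matrix of coordinates (Angstrom), rows in canonical
#'   order, with attribute `source_pose` = the pose id.
#' @export
extract_rfa_frame <- function(pose) {
  stopifnot(inherits(pose, "docking_pose"))
  at <- pose$atoms
  rkey <- paste(at$chain, at$res_seq, at$ins, sep = "|")
  res_order <- unique(rkey)           # file order
  res_name <- at$res_name[match(res_order, rkey)]

  # locate the C-terminal amide nitrogen
  amide_idx <- NA_integer_
  # (a) explicit NT / NXT atom, C-terminal-most occurrence
  cand <- which(at$name %in% c("NT", "NXT"))
  # (b) an NH2-named nitrogen outside an Arg side chain (e.g. an NH2 cap
  #     residue written by some builders)
  cand2 <- which(at$name == "NH2" & at$res_name != "ARG")
  cand <- c(cand, cand2)
  if (length(cand)) amide_idx <- cand[length(cand)]
  if (is.na(amide_idx))
    stop("pose ", pose$pose_id,
         ": C-terminal amide nitrogen (NT/NXT/NH2) not found")

  # C-terminal-most Phe at or before the amide residue, preceded by an Arg
  phe_pos <- which(res_name == "PHE")
  amide_res_pos <- match(rkey[amide_idx], res_order)
  phe_pos <- phe_pos[phe_pos <= amide_res_pos]
  if (length(phe_pos) == 0L)
    stop("pose ", pose$pose_id, ": RFa motif absent (no Phe before amide)")
  phe_pos <- max(phe_pos)
  if (phe_pos < 2L || res_name[phe_pos - 1L] != "ARG")
    stop("pose ", pose$pose_id, ": RFa motif absent (Phe not preceded by Arg)")

  pick <- function(res_pos, atom_name) {
    i <- which(rkey == res_order[res_pos] & at$name == atom_name)
    if (length(i) == 0L)
      stop("pose ", pose$pose_id, ": missing atom ", atom_name,
           " in residue ", res_name[res_pos], sub("^[^|]*\\|", " ",
                                                  res_order[res_pos]))
    i[1]
  }
  idx <- c(vapply(c("N", "CA", "CG", "CZ"), pick, integer(1),
                  res_pos = phe_pos - 1L),
           vapply(c("N", "CA", "CG", "CZ"), pick, integer(1),
                  res_pos = phe_pos),
           amide_idx)
  m <- as.matrix(at[idx, c("x", "y", "z")])
  dimnames(m) <- list(RFA_FRAME_ATOMS, c("x", "y", "z"))
  if (!all(is.finite(m))) stop("RFa frame coordinates must be finite")
  attr(m, "source_pose") <- pose$pose_id
  m
}

#' RMSD between two RFa frames
#'
#' Plain root-mean-square deviation over the nine canonical atoms with
#' positional correspondence. No superposition is performed: both peptides
#' are docked to the same rigid receptor, so their poses already share a
#' coordinate frame, and fitting would alter the 1-Angstrom selection
#' criterion. For poses in different frames, superpose the receptors first
#' (see [superpose_transform]).
#'
#' @param a,b 9 x 3 frame matrices from [extract_rfa_frame].
#' @return RMSD in Angstrom.
#' @export
rfa_rmsd <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b),
            nrow(a) == 9L, nrow(b) == 9L, ncol(a) == 3L, ncol(b) == 3L)
  d <- a - b
  sqrt(mean(rowSums(d * d)))
}

#' Rigid superposition transform from receptor C-alpha atoms
#'
#' Least-squares (Kabsch) fit of the `mobile` receptor's C-alpha atoms onto
#' `target`'s, matched by (chain, residue). Returns a function that maps an
#' n x 3 coordinate matrix from the mobile frame into the target frame; apply
#' it to pose coordinates docked against `mobile` before cross-frame RMSDs.
#'
#' @param mobile,target [structure3d] receptors sharing residue numbering.
#' @return function(coords_matrix) -> transformed matrix.
#' @export
superpose_transform <- function(mobile, target) {
  ca_m <- mobile$atoms[mobile$atoms$name == "CA", ]
  ca_t <- target$atoms[target$atoms$name == "CA", ]
  key_m <- paste(ca_m$chain, ca_m$res_seq, ca_m$ins)
  key_t <- paste(ca_t$chain, ca_t$res_seq, ca_t$ins)
  common <- intersect(key_m, key_t)
  if (length(common) < 3L)
    stop("fewer than 3 common C-alpha atoms; cannot superpose")
  A <- as.matrix(ca_m[match(common, key_m), c("x", "y", "z")])
  B <- as.matrix(ca_t[match(common, key_t), c("x", "y", "z")])
  ca_A <- colMeans(A); ca_B <- colMeans(B)
  H <- crossprod(sweep(A, 2, ca_A), sweep(B, 2, ca_B))
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  function(coords) {
    stopifnot(is.matrix(coords), ncol(coords) == 3L)
    sweep(sweep(coords, 2, ca_A) %*% t(R), 2, ca_B, `+`)
  }
}

#' Filter a pose ensemble by energy window
#'
#' Retains poses whose docking score lies within `window` kcal/mol of the
#' best (most negative) score, inclusive; the best pose is always retained
#' and pose order is preserved.
#'
#' @param ensemble a [pose_ensemble].
#' @param window kcal/mol (default 1.0); `window = 0` keeps only poses tied
#'   with the best score.
#' @return a [pose_ensemble] containing the surviving poses.
#' @export
energy_window <- function(ensemble, window = 1.0) {
  stopifnot(inherits(ensemble, "pose_ensemble"))
  if (window < 0) stop("energy window must be non-negative")
  sc <- ensemble_scores(ensemble)
  keep <- sc <= min(sc) + window
  pose_ensemble(ensemble$peptide_name, ensemble$poses[keep],
                receptor_id = ensemble$receptor_id)
}

#' Cross-peptide consensus matching of docking poses
#'
#' Implements the selection rule used to find binding modes compatible with
#' both a short and a long RFamide peptide docked to the same rigid receptor:
#' every pose of `ens_a` surviving the energy window is compared, by RFa-frame
#' RMSD, against all poses of `ens_b`; a consensus match is reported for each
#' A-pose whose minimum RMSD is strictly below the cutoff, together with its
#' best partner. Ties are broken deterministically by (rmsd, then pose_b id).
#'
#' @param ens_a [pose_ensemble] of the peptide being selected (windowed).
#' @param ens_b [pose_ensemble] of the comparison peptide (all poses used by
#'   default).
#' @param params a [consensus_params] object.
#' @param window_b also apply the energy window to `ens_b` before matching
#'   (default `FALSE`; whether the original procedure windowed the long
#'   peptide is unstated, so this is exposed as an option).
#' @return data.frame with columns `pose_a`, `pose_b`, `rmsd`, `score_a`;
#'   zero rows when no pair qualifies.
#' @export
match_consensus <- function(ens_a, ens_b, params = consensus_params(),
                            window_b = FALSE) {
  stopifnot(inherits(ens_a, "pose_ensemble"), inherits(ens_b, "pose_ensemble"))
  if (!identical(ens_a$receptor_id, ens_b$receptor_id))
    stop("ensembles were docked to different receptors: ",
         ens_a$receptor_id, " vs ", ens_b$receptor_id)
  a_win <- energy_window(ens_a, params$energy_window)
  b_use <- if (window_b) energy_window(ens_b, params$energy_window) else ens_b
  frames_b <- lapply(b_use$poses, extract_rfa_frame)
  ids_b <- vapply(b_use$poses, `[[`, character(1), "pose_id")
  out <- list()
  for (p in a_win$poses) {
    fa <- extract_rfa_frame(p)
    rmsds <- vapply(frames_b, rfa_rmsd, numeric(1), a = fa)
    # deterministic tie-break: smallest rmsd, then lexicographic pose_b id
    ord <- order(rmsds, ids_b)
    best <- ord[1]
    if (rmsds[best] < params$rmsd_cutoff) {
      out[[length(out) + 1L]] <- data.frame(
        pose_a = p$pose_id, pose_b = ids_b[best],
        rmsd = rmsds[best], score_a = p$score,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(pose_a = character(0), pose_b = character(0),
                      rmsd = numeric(0), score_a = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$pose_a), , drop = FALSE]
}

#' Write consensus matches as TSV
#'
#' @param matches data.frame from [match_consensus]; a `pocket_label` column
#'   is appended as `NA` if absent.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matches_tsv <- function(matches, path) {
  if (is.null(matches$pocket_label))
    matches$pocket_label <- rep(NA_character_, nrow(matches))
  cols <- c("pose_a", "pose_b", "rmsd", "score_a", "pocket_label")
  write.table(matches[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' N-terminus orientation criterion
#'
#' Poses relevant for longer RFamide peptides must have the peptide
#' N-terminus pointing towards the pocket entrance. This is operationalized
#' on the cavity grid: the burial depth of an atom is the breadth-first path
#' length through solvent-accessible voxels from the atom's nearest
#' accessible voxel to bulk solvent, and the criterion holds when the
#' N-terminal amine nitrogen is no more buried than the C-terminal amide
#' nitrogen.
#'
#' @param pose a [docking_pose] with the RFa motif.
#' @param cavities result of [probe_accessible_cavities] computed on the same
#'   structure/frame (carries the grid).
#' @return `TRUE`/`FALSE`. Errors if the pose does not lie within any
#'   detected cavity (e.g. a pose floating in bulk solvent).
#' @export
nterm_orientation_ok <- function(pose, cavities) {
  stopifnot(inherits(pose, "docking_pose"))
  grid <- attr(cavities, "grid")
  if (is.null(grid))
    stop("`cavities` must come from probe_accessible_cavities()")
  lab <- assign_pose_pocket(pose, cavities)
  if (is.na(lab))
    stop("pose ", pose$pose_id,
         " is not within the margin of any cavity; orientation undefined")
  at <- pose$atoms
  rkey <- paste(at$chain, at$res_seq, at$ins, sep = "|")
  first_res <- rkey == rkey[1]
  i_nterm <- which(first_res & at$name == "N")
  if (length(i_nterm) == 0L)
    stop("pose ", pose$pose_id, ": no N-terminal backbone nitrogen")
  frame <- extract_rfa_frame(pose)
  p_nterm <- as.numeric(at[i_nterm[1], c("x", "y", "z")])
  p_amide <- frame["NH2 N", ]
  d_n <- atom_burial_depth(p_nterm, grid)
  d_c <- atom_burial_depth(p_amide, grid)
  d_n <= d_c
}

# burial depth (BFS steps to bulk) at the accessible voxel nearest to `p`
atom_burial_depth <- function(p, grid) {
  idx <- nearest_accessible_voxel(p, grid)
  if (is.na(idx))
    stop("no solvent-accessible voxel near atom; atom buried in protein")
  grid$depth[idx]
}

nearest_accessible_voxel <- function(p, grid, max_shells = 8L) {
  dims <- grid$dims
  i0 <- round((p - grid$origin) / grid$spacing) + 1
  i0 <- pmin(pmax(i0, 1), dims)
  for (shell in 0:max_shells) {
    rng <- lapply(1:3, function(k)
      max(1, i0[k] - shell):min(dims[k], i0[k] + shell))
    g <- as.matrix(expand.grid(ix = rng[[1]], iy = rng[[2]], iz = rng[[3]]))
    lin <- g[, 1] + dims[1] * ((g[, 2] - 1) + dims[2] * (g[, 3] - 1))
    acc <- grid$accessible[lin]
    if (any(acc)) {
      centers <- sweep(sweep(g - 1, 2, rep(grid$spacing, 3), `*`),
                       2, grid$origin, `+`)
      d2 <- rowSums(sweep(centers, 2, p)^2)
      d2[!acc] <- Inf
      return(lin[which.min(d2)])
    }
  }
  NA_integer_
}
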