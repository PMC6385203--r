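# Chemistry tables for interaction typing. Heavy-atom names follow PDB
# conventions; hydrogens are used only for hydrogen-bond angle checks when
# present (docking outputs often carry polar hydrogens only).

HB_DONORS <- list(
  backbone = "N",
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
  TRP = "NE1", ASN = "ND2", GLN = "NE2", SER = "OG", THR = "OG1",
  TYR = "OH", CYS = "SG", NH2 = "N")

HB_ACCEPTORS <- list(
  backbone = c("O", "OXT"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD")

# side-chain carbons counted as apolar (exclude carbons bonded to N/O)
APOLAR_EXCLUDE <- list(ARG = "CZ", ASP = "CG", GLU = "CD", ASN = "CG",
                       GLN = "CD", TYR = "CZ", HIS = c("CG", "CD2", "CE1"),
                       TRP = c("CD1", "CE2"))

RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))

CATION_ATOMS <- list(ARG = "CZ", LYS = "NZ")
POS_CHARGED <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ")
NEG_CHARGED <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Geometric criteria for interaction detection
#'
#' Distance/angle thresholds for the five interaction types. The literature
#' tools that draw such diagrams use slightly different stringencies, so all
#' thresholds are exposed here rather than hard-coded.
#'
#' @param hbond_dist donor-acceptor heavy-atom distance, Angstrom (3.5).
#' @param hbond_angle minimum D-H...A angle in degrees, applied only when a
#'   hydrogen is bonded to the donor (120).
#' @param hydrophobic_dist apolar C...C distance (4.0).
#' @param stacking_dist ring-centroid distance (5.0).
#' @param stacking_parallel_max max inter-plane angle for parallel stacking
#'   (30).
#' @param stacking_tshape_min,stacking_tshape_max inter-plane angle window
#'   for T-shaped stacking (60, 90).
#' @param cation_pi_dist cation (Arg CZ / Lys NZ) to ring centroid (6.0).
#' @param salt_bridge_dist opposite-charge heavy-atom distance (4.0).
#' @return list of class `interaction_criteria`.
#' @export
interaction_criteria <- function(hbond_dist = 3.5, hbond_angle = 120,
                                 hydrophobic_dist = 4.0, stacking_dist = 5.0,
                                 stacking_parallel_max = 30,
                                 stacking_tshape_min = 60,
                                 stacking_tshape_max = 90,
                                 cation_pi_dist = 6.0,
                                 salt_bridge_dist = 4.0) {
  structure(as.list(environment()), class = "interaction_criteria")
}

atom_roles <- function(atoms) {
  res <- atoms$res_name
  nm <- atoms$name
  donor <- nm %in% HB_DONORS$backbone
  acceptor <- nm %in% HB_ACCEPTORS$backbone
  apolar <- atoms$element == "C" & !(nm %in% c("C"))
  pos <- logical(nrow(atoms)); neg <- logical(nrow(atoms))
  cation <- logical(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    r <- res[i]
    if (!is.null(HB_DONORS[[r]]) && nm[i] %in% HB_DONORS[[r]]) donor[i] <- TRUE
    if (!is.null(HB_ACCEPTORS[[r]]) && nm[i] %in% HB_ACCEPTORS[[r]])
      acceptor[i] <- TRUE
    if (!is.null(APOLAR_EXCLUDE[[r]]) && nm[i] %in% APOLAR_EXCLUDE[[r]])
      apolar[i] <- FALSE
    if (!is.null(POS_CHARGED[[r]]) && nm[i] %in% POS_CHARGED[[r]]) pos[i] <- TRUE
    if (!is.null(NEG_CHARGED[[r]]) && nm[i] %in% NEG_CHARGED[[r]]) neg[i] <- TRUE
    if (!is.null(CATION_ATOMS[[r]]) && nm[i] %in% CATION_ATOMS[[r]])
      cation[i] <- TRUE
  }
  # C-terminal amide nitrogen donates
  donor <- donor | nm %in% c("NT", "NXT")
  hyd <- atoms$element %in% c("H", "D")
  apolar[hyd] <- FALSE
  list(donor = donor & !hyd, acceptor = acceptor & !hyd, apolar = apolar,
       pos = pos, neg = neg, cation = cation, hydrogen = hyd)
}

residue_rings <- function(atoms) {
  rkey <- paste(atoms$chain, atoms$res_seq, atoms$ins, sep = "|")
  out <- list()
  for (k in unique(rkey)) {
    sel <- which(rkey == k)
    r <- atoms$res_name[sel[1]]
    if (is.null(RING_ATOMS[[r]])) next
    ra <- sel[match(RING_ATOMS[[r]], atoms$name[sel])]
    if (anyNA(ra)) next
    m <- as.matrix(atoms[ra, c("x", "y", "z")])
    cen <- colMeans(m)
    sv <- svd(sweep(m, 2, cen))
    out[[length(out) + 1L]] <- list(
      res = atoms[sel[1], c("chain", "res_seq", "res_name")],
      id = sprintf("%s:%s%d", atoms$chain[sel[1]], r, atoms$res_seq[sel[1]]),
      centroid = cen, normal = sv$v[, 3])
  }
  out
}

ang_deg <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  acos(pmin(1, pmax(-1, abs(cosang)))) * 180 / pi  # plane angles: 0..90
}

#' Detect protein-peptide interactions
#'
#' Computes a typed interaction fingerprint between a docked peptide pose and
#' a receptor structure sharing its frame: hydrogen bonds, hydrophobic
#' contacts, aromatic stacking (parallel or T-shaped), cation-pi contacts and
#' salt bridges, under the geometric criteria of [interaction_criteria]. One
#' interaction is reported per (peptide atom or ring, receptor residue, kind),
#' keeping the shortest distance. The result is deterministic for fixed
#' inputs and criteria, and invariant under global rigid motion of the
#' complex.
#'
#' @param pose a [docking_pose].
#' @param structure receptor [structure3d] in the same frame.
#' @param criteria an [interaction_criteria] object.
#' @return object of class `interaction_fingerprint`: list with `pose_id` and
#'   `interactions`, a data.frame with columns `kind`, `peptide_atom`,
#'   `peptide_res`, `chain`, `res_seq`, `res_name`, `distance`, `angle`.
#' @export
detect_interactions <- function(pose, structure,
                                criteria = interaction_criteria()) {
  stopifnot(inherits(pose, "docking_pose"), inherits(structure, "structure3d"))
  pa <- pose$atoms
  ra <- structure$atoms
  proles <- atom_roles(pa)
  rroles <- atom_roles(ra)
  pxyz <- as.matrix(pa[, c("x", "y", "z")])
  rxyz <- as.matrix(ra[, c("x", "y", "z")])

  # pairwise distances, peptide x receptor, pruned to the largest cutoff
  maxcut <- max(criteria$hbond_dist, criteria$hydrophobic_dist,
                criteria$salt_bridge_dist)
  d2 <- outer(rowSums(pxyz^2), rowSums(rxyz^2), `+`) - 2 * pxyz %*% t(rxyz)
  d2[d2 < 0] <- 0
  dm <- sqrt(d2)

  rows <- list()
  add <- function(kind, pi_, ri_, dist, angle = NA_real_,
                  patom = NULL) {
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind,
      peptide_atom = if (is.null(patom))
        sprintf("%s%d:%s", pa$res_name[pi_], pa$res_seq[pi_], pa$name[pi_])
      else patom,
      peptide_res = if (is.null(patom))
        sprintf("%s%d", pa$res_name[pi_], pa$res_seq[pi_])
      else sub(":ring$", "", patom),
      chain = ra$chain[ri_], res_seq = ra$res_seq[ri_],
      res_name = ra$res_name[ri_],
      distance = dist, angle = angle, stringsAsFactors = FALSE)
  }

  hb_angle_ok <- function(don_xyz, don_i, don_atoms, acc_xyz, minang) {
    # TRUE if no H on the donor, else any D-H...A angle >= minang
    axyz <- as.matrix(don_atoms[, c("x", "y", "z")])
    hsel <- which(don_atoms$element %in% c("H", "D"))
    if (length(hsel) == 0L) return(list(ok = TRUE, angle = NA_real_))
    dh <- sqrt(rowSums(sweep(axyz[hsel, , drop = FALSE], 2, don_xyz)^2))
    hsel <- hsel[dh <= 1.25]
    if (length(hsel) == 0L) return(list(ok = TRUE, angle = NA_real_))
    best <- -Inf
    for (h in hsel) {
      hv <- as.numeric(axyz[h, ])
      v1 <- don_xyz - hv; v2 <- acc_xyz - hv
      a <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                               sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (a > best) best <- a
    }
    list(ok = best >= minang, angle = best)
  }

  # hydrogen bonds (both directions)
  for (dirn in 1:2) {
    if (dirn == 1) { di <- which(proles$donor); ai <- which(rroles$acceptor) }
    else { di <- which(rroles$donor); ai <- which(proles$acceptor) }
    for (d in di) for (a in ai) {
      dist <- if (dirn == 1) dm[d, a] else dm[a, d]
      if (dist > criteria$hbond_dist || dist < 1e-6) next
      if (dirn == 1) {
        chk <- hb_angle_ok(as.numeric(pxyz[d, ]), d, pa,
                           as.numeric(rxyz[a, ]), criteria$hbond_angle)
        if (chk$ok) add("hbond", d, a, dist, chk$angle)
      } else {
        chk <- hb_angle_ok(as.numeric(rxyz[d, ]), d, ra,
                           as.numeric(pxyz[a, ]), criteria$hbond_angle)
        if (chk$ok) add("hbond", a, d, dist, chk$angle)
      }
    }
  }

  # hydrophobic contacts
  pi_ <- which(proles$apolar); ri_ <- which(rroles$apolar)
  if (length(pi_) && length(ri_)) {
    sub <- dm[pi_, ri_, drop = FALSE] <= criteria$hydrophobic_dist
    hits <- which(sub, arr.ind = TRUE)
    for (k in seq_len(nrow(hits)))
      add("hydrophobic", pi_[hits[k, 1]], ri_[hits[k, 2]],
          dm[pi_[hits[k, 1]], ri_[hits[k, 2]]])
  }

  # salt bridges
  for (sgn in 1:2) {
    if (sgn == 1) { pi_ <- which(proles$pos); ri_ <- which(rroles$neg) }
    else { pi_ <- which(proles$neg); ri_ <- which(rroles$pos) }
    for (p in pi_) for (r in ri_)
      if (dm[p, r] <= criteria$salt_bridge_dist)
        add("salt_bridge", p, r, dm[p, r])
  }

  # rings
  prings <- residue_rings(pa)
  rrings <- residue_rings(ra)
  for (pr in prings) for (rr in rrings) {
    dist <- sqrt(sum((pr$centroid - rr$centroid)^2))
    if (dist > criteria$stacking_dist) next
    a <- ang_deg(pr$normal, rr$normal)
    if (a <= criteria$stacking_parallel_max ||
        (a >= criteria$stacking_tshape_min && a <= criteria$stacking_tshape_max)) {
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "stacking", peptide_atom = paste0(pr$id, ":ring"),
        peptide_res = pr$id, chain = rr$res$chain, res_seq = rr$res$res_seq,
        res_name = rr$res$res_name, distance = dist, angle = a,
        stringsAsFactors = FALSE)
    }
  }

  # cation-pi: peptide cation vs receptor ring and vice versa
  pcat <- which(proles$cation)
  rcat <- which(rroles$cation)
  for (p in pcat) for (rr in rrings) {
    dist <- sqrt(sum((as.numeric(pxyz[p, ]) - rr$centroid)^2))
    if (dist <= criteria$cation_pi_dist)
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "cation_pi",
        peptide_atom = sprintf("%s%d:%s", pa$res_name[p], pa$res_seq[p],
                               pa$name[p]),
        peptide_res = sprintf("%s%d", pa$res_name[p], pa$res_seq[p]),
        chain = rr$res$chain, res_seq = rr$res$res_seq,
        res_name = rr$res$res_name, distance = dist, angle = NA_real_,
        stringsAsFactors = FALSE)
  }
  for (pr in prings) for (r in rcat) {
    dist <- sqrt(sum((pr$centroid - as.numeric(rxyz[r, ]))^2))
    if (dist <= criteria$cation_pi_dist)
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "cation_pi", peptide_atom = paste0(pr$id, ":ring"),
        peptide_res = pr$id, chain = ra$chain[r], res_seq = ra$res_seq[r],
        res_name = ra$res_name[r], distance = dist, angle = NA_real_,
        stringsAsFactors = FALSE)
  }

  if (length(rows) == 0L) {
    tab <- data.frame(kind = character(0), peptide_atom = character(0),
                      peptide_res = character(0), chain = character(0),
                      res_seq = integer(0), res_name = character(0),
                      distance = numeric(0), angle = numeric(0),
                      stringsAsFactors = FALSE)
  } else {
    tab <- do.call(rbind, rows)
    # one interaction per (peptide atom/ring, receptor residue, kind)
    key <- paste(tab$kind, tab$peptide_atom, tab$chain, tab$res_seq)
    tab <- tab[order(key, tab$distance), ]
    tab <- tab[!duplicated(paste(tab$kind, tab$peptide_atom, tab$chain,
                                 tab$res_seq)), ]
    tab <- tab[order(tab$kind, tab$res_seq, tab$peptide_atom), ]
    rownames(tab) <- NULL
  }
  structure(list(pose_id = pose$pose_id, interactions = tab),
            class = "interaction_fingerprint")
}

#' @export
print.interaction_fingerprint <- function(x, ...) {
  cat(sprintf("<interaction_fingerprint> pose %s: %d interactions\n",
              x$pose_id, nrow(x$interactions)))
  if (nrow(x$interactions)) print(table(x$interactions$kind))
  invisible(x)
}

#' Write interaction fingerprints as TSV
#'
#' @param fps a single `interaction_fingerprint` or a list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fingerprints_tsv <- function(fps, path) {
  if (inherits(fps, "interaction_fingerprint")) fps <- list(fps)
  tabs <- lapply(fps, function(f) {
    if (nrow(f$interactions) == 0L) return(NULL)
    cbind(pose = f$pose_id, f$interactions)
  })
  tabs <- tabs[!vapply(tabs, is.null, logical(1))]
  out <- if (length(tabs)) do.call(rbind, tabs) else
    data.frame(pose = character(0), kind = character(0),
               peptide_atom = character(0), peptide_res = character(0),
               chain = character(0), res_seq = integer(0),
               res_name = character(0), distance = numeric(0),
               angle = numeric(0))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
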