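#' Grid specification for cavity detection
#'
#' Parameters of the voxel-grid cavity detector. Cavity volumes are
#' probe-accessible volumes: a voxel is occupied when its center lies within
#' (van der Waals radius + `probe_radius`) of any heavy atom. The standard
#' water-sized probe is 1.4 Angstrom; a coarser probe (e.g. 2.0) merges less
#' and can separate cavities that are connected at 1.4. `seal_probe_radius`
#' is the larger probe used only to close pocket mouths so that open pockets
#' can be reported at all (see [probe_accessible_cavities]).
#'
#' @param spacing voxel edge length, Angstrom (default 0.5).
#' @param probe_radius solvent probe radius, Angstrom (default 1.4).
#' @param padding empty margin added around the structure (default 4.0).
#' @param seal_probe_radius mouth-sealing probe radius (default 4.0).
#' @param radii_table named vector of van der Waals radii per element;
#'   defaults C 1.70, N 1.55, O 1.52, S 1.80 (Bondi-style, united-atom:
#'   hydrogens are ignored).
#' @param default_radius radius for elements absent from the table.
#' @param max_voxels voxel budget guard; exceeding it is an error advising a
#'   coarser spacing.
#' @param min_volume smallest cavity volume reported, Angstrom^3 (default
#'   25, about two water volumes); suppresses sub-probe-scale surface
#'   dimples that the two-probe scheme can otherwise pick up.
#' @return list of class `grid_spec`.
#' @export
grid_spec <- function(spacing = 0.5, probe_radius = 1.4, padding = 4.0,
                      seal_probe_radius = 4.0,
                      radii_table = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80),
                      default_radius = 1.70, max_voxels = 6e7,
                      min_volume = 25) {
  if (spacing <= 0) stop("grid spacing must be positive")
  if (probe_radius < 0) stop("probe radius must be non-negative")
  structure(list(spacing = spacing, probe_radius = probe_radius,
                 padding = padding, seal_probe_radius = seal_probe_radius,
                 radii_table = radii_table, default_radius = default_radius,
                 max_voxels = max_voxels, min_volume = min_volume),
            class = "grid_spec")
}

heavy_atoms <- function(atoms) {
  atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
}

atom_radii <- function(atoms, spec) {
  r <- spec$radii_table[atoms$element]
  r[is.na(r)] <- spec$default_radius
  as.numeric(r)
}

#' Detect probe-accessible cavities and their volumes
#'
#' Grid approximation of probe-accessible cavity volumes (a stand-in for
#' alpha-shape pocket software; reported volumes are approximations, in line
#' with the "~" precision such volumes are usually quoted at). The
#' algorithm:
#' \enumerate{
#'   \item lay a rectilinear grid with `padding` around the heavy atoms;
#'   \item mark voxels occupied within (vdW + `probe_radius`) of any atom;
#'   \item flood-fill unoccupied voxels from the grid boundary
#'     (6-connectivity, so diagonal leaks through occupied walls are
#'     impossible) = bulk solvent;
#'   \item additionally flood-fill with occupancy inflated to
#'     `seal_probe_radius`; the larger probe cannot pass pocket mouths, so
#'     accessible voxels that it cannot reach, and that lie deeper than the
#'     surface skin it leaves, are pocket voxels even when a path to bulk
#'     exists for the small probe;
#'   \item connected components (26-connectivity) of the pocket voxels are
#'     the reported regions; `sealed` is `TRUE` when the small probe has no
#'     path from the region to bulk. The raw estimate voxel_count x spacing^3
#'     (column `volume_voxel`) carries an origin-dependent lattice
#'     oscillation, so the headline `volume` column antialiases wall-facing
#'     voxels with 64 scrambled quasi-random sub-points per voxel, which
#'     makes the volume converge smoothly as the spacing shrinks.
#' }
#' Lining residues are heavy atoms within (vdW + probe + spacing) of any
#' region voxel. The returned object carries the full grid (occupancy, bulk,
#' labels and a breadth-first burial-depth map) as attribute `"grid"` for
#' downstream pose assignment and orientation filtering.
#'
#' @param structure a [structure3d]; must contain at least one heavy atom.
#' @param spec a [grid_spec].
#' @param landmarks optional named list of landmark residue sets used to name
#'   regions (see [label_pockets]).
#' @return data.frame with one row per cavity: `label`, `voxel_count`,
#'   `volume` (antialiased, Angstrom^3), `volume_voxel` (raw voxel count x
#'   spacing^3), `cx`, `cy`, `cz` (centroid), `sealed`; attribute
#'   `lining` is a list of per-region lining-residue data.frames and
#'   attribute `grid` the voxel grid. Rows are sorted by decreasing volume.
#' @export
probe_accessible_cavities <- function(structure, spec = grid_spec(),
                                      landmarks = NULL) {
  stopifnot(inherits(structure, "structure3d"), inherits(spec, "grid_spec"))
  at <- heavy_atoms(structure$atoms)
  if (nrow(at) == 0L) stop("structure contains no heavy atoms")
  coords <- as.matrix(at[, c("x", "y", "z")])
  radii <- atom_radii(at, spec)

  lo <- apply(coords, 2, min) - spec$padding
  hi <- apply(coords, 2, max) + spec$padding
  dims <- as.integer(ceiling((hi - lo) / spec$spacing)) + 1L
  if (prod(as.numeric(dims)) > spec$max_voxels)
    stop(sprintf(paste0("grid of %d x %d x %d voxels exceeds the budget ",
                        "(%g); use a coarser spacing"),
                 dims[1], dims[2], dims[3], spec$max_voxels))
  origin <- lo

  occ <- grid_occupancy_cpp(coords, radii + spec$probe_radius,
                            origin, spec$spacing, dims)
  accessible <- !occ
  bulk_small <- grid_flood_bulk_cpp(occ, dims)
  occ_large <- grid_occupancy_cpp(coords, radii + spec$seal_probe_radius,
                                  origin, spec$spacing, dims)
  bulk_large <- grid_flood_bulk_cpp(occ_large, dims)

  # burial depth: BFS steps from large-probe bulk through accessible space
  depth <- grid_bfs_depth_cpp(accessible, bulk_large & accessible, dims)

  # surface skin left between the two probes; anything deeper is pocket
  skin_steps <- ceiling((spec$seal_probe_radius - spec$probe_radius) /
                          spec$spacing) + 1L
  pocketvox <- accessible & (depth < 0L | depth > skin_steps)
  labels <- grid_label_components_cpp(pocketvox, dims)
  nlab <- max(labels)

  # drop regions below the minimum reportable volume (surface dimples)
  if (nlab > 0L && spec$min_volume > 0) {
    vc0 <- tabulate(labels[labels > 0L], nbins = nlab)
    keep <- vc0 * spec$spacing^3 >= spec$min_volume
    remap <- integer(nlab)
    remap[keep] <- seq_len(sum(keep))
    labels[labels > 0L] <- remap[labels[labels > 0L]]
    nlab <- sum(keep)
  }

  if (nlab == 0L) {
    out <- data.frame(label = character(0), voxel_count = integer(0),
                      volume = numeric(0), volume_voxel = numeric(0),
                      cx = numeric(0), cy = numeric(0),
                      cz = numeric(0), sealed = logical(0),
                      stringsAsFactors = FALSE)
    attr(out, "lining") <- list()
    attr(out, "grid") <- list(dims = dims, origin = origin,
                              spacing = spec$spacing, accessible = accessible,
                              occupied = occ, labels = labels, depth = depth,
                              bulk = accessible & labels == 0L)
    return(out)
  }

  vc <- tabulate(labels[labels > 0L], nbins = nlab)
  sealed <- !as.logical(tapply(bulk_small[labels > 0L], labels[labels > 0L],
                               any))

  # antialiased volumes: voxels facing an occupied wall are weighted by the
  # unoccupied fraction of 64 scrambled sub-points, which suppresses the
  # origin-dependent lattice oscillation of plain voxel counting
  lin0 <- which(labels > 0L) - 1L
  izb <- lin0 %/% (dims[1] * dims[2])
  iyb <- (lin0 %/% dims[1]) %% dims[2]
  ixb <- lin0 %% dims[1]
  wall <- rep(FALSE, length(lin0))        # region voxels touching a wall
  outer_lab <- integer(0)                 # occupied voxels touching a region
  outer_lin <- integer(0)
  dirs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  dirs <- dirs[!(dirs$dx == 0 & dirs$dy == 0 & dirs$dz == 0), ]
  for (di in seq_len(nrow(dirs))) {
    d <- as.integer(dirs[di, ])
    jx <- ixb + d[1]; jy <- iyb + d[2]; jz <- izb + d[3]
    inb <- jx >= 0L & jx < dims[1] & jy >= 0L & jy < dims[2] &
      jz >= 0L & jz < dims[3]
    nl <- jx[inb] + dims[1] * (jy[inb] + dims[2] * jz[inb]) + 1L
    hit <- occ[nl]
    w <- wall[inb]
    w[hit] <- TRUE
    wall[inb] <- w
    outer_lin <- c(outer_lin, nl[hit] - 1L)
    outer_lab <- c(outer_lab, labels[lin0[inb] + 1L][hit])
  }
  keep1 <- !duplicated(outer_lin)         # first region wins, deterministic
  outer_lin <- outer_lin[keep1]
  outer_lab <- outer_lab[keep1]
  bvox <- c(lin0[wall], outer_lin)
  labf <- c(labels[lin0[wall] + 1L], outer_lab)
  vol_ref <- vc * spec$spacing^3
  if (length(bvox)) {
    frac <- grid_boundary_fractions_cpp(coords, radii + spec$probe_radius,
                                        origin, spec$spacing, dims, bvox)
    # inner wall voxels: full cell replaced by unoccupied fraction;
    # outer (occupied-center) voxels: their unoccupied corners are added
    delta <- c(frac[seq_len(sum(wall))] - 1,
               frac[seq_len(length(outer_lin)) + sum(wall)])
    adj <- tapply(delta, labf, sum)
    vol_ref[as.integer(names(adj))] <- vol_ref[as.integer(names(adj))] +
      as.numeric(adj) * spec$spacing^3
  }

  # centroids
  lin <- which(labels > 0L)
  iz <- (lin - 1L) %/% (dims[1] * dims[2])
  iy <- ((lin - 1L) %/% dims[1]) %% dims[2]
  ix <- (lin - 1L) %% dims[1]
  cx <- tapply(origin[1] + ix * spec$spacing, labels[lin], mean)
  cy <- tapply(origin[2] + iy * spec$spacing, labels[lin], mean)
  cz <- tapply(origin[3] + iz * spec$spacing, labels[lin], mean)

  # lining residues: heavy atoms near any region voxel
  cutoffs <- radii + spec$probe_radius + spec$spacing
  mind <- grid_atom_label_mindist_cpp(coords, labels, nlab, origin,
                                      spec$spacing, dims, max(cutoffs))
  lining <- lapply(seq_len(nlab), function(l) {
    sel <- mind[, l] <= cutoffs
    res <- unique(at[sel, c("chain", "res_seq", "res_name")])
    res[order(res$chain, res$res_seq), , drop = FALSE]
  })

  out <- data.frame(label = sprintf("cavity_%d", seq_len(nlab)),
                    voxel_count = vc,
                    volume = vol_ref,
                    volume_voxel = vc * spec$spacing^3,
                    cx = as.numeric(cx), cy = as.numeric(cy),
                    cz = as.numeric(cz),
                    sealed = as.logical(sealed), stringsAsFactors = FALSE)
  ord <- order(-out$volume, out$label)
  out <- out[ord, , drop = FALSE]
  lining <- lining[ord]
  # relabel in reported order, keep voxel labels consistent
  relab <- integer(nlab)
  relab[ord] <- seq_len(nlab)
  labels[labels > 0L] <- relab[labels[labels > 0L]]
  out$label <- sprintf("cavity_%d", seq_len(nlab))
  rownames(out) <- NULL
  names(lining) <- out$label
  attr(out, "lining") <- lining
  attr(out, "grid") <- list(dims = dims, origin = origin,
                            spacing = spec$spacing, accessible = accessible,
                            occupied = occ, labels = labels, depth = depth,
                            bulk = accessible & labels == 0L)
  if (!is.null(landmarks)) out <- label_pockets(out, landmarks)
  out
}

#' Name cavities after landmark residue sets
#'
#' Attaches field names (e.g. `acidic_pocket`, `thumb_base`,
#' `central_vestibule`, `side_cavity`) to detected cavity regions by matching
#' their lining residues against user-supplied landmark sets. Each region is
#' renamed after the landmark set with which its lining shares the most
#' residues (at least one); ties are broken by landmark order, and several
#' regions may map to the same landmark (suffixed `_2`, `_3`, ...).
#'
#' @param cavities result of [probe_accessible_cavities].
#' @param landmarks named list; each element a character vector of residues
#'   as one-letter code + residue number, e.g. `c("D237", "E242", "D347")`
#'   (any chain matches). A default set for human ASIC1a numbering is shipped
#'   in `system.file("extdata", "landmarks_asic1a.json", package =
#'   "rfasite")`.
#' @return `cavities` with labels replaced where a landmark matched.
#' @export
label_pockets <- function(cavities, landmarks) {
  if (is.character(landmarks) && length(landmarks) == 1L)
    landmarks <- jsonlite::read_json(landmarks, simplifyVector = TRUE)
  lining <- attr(cavities, "lining")
  used <- integer(length(landmarks))
  labs <- cavities$label
  for (i in seq_len(nrow(cavities))) {
    res <- lining[[i]]
    code <- paste0(AA1[res$res_name], res$res_seq)
    hits <- vapply(landmarks, function(lm) sum(lm %in% code), integer(1))
    if (any(hits > 0L)) {
      j <- which.max(hits)
      used[j] <- used[j] + 1L
      labs[i] <- if (used[j] == 1L) names(landmarks)[j] else
        sprintf("%s_%d", names(landmarks)[j], used[j])
    }
  }
  g <- attr(cavities, "grid")
  cavities$label <- labs
  names(lining) <- labs
  attr(cavities, "lining") <- lining
  attr(cavities, "grid") <- g
  cavities
}

AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")
AA3 <- setNames(names(AA1), AA1)

#' Assign a docking pose to a cavity
#'
#' A pose belongs to the cavity containing the largest number of its heavy
#' atoms within `cutoff` of a cavity voxel center; it is unassigned
#' (`NA`) when that count is below `min_frac` of its heavy atoms. Ties are
#' broken by larger cavity volume, then label order.
#'
#' @param pose a [docking_pose] in the same frame as the cavities.
#' @param cavities result of [probe_accessible_cavities].
#' @param cutoff atom-to-voxel-center distance, Angstrom (default 2.0).
#' @param min_frac minimum assigned fraction of heavy atoms (default 0.25).
#' @return the cavity label, or `NA_character_` if unassigned.
#' @export
assign_pose_pocket <- function(pose, cavities, cutoff = 2.0,
                               min_frac = 0.25) {
  stopifnot(inherits(pose, "docking_pose"))
  if (nrow(cavities) == 0L) stop("empty cavity list")
  g <- attr(cavities, "grid")
  if (is.null(g)) stop("`cavities` must come from probe_accessible_cavities()")
  at <- heavy_atoms(pose$atoms)
  coords <- as.matrix(at[, c("x", "y", "z")])
  nlab <- nrow(cavities)
  counts <- grid_atom_label_counts_cpp(coords, g$labels, nlab, g$origin,
                                       g$spacing, g$dims, cutoff)
  in_cav <- colSums(counts > 0L)   # atoms with >=1 voxel of that cavity nearby
  if (max(in_cav) < min_frac * nrow(at)) return(NA_character_)
  ord <- order(-in_cav, -cavities$volume, cavities$label)
  cavities$label[ord[1]]
}

#' Write a cavity report as TSV
#'
#' One row per region: label, volume, sealed flag and the lining residues as
#' a comma-separated list.
#'
#' @param cavities result of [probe_accessible_cavities].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cavities_tsv <- function(cavities, path) {
  lining <- attr(cavities, "lining")
  lin_str <- vapply(seq_len(nrow(cavities)), function(i) {
    r <- lining[[i]]
    paste(sprintf("%s:%s%d", r$chain, r$res_name, r$res_seq), collapse = ",")
  }, character(1))
  df <- data.frame(label = cavities$label,
                   volume_A3 = cavities$volume,
                   sealed = cavities$sealed,
                   lining_residues = lin_str, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
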