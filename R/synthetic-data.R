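# ---- peptide templates ----------------------------------------------------

# Idealized per-residue heavy-atom geometry (bond lengths roughly standard;
# chemistry realism is not a goal: templates only need correct atom names
# and topology for RFa-frame extraction and interaction typing).
SIDE_CHAINS <- list(
  PHE = list(CB = c(-0.5, 1.3, 0.6), CG = c(-0.5, 2.6, 1.2),
             CD1 = c(-1.6, 3.3, 1.6), CD2 = c(0.7, 3.2, 1.4),
             CE1 = c(-1.6, 4.6, 2.2), CE2 = c(0.7, 4.5, 2.0),
             CZ = c(-0.4, 5.2, 2.4)),
  ARG = list(CB = c(-0.5, 1.3, 0.6), CG = c(-0.5, 2.7, 1.1),
             CD = c(-1.2, 3.7, 0.3), NE = c(-1.2, 5.0, 0.9),
             CZ = c(-1.8, 6.1, 0.4), NH1 = c(-2.4, 6.1, -0.8),
             NH2 = c(-1.8, 7.2, 1.1)),
  LYS = list(CB = c(-0.5, 1.3, 0.6), CG = c(-0.5, 2.7, 1.1),
             CD = c(-1.2, 3.7, 0.3), CE = c(-1.2, 5.1, 0.8),
             NZ = c(-1.9, 6.0, 0.0)),
  ASN = list(CB = c(-0.5, 1.3, 0.6), CG = c(-0.5, 2.7, 1.1),
             OD1 = c(-1.5, 3.4, 1.0), ND2 = c(0.6, 3.3, 1.6)),
  LEU = list(CB = c(-0.5, 1.3, 0.6), CG = c(-0.5, 2.7, 1.1),
             CD1 = c(-1.7, 3.4, 0.6), CD2 = c(0.8, 3.4, 0.8)))

#' Build an idealized peptide template
#'
#' Constructs an extended-chain peptide with standard atom names from a
#' one-letter sequence, optionally C-terminally amidated (atom `NT` on the
#' last residue). Geometry is idealized; these templates exist so that
#' docking-pose generators produce inputs that satisfy the RFa-motif and
#' interaction-typing conventions.
#'
#' @param sequence one-letter amino-acid string, e.g. `"FRRF"`.
#' @param amidated append the C-terminal amide nitrogen (default TRUE).
#' @param chain chain identifier.
#' @return atom data.frame as used by [docking_pose].
#' @export
build_peptide_template <- function(sequence, amidated = TRUE, chain = "P") {
  aa <- strsplit(sequence, "")[[1]]
  if (!all(aa %in% names(AA3))) stop("unknown residue in sequence")
  rows <- list()
  serial <- 0L
  addat <- function(name, res_name, res_seq, xyz) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = serial, name = name,
      element = substr(sub("^[0-9]", "", name), 1, 1),
      res_name = res_name, res_seq = res_seq, ins = "", chain = chain,
      x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
  }
  for (r in seq_along(aa)) {
    res <- AA3[aa[r]]
    o <- c((r - 1) * 3.8, 0, 0)
    addat("N", res, r, o + c(0.0, 0.0, 0.0))
    addat("CA", res, r, o + c(1.46, 0.0, 0.0))
    addat("C", res, r, o + c(2.2, 1.2, 0.0))
    addat("O", res, r, o + c(1.8, 2.35, 0.0))
    sc <- SIDE_CHAINS[[res]]
    if (!is.null(sc))
      for (nm in names(sc)) addat(nm, res, r, o + c(1.46, 0, 0) + sc[[nm]])
  }
  if (amidated) {
    r <- length(aa)
    o <- c((r - 1) * 3.8, 0, 0)
    addat("NT", AA3[aa[r]], r, o + c(3.55, 1.3, 0.0))
  }
  do.call(rbind, rows)
}

random_rotation <- function() {
  # uniform rotation from a normalized quaternion
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

transform_atoms <- function(atoms, R, shift) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, shift, `+`)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

#' Specification for the docking-pose generator
#'
#' Describes a synthetic pair of docking ensembles: a short RFa peptide
#' ("A", FRRFa-like 4-mer) and a longer one ("B", KNFLRFa-like 6-mer), both
#' placed rigidly in a bounded box around a common receptor frame. Exactly
#' `n_planted` A-poses carry an RFa frame at `planted_rmsd` of some B-pose;
#' all other cross-peptide frame pairs are kept at least `decoy_margin`
#' apart by rejection sampling, so the planted truth table is exact.
#'
#' @param seed RNG seed.
#' @param n_decoys_a,n_decoys_b decoy pose counts.
#' @param n_planted number of planted consensus pairs.
#' @param planted_rmsd Angstrom, must be below any sensible cutoff (< 1).
#' @param decoy_margin Angstrom, minimal decoy frame separation (> cutoff).
#' @param score_range kcal/mol range (best, worst) for decoy scores.
#' @param box half-width of the placement box, Angstrom.
#' @param max_retries rejection-sampling cap per decoy.
#' @param planted_center optional 3-vector: center the planted placements
#'   here (e.g. a known cavity centroid) instead of anywhere in the box.
#' @param planted_spread half-width of the planted placement region around
#'   `planted_center`, Angstrom.
#' @return list of class `pose_gen_spec`.
#' @export
pose_gen_spec <- function(seed = 1, n_decoys_a = 50, n_decoys_b = 50,
                          n_planted = 3, planted_rmsd = 0.5,
                          decoy_margin = 2.5, score_range = c(-9, -4),
                          box = 25, max_retries = 500,
                          planted_center = NULL, planted_spread = 2) {
  if (planted_rmsd >= decoy_margin)
    stop("planted_rmsd must be smaller than decoy_margin")
  structure(list(seed = seed, n_decoys_a = n_decoys_a,
                 n_decoys_b = n_decoys_b, n_planted = n_planted,
                 planted_rmsd = planted_rmsd, decoy_margin = decoy_margin,
                 score_range = score_range, box = box,
                 max_retries = max_retries, planted_center = planted_center,
                 planted_spread = planted_spread),
            class = "pose_gen_spec")
}

#' Generate a pair of docking ensembles with planted consensus matches
#'
#' Produces FRRFa-like and KNFLRFa-like pose ensembles in a common receptor
#' frame together with the exact truth table of planted cross-peptide
#' matches. Planted A-poses score inside the default 1 kcal/mol energy
#' window of the best pose; decoys are spread over `score_range`. Planted
#' B-poses are the corresponding A placements shifted by a random vector of
#' length `planted_rmsd`, so the pairwise frame RMSD is exactly that value
#' (a translation moves every frame atom equally). Deterministic given the
#' spec.
#'
#' @param spec a [pose_gen_spec].
#' @return list with `ens_a`, `ens_b` ([pose_ensemble]s) and `truth`, a
#'   data.frame of planted pairs (`pose_a`, `pose_b`, `rmsd`).
#' @export
gen_pose_ensembles <- function(spec = pose_gen_spec()) {
  stopifnot(inherits(spec, "pose_gen_spec"))
  with_seed(spec$seed, {
    tmpl_a <- build_peptide_template("FRRF")
    tmpl_b <- build_peptide_template("KNFLRF")
    frame_local_a <- extract_rfa_frame(docking_pose(tmpl_a, -1, "tmplA"))
    frame_local_b <- extract_rfa_frame(docking_pose(tmpl_b, -1, "tmplB"))
    # align B's local RFa frame onto A's (the templates are congruent up to a
    # chain-offset translation)
    d_ab <- colMeans(frame_local_b) - colMeans(frame_local_a)
    if (max(abs(sweep(frame_local_b, 2, d_ab) - frame_local_a)) > 1e-9)
      stop("internal: template RFa frames are not translation-congruent")

    n_a <- spec$n_decoys_a + spec$n_planted
    n_b <- spec$n_decoys_b + spec$n_planted
    if (spec$n_planted > 0 && spec$box^3 < 10 * (n_a + n_b) *
        (spec$decoy_margin / 2)^3)
      stop("infeasible spec: placement box too small for the decoy margin")

    place <- function(planted = FALSE) {
      if (planted && !is.null(spec$planted_center))
        list(R = random_rotation(),
             c = spec$planted_center + runif(3, -spec$planted_spread,
                                             spec$planted_spread))
      else list(R = random_rotation(), c = runif(3, -spec$box, spec$box))
    }
    frame_of <- function(tr, local_frame, off = c(0, 0, 0)) {
      sweep((local_frame %*% t(tr$R)), 2, tr$c + off, `+`)
    }

    # planted placements first
    planted_tr <- replicate(spec$n_planted, place(planted = TRUE), simplify = FALSE)
    planted_shift <- lapply(seq_len(spec$n_planted), function(k) {
      v <- rnorm(3); v / sqrt(sum(v^2)) * spec$planted_rmsd
    })
    frames_a <- lapply(planted_tr, frame_of, local_frame = frame_local_a)
    frames_b <- lapply(seq_len(spec$n_planted), function(k)
      sweep(frames_a[[k]], 2, planted_shift[[k]], `+`))

    min_dist_to <- function(fr, frames) {
      if (length(frames) == 0L) return(Inf)
      min(vapply(frames, rfa_rmsd, numeric(1), a = fr))
    }
    # planted pairs must be mutually well separated so that each planted A
    # matches exactly its partner
    ok <- TRUE
    for (i in seq_len(spec$n_planted)) {
      others <- frames_b[-i]
      if (spec$n_planted > 1 &&
          min_dist_to(frames_a[[i]], others) < spec$decoy_margin) ok <- FALSE
    }
    tries <- 0L
    while (!ok && tries < spec$max_retries) {
      tries <- tries + 1L
      planted_tr <- replicate(spec$n_planted, place(planted = TRUE), simplify = FALSE)
      frames_a <- lapply(planted_tr, frame_of, local_frame = frame_local_a)
      frames_b <- lapply(seq_len(spec$n_planted), function(k)
        sweep(frames_a[[k]], 2, planted_shift[[k]], `+`))
      ok <- all(vapply(seq_len(spec$n_planted), function(i)
        spec$n_planted == 1 ||
          min_dist_to(frames_a[[i]], frames_b[-i]) >= spec$decoy_margin,
        logical(1)))
    }
    if (!ok) stop("could not separate planted pairs within the retry cap")

    sample_decoys <- function(n, local_frame, against) {
      trs <- list(); frames <- list()
      for (k in seq_len(n)) {
        for (try in seq_len(spec$max_retries)) {
          tr <- place()
          fr <- frame_of(tr, local_frame)
          if (min_dist_to(fr, against) >= spec$decoy_margin) break
          tr <- NULL
        }
        if (is.null(tr))
          stop("infeasible spec: decoy margin unachievable in box")
        trs[[k]] <- tr; frames[[k]] <- fr
        against <- c(against, list(fr))
      }
      list(trs = trs, frames = frames, all = against)
    }
    # A decoys must avoid all B frames (planted B + later B decoys); B decoys
    # must avoid all A frames. Sample against the union of both peptides'
    # frames: conservative but simple, and guarantees the truth table.
    avoid <- c(frames_a, frames_b)
    dec_a <- sample_decoys(spec$n_decoys_a, frame_local_a, avoid)
    dec_b <- sample_decoys(spec$n_decoys_b, frame_local_b, dec_a$all)

    smin <- spec$score_range[1]; smax <- spec$score_range[2]
    mk_pose <- function(tmpl, tr, off, score, id) {
      at <- transform_atoms(tmpl, tr$R, tr$c + off)
      docking_pose(at, score, id)
    }
    poses_a <- list(); truth_a <- character(0)
    for (k in seq_len(spec$n_planted)) {
      id <- sprintf("FRRFa_p%02d", k)
      poses_a[[length(poses_a) + 1L]] <-
        mk_pose(tmpl_a, planted_tr[[k]], c(0, 0, 0),
                smin + (k - 1) * (0.4 / max(1, spec$n_planted)), id)
      truth_a <- c(truth_a, id)
    }
    for (k in seq_len(spec$n_decoys_a))
      poses_a[[length(poses_a) + 1L]] <-
        mk_pose(tmpl_a, dec_a$trs[[k]], c(0, 0, 0),
                runif(1, smin + 0.05, smax), sprintf("FRRFa_d%03d", k))

    # planted B pose: same rotation as its A partner, template translated so
    # its RFa frame lands on A's frame + the planted shift
    poses_b <- list(); truth_b <- character(0)
    for (k in seq_len(spec$n_planted)) {
      id <- sprintf("KNFLRFa_p%02d", k)
      off <- planted_shift[[k]] - as.numeric(planted_tr[[k]]$R %*% d_ab)
      poses_b[[length(poses_b) + 1L]] <-
        mk_pose(tmpl_b, planted_tr[[k]], off, runif(1, smin, smax), id)
      truth_b <- c(truth_b, id)
    }
    for (k in seq_len(spec$n_decoys_b))
      poses_b[[length(poses_b) + 1L]] <-
        mk_pose(tmpl_b, dec_b$trs[[k]], c(0, 0, 0),
                runif(1, smin, smax), sprintf("KNFLRFa_d%03d", k))

    truth <- data.frame(pose_a = truth_a, pose_b = truth_b,
                        rmsd = rep(spec$planted_rmsd,
                                   length.out = spec$n_planted),
                        stringsAsFactors = FALSE)
    if (spec$n_planted == 0L)
      truth <- data.frame(pose_a = character(0), pose_b = character(0),
                          rmsd = numeric(0), stringsAsFactors = FALSE)
    list(ens_a = pose_ensemble("FRRFa", poses_a, receptor_id = "synthetic"),
         ens_b = pose_ensemble("KNFLRFa", poses_b, receptor_id = "synthetic"),
         truth = truth[order(truth$pose_a), , drop = FALSE])
  })
}

# ---- cavity phantoms ------------------------------------------------------

fibonacci_sphere <- function(n, radius, center = c(0, 0, 0)) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(center[1] + radius * sin(phi) * cos(theta),
        center[2] + radius * sin(phi) * sin(theta),
        center[3] + radius * cos(phi))
}

shell_atoms <- function(center, r_interior, probe, vdw = 1.70,
                        point_sep = 0.25, hole_axis = NULL, hole_radius = 0,
                        chain = "S", res_seq0 = 1L, serial0 = 0L) {
  R <- r_interior + vdw + probe
  n <- ceiling(4 * pi * R^2 / point_sep^2)
  pts <- fibonacci_sphere(n, R, center)
  if (!is.null(hole_axis) && hole_radius > 0) {
    # remove a spherical cap so the occluded shell leaves an open mouth with
    # the requested accessible aperture radius
    hole_r_atoms <- hole_radius + vdw + probe
    u <- hole_axis / sqrt(sum(hole_axis^2))
    proj <- as.numeric(sweep(pts, 2, center) %*% u)
    perp <- sqrt(pmax(0, rowSums(sweep(pts, 2, center)^2) - proj^2))
    keep <- !(proj > 0 & perp < hole_r_atoms)
    pts <- pts[keep, , drop = FALSE]
  }
  n <- nrow(pts)
  data.frame(serial = serial0 + seq_len(n), name = "C", element = "C",
             res_name = "SPH", res_seq = res_seq0, ins = "", chain = chain,
             x = pts[, 1], y = pts[, 2], z = pts[, 3],
             stringsAsFactors = FALSE)
}

#' Generate cavity phantom structures with analytic volumes
#'
#' Pseudo-atom shell structures whose probe-accessible interior volume is
#' known in closed form, used as oracles for the grid cavity detector:
#' \describe{
#'   \item{sealed_sphere}{a closed shell with interior radius `r` (truth
#'     volume `4/3 * pi * r^3`).}
#'   \item{open_pocket}{the same shell with a circular mouth of accessible
#'     aperture radius `mouth_radius` opening along +z.}
#'   \item{double_void}{two identical disjoint sealed shells.}
#' }
#' Shell atoms are carbon pseudo-atoms placed densely (Fibonacci lattice) at
#' the radius that puts the probe-accessible boundary at `r`.
#'
#' @param kind one of `"sealed_sphere"`, `"open_pocket"`, `"double_void"`.
#' @param r interior (accessible) radius, Angstrom.
#' @param mouth_radius accessible aperture radius of the mouth (open_pocket).
#' @param probe probe radius the phantom is built for (must match the
#'   [grid_spec] used on it; default 1.4).
#' @param separation center-to-center distance of the two voids
#'   (double_void); default puts them well apart.
#' @return list with `structure` ([structure3d]) and `truth` (kind, interior
#'   volume, centers, and for open_pocket the mouth axis).
#' @export
gen_cavity_structure <- function(kind = c("sealed_sphere", "open_pocket",
                                          "double_void"),
                                 r = 5, mouth_radius = 1.5, probe = 1.4,
                                 separation = NULL) {
  kind <- match.arg(kind)
  if (r <= 0) stop("interior radius must be positive")
  vol <- 4 / 3 * pi * r^3
  if (kind == "sealed_sphere") {
    at <- shell_atoms(c(0, 0, 0), r, probe)
    truth <- list(kind = kind, volume = vol, centers = rbind(c(0, 0, 0)))
  } else if (kind == "open_pocket") {
    if (mouth_radius >= r)
      stop("mouth radius must be smaller than the interior radius")
    at <- shell_atoms(c(0, 0, 0), r, probe, hole_axis = c(0, 0, 1),
                      hole_radius = mouth_radius)
    truth <- list(kind = kind, volume = vol, centers = rbind(c(0, 0, 0)),
                  axis = c(0, 0, 1), mouth_radius = mouth_radius)
  } else {
    sep <- if (is.null(separation)) 2 * (r + 1.7 + probe) + 6 else separation
    c1 <- c(-sep / 2, 0, 0); c2 <- c(sep / 2, 0, 0)
    a1 <- shell_atoms(c1, r, probe, res_seq0 = 1L)
    a2 <- shell_atoms(c2, r, probe, res_seq0 = 2L, serial0 = nrow(a1))
    at <- rbind(a1, a2)
    truth <- list(kind = kind, volume = vol, centers = rbind(c1, c2))
  }
  list(structure = structure3d(at, id = paste0("phantom_", kind)),
       truth = truth)
}

# ---- current traces and fit series ---------------------------------------

#' Specification for the current-trace generator
#'
#' Truth parameters of a synthetic acid-evoked current: instant peak at acid
#' onset, mono-exponential desensitization towards a sustained plateau, and
#' seeded Gaussian noise. Defaults emulate a wild-type-like cell: 5 uA peak
#' inward current, sustained fraction 3% (the 1 mM-modulator wild-type
#' value), 10 s acid application.
#'
#' @param seed RNG seed.
#' @param protocol a [stimulus_protocol].
#' @param i_peak peak current, uA (inward negative).
#' @param ratio truth sustained/peak ratio.
#' @param tau_des desensitization time constant, s.
#' @param noise_sd additive Gaussian noise, uA.
#' @param fs sampling rate, Hz.
#' @param t_end trace duration, s (default: 2 s past acid end).
#' @return list of class `trace_gen_spec`.
#' @export
trace_gen_spec <- function(seed = 1,
                           protocol = stimulus_protocol(5, 15),
                           i_peak = -5, ratio = 0.03, tau_des = 0.5,
                           noise_sd = 0.02, fs = 200,
                           t_end = NULL) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(seed = seed, protocol = protocol, i_peak = i_peak,
                 ratio = ratio, tau_des = tau_des, noise_sd = noise_sd,
                 fs = fs,
                 t_end = if (is.null(t_end)) protocol$acid_end + 2 else t_end),
            class = "trace_gen_spec")
}

#' Generate synthetic current traces
#'
#' @param spec a [trace_gen_spec].
#' @param n_replicates number of traces (independent noise draws).
#' @return list of [current_trace] objects.
#' @export
gen_current_traces <- function(spec = trace_gen_spec(), n_replicates = 1) {
  stopifnot(inherits(spec, "trace_gen_spec"))
  p <- spec$protocol
  if (p$acid_end > spec$t_end) stop("protocol inconsistent with trace length")
  with_seed(spec$seed, {
    t <- seq(0, spec$t_end, by = 1 / spec$fs)
    i_sust <- spec$i_peak * spec$ratio
    clean <- numeric(length(t))
    acid <- t >= p$acid_start & t <= p$acid_end
    clean[acid] <- i_sust + (spec$i_peak - i_sust) *
      exp(-(t[acid] - p$acid_start) / spec$tau_des)
    post <- t > p$acid_end
    i_end <- i_sust + (spec$i_peak - i_sust) *
      exp(-(p$acid_end - p$acid_start) / spec$tau_des)
    clean[post] <- i_end * exp(-(t[post] - p$acid_end) / 0.2)
    lapply(seq_len(n_replicates), function(k) {
      noise <- if (spec$noise_sd > 0) rnorm(length(t), 0, spec$noise_sd) else 0
      current_trace(t, clean + noise, p)
    })
  })
}

#' Generate steady-state desensitization, dose-response and kinetic series
#'
#' Companion series sampled from the closed-form models the fitting
#' functions assume, with seeded additive Gaussian noise:
#' `gen_ssd_series()` from the SSD Hill curve, `gen_dose_response_series()`
#' from the Hill-Langmuir curve, and `gen_kinetic_series()` from a
#' mono-exponential decay or rise.
#'
#' @param pH,conc,t sampling points of the respective series.
#' @param pHD50,nH,Imax SSD truth parameters.
#' @param EC50,hill,r_max,r_0 dose-response truth parameters (EC50 in mol/L).
#' @param rate,amplitude,offset,mode kinetics truth parameters.
#' @param noise_sd additive Gaussian noise SD (same units as the response).
#' @param seed RNG seed.
#' @return data.frame of the sampled series.
#' @export
gen_ssd_series <- function(pH = seq(6.6, 7.8, by = 0.15), pHD50 = 7.2,
                           nH = 3, Imax = 1, noise_sd = 0, seed = 1) {
  with_seed(seed, {
    I <- hill_ssd(pH, pHD50, nH, Imax)
    if (noise_sd > 0) I <- I + rnorm(length(pH), 0, noise_sd)
    data.frame(pH = pH, I = I)
  })
}

#' @rdname gen_ssd_series
#' @export
gen_dose_response_series <- function(conc = c(0, 1, 3, 10, 30, 100, 300,
                                              1000) * 1e-6,
                                     EC50 = 37e-6, hill = 1, r_max = 0.035,
                                     r_0 = 0.003, noise_sd = 0, seed = 1) {
  with_seed(seed, {
    r <- r_0 + (r_max - r_0) * ifelse(conc > 0,
                                      conc^hill / (EC50^hill + conc^hill), 0)
    if (noise_sd > 0) r <- r + rnorm(length(conc), 0, noise_sd)
    data.frame(conc = conc, ratio = r)
  })
}

#' @rdname gen_ssd_series
#' @export
gen_kinetic_series <- function(t = seq(0, 120, by = 10), rate = 0.025,
                               amplitude = 1, offset = 0,
                               mode = c("decay", "rise"), noise_sd = 0,
                               seed = 1) {
  mode <- match.arg(mode)
  with_seed(seed, {
    y <- if (mode == "decay") amplitude * exp(-rate * t) + offset
    else amplitude * (1 - exp(-rate * t)) + offset
    if (noise_sd > 0) y <- y + rnorm(length(t), 0, noise_sd)
    data.frame(t = t, y = y)
  })
}

#' Generate wild-type and mutant modulation replicate tables
#'
#' Per-cell replicate tables in the format [compare_modulation] consumes,
#' drawn around stated truth means with Gaussian noise. Wild-type defaults:
#' control sustained fraction 0.01, modulator-induced fold change 3, SSD
#' shift -0.15 pH units, Hill-ratio 0.5. Mutant effects are expressed
#' relative to WT: `fold_mult` scales the modulator-induced fold increase
#' above 1, `dphd50_mult` scales the pHD50 shift and `nh_attenuation`
#' moves the Hill ratio towards 1 (1 = no change from WT, 0 = modulator
#' effect fully suppressed).
#'
#' @param seed RNG seed.
#' @param n_wt,n_mut replicate counts.
#' @param isust_ctrl control sustained/peak ratio truth.
#' @param fold_wt WT modulator-induced fold change of that ratio.
#' @param dphd50_wt WT modulator-induced pHD50 shift, pH units.
#' @param nh_ratio_wt WT Hill-coefficient ratio (modulator/control).
#' @param fold_mult,dphd50_mult,nh_attenuation mutant effect scalings.
#' @param cv relative noise (coefficient of variation) on each quantity.
#' @details Effects the mutant leaves unchanged (`fold_mult = 1`,
#'   `dphd50_mult = 1` or `nh_attenuation = 0`, with `n_mut == n_wt`) reuse
#'   the wild-type effect realizations cell-for-cell, so the corresponding
#'   "no difference" classifications hold exactly by construction instead of
#'   being exposed to alpha-level false positives of the significance test.
#' @return list with `wt` and `mut` replicate data.frames.
#' @export
gen_modulation_dataset <- function(seed = 1, n_wt = 10, n_mut = 10,
                                   isust_ctrl = 0.01, fold_wt = 3,
                                   dphd50_wt = -0.15, nh_ratio_wt = 0.5,
                                   fold_mult = 1, dphd50_mult = 1,
                                   nh_attenuation = 0, cv = 0.1) {
  with_seed(seed, {
    draw <- function(n, mean, sdfrac = cv) rnorm(n, mean, abs(mean) * sdfrac)
    fold_mut <- 1 + (fold_wt - 1) * fold_mult
    nhr_mut <- nh_ratio_wt + (1 - nh_ratio_wt) * nh_attenuation
    dphd50_mut <- dphd50_wt * dphd50_mult
    # wild-type effect realizations, reused for unchanged mutant effects
    fold_w <- draw(n_wt, fold_wt)
    dphd_w <- rnorm(n_wt, dphd50_wt, max(0.01, abs(dphd50_wt) * cv))
    nhr_w <- draw(n_wt, nh_ratio_wt)
    same <- function(changed, wt_draws, n, mean, sd = NULL) {
      if (!changed && n == length(wt_draws)) return(wt_draws)
      if (is.null(sd)) draw(n, mean) else rnorm(n, mean, sd)
    }
    fold_m <- same(fold_mult != 1, fold_w, n_mut, fold_mut)
    dphd_m <- same(dphd50_mult != 1, dphd_w, n_mut, dphd50_mut,
                   max(0.01, abs(dphd50_mut) * cv))
    nhr_m <- same(nh_attenuation != 0, nhr_w, n_mut, nhr_mut)
    mk <- function(n, fold_d, dphd_d, nhr_d) {
      ctrl <- draw(n, isust_ctrl)
      phd50_ctrl <- rnorm(n, 7.2, 0.02)
      nh_ctrl <- draw(n, 4)
      data.frame(
        isust_ctrl = ctrl,
        isust_frrfa = ctrl * fold_d,
        phd50_ctrl = phd50_ctrl,
        phd50_frrfa = phd50_ctrl + dphd_d,
        nh_ctrl = nh_ctrl,
        nh_frrfa = nh_ctrl * nhr_d)
    }
    list(wt = mk(n_wt, fold_w, dphd_w, nhr_w),
         mut = mk(n_mut, fold_m, dphd_m, nhr_m))
  })
}
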