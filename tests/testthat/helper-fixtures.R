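# Fixtures are built in code: small PDB texts, toy structures and rigid
# transforms used across the test files.

pdb_atom_line <- function(serial, name, res_name, chain, res_seq, x, y, z,
                          element = substr(name, 1, 1)) {
  nm <- if (nchar(name) < 4) paste0(" ", formatC(name, width = 3, flag = "-"))
  else name
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, nm, res_name, chain, res_seq, x, y, z, element)
}

write_two_atom_pdb <- function(path) {
  writeLines(c(
    pdb_atom_line(1, "N", "GLY", "A", 1, 1.0, 2.0, 3.0),
    pdb_atom_line(2, "CA", "GLY", "A", 1, 4.0, 5.0, 6.0, element = "C"),
    "END"), path)
  path
}

# multi-MODEL PDB ensemble with given scores, one glycine atom per model
write_scored_ensemble_pdb <- function(path, scores, with_score = TRUE) {
  out <- character(0)
  for (k in seq_along(scores)) {
    out <- c(out, sprintf("MODEL %8d", k))
    if (with_score)
      out <- c(out, sprintf("REMARK VINA RESULT: %8.3f      0.000      0.000",
                            scores[k]))
    out <- c(out, pdb_atom_line(1, "CA", "GLY", "A", 1, k, 0, 0,
                                element = "C"),
             "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  path
}

# AutoDock-style result text: USER-tagged energies
write_autodock_ensemble <- function(path, scores) {
  out <- character(0)
  for (k in seq_along(scores)) {
    out <- c(out,
             sprintf("MODEL %8d", k),
             sprintf("USER    Estimated Free Energy of Binding    = %8.2f kcal/mol",
                     scores[k]),
             pdb_atom_line(1, "CA", "GLY", "A", 1, k, 0, 0, element = "C"),
             "ENDMDL")
  }
  writeLines(out, path)
  path
}

# toy trimer: three chains, each with CA atoms for the listed residues
toy_trimer <- function(res_seqs = c(236L, 278L, 312L, 380L),
                       res_names = c("THR", "GLN", "ILE", "LYS")) {
  rows <- list()
  serial <- 0L
  for (ci in 1:3) {
    for (k in seq_along(res_seqs)) {
      serial <- serial + 1L
      rows[[serial]] <- data.frame(
        serial = serial, name = "CA", element = "C",
        res_name = res_names[k], res_seq = res_seqs[k], ins = "",
        chain = LETTERS[ci],
        x = 10 * ci + k, y = 5 * k, z = ci + k, stringsAsFactors = FALSE)
    }
  }
  structure3d(do.call(rbind, rows), id = "toy_trimer")
}

rotation_matrix <- function(axis = c(0, 0, 1), angle = pi / 5) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

rigid_transform_pose <- function(pose, R = rotation_matrix(),
                                 shift = c(0, 0, 0)) {
  xyz <- as.matrix(pose$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, shift, `+`)
  at <- pose$atoms
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  docking_pose(at, pose$score, pose$pose_id)
}

rigid_transform_structure <- function(s, R = rotation_matrix(),
                                      shift = c(0, 0, 0)) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, shift, `+`)
  at <- s$atoms
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  structure3d(at, id = s$id)
}

# random pose ensembles (no planted structure) for brute-force comparisons
random_ensembles <- function(seed, n_a = 10, n_b = 10, box = 20) {
  set.seed(seed)
  tmpl_a <- build_peptide_template("FRRF")
  tmpl_b <- build_peptide_template("KNFLRF")
  rand_rot <- function() {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  mk <- function(tmpl, n, prefix) {
    lapply(seq_len(n), function(k) {
      at <- tmpl
      xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(rand_rot())
      xyz <- sweep(xyz, 2, runif(3, -box, box), `+`)
      at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
      docking_pose(at, runif(1, -9, -4), sprintf("%s_%02d", prefix, k))
    })
  }
  list(ens_a = pose_ensemble("FRRFa", mk(tmpl_a, n_a, "A"), "rec"),
       ens_b = pose_ensemble("KNFLRFa", mk(tmpl_b, n_b, "B"), "rec"))
}

# exhaustive double-loop oracle for match_consensus
brute_force_consensus <- function(ens_a, ens_b, window = 1.0, cutoff = 1.0) {
  sc <- ensemble_scores(ens_a)
  keep <- which(sc <= min(sc) + window)
  out <- list()
  for (i in keep) {
    fa <- extract_rfa_frame(ens_a$poses[[i]])
    best_r <- Inf; best_id <- NA_character_
    for (j in seq_along(ens_b$poses)) {
      fb <- extract_rfa_frame(ens_b$poses[[j]])
      # per-atom arithmetic, no shared code with rfa_rmsd internals
      ss <- 0
      for (r in 1:9) ss <- ss + sum((fa[r, ] - fb[r, ])^2)
      rr <- sqrt(ss / 9)
      id <- ens_b$poses[[j]]$pose_id
      if (rr < best_r || (rr == best_r && id < best_id)) {
        best_r <- rr; best_id <- id
      }
    }
    if (best_r < cutoff)
      out[[length(out) + 1L]] <- data.frame(
        pose_a = ens_a$poses[[i]]$pose_id, pose_b = best_id, rmsd = best_r,
        score_a = ens_a$poses[[i]]$score, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(pose_a = character(0), pose_b = character(0),
                      rmsd = numeric(0), score_a = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$pose_a), , drop = FALSE]
}
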