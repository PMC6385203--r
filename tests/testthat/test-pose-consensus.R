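test_that("RFa frame extraction picks the C-terminal Arg-Phe-amide atoms", {
  p4 <- docking_pose(build_peptide_template("FRRF"), -7, "frrfa")
  fr <- extract_rfa_frame(p4)
  expect_equal(dim(fr), c(9L, 3L))
  expect_equal(rownames(fr), c("ARG N", "ARG CA", "ARG CG", "ARG CZ",
                               "PHE N", "PHE CA", "PHE CG", "PHE CZ",
                               "NH2 N"))
  # Arg3/Phe4 for the 4-mer: Arg backbone N sits at the residue-3 offset
  expect_equal(unname(fr["ARG N", ]), c(2 * 3.8, 0, 0))
  expect_equal(unname(fr["PHE N", ]), c(3 * 3.8, 0, 0))
  expect_equal(attr(fr, "source_pose"), "frrfa")

  # Arg5/Phe6 for the 6-mer
  p6 <- docking_pose(build_peptide_template("KNFLRF"), -7, "knflrfa")
  fr6 <- extract_rfa_frame(p6)
  expect_equal(unname(fr6["ARG N", ]), c(4 * 3.8, 0, 0))
  expect_equal(unname(fr6["PHE N", ]), c(5 * 3.8, 0, 0))
})

test_that("RFa frame extraction fails informatively on broken motifs", {
  # no C-terminal amide
  p <- docking_pose(build_peptide_template("FRRF", amidated = FALSE), -7, "x")
  expect_error(extract_rfa_frame(p), "amide")
  # Phe not preceded by Arg
  p2 <- docking_pose(build_peptide_template("FGGF"), -7, "y")
  expect_error(extract_rfa_frame(p2), "motif absent")
  # missing side-chain atom
  at <- build_peptide_template("FRRF")
  at <- at[!(at$res_seq == 4 & at$name == "CZ"), ]
  expect_error(extract_rfa_frame(docking_pose(at, -7, "z")), "CZ")
})

test_that("an Arg side-chain NH2 is never mistaken for the amide nitrogen", {
  at <- build_peptide_template("FRFR", amidated = FALSE)
  # last residue is Arg with an NH2 side-chain atom but no amide: must fail
  expect_error(extract_rfa_frame(docking_pose(at, -5, "argend")), "amide")
})

test_that("rfa_rmsd matches hand arithmetic and obeys the translation law", {
  p <- docking_pose(build_peptide_template("FRRF"), -7, "a")
  fr <- extract_rfa_frame(p)
  expect_identical(rfa_rmsd(fr, fr), 0)
  expect_equal(rfa_rmsd(fr, sweep(fr, 2, c(3, 0, 0), `+`)), 3.0)

  set.seed(9)
  for (k in 1:25) {
    a <- matrix(rnorm(27, sd = 5), 9, 3)
    b <- matrix(rnorm(27, sd = 5), 9, 3)
    # independent per-atom oracle
    ss <- 0
    for (r in 1:9) ss <- ss + sum((a[r, ] - b[r, ])^2)
    expect_equal(rfa_rmsd(a, b), sqrt(ss / 9), tolerance = 1e-12)
    # symmetry, non-negativity
    expect_identical(rfa_rmsd(a, b), rfa_rmsd(b, a))
    expect_gte(rfa_rmsd(a, b), 0)
    # translation law
    t3 <- rnorm(3)
    expect_equal(rfa_rmsd(a, sweep(a, 2, t3, `+`)), sqrt(sum(t3^2)),
                 tolerance = 1e-9)
  }
})

test_that("energy_window keeps the best pose and is monotone", {
  mk <- function(scores) pose_ensemble("p", lapply(seq_along(scores),
    function(k) docking_pose(build_peptide_template("FRRF"), scores[k],
                             sprintf("p%d", k))), "rec")
  ens <- mk(c(-8.0, -7.5, -6.9))
  expect_equal(ensemble_scores(energy_window(ens, 1.0)), c(-8.0, -7.5))
  expect_equal(ensemble_scores(energy_window(ens, 0)), -8.0)
  ens2 <- mk(c(-8.0, -8.0, -6.9))
  expect_equal(ensemble_scores(energy_window(ens2, 0)), c(-8.0, -8.0))
  # monotonicity: enlarging the window never drops a pose
  for (w in c(0, 0.5, 1.1, 2)) {
    small <- energy_window(ens, w)
    big <- energy_window(ens, w + 0.5)
    ids <- function(e) vapply(e$poses, `[[`, character(1), "pose_id")
    expect_true(all(ids(small) %in% ids(big)))
  }
})

test_that("match_consensus equals the exhaustive double-loop oracle", {
  for (seed in c(101, 202, 303, 404)) {
    e <- random_ensembles(seed)
    got <- match_consensus(e$ens_a, e$ens_b,
                           consensus_params(1.0, 1.0))
    want <- brute_force_consensus(e$ens_a, e$ens_b, 1.0, 1.0)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("match_consensus recovers exactly the planted matches", {
  sim <- gen_pose_ensembles(pose_gen_spec(seed = 17, n_planted = 1,
                                          n_decoys_a = 10, n_decoys_b = 10,
                                          planted_rmsd = 0.5))
  m <- match_consensus(sim$ens_a, sim$ens_b)
  expect_equal(nrow(m), 1L)
  expect_equal(m$pose_a, sim$truth$pose_a)
  expect_equal(m$pose_b, sim$truth$pose_b)
  expect_equal(m$rmsd, 0.5, tolerance = 1e-9)

  none <- gen_pose_ensembles(pose_gen_spec(seed = 18, n_planted = 0,
                                           n_decoys_a = 10, n_decoys_b = 10))
  expect_equal(nrow(match_consensus(none$ens_a, none$ens_b)), 0L)
})

test_that("match_consensus is invariant to input pose order", {
  e <- random_ensembles(55)
  ref <- match_consensus(e$ens_a, e$ens_b)
  set.seed(1)
  shuf_b <- pose_ensemble("KNFLRFa", sample(e$ens_b$poses), "rec")
  shuf_a <- pose_ensemble("FRRFa", sample(e$ens_a$poses), "rec")
  expect_equal(match_consensus(shuf_a, shuf_b), ref, ignore_attr = TRUE)
})

test_that("match_consensus rejects mismatched receptors", {
  e <- random_ensembles(7)
  other <- pose_ensemble("KNFLRFa", e$ens_b$poses, "another_receptor")
  expect_error(match_consensus(e$ens_a, other), "different receptors")
})

test_that("matches TSV includes the documented columns", {
  e <- random_ensembles(101)
  m <- match_consensus(e$ens_a, e$ens_b)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matches_tsv(m, f)
  back <- read.delim(f)
  expect_named(back, c("pose_a", "pose_b", "rmsd", "score_a", "pocket_label"))
})

test_that("superpose_transform undoes a rigid motion of the receptor", {
  s <- toy_trimer()
  R <- rotation_matrix(c(1, 2, 3), 0.7)
  moved <- rigid_transform_structure(s, R, c(5, -3, 2))
  tf <- superpose_transform(moved, s)
  back <- tf(as.matrix(moved$atoms[, c("x", "y", "z")]))
  expect_equal(back, as.matrix(s$atoms[, c("x", "y", "z")]),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("N-terminus orientation is read off the burial-depth map", {
  ph <- gen_cavity_structure("open_pocket", r = 7, mouth_radius = 1.6)
  cav <- probe_accessible_cavities(ph$structure, grid_spec(spacing = 0.4))
  tmpl <- build_peptide_template("RF")
  R <- matrix(c(0, 0, 1, 0, 1, 0, -1, 0, 0), 3, 3, byrow = TRUE)
  xyz <- as.matrix(tmpl[, c("x", "y", "z")]) %*% t(R)
  at_out <- tmpl
  at_out$x <- xyz[, 1]; at_out$y <- xyz[, 2]; at_out$z <- xyz[, 3] + 3
  at_in <- tmpl
  at_in$x <- xyz[, 1]; at_in$y <- xyz[, 2]; at_in$z <- -xyz[, 3] - 3
  expect_true(nterm_orientation_ok(docking_pose(at_out, -7, "out"), cav))
  expect_false(nterm_orientation_ok(docking_pose(at_in, -7, "in"), cav))
  # a pose floating in bulk solvent has no defined orientation
  at_bulk <- tmpl; at_bulk$z <- at_bulk$z + 40
  expect_error(nterm_orientation_ok(docking_pose(at_bulk, -7, "bulk"), cav),
               "not within the margin")
})
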