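mk_ring <- function(z = 0, chain = "A", res_seq = 50L, tilt = 0,
                    center = c(0, 0, 0)) {
  ring <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  ang <- seq(0, 300, by = 60) * pi / 180
  xyz <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  if (tilt != 0) {
    R <- rotation_matrix(c(1, 0, 0), tilt)
    xyz <- xyz %*% t(R)
  }
  data.frame(serial = seq_along(ring), name = ring, element = "C",
             res_name = "PHE", res_seq = res_seq, ins = "", chain = chain,
             x = xyz[, 1] + center[1], y = xyz[, 2] + center[2],
             z = xyz[, 3] + z + center[3], stringsAsFactors = FALSE)
}

test_that("a constructed N-H...O=C pair is one hydrogen bond", {
  rec <- structure3d(data.frame(serial = 1:2, name = c("C", "O"),
                                element = c("C", "O"), res_name = "GLY",
                                res_seq = 10L, ins = "", chain = "A",
                                x = 0, y = 0, z = c(1.23, 0)), id = "rec")
  # donor N at 2.9 A below the O, H placed for a ~150 degree D-H...A angle
  pep <- data.frame(serial = 1:3, name = c("N", "H", "CA"),
                    element = c("N", "H", "C"), res_name = "GLY",
                    res_seq = 1L, ins = "", chain = "P",
                    x = c(0, 0.34, 1.4), y = 0, z = c(-2.9, -1.96, -3.5))
  fp <- detect_interactions(docking_pose(pep, -5, "hb"), rec)
  hb <- fp$interactions[fp$interactions$kind == "hbond", ]
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance, 2.9, tolerance = 1e-6)
  expect_gt(hb$angle, 120)

  # pull the acceptor out of range: no bond
  rec_far <- rec
  rec_far$atoms$z <- rec_far$atoms$z + 1.5
  fp2 <- detect_interactions(docking_pose(pep, -5, "hb"), rec_far)
  expect_equal(nrow(fp2$interactions[fp2$interactions$kind == "hbond", ]), 0L)

  # bad geometry: H pointing away fails the angle test
  pep_bad <- pep
  pep_bad[2, c("x", "z")] <- c(0, -3.9)
  fp3 <- detect_interactions(docking_pose(pep_bad, -5, "hb"), rec)
  expect_equal(nrow(fp3$interactions[fp3$interactions$kind == "hbond", ]), 0L)
})

test_that("parallel and T-shaped ring geometries count as stacking", {
  rec <- structure3d(mk_ring(0, "A", 50L), id = "r")
  par <- detect_interactions(docking_pose(mk_ring(4.0, "P", 1L), -5, "s"),
                             rec)$interactions
  expect_equal(sum(par$kind == "stacking"), 1L)
  expect_equal(par$angle[par$kind == "stacking"], 0, tolerance = 1e-6)

  tsh <- detect_interactions(
    docking_pose(mk_ring(4.5, "P", 1L, tilt = pi / 2), -5, "t"),
    rec)$interactions
  expect_equal(sum(tsh$kind == "stacking"), 1L)
  expect_equal(tsh$angle[tsh$kind == "stacking"], 90, tolerance = 1e-6)

  # 45 degrees falls in neither window
  mid <- detect_interactions(
    docking_pose(mk_ring(4.5, "P", 1L, tilt = pi / 4), -5, "m"),
    rec)$interactions
  expect_equal(sum(mid$kind == "stacking"), 0L)
})

test_that("cation-pi and salt bridges follow the charge tables", {
  arg <- build_peptide_template("R", amidated = FALSE)
  cz <- as.numeric(arg[arg$name == "CZ", c("x", "y", "z")])
  ring_at <- mk_ring(0, "A", 20L, center = cz + c(0, 0, 4.5))
  rec <- structure3d(ring_at, id = "ring")
  fp <- detect_interactions(docking_pose(arg, -5, "cp"), rec)
  expect_true("cation_pi" %in% fp$interactions$kind)

  # Arg guanidinium vs Glu carboxylate within 4 A
  nh1 <- as.numeric(arg[arg$name == "NH1", c("x", "y", "z")])
  glu <- data.frame(serial = 1:2, name = c("OE1", "OE2"), element = "O",
                    res_name = "GLU", res_seq = 30L, ins = "", chain = "A",
                    x = nh1[1] + c(2.8, 3.4), y = nh1[2], z = nh1[3],
                    stringsAsFactors = FALSE)
  fp2 <- detect_interactions(docking_pose(arg, -5, "sb"),
                             structure3d(glu, "glu"))
  expect_true("salt_bridge" %in% fp2$interactions$kind)
})

test_that("fingerprints are invariant under global rigid motion", {
  sim <- gen_pose_ensembles(pose_gen_spec(seed = 3, n_planted = 1,
                                          n_decoys_a = 2, n_decoys_b = 2))
  pose <- sim$ens_a$poses[[1]]
  # receptor: a phenylalanine ring plus a glutamate near the pose
  ctr <- unname(colMeans(pose$atoms[, c("x", "y", "z")]))
  rec_at <- rbind(mk_ring(0, "A", 50L, center = as.numeric(ctr) + c(4, 0, 0)),
                  data.frame(serial = 7:8, name = c("OE1", "OE2"),
                             element = "O", res_name = "GLU", res_seq = 60L,
                             ins = "", chain = "A",
                             x = ctr[1] + c(3, 3.6), y = ctr[2],
                             z = ctr[3], stringsAsFactors = FALSE))
  rec <- structure3d(rec_at, "near")
  ref <- detect_interactions(pose, rec)$interactions
  R <- rotation_matrix(c(2, -1, 1), 1.1)
  sh <- c(7, -4, 12)
  moved <- detect_interactions(rigid_transform_pose(pose, R, sh),
                               rigid_transform_structure(rec, R, sh))
  got <- moved$interactions
  expect_equal(got[, c("kind", "peptide_atom", "res_seq")],
               ref[, c("kind", "peptide_atom", "res_seq")])
  expect_equal(got$distance, ref$distance, tolerance = 1e-8)
  expect_equal(got$angle, ref$angle, tolerance = 1e-6)
})

test_that("fingerprint TSV export flattens pose and interaction columns", {
  rec <- structure3d(mk_ring(0, "A", 50L), id = "r")
  fp <- detect_interactions(docking_pose(mk_ring(4.0, "P", 1L), -5, "s"), rec)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_fingerprints_tsv(fp, f)
  back <- read.delim(f)
  expect_true(all(c("pose", "kind", "peptide_atom", "res_seq", "distance")
                  %in% names(back)))
  expect_equal(unique(back$pose), "s")
})
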