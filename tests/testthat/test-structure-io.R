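test_that("read_structure parses fixed-column ATOM records exactly", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_two_atom_pdb(f)
  s <- read_structure(f)
  expect_s3_class(s, "structure3d")
  expect_equal(nrow(s$atoms), 2L)
  expect_equal(unname(as.matrix(s$atoms[, c("x", "y", "z")])),
               matrix(c(1, 2, 3, 4, 5, 6), 2, 3, byrow = TRUE))
  expect_equal(s$atoms$element, c("N", "C"))
  expect_equal(s$atoms$res_name, c("GLY", "GLY"))
  expect_equal(s$chains, "A")
})

test_that("read_structure rejects empty or atom-free files", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(0), f)
  expect_error(read_structure(f), "no ATOM")
  writeLines(c("HEADER  test", "END"), f)
  expect_error(read_structure(f), "no ATOM")
  expect_error(read_structure(file.path(tempdir(), "nope_missing.pdb")),
               "cannot read")
})

test_that("coordinate parsing agrees with an independent PDB reader", {
  skip_if_not_installed("bio3d")
  f <- withr::local_tempfile(fileext = ".pdb")
  set.seed(42)
  lines <- vapply(1:20, function(k)
    pdb_atom_line(k, c("N", "CA", "C", "O")[(k - 1) %% 4 + 1], "ALA", "B",
                  (k - 1) %/% 4 + 1,
                  round(runif(1, -50, 50), 3), round(runif(1, -50, 50), 3),
                  round(runif(1, -50, 50), 3)), character(1))
  writeLines(c(lines, "END"), f)
  ours <- read_structure(f)
  ref <- bio3d::read.pdb(f)
  expect_equal(unname(as.matrix(ours$atoms[, c("x", "y", "z")])),
               unname(matrix(ref$xyz, ncol = 3, byrow = TRUE)))
  expect_equal(ours$atoms$name, ref$atom$elety)
  expect_equal(ours$atoms$res_seq, ref$atom$resno)
})

test_that("pose ensembles parse scores and sort best-first", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_scored_ensemble_pdb(f, c(-7.0, -6.5, -6.0))
  ens <- read_pose_ensemble(f, "FRRFa")
  expect_length(ens$poses, 3L)
  expect_equal(ensemble_scores(ens), c(-7.0, -6.5, -6.0))

  # scrambled file order is re-sorted
  write_scored_ensemble_pdb(f, c(-6.0, -7.0))
  ens2 <- read_pose_ensemble(f, "FRRFa")
  expect_equal(ensemble_scores(ens2), c(-7.0, -6.0))
  expect_equal(ens2$poses[[1]]$pose_id, "FRRFa_002")
})

test_that("AutoDock-style USER energy lines are parsed", {
  f <- withr::local_tempfile(fileext = ".dock4")
  write_autodock_ensemble(f, c(-5.25, -8.75))
  ens <- read_pose_ensemble(f, "KNFLRFa")
  expect_equal(ensemble_scores(ens), c(-8.75, -5.25))
})

test_that("pose files without scores or poses are rejected by name", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_scored_ensemble_pdb(f, c(-7.0, -6.0), with_score = FALSE)
  expect_error(read_pose_ensemble(f, "FRRFa"), "pose 1")
  writeLines(c(pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0), "END"), f)
  expect_error(read_pose_ensemble(f, "FRRFa"), "no poses|no MODEL")
})

test_that("write/read round-trip preserves coordinates and order", {
  sim <- gen_pose_ensembles(pose_gen_spec(seed = 5, n_planted = 1,
                                          n_decoys_a = 3, n_decoys_b = 3))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pose_ensemble(sim$ens_a, f)
  back <- read_pose_ensemble(f, "FRRFa")
  expect_length(back$poses, length(sim$ens_a$poses))
  for (k in seq_along(back$poses)) {
    a <- sim$ens_a$poses[[k]]$atoms
    b <- back$poses[[k]]$atoms
    expect_equal(b$name, a$name)
    # PDB precision is 3 decimals: round-trip exact at that precision
    expect_equal(b$x, round(a$x, 3))
    expect_equal(b$y, round(a$y, 3))
    expect_equal(b$z, round(a$z, 3))
    expect_equal(back$poses[[k]]$score, sim$ens_a$poses[[k]]$score,
                 tolerance = 1e-3)
  }

  s <- toy_trimer()
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f2)
  s2 <- read_structure(f2)
  expect_equal(s2$atoms$res_seq, s$atoms$res_seq)
  expect_equal(as.matrix(s2$atoms[, c("x", "y", "z")]),
               as.matrix(s$atoms[, c("x", "y", "z")]), ignore_attr = TRUE)
})

test_that("search boxes are centered on the requested C-alphas", {
  s <- toy_trimer()
  resids <- expand.grid(chain = c("A", "B", "C"),
                        res_seq = c(236L, 278L, 312L, 380L),
                        stringsAsFactors = FALSE)
  boxes <- make_search_boxes(s, resids, side = 35)
  expect_equal(nrow(boxes), 12L)
  expect_true(all(boxes$side == 35))
  # each box center equals that residue's CA
  for (k in seq_len(nrow(boxes))) {
    ca <- s$atoms[s$atoms$chain == boxes$chain[k] &
                    s$atoms$res_seq == boxes$res_seq[k] &
                    s$atoms$name == "CA", ]
    expect_equal(c(boxes$cx[k], boxes$cy[k], boxes$cz[k]),
                 c(ca$x, ca$y, ca$z))
  }

  one <- make_search_boxes(s, data.frame(chain = "B", res_seq = 278L), 20)
  expect_equal(nrow(one), 1L)
  expect_equal(one$res_name, "GLN")

  expect_error(make_search_boxes(s, data.frame(chain = "A", res_seq = 999L)),
               "A999")
  expect_error(make_search_boxes(s, resids, side = 0), "positive")
})

test_that("structure and pose invariants are enforced", {
  at <- data.frame(serial = c(1L, 1L), name = "CA", element = "C",
                   res_name = "GLY", res_seq = 1L, ins = "", chain = "A",
                   x = 0, y = 0, z = 0)
  expect_error(structure3d(at), "unique")
  at2 <- at[1, ]; at2$x <- NA_real_
  expect_error(structure3d(at2), "finite")
  expect_error(docking_pose(at[1, ], NaN), "finite")
  expect_error(pose_ensemble("p", list()), "at least one")
})
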