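test_that("a sealed spherical void is recovered near its analytic volume", {
  ph <- gen_cavity_structure("sealed_sphere", r = 5)
  cav <- probe_accessible_cavities(ph$structure, grid_spec(spacing = 0.4))
  main <- cav[cav$sealed, ][1, ]
  expect_false(is.na(main$label))
  expect_lt(abs(main$volume - ph$truth$volume) / ph$truth$volume, 0.05)
  expect_equal(main$volume_voxel, main$voxel_count * 0.4^3)
  expect_lt(abs(main$volume_voxel - ph$truth$volume) / ph$truth$volume, 0.05)
  expect_equal(c(main$cx, main$cy, main$cz), c(0, 0, 0), tolerance = 0.05)
})

test_that("structures without heavy atoms and oversize grids are rejected", {
  h_only <- structure3d(data.frame(serial = 1L, name = "H", element = "H",
                                   res_name = "GLY", res_seq = 1L, ins = "",
                                   chain = "A", x = 0, y = 0, z = 0))
  expect_error(probe_accessible_cavities(h_only), "no heavy atoms")
  ph <- gen_cavity_structure("sealed_sphere", r = 5)
  expect_error(probe_accessible_cavities(ph$structure,
                                         grid_spec(spacing = 0.05)),
               "coarser spacing")
})

test_that("two identical disjoint voids give two equal regions", {
  dv <- gen_cavity_structure("double_void", r = 4)
  cav <- probe_accessible_cavities(dv$structure, grid_spec(spacing = 0.4))
  sealed <- cav[cav$sealed, ]
  expect_equal(nrow(sealed), 2L)
  # equal up to one voxel
  expect_lte(abs(sealed$voxel_count[1] - sealed$voxel_count[2]), 30)
  expect_lt(abs(sealed$volume[1] - dv$truth$volume) / dv$truth$volume, 0.06)
})

test_that("an open pocket is reported and flagged unsealed", {
  ph <- gen_cavity_structure("open_pocket", r = 6, mouth_radius = 1.6)
  cav <- probe_accessible_cavities(ph$structure, grid_spec(spacing = 0.4))
  main <- cav[1, ]  # largest
  expect_false(main$sealed)
  # most of the interior is recovered even though the mouth is open
  expect_lt(abs(main$volume - ph$truth$volume) / ph$truth$volume, 0.15)
})

test_that("voxel bookkeeping is conserved: occupied + bulk + cavity = total", {
  for (kind in c("sealed_sphere", "open_pocket")) {
    ph <- gen_cavity_structure(kind, r = 5, mouth_radius = 1.5)
    cav <- probe_accessible_cavities(ph$structure, grid_spec(spacing = 0.5))
    g <- attr(cav, "grid")
    total <- prod(g$dims)
    expect_identical(sum(g$occupied) + sum(g$bulk) + sum(g$labels > 0L),
                     as.integer(total))
    # cavity voxels are exactly the labelled ones
    expect_identical(sum(g$labels > 0L), sum(cav$voxel_count))
  }
})

test_that("pose-to-pocket assignment follows the atom-count rule", {
  dv <- gen_cavity_structure("double_void", r = 6)
  cav <- probe_accessible_cavities(dv$structure, grid_spec(spacing = 0.5))
  tmpl <- build_peptide_template("RF")
  ctr <- dv$truth$centers
  at1 <- tmpl
  at1$x <- at1$x + ctr[1, 1] - 3.5  # roughly centered in void 1
  p1 <- docking_pose(at1, -6, "inside1")
  lab1 <- assign_pose_pocket(p1, cav)
  expect_false(is.na(lab1))
  # the matching cavity is the one whose centroid is nearest
  d <- sqrt((cav$cx - ctr[1, 1])^2 + cav$cy^2 + cav$cz^2)
  expect_equal(lab1, cav$label[which.min(d)])

  # far away: unassigned
  at2 <- tmpl; at2$z <- at2$z + 100
  expect_true(is.na(assign_pose_pocket(docking_pose(at2, -6, "far"), cav)))

  # invariance to cavity list order
  rev_cav <- cav[rev(seq_len(nrow(cav))), ]
  attr(rev_cav, "grid") <- attr(cav, "grid")
  attr(rev_cav, "lining") <- rev(attr(cav, "lining"))
  expect_equal(assign_pose_pocket(p1, rev_cav), lab1)
})

test_that("landmark sets rename cavities from their lining residues", {
  # a sealed void lined by pseudo-residues we can name
  ph <- gen_cavity_structure("sealed_sphere", r = 5)
  at <- ph$structure$atoms
  at$res_name <- "GLU"
  at$res_seq <- 413L
  s <- structure3d(at, "landmarked")
  cav <- probe_accessible_cavities(s, grid_spec(spacing = 0.5),
                                   landmarks = list(
                                     central_vestibule = c("E413"),
                                     acidic_pocket = c("D237")))
  sealed <- cav[cav$sealed, ]
  expect_true("central_vestibule" %in% sealed$label)
  # shipped default landmark file parses
  lmf <- system.file("extdata", "landmarks_asic1a.json", package = "rfasite")
  expect_true(nzchar(lmf))
  lm <- jsonlite::read_json(lmf, simplifyVector = TRUE)
  expect_true(all(c("acidic_pocket", "thumb_base", "central_vestibule",
                    "side_cavity") %in% names(lm)))
})

test_that("cavity TSV report carries volumes and lining residues", {
  ph <- gen_cavity_structure("sealed_sphere", r = 4)
  cav <- probe_accessible_cavities(ph$structure, grid_spec(spacing = 0.5))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cavities_tsv(cav, f)
  back <- read.delim(f)
  expect_named(back, c("label", "volume_A3", "sealed", "lining_residues"))
  expect_true(any(grepl("SPH", back$lining_residues)))
})
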