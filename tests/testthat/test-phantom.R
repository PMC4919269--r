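test_that("noiseless phantom round-trips every organ TAC exactly", {
  geom <- test_geometry()
  cp <- frame_average(ref_input, default_sched, "heart")
  ct <- simulate_tissue_tac(ref_input, 0.8, 0.15, default_sched)
  bl <- bladder_tac(ref_input, default_sched)
  ph <- render_phantom(list(heart = cp, kidney_cortex_l = ct,
                            kidney_cortex_r = ct, bladder = bl), geom)
  for (org in c("heart", "kidney_cortex_l", "bladder")) {
    src <- switch(org, heart = cp, kidney_cortex_l = ct, bladder = bl)
    expect_equal(extract_tac(ph, organ_mask(ph, org))$values, src$values)
  }
  # background voxels are zero in every frame
  bg <- ph$voxels[cbind(which(ph$labels == 0L, arr.ind = TRUE)[1:50, ], 1)]
  expect_equal(bg, rep(0, 50))
  # bladder is non-decreasing over frames
  bt <- extract_tac(ph, organ_mask(ph, "bladder"))
  expect_true(all(diff(bt$values) >= -1e-12))
})

test_that("TAC extraction is the arithmetic mean over masked voxels", {
  geom <- test_geometry()
  a_val <- 10; b_val <- 4
  ph <- render_phantom(list(heart = tac(default_sched, rep(a_val, 33)),
                            liver = tac(default_sched, rep(b_val, 33))), geom)
  # mask half in the heart, half in the liver -> (a+b)/2
  hi <- which(ph$labels == 1L); li <- which(ph$labels == 2L)
  k <- min(length(hi), length(li))
  m <- array(FALSE, dim(ph$labels)); m[c(hi[1:k], li[1:k])] <- TRUE
  expect_equal(extract_tac(ph, voi_mask(m))$values,
               rep((a_val + b_val) / 2, 33))
  # single-voxel mask returns that voxel's series
  m1 <- array(FALSE, dim(ph$labels)); m1[hi[1]] <- TRUE
  expect_equal(extract_tac(ph, voi_mask(m1))$values, rep(a_val, 33))
  expect_error(voi_mask(array(FALSE, dim(ph$labels))), "at least one")
})

test_that("overlapping organ geometry is rejected", {
  geom <- test_geometry()
  geom$organs$liver$center <- geom$organs$heart$center
  expect_error(make_labels(geom), "overlaps")
})

test_that("IDIF of a homogeneous heart equals the frame-averaged input", {
  geom <- test_geometry()
  cp <- frame_average(ref_input, default_sched, "heart")
  ph <- render_phantom(list(heart = cp), geom)
  idif <- build_idif(ph, circle_diameter_px = 7, n_slices = 3)
  expect_equal(idif$values, cp$values)
  expect_length(attr(idif, "slices"), 3L)
  expect_error(build_idif(ph, early_window_s = 1), "early window")
  expect_error(build_idif(ph, n_slices = 1000), "fewer axial slices")
})

test_that("axial translation moves slice indices but not IDIF values", {
  geom <- test_geometry()
  cp <- frame_average(ref_input, default_sched, "heart")
  ph <- render_phantom(list(heart = cp), geom)
  # shift the whole image one voxel in +z (background pads the edge)
  shifted <- ph
  nz <- dim(ph$labels)[3]
  shifted$voxels <- ph$voxels[, , c(nz, seq_len(nz - 1)), , drop = FALSE]
  shifted$labels <- ph$labels[, , c(nz, seq_len(nz - 1))]
  i1 <- build_idif(ph, circle_diameter_px = 7, n_slices = 3)
  i2 <- build_idif(shifted, circle_diameter_px = 7, n_slices = 3)
  expect_equal(attr(i2, "slices"), attr(i1, "slices") + 1L)
  expect_equal(i2$values, i1$values)
})

test_that("diluted heart signal inflates TBC by the reciprocal factor", {
  geom <- test_geometry()
  subj <- subject_record("m1", "WT", 25, 7700)
  cp <- frame_average(ref_input, default_sched, "heart")
  d <- 0.8
  diluted <- tac(default_sched, cp$values * d, "heart")
  ph <- render_phantom(list(heart = diluted), geom)
  idif <- build_idif(ph, circle_diameter_px = 7, n_slices = 3)
  expect_equal(idif$values, cp$values * d)
  expect_equal(tbc(subj, idif)$tbc, tbc(subj, cp)$tbc / d,
               tolerance = 1e-12)
})

test_that("SUV conversion follows the definition and refuses re-application", {
  subj <- subject_record("m1", "WT", 20, 7700)
  x <- tac(default_sched, rep(5, 33))
  s <- to_suv(x, subj)
  expect_equal(s$values[1], 5 * 20 / 7700)
  expect_equal(s$units_mode, "SUV")
  expect_error(to_suv(s, subj), "double conversion")
  # C = ID / BW gives SUV exactly 1
  u <- to_suv(tac(default_sched, rep(7700 / 20, 33)), subj)
  expect_equal(u$values, rep(1, 33))
  # doubling both concentration and dose leaves SUV unchanged
  subj2 <- subject_record("m2", "WT", 20, 2 * 7700)
  s2 <- to_suv(tac(default_sched, rep(10, 33)), subj2)
  expect_equal(s2$values, s$values)
})

test_that("phantom and VOI NIfTI round-trips preserve data", {
  geom <- test_geometry()
  cp <- frame_average(ref_input, default_sched, "heart")
  ph <- render_phantom(list(heart = cp), geom)
  prefix <- file.path(withr::local_tempdir(), "ph")
  write_phantom(ph, prefix)
  back <- read_phantom(prefix)
  expect_equal(back$voxels, unclass(ph$voxels), ignore_attr = TRUE)
  expect_equal(back$labels, ph$labels, ignore_attr = TRUE)
  expect_equal(back$voxel_mm, c(0.8, 0.8, 0.8))
  expect_equal(back$schedule$start_s, default_sched$start_s)
  voi <- organ_mask(ph, "heart")
  vpath <- file.path(withr::local_tempdir(), "voi.nii")
  write_voi(voi, vpath)
  expect_equal(read_voi(vpath, "heart")$mask, voi$mask, ignore_attr = TRUE)
})
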