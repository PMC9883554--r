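test_that("layered phantom nests correctly and voxelizes layer volumes", {
  cfg <- phantom_config(spacing = 2)
  ph <- build_head_phantom(cfg)
  d <- dim(ph$labels)
  ctr <- (d + 1) / 2
  expect_identical(ph$labels[ctr[1], ctr[2], ctr[3]],
                   ttfieldsim:::label_code("white_matter"))
  expect_identical(ph$labels[1, 1, 1], 0L)    # corner is outside
  # scalp shell volume vs analytic 4/3*pi*(r1^3 - r2^3), <= 3% at 2 mm
  v_vox <- sum(ph$labels == ttfieldsim:::label_code("scalp")) * cfg$spacing^3
  v_ana <- 4 / 3 * pi * (92^3 - 85^3)
  expect_lt(abs(v_vox - v_ana) / v_ana, 0.03)
  expect_true(validate_phantom(ph))
  expect_error(phantom_config(radii = c(scalp = 80, skull = 85, csf = 78,
                                        gm = 75, wm = 60)),
               "decreasing")
})

test_that("tumor embedding voxelizes the core and keeps shell contact", {
  cfg <- phantom_config(spacing = 2)
  ph <- build_head_phantom(cfg)
  n_dom <- sum(ph$labels != 0L)
  ph2 <- embed_tumor(ph, c(40, 0, 0), r_core = 12, t_shell = 6)
  v_core <- sum(ph2$labels == ttfieldsim:::label_code("tumor_core")) * 8
  expect_lt(abs(v_core - 4 / 3 * pi * 12^3) / (4 / 3 * pi * 12^3), 0.03)
  expect_true(validate_phantom(ph2))                 # core boundary in shell
  expect_identical(sum(ph2$labels != 0L), n_dom)     # relabeling conserves
  # shell-only lesion
  ph3 <- embed_tumor(ph, c(40, 0, 0), r_core = 0, t_shell = 6)
  expect_identical(sum(ph3$labels == ttfieldsim:::label_code("tumor_core")), 0L)
  expect_gt(sum(ph3$labels == ttfieldsim:::label_code("tumor_shell")), 0L)
  expect_error(embed_tumor(ph, c(70, 0, 0), 12, 6), "outside the brain")
})

test_that("skull defect relabels only skull voxels inside the window", {
  cfg <- phantom_config(spacing = 2)
  ph <- build_head_phantom(cfg)
  before <- ph$labels
  expect_warning(ph0 <- apply_skull_defect(ph, diameter = 0), "unchanged")
  expect_identical(ph0$labels, before)
  expect_false(any(ph0$defect_mask))
  ph2 <- apply_skull_defect(ph, axis_center = c(0, 0), diameter = 50,
                            side = 1L)
  expect_true(all(before[ph2$defect_mask] ==
                  ttfieldsim:::label_code("skull")))
  expect_true(all(ph2$labels[ph2$defect_mask] ==
                  ttfieldsim:::label_code("scalp")))
  expect_identical(ph2$labels[!ph2$defect_mask], before[!ph2$defect_mask])
  # converted count vs flat-disc volume pi*(d/2)^2 * t_skull, <= 10% at 2 mm
  n_exp <- pi * 25^2 * (92 - 85) / cfg$spacing^3
  expect_lt(abs(sum(ph2$defect_mask) - n_exp) / n_exp, 0.10)
  expect_identical(sum(ph2$labels != 0L), sum(before != 0L))
})

test_that("array placement produces 18 conforming transducers", {
  pl <- ttfieldsim:::build_case_phantom(mini_study_config(), "intact")
  ph <- pl$phantom; spec <- pl$arrays
  expect_s3_class(spec, "array_spec")
  expect_identical(nrow(spec$transducers), 18L)
  expect_setequal(unique(ph$tid[ph$tid > 0]), 1:18)
  expect_true(all(spec$transducers$n_gel_vox > 0))
  expect_true(all(spec$transducers$n_electrode_vox > 0))
  expect_true(validate_phantom(ph))   # electrode-gel and gel-scalp contact
  expect_false(any(ph$insulation))
  # the two arrays sit on opposite sides of the montage axis
  expect_setequal(unique(spec$transducers$side), c(-1, 1))
})

test_that("gel thickness is one 1 mm voxel layer at 1 mm spacing", {
  cfg <- mini_phantom_config(spacing = 1)
  ph <- build_head_phantom(cfg)
  pl <- place_arrays(ph)
  expect_equal(pl$arrays$gel_thickness, 1)
  expect_equal(pl$arrays$transducer_height, 1)
  # a column through the center transducer has exactly 1 gel + 1 electrode
  lab <- pl$phantom$labels
  d <- dim(lab)
  ctr <- (d + 1) / 2
  col <- lab[, ctr[2], ctr[3]]
  expect_equal(sum(col == ttfieldsim:::label_code("hydrogel")), 2L)   # both sides
  expect_equal(sum(col == ttfieldsim:::label_code("electrode")), 2L)
})

test_that("overlapping transducers raise a placement error", {
  cfg <- mini_phantom_config()
  cfg$array$pitch <- 10   # < 2 * gel_radius
  ph <- build_head_phantom(cfg)
  expect_error(place_arrays(ph), "overlap")
})

test_that("phantom construction is deterministic and mirror-symmetric", {
  cfg <- mini_phantom_config(tumor_center = c(24, 0, 0))
  a <- ttfieldsim:::build_case_phantom(
    study_config(phantom = cfg, solver = solver_config(mode = "direct")),
    "defect")$phantom
  b <- ttfieldsim:::build_case_phantom(
    study_config(phantom = cfg, solver = solver_config(mode = "direct")),
    "defect")$phantom
  expect_identical(a$labels, b$labels)
  expect_identical(a$tid, b$tid)
  # mirror in y (axis 2): config is symmetric under y -> -y
  d <- dim(a$labels)
  expect_identical(a$labels, a$labels[, d[2]:1, , drop = FALSE])
  # mirror in z as well
  expect_identical(a$labels, a$labels[, , d[3]:1, drop = FALSE])
})

test_that("jitter is applied only when a seed is supplied and is reproducible", {
  cfg <- mini_phantom_config()
  cfg$array$pitch <- 20
  cfg$array$jitter_sd <- 0.5
  ph0 <- place_arrays(build_head_phantom(cfg))$arrays       # no seed: no jitter
  expect_true(all(ph0$transducers$t1 %in% c(-20, 0, 20)))
  cfg$array$seed <- 42L
  ph1 <- place_arrays(build_head_phantom(cfg))$arrays
  ph2 <- place_arrays(build_head_phantom(cfg))$arrays
  expect_identical(ph1$transducers$t1, ph2$transducers$t1)
  expect_false(all(ph1$transducers$t1 %in% c(-20, 0, 20)))
})
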