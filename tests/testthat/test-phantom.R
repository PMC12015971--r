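test_that("noiseless echo ratio follows the mono-exponential model", {
  set.seed(2)
  subj <- draw_subject("HC")
  subj$true_fascicle_t2star_ms <- 20
  ph <- build_phantom(subj, tiny_geometry(), noiseless_acq())
  fas <- ph$labels$labels == 2L
  ratio <- ph$echoes$echo2[fas] / ph$echoes$echo1[fas]
  expect_equal(unique(round(ratio, 12)), round(exp(-(5.37 - 1.05) / 20), 12))
})

test_that("label maps partition the nerve exactly on every slice", {
  set.seed(3)
  for (grp in c("ATTRv", "HC")) {
    subj <- draw_subject(grp)
    ph <- build_phantom(subj, tiny_geometry())
    prof <- csa_per_slice(ph$labels)
    wide <- tidyr::pivot_wider(prof, names_from = "structure",
                               values_from = "area_mm2")
    expect_equal(wide$fascicle + wide$epineurium, wide$nerve)
    expect_true(all(ph$labels$labels %in% 0:2))
  }
})

test_that("rendered geometry matches the subject's true CSA and fraction", {
  set.seed(4)
  geom <- tiny_geometry()
  for (i in 1:5) {
    subj <- draw_subject(sample(c("ATTRv", "HC"), 1))
    ph <- build_phantom(subj, geom)
    agg <- aggregate_areas(csa_per_slice(ph$labels),
                           select_analysis_slices(geom$nslices))
    csa <- agg$area_mm2[agg$structure == "nerve"]
    frac <- agg$area_mm2[agg$structure == "fascicle"] / csa
    expect_lt(abs(csa - subj$true_csa_mm2) / subj$true_csa_mm2, 0.05)
    expect_lt(abs(frac - subj$true_fasc_fraction) / subj$true_fasc_fraction, 0.05)
    # voxel-count rendering is in fact within one voxel of the target
    expect_lte(abs(csa - subj$true_csa_mm2), geom$dx * geom$dy)
  }
})

test_that("fascicles are hyperintense and epineurium hypointense at TE1", {
  set.seed(6)
  subj <- draw_subject("HC")
  ph <- build_phantom(subj, tiny_geometry(), noiseless_acq())
  e1 <- ph$echoes$echo1
  lab <- ph$labels$labels
  expect_gt(min(e1[lab == 2L]), max(e1[lab == 1L]))
})

test_that("amplitudes cancel out of the noiseless pT2* map", {
  set.seed(8)
  subj <- draw_subject("HC")
  geom <- tiny_geometry()
  set.seed(123)
  ph1 <- build_phantom(subj, geom, noiseless_acq(), default_compartments())
  set.seed(123)
  ph2 <- build_phantom(subj, geom, noiseless_acq(),
                       default_compartments(fascicle_amplitude = 3,
                                            epineurium_amplitude = 0.2,
                                            muscle_amplitude = 1.5))
  m1 <- compute_pt2star(ph1$echoes)
  m2 <- compute_pt2star(ph2$echoes)
  expect_equal(m1$values, m2$values, tolerance = 1e-12)
})

test_that("noiseless phantom recovers the configured t2star end to end", {
  set.seed(9)
  subj <- draw_subject("HC")
  subj$true_fascicle_t2star_ms <- 15
  ph <- build_phantom(subj, tiny_geometry(), noiseless_acq())
  m <- analyze_phantom(ph$echoes, ph$labels)
  expect_lt(abs(m$fascicle_pt2star_ms - 15) / 15, 1e-9)
  expect_lt(abs(m$epineurium_pt2star_ms - subj$true_epineurium_t2star_ms) /
              subj$true_epineurium_t2star_ms, 1e-9)
  # roi-signal path agrees in the noiseless limit
  m2 <- analyze_phantom(ph$echoes, ph$labels, method = "roi_signal")
  expect_equal(m$fascicle_pt2star_ms, m2$fascicle_pt2star_ms, tolerance = 1e-9)
})

test_that("an oversized nerve is rejected before rendering", {
  set.seed(10)
  subj <- draw_subject("HC")
  subj$true_csa_mm2 <- 4000
  expect_error(build_phantom(subj, tiny_geometry()), "does not fit")
})

test_that("mask perturbation preserves validity and only acts on boundaries", {
  set.seed(12)
  subj <- draw_subject("HC")
  ph <- build_phantom(subj, tiny_geometry())
  expect_identical(perturb_mask(ph$labels, 0)$labels, ph$labels$labels)
  expect_equal(dice_coefficient(ph$labels, perturb_mask(ph$labels, 0), "nerve"), 1)

  pert <- perturb_mask(ph$labels, 0.2)
  expect_true(all(pert$labels %in% 0:2))
  d <- dice_coefficient(ph$labels, pert, "fascicle")
  expect_true(d > 0 && d < 1)

  # interior voxels are untouched: changed voxels must lie on a boundary
  changed <- which(pert$labels != ph$labels$labels)
  lab <- ph$labels$labels
  dims <- dim(lab)
  for (idx in head(changed, 50)) {
    pos <- arrayInd(idx, dims)
    i <- pos[1]; j <- pos[2]; s <- pos[3]
    nb <- c(lab[max(i - 1, 1), j, s], lab[min(i + 1, dims[1]), j, s],
            lab[i, max(j - 1, 1), s], lab[i, min(j + 1, dims[2]), s])
    expect_true(any(nb != lab[i, j, s]))
  }
  expect_error(perturb_mask(ph$labels, 0.7), "\\[0, 0.5\\]")
})

test_that("rate-zero perturbation leaves derived measures with ICC 1", {
  set.seed(13)
  cc <- run_cohort(3, 3, tiny_config(), seed = 13)
  rel <- reliability_stage(cc, flip_rate = 0)
  expect_equal(rel$dice$dice, rep(1, 3))
  expect_equal(rel$icc$icc, rep(1, 2), tolerance = 1e-12)
})

test_that("acquisition geometry books a 6 cm slab from 12 x 5 mm slices", {
  expect_equal(slab_coverage_mm(geometry_config()), 60)
  expect_equal(slab_coverage_mm(geometry_config(nslices = 4, dz = 2.5)), 10)
})
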