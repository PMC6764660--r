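test_that("brain mask voxel counts match sphere volumes across resolutions", {
  # 74 mm radius at 1 mm resolution: ~1.7M voxel centers inside the sphere
  n_1mm <- sum(make_brain_mask(sim_config(voxel_size_mm = 1)))
  expect_gte(n_1mm, 1.69e6)
  expect_lte(n_1mm, 1.71e6)

  # degenerate sphere of half a voxel: only the central voxel
  expect_equal(sum(make_brain_mask(
    sim_config(brain_radius_mm = 0.5, voxel_size_mm = 1,
               tumor_diameter_mm = 1, effect_region_diameter_mm = 0.5,
               effect_region_center = c(0, 0, 0)))), 1)

  # halving the voxel size scales the count by ~8 (volume scaling)
  cfg_h <- sim_config(brain_radius_mm = 20, voxel_size_mm = 2,
                      tumor_diameter_mm = 20,
                      effect_region_diameter_mm = 8,
                      effect_region_center = c(0, 0, 0))
  cfg_h2 <- sim_config(brain_radius_mm = 20, voxel_size_mm = 1,
                       tumor_diameter_mm = 20,
                       effect_region_diameter_mm = 8,
                       effect_region_center = c(0, 0, 0))
  ratio <- sum(make_brain_mask(cfg_h2)) / sum(make_brain_mask(cfg_h))
  expect_lt(abs(ratio - 8) / 8, 0.05)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(tumor_diameter_mm = 200), "brain diameter")
  expect_error(sim_config(effect_region_center = c(70, 0, 0)),
               "inside the brain")
  expect_error(sim_config(p_avoid_A = 1.2))
  expect_error(sim_config(voxel_size_mm = 4, analysis_voxel_size_mm = 6),
               "integer multiple")
})

test_that("per-patient masks respect residue within tumor within brain", {
  cfg <- tiny_cfg()
  cs <- simulate_cohorts(cfg, seed = 11)
  brain <- cs$brain
  for (p in cs$cases) {
    expect_true(all(p$tumor[p$residue]))     # residue subset of tumor
    expect_true(all(brain[which(p$tumor)]))  # tumor subset of brain
    expect_gt(sum(p$tumor), 0)
  }
})

test_that("full resection leaves an empty residue", {
  cfg <- tiny_cfg(extent_of_resection = 1, p_avoid_A = 0, p_avoid_B = 0)
  cs <- simulate_cohorts(cfg, seed = 5)
  for (p in cs$cases) expect_equal(sum(p$residue), 0)
})

test_that("guaranteed avoidance leaves all effect-region tumor as residue", {
  cfg <- tiny_cfg(p_avoid_B = 1)
  cs <- simulate_cohorts(cfg, seed = 3)
  eff <- cs$effect
  for (p in cs$cases) {
    if (p$cohort != "B") next
    in_eff_tumor <- which(p$tumor & eff)
    expect_true(all(p$residue[in_eff_tumor]))
  }
})

test_that("achieved extent of resection matches the target without avoidance", {
  cfg <- tiny_cfg(p_avoid_A = 0, p_avoid_B = 0)
  cs <- simulate_cohorts(cfg, seed = 9)
  for (p in cs$cases) {
    achieved <- 1 - sum(p$residue) / sum(p$tumor)
    expect_gte(achieved, cfg$extent_of_resection - 1e-12)
    # ties at the cavity boundary can only add a few voxels
    expect_lte(achieved, cfg$extent_of_resection + 0.1)
  }
})

test_that("cavity radius fit is exact and minimal", {
  # concentric spheres: radius ratio is the cube root of the volume ratio
  dim <- c(25, 25, 25)
  d2 <- outer(outer((1:25 - 13)^2, (1:25 - 13)^2, "+"), (1:25 - 13)^2, "+")
  tumor <- d2 <= 10^2
  attr(tumor, "voxel_size_mm") <- 1
  rad <- fit_cavity_radius(tumor, c(13, 13, 13), 0.6)
  expect_lt(abs(rad / 10 - 0.6^(1/3)), 1 / 10)

  # covering the whole tumor from the center needs at least the tumor radius
  expect_gte(fit_cavity_radius(tumor, c(13, 13, 13), 1), 10 - 1e-9)
  # a vanishing fraction needs at most one voxel
  expect_lte(fit_cavity_radius(tumor, c(13, 13, 13), 1e-9), 1)

  # off-center: brute-force recount at the returned radius covers >= the
  # target, and the next-smaller radius does not (minimality)
  center <- c(16, 13, 13)
  frac <- 0.6
  rad <- fit_cavity_radius(tumor, center, frac)
  idx <- which(tumor)
  ijk <- arrayInd(idx, dim)
  d2c <- (ijk[, 1] - center[1])^2 + (ijk[, 2] - center[2])^2 +
         (ijk[, 3] - center[3])^2
  covered <- mean(d2c <= rad^2 + 1e-9)
  expect_gte(covered, frac)
  smaller <- max(sqrt(d2c[d2c < rad^2 - 1e-9]), 0)
  expect_lt(mean(d2c <= smaller^2 + 1e-9), frac)

  expect_error(fit_cavity_radius(tumor, c(13, 13, 13), 1.2), "target_fraction")
  expect_error(fit_cavity_radius(tumor, c(1, 1, 1), 0.5), "inside the tumor")
})

test_that("cohort generation is balanced, labeled, and seed-reproducible", {
  cs <- simulate_cohorts(sim_config(voxel_size_mm = 4), seed = 21,
                         compact = TRUE)
  labels <- vapply(cs$cases, function(p) p$cohort, "")
  expect_equal(sum(labels == "A"), 50)
  expect_equal(sum(labels == "B"), 50)

  cfg <- tiny_cfg()
  a <- simulate_cohorts(cfg, seed = 77)
  b <- simulate_cohorts(cfg, seed = 77)
  for (i in seq_along(a$cases)) {
    expect_identical(which(a$cases[[i]]$tumor), which(b$cases[[i]]$tumor))
    expect_identical(which(a$cases[[i]]$residue), which(b$cases[[i]]$residue))
  }
})

test_that("equal avoidance probabilities make the cohorts exchangeable", {
  cfg <- tiny_cfg(p_avoid_A = 0.5, p_avoid_B = 0.5,
                  n_patients_per_cohort = 40)
  pr <- sapply(1:10, function(s) {
    cs <- simulate_cohorts(cfg, seed = 100 + s, compact = TRUE)
    cm <- aggregate_counts(cs$cases)
    eff <- which(cs$effect)
    c(sum(cm$r_A[eff]) / max(sum(cm$t_A[eff]), 1),
      sum(cm$r_B[eff]) / max(sum(cm$t_B[eff]), 1))
  })
  # pooled effect-region residue rates agree within sampling noise;
  # patients are the independent unit, so the tolerance is per-patient
  expect_lt(abs(mean(pr[1, ]) - mean(pr[2, ])), 0.15)
})

test_that("analysis-grid cases equal majority-downsampled generation-grid cases", {
  cfg_c <- tiny_cfg(voxel_size_mm = 2, analysis_voxel_size_mm = 4,
                    n_patients_per_cohort = 3)
  cfg_f <- tiny_cfg(voxel_size_mm = 2, analysis_voxel_size_mm = 2,
                    n_patients_per_cohort = 3)
  cs_c <- simulate_cohorts(cfg_c, seed = 13, compact = TRUE)
  cs_f <- simulate_cohorts(cfg_f, seed = 13)
  for (i in seq_along(cs_c$cases)) {
    expect_identical(as.integer(cs_c$cases[[i]]$tumor),
                     which(downsample_mask(cs_f$cases[[i]]$tumor, 2)))
    expect_identical(as.integer(cs_c$cases[[i]]$residue),
                     which(downsample_mask(cs_f$cases[[i]]$residue, 2)))
  }
  expect_identical(which(cs_c$effect),
                   which(downsample_mask(cs_f$effect, 2)))
})
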