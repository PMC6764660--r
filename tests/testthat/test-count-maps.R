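test_that("aggregation counts tumors and residues per cohort", {
  dm <- c(3, 3, 3)
  v <- 14L  # central voxel
  cases <- list(
    mk_case(dm, c(v, 1L), c(v), "A"),
    mk_case(dm, c(v, 2L), integer(0), "A"),
    mk_case(dm, c(v), c(v), "B"))
  cm <- aggregate_counts(cases)
  expect_equal(cm$t_A[v], 2L)
  expect_equal(cm$r_A[v], 1L)
  expect_equal(cm$t_B[v], 1L)
  expect_equal(cm$r_B[v], 1L)
  expect_equal(cm$n_A, 2L)
  expect_true(all(cm$r_A <= cm$t_A) && all(cm$r_B <= cm$t_B))

  # empty case list with an explicit grid gives an all-zero map
  cm0 <- aggregate_counts(list(), dim = dm)
  expect_true(all(cm0$t_A == 0) && all(cm0$r_B == 0))

  # mixed grids are rejected
  expect_error(aggregate_counts(list(cases[[1]],
                                     mk_case(c(4, 4, 4), 1L, 1L, "A"))),
               "share one grid")
})

test_that("aggregation is invariant to patient order and conserves volume", {
  cfg <- tiny_cfg()
  cs <- simulate_cohorts(cfg, seed = 31)
  cm1 <- aggregate_counts(cs$cases)
  cm2 <- aggregate_counts(rev(cs$cases))
  expect_identical(cm1$t_A, cm2$t_A)
  expect_identical(cm1$r_B, cm2$r_B)
  volsA <- sum(vapply(cs$cases, function(p)
    if (p$cohort == "A") sum(p$tumor) else 0L, numeric(1)))
  expect_equal(sum(cm1$t_A), volsA)
})

test_that("forced avoidance makes r_B equal t_B inside the effect region", {
  cfg <- tiny_cfg(p_avoid_B = 1)
  cs <- simulate_cohorts(cfg, seed = 17)
  cm <- aggregate_counts(cs$cases)
  eff <- which(cs$effect)
  expect_identical(cm$r_B[eff], cm$t_B[eff])
})

test_that("downsampling follows the majority rule with zero padding", {
  m <- array(FALSE, c(4, 4, 4))
  expect_identical(downsample_mask(m, 1), m)

  m[] <- TRUE
  expect_true(all(downsample_mask(m, 2)))
  expect_equal(dim(downsample_mask(m, 2)), c(2, 2, 2))

  # exactly half the block set -> set under the >= 50% rule
  m <- array(FALSE, c(2, 2, 2)); m[1:4] <- TRUE
  expect_true(downsample_mask(m, 2)[1, 1, 1])
  m[] <- FALSE; m[1:3] <- TRUE  # under half
  expect_false(downsample_mask(m, 2)[1, 1, 1])
  expect_true(downsample_mask(m, 2, rule = "any")[1, 1, 1])

  # non-divisible shapes are zero-padded at the upper end
  m <- array(TRUE, c(3, 3, 3))
  ds <- downsample_mask(m, 2)
  expect_equal(dim(ds), c(2, 2, 2))
  expect_true(ds[1, 1, 1])       # 8/8 fine voxels set
  expect_false(ds[2, 2, 2])      # 1/8 after padding

  # voxel size attribute scales
  attr(m, "voxel_size_mm") <- 2
  expect_equal(attr(downsample_mask(m, 2), "voxel_size_mm"), 4)
})

test_that("the tested-voxel filter applies an inclusive threshold", {
  dm <- c(3, 3, 3)
  cases <- c(
    lapply(1:3, function(i) mk_case(dm, c(1L, 2L), integer(0), "A")),
    lapply(1:3, function(i) mk_case(dm, c(1L), integer(0), "B")))
  cm <- aggregate_counts(cases)
  # voxel 1: t_A=3, t_B=3 -> exactly 6, included (boundary of "fewer than 6")
  expect_true(1L %in% tested_voxels(cm, 6))
  # voxel 2: t_A=3, t_B=0 -> excluded at threshold 6
  expect_false(2L %in% tested_voxels(cm, 6))
  # threshold 0 keeps every voxel
  expect_equal(length(tested_voxels(cm, 0)), prod(dm))
})

test_that("NIfTI cohorts round-trip and clip stray residue voxels", {
  dir <- withr::local_tempdir()
  cfg <- tiny_cfg(n_patients_per_cohort = 2)
  cs <- simulate_cohorts(cfg, seed = 4)
  manifest <- write_cohort_nifti(cs$cases, dir)
  reloaded <- load_clinical_cohort(manifest)
  cm_orig <- aggregate_counts(cs$cases)
  cm_re <- aggregate_counts(reloaded)
  expect_equal(as.vector(cm_re$t_A), as.vector(cm_orig$t_A))
  expect_equal(as.vector(cm_re$r_B), as.vector(cm_orig$r_B))

  # a residue voxel outside the tumor triggers a warning and is clipped
  bad <- mk_case(c(3, 3, 3), c(1L, 2L), c(1L, 5L), "A")
  write_cohort_nifti(list(bad), dir, prefix = "bad")
  man <- data.frame(
    tumor_path = file.path(dir, "bad001_tumor.nii.gz"),
    residue_path = file.path(dir, "bad001_residue.nii.gz"),
    cohort = "A")
  expect_warning(fixed <- load_clinical_cohort(man), "outside the tumor")
  expect_false(fixed[[1]]$residue[5])
  expect_true(fixed[[1]]$residue[1])

  # an empty residue image contributes no residue counts
  none <- mk_case(c(3, 3, 3), c(1L, 2L), integer(0), "B")
  write_cohort_nifti(list(none), dir, prefix = "none")
  man2 <- data.frame(
    tumor_path = file.path(dir, "none001_tumor.nii.gz"),
    residue_path = file.path(dir, "none001_residue.nii.gz"),
    cohort = "B")
  cm_none <- aggregate_counts(load_clinical_cohort(man2))
  expect_equal(sum(cm_none$r_B), 0)
})
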