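#' Configuration for the spherical synthetic-cohort simulator
#'
#' Collects and validates the parameters of the generative model for
#' synthetic brain-tumor resections: a spherical brain, spherical tumors
#' with spherical resection cavities leaving crescent residues, and a
#' spherical surgical-avoidance (effect) region in which the two cohorts'
#' surgical practices differ.
#'
#' The defaults reproduce the nominal benchmarking conditions: 50 patients
#' per cohort, 8 cm tumors resected to 60% of their (in-brain) volume, a
#' 4 cm avoidance sphere, and avoidance probabilities of 0% in practice A
#' versus 100% in practice B. The brain is a 74 mm radius sphere, which at
#' 1 mm resolution contains approximately 1.7 million voxel centers.
#'
#' @param brain_radius_mm Radius of the spherical brain in mm.
#' @param voxel_size_mm Isotropic voxel edge length of the generation grid
#'   in mm. 4 mm is the benchmarking default; the reference model is
#'   defined at 1 mm.
#' @param analysis_voxel_size_mm Voxel size of the analysis grid on which
#'   counts are aggregated and statistics computed; must be an integer
#'   multiple of \code{voxel_size_mm}. When larger than the generation
#'   grid, per-patient masks are sub-sampled to this grid by the majority
#'   rule before aggregation, reproducing the partial-volume mixing at
#'   mask boundaries that coarse analyses of finely generated data
#'   exhibit. Defaults to \code{voxel_size_mm} (no sub-sampling).
#' @param n_patients_per_cohort Number of patients simulated per cohort.
#' @param tumor_diameter_mm Diameter of the spherical tumor in mm.
#' @param extent_of_resection Fraction in (0, 1] of the realized (in-brain)
#'   tumor volume that the planned resection cavity must cover.
#' @param effect_region_diameter_mm Diameter of the spherical avoidance
#'   region in mm.
#' @param effect_region_center Numeric length-3 offset (mm) of the avoidance
#'   sphere center from the brain center.
#' @param p_avoid_A,p_avoid_B Per-patient probabilities that the avoidance
#'   region is spared (subtracted from the planned cavity) in cohorts A and B.
#' @param n_repetitions Default number of benchmark repetitions.
#' @param rng_seed Optional integer seed; repetition \code{j} of a benchmark
#'   uses seed \code{rng_seed + j} so repetitions are individually
#'   reproducible.
#'
#' @return An object of class \code{"sim_config"}.
#' @examples
#' cfg <- sim_config(voxel_size_mm = 4)
#' cfg
#' @export
sim_config <- function(brain_radius_mm = 74,
                       voxel_size_mm = 4,
                       analysis_voxel_size_mm = voxel_size_mm,
                       n_patients_per_cohort = 50,
                       tumor_diameter_mm = 80,
                       extent_of_resection = 0.60,
                       effect_region_diameter_mm = 40,
                       effect_region_center = c(30, 0, 0),
                       p_avoid_A = 0,
                       p_avoid_B = 1,
                       n_repetitions = 1000,
                       rng_seed = NULL) {
  stopifnot(brain_radius_mm > 0, voxel_size_mm > 0,
            n_patients_per_cohort >= 1,
            tumor_diameter_mm > 0,
            extent_of_resection > 0, extent_of_resection <= 1,
            effect_region_diameter_mm > 0,
            length(effect_region_center) == 3,
            p_avoid_A >= 0, p_avoid_A <= 1,
            p_avoid_B >= 0, p_avoid_B <= 1,
            n_repetitions >= 1)
  if (tumor_diameter_mm > 2 * brain_radius_mm)
    stop("tumor_diameter_mm must not exceed the brain diameter")
  if (sqrt(sum(effect_region_center^2)) + effect_region_diameter_mm / 2 >
      brain_radius_mm)
    stop("effect region sphere must lie entirely inside the brain sphere")
  factor <- analysis_voxel_size_mm / voxel_size_mm
  if (abs(factor - round(factor)) > 1e-9 || factor < 1)
    stop("analysis_voxel_size_mm must be a positive integer multiple of voxel_size_mm")
  structure(list(
    brain_radius_mm = brain_radius_mm,
    voxel_size_mm = voxel_size_mm,
    analysis_voxel_size_mm = analysis_voxel_size_mm,
    n_patients_per_cohort = n_patients_per_cohort,
    tumor_diameter_mm = tumor_diameter_mm,
    extent_of_resection = extent_of_resection,
    effect_region_diameter_mm = effect_region_diameter_mm,
    effect_region_center = as.numeric(effect_region_center),
    p_avoid_A = p_avoid_A,
    p_avoid_B = p_avoid_B,
    n_repetitions = n_repetitions,
    rng_seed = rng_seed
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic resection cohort configuration\n")
  cat(sprintf("  brain radius        : %g mm (generated at %g mm%s)\n",
              x$brain_radius_mm, x$voxel_size_mm,
              if (x$analysis_voxel_size_mm != x$voxel_size_mm)
                sprintf(", analyzed at %g mm", x$analysis_voxel_size_mm)
              else ""))
  cat(sprintf("  patients per cohort : %d\n", x$n_patients_per_cohort))
  cat(sprintf("  tumor diameter      : %g mm, extent of resection %g%%\n",
              x$tumor_diameter_mm, 100 * x$extent_of_resection))
  cat(sprintf("  effect region       : %g mm sphere at (%s) mm\n",
              x$effect_region_diameter_mm,
              paste(x$effect_region_center, collapse = ", ")))
  cat(sprintf("  avoidance Pr        : A %g, B %g\n", x$p_avoid_A, x$p_avoid_B))
  invisible(x)
}

# Internal grid helpers: an odd-sized cubic grid centered on the brain
# center, voxel centers at (i - (n+1)/2) * h mm.
grid_dim <- function(radius_mm, voxel_mm) {
  2L * as.integer(ceiling(radius_mm / voxel_mm)) + 1L
}

axis_coords <- function(n, voxel_mm) {
  (seq_len(n) - (n + 1) / 2) * voxel_mm
}

# Squared distance of every voxel center to a point (mm), as an n^3 array.
grid_dist2 <- function(n, voxel_mm, center = c(0, 0, 0)) {
  ax <- axis_coords(n, voxel_mm)
  dx2 <- (ax - center[1])^2
  dy2 <- (ax - center[2])^2
  dz2 <- (ax - center[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+")
}
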