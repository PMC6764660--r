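#' Spherical brain mask
#'
#' Builds the binary brain mask on an isotropic cubic grid just large enough
#' to contain the brain sphere. A voxel belongs to the sphere iff its center
#' lies within \code{brain_radius_mm} of the grid center. At the default
#' 74 mm radius and 1 mm voxels the mask holds about 1.7 million voxels,
#' matching the brain mask of a 1 mm atlas.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return A 3-D logical array with attribute \code{voxel_size_mm}.
#' @examples
#' sum(make_brain_mask(sim_config(voxel_size_mm = 4)))
#' @export
make_brain_mask <- function(cfg) {
  n <- grid_dim(cfg$brain_radius_mm, cfg$voxel_size_mm)
  mask <- grid_dist2(n, cfg$voxel_size_mm) <= cfg$brain_radius_mm^2
  attr(mask, "voxel_size_mm") <- cfg$voxel_size_mm
  mask
}

#' Surgical-avoidance (effect) region mask
#'
#' The spherical region, fixed in atlas space and shared by all patients, in
#' which the two practices differ: with probability \code{p_avoid} a
#' patient's planned resection cavity is pruned of this region so that any
#' tumor inside it is left as residue. Serves as the ground-truth positive
#' set when benchmarking.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return A 3-D logical array on the same grid as
#'   \code{\link{make_brain_mask}}.
#' @export
effect_region_mask <- function(cfg) {
  n <- grid_dim(cfg$brain_radius_mm, cfg$voxel_size_mm)
  mask <- grid_dist2(n, cfg$voxel_size_mm, cfg$effect_region_center) <=
    (cfg$effect_region_diameter_mm / 2)^2
  attr(mask, "voxel_size_mm") <- cfg$voxel_size_mm
  mask
}

#' Smallest cavity radius covering a target fraction of a tumor
#'
#' Given a binary tumor mask and a cavity center, returns the smallest
#' radius whose sphere, intersected with the tumor, covers at least
#' \code{target_fraction} of the tumor's voxels. Computed exactly as the
#' k-th smallest voxel-center distance from the cavity center, with
#' \code{k = ceiling(target_fraction * n_tumor_voxels)}.
#'
#' @param tumor 3-D logical tumor mask.
#' @param cavity_center Integer voxel indices (i, j, k) of the cavity
#'   center; must lie inside the tumor.
#' @param target_fraction Fraction in (0, 1] of tumor voxels to cover.
#' @param voxel_size_mm Voxel edge length in mm (defaults to the mask's
#'   \code{voxel_size_mm} attribute, or 1).
#' @return The cavity radius in mm.
#' @export
fit_cavity_radius <- function(tumor, cavity_center, target_fraction,
                              voxel_size_mm = NULL) {
  if (target_fraction > 1 || target_fraction <= 0)
    stop("target_fraction must be in (0, 1]")
  if (is.null(voxel_size_mm))
    voxel_size_mm <- attr(tumor, "voxel_size_mm") %||% 1
  cavity_center <- as.integer(round(cavity_center))
  if (!isTRUE(tumor[cavity_center[1], cavity_center[2], cavity_center[3]]))
    stop("cavity_center must lie inside the tumor mask")
  idx <- which(tumor)
  ijk <- arrayInd(idx, dim(tumor))
  d2 <- ((ijk[, 1] - cavity_center[1])^2 +
         (ijk[, 2] - cavity_center[2])^2 +
         (ijk[, 3] - cavity_center[3])^2) * voxel_size_mm^2
  k <- ceiling(target_fraction * length(d2))
  sqrt(sort(d2, partial = k)[k])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Internal precomputed geometry shared across patients of one simulation:
# fine-grid dimensions and axis coordinates, brain voxel indices (for
# uniform tumor-center sampling), and the analysis-grid decimation factor.
cohort_geometry <- function(cfg) {
  key <- paste(cfg$brain_radius_mm, cfg$voxel_size_mm,
               cfg$analysis_voxel_size_mm, sep = "|")
  hit <- .geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  geom <- cohort_geometry_build(cfg)
  .geom_cache[[key]] <- geom
  geom
}

.geom_cache <- new.env(parent = emptyenv())

cohort_geometry_build <- function(cfg) {
  n <- grid_dim(cfg$brain_radius_mm, cfg$voxel_size_mm)
  ax <- axis_coords(n, cfg$voxel_size_mm)
  brain_idx <- which(grid_dist2(n, cfg$voxel_size_mm) <=
                     cfg$brain_radius_mm^2)
  f <- as.integer(round(cfg$analysis_voxel_size_mm / cfg$voxel_size_mm))
  nc <- as.integer(ceiling(n / f))
  list(n = n, dim = c(n, n, n), ax = ax, brain_idx = brain_idx,
       factor = f, nc = nc,
       out_dim = if (f == 1L) c(n, n, n) else c(nc, nc, nc))
}

# a[i] + b[j] + c[k] as a 3-D array
outer3 <- function(a, b, c) outer(outer(a, b, "+"), c, "+")

# Core patient draw on precomputed geometry, working in the tumor's
# bounding box only (C++ kernel). Returns linear voxel indices of tumor
# and residue on the analysis grid (majority-rule sub-sampled when
# factor > 1).
draw_patient <- function(cfg, geom, cohort) {
  h <- cfg$voxel_size_mm
  n <- geom$n
  ax <- geom$ax
  rt <- cfg$tumor_diameter_mm / 2

  tci <- arrayInd(geom$brain_idx[sample.int(length(geom$brain_idx), 1L)],
                  geom$dim)
  tc <- ax[tci]
  w <- ceiling(rt / h)
  rng <- lapply(1:3, function(a) max(1L, tci[a] - w):min(n, tci[a] + w))
  xs <- ax[rng[[1]]]; ys <- ax[rng[[2]]]; zs <- ax[rng[[3]]]

  cavity_u <- stats::runif(1)
  p_avoid <- if (cohort == "A") cfg$p_avoid_A else cfg$p_avoid_B
  avoided <- stats::runif(1) < p_avoid

  kern <- .patient_kernel(xs, ys, zs, as.numeric(tc), rt^2,
                          cfg$brain_radius_mm^2, cavity_u,
                          cfg$extent_of_resection, avoided,
                          as.numeric(cfg$effect_region_center),
                          (cfg$effect_region_diameter_mm / 2)^2)
  idx_t <- kern$idx_t
  idx_r <- kern$idx_r

  f <- geom$factor
  if (f == 1L) {
    gidx <- outer3(rng[[1]], (rng[[2]] - 1) * n, (rng[[3]] - 1) * n^2)
    list(tumor = gidx[idx_t], residue = gidx[idx_r],
         cohort = cohort, avoided = avoided)
  } else {
    nc <- geom$nc
    bid <- outer3((rng[[1]] - 1L) %/% f + 1L,
                  ((rng[[2]] - 1L) %/% f) * nc,
                  ((rng[[3]] - 1L) %/% f) * nc^2)
    half <- f^3 / 2
    nb <- nc^3
    list(tumor = which(tabulate(bid[idx_t], nb) >= half),
         residue = which(tabulate(bid[idx_r], nb) >= half),
         cohort = cohort, avoided = avoided)
  }
}

indices_to_mask <- function(idx, dim, voxel_size_mm) {
  m <- array(FALSE, dim)
  m[idx] <- TRUE
  attr(m, "voxel_size_mm") <- voxel_size_mm
  m
}

#' Simulate one synthetic patient
#'
#' Draws a spherical tumor centered uniformly over brain-interior voxel
#' centers, then a spherical resection cavity centered uniformly over tumor
#' voxel centers, with radius fitted so the cavity covers the configured
#' extent of resection of the (in-brain) tumor volume, leaving a crescent
#' residue. With the cohort's avoidance probability, the effect region is
#' subtracted from the planned cavity before it is applied, so tumor inside
#' the region is left behind. Tumor and residue are cropped to the brain.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param brain Brain mask from \code{\link{make_brain_mask}} (used for its
#'   grid; may be \code{NULL} to derive from \code{cfg}).
#' @param effect Effect-region mask (unused when \code{NULL}; derived from
#'   \code{cfg}).
#' @param cohort \code{"A"} or \code{"B"}.
#' @return An object of class \code{"patient_case"}: a list with logical
#'   3-D \code{tumor} and \code{residue} masks, the \code{cohort} label and
#'   whether the avoidance region was spared (\code{avoided}).
#' @export
simulate_patient <- function(cfg, brain = NULL, effect = NULL, cohort = "A") {
  stopifnot(cohort %in% c("A", "B"))
  fine_cfg <- cfg
  fine_cfg$analysis_voxel_size_mm <- cfg$voxel_size_mm  # generation grid
  geom <- cohort_geometry(fine_cfg)
  pc <- draw_patient(fine_cfg, geom, cohort)
  new_patient_case(pc, geom$dim, cfg$voxel_size_mm)
}

new_patient_case <- function(pc, dim, voxel_size_mm) {
  structure(list(
    tumor = indices_to_mask(pc$tumor, dim, voxel_size_mm),
    residue = indices_to_mask(pc$residue, dim, voxel_size_mm),
    cohort = pc$cohort, avoided = pc$avoided
  ), class = "patient_case")
}

#' @export
print.patient_case <- function(x, ...) {
  cat(sprintf("Patient case (cohort %s): %d tumor voxels, %d residue voxels%s\n",
              x$cohort, sum(x$tumor), sum(x$residue),
              if (isTRUE(x$avoided)) ", avoidance region spared" else ""))
  invisible(x)
}

#' Simulate two synthetic patient cohorts
#'
#' Generates \code{n_patients_per_cohort} patients for each of cohorts A
#' and B under identical generative distributions except for the surgical
#' avoidance probability inside the effect region.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param seed Optional integer seed (defaults to \code{cfg$rng_seed}).
#' @param compact Internal: when \code{TRUE}, cases carry voxel index
#'   vectors instead of full masks (used by the benchmark loop).
#' @return An object of class \code{"cohort_sim"}: list with \code{cases}
#'   (list of \code{patient_case}), \code{effect} and \code{brain} masks,
#'   and the \code{config}.
#' @examples
#' cs <- simulate_cohorts(sim_config(brain_radius_mm = 30, voxel_size_mm = 6,
#'                                   tumor_diameter_mm = 30,
#'                                   effect_region_diameter_mm = 12,
#'                                   effect_region_center = c(12, 0, 0),
#'                                   n_patients_per_cohort = 4), seed = 1)
#' table(vapply(cs$cases, function(p) p$cohort, ""))
#' @export
simulate_cohorts <- function(cfg, seed = cfg$rng_seed, compact = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  geom <- cohort_geometry(cfg)
  draws <- c(
    lapply(seq_len(cfg$n_patients_per_cohort),
           function(i) draw_patient(cfg, geom, "A")),
    lapply(seq_len(cfg$n_patients_per_cohort),
           function(i) draw_patient(cfg, geom, "B"))
  )
  out_vox <- cfg$analysis_voxel_size_mm
  cases <- if (compact) {
    lapply(draws, function(pc) {
      structure(c(pc, list(dim = geom$out_dim, voxel_size_mm = out_vox)),
                class = "patient_indices")
    })
  } else {
    lapply(draws, new_patient_case, dim = geom$out_dim,
           voxel_size_mm = out_vox)
  }
  masks <- region_masks(cfg, geom)
  structure(list(cases = cases, effect = masks$effect,
                 brain = masks$brain, config = cfg),
            class = "cohort_sim")
}

# Effect-region and brain masks on the analysis grid, cached per
# configuration (they are deterministic given the geometry).
region_masks <- function(cfg, geom) {
  key <- paste(cfg$brain_radius_mm, cfg$voxel_size_mm,
               cfg$analysis_voxel_size_mm,
               paste(cfg$effect_region_center, collapse = ","),
               cfg$effect_region_diameter_mm, sep = "|")
  hit <- .geom_cache[[paste0("masks|", key)]]
  if (!is.null(hit)) return(hit)
  n <- geom$n
  eff_fine <- grid_dist2(n, cfg$voxel_size_mm, cfg$effect_region_center) <=
    (cfg$effect_region_diameter_mm / 2)^2
  brain_fine <- indices_to_mask(geom$brain_idx, geom$dim, cfg$voxel_size_mm)
  attr(eff_fine, "voxel_size_mm") <- cfg$voxel_size_mm
  out <- if (geom$factor > 1L) {
    list(effect = downsample_mask(eff_fine, geom$factor),
         brain = downsample_mask(brain_fine, geom$factor))
  } else {
    list(effect = eff_fine, brain = brain_fine)
  }
  .geom_cache[[paste0("masks|", key)]] <- out
  out
}

#' @export
print.cohort_sim <- function(x, ...) {
  nA <- sum(vapply(x$cases, function(p) p$cohort == "A", NA))
  cat(sprintf(
    "Synthetic cohorts: %d + %d patients on a %s grid (%g mm voxels)\n",
    nA, length(x$cases) - nA,
    paste(dim(x$effect), collapse = "x"), x$config$voxel_size_mm))
  invisible(x)
}
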