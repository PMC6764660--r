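#' Aggregate per-patient masks into per-voxel contingency counts
#'
#' For every voxel, counts the cohort-A and cohort-B patients whose tumor
#' covers the voxel (\code{t_A}, \code{t_B}) and whose residue covers it
#' (\code{r_A}, \code{r_B}). These four counts are the per-voxel 2x2
#' contingency data on which all three statistical methods operate.
#'
#' @param cases List of \code{patient_case} objects sharing one grid.
#' @param dim Grid dimensions, required only when \code{cases} is empty.
#' @param voxel_size_mm Voxel size, used when \code{cases} is empty.
#' @return An object of class \code{"count_map"}: integer 3-D arrays
#'   \code{t_A}, \code{r_A}, \code{t_B}, \code{r_B}, plus grid geometry and
#'   cohort sizes \code{n_A}, \code{n_B}.
#' @export
aggregate_counts <- function(cases, dim = NULL, voxel_size_mm = 1) {
  if (length(cases) == 0) {
    if (is.null(dim)) stop("dim must be given for an empty case list")
    z <- array(0L, dim)
    return(new_count_map(z, z, z, z, voxel_size_mm, 0L, 0L))
  }
  dm <- case_dim(cases[[1]])
  for (p in cases)
    if (!identical(case_dim(p), dm))
      stop("all cases must share one grid")
  vox <- attr(cases[[1]]$tumor, "voxel_size_mm") %||%
    cases[[1]]$voxel_size_mm %||% voxel_size_mm
  tA <- rA <- tB <- rB <- array(0L, dm)
  nA <- nB <- 0L
  for (p in cases) {
    ti <- case_indices(p, "tumor"); ri <- case_indices(p, "residue")
    if (p$cohort == "A") {
      tA[ti] <- tA[ti] + 1L; rA[ri] <- rA[ri] + 1L; nA <- nA + 1L
    } else {
      tB[ti] <- tB[ti] + 1L; rB[ri] <- rB[ri] + 1L; nB <- nB + 1L
    }
  }
  new_count_map(tA, rA, tB, rB, vox, nA, nB)
}

case_dim <- function(p) {
  if (inherits(p, "patient_indices")) p$dim else dim(p$tumor)
}

case_indices <- function(p, field) {
  if (inherits(p, "patient_indices")) p[[field]] else which(p[[field]])
}

new_count_map <- function(tA, rA, tB, rB, voxel_size_mm, nA, nB) {
  structure(list(t_A = tA, r_A = rA, t_B = tB, r_B = rB,
                 dim = dim(tA), voxel_size_mm = voxel_size_mm,
                 n_A = nA, n_B = nB),
            class = "count_map")
}

#' @export
print.count_map <- function(x, ...) {
  cat(sprintf("Count map on a %s grid (%g mm voxels): %d + %d patients\n",
              paste(x$dim, collapse = "x"), x$voxel_size_mm, x$n_A, x$n_B))
  cat(sprintf("  voxels with any tumor: %d (max t_A+t_B = %d)\n",
              sum(x$t_A + x$t_B > 0), max(x$t_A + x$t_B)))
  invisible(x)
}

#' Downsample a binary mask by an integer factor
#'
#' Aggregates each \code{factor^3} block of fine voxels into one coarse
#' voxel. Under the default \code{"majority"} rule a coarse voxel is set
#' iff at least 50% of its fine voxels are set; under \code{"any"} iff at
#' least one is. Masks whose dimensions are not divisible by the factor are
#' zero-padded at the upper end.
#'
#' @param mask 3-D logical (or 0/1) array.
#' @param factor Integer downsampling factor, \code{>= 1}.
#' @param rule \code{"majority"} or \code{"any"}.
#' @return Downsampled logical array; the \code{voxel_size_mm} attribute,
#'   when present, is multiplied by \code{factor}.
#' @export
downsample_mask <- function(mask, factor, rule = c("majority", "any")) {
  rule <- match.arg(rule)
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1L) return(mask)
  vox <- attr(mask, "voxel_size_mm")
  dm <- dim(mask)
  pad <- (factor - dm %% factor) %% factor
  if (any(pad > 0)) {
    padded <- array(FALSE, dm + pad)
    padded[seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3])] <- mask
    mask <- padded
    dm <- dim(mask)
  }
  counts <- block_sum(mask + 0, factor)
  out <- if (rule == "majority") counts >= factor^3 / 2 else counts >= 1
  if (!is.null(vox)) attr(out, "voxel_size_mm") <- vox * factor
  out
}

# Sum over factor^3 blocks by collapsing one axis at a time.
block_sum <- function(x, f) {
  for (ax in 1:3) {
    dm <- dim(x)
    dim(x) <- c(f, dm[1] / f, dm[2], dm[3])
    x <- colSums(x)            # collapse leading factor -> (d1/f, d2, d3)
    x <- aperm(x, c(2, 3, 1))  # rotate so next axis leads
  }
  x
}

#' Voxels with enough observed tumors to test
#'
#' The permutation method excludes voxels observed in too few patients:
#' only voxels with \code{t_A + t_B >= min_total_tumors} are tested (the
#' original analysis removed voxels with fewer than 6).
#'
#' @param cm A \code{\link{aggregate_counts}} count map.
#' @param min_total_tumors Minimum total tumor count (inclusive).
#' @return Integer vector of linear voxel indices.
#' @export
tested_voxels <- function(cm, min_total_tumors = 6) {
  stopifnot(min_total_tumors >= 0)
  which(cm$t_A + cm$t_B >= min_total_tumors)
}

#' Load a clinical cohort of registered NIfTI mask pairs
#'
#' Reads per-patient pre-operative tumor and post-operative residue masks,
#' already registered to a common atlas grid, and binarizes them at
#' strictly positive intensity. Residue voxels falling outside the tumor
#' (possible with independent clinical segmentations) trigger a warning
#' with the voxel count and are clipped to the tumor.
#'
#' @param manifest Data frame (or path to a CSV) with columns
#'   \code{tumor_path}, \code{residue_path}, \code{cohort}.
#' @return List of \code{patient_case} objects.
#' @export
load_clinical_cohort <- function(manifest) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  stopifnot(all(c("tumor_path", "residue_path", "cohort") %in%
                names(manifest)))
  ref_dim <- NULL
  lapply(seq_len(nrow(manifest)), function(i) {
    tum <- RNifti::readNifti(manifest$tumor_path[i])
    res <- RNifti::readNifti(manifest$residue_path[i])
    if (!identical(dim(tum), dim(res)))
      stop("tumor and residue image dimensions differ for row ", i)
    if (!isTRUE(all.equal(RNifti::xform(tum), RNifti::xform(res),
                          tolerance = 1e-4)))
      stop("tumor and residue affines differ for row ", i,
           "; images must be registered to one grid")
    if (is.null(ref_dim)) ref_dim <<- dim(tum)
    else if (!identical(dim(tum), ref_dim))
      stop("all cohort images must share one grid (row ", i, ")")
    tmask <- as.array(tum) > 0
    rmask <- as.array(res) > 0
    outside <- sum(rmask & !tmask)
    if (outside > 0) {
      warning(sprintf(
        "row %d: %d residue voxel(s) outside the tumor mask; clipped",
        i, outside))
      rmask <- rmask & tmask
    }
    vox <- RNifti::pixdim(tum)[1]
    attr(tmask, "voxel_size_mm") <- vox
    attr(rmask, "voxel_size_mm") <- vox
    structure(list(tumor = tmask, residue = rmask,
                   cohort = as.character(manifest$cohort[i]),
                   avoided = NA),
              class = "patient_case")
  })
}

#' Write a cohort of patient cases as NIfTI mask pairs
#'
#' @param cases List of \code{patient_case}.
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @return Invisibly, the manifest data frame describing the written files.
#' @export
write_cohort_nifti <- function(cases, dir, prefix = "case") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(cases), function(i) {
    p <- cases[[i]]
    vox <- attr(p$tumor, "voxel_size_mm") %||% 1
    tpath <- file.path(dir, sprintf("%s%03d_tumor.nii.gz", prefix, i))
    rpath <- file.path(dir, sprintf("%s%03d_residue.nii.gz", prefix, i))
    img_t <- RNifti::asNifti(p$tumor + 0L, pixdim = rep(vox, 3))
    img_r <- RNifti::asNifti(p$residue + 0L, pixdim = rep(vox, 3))
    RNifti::writeNifti(img_t, tpath)
    RNifti::writeNifti(img_r, rpath)
    data.frame(tumor_path = tpath, residue_path = rpath, cohort = p$cohort)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
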