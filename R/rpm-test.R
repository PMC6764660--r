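#' Voxelwise test for practice variation between two surgical cohorts
#'
#' The central fitting function: localizes voxels where the probability of
#' residual tumor differs between cohorts A and B, using one of three
#' methods on the per-voxel tumor/residue contingency counts.
#'
#' \describe{
#'   \item{\code{"fisher"}}{Two-sided Fisher exact p-value per voxel from
#'     the hypergeometric null with fixed marginals, and q-values from an
#'     explicitly constructed exact null histogram of all attainable
#'     p-values over the tested voxels (see
#'     \code{\link{exact_null_histogram}} and
#'     \code{\link{q_from_exact_null}}). Voxels with a degenerate
#'     single-point support (no residues, all residues, or a cohort with
#'     no tumors) carry no information under fixed marginals; they are
#'     reported with p = q = 1 and contribute neither to the null
#'     histogram nor to the voxel count N, which leaves all other voxels'
#'     q-values unchanged whether or not they are included.}
#'   \item{\code{"permutation"}}{Exact-rational risk-minus statistic
#'     \code{|r_A/t_A - r_B/t_B|} per voxel, p-values by cumulative lookup
#'     in a null histogram pooled over all tested voxels and \code{n_perm}
#'     random patient relabelings, and q-values from the empirical
#'     p-value distribution (see \code{\link{permutation_null}},
#'     \code{\link{p_from_null}}, \code{\link{q_from_p}}). Voxels with
#'     fewer than \code{min_tumors} total tumors (default 6) are removed
#'     before testing.}
#'   \item{\code{"bayes"}}{Hierarchical binomial model with partial
#'     pooling across voxels, sampled by MCMC; each voxel is scored by the
#'     probability level of the largest centered credible interval of the
#'     between-cohort resection-rate difference that excludes zero (see
#'     \code{\link{fit_bayes_pooling}} and
#'     \code{\link{hdi_exclusion_level}}).}
#' }
#'
#' @param x A \code{cohort_sim}, a list of \code{patient_case} objects, or
#'   a \code{count_map}. The permutation method needs per-patient cases
#'   (labels are reshuffled at the patient level).
#' @param method One of \code{"fisher"}, \code{"permutation"},
#'   \code{"bayes"}.
#' @param min_tumors Minimum \code{t_A + t_B} for a voxel to be tested.
#'   Defaults: 1 (fisher, bayes), 6 (permutation).
#' @param n_perm Number of permutations (permutation method).
#' @param seed Optional integer seed (permutation and bayes methods).
#' @param ... Passed to \code{\link{fit_bayes_pooling}} for
#'   \code{method = "bayes"} (e.g. \code{chains}, \code{iter},
#'   \code{shared_population}).
#' @return An object of class \code{"rpm_test"} with elements
#'   \code{method}, \code{voxels} (linear indices of tested voxels),
#'   \code{counts} (data frame of t_A, r_A, t_B, r_B), \code{p} and
#'   \code{q} (fisher, permutation) or \code{hdi_level} (bayes),
#'   \code{score} and \code{direction} (\code{"low"} when small scores
#'   mark detections, \code{"high"} otherwise), \code{dim}, and
#'   method-specific extras (\code{stat}, \code{null},
#'   \code{diagnostics}).
#' @examples
#' cfg <- sim_config(brain_radius_mm = 30, voxel_size_mm = 6,
#'                   tumor_diameter_mm = 30, effect_region_diameter_mm = 14,
#'                   effect_region_center = c(10, 0, 0),
#'                   n_patients_per_cohort = 10)
#' cs <- simulate_cohorts(cfg, seed = 7)
#' fit <- rpm_test(cs, method = "fisher")
#' fit
#' @export
rpm_test <- function(x, method = c("fisher", "permutation", "bayes"),
                     min_tumors = NULL, n_perm = 1000, seed = NULL, ...) {
  method <- match.arg(method)
  cases <- NULL
  if (inherits(x, "cohort_sim")) {
    cases <- x$cases
    cm <- aggregate_counts(cases)
  } else if (inherits(x, "count_map")) {
    cm <- x
  } else if (is.list(x)) {
    cases <- x
    cm <- aggregate_counts(cases)
  } else stop("x must be a cohort_sim, a list of patient cases, or a count_map")
  if (is.null(min_tumors))
    min_tumors <- if (method == "permutation") 6 else 1
  vox <- tested_voxels(cm, min_tumors)
  if (length(vox) == 0) stop("no voxels pass the minimum-tumor filter")
  counts <- data.frame(t_A = cm$t_A[vox], r_A = cm$r_A[vox],
                       t_B = cm$t_B[vox], r_B = cm$r_B[vox])
  if (method == "permutation") {
    # observed risk-minus needs both cohorts present at the voxel
    keep <- counts$t_A >= 1 & counts$t_B >= 1
    vox <- vox[keep]
    counts <- counts[keep, , drop = FALSE]
    if (length(vox) == 0) stop("no voxels observed in both cohorts")
  }
  fit <- switch(method,
    fisher = rpm_fisher(counts),
    permutation = rpm_permutation(cases, cm, vox, counts, n_perm, seed),
    bayes = rpm_bayes(counts, seed = seed, ...))
  structure(c(list(method = method, voxels = vox, counts = counts,
                   dim = cm$dim, voxel_size_mm = cm$voxel_size_mm,
                   n_A = cm$n_A, n_B = cm$n_B, min_tumors = min_tumors,
                   call = sys.call()),
              fit),
            class = "rpm_test")
}

rpm_fisher <- function(counts) {
  with(counts, {
    r <- r_A + r_B
    t <- t_A + t_B
    informative <- r > 0 & r < t & t_A > 0 & t_B > 0
    p <- rep(1, nrow(counts))
    p[informative] <- fisher_two_sided_p(t_A[informative], r_A[informative],
                                         t_B[informative], r_B[informative])
    q <- rep(1, nrow(counts))
    null <- NULL
    if (any(informative)) {
      tabs <- data.frame(t_A = t_A[informative], t_B = t_B[informative],
                         r = r[informative])
      keyed <- paste(tabs$t_A, tabs$t_B, tabs$r)
      uniq <- !duplicated(keyed)
      null <- exact_null_histogram(tabs[uniq, , drop = FALSE],
                                   weights = as.numeric(table(keyed)[keyed[uniq]]))
      q[informative] <- q_from_exact_null(p[informative], null)
    }
    list(p = p, q = q, score = q, direction = "low",
         informative = informative, null = null)
  })
}

rpm_permutation <- function(cases, cm, vox, counts, n_perm, seed) {
  if (is.null(cases))
    stop("the permutation method needs per-patient cases, not a count map")
  stat <- with(counts, abs(r_A * t_B - r_B * t_A) / (t_A * t_B))
  null <- permutation_null(cases, vox, n_perm = n_perm, seed = seed)
  p <- p_from_null(stat, null)
  q <- q_from_p(p)
  list(stat = stat, p = p, q = q, score = q, direction = "low", null = null)
}

rpm_bayes <- function(counts, seed = NULL, ...) {
  fit <- fit_bayes_pooling(counts, seed = seed, ...)
  list(hdi_level = fit$hdi_level, score = fit$hdi_level, direction = "high",
       delta_mean = fit$delta_mean, diagnostics = fit$diagnostics,
       theta_mean = fit$theta_mean)
}

#' @export
print.rpm_test <- function(x, ...) {
  cat(sprintf("Voxelwise practice-variation test (%s method)\n", x$method))
  cat(sprintf("  cohorts: %d (A) vs %d (B) patients\n", x$n_A, x$n_B))
  cat(sprintf("  tested voxels: %d (t_A + t_B >= %g) on a %s grid\n",
              length(x$voxels), x$min_tumors,
              paste(x$dim, collapse = "x")))
  if (x$method == "bayes") {
    cat(sprintf("  HDI exclusion level: median %.3f, max %.3f\n",
                stats::median(x$hdi_level), max(x$hdi_level)))
  } else {
    cat(sprintf("  q-values: min %.4f, median %.4f\n",
                min(x$q), stats::median(x$q)))
    for (thr in c(0.05, 0.1, 0.25))
      cat(sprintf("  voxels with q <= %.2f: %d\n", thr, sum(x$q <= thr)))
  }
  invisible(x)
}

#' @export
summary.rpm_test <- function(object, n_top = 10, ...) {
  df <- as.data.frame(object)
  df$score <- object$score
  df <- df[order(df$score, decreasing = object$direction == "high"), ]
  structure(list(method = object$method, n_tested = nrow(df),
                 top = utils::head(df, n_top),
                 score_summary = summary(df$score)),
            class = "summary.rpm_test")
}

#' @export
print.summary.rpm_test <- function(x, ...) {
  cat(sprintf("%s method, %d tested voxels\n", x$method, x$n_tested))
  cat("Score distribution:\n"); print(x$score_summary)
  cat(sprintf("Top %d voxels:\n", nrow(x$top)))
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.rpm_test <- function(x, ...) {
  ijk <- arrayInd(x$voxels, x$dim)
  df <- data.frame(voxel = x$voxels, i = ijk[, 1], j = ijk[, 2],
                   k = ijk[, 3], x$counts)
  if (!is.null(x$stat)) df$stat <- x$stat
  if (!is.null(x$p)) df$p <- x$p
  if (!is.null(x$q)) df$q <- x$q
  if (!is.null(x$hdi_level)) df$hdi_level <- x$hdi_level
  df
}

#' Extract the per-voxel score map as a 3-D array
#'
#' @param x An \code{rpm_test} object.
#' @param fill Value for untested voxels (default \code{NA}).
#' @return 3-D numeric array of q-values (fisher, permutation) or HDI
#'   exclusion levels (bayes).
#' @export
score_map <- function(x, fill = NA_real_) {
  stopifnot(inherits(x, "rpm_test"))
  m <- array(fill, x$dim)
  m[x$voxels] <- x$score
  m
}

#' @export
plot.rpm_test <- function(x, slice = NULL, ...) {
  m <- score_map(x)
  if (is.null(slice)) slice <- ceiling(x$dim[3] / 2)
  img <- m[, , slice]
  graphics::image(seq_len(x$dim[1]), seq_len(x$dim[2]), img,
                  col = grDevices::hcl.colors(64, "viridis", rev = x$direction == "low"),
                  xlab = "i", ylab = "j",
                  main = sprintf("%s %s, slice k=%d", x$method,
                                 if (x$method == "bayes") "HDI level" else "q-value",
                                 slice), ...)
  invisible(x)
}

#' Write the score map of a fitted test as NIfTI and CSV
#'
#' @param x An \code{rpm_test} object.
#' @param prefix Output path prefix; writes \code{<prefix>.nii.gz} and
#'   \code{<prefix>.csv}.
#' @return Invisibly, the paths written.
#' @export
write_rpm_test <- function(x, prefix) {
  stopifnot(inherits(x, "rpm_test"))
  m <- score_map(x, fill = NA_real_)
  img <- RNifti::asNifti(m, pixdim = rep(x$voxel_size_mm, 3))
  nii <- paste0(prefix, ".nii.gz")
  csv <- paste0(prefix, ".csv")
  RNifti::writeNifti(img, nii)
  utils::write.csv(as.data.frame(x), csv, row.names = FALSE)
  invisible(c(nii, csv))
}
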