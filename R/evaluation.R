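#' Observed false-discovery-rate curve against a ground-truth region
#'
#' For each cut-off on the per-voxel score, voxels are declared different
#' (score \code{<=} cut-off when \code{direction = "low"}, \code{>=} when
#' \code{"high"}) and the observed FDR is the fraction of declared voxels
#' lying outside the true effect region. Undefined (NA) where no voxel is
#' declared.
#'
#' @param scores Per-voxel scores over the tested voxels.
#' @param truth Logical vector (same length) marking tested voxels inside
#'   the true effect region.
#' @param direction \code{"low"} if small scores mark detections
#'   (q-values) or \code{"high"} (HDI levels).
#' @param cutoffs Cut-off grid; defaults to the unique observed scores.
#' @return Data frame with \code{cutoff}, \code{n_declared},
#'   \code{fdr}.
#' @export
observed_fdr_curve <- function(scores, truth, direction = c("low", "high"),
                               cutoffs = NULL) {
  direction <- match.arg(direction)
  stopifnot(length(scores) == length(truth))
  if (is.null(cutoffs)) cutoffs <- sort(unique(scores))
  s <- if (direction == "low") -scores else scores
  cs <- if (direction == "low") -cutoffs else cutoffs
  o <- order(s, decreasing = TRUE)
  s_sorted <- s[o]
  fp_cum <- cumsum(!truth[o])
  n_cum <- seq_along(s_sorted)
  idx <- findInterval(-cs, -s_sorted)  # declared count at each cutoff
  n_declared <- ifelse(idx == 0, 0L, n_cum[pmax(idx, 1)])
  fp <- ifelse(idx == 0, 0L, fp_cum[pmax(idx, 1)])
  data.frame(cutoff = cutoffs, n_declared = n_declared,
             fdr = ifelse(n_declared == 0, NA_real_, fp / n_declared))
}

#' ROC and precision-recall curves with AUC
#'
#' Ranks tested voxels by score (with the stated direction), groups tied
#' scores, and sweeps the threshold to build the ROC (false positive rate
#' vs true positive rate) and precision-recall curves. The area under the
#' ROC is computed by the trapezoid rule, equivalent to the tie-corrected
#' rank statistic.
#'
#' @inheritParams observed_fdr_curve
#' @return A list of class \code{"roc_prc"} with \code{roc} (data frame
#'   \code{threshold}, \code{fpr}, \code{tpr}), \code{prc}
#'   (\code{threshold}, \code{recall}, \code{precision}) and \code{auc}.
#' @examples
#' roc_prc_auc(c(.1, .2, .3, .4), c(TRUE, TRUE, FALSE, FALSE), "low")$auc
#' @export
roc_prc_auc <- function(scores, truth, direction = c("low", "high")) {
  direction <- match.arg(direction)
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth))
  P <- sum(truth); Nn <- sum(!truth)
  if (P == 0 || Nn == 0)
    stop("both classes must be present among the tested voxels")
  s <- if (direction == "low") -scores else scores
  o <- order(s, decreasing = TRUE)
  s_sorted <- s[o]
  tp <- cumsum(truth[o])
  fp <- cumsum(!truth[o])
  last <- !duplicated(s_sorted, fromLast = TRUE)  # last index of each tie group
  tp <- tp[last]; fp <- fp[last]
  thr <- if (direction == "low") -s_sorted[last] else s_sorted[last]
  tpr <- c(0, tp / P); fpr <- c(0, fp / Nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  roc <- data.frame(threshold = c(thr[1], thr), fpr = fpr, tpr = tpr)
  prc <- data.frame(threshold = thr, recall = tp / P,
                    precision = tp / (tp + fp))
  structure(list(roc = roc, prc = prc, auc = auc), class = "roc_prc")
}

#' @export
print.roc_prc <- function(x, ...) {
  cat(sprintf("ROC/PRC curves over %d thresholds; AUC = %.4f\n",
              nrow(x$prc), x$auc))
  invisible(x)
}

#' Evaluate a fitted voxelwise test against the simulated effect region
#'
#' Restricts the ground-truth avoidance sphere to the tested voxels
#' (untested voxels never enter any curve) and computes the observed-FDR
#' curve, ROC/PRC curves and AUC for the fit's score map.
#'
#' @param fit An \code{\link{rpm_test}} object.
#' @param effect Effect-region mask on the fit's grid (or a
#'   \code{cohort_sim}).
#' @param cutoffs Cut-off grid for the FDR curve.
#' @return A list with \code{truth}, \code{fdr}, \code{roc_prc},
#'   \code{auc}.
#' @export
evaluate_fit <- function(fit, effect, cutoffs = seq(0, 1, by = 0.02)) {
  stopifnot(inherits(fit, "rpm_test"))
  if (inherits(effect, "cohort_sim")) effect <- effect$effect
  truth <- effect[fit$voxels]
  rp <- roc_prc_auc(fit$score, truth, fit$direction)
  fdr <- observed_fdr_curve(fit$score, truth, fit$direction,
                            cutoffs = cutoffs)
  list(truth = truth, fdr = fdr, roc_prc = rp, auc = rp$auc)
}

#' Run a repeated synthetic benchmark of one method
#'
#' Repeats the full pipeline -- simulate two cohorts, aggregate counts,
#' fit the voxelwise test, score against the true avoidance region --
#' \code{n_repetitions} times, each repetition with its own seed
#' (\code{base seed + repetition index}), and aggregates per-repetition
#' AUC values and observed-FDR curves into percentile bands.
#'
#' @param cfg A \code{\link{sim_config}}; \code{cfg$rng_seed} (or
#'   \code{seed}) is the base seed.
#' @param method \code{"fisher"}, \code{"permutation"} or \code{"bayes"}.
#' @param n_repetitions Number of repetitions.
#' @param seed Base seed (defaults to \code{cfg$rng_seed}, or 0).
#' @param cutoffs Common cut-off grid for FDR aggregation.
#' @param keep_fits Keep each repetition's fitted object (memory-heavy).
#' @param ... Passed to \code{\link{rpm_test}} (e.g. \code{n_perm},
#'   \code{min_tumors}, \code{chains}).
#' @return Object of class \code{"eval_curves"}: per-repetition
#'   \code{auc}, its mean and 2.5/50/97.5 percentiles, the FDR matrix
#'   (repetitions x cutoffs) with percentile bands, and the pooled-over-
#'   repetitions mean AUC alternative (\code{auc_pooled}).
#' @export
run_benchmark <- function(cfg, method = c("fisher", "permutation", "bayes"),
                          n_repetitions = cfg$n_repetitions,
                          seed = NULL, cutoffs = seq(0, 1, by = 0.02),
                          keep_fits = FALSE, ...) {
  method <- match.arg(method)
  base_seed <- seed %||% cfg$rng_seed %||% 0
  auc <- numeric(n_repetitions)
  fdr <- matrix(NA_real_, n_repetitions, length(cutoffs))
  fits <- if (keep_fits) vector("list", n_repetitions) else NULL
  pooled_scores <- list(); pooled_truth <- list()
  for (rep_i in seq_len(n_repetitions)) {
    cs <- simulate_cohorts(cfg, seed = base_seed + rep_i, compact = TRUE)
    fit <- rpm_test(cs, method = method, seed = base_seed + rep_i, ...)
    ev <- evaluate_fit(fit, cs$effect, cutoffs = cutoffs)
    auc[rep_i] <- ev$auc
    fdr[rep_i, ] <- ev$fdr$fdr
    pooled_scores[[rep_i]] <- fit$score
    pooled_truth[[rep_i]] <- ev$truth
    if (keep_fits) fits[[rep_i]] <- fit
  }
  direction <- if (method == "bayes") "high" else "low"
  auc_pooled <- roc_prc_auc(unlist(pooled_scores), unlist(pooled_truth),
                            direction)$auc
  qtl <- function(v) stats::quantile(v, c(0.025, 0.5, 0.975), na.rm = TRUE)
  structure(list(
    method = method, config = cfg, n_repetitions = n_repetitions,
    cutoffs = cutoffs,
    auc = auc, auc_mean = mean(auc), auc_bands = qtl(auc),
    auc_pooled = auc_pooled,
    fdr = fdr,
    fdr_median = apply(fdr, 2, stats::median, na.rm = TRUE),
    fdr_bands = apply(fdr, 2, qtl),
    fits = fits
  ), class = "eval_curves")
}

#' @export
print.eval_curves <- function(x, ...) {
  cat(sprintf("Benchmark of the %s method, %d repetitions\n",
              x$method, x$n_repetitions))
  cat(sprintf("  mean AUC %.3f (2.5%% %.3f, median %.3f, 97.5%% %.3f)\n",
              x$auc_mean, x$auc_bands[1], x$auc_bands[2], x$auc_bands[3]))
  defined <- !is.na(x$fdr_median)
  if (any(defined))
    cat(sprintf("  median observed FDR at cutoff %.2f: %.3f\n",
                x$cutoffs[max(which(defined))],
                x$fdr_median[max(which(defined))]))
  invisible(x)
}

#' @export
plot.eval_curves <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  ok <- !is.na(x$fdr_median)
  graphics::plot(x$cutoffs[ok], x$fdr_median[ok], type = "s",
                 xlim = c(0, 1), ylim = c(0, 1),
                 xlab = if (x$method == "bayes") "HDI level cut-off"
                        else "q cut-off",
                 ylab = "observed FDR",
                 main = sprintf("%s: FDR vs cut-off", x$method))
  graphics::lines(x$cutoffs[ok], x$fdr_bands[1, ok], lty = 3)
  graphics::lines(x$cutoffs[ok], x$fdr_bands[3, ok], lty = 3)
  if (x$method != "bayes") graphics::abline(0, 1, col = "grey")
  graphics::hist(x$auc, breaks = 10, xlab = "per-repetition AUC",
                 main = sprintf("mean AUC %.3f", x$auc_mean))
  invisible(x)
}

#' Sweep one generative parameter and benchmark each value
#'
#' @param base A \code{\link{sim_config}} used for all non-swept
#'   parameters.
#' @param axis One of \code{"tumor_diameter_mm"},
#'   \code{"n_patients_per_cohort"}, \code{"effect_region_diameter_mm"},
#'   \code{"extent_of_resection"}, \code{"avoidance_contrast"},
#'   \code{"voxel_size_mm"}. An avoidance contrast \code{c} sets
#'   \code{p_avoid_A = (1 - c)/2} and \code{p_avoid_B = (1 + c)/2}
#'   (e.g. contrast 0.8 is 10\% vs 90\%).
#' @param values Parameter values to sweep.
#' @param method Statistical method to benchmark.
#' @param n_repetitions Repetitions per value.
#' @param seed Base seed; value \code{k} of the sweep uses
#'   \code{seed + (k - 1) * 10 * n_repetitions} so repetitions never
#'   overlap across values.
#' @param ... Passed to \code{\link{run_benchmark}}.
#' @return Data frame of class \code{"rpm_sweep"} with one row per value:
#'   mean AUC and 2.5/97.5 percentile bands.
#' @export
parameter_sweep <- function(base, axis, values,
                            method = "fisher", n_repetitions = 50,
                            seed = base$rng_seed %||% 0, ...) {
  axis <- match.arg(axis, c("tumor_diameter_mm", "n_patients_per_cohort",
                            "effect_region_diameter_mm",
                            "extent_of_resection", "avoidance_contrast",
                            "voxel_size_mm"))
  rows <- lapply(seq_along(values), function(k) {
    cfg_args <- unclass(base)
    cfg_args$rng_seed <- NULL
    if (axis == "avoidance_contrast") {
      cfg_args$p_avoid_A <- (1 - values[k]) / 2
      cfg_args$p_avoid_B <- (1 + values[k]) / 2
    } else {
      cfg_args[[axis]] <- values[k]
    }
    cfg <- do.call(sim_config, cfg_args)
    bm <- run_benchmark(cfg, method = method,
                        n_repetitions = n_repetitions,
                        seed = seed + (k - 1) * 10 * n_repetitions, ...)
    data.frame(value = values[k], mean_auc = bm$auc_mean,
               auc_lo = bm$auc_bands[[1]], auc_hi = bm$auc_bands[[3]])
  })
  structure(do.call(rbind, rows),
            class = c("rpm_sweep", "data.frame"),
            axis = axis, method = method)
}
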