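#' Risk-minus statistic as an exact rational
#'
#' The voxelwise statistic of the permutation method: the absolute
#' difference of residue proportions between the cohorts,
#' \code{|r_A/t_A - r_B/t_B|}, kept as an exact rational in lowest terms so
#' that equal values from different tables (1/2 from a t=2 voxel, 2/4 from
#' a t=4 voxel) pool into a single histogram bin.
#'
#' @param t_A,r_A,t_B,r_B Integer counts (vectorized); requires
#'   \code{t_A >= 1} and \code{t_B >= 1}.
#' @return A data frame with columns \code{numerator}, \code{denominator}
#'   (lowest terms) and \code{value}, of class \code{"risk_minus"}.
#' @examples
#' risk_minus(2, 1, 4, 1)  # 1/4
#' @export
risk_minus <- function(t_A, r_A, t_B, r_B) {
  if (any(t_A < 1) || any(t_B < 1))
    stop("risk-minus is undefined when a cohort has no tumors (t = 0)")
  stopifnot(all(r_A >= 0), all(r_B >= 0), all(r_A <= t_A), all(r_B <= t_B))
  num <- abs(r_A * t_B - r_B * t_A)
  den <- t_A * t_B
  g <- mapply(gcd2, num, den)
  structure(data.frame(numerator = num / g, denominator = den / g,
                       value = num / den),
            class = c("risk_minus", "data.frame"))
}

gcd2 <- function(a, b) {
  while (b > 0) { t <- b; b <- a %% b; a <- t }
  max(a, 1)
}

#' Construct a null histogram from a multiset of statistic values
#'
#' @param values Numeric statistic values (exact rationals represented as
#'   correctly rounded doubles pool exactly).
#' @param counts Optional multiplicities (default 1 each).
#' @return An object of class \code{"null_histogram"} supporting
#'   cumulative tail queries via \code{\link{p_from_null}}.
#' @export
null_histogram <- function(values, counts = NULL) {
  if (is.null(counts)) counts <- rep(1, length(values))
  stopifnot(length(values) == length(counts))
  o <- order(values)
  values <- values[o]; counts <- counts[o]
  new_run <- !duplicated(values)
  grp <- cumsum(new_run)
  agg <- rowsum(counts, grp)
  structure(list(values = values[new_run], counts = as.numeric(agg),
                 total = sum(counts)),
            class = "null_histogram")
}

#' @export
print.null_histogram <- function(x, ...) {
  cat(sprintf("Null histogram: %d distinct values, total mass %g\n",
              length(x$values), x$total))
  invisible(x)
}

#' Pooled permutation null distribution of risk-minus values
#'
#' Reshuffles the cohort labels of the patients uniformly (preserving the
#' cohort sizes), re-aggregates the per-voxel counts, and pools the exact
#' risk-minus values of all tested voxels over all permutations into one
#' cumulative histogram, the null distribution of the statistic.
#' Voxel-permutation pairs in which one relabeled cohort has no tumors at
#' the voxel have an undefined statistic and contribute no mass.
#'
#' @param cases List of \code{patient_case} objects.
#' @param tested Integer voxel indices to pool over (typically
#'   \code{\link{tested_voxels}} of the observed counts; the
#'   \code{t_A + t_B} total is label-invariant).
#' @param n_perm Number of random relabelings (default 1000).
#' @param seed Optional integer seed.
#' @param permutations Optional explicit 0/1 matrix (patients x
#'   permutations; 1 = cohort A) overriding random sampling, e.g. a full
#'   enumeration for small cohorts.
#' @return A \code{\link{null_histogram}}.
#' @export
permutation_null <- function(cases, tested, n_perm = 1000, seed = NULL,
                             permutations = NULL) {
  stopifnot(length(tested) >= 1)
  if (!is.null(seed)) set.seed(seed)
  np <- length(cases)
  n_A <- sum(vapply(cases, function(p) p$cohort == "A", NA))
  if (is.null(permutations)) {
    stopifnot(n_perm >= 1)
    permutations <- matrix(0, np, n_perm)
    for (j in seq_len(n_perm))
      permutations[sample.int(np, n_A), j] <- 1
  } else {
    permutations <- as.matrix(permutations) + 0
    stopifnot(nrow(permutations) == np)
    n_perm <- ncol(permutations)
  }
  # patient-by-voxel incidence over the tested voxels only
  Tm <- vapply(cases, function(p) {
    v <- logical(length(tested)); m <- case_indices(p, "tumor")
    v[match(intersect(m, tested), tested)] <- TRUE; v
  }, logical(length(tested)))
  Rm <- vapply(cases, function(p) {
    v <- logical(length(tested)); m <- case_indices(p, "residue")
    v[match(intersect(m, tested), tested)] <- TRUE; v
  }, logical(length(tested)))
  Tm <- matrix(as.double(Tm), nrow = length(tested))
  Rm <- matrix(as.double(Rm), nrow = length(tested))
  t_tot <- rowSums(Tm); r_tot <- rowSums(Rm)

  max_den <- floor((np / 2)^2)            # t_A * t_B <= (t/2)^2 <= (np/2)^2
  use_tab <- max_den <= 4e3               # integer-key tabulation feasible
  bins <- if (use_tab) max_den * (max_den + 1L) else 0L
  acc <- if (use_tab) numeric(bins) else NULL
  vals_list <- list()
  chunk <- 250L
  for (start in seq(1L, n_perm, by = chunk)) {
    cols <- start:min(start + chunk - 1L, n_perm)
    L <- permutations[, cols, drop = FALSE]
    TA <- Tm %*% L
    RA <- Rm %*% L
    TB <- t_tot - TA
    valid <- TA > 0 & TB > 0
    num <- abs(RA * t_tot - r_tot * TA)[valid]
    den <- (TA * TB)[valid]
    if (use_tab) {
      key <- (den - 1) * (max_den + 1) + num + 1
      acc <- acc + tabulate(key, nbins = bins)
    } else {
      vals_list[[length(vals_list) + 1L]] <- num / den
    }
  }
  if (use_tab) {
    nz <- which(acc > 0)
    den <- (nz - 1) %/% (max_den + 1) + 1
    num <- (nz - 1) %% (max_den + 1)
    null_histogram(num / den, acc[nz])
  } else {
    v <- unlist(vals_list)
    dt <- data.table::data.table(v = v)[, .N, by = "v"]
    null_histogram(dt$v, dt$N)
  }
}

#' p-value by cumulative lookup in a null histogram
#'
#' \code{p = (mass of null values >= stat) / total mass}; ties with the
#' observed statistic are counted in the tail.
#'
#' @param stat Numeric statistic value(s), or a \code{\link{risk_minus}}
#'   object.
#' @param null A \code{\link{null_histogram}}.
#' @return p-value(s) in [0, 1].
#' @examples
#' h <- null_histogram(c(0, 0, 1/4, 1/2))
#' p_from_null(1/2, h)  # 0.25
#' @export
p_from_null <- function(stat, null) {
  stopifnot(inherits(null, "null_histogram"), null$total > 0)
  if (inherits(stat, "risk_minus")) stat <- stat$value
  cum <- cumsum(null$counts)
  # mass strictly below stat; findInterval with left.open counts values < stat
  below <- findInterval(stat, null$values, left.open = TRUE)
  mass_lt <- ifelse(below == 0, 0, cum[pmax(below, 1)])
  (null$total - mass_lt) / null$total
}

#' q-values from the empirical distribution of p-values
#'
#' For each unique p, the expected number of falsely declared voxels
#' (\code{p * N}) is divided by the number of voxels declared at that
#' threshold; the raw ratios are made monotone in p by a running minimum
#' from the largest p downward and clamped to [0, 1].
#'
#' @param p Per-voxel p-values.
#' @param n_tested Number of tested voxels N (defaults to
#'   \code{length(p)}).
#' @return Per-voxel q-values, aligned with \code{p}.
#' @export
q_from_p <- function(p, n_tested = length(p)) {
  stopifnot(n_tested >= 1, length(p) >= 1)
  up <- sort(unique(p))
  i <- cumsum(tabulate(match(p, up), length(up)))
  q_raw <- pmin(up * n_tested / i, 1)
  q_mono <- rev(cummin(rev(q_raw)))
  q_mono[match(p, up)]
}
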