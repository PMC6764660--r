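#' Hypergeometric null distribution of a voxel table
#'
#' Under the null hypothesis of equal resection probability in the two
#' practices, and conditioning on the voxel's marginals (tumor counts
#' \code{t_A}, \code{t_B} and total residues \code{r}), the cohort-A
#' residue count follows the hypergeometric distribution.
#'
#' @param t_A,t_B Tumor counts per cohort.
#' @param r Total residue count; must satisfy \code{r <= t_A + t_B}.
#' @return A list with the integer \code{support}
#'   (\code{max(0, r - t_B) ... min(r, t_A)}) and the probability vector
#'   \code{prob} over it (sums to 1).
#' @examples
#' hypergeom_pmf(5, 5, 5)$prob[1]  # Pr(r_A = 0) = 1/252
#' @export
hypergeom_pmf <- function(t_A, t_B, r) {
  stopifnot(t_A >= 0, t_B >= 0, r >= 0)
  if (r > t_A + t_B)
    stop("inconsistent marginals: r exceeds t_A + t_B")
  support <- max(0, r - t_B):min(r, t_A)
  prob <- stats::dhyper(support, t_A, t_B, r)
  prob <- prob / sum(prob)
  list(support = support, prob = prob)
}

# Full enumeration for one set of marginals: for every attainable r_A the
# hypergeometric probability and the two-sided p-value it would yield.
# The two-sided rule: one-sided p is the smaller tail (inclusive of the
# observed value); probabilities strictly smaller than the observed one
# (relative tolerance 1e-12; ties count as equal, not smaller) are added
# walking inward from the opposing extreme, stopping just before the total
# would exceed twice the one-sided p.
fisher_enum <- function(t_A, t_B, r) {
  hg <- hypergeom_pmf(t_A, t_B, r)
  pmf <- hg$prob
  m <- length(pmf)
  if (m == 1L)
    return(list(support = hg$support, prob = pmf, p = 1))
  cum_lo <- cumsum(pmf)
  cum_hi <- rev(cumsum(rev(pmf)))
  p1 <- pmin(cum_lo, cum_hi)
  side_lo <- cum_lo <= cum_hi
  pk <- pmf
  thresh <- pk * (1 - 1e-12)

  mode_last <- max(which(pmf >= max(pmf) * (1 - 1e-12)))
  mode_first <- min(which(pmf >= max(pmf) * (1 - 1e-12)))

  # opposing side = top: entries m, m-1, ..., mode_last+1 (non-decreasing)
  top_vals <- rev(pmf)[seq_len(m - mode_last)]
  g_top <- cumsum(top_vals)
  n_small_top <- findInterval(thresh, top_vals, left.open = TRUE)
  n_mass_top <- findInterval(p1 * (1 + 1e-9), g_top)
  k_top <- pmin(n_small_top, n_mass_top, m - seq_len(m))
  add_top <- ifelse(k_top > 0, g_top[pmax(k_top, 1)], 0)

  # opposing side = bottom: entries 1, 2, ..., mode_first-1 (non-decreasing)
  bot_vals <- pmf[seq_len(mode_first - 1)]
  g_bot <- cumsum(bot_vals)
  n_small_bot <- findInterval(thresh, bot_vals, left.open = TRUE)
  n_mass_bot <- findInterval(p1 * (1 + 1e-9), g_bot)
  k_bot <- pmin(n_small_bot, n_mass_bot, seq_len(m) - 1L)
  add_bot <- ifelse(k_bot > 0, g_bot[pmax(k_bot, 1)], 0)

  p <- pmin(p1 + ifelse(side_lo, add_top, add_bot), 1)
  list(support = hg$support, prob = pmf, p = p)
}

# Memoization cache for fisher_enum keyed by (t_A, t_B, r); persists for
# the lifetime of the package namespace, so repeated benchmarks reuse it.
.fisher_cache <- new.env(parent = emptyenv())

fisher_enum_cached <- function(t_A, t_B, r) {
  key <- paste(t_A, t_B, r, sep = ",")
  got <- .fisher_cache[[key]]
  if (is.null(got)) {
    got <- fisher_enum(t_A, t_B, r)
    .fisher_cache[[key]] <- got
  }
  got
}

#' Two-sided Fisher exact p-value for a voxel table
#'
#' Computes the two-sided p-value of the 2x2 voxel table with the
#' tail-doubling termination rule: the one-sided p (smaller of the two
#' inclusive tails of the hypergeometric distribution of \code{r_A}) plus
#' those probabilities from the opposing extreme that are strictly smaller
#' than the observed one, stopping just before the total would exceed
#' twice the one-sided p. Strictness uses a relative tolerance of 1e-12;
#' equal probabilities on the opposing side are not added. Degenerate
#' tables (single-point support: \code{r = 0}, \code{r = t}, or a cohort
#' with no tumors) give p = 1.
#'
#' @param t_A,r_A,t_B,r_B Integer counts (vectorized).
#' @return Two-sided p-value(s) in (0, 1].
#' @examples
#' fisher_two_sided_p(3, 0, 3, 2)  # 0.2
#' @export
fisher_two_sided_p <- function(t_A, r_A, t_B, r_B) {
  stopifnot(all(r_A >= 0), all(r_A <= t_A), all(r_B >= 0), all(r_B <= t_B))
  n <- max(length(t_A), length(r_A), length(t_B), length(r_B))
  t_A <- rep_len(t_A, n); r_A <- rep_len(r_A, n)
  t_B <- rep_len(t_B, n); r_B <- rep_len(r_B, n)
  vapply(seq_len(n), function(i) {
    en <- fisher_enum_cached(t_A[i], t_B[i], r_A[i] + r_B[i])
    en$p[match(r_A[i], en$support)]
  }, numeric(1))
}

#' Exact null histogram of attainable Fisher p-values
#'
#' For every voxel, each attainable residue split \code{r_A} contributes
#' its hypergeometric null probability as mass at the two-sided p-value
#' that split would yield. Accumulated over voxels this is the expected
#' distribution of p-values under the null hypothesis, respecting the
#' heterogeneous discrete supports of the voxels. Total mass equals the
#' number of voxels contributing.
#'
#' @param tables Data frame with columns \code{t_A}, \code{t_B}, \code{r}
#'   (one row per voxel), or a list of such marginal triples.
#' @param weights Optional per-row multiplicities (voxels sharing
#'   marginals).
#' @return An object of class \code{"exact_null_histogram"}: sorted
#'   p-value keys (rounded to 12 significant digits), their expected
#'   counts, the cumulative counts, and the total mass.
#' @examples
#' exact_null_histogram(data.frame(t_A = 1, t_B = 1, r = 1))
#' @export
exact_null_histogram <- function(tables, weights = NULL) {
  tables <- as.data.frame(tables)
  if (is.null(weights)) weights <- rep(1, nrow(tables))
  ps <- vector("list", nrow(tables))
  ms <- vector("list", nrow(tables))
  for (i in seq_len(nrow(tables))) {
    en <- fisher_enum_cached(tables$t_A[i], tables$t_B[i], tables$r[i])
    ps[[i]] <- en$p
    ms[[i]] <- en$prob * weights[i]
  }
  key <- signif(unlist(ps), 12)
  mass <- unlist(ms)
  o <- order(key)
  key <- key[o]; mass <- mass[o]
  first <- !duplicated(key)
  grp <- cumsum(first)
  agg <- as.numeric(rowsum(mass, grp))
  structure(list(p = key[first], mass = agg, cum = cumsum(agg),
                 total = sum(agg)),
            class = "exact_null_histogram")
}

#' @export
print.exact_null_histogram <- function(x, ...) {
  cat(sprintf(
    "Exact null histogram: %d distinct p-values, total mass %g\n",
    length(x$p), x$total))
  invisible(x)
}

# F0(p): expected count of null p-values <= p.
null_cum_at <- function(null, p) {
  idx <- findInterval(signif(p, 12) * (1 + 1e-12), null$p)
  ifelse(idx == 0, 0, null$cum[pmax(idx, 1)])
}

#' q-values from observed p-values and the exact null histogram
#'
#' At each threshold p, with \code{i} observed voxels declared
#' (\code{p-value <= p}), \code{N} tested voxels, and \code{f0 = F0(p)/N}
#' the expected null fraction at the threshold, the estimated false
#' discovery rate is \code{q = f0/(1-f0) * (N-i)/i}, clamped to [0, 1]
#' (with \code{f0 = 1} giving q = 1). The raw values are made monotone in
#' p by a running minimum from the largest p downward.
#'
#' @param p_map Observed per-voxel p-values.
#' @param null An \code{\link{exact_null_histogram}}.
#' @param n_tested N, the number of tested voxels (defaults to the
#'   histogram's total mass).
#' @return Per-voxel q-values aligned with \code{p_map}.
#' @export
q_from_exact_null <- function(p_map, null, n_tested = null$total) {
  stopifnot(inherits(null, "exact_null_histogram"), length(p_map) >= 1)
  N <- n_tested
  up <- sort(unique(p_map))
  i <- cumsum(tabulate(match(p_map, up), length(up)))
  f0 <- pmin(null_cum_at(null, up) / N, 1)
  q_raw <- ifelse(f0 >= 1 - 1e-12, 1,
                  pmin(f0 / (1 - f0) * (N - i) / i, 1))
  q_mono <- rev(cummin(rev(q_raw)))
  q_mono[match(p_map, up)]
}
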