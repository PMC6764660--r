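test_that("hypergeometric pmf matches direct binomial-coefficient evaluation", {
  hg <- hypergeom_pmf(5, 5, 5)
  expect_equal(hg$support, 0:5)
  expect_equal(hg$prob[1], 1 / 252)
  expect_equal(sum(hg$prob), 1)

  expect_equal(hypergeom_pmf(4, 3, 0)$prob, 1)        # r = 0: point mass
  hg0 <- hypergeom_pmf(4, 0, 3)                        # t_B = 0: r_A = r
  expect_equal(hg0$support, 3)
  expect_equal(hg0$prob, 1)

  expect_error(hypergeom_pmf(2, 2, 5), "inconsistent marginals")
})

test_that("two-sided p-value follows the tail-doubling termination rule", {
  # pmf (0.2, 0.6, 0.2); opposing extreme not strictly smaller -> one tail
  expect_equal(fisher_two_sided_p(3, 0, 3, 2), 0.2)
  # r = 0: single support point
  expect_equal(fisher_two_sided_p(4, 0, 6, 0), 1)
  # complete separation, 5 vs 5
  expect_equal(fisher_two_sided_p(5, 0, 5, 5),
               fisher_p_oracle(5, 0, 5, 5))
})

test_that("two-sided p-values equal exact-integer enumeration for all small tables", {
  for (t_A in 1:6) for (t_B in 1:6) {
    for (r in 0:(t_A + t_B)) {
      supp <- max(0, r - t_B):min(r, t_A)
      for (r_A in supp) {
        expect_equal(
          fisher_two_sided_p(t_A, r_A, t_B, r - r_A),
          fisher_p_oracle(t_A, r_A, t_B, r - r_A),
          tolerance = 1e-10,
          info = sprintf("t_A=%d r_A=%d t_B=%d r_B=%d",
                         t_A, r_A, t_B, r - r_A))
      }
    }
  }
  # a band of larger, asymmetric tables
  for (tab in list(c(12, 3, 9, 1), c(10, 10, 2, 1), c(7, 0, 12, 6),
                   c(11, 11, 1, 0), c(9, 4, 3, 3))) {
    expect_equal(fisher_two_sided_p(tab[1], tab[2], tab[3], tab[4]),
                 fisher_p_oracle(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-10)
  }
})

test_that("exact null histogram accumulates hypergeometric mass at p-values", {
  # single voxel t_A = t_B = 1, r = 1: both outcomes give p = 0.5
  h <- exact_null_histogram(data.frame(t_A = 1, t_B = 1, r = 1))
  expect_equal(h$p, 0.5)
  expect_equal(h$mass, 1)

  # r = 0 voxel: all mass at p = 1
  h0 <- exact_null_histogram(data.frame(t_A = 3, t_B = 2, r = 0))
  expect_equal(h0$p, 1)
  expect_equal(h0$mass, 1)

  # total mass equals the number of voxels
  set.seed(8)
  tabs <- data.frame(t_A = sample(1:8, 20, TRUE),
                     t_B = sample(1:8, 20, TRUE))
  tabs$r <- mapply(function(a, b) sample(0:(a + b), 1), tabs$t_A, tabs$t_B)
  hN <- exact_null_histogram(tabs)
  expect_equal(hN$total, 20)
})

test_that("exact-null q-values follow the printed formula with regularization", {
  # N = 1000, i = 20, f0 = 0.01 -> q = (0.01/0.99) * (980/20)
  null <- structure(list(p = c(0.001, 1), mass = c(10, 990),
                         cum = c(10, 1000), total = 1000),
                    class = "exact_null_histogram")
  p_map <- c(rep(0.001, 20), rep(1, 980))
  q <- q_from_exact_null(p_map, null)
  expect_equal(q[1], (0.01 / 0.99) * (980 / 20), tolerance = 1e-12)
  expect_equal(q[21], 1)  # f0 = 1 at p = 1

  # direct-algebra oracle on random maps
  set.seed(99)
  for (i in 1:10) {
    tabs <- data.frame(t_A = sample(1:6, 15, TRUE),
                       t_B = sample(1:6, 15, TRUE))
    tabs$r <- mapply(function(a, b) sample(0:(a + b), 1), tabs$t_A, tabs$t_B)
    keep <- tabs$r > 0 & tabs$r < tabs$t_A + tabs$t_B
    tabs <- tabs[keep, , drop = FALSE]
    if (nrow(tabs) < 2) next
    null <- exact_null_histogram(tabs)
    p_map <- mapply(function(a, b, r) {
      rA <- sample(max(0, r - b):min(r, a), 1)
      fisher_two_sided_p(a, rA, b, r - rA)
    }, tabs$t_A, tabs$t_B, tabs$r)
    expect_equal(q_from_exact_null(p_map, null),
                 q_exact_oracle(p_map, null$p, null$mass, null$total),
                 tolerance = 1e-9)
  }
})

test_that("non-informative voxels do not alter other voxels' q-values", {
  set.seed(123)
  dm <- c(4, 4, 4)
  cfg <- tiny_cfg(n_patients_per_cohort = 8)
  cs <- simulate_cohorts(cfg, seed = 61)
  cm <- aggregate_counts(cs$cases)
  fit_all <- rpm_test(cm, method = "fisher", min_tumors = 1)
  # drop voxels that carry no information under fixed marginals
  informative <- with(fit_all$counts,
                      r_A + r_B > 0 & r_A + r_B < t_A + t_B &
                      t_A > 0 & t_B > 0)
  expect_true(any(informative) && any(!informative))
  expect_true(all(fit_all$q[!informative] == 1))

  cm2 <- cm
  drop <- fit_all$voxels[!informative]
  cm2$t_A[drop] <- 0L; cm2$r_A[drop] <- 0L
  cm2$t_B[drop] <- 0L; cm2$r_B[drop] <- 0L
  fit_inf <- rpm_test(cm2, method = "fisher", min_tumors = 1)
  m <- match(fit_inf$voxels, fit_all$voxels)
  expect_equal(fit_inf$q, fit_all$q[m])
  expect_equal(fit_inf$p, fit_all$p[m])
})

test_that("per-voxel null calibration matches the exact null distribution", {
  # simulate tables under H0 with fixed marginals; the frequency of
  # p <= alpha must not exceed the exact-null expectation
  set.seed(7)
  t_A <- 8; t_B <- 6; r <- 5
  en_p <- sapply(max(0, r - t_B):min(r, t_A), function(k)
    fisher_two_sided_p(t_A, k, t_B, r - k))
  hg <- hypergeom_pmf(t_A, t_B, r)
  draws <- sample(hg$support, 4000, replace = TRUE, prob = hg$prob)
  p_sim <- en_p[match(draws, hg$support)]
  for (alpha in c(0.05, 0.1, 0.3, 0.6)) {
    expected <- sum(hg$prob[en_p <= alpha * (1 + 1e-12)])
    # allow binomial sampling slack on 4000 draws
    expect_lte(mean(p_sim <= alpha),
               expected + 3 * sqrt(expected * (1 - expected) / 4000) + 1e-9)
  }
})
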