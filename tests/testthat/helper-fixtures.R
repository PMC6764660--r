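# Small, fast simulator configuration for unit tests (not the
# benchmarking conditions): 24 mm brain at 4 mm voxels, 6 patients/cohort.
tiny_cfg <- function(...) {
  args <- list(brain_radius_mm = 24, voxel_size_mm = 4,
               tumor_diameter_mm = 24, effect_region_diameter_mm = 12,
               effect_region_center = c(10, 0, 0),
               n_patients_per_cohort = 6)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# Hand-built patient case on a small grid from voxel index vectors.
mk_case <- function(dim, tumor_idx, residue_idx, cohort, voxel = 1) {
  tum <- array(FALSE, dim); tum[tumor_idx] <- TRUE
  res <- array(FALSE, dim); res[residue_idx] <- TRUE
  attr(tum, "voxel_size_mm") <- voxel
  attr(res, "voxel_size_mm") <- voxel
  structure(list(tumor = tum, residue = res, cohort = cohort,
                 avoided = NA), class = "patient_case")
}

# Independent oracle for the two-sided Fisher p-value, in exact integer
# arithmetic (valid for t_A + t_B small enough that binomial coefficients
# stay exact). Works on pmf numerators over the common denominator
# choose(t, r): one-sided tail = smaller inclusive tail; opposing-side
# terms strictly smaller than the observed probability are added walking
# inward from the opposing extreme, stopping just before the total would
# exceed twice the one-sided tail.
fisher_p_oracle <- function(t_A, r_A, t_B, r_B) {
  r <- r_A + r_B
  lo <- max(0, r - t_B); hi <- min(r, t_A)
  supp <- lo:hi
  num <- choose(t_A, supp) * choose(t_B, r - supp)
  den <- choose(t_A + t_B, r)
  m <- length(supp)
  if (m == 1) return(1)
  k <- match(r_A, supp)
  lo_tail <- sum(num[1:k]); hi_tail <- sum(num[k:m])
  if (lo_tail <= hi_tail) {
    p1 <- lo_tail
    opp <- if (k < m) rev(num[(k + 1):m]) else numeric(0)  # from extreme inward
  } else {
    p1 <- hi_tail
    opp <- if (k > 1) num[1:(k - 1)] else numeric(0)
  }
  added <- 0
  for (v in opp) {
    if (v >= num[k]) break
    if (added + v > p1) break
    added <- added + v
  }
  min((p1 + added) / den, 1)
}

# Oracle risk-minus histogram over explicit relabelings, computed naively
# from scratch (no shared code with permutation_null).
perm_null_oracle <- function(cases, tested, labels_mat) {
  vals <- c()
  for (j in seq_len(ncol(labels_mat))) {
    isA <- labels_mat[, j] == 1
    for (v in tested) {
      tA <- rA <- tB <- rB <- 0
      for (i in seq_along(cases)) {
        tum <- cases[[i]]$tumor[v]
        res <- cases[[i]]$residue[v]
        if (isA[i]) { tA <- tA + tum; rA <- rA + res }
        else        { tB <- tB + tum; rB <- rB + res }
      }
      if (tA >= 1 && tB >= 1)
        vals <- c(vals, abs(rA / tA - rB / tB))
    }
  }
  vals
}

# Direct-algebra oracle for the exact-null q-value formula.
q_exact_oracle <- function(p_map, null_p, null_mass, N) {
  q <- numeric(length(p_map))
  for (v in seq_along(p_map)) {
    i <- sum(p_map <= p_map[v])
    # histogram keys are 12-significant-digit rounded; compare on that scale
    f0 <- sum(null_mass[null_p <= signif(p_map[v], 12) * (1 + 1e-12)]) / N
    q[v] <- if (f0 >= 1 - 1e-12) 1 else min(f0 / (1 - f0) * (N - i) / i, 1)
  }
  # monotone regularization: running min from largest p down
  o <- order(p_map)
  qo <- q[o]
  for (j in rev(seq_along(qo))[-1]) qo[j] <- min(qo[j], qo[j + 1])
  q[o] <- qo
  pmin(q, 1)
}
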