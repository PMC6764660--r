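#' Probability level of the largest centered interval excluding zero
#'
#' The Bayesian per-voxel evidence score: the probability mass of the
#' largest credible interval of the posterior between-cohort difference,
#' centered within the distribution, that excludes zero. Implemented on
#' sample ranks as \code{1 - 2 * min(Pr(draws < 0), Pr(draws > 0))}, with
#' draws exactly at zero split evenly between the sides. A level near 1
#' means nearly all posterior mass lies on one side of zero (strong
#' evidence of a difference); 0 means the posterior median difference is
#' zero.
#'
#' @param delta_draws Numeric vector of posterior draws of the difference
#'   (at least 2).
#' @return Level in [0, 1].
#' @examples
#' hdi_exclusion_level(c(rep(1, 900), rep(-1, 100)))  # 0.8
#' @export
hdi_exclusion_level <- function(delta_draws) {
  stopifnot(length(delta_draws) >= 2)
  zero <- mean(delta_draws == 0) / 2
  lo <- mean(delta_draws < 0) + zero
  hi <- mean(delta_draws > 0) + zero
  max(1 - 2 * min(lo, hi), 0)
}

# JAGS source of the hierarchical binomial partial-pooling model. Success
# = resection (s = t - r). Per cohort k a population location mu_k (logit
# scale, Normal(0,1) prior) and scale sigma_k (Half-Normal(0,1));
# voxelwise effects are non-centered: eta ~ Normal(0,1), logit(theta) =
# mu + sigma * eta. Voxels observed in only one cohort still draw a theta
# for the other (no likelihood term).
pooling_model_source <- function(shared_population = FALSE) {
  pop <- if (shared_population) "
  mu0 ~ dnorm(0, 1)
  sigma0 ~ dnorm(0, 1) T(0,)
  for (k in 1:2) { mu[k] <- mu0
                   sigma[k] <- sigma0 }
" else "
  for (k in 1:2) {
    mu[k] ~ dnorm(0, 1)
    sigma[k] ~ dnorm(0, 1) T(0,)
  }
"
  paste0("model {", pop, "
  for (v in 1:V) {
    for (k in 1:2) {
      eta[v, k] ~ dnorm(0, 1)
      logit(theta[v, k]) <- mu[k] + sigma[k] * eta[v, k]
    }
  }
  for (n in 1:Nobs) {
    s[n] ~ dbin(theta[vox[n], coh[n]], t[n])
  }
}
")
}

#' Fit the hierarchical binomial partial-pooling model
#'
#' Treats every tested voxel's resection outcome in each cohort as a
#' binomial trial whose success rate (resection probability,
#' \code{(t - r) / t}) is partially pooled across voxels: logit success
#' rates are drawn from a cohort-level normal population with vague
#' priors (location Normal(0,1), scale Half-Normal(0,1)), with
#' non-centered voxel effects for sampling efficiency. The shrinkage of
#' per-voxel estimates toward the population rate implicitly controls the
#' multiplicity over voxels. Sampling uses MCMC via JAGS: by default 4
#' chains of 500 iterations each, the first half discarded as burn-in,
#' retaining 1000 posterior draws.
#'
#' @param counts Data frame with columns \code{t_A}, \code{r_A},
#'   \code{t_B}, \code{r_B}, one row per voxel (every row must have
#'   \code{t_A >= 1} or \code{t_B >= 1}).
#' @param chains,iter MCMC chains and iterations per chain (half burn-in).
#' @param seed Optional integer seed (per-chain RNGs are derived from it).
#' @param shared_population Share the population location/scale between
#'   cohorts instead of cohort-specific parameters.
#' @param adapt JAGS adaptation iterations before burn-in.
#' @param hdi Either \code{"equal-tailed"} (rank-based level, the
#'   default) or \code{"highest-density"} for skew-robust intervals.
#' @return A list with \code{hdi_level}, \code{delta_mean},
#'   \code{theta_mean} (matrix V x 2), \code{delta_draws} (draws x V),
#'   and \code{diagnostics} (split R-hat for the population parameters,
#'   retained draw count).
#' @export
fit_bayes_pooling <- function(counts, chains = 4, iter = 500, seed = NULL,
                              shared_population = FALSE, adapt = 100,
                              hdi = c("equal-tailed", "highest-density")) {
  hdi <- match.arg(hdi)
  if (!requireNamespace("rjags", quietly = TRUE))
    stop("the bayes method requires the rjags package")
  stopifnot(nrow(counts) >= 1, all(counts$t_A + counts$t_B >= 1))
  V <- nrow(counts)
  obs <- rbind(
    data.frame(vox = seq_len(V), coh = 1L, t = counts$t_A,
               s = counts$t_A - counts$r_A),
    data.frame(vox = seq_len(V), coh = 2L, t = counts$t_B,
               s = counts$t_B - counts$r_B))
  obs <- obs[obs$t > 0, ]
  if (is.null(seed)) seed <- sample.int(1e6, 1)
  inits <- lapply(seq_len(chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed + ch)))
  model <- rjags::jags.model(
    textConnection(pooling_model_source(shared_population)),
    data = list(V = V, Nobs = nrow(obs), vox = obs$vox, coh = obs$coh,
                t = obs$t, s = obs$s),
    inits = inits, n.chains = chains, n.adapt = adapt, quiet = TRUE)
  burn <- floor(iter / 2)
  stats::update(model, burn, progress.bar = "none")
  samp <- rjags::coda.samples(model, c("theta", "mu", "sigma"),
                              n.iter = iter - burn, progress.bar = "none")
  draws <- do.call(rbind, lapply(samp, as.matrix))
  thA <- draws[, sprintf("theta[%d,1]", seq_len(V)), drop = FALSE]
  thB <- draws[, sprintf("theta[%d,2]", seq_len(V)), drop = FALSE]
  delta <- thA - thB
  level <- if (hdi == "equal-tailed") {
    apply(delta, 2, hdi_exclusion_level)
  } else {
    apply(delta, 2, hdi_exclusion_level_hd)
  }
  pop_names <- intersect(colnames(draws),
                         c("mu[1]", "mu[2]", "sigma[1]", "sigma[2]"))
  rhat <- split_rhat(samp, pop_names)
  n_ret <- nrow(draws)
  if (any(rhat > 1.05, na.rm = TRUE))
    warning("split R-hat above 1.05 for: ",
            paste(names(rhat)[rhat > 1.05], collapse = ", "))
  list(hdi_level = level,
       delta_mean = colMeans(delta),
       theta_mean = cbind(A = colMeans(thA), B = colMeans(thB)),
       delta_draws = delta,
       diagnostics = list(rhat = rhat, n_draws = n_ret,
                          mu = colMeans(draws[, grep("^mu", colnames(draws)),
                                              drop = FALSE]),
                          sigma = colMeans(draws[, grep("^sigma", colnames(draws)),
                                                 drop = FALSE])))
}

# Largest highest-density credible interval excluding zero, for skewed
# posteriors: the level at which the narrowest interval of that mass
# first touches zero, found by bisection over the level.
hdi_exclusion_level_hd <- function(delta_draws) {
  x <- sort(delta_draws)
  n <- length(x)
  excludes_zero <- function(level) {
    m <- max(1L, ceiling(level * n))
    if (m >= n) return(x[1] > 0 || x[n] < 0)
    w <- x[(m + 1):n] - x[1:(n - m)]
    j <- which.min(w)
    x[j] > 0 || x[j + m] < 0
  }
  if (!excludes_zero(1 / n)) return(0)
  lo <- 1 / n; hi <- 1
  if (excludes_zero(1)) return(1)
  for (it in 1:30) {
    mid <- (lo + hi) / 2
    if (excludes_zero(mid)) lo <- mid else hi <- mid
  }
  lo
}

# Split R-hat per parameter from an mcmc.list: each chain is split in two
# halves; R-hat = sqrt((W * (m-1)/m + B/m) / W) over the 2*chains halves.
split_rhat <- function(samp, par_names) {
  out <- vapply(par_names, function(pn) {
    halves <- unlist(lapply(samp, function(ch) {
      v <- as.matrix(ch)[, pn]
      m <- length(v) %/% 2
      list(v[seq_len(m)], v[(m + 1):(2 * m)])
    }), recursive = FALSE)
    m <- length(halves[[1]])
    means <- vapply(halves, mean, numeric(1))
    vars <- vapply(halves, stats::var, numeric(1))
    W <- mean(vars)
    B <- m * stats::var(means)
    if (W <= 0) return(NA_real_)
    sqrt((W * (m - 1) / m + B / m) / W)
  }, numeric(1))
  names(out) <- par_names
  out
}
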