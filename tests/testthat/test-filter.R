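# The rho = 0, n = 2 case has a closed-form marginal likelihood and
# posterior: with m singletons on length L the posterior of the TMRCA is
# Gamma(m + 1, 1/(2 Ne) + 2 mu L).  This exercises the full weight
# bookkeeping of the engine end to end.
ref_case <- function(Ne = 1e4, mu = 2.5e-8, L = 2e5, m = 3, seed = 99) {
  set.seed(seed)
  loci <- sort(runif(m, 1, L - 1))
  obs <- observation(loci = loci, patterns = matrix(rep(c(1L, 0L), m), 2), L = L)
  rtot <- 1 / (2 * Ne) + 2 * mu * L
  list(obs = obs,
       model = demographic_model(ne = Ne, rho = 0, mu = mu),
       loglik = log(1 / (2 * Ne)) + m * log(mu) + lgamma(m + 1) - (m + 1) * log(rtot),
       post_mean = (m + 1) / rtot)
}

test_that("marginal likelihood and posterior match the analytic oracle", {
  rc <- ref_case()
  set.seed(50)
  reps <- replicate(10, {
    f <- run_filter(rc$obs, rc$model, n_particles = 2000)
    c(exp(f$loglik - rc$loglik), sum(f$final_w * f$final_tmrca))
  })
  expect_lt(abs(mean(reps[1, ]) - 1), 3 * sd(reps[1, ]) / sqrt(10))
  expect_lt(abs(mean(reps[2, ]) - rc$post_mean), 3 * sd(reps[2, ]) / sqrt(10))
})

test_that("likelihood variance decreases with the particle count", {
  rc <- ref_case(m = 2)
  est <- function(N) {
    replicate(8, run_filter(rc$obs, rc$model, n_particles = N)$loglik)
  }
  set.seed(51)
  v_small <- var(est(100))
  v_large <- var(est(3200))
  expect_lt(v_large, v_small)
})

test_that("resampling resets the ensemble to near-full ESS", {
  m <- const_model()
  set.seed(52)
  sim <- simulate_genomes(m, n = 4, L = 1e5)
  f <- run_filter(sim$obs, m, n_particles = 200)
  expect_true(any(f$resampled))
  # at the waypoint after a resample the pre-resampling ESS is close to N
  # (only one gap's weight spread has accrued since)
  idx <- which(f$resampled)
  idx <- idx[idx < length(f$ess_w)]
  # restrict to event-free following gaps
  gaps_ok <- !vapply(idx, function(k)
    any(sim$obs$loci > f$waypoints[k] & sim$obs$loci <= f$waypoints[k + 1]),
    logical(1))
  expect_gt(median(f$ess_w[idx[gaps_ok] + 1] / f$n_particles), 0.9)
})

test_that("filter runs are reproducible at a fixed seed", {
  m <- const_model()
  set.seed(53)
  sim <- simulate_genomes(m, n = 4, L = 5e4)
  set.seed(7)
  a <- run_filter(sim$obs, m, n_particles = 100)
  set.seed(7)
  b <- run_filter(sim$obs, m, n_particles = 100)
  expect_identical(a$loglik, b$loglik)
  expect_identical(a$ess_w, b$ess_w)
  expect_identical(a$stats, b$stats)
})

test_that("masks remove unobserved intervals from the weight updates", {
  rc <- ref_case(m = 0, L = 1e5)
  obs0 <- observation(loci = numeric(0), patterns = matrix(integer(0), 2, 0), L = 1e5)
  mk <- observed_mask(0, 5e4, L = 1e5)
  set.seed(54)
  ll <- replicate(6, run_filter(obs0, rc$model, n_particles = 2000, mask = mk)$loglik)
  # loglik = log E[exp(-2 mu t * 5e4)] with t ~ Exp(1/2Ne)
  r0 <- 1 / 2e4
  ref <- log(r0 / (r0 + 2 * rc$model$mu * 5e4))
  expect_lt(abs(log(mean(exp(ll - ref)))), 0.15)
})

test_that("event-free ESS retention respects the waypoint bound", {
  # waypoints at the 1/(2 theta) rule: per-gap ESS loss should typically stay
  # above exp(-1/2) ~ 0.6 on event-free gaps
  m <- const_model(ne = 1e4, mu = 2.5e-8)
  theta <- 4 * 1e4 * 2.5e-8
  set.seed(55)
  sim <- simulate_genomes(m, n = 4, L = 3e5)
  f <- run_filter(sim$obs, m, n_particles = 300, theta = theta)
  ret <- coalpf:::ess_retention(f)
  K <- length(f$waypoints)
  event_free <- !vapply(seq_len(K - 1), function(k)
    any(sim$obs$loci > f$waypoints[k] & sim$obs$loci <= f$waypoints[k + 1]),
    logical(1))
  expect_gt(median(ret[event_free], na.rm = TRUE), exp(-0.5))
})
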