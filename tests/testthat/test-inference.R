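fake_stats <- function(rc, ro, cc, co, start = 0) {
  data.frame(epoch = seq_along(cc), start = start, end = Inf,
             recomb_count = rc, recomb_opp = ro,
             coal_count = cc, coal_opp = co)
}

test_that("SEM update is count over opportunity", {
  s <- fake_stats(10, 2e5, 10, 2e5)
  up <- sem_update(s)
  expect_equal(up$rho, 5e-5)
  expect_equal(up$coal_rate, 5e-5)
  expect_equal(up$ne, 1e4)
  # zero count with positive opportunity: the zero-rate fixed point
  expect_equal(sem_update(fake_stats(0, 1e5, 0, 1e5))$rho, 0)
  expect_error(sem_update(fake_stats(1, 1, 1, 0)), "merge epochs")
  # scale invariance: expected statistics scaled by any constant
  s2 <- fake_stats(10 * 3, 2e5 * 3, 10 * 3, 2e5 * 3)
  expect_equal(sem_update(s2)$rho, up$rho)
})

test_that("VB update is the conjugate Gamma posterior", {
  s <- fake_stats(10, 2e5, 10, 2e5)
  prior <- list(alpha_rho = 1, beta_rho = 1e4, alpha_coal = 1, beta_coal = 1e4)
  up <- vb_update(s, prior)
  expect_equal(up$alpha_rho, 11)
  expect_equal(up$beta_rho, 2.1e5)
  expect_equal(up$rho, 11 / 2.1e5)
  expect_equal(up$rho, 5.238e-5, tolerance = 1e-3)
  # zero count keeps a strictly positive posterior mean
  z <- vb_update(fake_stats(0, 1e5, 0, 1e5), prior)
  expect_gt(z$rho, 0)
  expect_gt(min(z$coal_rate), 0)
  # with overwhelming data the posterior mean approaches the SEM estimate
  big <- fake_stats(1e6, 2e10, 1e6, 2e10)
  expect_equal(vb_update(big, prior)$rho, sem_update(big)$rho, tolerance = 1e-4)
  # and with a vanishing prior they coincide
  tiny <- list(alpha_rho = 1e-10, beta_rho = 1e-10, alpha_coal = 1e-10,
               beta_coal = 1e-10)
  s3 <- fake_stats(7, 3e5, 4, 8e4)
  expect_equal(vb_update(s3, tiny)$rho, sem_update(s3)$rho, tolerance = 1e-9)
  expect_equal(vb_update(s3, tiny)$coal_rate, sem_update(s3)$coal_rate,
               tolerance = 1e-9)
  expect_error(vb_update(s, list(alpha_rho = 0, beta_rho = 1, alpha_coal = 1,
                                 beta_coal = 1)), "positive")
})

test_that("the VB per-event weight factor behaves as eta(alpha)", {
  expect_equal(event_weight_factor(1), exp(-0.57721566490153286), tolerance = 1e-10)
  a <- c(0.5, 1, 2, 5, 20, 100, 1e4)
  eta <- event_weight_factor(a)
  expect_true(all(eta < 1))
  expect_true(all(diff(eta) > 0))
  expect_equal(event_weight_factor(1e8), 1, tolerance = 1e-7)
  expect_error(event_weight_factor(0), "positive")
})

test_that("correlation distances: analytic init and empirical override", {
  m <- const_model(rho = 1e-8)
  ch <- estimate_correlation_distances(NULL, m)
  expect_length(ch, 1)
  # multi-epoch: recent epochs have longer correlation distances
  ep <- parse_epoch_spec("400,800,1200,2000,4000,8000,20000,40000,60000")
  m9 <- demographic_model(ne = rep(1e4, 10), epoch_start = ep, rho = 1e-8, mu = 2.5e-8)
  ch9 <- estimate_correlation_distances(NULL, m9)
  expect_true(all(diff(ch9) < 0))
  expect_equal(ch9[5], 1 / (2 * 1e-8 * 3000))  # epoch [2000, 4000): midpoint 3000
  # empirical values win where counts exist; analytic fills the gaps
  life <- data.frame(epoch = 1:10, life_sum = c(2e4, rep(0, 9)),
                     life_count = c(10, rep(0, 9)))
  che <- estimate_correlation_distances(life, m9)
  expect_equal(che[1], 2000)
  expect_equal(che[-1], ch9[-1])
})

test_that("node lifetimes from the filter reflect the epoch ages", {
  m <- const_model()
  set.seed(70)
  sim <- simulate_genomes(m, n = 4, L = 3e5)
  ep <- c(0, 2000, 20000)
  m3 <- demographic_model(ne = rep(1e4, 3), epoch_start = ep, rho = 1e-8, mu = 2.5e-8)
  f <- suppressWarnings(run_filter(sim$obs, m3, n_particles = 100, track_life = TRUE))
  expect_true(all(f$node_life$life_count[2:3] > 0))
  emp <- f$node_life$life_sum / pmax(f$node_life$life_count, 1)
  # deeper-epoch nodes are destroyed after shorter genomic distances
  expect_gt(emp[2], emp[3])
})

test_that("harvested statistics equal ensemble expectations in closed form", {
  # with rho = 0 there are no events: the only statistic is the recombination
  # opportunity, which must equal the weighted ensemble's B times L exactly
  m <- const_model(rho = 0)
  set.seed(71)
  sim <- simulate_genomes(const_model(), n = 2, L = 5e4)
  f <- run_filter(sim$obs, m, n_particles = 200)
  expect_equal(sum(f$stats$recomb_opp), sum(f$final_w * f$final_B) * 5e4,
               tolerance = 1e-9)
  expect_equal(sum(f$stats$recomb_count), 0)
  expect_equal(sum(f$stats$coal_count), 0)
})

test_that("generative identity: filtered statistics recover the true rates", {
  # with an uninformative observation process (nearly nothing observed) the
  # filter samples the prior: expected count / opportunity converges to the
  # generating rates.  Note an EMPTY variant list over an observed region is
  # informative (it conditions on zero mutations), hence the 1 bp mask.
  m <- const_model(ne = 1e4, rho = 1e-8)
  obs0 <- observation(loci = numeric(0), patterns = matrix(integer(0), 4, 0), L = 5e5)
  mk <- observed_mask(0, 1, L = 5e5)
  set.seed(72)
  f <- run_filter(obs0, m, n_particles = 50, mask = mk, spacing = 1e4)
  rho_hat <- sum(f$stats$recomb_count) / sum(f$stats$recomb_opp)
  C_hat <- sum(f$stats$coal_count) / sum(f$stats$coal_opp)
  expect_lt(abs(rho_hat - 1e-8) / 1e-8, 0.15)
  expect_lt(abs(C_hat - 5e-5) / 5e-5, 0.15)
})

test_that("fit is deterministic at a fixed seed and tracks the truth", {
  m <- const_model()
  set.seed(73)
  sim <- simulate_genomes(m, n = 4, L = 2e5)
  init <- demographic_model(ne = 5000, rho = 1e-8, mu = 2.5e-8)
  set.seed(74)
  f1 <- suppressWarnings(fit(sim$obs, init, n_particles = 100, iterations = 2, mode = "vb"))
  set.seed(74)
  f2 <- suppressWarnings(fit(sim$obs, init, n_particles = 100, iterations = 2, mode = "vb"))
  expect_identical(f1$trace, f2$trace)
  # the single-epoch Ne moves from the 5000 start towards 10000
  ne2 <- f1$trace$ne[f1$trace$iteration == 2 & f1$trace$type == "Coal"]
  expect_gt(ne2, 6000)
})

test_that("without data the fit reverts to the sampling rates", {
  obs0 <- observation(loci = numeric(0), patterns = matrix(integer(0), 4, 0), L = 3e5)
  mk <- observed_mask(0, 1, L = 3e5)
  init <- demographic_model(ne = 8000, rho = 2e-8, mu = 2.5e-8)
  set.seed(75)
  f <- fit(obs0, init, n_particles = 60, iterations = 1, mode = "vb",
           alpha_lag = 0, mask = mk, spacing = 5e3)
  # prior-dominated regime: estimates stay at the rates that generated the
  # paths (the current model), not at some data-driven value
  expect_lt(abs(f$model$ne[1] - 8000) / 8000, 0.2)
  expect_lt(abs(f$model$rho - 2e-8) / 2e-8, 0.2)
})

test_that("chunked inference pools sufficient statistics additively", {
  m <- const_model()
  set.seed(76)
  sim <- simulate_genomes(m, n = 4, L = 2e5)
  chunks <- coalpf:::split_chunks(sim$obs, NULL, 5e4)
  expect_length(chunks, 4)
  expect_equal(sum(vapply(chunks, function(c) length(c$obs$loci), numeric(1))),
               length(sim$obs$loci))
  # chunk-local coordinates stay in range
  for (ch in chunks) {
    expect_true(all(ch$obs$loci >= 0 & ch$obs$loci < ch$obs$L))
  }
  # masks are clipped into chunk coordinates
  mk <- observed_mask(c(0, 1.2e5), c(9e4, 1.9e5), L = 2e5)
  chm <- coalpf:::split_chunks(sim$obs, mk, 1e5)
  expect_equal(chm[[1]]$mask$end, 9e4)
  expect_equal(chm[[2]]$mask$start, 2e4)
  expect_equal(chm[[2]]$mask$end, 9e4)
})
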