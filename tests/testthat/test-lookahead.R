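test_that("digest fixes mutually consistent cherries greedily", {
  # six lineages; doubletons supporting three disjoint cherries are kept,
  # doubletons sharing a leaf with a fixed cherry are discarded
  pats <- cbind(
    c(1L,1L,0L,0L,0L,0L),  # locus 10: cherry (1,2)
    c(0L,0L,1L,1L,0L,0L),  # locus 20: cherry (3,4)
    c(0L,1L,1L,0L,0L,0L),  # locus 30: shares leaves with both -> discarded
    c(0L,0L,0L,1L,1L,0L),  # locus 40: shares leaf 4 -> discarded
    c(1L,0L,0L,0L,0L,0L),  # locus 50: singleton on 1
    c(0L,0L,0L,0L,1L,1L),  # locus 60: cherry (5,6)
    c(1L,1L,0L,0L,0L,0L)   # locus 70: more support for (1,2)
  )
  obs <- observation(loci = c(10, 20, 30, 40, 50, 60, 70), patterns = pats, L = 1000)
  d <- build_digest(obs, 0)
  expect_length(d$cherries, 3)
  pairs <- vapply(d$cherries, function(c) paste(c$a, c$b), character(1))
  expect_setequal(pairs, c("1 2", "3 4", "5 6"))
  c12 <- d$cherries[[which(pairs == "1 2")]]
  expect_equal(c12$support, c(10, 70))
  # singleton distances: lineage 1 at 50, others censored at L - s
  expect_equal(d$s_dist[1], 50)
  expect_true(d$censored[2])
  expect_equal(d$s_dist[2], 1000)

  # scanning from s = 15 drops the first doubleton but keeps the cherry alive
  d2 <- build_digest(obs, 15)
  p2 <- vapply(d2$cherries, function(c) paste(c$a, c$b), character(1))
  c12b <- d2$cherries[[which(p2 == "1 2")]]
  expect_equal(c12b$support[c12b$support > 15], 70)

  # two doubletons sharing one leaf: only the first becomes a cherry
  pats3 <- cbind(c(1L,1L,0L,0L), c(0L,1L,1L,0L))
  obs3 <- observation(loci = c(5, 8), patterns = pats3, L = 100)
  d3 <- build_digest(obs3, 0)
  expect_length(d3$cherries, 1)
  expect_equal(c(d3$cherries[[1]]$a, d3$cherries[[1]]$b), c(1, 2))
})

test_that("singleton lookahead has the stated limits", {
  mu <- 2.5e-8; n <- 4; l <- 1e4; s <- 2000
  # rho = 0 reduces to the pure-Poisson likelihood mu_i exp(-mu_i s)
  expect_equal(singleton_lookahead(l, s, FALSE, rho = 0, mu = mu, n = n),
               mu * l * exp(-mu * l * s), tolerance = 1e-12)
  # l' = l at any rho: a branch change of equal length is invisible
  expect_equal(singleton_lookahead(l, s, FALSE, rho = 1e-8, mu = mu, n = n,
                                   lprime = l),
               mu * l * exp(-mu * l * s), tolerance = 1e-9)
  # censored variant with l' = l
  expect_equal(singleton_lookahead(l, s, TRUE, rho = 1e-8, mu = mu, n = n,
                                   lprime = l),
               exp(-mu * l * s), tolerance = 1e-9)
  # removable singularity: continuous in mu' around rho_i + mu_i
  rho <- 4e-7
  rho_i <- 2 * l * rho * (n - 1) / n
  lp_sing <- (rho_i + mu * l) / mu
  v0 <- coalpf:::cpp_singleton_term(rho_i, mu * l, mu * lp_sing, s, FALSE)
  v1 <- coalpf:::cpp_singleton_term(rho_i, mu * l, mu * lp_sing * (1 + 1e-6), s, FALSE)
  expect_lt(abs(v0 - v1) / v0, 1e-3)
  expect_error(singleton_lookahead(-1, s, FALSE, rho = 0, mu = mu, n = n), "negative")
})

test_that("cherry terms interpolate to the equilibrium probability", {
  n <- 4
  expect_equal(cherry_present_lookahead(0, 1e-3, n), 1)
  expect_equal(cherry_present_lookahead(1e9, 1e-3, n), 2 / (3 * (n - 1)),
               tolerance = 1e-9)
  # rho_C s'' = 1
  expect_equal(cherry_present_lookahead(1, 1, 4), exp(-1) + (2 / 9) * (1 - exp(-1)),
               tolerance = 1e-12)
  expect_equal(cherry_present_lookahead(1, 1, 4), 0.5083, tolerance = 1e-4)

  expect_equal(cherry_absent_lookahead(0, 1e-3, n), 0)
  expect_equal(cherry_absent_lookahead(1e9, 1e-3, n), 2 / (3 * (n - 1)),
               tolerance = 1e-9)
  s <- seq(0, 5000, by = 100)
  vals <- vapply(s, cherry_absent_lookahead, numeric(1), rho_Cp = 1e-3, n = 6)
  expect_true(all(diff(vals) >= 0))
  expect_error(cherry_present_lookahead(1, 1, 2), "n >= 3")
})

test_that("lookahead likelihood is positive and trivial without a digest", {
  m <- const_model()
  obs0 <- observation(loci = numeric(0), patterns = matrix(integer(0), 4, 0), L = 1e5)
  d0 <- build_digest(obs0, 0)
  set.seed(60)
  g <- sample_stationary_tree(m, 4)
  # empty digest: only censored singleton factors remain, all near 1;
  # with no cherries and s censored the product is bounded and positive
  h <- lookahead_likelihood(g, d0, m)
  expect_gt(h, 0)
  expect_lte(h, 1 + 1e-12)
  # strictly positive over random trees and digests (heavy-tail requirement)
  sim <- simulate_genomes(m, n = 4, L = 1e5)
  d <- build_digest(sim$obs, 0)
  for (i in 1:20) {
    g <- sample_stationary_tree(m, 4)
    expect_gt(lookahead_likelihood(g, d, m), 0)
  }
})

test_that("engine and R lookahead likelihoods agree", {
  m <- const_model()
  set.seed(61)
  sim <- simulate_genomes(m, n = 4, L = 2e5)
  obs <- sim$obs
  eng_obs <- coalpf:::engine_obs(obs, NULL)
  cfg <- list(N = 8L, lookahead = TRUE, unphased = FALSE, ess_frac = 0.5,
              atoms = 16L, atom_refresh = 32L, harvest_stride = 32L,
              vb_mode = FALSE, eta_rho = 1, eta_coal = 1, lags = Inf,
              waypoints = c(0, obs$L), track_life = FALSE,
              return_final_trees = FALSE, track_loci = numeric(0))
  set.seed(62)
  dbg <- coalpf:::cpp_lookahead_debug(eng_obs, coalpf:::as_engine_model(m), cfg)
  dig <- build_digest(obs, 0)
  for (i in seq_len(8)) {
    g <- coalpf:::from_cpp_tree(dbg$trees[[i]])
    hr <- lookahead_likelihood(g, dig, m, lprime = dbg$atoms, mu_eff = dbg$mu_eff)
    expect_equal(dbg$log_h[i], log(hr), tolerance = 1e-10)
  }
})

test_that("digest construction is deterministic and stable to locus jitter", {
  m <- const_model()
  set.seed(63)
  sim <- simulate_genomes(m, n = 6, L = 1e5)
  d1 <- build_digest(sim$obs, 0)
  d2 <- build_digest(sim$obs, 0)
  expect_identical(d1, d2)
  # shifting all loci by +0.25 (order-preserving) keeps the cherry structure
  obs_j <- observation(loci = sim$obs$loci + 0.25, patterns = sim$obs$patterns,
                       L = sim$obs$L)
  d3 <- build_digest(obs_j, 0)
  expect_equal(length(d3$cherries), length(d1$cherries))
  unc <- !d1$censored
  expect_equal(d3$s_dist[unc], d1$s_dist[unc] + 0.25, tolerance = 1e-9)
})

test_that("n = 2 lookahead uses singleton terms only", {
  m <- const_model()
  sim <- list()
  set.seed(64)
  s2 <- simulate_genomes(m, n = 2, L = 1e5)
  d <- build_digest(s2$obs, 0)
  expect_length(d$cherries, 0)
  g <- sample_stationary_tree(m, 2)
  h <- lookahead_likelihood(g, d, m)
  ref <- 1
  for (rhoP in c(m$rho, m$rho / 2)) {
    val <- 1
    for (i in 1:2)
      val <- val * singleton_lookahead(tmrca(g), d$s_dist[i], d$censored[i],
                                       rho = rhoP, mu = m$mu, n = 2, mixture = FALSE)
    ref <- if (rhoP == m$rho) 0.5 * val else ref + 0.5 * val
  }
  expect_equal(h, ref, tolerance = 1e-12)
})

test_that("lookahead and plain filters estimate the same posterior", {
  m <- const_model()
  set.seed(65)
  sim <- simulate_genomes(m, n = 4, L = 1e5)
  run1 <- function(la) {
    f <- run_filter(sim$obs, m, n_particles = 400, lookahead = la)
    c(f$loglik, sum(f$final_w * f$final_B))
  }
  set.seed(66)
  a <- replicate(6, run1(FALSE))
  b <- replicate(6, run1(TRUE))
  se <- function(x) sd(x) / sqrt(length(x))
  expect_lt(abs(mean(a[1, ]) - mean(b[1, ])),
            3 * sqrt(se(a[1, ])^2 + se(b[1, ])^2))
  expect_lt(abs(mean(a[2, ]) - mean(b[2, ])),
            3 * sqrt(se(a[2, ])^2 + se(b[2, ])^2))
})
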