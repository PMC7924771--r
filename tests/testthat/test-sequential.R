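test_that("jump distances are exponential with rate rho * B", {
  m <- const_model(rho = 1e-8)
  g <- g2(2e4)  # B = 4e4, rate = 4e-4 per bp, mean 2500
  set.seed(1)
  d <- replicate(4000, sample_jump(g, 0, m)$locus)
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 2500), 3 * se)
  # overshooting the sequence end returns the Inf sentinel
  set.seed(2)
  j <- sample_jump(g, 0, m, L = 1e-6)
  expect_identical(j$locus, Inf)
  expect_error(sample_jump(g2(0.1) , 0, const_model(rho = 0), L = -1), "beyond")
})

test_that("recombination points fall on branches proportionally to length", {
  m <- const_model()
  g <- g3(1000, 4000)  # branch lengths: 1000, 1000, 4000, 3000
  set.seed(3)
  br <- replicate(4000, sample_jump(g, 0, m)$branch)
  len <- coalpf:::branch_lengths(g)
  p <- len / sum(len)
  for (v in 1:4) {
    ph <- mean(br == v)
    expect_lt(abs(ph - p[v]), 3 * sqrt(p[v] * (1 - p[v]) / 4000) + 1e-3)
  }
})

test_that("re-coalescence follows the b_u C(u) hazard and SMC' semantics", {
  m <- const_model(ne = 1e4)
  g <- g2(3e4)
  set.seed(4)
  out <- replicate(2000, {
    r <- apply_recombination(g, 1, 1e4, m)
    c(r$record$tau, r$record$changed_tree, tmrca(r$genealogy))
  })
  taus <- out[1, ]
  # time-rescaling: the integrated hazard at tau is Exp(1)
  H <- vapply(taus, function(tt)
    coalpf:::cpp_coal_hazard(coalpf:::as_cpp_tree(g), 1e4, tt,
                             coalpf:::as_engine_model(m)), numeric(1))
  expect_gt(suppressWarnings(ks.test(H, "pexp", 1)$p.value), 1e-4)
  # silent events (re-coalescence into the origin branch) leave the tree be
  silent <- out[2, ] == 0
  expect_true(any(silent) && any(!silent))
  expect_true(all(out[3, silent] == 3e4))
  # for n=2 a change above the old TMRCA sets the new TMRCA to tau
  hi <- !silent & taus > 3e4
  expect_true(all(abs(out[3, hi] - taus[hi]) < 1e-9))
  expect_error(apply_recombination(g, 1, 5e4, m), "span")
})

test_that("marginal genealogy law is stationary along the genome", {
  m <- const_model(ne = 1e4)
  set.seed(5)
  v <- unlist(lapply(1:25, function(i) {
    s <- simulate_genomes(m, n = 2, L = 4e6, window = 100)
    s$truth$tmrca[seq(1, nrow(s$truth), by = 5000)]
  }))
  expect_gt(suppressWarnings(ks.test(v, "pexp", 1 / 2e4)$p.value), 1e-4)
})

test_that("log prior path density composes and matches the no-event term", {
  m <- const_model(rho = 1e-8)
  g <- g2(2e4)
  expect_equal(log_prior_path_density(g, list(), c(0, 1e4), m),
               -1e-8 * 4e4 * 1e4)
  # one-event density: survival * rho * C(tau) * exp(-hazard)
  set.seed(6)
  p <- advance_particle(list(tree = g, log_w = 0), 0, 5e4, NULL, m)
  if (length(p$records)) {
    lp <- log_prior_path_density(g, p$records, c(0, 5e4), m)
    expect_true(is.finite(lp))
    # additivity under splitting at an interior point
    cut <- p$records[[1]]$locus + 0.5 * (5e4 - p$records[[1]]$locus)
    left <- Filter(function(r) r$locus < cut, p$records)
    right <- Filter(function(r) r$locus >= cut, p$records)
    gmid <- Reduce(coalpf:::replay_record, left, g)
    expect_equal(lp, log_prior_path_density(g, left, c(0, cut), m) +
                   log_prior_path_density(gmid, right, c(cut, 5e4), m),
                 tolerance = 1e-9)
  }
})

test_that("accumulated sufficient statistics are additive and consistent", {
  m <- two_epoch_model(ne = c(5000, 2e4), split = 8000, rho = 2e-8)
  set.seed(7)
  g <- sample_stationary_tree(m, 4)
  # no events: recombination opportunity is B * length, counts zero
  s0 <- accumulate_stats(g, list(), c(0, 1000), m)
  expect_equal(sum(s0$recomb_opp), total_branch_length(g) * 1000)
  expect_equal(sum(s0$recomb_count) + sum(s0$coal_count), 0)

  p <- advance_particle(list(tree = g, log_w = 0), 0, 2e5, NULL, m)
  s <- accumulate_stats(g, p$records, c(0, 2e5), m)
  expect_equal(sum(s$recomb_count), length(p$records))
  expect_equal(sum(s$coal_count), length(p$records))
  # a coalescence at tau in epoch 2 is counted there only
  for (r in p$records) {
    e <- if (r$tau >= 8000) 2 else 1
    expect_equal(r$epoch_tau, e)
  }
  # additivity over a split of the interval
  cut <- 1e5
  left <- Filter(function(r) r$locus < cut, p$records)
  right <- Filter(function(r) r$locus >= cut, p$records)
  gmid <- Reduce(coalpf:::replay_record, left, g)
  sl <- accumulate_stats(g, left, c(0, cut), m)
  sr <- accumulate_stats(gmid, right, c(cut, 2e5), m)
  for (cl in c("recomb_count", "recomb_opp", "coal_count", "coal_opp"))
    expect_equal(s[[cl]], sl[[cl]] + sr[[cl]], tolerance = 1e-9)
})

test_that("simulated event frequencies match their rates (generative check)", {
  m <- const_model(ne = 8000, rho = 2e-8)
  set.seed(8)
  g <- sample_stationary_tree(m, 4)
  p <- advance_particle(list(tree = g, log_w = 0), 0, 1e6, NULL, m)
  s <- accumulate_stats(g, p$records, c(0, 1e6), m)
  # counts / opportunity estimate rho and C (Poisson MC error)
  rho_hat <- sum(s$recomb_count) / sum(s$recomb_opp)
  expect_lt(abs(rho_hat - 2e-8), 3 * sqrt(sum(s$recomb_count)) / sum(s$recomb_opp))
  C_hat <- sum(s$coal_count) / sum(s$coal_opp)
  expect_lt(abs(C_hat - 1 / 16000), 3 * sqrt(sum(s$coal_count)) / sum(s$coal_opp))
})

test_that("advance_particle honours its weight contract", {
  m <- const_model(rho = 0, mu = 2.5e-8)  # no jumps: weight is the exponent only
  g <- g2(1e4)
  p <- advance_particle(list(tree = g, log_w = 0), 0, 0, NULL, m)
  expect_equal(p$log_w, 0)
  expect_equal(p$tree, g)
  p <- advance_particle(list(tree = g, log_w = 0), 0, 5e4, NULL, m)
  expect_equal(p$log_w, -2.5e-8 * 2e4 * 5e4)
})

test_that("multiplicity bundles are equivalent to independent advances", {
  m <- const_model(ne = 1e4, rho = 1e-8)
  g <- g2(2e4)
  # k = 1 is identical to advance_particle at the same seed
  set.seed(9)
  a <- multiplicity_advance(list(tree = g, log_w = 0, multiplicity = 1L),
                            0, 1e4, NULL, m)
  set.seed(9)
  b <- advance_particle(list(tree = g, log_w = 0), 0, 1e4, NULL, m)
  expect_length(a, 1)
  expect_equal(a[[1]]$tree, b$tree)
  expect_equal(a[[1]]$log_w, b$log_w)

  # time to first spawn ~ Exp(k * rho * B); truncation at 2e4 is negligible
  set.seed(10)
  k <- 3
  d <- replicate(2000, {
    out <- multiplicity_advance(list(tree = g, log_w = 0, multiplicity = k),
                                0, 2e4, NULL, m)
    if (length(out) > 1) out[[1]]$records[[1]]$locus else NA_real_
  })
  d <- d[!is.na(d)]
  rate <- k * m$rho * 4e4
  expect_lt(abs(mean(d) - 1 / rate), 3 * sd(d) / sqrt(length(d)))

  # first-event loci across the bundle match k independent advances
  set.seed(11)
  bundle <- unlist(replicate(600, {
    out <- multiplicity_advance(list(tree = g, log_w = 0, multiplicity = k),
                                0, 2e4, NULL, m)
    vapply(out, function(q) if (length(q$records)) q$records[[1]]$locus else Inf,
           numeric(1))
  }))
  indep <- unlist(replicate(600, {
    replicate(k, {
      p <- advance_particle(list(tree = g, log_w = 0), 0, 2e4, NULL, m)
      if (length(p$records)) p$records[[1]]$locus else Inf
    })
  }))
  bf <- bundle[is.finite(bundle)]; bi <- indep[is.finite(indep)]
  expect_lt(abs(mean(is.finite(bundle)) - mean(is.finite(indep))), 0.05)
  expect_gt(suppressWarnings(ks.test(bf, bi)$p.value), 1e-4)
})
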