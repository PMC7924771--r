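test_that("pattern likelihood is mu times the matching branch length", {
  mu <- 2.5e-8
  g <- g2(1e4)
  expect_equal(pattern_likelihood(g, c(1L, 0L), mu), mu * 1e4)
  expect_equal(pattern_likelihood(g, c(0L, 1L), mu), mu * 1e4)

  g <- g4(1000, 2000, 5000)
  # (1,1,0,0) matches exactly the branch above the (1,2) cherry
  expect_equal(pattern_likelihood(g, c(1L, 1L, 0L, 0L), mu), mu * (5000 - 1000))
  # (1,0,1,0) matches no branch
  expect_equal(pattern_likelihood(g, c(1L, 0L, 1L, 0L), mu), 0)
  # brute force over all branches via descendant sets
  d <- coalpf:::descendant_tips(g)
  len <- coalpf:::branch_lengths(g)
  for (A in list(c(1L,0L,0L,0L), c(0L,0L,1L,1L), c(1L,1L,1L,1L))) {
    ref <- sum(len[vapply(seq_along(d), function(v)
      setequal(d[[v]], which(A == 1)) && len[v] > 0, logical(1))])
    expect_equal(pattern_likelihood(g, A, mu), mu * ref)
  }
  expect_error(pattern_likelihood(g, c(NA, NA, NA, NA), mu), "missing")
  expect_error(pattern_likelihood(g, c(0L, 0L, 0L, NA), mu), "carrier")
})

test_that("missing tips are marginalised", {
  mu <- 1e-8
  g <- g4(1000, 2000, 5000)
  # tip 2 missing: carriers {1} now also matched by the (1,2) cherry branch
  expect_equal(pattern_likelihood(g, c(1L, NA, 0L, 0L), mu),
               mu * (1000 + (5000 - 1000)))
})

test_that("the emission normalisation identity holds exactly", {
  m <- const_model()
  mu <- m$mu
  set.seed(20)
  for (i in 1:100) {
    n <- sample(2:8, 1)
    g <- sample_stationary_tree(m, n)
    tot <- sum(apply(all_patterns(n), 1, function(A)
      pattern_likelihood(g, as.integer(A), mu)))
    expect_equal(tot, mu * total_branch_length(g), tolerance = 1e-12)
  }
})

test_that("unphased likelihoods sum the compatible phasings", {
  mu <- 2.5e-8
  g <- g4(1000, 2000, 5000)
  # one heterozygous individual: sum of its two terminal branch lengths
  expect_equal(unphased_pattern_likelihood(g, c(1L, 0L), mu), mu * (1000 + 1000))
  # homozygous-alt individual: identical to the phased (1,1,0,0) pattern
  expect_equal(unphased_pattern_likelihood(g, c(2L, 0L), mu),
               pattern_likelihood(g, c(1L, 1L, 0L, 0L), mu))
  # general: equals the sum over explicit phasings, enumerated
  set.seed(21)
  for (i in 1:20) {
    n <- sample(c(4L, 6L), 1)
    g <- sample_stationary_tree(const_model(), n)
    geno <- sample(0:2, n / 2, replace = TRUE)
    if (sum(geno) == 0) geno[1] <- 1L
    combos <- as.matrix(expand.grid(rep(list(0:1), n / 2)))
    tot <- 0
    for (r in seq_len(nrow(combos))) {
      A <- integer(n)
      ok <- TRUE
      for (j in seq_len(n / 2)) {
        gj <- geno[j]
        if (gj == 0) { A[2*j-1] <- 0L; A[2*j] <- 0L }
        else if (gj == 2) { A[2*j-1] <- 1L; A[2*j] <- 1L }
        else { A[2*j-1] <- combos[r, j]; A[2*j] <- 1L - combos[r, j] }
      }
      if (ok) tot <- tot + pattern_likelihood(g, A, mu)
    }
    # each non-het individual contributes identical terms 2^(n/2 - het) times
    nhet <- sum(geno == 1)
    tot <- tot / 2^(n / 2 - nhet)
    expect_equal(unphased_pattern_likelihood(g, geno, mu), tot, tolerance = 1e-12)
  }
  expect_error(unphased_pattern_likelihood(g3(1, 2), c(1L), mu), "even number")
})

test_that("segment log-density composes exponent and site factors", {
  mu <- 2.5e-8
  g <- g2(1e4)
  expect_equal(segment_log_density(g, c(0, 1000), NULL, mu), -2 * mu * 1e4 * 1000)
  # empty mask: unobserved intervals drop out entirely
  mk <- observed_mask(0, 1, L = 1e6)
  expect_equal(segment_log_density(g, c(10, 1000), NULL, mu, mk), 0)
  # one singleton composes the two factors
  ob <- observation(loci = 500, patterns = matrix(c(1L, 0L)), L = 1e6)
  expect_equal(segment_log_density(g, c(0, 1000), ob, mu),
               -2 * mu * 1e4 * 1000 + log(mu * 1e4))
  expect_error(segment_log_density(g, c(0, 400), ob, mu), "outside")
})

test_that("shrinking the mask never decreases the no-event factor", {
  mu <- 2.5e-8
  g <- g4()
  set.seed(22)
  for (i in 1:20) {
    a <- sort(runif(4, 0, 1e4))
    full <- observed_mask(c(a[1], a[3]), c(a[2], a[4]), L = 1e4)
    part <- observed_mask(a[1], a[2], L = 1e4)
    expect_gte(segment_log_density(g, c(0, 1e4), NULL, mu, part),
               segment_log_density(g, c(0, 1e4), NULL, mu, full))
  }
})
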