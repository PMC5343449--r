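# Genetic algorithm: roulette selection, crossover, mutation, knockout

test_that("selection distribution follows the squared min-centered payoff", {
  expect_equal(selection_distribution(c(0, 3, 6)), c(0, 0.2, 0.8))
  expect_equal(selection_distribution(c(-2, 4)), c(0, 1))
  # degenerate all-equal payoffs fall back to uniform
  expect_equal(selection_distribution(c(5, 5, 5)), rep(1 / 3, 3))
  expect_equal(selection_distribution(0), 1)
  expect_error(selection_distribution(numeric(0)), "non-empty")
})

test_that("selection distribution normalizes and is shift-invariant", {
  set.seed(4)
  for (i in 1:50) {
    U <- rnorm(sample(2:30, 1), sd = 10)
    Pi <- selection_distribution(U)
    expect_true(all(Pi >= 0))
    expect_equal(sum(Pi), 1, tolerance = 1e-12)
    expect_equal(selection_distribution(U + 17.3), Pi, tolerance = 1e-12)
  }
})

test_that("select_parents draws i.i.d. from the distribution", {
  set.seed(1)
  expect_identical(select_parents(c(0, 1)), c(2L, 2L))
  # zero-mass index never drawn
  draws <- replicate(500, select_parents(c(0, 0.2, 0.8)))
  expect_false(any(draws == 1L))
  # 50/50 mass: frequency within 3 sigma of one half over 10,000 draws
  draws <- replicate(5000, select_parents(c(0.5, 0.5)))
  expect_lt(abs(mean(draws == 1L) - 0.5), 3 * 0.5 / sqrt(10000))
})

test_that("uniform crossover copies each locus from either parent", {
  set.seed(2)
  expect_identical(uniform_crossover("ALLG", "ALLG"), "ALLG")
  expect_identical(uniform_crossover("SJ", "SJ"), "SJ")
  expect_identical(unique(uniform_crossover(rep("SJ", 50), rep("SJ", 50))),
                   "SJ")
  # offspring loci come from one of the parents
  kids <- uniform_crossover(rep("SH", 200), rep("ST", 200))
  # SH = GBBB, ST = GGBG: loci 1 and 3 agree, so every child has G?B?
  expect_true(all(grepl("^G.B.$", norm_label(norm_code(kids), genotype = TRUE))))
})

test_that("crossover of GGGG x BBBB is uniform over the 16 norms", {
  set.seed(3)
  kids <- uniform_crossover(rep(15L, 16000L), rep(0L, 16000L))
  tab <- tabulate(kids + 1L, nbins = 16L)
  expect_gt(stats::chisq.test(tab)$p.value, 1e-3)
})

test_that("mutation inverts loci independently at rate m", {
  set.seed(5)
  norms <- random_norms(100)
  expect_identical(mutate(norms, 0), norms)
  expect_identical(mutate(15L, 1), 0L)
  expect_identical(mutate("ALLB", 1), "ALLG")
  # Monte Carlo per-locus flip rate vs binomial at m = 0.1
  n <- 20000L
  flipped <- mutate(rep(0L, n), 0.1)
  nbits <- sapply(0:15, function(k) sum(bitwAnd(bitwShiftR(k, 0:3), 1L)))
  rate <- sum(nbits[flipped + 1L]) / (4 * n)
  expect_lt(abs(rate - 0.1), 4 * sqrt(0.1 * 0.9 / (4 * n)))
})

test_that("enforce_knockout reassigns uniformly over the complement and is idempotent", {
  expect_identical(enforce_knockout(c("SH", "SJ"), character()), c("SH", "SJ"))
  set.seed(6)
  out <- enforce_knockout(rep("SH", 15000L), "SH")
  expect_false(any(out == "SH"))
  tab <- table(factor(out, levels = setdiff(norm_labels(), "SH")))
  expect_gt(stats::chisq.test(as.integer(tab))$p.value, 1e-3)
  # multiple simultaneous knockouts: uniform over the remaining 14
  out2 <- enforce_knockout(rep(c("SH", "IS"), 7000L), c("SH", "IS"))
  expect_false(any(out2 %in% c("SH", "IS")))
  tab2 <- table(factor(out2, levels = setdiff(norm_labels(), c("SH", "IS"))))
  expect_gt(stats::chisq.test(as.integer(tab2))$p.value, 1e-3)
  # idempotence: a knockout-free population passes through unchanged
  expect_identical(enforce_knockout(out, "SH"), out)
  expect_error(enforce_knockout("SJ", norm_labels()), "strict subset")
})

test_that("next_generation keeps fixed points and conserves population size", {
  cfg <- tiny_config(N = 10, m = 0)
  set.seed(7)
  # monomorphic ALLG with zero mutation is an exact fixed point
  expect_identical(next_generation(rep("ALLG", 10), rep(1, 10), cfg),
                   rep("ALLG", 10))
  # point-mass selection on a single SJ agent
  U <- c(rep(0, 9), 10)
  norms <- c(random_norms(9), norm_code("SJ"))
  norms[1:9] <- norm_code("ALLB")
  expect_identical(next_generation(norm_label(norms), U, cfg), rep("SJ", 10))
  # size conserved for arbitrary inputs
  cfg2 <- tiny_config(N = 10, m = 0.3, knockout = "SH")
  out <- next_generation(random_norms(10), rnorm(10), cfg2)
  expect_length(out, 10)
  expect_false(any(out == norm_code("SH")))
  expect_error(next_generation(random_norms(3), rnorm(4), cfg), "equal length")
})

test_that("mutation keeps the norm space ergodic", {
  cfg <- tiny_config(N = 30, m = 0.25)
  set.seed(8)
  seen <- logical(16)
  norms <- rep(norm_code("ALLB"), 30)
  for (g in 1:40) {
    norms <- next_generation(norms, rep(1, 30), cfg)
    seen[unique(norms) + 1L] <- TRUE
  }
  expect_true(all(seen))
})
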