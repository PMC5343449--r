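# Game engine: generation state, round phases, conservation, and
# agreement between the compiled and reference engines

test_that("init_generation sets all-Good images and zero payoffs", {
  cfg <- tiny_config(N = 3)
  st <- init_generation(cfg, rep("SJ", 3))
  expect_identical(st$images, matrix(1L, 3, 3))
  expect_identical(st$U, c(0, 0, 0))
  expect_identical(st$W, integer(3))
  expect_identical(st$V, integer(3))
  # boundary: N = 2 is valid
  st2 <- init_generation(tiny_config(N = 2), c("ALLG", "ALLB"))
  expect_identical(dim(st2$images), c(2L, 2L))
  expect_error(init_generation(cfg, rep("SJ", 4)), "length N")
  expect_error(
    init_generation(tiny_config(N = 3, knockout = "SH"), c("SH", "SJ", "ST")),
    "knocked-out"
  )
})

test_that("phase A pays b to the recipient and c by the donor per realized C", {
  cfg <- tiny_config(N = 4, b = 5, c = 1, q = 0)
  st <- init_generation(cfg, rep("ALLG", 4))
  set.seed(7)
  ph <- play_phase_A(st)
  rec <- ph$record
  expect_true(all(rec$recipient != seq_len(4)))
  expect_true(all(rec$recipient %in% 1:4))
  # all images Good and q = 0: everyone cooperates
  expect_identical(rec$intended, rep(1L, 4))
  expect_identical(rec$realized, rep(1L, 4))
  expect_equal(ph$state$U, 5 * ph$state$W - 1)
  expect_equal(sum(ph$state$U), 4 * (5 - 1))
  # a donor with a Bad image of its recipient defects, nothing transfers
  st$images[1, ] <- 0L
  st$images[1, 1] <- 1L
  set.seed(7)
  ph2 <- play_phase_A(st)
  expect_identical(ph2$record$realized[1], 0L)
  expect_identical(ph2$state$V[1], 0L)
})

test_that("q = 0.5 realizes roughly half the intended actions", {
  cfg <- tiny_config(N = 200, q = 0.5)
  st <- init_generation(cfg, rep("ALLG", 200))
  set.seed(11)
  flips <- replicate(50, mean(play_phase_A(st)$record$realized))
  # binomial(10000, 1/2) mean within 4 sigma
  expect_lt(abs(mean(flips) - 0.5), 4 * 0.5 / sqrt(200 * 50))
})

test_that("phase B follows the hand-traced ALLB round and the ALLG fixed point", {
  # all-ALLB, images all Good entering round 1, p = q = 0: everyone
  # cooperates in round 1 and every off-diagonal image turns Bad
  cfg <- tiny_config(N = 5, R = 1, q = 0, p = 0)
  st <- init_generation(cfg, rep("ALLB", 5))
  set.seed(3)
  ph <- play_phase_A(st)
  expect_identical(sum(ph$record$realized), 5L)
  st2 <- play_phase_B(ph$state, ph$record)
  expected <- matrix(0L, 5, 5)
  diag(expected) <- 1L
  expect_identical(st2$images, expected)
  # all-ALLG: images stay Good for any record when p = 0
  stg <- init_generation(cfg, rep("ALLG", 5))
  set.seed(3)
  phg <- play_phase_A(stg)
  expect_identical(play_phase_B(phg$state, phg$record)$images,
                   matrix(1L, 5, 5))
})

test_that("p = 1 negates every off-diagonal assessment", {
  cfg <- tiny_config(N = 6, p = 1, q = 0)
  st <- init_generation(cfg, rep("ALLG", 6))
  set.seed(5)
  ph <- play_phase_A(st)
  st2 <- play_phase_B(ph$state, ph$record)
  # ALLG assesses everything Good; forced flip makes all off-diagonal Bad
  expected <- matrix(0L, 6, 6)
  diag(expected) <- 1L
  expect_identical(st2$images, expected)
})

test_that("an all-ALLB generation cooperates only in round 1 (ratio 1/R)", {
  for (R in c(1L, 5L, 10L)) {
    cfg <- tiny_config(N = 6, R = R)
    set.seed(R)
    res <- run_generation(cfg, rep("ALLB", 6))
    expect_identical(res$coop_counts, c(6L, integer(R - 1L)))
    expect_equal(cooperation_ratio(res$coop_counts, 6, R), 1 / R)
  }
})

test_that("a monomorphic ALLG population cooperates every round", {
  cfg <- tiny_config(N = 8, R = 7, b = 4)
  set.seed(2)
  res <- run_generation(cfg, rep("ALLG", 8))
  expect_identical(res$coop_counts, rep(8L, 7))
  expect_identical(sum(res$W), 8L * 7L)
  expect_equal(res$U, 4 * res$W - 1 * 7)
})

test_that("payoffs conserve: sum(U) = (b - c) * total realized cooperation", {
  for (seed in 1:100) {
    cfg <- random_small_config(seed)
    norms <- random_norms(cfg$N)
    res <- run_generation(cfg, norms)
    expect_equal(sum(res$U), (cfg$b - cfg$c) * sum(res$coop_counts),
                 tolerance = 1e-12)
    expect_equal(res$U, cfg$b * res$W - cfg$c * res$V)
  }
})

test_that("compiled and reference engines are bit-identical across 100 seeds", {
  for (seed in 1:100) {
    cfg <- random_small_config(seed)
    norms <- random_norms(cfg$N)
    set.seed(seed * 31L)
    fast <- run_generation(cfg, norms, engine = "fast")
    set.seed(seed * 31L)
    ref <- run_generation(cfg, norms, engine = "reference")
    expect_identical(fast$images, ref$images)
    expect_identical(fast$coop_counts, ref$coop_counts)
    expect_identical(fast$W, ref$W)
    expect_identical(fast$V, ref$V)
    expect_identical(fast$U, ref$U)
  }
})

test_that("perception error flips off-diagonal entries at rate p", {
  N <- 60L
  p <- 0.05
  set.seed(13)
  flips <- 0L
  trials <- 20L
  for (i in seq_len(trials)) {
    img <- matrix(1L, N, N)
    out <- normknockout:::apply_perception_error(img, p)
    expect_identical(diag(out), rep(1L, N))  # diagonal untouched
    flips <- flips + sum(out == 0L)
  }
  n <- trials * N * (N - 1)
  expect_lt(abs(flips / n - p), 4 * sqrt(p * (1 - p) / n))
})

test_that("image-matrix diagonal stays Good through every round", {
  for (seed in c(1, 2, 3)) {
    cfg <- tiny_config(N = 10, R = 12, p = 0.3, q = 0.3)
    set.seed(seed)
    res <- run_generation(cfg, random_norms(10))
    expect_identical(diag(res$images), rep(1L, 10))
  }
})

test_that("lagged timing evaluates the previous round's record", {
  # all-ALLB lagged: round 1 evaluates a synthetic random record, but ALLB
  # assesses everything Bad regardless, so cooperation still dies after
  # round 1; the engines agree under lagged timing too (covered above via
  # random timing draws, pinned here explicitly)
  cfg <- tiny_config(N = 6, R = 4, timing = "lagged")
  set.seed(9)
  fast <- run_generation(cfg, rep("ALLB", 6))
  set.seed(9)
  ref <- run_generation(cfg, rep("ALLB", 6), engine = "reference")
  expect_identical(fast$images, ref$images)
  expect_identical(fast$coop_counts, ref$coop_counts)
  expect_identical(fast$coop_counts, c(6L, integer(3)))
})
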