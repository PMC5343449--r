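# shared fixture builders for the test suite

tiny_config <- function(N = 4L, R = 3L, G = 1L, b = 5, c = 1, p = 0, q = 0,
                        m = 0.01, knockout = character(),
                        timing = "same_round") {
  sim_config(N = N, G = G, R = R, b = b, c = c, p = p, q = q, m = m,
             knockout = knockout, timing = timing)
}

# random small config for property-style loops
random_small_config <- function(seed) {
  set.seed(seed)
  tiny_config(
    N = sample(2:12, 1), R = sample(1:8, 1),
    b = runif(1, 2, 6), c = 1,
    p = sample(c(0, runif(1, 0, 0.3)), 1),
    q = sample(c(0, runif(1, 0, 0.3)), 1),
    timing = sample(c("same_round", "lagged"), 1)
  )
}

random_norms <- function(N) sample(0:15, N, replace = TRUE)

# trajectory built directly from vectors, bypassing the simulator, for
# observable tests
synthetic_trajectory <- function(coop_ratio, majority, N = 100L) {
  stopifnot(length(coop_ratio) == length(majority))
  counts <- matrix(0L, length(coop_ratio), 16L,
                   dimnames = list(NULL, norm_labels()))
  counts[cbind(seq_along(majority), norm_code(majority) + 1L)] <- N
  cfg <- sim_config(N = N, G = length(coop_ratio), R = 10L)
  normknockout:::new_trajectory(coop_ratio, counts, cfg, 0L)
}
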