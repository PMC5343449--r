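# Game engine ------------------------------------------------------------
#
# One generation = R rounds. Each round has phase A (every agent donates
# once to a random recipient, paying c and conferring b on cooperation)
# and phase B (every agent re-evaluates every donor under its norm, with
# perception error p), updated synchronously from the pre-phase-B matrix.
#
# Two engines share one documented RNG draw order and are bit-identical on
# the same stream: the compiled production engine (.engine_run_generation)
# and the naive double-loop reference below, kept deliberately literal as
# an executable description of the model.

#' Initialize the state of one generation
#'
#' All images start Good (self-images included), payoffs and donation
#' counters start at zero.
#'
#' @param config A [sim_config()].
#' @param norms Per-agent norms (labels or codes), length `config$N`; must
#'   not contain a knocked-out norm.
#' @return A `generation_state`: list with `images` (N x N integer matrix,
#'   entry (i, j) = agent i's image of agent j, 1 = Good), `norms`
#'   (integer codes), payoff vectors `U`, `W`, `V`, the `round` counter
#'   and the `config`.
#' @examples
#' st <- init_generation(sim_config(N = 3, G = 1, R = 1), rep("ALLG", 3))
#' st$images
#' @export
init_generation <- function(config, norms) {
  stopifnot(inherits(config, "sim_config"))
  codes <- norm_code(norms)
  if (length(codes) != config$N) {
    stop("norms must have length N = ", config$N, ", got ", length(codes),
         call. = FALSE)
  }
  if (length(config$knockout)) {
    bad <- codes %in% norm_code(config$knockout)
    if (any(bad)) {
      stop("knocked-out norm(s) present in the population: ",
           paste(unique(norm_label(codes[bad])), collapse = ", "),
           call. = FALSE)
    }
  }
  N <- config$N
  structure(
    list(images = matrix(1L, N, N), norms = codes,
         U = numeric(N), W = integer(N), V = integer(N),
         round = 0L, config = config),
    class = "generation_state"
  )
}

# recipient draw shared by both engines: one uniform per donor, uniform
# over the N-1 other agents
draw_recipients <- function(N) {
  u <- stats::runif(N)
  k <- pmin(floor(u * (N - 1)), N - 2)
  k <- ifelse(k >= seq_len(N) - 1L, k + 1, k)
  as.integer(k + 1)
}

#' Phase A: play the giving games of one round
#'
#' Every agent acts once as donor toward a recipient drawn uniformly from
#' the other N - 1 agents. The intended action is C iff the donor's image
#' of its recipient is Good; the realized action is the intended one
#' inverted independently with probability q. Each realized cooperation
#' costs the donor c and confers b on the recipient.
#'
#' @param state A `generation_state`.
#' @return List with the updated `state` and the round `record`: a list
#'   with integer vectors `recipient`, `intended` and `realized`
#'   (1 = C, 0 = D).
#' @export
play_phase_A <- function(state) {
  cfg <- state$config
  N <- cfg$N
  recipient <- draw_recipients(N)
  intended <- state$images[cbind(seq_len(N), recipient)]
  u <- stats::runif(N)
  realized <- ifelse(u < cfg$q, 1L - intended, intended)
  for (j in seq_len(N)) {
    if (realized[j] == 1L) {
      state$U[j] <- state$U[j] - cfg$c
      state$V[j] <- state$V[j] + 1L
      state$U[recipient[j]] <- state$U[recipient[j]] + cfg$b
      state$W[recipient[j]] <- state$W[recipient[j]] + 1L
    }
  }
  list(state = state,
       record = list(recipient = recipient, intended = as.integer(intended),
                     realized = as.integer(realized)))
}

# perception-error flips: exact i.i.d. Bernoulli(p) over the off-diagonal
# entries in column-major order, via geometric skipping (no draws at p = 0)
apply_perception_error <- function(images, p) {
  N <- nrow(images)
  if (p <= 0) return(images)
  if (p >= 1) {
    flipped <- 1L - images
    diag(flipped) <- diag(images)
    return(flipped)
  }
  total <- as.double(N) * (N - 1)
  denom <- log(1 - p)
  t <- -1
  repeat {
    u <- stats::runif(1)
    t <- t + 1 + floor(log(u) / denom)
    if (t >= total) break
    j0 <- t %/% (N - 1)
    i0 <- t %% (N - 1)
    if (i0 >= j0) i0 <- i0 + 1
    images[i0 + 1, j0 + 1] <- 1L - images[i0 + 1, j0 + 1]
  }
  images
}

#' Phase B: update all images from a round record
#'
#' Every observer i re-evaluates every donor j (i != j) under i's norm,
#' using j's realized action and i's pre-update image of j's recipient;
#' the whole matrix is updated synchronously, then each off-diagonal entry
#' is inverted independently with probability p. Self-images stay Good.
#'
#' Which record is evaluated depends on the configured timing: the caller
#' passes the current round's record (`same_round`) or the previous one
#' (`lagged`).
#'
#' @param state A `generation_state`.
#' @param record A round record as returned by [play_phase_A()].
#' @return The state with its image matrix updated.
#' @export
play_phase_B <- function(state, record) {
  cfg <- state$config
  N <- cfg$N
  old <- state$images
  new <- old
  for (j in seq_len(N)) {
    a <- record$realized[j]
    k <- record$recipient[j]
    for (i in seq_len(N)) {
      if (i == j) next
      new[i, j] <- assess_bit(state$norms[i], a, old[i, k])
    }
    new[j, j] <- 1L
  }
  state$images <- apply_perception_error(new, cfg$p)
  state$round <- state$round + 1L
  state
}

#' Run one generation of the giving game
#'
#' Executes R rounds of phase A then phase B under the configured
#' evaluation timing and returns the accumulated payoffs and per-round
#' realized cooperation counts. `engine = "fast"` runs the compiled
#' production engine; `engine = "reference"` runs the naive double-loop
#' implementation. Both consume the RNG stream identically and return
#' bit-identical results.
#'
#' @param config A [sim_config()].
#' @param norms Per-agent norms (labels or codes), length N.
#' @param engine `"fast"` (compiled) or `"reference"` (naive R).
#' @return List with `U` (accumulated payoffs, `U = b*W - c*V`), `W`
#'   (donations received), `V` (donations given), `coop_counts`
#'   (realized cooperations per round) and `images` (final image matrix).
#' @examples
#' cfg <- sim_config(N = 4, G = 1, R = 5, b = 5)
#' set.seed(1)
#' run_generation(cfg, rep("ALLG", 4))$coop_counts
#' @export
run_generation <- function(config, norms, engine = c("fast", "reference")) {
  engine <- match.arg(engine)
  stopifnot(inherits(config, "sim_config"))
  codes <- norm_code(norms)
  if (length(codes) != config$N) {
    stop("norms must have length N = ", config$N, call. = FALSE)
  }
  if (engine == "fast") {
    res <- .engine_run_generation(codes, config$R, config$b, config$c,
                                  config$p, config$q,
                                  config$timing == "lagged")
    return(res)
  }
  run_generation_reference(config, codes)
}

# naive reference engine: literal double-loop transcription of the model
run_generation_reference <- function(config, codes) {
  state <- init_generation(config, codes)
  N <- config$N
  lagged <- config$timing == "lagged"
  prev <- NULL
  if (lagged) {
    rec0 <- draw_recipients(N)
    u <- stats::runif(N)
    prev <- list(recipient = rec0, intended = as.integer(u < 0.5),
                 realized = as.integer(u < 0.5))
  }
  coop <- integer(config$R)
  for (r in seq_len(config$R)) {
    phA <- play_phase_A(state)
    state <- phA$state
    coop[r] <- sum(phA$record$realized)
    state <- play_phase_B(state, if (lagged) prev else phA$record)
    if (lagged) prev <- phA$record
  }
  list(U = state$U, W = state$W, V = state$V, coop_counts = coop,
       images = state$images)
}
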