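# Genetic algorithm ------------------------------------------------------
#
# End-of-generation norm update: squared min-centered payoff roulette
# selection of two parents per offspring slot (with replacement, self
# allowed), per-locus uniform crossover, per-locus mutation, and knockout
# enforcement. All offspring descend from the same parent generation
# (synchronous replacement).

#' Roulette-selection distribution from accumulated payoffs
#'
#' Selection probabilities are proportional to the squared min-centered
#' payoff: `Pi_i = (U_i - U_min)^2 / sum_j (U_j - U_min)^2`. When all
#' payoffs are equal the formula is 0/0; the distribution is then uniform,
#' the unique symmetric completion.
#'
#' @param U Numeric vector of accumulated payoffs.
#' @return Numeric vector of selection probabilities summing to 1.
#' @examples
#' selection_distribution(c(0, 3, 6))  # 0, 0.2, 0.8
#' @export
selection_distribution <- function(U) {
  if (length(U) == 0L) stop("payoff vector must be non-empty", call. = FALSE)
  d <- (U - min(U))^2
  s <- sum(d)
  if (s == 0) rep(1 / length(U), length(U)) else d / s
}

# inverse-CDF index draw; one uniform per index
roulette_index <- function(u, cum) {
  idx <- findInterval(u, cum) + 1L
  pmin(idx, length(cum))
}

#' Draw two parents from a selection distribution
#'
#' Parents are drawn i.i.d. with replacement (an agent may be selected
#' twice, and may be its own parent).
#'
#' @param dist Selection probabilities (see [selection_distribution()]).
#' @return Integer vector of two parent indices.
#' @export
select_parents <- function(dist) {
  cum <- cumsum(dist)
  roulette_index(stats::runif(2), cum)
}

# locus bit weights, locus 1 first
.locus_weights <- c(8L, 4L, 2L, 1L)

#' Uniform crossover of two norms
#'
#' Each of the four loci is independently copied from either parent with
#' probability 1/2. Vectorized over pairs of parents; draw order is the
#' 4 locus uniforms of pair 1, then pair 2, and so on.
#'
#' @param parent_a,parent_b Norm labels or codes (recycled to equal length).
#' @return Offspring norms, as labels if `parent_a` is character, else codes.
#' @examples
#' set.seed(1)
#' uniform_crossover("ALLG", "ALLB")
#' @export
uniform_crossover <- function(parent_a, parent_b) {
  a <- norm_code(parent_a)
  b <- norm_code(parent_b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  take_a <- matrix(stats::runif(4L * n) < 0.5, nrow = 4L)
  mask <- as.integer(.locus_weights %*% take_a)
  child <- bitwOr(bitwAnd(a, mask), bitwAnd(b, bitwAnd(bitwNot(mask), 15L)))
  if (is.character(parent_a)) norm_label(child) else child
}

#' Per-locus mutation
#'
#' Each locus is independently inverted (G to B or B to G) with
#' probability `m`. Draw order: the 4 locus uniforms of norm 1, then
#' norm 2, and so on.
#'
#' @param norm Norm labels or codes.
#' @param m Per-locus mutation probability.
#' @return Mutated norms, same representation as the input.
#' @export
mutate <- function(norm, m) {
  stopifnot(is.numeric(m), length(m) == 1L, m >= 0, m <= 1)
  code <- norm_code(norm)
  n <- length(code)
  flips <- matrix(stats::runif(4L * n) < m, nrow = 4L)
  out <- bitwXor(code, as.integer(.locus_weights %*% flips))
  if (is.character(norm)) norm_label(out) else out
}

#' Enforce a norm knockout on a population
#'
#' Every agent whose norm is in the knockout set is reassigned a norm
#' drawn uniformly from the non-knocked-out norms; other agents are
#' untouched. Idempotent.
#'
#' @param norms Per-agent norm labels or codes.
#' @param knockout Norm labels or codes to exclude (strict subset of the
#'   16 norms); empty for a no-op.
#' @return Norms with the knockout applied, same representation as input.
#' @export
enforce_knockout <- function(norms, knockout) {
  code <- norm_code(norms)
  if (length(knockout) == 0L) {
    return(if (is.character(norms)) norm_label(code) else code)
  }
  ko <- unique(norm_code(knockout))
  if (length(ko) >= 16L) {
    stop("knockout must be a strict subset of the 16 norms", call. = FALSE)
  }
  allowed <- setdiff(0:15, ko)
  hit <- which(code %in% ko)
  if (length(hit)) {
    u <- stats::runif(length(hit))
    code[hit] <- allowed[floor(u * length(allowed)) + 1L]
  }
  if (is.character(norms)) norm_label(code) else code
}

#' Produce the next generation of norms
#'
#' For each of the N offspring slots independently: draw two parents by
#' squared-payoff roulette, apply per-locus uniform crossover, then
#' per-locus mutation; finally enforce the knockout. Draw order: 2N parent
#' uniforms (pairs per slot), 4N crossover uniforms, 4N mutation uniforms,
#' then one uniform per knockout reassignment.
#'
#' @param norms Per-agent norm labels or codes of the parent generation.
#' @param U Accumulated payoffs of the parent generation.
#' @param config A [sim_config()] supplying `m` and `knockout`.
#' @return Offspring norms, same length and representation as `norms`.
#' @examples
#' cfg <- sim_config(N = 4, G = 1, R = 1, m = 0)
#' set.seed(1)
#' next_generation(rep("ALLG", 4), c(1, 1, 1, 1), cfg)  # fixed point
#' @export
next_generation <- function(norms, U, config) {
  stopifnot(inherits(config, "sim_config"))
  code <- norm_code(norms)
  N <- length(code)
  if (length(U) != N) {
    stop("norms and payoffs must have equal length", call. = FALSE)
  }
  cum <- cumsum(selection_distribution(U))
  u <- matrix(stats::runif(2L * N), nrow = 2L)
  pa <- code[roulette_index(u[1L, ], cum)]
  pb <- code[roulette_index(u[2L, ], cum)]
  child <- uniform_crossover(pa, pb)
  child <- mutate(child, config$m)
  child <- enforce_knockout(child, config$knockout)
  if (is.character(norms)) norm_label(child) else child
}
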