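# Simulation configuration ----------------------------------------------

#' Simulation configuration
#'
#' Bundles every parameter of a single simulation run: population size,
#' schedule, payoffs, error rates, mutation rate, the knockout set and the
#' image-evaluation timing.
#'
#' @param N Number of agents (>= 2).
#' @param G Number of generations (>= 1).
#' @param R Rounds of the giving game per generation (>= 1).
#' @param b Benefit received by a recipient of a donation; must exceed `c`.
#' @param c Cost paid by a cooperating donor; must be positive.
#' @param p Perception-error probability: each image update is recorded
#'   inverted independently with probability `p`.
#' @param q Implementation-error probability: each donor's action is
#'   executed inverted independently with probability `q`.
#' @param m Per-locus mutation probability in the genetic algorithm.
#' @param knockout Character vector of norm labels excluded from the
#'   population for the whole run (a strict subset of the 16 norms);
#'   empty for no knockout.
#' @param timing Image-evaluation timing. `"same_round"` (default):
#'   phase B of round t evaluates round t's realized actions and pairings
#'   against the pre-update image matrix. `"lagged"`: phase B of round t
#'   evaluates round t-1's record; in round 1 each donor is attributed a
#'   uniformly random action and recipient.
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' sim_config(N = 100, G = 50, R = 100, b = 5, knockout = "SH")
#' @export
sim_config <- function(N = 500L, G = 1000L, R = 500L, b = 5, c = 1,
                       p = 0, q = 0, m = 0.01, knockout = character(),
                       timing = c("same_round", "lagged")) {
  timing <- match.arg(timing)
  N <- as.integer(N); G <- as.integer(G); R <- as.integer(R)
  stopifnot(N >= 2L, G >= 1L, R >= 1L)
  if (!(b > c && c > 0)) stop("payoffs must satisfy b > c > 0", call. = FALSE)
  for (nm in c("p", "q", "m")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop(nm, " must be a probability in [0, 1]", call. = FALSE)
    }
  }
  ko <- unique(norm_code(knockout))
  if (length(ko) >= 16L) {
    stop("knockout must be a strict subset of the 16 norms", call. = FALSE)
  }
  structure(
    list(N = N, G = G, R = R, b = b, c = c, p = p, q = q, m = m,
         knockout = norm_label(ko), timing = timing),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  ko <- if (length(x$knockout)) paste(x$knockout, collapse = ", ") else "none"
  cat("Giving-game simulation configuration\n")
  cat(sprintf("  N = %d agents, G = %d generations, R = %d rounds/generation\n",
              x$N, x$G, x$R))
  cat(sprintf("  payoffs: b = %g, c = %g; errors: p = %g, q = %g; mutation m = %g\n",
              x$b, x$c, x$p, x$q, x$m))
  cat(sprintf("  knockout: %s; evaluation timing: %s\n", ko, x$timing))
  invisible(x)
}

#' Scale presets
#'
#' `"paper"` is the full published scale (N = 500, R = 500, G = 1000),
#' hours of compute per sweep; `"desk"` is a scaled-down configuration
#' (N = 200, R = 200, G = 500) that reproduces the qualitative phenomena
#' (cooperation emergence, knockout collapse) in minutes.
#'
#' @param scale `"paper"` or `"desk"`. (Named `scale` so that partial
#'   matching cannot capture the `p` error-rate override.)
#' @param ... Overrides passed on to [sim_config()] (e.g. `b`, `p`, `q`,
#'   `knockout`).
#' @return A `sim_config`.
#' @examples
#' sim_preset("desk", knockout = "IS")
#' @export
sim_preset <- function(scale = c("desk", "paper"), ...) {
  scale <- match.arg(scale)
  dims <- switch(scale,
                 paper = list(N = 500L, G = 1000L, R = 500L),
                 desk  = list(N = 200L, G = 500L, R = 200L))
  args <- utils::modifyList(dims, list(...))
  do.call(sim_config, args)
}

#' Default replication count for a preset
#'
#' 50 replications at full scale, 10 at desk scale.
#' @param scale `"paper"` or `"desk"`.
#' @return An integer.
#' @export
preset_replications <- function(scale = c("desk", "paper")) {
  switch(match.arg(scale), paper = 50L, desk = 10L)
}

#' Read a simulation configuration from a flat key/value file
#'
#' The file format is flat YAML-like `key: value` lines (or `key = value`),
#' with keys named as in the model description: `N`, `G`, `R`, `b`, `c`,
#' `p`, `q`, `m`, plus `knockout` (comma-separated labels) and `timing`.
#' Blank lines and `#` comments are ignored.
#'
#' @param path Path to the config file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "[:=]", fixed = FALSE)[[1]]
    if (length(parts) < 2L) {
      stop("malformed config line: ", ln, call. = FALSE)
    }
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = ":"))
    args[[key]] <- switch(key,
      N = , G = , R = as.integer(val),
      b = , c = , p = , q = , m = as.numeric(val),
      knockout = if (nzchar(val)) trimws(strsplit(val, ",")[[1]]) else character(),
      timing = val,
      stop("unknown config key: ", key, call. = FALSE)
    )
  }
  do.call(sim_config, args)
}
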