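# Replications and trajectory serialization ------------------------------

#' Run one replication of the full simulation
#'
#' Draws the initial norms uniformly from the non-knocked-out norms, then
#' loops G times: initialize the generation (all images Good, payoffs 0),
#' play R rounds of the giving game, and evolve the norms by the genetic
#' algorithm. The trajectory records, per generation, the cooperation
#' ratio and the census of the 16 norms of the population that played.
#'
#' All randomness is drawn from R's RNG seeded once with `seed`, with a
#' fixed documented draw order, so a (config, seed) pair reproduces the
#' trajectory bit-for-bit.
#'
#' @param config A [sim_config()].
#' @param seed Integer RNG seed for this replication.
#' @param engine Engine passed to [run_generation()]; the compiled
#'   `"fast"` engine is the default.
#' @return An `ir_trajectory`: a data frame with columns `generation`,
#'   `coop_ratio` and one count column per norm (named as
#'   [norm_labels()]), with the `config` and `seed` kept as attributes.
#' @examples
#' traj <- run_replication(sim_config(N = 30, G = 5, R = 20), seed = 1)
#' traj$coop_ratio
#' @export
run_replication <- function(config, seed, engine = c("fast", "reference")) {
  engine <- match.arg(engine)
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  N <- config$N
  allowed <- setdiff(0:15, norm_code(config$knockout))
  u <- stats::runif(N)
  norms <- allowed[floor(u * length(allowed)) + 1L]
  coop_ratio <- numeric(config$G)
  counts <- matrix(0L, config$G, 16L, dimnames = list(NULL, norm_labels()))
  for (g in seq_len(config$G)) {
    counts[g, ] <- tabulate(norms + 1L, nbins = 16L)
    res <- run_generation(config, norms, engine = engine)
    coop_ratio[g] <- cooperation_ratio(res$coop_counts, N, config$R)
    norms <- next_generation(norms, res$U, config)
  }
  new_trajectory(coop_ratio, counts, config, as.integer(seed))
}

new_trajectory <- function(coop_ratio, counts, config, seed) {
  traj <- data.frame(generation = seq_along(coop_ratio),
                     coop_ratio = coop_ratio)
  traj <- cbind(traj, as.data.frame(counts))
  attr(traj, "config") <- config
  attr(traj, "seed") <- seed
  class(traj) <- c("ir_trajectory", "data.frame")
  traj
}

#' Norm-census matrix of a trajectory
#'
#' @param traj An `ir_trajectory` (or any data frame with the 16 norm
#'   count columns).
#' @return Integer matrix, generations x 16, columns ordered by norm code.
#' @export
trajectory_counts <- function(traj) {
  miss <- setdiff(norm_labels(), names(traj))
  if (length(miss)) {
    stop("trajectory lacks norm count column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  as.matrix(traj[, norm_labels(), drop = FALSE])
}

#' @export
print.ir_trajectory <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Giving-game trajectory: %d generations (N = %d, R = %d, seed = %s)\n",
              nrow(x), cfg$N, cfg$R, format(attr(x, "seed"))))
  cat(sprintf("  final cooperation ratio %.3f, terminal majority norm %s\n",
              x$coop_ratio[nrow(x)],
              majority_norm(trajectory_counts(x)[nrow(x), ])))
  invisible(x)
}

# header keys serialized with a trajectory
.traj_header_keys <- c("N", "G", "R", "b", "c", "p", "q", "m",
                       "knockout", "timing", "seed")

#' Write / read a trajectory
#'
#' Trajectories are stored as plain-text CSV: `#key=value` header lines
#' carrying the full configuration and seed, then one row per generation
#' with `generation`, `coop_ratio` and the 16 norm-count columns headed by
#' the canonical norm labels. The round-trip is lossless.
#'
#' @param traj An `ir_trajectory`.
#' @param path File path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns the `ir_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  cfg <- attr(traj, "config")
  vals <- c(cfg[c("N", "G", "R", "b", "c", "p", "q", "m")],
            list(knockout = paste(cfg$knockout, collapse = ","),
                 timing = cfg$timing, seed = attr(traj, "seed")))
  header <- sprintf("#%s=%s", names(vals),
                    vapply(vals, function(v) format(v, digits = 17),
                           character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  df <- as.data.frame(traj)
  df$coop_ratio <- sprintf("%.17g", df$coop_ratio)  # lossless round-trip
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nhead <- length(.traj_header_keys)
  if (length(lines) < nhead + 2L) {
    stop("malformed trajectory file (line ", length(lines),
         "): truncated before data", call. = FALSE)
  }
  kv <- list()
  for (i in seq_len(nhead)) {
    ln <- lines[i]
    if (!startsWith(ln, "#") || !grepl("=", ln, fixed = TRUE)) {
      stop("malformed trajectory header (line ", i, "): ", ln, call. = FALSE)
    }
    eq <- regexpr("=", ln, fixed = TRUE)
    kv[[substr(ln, 2L, eq - 1L)]] <- substr(ln, eq + 1L, nchar(ln))
  }
  miss <- setdiff(.traj_header_keys, names(kv))
  if (length(miss)) {
    stop("trajectory header lacks key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cfg <- sim_config(
    N = as.integer(kv$N), G = as.integer(kv$G), R = as.integer(kv$R),
    b = as.numeric(kv$b), c = as.numeric(kv$c), p = as.numeric(kv$p),
    q = as.numeric(kv$q), m = as.numeric(kv$m),
    knockout = if (nzchar(kv$knockout)) strsplit(kv$knockout, ",")[[1]]
               else character(),
    timing = kv$timing
  )
  expected <- c("generation", "coop_ratio", norm_labels())
  head_fields <- strsplit(lines[nhead + 1L], ",", fixed = TRUE)[[1]]
  if (!identical(head_fields, expected)) {
    stop("malformed trajectory file (line ", nhead + 1L,
         "): expected columns ", paste(expected, collapse = ","),
         call. = FALSE)
  }
  body <- lines[-seq_len(nhead + 1L)]
  nf <- lengths(strsplit(body, ",", fixed = TRUE))
  if (any(nf != length(expected))) {
    bad <- which(nf != length(expected))[1L]
    stop("malformed trajectory file (line ", nhead + 1L + bad,
         "): expected ", length(expected), " fields, found ", nf[bad],
         call. = FALSE)
  }
  df <- utils::read.csv(textConnection(lines[-seq_len(nhead)]))
  counts <- as.matrix(df[, norm_labels(), drop = FALSE])
  storage.mode(counts) <- "integer"
  new_trajectory(df$coop_ratio, counts, cfg, as.integer(kv$seed))
}
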