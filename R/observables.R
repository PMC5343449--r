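# Observation indexes ----------------------------------------------------
#
# Three indexes summarise a run: the cooperation ratio, the norm census
# (population of each of the 16 norms), and the transition of the
# majority norm. The indispensability classification is built on the
# terminal cooperation ratio of knockout runs.

#' Cooperation ratio of a generation
#'
#' Fraction of realized donor actions that were cooperation:
#' `sum(coop_counts) / (N * R)`. Realized (post implementation-error)
#' actions are counted, since those are what recipients experience.
#'
#' @param coop_counts Realized cooperations per round, each in `[0, N]`.
#' @param N Number of agents.
#' @param R Number of rounds; defaults to `length(coop_counts)`.
#' @return A number in `[0, 1]`.
#' @export
cooperation_ratio <- function(coop_counts, N, R = length(coop_counts)) {
  if (any(coop_counts < 0 | coop_counts > N)) {
    stop("cooperation counts must lie in [0, N]", call. = FALSE)
  }
  sum(coop_counts) / (as.double(N) * R)
}

# accept a 16-vector or a (generations x 16) matrix of norm counts
.as_census_matrix <- function(norm_counts) {
  if (is.data.frame(norm_counts)) norm_counts <- as.matrix(norm_counts)
  if (!is.matrix(norm_counts)) norm_counts <- matrix(norm_counts, nrow = 1L)
  if (ncol(norm_counts) != 16L) {
    stop("norm counts must have 16 columns (one per norm)", call. = FALSE)
  }
  norm_counts
}

#' Majority norm of a census
#'
#' The norm with the greatest population. Ties are broken by the lowest
#' integer norm code, deterministically, so replications are exactly
#' reproducible. Columns are assumed ordered by norm code 0-15 (the order
#' of [norm_labels()]).
#'
#' @param norm_counts A 16-vector of counts, or a (generations x 16)
#'   matrix/data frame.
#' @return Canonical norm label(s), one per row.
#' @export
majority_norm <- function(norm_counts) {
  counts <- .as_census_matrix(norm_counts)
  idx <- apply(counts, 1L, which.max)  # first maximum = lowest code
  norm_labels()[idx]
}

#' Majority-norm transition sequence around the rise of cooperation
#'
#' Samples the majority norm per generation over a window of `pre_window`
#' generations before and `post_window` generations after the first
#' generation whose cooperation ratio exceeds `coop_threshold`, truncates
#' at the first generation where `stop_at` (default ALLG) is the majority
#' (in the cooperative regime tolerant norms trade places frequently,
#' making later majorities uninformative), and collapses consecutive
#' duplicates. If the run never crosses the threshold the sequence over
#' the whole run is returned, flagged non-cooperative.
#'
#' @param traj A trajectory (see [run_replication()]).
#' @param coop_threshold Cooperation-ratio threshold defining the rise.
#' @param pre_window,post_window Generations sampled before/after the
#'   crossing.
#' @param stop_at Norm label at which sampling stops (inclusive).
#' @return A `transition_sequence`: list with `labels`, the generation
#'   stamps `generations` (first generation of each majority run),
#'   `cooperative` (did the run cross the threshold) and
#'   `crossing_generation` (NA if it did not).
#' @export
transition_sequence <- function(traj, coop_threshold = 0.8,
                                pre_window = 20L, post_window = 100L,
                                stop_at = "ALLG") {
  counts <- trajectory_counts(traj)
  coop <- traj$coop_ratio
  stop_lab <- norm_label(norm_code(stop_at))
  cross <- which(coop > coop_threshold)
  cooperative <- length(cross) > 0L
  if (cooperative) {
    t_star <- cross[1L]
    gens <- max(1L, t_star - pre_window):min(nrow(counts), t_star + post_window)
  } else {
    t_star <- NA_integer_
    gens <- seq_len(nrow(counts))
  }
  maj <- majority_norm(counts[gens, , drop = FALSE])
  hit <- which(maj == stop_lab)
  if (length(hit)) {
    maj <- maj[seq_len(hit[1L])]
    gens <- gens[seq_len(hit[1L])]
  }
  keep <- c(TRUE, maj[-1L] != maj[-length(maj)])
  structure(
    list(labels = maj[keep], generations = gens[keep],
         cooperative = cooperative, crossing_generation = t_star),
    class = "transition_sequence"
  )
}

#' @export
print.transition_sequence <- function(x, ...) {
  cat(if (x$cooperative) {
    sprintf("Majority-norm transitions (cooperation threshold crossed at generation %d):\n",
            x$crossing_generation)
  } else {
    "Majority-norm transitions (non-cooperative run, whole-run majorities):\n"
  })
  cat(" ", paste(x$labels, collapse = " -> "), "\n")
  invisible(x)
}

#' Mean cooperation ratio over the final generations of a run
#'
#' @param traj A trajectory (see [run_replication()]).
#' @param window Number of terminal generations to average; defaults to
#'   the final 10\% of the run (at least 1 generation).
#' @return The arithmetic mean cooperation ratio over the window.
#' @export
mean_terminal_cooperation <- function(traj, window = NULL) {
  coop <- traj$coop_ratio
  if (is.null(window)) window <- max(1L, floor(length(coop) / 10))
  window <- as.integer(window)
  if (window < 1L || window > length(coop)) {
    stop("window must be between 1 and the run length (", length(coop), ")",
         call. = FALSE)
  }
  mean(coop[(length(coop) - window + 1L):length(coop)])
}

#' Classify knocked-out norms as indispensable
#'
#' A norm is indispensable for the evolution of cooperation if, when it is
#' knocked out, the replication-averaged mean terminal cooperation ratio
#' falls below `threshold` (default 0.1).
#'
#' @param knockout_runs Named list: norm label -> list of trajectories
#'   from runs with that norm knocked out (>= 1 replication each).
#' @param threshold Cooperation-ratio threshold below which the knockout
#'   is deemed to have prevented cooperation.
#' @param window Terminal window passed to [mean_terminal_cooperation()].
#' @return Character vector of indispensable norm labels.
#' @examples
#' \dontrun{
#' runs <- lapply(c(SH = "SH", SJ = "SJ"), function(ko) {
#'   lapply(0:2, function(s)
#'     run_replication(sim_preset("desk", knockout = ko), seed = s))
#' })
#' classify_indispensable(runs)
#' }
#' @export
classify_indispensable <- function(knockout_runs, threshold = 0.1,
                                   window = NULL) {
  if (length(knockout_runs) == 0L || is.null(names(knockout_runs))) {
    stop("knockout_runs must be a named list of replication lists",
         call. = FALSE)
  }
  means <- vapply(knockout_runs, function(reps) {
    if (length(reps) == 0L) {
      stop("each knocked-out norm needs at least one replication",
           call. = FALSE)
    }
    mean(vapply(reps, mean_terminal_cooperation, numeric(1), window = window))
  }, numeric(1))
  names(means)[means < threshold]
}
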