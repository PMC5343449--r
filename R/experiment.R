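# Experiment sweeps ------------------------------------------------------

#' Specify an experiment sweep
#'
#' An experiment is the Cartesian product of benefit values and knockout
#' settings, each cell run for a number of replications with seeds derived
#' from a master seed.
#'
#' @param config Base [sim_config()] (its `b` and `knockout` are
#'   overridden per cell when sweeps are given).
#' @param replications Replications per cell (>= 1).
#' @param b_sweep Optional numeric vector of benefit values; each must
#'   exceed the cost.
#' @param knockout_sweep Optional character vector of norm labels; each
#'   cell knocks out exactly one of them, plus a no-knockout control cell.
#' @param seed Master seed; the seed of replication r (0-based) in cell k
#'   (0-based) is `seed + 1000 * k + r`.
#' @param terminal_window Terminal window (generations) used for the
#'   summary statistic; default final 10\% of G.
#' @param output_dir Optional directory: trajectories and the summary are
#'   written there as plain text.
#' @return An `experiment_spec` list.
#' @export
experiment_spec <- function(config, replications = 10L, b_sweep = NULL,
                            knockout_sweep = NULL, seed = 0L,
                            terminal_window = NULL, output_dir = NULL) {
  stopifnot(inherits(config, "sim_config"), replications >= 1L)
  if (!is.null(b_sweep) && any(b_sweep <= config$c)) {
    stop("every swept b must exceed the cost c = ", config$c, call. = FALSE)
  }
  if (!is.null(knockout_sweep)) norm_code(knockout_sweep)  # validate labels
  structure(
    list(config = config, replications = as.integer(replications),
         b_sweep = b_sweep, knockout_sweep = knockout_sweep,
         seed = as.integer(seed), terminal_window = terminal_window,
         output_dir = output_dir),
    class = "experiment_spec"
  )
}

#' Seed of one replication in an experiment
#'
#' Documented splitting rule: `master + 1000 * cell + replication`, with
#' the cell index and replication index 0-based.
#'
#' @param master Master seed.
#' @param cell 0-based cell index.
#' @param replication 0-based replication index.
#' @return Integer seed.
#' @export
replication_seed <- function(master, cell, replication) {
  as.integer(master + 1000L * cell + replication)
}

#' Run an experiment sweep
#'
#' Runs every (b, knockout) cell for the specified replications, each with
#' its derived seed, and summarises the replication-averaged mean terminal
#' cooperation per cell. If the spec has an `output_dir`, per-run
#' trajectory files and a JSON summary are written there.
#'
#' @param spec An [experiment_spec()].
#' @param verbose Log one line per replication via `message()`.
#' @return List with `summary` (data frame: `b`, `knockout`,
#'   `mean_terminal`, `sd_terminal`, `replications`) and `trajectories`
#'   (list of cells, each a list of `ir_trajectory`).
#' @export
run_experiment <- function(spec, verbose = interactive()) {
  stopifnot(inherits(spec, "experiment_spec"))
  if (!is.null(spec$output_dir)) {
    dir.create(spec$output_dir, showWarnings = FALSE, recursive = TRUE)
    probe <- file.path(spec$output_dir, ".write_probe")
    ok <- tryCatch({ writeLines("", probe); TRUE }, error = function(e) FALSE)
    if (!ok) {
      stop("output directory is not writable: ", spec$output_dir,
           call. = FALSE)
    }
    unlink(probe)
  }
  b_values <- if (is.null(spec$b_sweep)) spec$config$b else spec$b_sweep
  ko_values <- if (is.null(spec$knockout_sweep)) {
    list(spec$config$knockout)
  } else {
    c(list(character()), as.list(spec$knockout_sweep))
  }
  cells <- expand.grid(ko = seq_along(ko_values), b = seq_along(b_values))
  summary_rows <- vector("list", nrow(cells))
  trajectories <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    b <- b_values[cells$b[k]]
    ko <- ko_values[[cells$ko[k]]]
    cfg <- spec$config
    cfg$b <- b
    cfg$knockout <- ko
    ko_label <- if (length(ko)) paste(ko, collapse = "+") else "none"
    reps <- vector("list", spec$replications)
    terminal <- numeric(spec$replications)
    for (r in seq_len(spec$replications)) {
      s <- replication_seed(spec$seed, k - 1L, r - 1L)
      reps[[r]] <- run_replication(cfg, seed = s)
      terminal[r] <- mean_terminal_cooperation(reps[[r]],
                                               window = spec$terminal_window)
      if (verbose) {
        message(sprintf(
          "cell %d/%d (b = %g, knockout = %s) replication %d/%d: terminal cooperation %.3f",
          k, nrow(cells), b, ko_label, r, spec$replications, terminal[r]))
      }
      if (!is.null(spec$output_dir)) {
        write_trajectory(reps[[r]], file.path(
          spec$output_dir,
          sprintf("traj_b%g_ko-%s_rep%02d_seed%d.csv", b, ko_label, r - 1L, s)))
      }
    }
    summary_rows[[k]] <- data.frame(
      b = b, knockout = ko_label, mean_terminal = mean(terminal),
      sd_terminal = stats::sd(terminal), replications = spec$replications)
    trajectories[[k]] <- reps
    names(trajectories)[k] <- sprintf("b%g_ko-%s", b, ko_label)
  }
  summary <- do.call(rbind, summary_rows)
  if (!is.null(spec$output_dir)) {
    jsonlite::write_json(summary, file.path(spec$output_dir, "summary.json"),
                         dataframe = "rows", digits = NA, pretty = TRUE)
  }
  list(summary = summary, trajectories = trajectories)
}
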