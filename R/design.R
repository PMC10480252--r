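#' Test-retest experiment design
#'
#' The full reproducibility protocol: 4 handling conditions x 2 sessions
#' (A and B, on different days), each condition subjected to 4 constant and
#' 4 pulsatile flow regimens (peak flows 100, 150, 200 and 250 ml/s), for 8
#' condition-session combinations and 64 flow experiments in total.
#'
#' @param base_config Base [phantom_config()] describing the untouched
#'   phantom.
#' @param conditions Handling condition labels, subset of 1:4.
#' @param sessions Sessions, subset of `c("A", "B")`.
#' @param peak_flows Peak flow rates, ml/s.
#' @param modes Flow modes, subset of `c("constant", "pulsatile")`.
#' @param heart_rate Heart rate for pulsatile regimens, bpm.
#' @param seed Master seed; every run's perturbation and noise seed derives
#'   from it.
#' @param perturbation_args Named list of overrides passed on to
#'   [apply_condition_perturbation()].
#' @return An object of class `experiment_design`.
#' @examples
#' design <- experiment_design(phantom_config(), seed = 1)
#' nrow(design$runs) # 64
#' @export
experiment_design <- function(base_config = phantom_config(),
                              conditions = 1:4,
                              sessions = c("A", "B"),
                              peak_flows = c(100, 150, 200, 250),
                              modes = c("constant", "pulsatile"),
                              heart_rate = 75,
                              seed = 1L,
                              perturbation_args = list()) {
  validate_phantom_config(base_config)
  stopifnot(all(conditions %in% 1:4), all(sessions %in% c("A", "B")),
            all(modes %in% c("constant", "pulsatile")))
  runs <- expand.grid(peak_flow = peak_flows, mode = modes,
                      condition = conditions, session = sessions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  structure(
    list(base_config = base_config,
         runs = runs,
         heart_rate = heart_rate,
         seed = as.integer(seed),
         perturbation_args = perturbation_args),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("<experiment_design> %d runs (seed %d)\n", nrow(x$runs), x$seed))
  invisible(x)
}

#' Run the full test-retest harness
#'
#' Simulates and analyses every run of the design deterministically under
#' the master seed. The phantom is perturbed once per condition-session
#' combination (the valve is handled once, then subjected to all eight flow
#' regimens), and each run draws its own noise seed. Sub-seeds are drawn up
#' front from the master seed in a fixed order, so the full table is
#' reproducible bit for bit.
#'
#' @param design An [experiment_design()].
#' @param ... Passed on to [analyze_recording()] (filter settings etc.).
#' @return A tibble with one row per run: `condition`, `session`, `mode`,
#'   `peak_flow`, the three metrics, `peak_instant`, `peak_location`,
#'   `true_peak_drop`, `true_net_drop`, `n_cycles`.
#' @export
run_harness <- function(design, ...) {
  stopifnot(inherits(design, "experiment_design"))
  runs <- design$runs
  combos <- unique(runs[, c("condition", "session")])

  set.seed(design$seed)
  combos$perturb_seed <- sample.int(.Machine$integer.max - 1L, nrow(combos))
  noise_seeds <- sample.int(.Machine$integer.max - 1L, nrow(runs))

  configs <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    configs[[i]] <- do.call(apply_condition_perturbation, c(
      list(config = design$base_config,
           condition_label = combos$condition[i],
           session = combos$session[i],
           seed = combos$perturb_seed[i]),
      design$perturbation_args))
  }

  out <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    row <- runs[i, ]
    ci <- which(combos$condition == row$condition &
                  combos$session == row$session)
    cfg <- configs[[ci]]
    cfg$rng_seed <- noise_seeds[i]
    cond <- flow_condition(row$mode, peak_flow = row$peak_flow,
                           heart_rate = if (row$mode == "pulsatile")
                             design$heart_rate else NA_real_)
    rec <- simulate_recording(cfg, cond,
                              provenance = list(condition = row$condition,
                                                session = row$session))
    m <- analyze_recording(rec, ...)
    det <- attr(m, "details")
    out[[i]] <- tibble::tibble(
      condition = row$condition, session = row$session,
      mode = row$mode, peak_flow = row$peak_flow,
      peak_drop = m$peak_drop, net_drop = m$net_drop,
      peak_to_peak_drop = m$peak_to_peak_drop,
      peak_instant = m$peak_instant, peak_location = m$peak_location,
      true_peak_drop = rec$ground_truth$true_peak_drop,
      true_net_drop = rec$ground_truth$true_net_drop,
      n_cycles = det$n_cycles)
  }
  do.call(rbind, out)
}
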