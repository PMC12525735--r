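# Descriptive summaries of simulated intake, the quartile-based
# LCI/MCI/HCI scenario bands, and convergence monitoring.
#
# Quantile convention: linear interpolation between order statistics
# (stats::quantile type 7, the spreadsheet-percentile rule). SD uses the
# n - 1 denominator.

#' Summarize simulated intake draws
#'
#' Computes the sample mean, sample SD and the three quartiles of both
#' outcomes (per-feed and per-day intake per kg) of one simulated age
#' group. Q1, Q2 and Q3 define the low (LCI), medium (MCI) and high
#' (HCI) caloric-intake scenarios.
#'
#' @param draws A `simulation_draws` object from [simulate_group()].
#' @return data.frame of class `intake_summary` with one row per outcome
#'   (`per_feed`, `per_day`) and columns `group_label`, `outcome`,
#'   `mean`, `sd`, `q1`, `q2`, `q3`, `n_iter`.
#' @export
summarize_draws <- function(draws) {
  stopifnot(inherits(draws, "simulation_draws"))
  if (draws$n_iter < 4L)
    stop("at least 4 draws are required to summarize", call. = FALSE)
  one <- function(outcome) {
    x <- draws[[outcome]]
    q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
    data.frame(group_label = draws$group_label, outcome = outcome,
               mean = mean(x), sd = stats::sd(x),
               q1 = q[1L], q2 = q[2L], q3 = q[3L],
               n_iter = draws$n_iter, stringsAsFactors = FALSE)
  }
  out <- rbind(one("per_feed"), one("per_day"))
  class(out) <- c("intake_summary", "data.frame")
  out
}

#' Classify a value into an intake scenario band
#'
#' Values at or below the first quartile are low caloric intake (LCI),
#' values at or above the third quartile are high (HCI), and values
#' strictly between the quartiles are medium (MCI).
#'
#' @param value Numeric vector of intake values, in the units of the
#'   summary row.
#' @param summary A single-row slice of an [summarize_draws()] result
#'   (or any list with elements `q1` and `q3`).
#' @return Character vector over `{"LCI", "MCI", "HCI"}`.
#' @export
classify_intake <- function(value, summary) {
  q1 <- summary$q1
  q3 <- summary$q3
  if (length(q1) != 1L || length(q3) != 1L)
    stop("classify_intake expects a single summary row", call. = FALSE)
  ifelse(value <= q1, "LCI", ifelse(value >= q3, "HCI", "MCI"))
}

#' Running statistics across iterations
#'
#' Tracks the running mean and quartiles of one outcome at iteration
#' checkpoints `step, 2 step, ..., n_iter` (the final checkpoint is
#' always `n_iter`, so it reproduces [summarize_draws()] exactly).
#'
#' @param draws A `simulation_draws` object.
#' @param step Checkpoint spacing (>= 1, <= `n_iter`).
#' @param outcome `"per_day"` (default) or `"per_feed"`.
#' @return An object of class `convergence_trace`: list with
#'   `checkpoints`, `running_mean`, `running_q1`, `running_q2`,
#'   `running_q3`, plus `group_label` and `outcome`.
#' @export
convergence_trace <- function(draws, step, outcome = c("per_day", "per_feed")) {
  stopifnot(inherits(draws, "simulation_draws"))
  outcome <- match.arg(outcome)
  step <- as.integer(step)
  if (is.na(step) || step < 1L)
    stop("step must be a positive integer", call. = FALSE)
  if (step > draws$n_iter)
    stop("step exceeds the number of iterations", call. = FALSE)
  x <- draws[[outcome]]
  checkpoints <- seq(step, draws$n_iter, by = step)
  if (checkpoints[length(checkpoints)] != draws$n_iter)
    checkpoints <- c(checkpoints, draws$n_iter)
  stat <- function(k, f) f(x[seq_len(k)])
  structure(list(
    checkpoints = checkpoints,
    running_mean = vapply(checkpoints, stat, 0, f = mean),
    running_q1 = vapply(checkpoints, stat, 0,
                        f = function(v) unname(stats::quantile(v, 0.25, type = 7))),
    running_q2 = vapply(checkpoints, stat, 0,
                        f = function(v) unname(stats::quantile(v, 0.5, type = 7))),
    running_q3 = vapply(checkpoints, stat, 0,
                        f = function(v) unname(stats::quantile(v, 0.75, type = 7))),
    group_label = draws$group_label, outcome = outcome
  ), class = "convergence_trace")
}

#' Convergence check on a running-statistics trace
#'
#' Declares the simulation converged when, over the trailing window of
#' checkpoints, the running mean and all three running quartiles each
#' stay within a relative tolerance of their final value.
#'
#' @param trace A [convergence_trace()] with at least 3 checkpoints.
#' @param rel_tol Maximum allowed relative change (default 0.005).
#' @param window_frac Fraction of trailing checkpoints examined
#'   (default 0.2).
#' @return List with `converged` (logical), `max_rel_change`, and
#'   `by_stat` (named vector of the maximum relative change of each
#'   statistic within the window).
#' @export
is_converged <- function(trace, rel_tol = 0.005, window_frac = 0.2) {
  stopifnot(inherits(trace, "convergence_trace"))
  n <- length(trace$checkpoints)
  if (n < 3L)
    stop("convergence check needs at least 3 checkpoints", call. = FALSE)
  w <- max(2L, ceiling(window_frac * n))
  idx <- seq.int(n - w + 1L, n)
  rel_change <- function(s) {
    ref <- s[n]
    if (ref == 0) return(max(abs(s[idx])))
    max(abs(s[idx] - ref) / abs(ref))
  }
  by_stat <- c(mean = rel_change(trace$running_mean),
               q1 = rel_change(trace$running_q1),
               q2 = rel_change(trace$running_q2),
               q3 = rel_change(trace$running_q3))
  list(converged = all(by_stat <= rel_tol),
       max_rel_change = max(by_stat),
       by_stat = by_stat)
}

#' Wide intake-summary table
#'
#' Arranges summaries into the reporting layout used for the model's
#' results: ten statistic rows (Mean, SD, LCI (Q1), MCI (Q2), HCI (Q3),
#' each for kcal/kg/feed and kcal/kg/day) by one column per age group,
#' rounded to 2 decimals for presentation (the long format keeps full
#' precision).
#'
#' @param summaries An `intake_summary` data.frame (rows from one or
#'   more groups, both outcomes per group).
#' @return data.frame with columns `statistic`, `outcome`, then one
#'   column per age group.
#' @export
intake_table <- function(summaries) {
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 1)
  if (anyDuplicated(summaries[, c("group_label", "outcome")]))
    stop("duplicate (group, outcome) rows in summaries", call. = FALSE)
  groups <- unique(summaries$group_label)
  stats_map <- c(Mean = "mean", SD = "sd", "LCI (Q1)" = "q1",
                 "MCI (Q2)" = "q2", "HCI (Q3)" = "q3")
  outcome_lab <- c(per_feed = "kcal/kg/feed", per_day = "kcal/kg/day")
  rows <- list()
  for (s in names(stats_map)) {
    for (o in c("per_feed", "per_day")) {
      vals <- vapply(groups, function(g) {
        row <- summaries[summaries$group_label == g &
                           summaries$outcome == o, , drop = FALSE]
        if (nrow(row) == 0L) NA_real_ else round(row[[stats_map[[s]]]], 2)
      }, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        statistic = s, outcome = outcome_lab[[o]],
        as.list(stats::setNames(vals, groups)),
        stringsAsFactors = FALSE, check.names = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Long intake-summary table
#'
#' Tidy long form of the summaries: one row per (group, outcome,
#' statistic) at full precision.
#'
#' @param summaries An `intake_summary` data.frame.
#' @return data.frame with columns `group`, `outcome`, `statistic`,
#'   `value`.
#' @export
intake_long_table <- function(summaries) {
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 1)
  stats_cols <- c("mean", "sd", "q1", "q2", "q3")
  do.call(rbind, lapply(seq_len(nrow(summaries)), function(i) {
    row <- summaries[i, ]
    data.frame(group = row$group_label, outcome = row$outcome,
               statistic = stats_cols,
               value = as.numeric(row[stats_cols]),
               stringsAsFactors = FALSE)
  }))
}

#' Write wide and long intake-summary CSVs
#'
#' @param summaries An `intake_summary` data.frame.
#' @param wide_path,long_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, a list with the two data.frames.
#' @export
write_intake_tables <- function(summaries, wide_path = NULL,
                                long_path = NULL) {
  wide <- intake_table(summaries)
  long <- intake_long_table(summaries)
  if (!is.null(wide_path))
    utils::write.csv(wide, wide_path, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(long_path))
    utils::write.csv(long, long_path, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(list(wide = wide, long = long))
}
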