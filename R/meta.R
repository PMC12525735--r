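# Random-effects pooling of study-level caloric-density measurements.
# Studies are held as a plain data.frame with columns
# study_id, age_group, mean, sd, n (kcal/dL scale throughout).

validate_studies <- function(studies) {
  needed <- c("study_id", "age_group", "mean", "sd", "n")
  if (!is.data.frame(studies) || nrow(studies) == 0L)
    stop("studies must be a non-empty data.frame", call. = FALSE)
  missing <- setdiff(needed, names(studies))
  if (length(missing))
    stop("study table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(!is.finite(studies$sd) | studies$sd <= 0))
    stop("all study sd values must be positive", call. = FALSE)
  if (any(!is.finite(studies$n) | studies$n < 2))
    stop("all study sample sizes must be >= 2", call. = FALSE)
  if (length(unique(studies$age_group)) != 1L)
    stop("all studies must share a single age_group; got: ",
         paste(unique(studies$age_group), collapse = ", "), call. = FALSE)
  invisible(studies)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Pools study-level means by inverse-variance weighting with a
#' between-study variance component estimated by the DerSimonian-Laird
#' moment method. Per-study standard errors are `sd / sqrt(n)`.
#' Heterogeneity is quantified by Cochran's Q, Tau-squared and the
#' I-squared percentage; with a single study the pooled estimate is the
#' study itself and Q = Tau2 = I2 = 0.
#'
#' @param studies data.frame with columns `study_id`, `age_group`,
#'   `mean`, `sd`, `n`; all rows must share one `age_group`.
#' @param z Normal quantile for the confidence interval (default 1.96,
#'   i.e. 95%).
#' @return An object of class `pooled_estimate`: a list with `k`,
#'   `pooled_mean`, `se`, `ci_low`, `ci_high`, `Q`, `tau2`, `i2`
#'   (percent), `weights` (relative random-effects weights summing to 1,
#'   named by study), `age_group` and `z`.
#' @examples
#' studies <- data.frame(study_id = c("s1", "s2"), age_group = "6-9",
#'                       mean = c(61.2, 62.4), sd = c(2.1, 1.8),
#'                       n = c(40, 55))
#' pool_random_effects(studies)
#' @export
pool_random_effects <- function(studies, z = 1.96) {
  validate_studies(studies)
  if (z <= 0) stop("z must be positive", call. = FALSE)
  k <- nrow(studies)
  x <- studies$mean
  se2 <- studies$sd^2 / studies$n

  w <- 1 / se2                       # fixed-effect weights
  x_fixed <- sum(w * x) / sum(w)
  Q <- sum(w * (x - x_fixed)^2)
  tau2 <- if (k > 1L)
    max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  else 0
  i2 <- if (k > 1L && Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0

  w_star <- 1 / (se2 + tau2)
  pooled <- sum(w_star * x) / sum(w_star)
  se <- 1 / sqrt(sum(w_star))
  weights <- w_star / sum(w_star)
  names(weights) <- as.character(studies$study_id)

  structure(list(
    k = k, pooled_mean = pooled, se = se,
    ci_low = pooled - z * se, ci_high = pooled + z * se,
    Q = Q, tau2 = tau2, i2 = i2,
    weights = weights,
    age_group = as.character(studies$age_group[1L]), z = z
  ), class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "<pooled_estimate> %s: k = %d, mean = %.4f [%.4f; %.4f], Q = %.4f, tau2 = %.4f, I2 = %.1f%%\n",
    x$age_group, x$k, x$pooled_mean, x$ci_low, x$ci_high, x$Q, x$tau2, x$i2))
  invisible(x)
}

#' Standard error from a confidence interval
#'
#' Back-computes the standard error implied by a symmetric normal
#' confidence interval: `(ci_high - ci_low) / (2 z)`. This is how the
#' sigma of a normal caloric-density input is obtained from a pooled
#' 95% CI.
#'
#' @param ci_low,ci_high Interval bounds, `ci_high > ci_low`.
#' @param z Normal quantile matching the interval's coverage
#'   (default 1.96 for 95%).
#' @return The implied standard error.
#' @examples
#' se_from_ci(60.18, 63.15)  # 0.7577; rounds to 0.76
#' @export
se_from_ci <- function(ci_low, ci_high, z = 1.96) {
  if (ci_high <= ci_low)
    stop("inverted confidence interval: ci_high must exceed ci_low",
         call. = FALSE)
  if (z <= 0) stop("z must be positive", call. = FALSE)
  (ci_high - ci_low) / (2 * z)
}

#' Caloric-density distribution from a pooled estimate
#'
#' Converts a pooled estimate into the distribution used by the intake
#' model: a normal distribution (pooled mean, sigma back-computed from
#' the CI) when heterogeneity is below the threshold, and a PERT
#' distribution with the CI limits as range and the pooled mean as mode
#' when heterogeneity is at or above it.
#'
#' @param est A [pool_random_effects()] result.
#' @param i2_threshold_pct I-squared percentage at or above which the
#'   PERT branch is taken (default 75, the conventional "high
#'   heterogeneity" cutoff). The boundary value itself is classified as
#'   high heterogeneity.
#' @return A [dist_spec()] in kcal/dL.
#' @export
density_spec_from_pooled <- function(est, i2_threshold_pct = 75) {
  stopifnot(inherits(est, "pooled_estimate"))
  if (est$i2 < i2_threshold_pct) {
    dist_spec("normal",
              list(mu = est$pooled_mean,
                   sigma = se_from_ci(est$ci_low, est$ci_high, est$z)),
              units = "kcal/dL")
  } else {
    dist_spec("pert",
              list(a = est$ci_low, m = est$pooled_mean, b = est$ci_high),
              units = "kcal/dL")
  }
}

#' Generate a synthetic study table
#'
#' Simulates `k` study-level means around a true mean with between-study
#' standard deviation `tau` and within-study sampling error
#' `within_sd / sqrt(n_per_study)`, for parameter-recovery testing of
#' the pooling stage.
#'
#' @param true_mean True underlying mean (kcal/dL).
#' @param tau Between-study SD (>= 0).
#' @param k Number of studies (>= 1).
#' @param within_sd Within-study SD (> 0), reported as each study's `sd`.
#' @param n_per_study Per-study sample size.
#' @param seed Integer seed; the same seed reproduces the same table.
#' @param age_group Label assigned to every study.
#' @return data.frame with columns `study_id`, `age_group`, `mean`,
#'   `sd`, `n`.
#' @export
synth_studies <- function(true_mean, tau, k, within_sd, n_per_study,
                          seed, age_group = "synthetic") {
  stopifnot(k >= 1, tau >= 0, within_sd > 0, n_per_study >= 2)
  means <- with_seed_local(seed,
    stats::rnorm(k, true_mean, sqrt(tau^2 + within_sd^2 / n_per_study)))
  data.frame(
    study_id = sprintf("study_%02d", seq_len(k)),
    age_group = age_group,
    mean = means,
    sd = rep(within_sd, k),
    n = rep(as.integer(n_per_study), k),
    stringsAsFactors = FALSE
  )
}

#' Read a study-level table from CSV
#'
#' Expects a header row and columns `study_id`, `age_group`, `mean`,
#' `sd`, `n` (point decimal, UTF-8). Additional columns are preserved.
#'
#' @param path Path to the CSV file.
#' @return data.frame of study records.
#' @export
read_study_table <- function(path) {
  if (!file.exists(path))
    stop("study table not found: ", path, call. = FALSE)
  studies <- utils::read.csv(path, stringsAsFactors = FALSE,
                             encoding = "UTF-8")
  needed <- c("study_id", "age_group", "mean", "sd", "n")
  missing <- setdiff(needed, names(studies))
  if (length(missing))
    stop(sprintf("study table %s is missing column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  for (col in c("mean", "sd", "n")) {
    if (!is.numeric(studies[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(studies[[col]]))))
      stop(sprintf("study table %s: column '%s' is not numeric (check row %s)",
                   path, col,
                   paste(utils::head(bad, 3L), collapse = ", ")),
           call. = FALSE)
    }
  }
  studies
}

#' Write pooled estimates to CSV
#'
#' One row per age group with the pooled mean, CI bounds, heterogeneity
#' statistics, and the caloric-density distribution chosen from them.
#'
#' @param estimates List of [pool_random_effects()] results.
#' @param path Output CSV path.
#' @param i2_threshold_pct Passed to [density_spec_from_pooled()].
#' @return Invisibly, the data.frame written.
#' @export
write_pooled_table <- function(estimates, path, i2_threshold_pct = 75) {
  stopifnot(length(estimates) >= 1)
  rows <- lapply(estimates, function(est) {
    spec <- density_spec_from_pooled(est, i2_threshold_pct)
    data.frame(
      age_group = est$age_group, k = est$k,
      pooled_mean = est$pooled_mean, se = est$se,
      ci_low = est$ci_low, ci_high = est$ci_high,
      Q = est$Q, tau2 = est$tau2, i2 = est$i2,
      density_family = spec$family,
      density_a = if (spec$family == "pert") spec$a else NA_real_,
      density_m = if (spec$family == "pert") spec$m else NA_real_,
      density_b = if (spec$family == "pert") spec$b else NA_real_,
      density_mu = if (spec$family == "normal") spec$mu else NA_real_,
      density_sigma = if (spec$family == "normal") spec$sigma else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(out)
}
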