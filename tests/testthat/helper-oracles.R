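# Independent brute-force DerSimonian-Laird pooling, written directly
# from the textbook formulas and kept separate from the package's
# implementation so the two can be cross-checked.
dl_pool_oracle <- function(means, sds, ns, z = 1.96) {
  k <- length(means)
  v <- sds^2 / ns
  w <- 1 / v
  x_fixed <- sum(w * means) / sum(w)
  Q <- sum(w * (means - x_fixed)^2)
  tau2 <- if (k > 1) max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))) else 0
  ws <- 1 / (v + tau2)
  mu <- sum(ws * means) / sum(ws)
  se <- sqrt(1 / sum(ws))
  list(pooled_mean = mu, se = se,
       ci_low = mu - z * se, ci_high = mu + z * se,
       Q = Q, tau2 = tau2,
       i2 = if (k > 1 && Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0)
}

studies_df <- function(means, sds, ns, age_group = "g") {
  data.frame(study_id = sprintf("s%d", seq_along(means)),
             age_group = age_group, mean = means, sd = sds, n = ns,
             stringsAsFactors = FALSE)
}

# Published per-group reference values for both outcomes (kcal/kg/feed
# and kcal/kg/day): mean, SD and the three quartiles at 5000 iterations.
reference_table5 <- function() {
  groups <- c("0-1", "1-3", "3-6", "6-9", "9-12", "12-18", "18-24")
  make <- function(...) stats::setNames(c(...), groups)
  list(
    per_feed = list(
      mean = make(13.71, 16.75, 13.46, 12.43, 15.32, 16.99, 17.11),
      sd   = make(2.96, 1.33, 1.31, 1.23, 1.92, 1.49, 1.16),
      q1   = make(11.49, 15.76, 12.51, 11.54, 13.95, 15.92, 16.30),
      q2   = make(13.71, 16.74, 13.42, 12.43, 15.27, 16.96, 17.06),
      q3   = make(15.91, 17.71, 14.42, 13.33, 16.67, 18.02, 17.93)),
    per_day = list(
      mean = make(150.80, 142.34, 100.92, 80.83, 84.28, 67.94, 51.33),
      sd   = make(36.88, 15.27, 12.77, 11.13, 14.17, 15.03, 7.77),
      q1   = make(124.11, 131.53, 91.68, 72.89, 74.14, 56.91, 45.73),
      q2   = make(148.33, 141.98, 100.41, 80.46, 83.42, 67.64, 51.01),
      q3   = make(176.09, 152.49, 109.56, 88.27, 93.68, 78.45, 56.90))
  )
}

all_default_specs <- function() {
  out <- list()
  for (g in default_config())
    for (v in c("feeds", "volume", "density", "weight"))
      out[[paste(g$label, v, sep = "/")]] <- g[[v]]
  out
}
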