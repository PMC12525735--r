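test_that("the default configuration covers 0-24 months with the stated families", {
  cfg <- default_config()
  expect_length(cfg, 7)
  expect_equal(names(cfg), c("0-1", "1-3", "3-6", "6-9", "9-12", "12-18",
                             "18-24"))
  starts <- vapply(cfg, `[[`, 0L, "age_start_months")
  ends <- vapply(cfg, `[[`, 0L, "age_end_months")
  expect_equal(unname(starts[1]), 0)
  expect_equal(unname(ends[7]), 24)
  expect_equal(unname(starts[-1]), unname(ends[-7]))  # contiguous

  for (g in cfg) {
    expect_equal(g$feeds$family, "triangular")
    expect_equal(g$volume$family, "pert")
    expect_true(g$density$family %in% c("normal", "pert"))
    expect_equal(g$weight$family, "uniform")
  }

  g1 <- cfg[["0-1"]]
  expect_equal(c(g1$feeds$a, g1$feeds$m, g1$feeds$b), c(8, 11, 14))
  expect_equal(c(g1$volume$a, g1$volume$m, g1$volume$b), c(30, 70, 110))
  expect_equal(c(g1$density$a, g1$density$m, g1$density$b),
               c(62.10, 63.70, 65.31))
  expect_equal(c(g1$weight$a, g1$weight$b), c(3.2, 3.3))
  g36 <- cfg[["3-6"]]
  expect_equal(g36$density$family, "normal")
  expect_equal(c(g36$density$mu, g36$density$sigma), c(61.66, 0.76))
  expect_equal(c(cfg[["6-9"]]$density$mu, cfg[["6-9"]]$density$sigma),
               c(61.74, 0.79))
})

test_that("config construction enforces family and age invariants", {
  cfg <- default_config()[["0-1"]]
  expect_error(age_group_config("x", 1, 1, cfg$feeds, cfg$volume,
                                cfg$density, cfg$weight),
               "age_start")
  expect_error(age_group_config("x", 0, 1, cfg$volume, cfg$volume,
                                cfg$density, cfg$weight),
               "triangular")
  expect_error(age_group_config("x", 0, 1, cfg$feeds, cfg$volume,
                                cfg$feeds, cfg$weight),
               "normal or pert")
})

test_that("intake equations are simple unit-forced arithmetic", {
  expect_equal(intake_per_feed(70, 63.70, 3.25), 13.719, tolerance = 1e-3)
  expect_equal(intake_per_feed(100, 100, 1), 100)
  expect_equal(intake_per_feed(210, 90.43, 11.1), 17.108, tolerance = 1e-3)
  expect_equal(intake_per_day(11, 13.719), 150.909, tolerance = 1e-3)
  expect_equal(intake_per_day(1, 7.3), 7.3)
  expect_equal(intake_per_day(3, 17.108), 51.324, tolerance = 1e-3)
  expect_error(intake_per_feed(-1, 60, 3), "positive")
  expect_error(intake_per_day(0, 10), "positive")
})

test_that("simulation is deterministic and respects algebraic identities", {
  cfg <- default_config()[["0-1"]]
  d1 <- simulate_group(cfg, n_iter = 2000, seed = 7)
  d2 <- simulate_group(cfg, n_iter = 2000, seed = 7)
  expect_identical(d1, d2)
  d3 <- simulate_group(cfg, n_iter = 2000, seed = 8)
  expect_false(identical(d1$per_day, d3$per_day))

  expect_equal(d1$per_feed,
               d1$volume * (d1$density / 100) / d1$weight)
  expect_equal(d1$per_day / d1$per_feed, d1$feeds)
  expect_true(all(d1$per_day > 0))
})

test_that("simulated outcomes stay inside the algebraic support bounds", {
  for (g in default_config()) {
    if (g$density$family != "pert") next
    d <- simulate_group(g, n_iter = 5000, seed = 3)
    lo <- g$feeds$a * g$volume$a * (g$density$a / 100) / g$weight$b
    hi <- g$feeds$b * g$volume$b * (g$density$b / 100) / g$weight$a
    expect_gte(min(d$per_day), lo)
    expect_lte(max(d$per_day), hi)
  }
})

test_that("simulated means agree with the analytic expectation", {
  n <- 1e5
  for (g in default_config()) {
    d <- simulate_group(g, n_iter = n, seed = 17)
    ex <- expected_intake(g)
    expect_lt(abs(mean(d$per_feed) - ex[["per_feed"]]),
              4 * stats::sd(d$per_feed) / sqrt(n))
    expect_lt(abs(mean(d$per_day) - ex[["per_day"]]),
              4 * stats::sd(d$per_day) / sqrt(n))
  }
})

test_that("scaling both weight bounds by c divides expected intake by c", {
  g <- default_config()[["9-12"]]
  ex <- expected_intake(g)
  for (c_ in c(0.5, 2, 3.7)) {
    g2 <- g
    g2$weight <- dist_spec("uniform",
                           list(a = g$weight$a * c_, b = g$weight$b * c_),
                           units = "kg")
    expect_equal(unname(expected_intake(g2)), unname(ex) / c_,
                 tolerance = 1e-12)
  }
})

test_that("near-degenerate inputs collapse to the deterministic product", {
  eps <- 1e-9
  tight <- function(family, v, units) {
    if (family == "triangular")
      dist_spec("triangular", list(a = v - eps, m = v, b = v + eps), units)
    else if (family == "pert")
      dist_spec("pert", list(a = v - eps, m = v, b = v + eps), units)
    else dist_spec("uniform", list(a = v - eps, b = v + eps), units)
  }
  cfg <- age_group_config("pt", 0, 1,
                          tight("triangular", 6, "feeds/day"),
                          tight("pert", 150, "mL"),
                          tight("pert", 65, "kcal/dL"),
                          tight("uniform", 5, "kg"))
  d <- simulate_group(cfg, n_iter = 100, seed = 1)
  expect_equal(d$per_day, rep(6 * 150 * 0.65 / 5, 100), tolerance = 1e-8)
  expect_equal(unname(expected_intake(cfg)[["per_day"]]), 6 * 150 * 0.65 / 5,
               tolerance = 1e-8)
})

test_that("run_all is deterministic and order-invariant per group", {
  groups <- default_config()
  res <- run_all(groups, n_iter_per_group = 1000, master_seed = 5)
  expect_length(res, 7)
  expect_true(all(vapply(res, `[[`, 0L, "n_iter") == 1000L))

  res2 <- run_all(groups, n_iter_per_group = 1000, master_seed = 5)
  expect_identical(res, res2)

  perm <- rev(groups)
  res3 <- run_all(perm, n_iter_per_group = 1000, master_seed = 5)
  for (lab in names(res))
    expect_identical(res3[[lab]], res[[lab]])
})

test_that("configs round-trip through YAML and JSON", {
  groups <- default_config()
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_config(groups, path)
    back <- read_config(path)
    expect_equal(back, groups)
  }

  # editing a single parameter changes only that group
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(groups, path)
  y <- yaml::read_yaml(path)
  y[[1]]$feeds$params$m <- 12
  writeLines(yaml::as.yaml(y), path)
  edited <- read_config(path)
  expect_equal(edited[["0-1"]]$feeds$m, 12)
  expect_equal(edited[-1], groups[-1])

  # invalid edits are rejected with the offending group named
  y[[3]]$density$params$sigma <- -1
  writeLines(yaml::as.yaml(y), path)
  expect_error(read_config(path), "3-6.*sigma")
})
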