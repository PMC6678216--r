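test_that("a hand-written tidy table round-trips through read_timeseries", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  frac <- rbind(c(0.79, 0.13, 0.08), c(0.5, 0.3, 0.2), c(0.4, 0.35, 0.25))
  write_fixture_csv(tmp, c(0, 12, 24), frac, total_fold = c(1, 1.1, 1.2))
  ds <- read_timeseries(tmp, validation = "strict")
  expect_length(ds$snapshots, 3)
  expect_equal(snapshot_times <- sapply(ds$snapshots, `[[`, "time"), c(0, 12, 24))
  for (k in 1:3)
    expect_equal(unname(ds$snapshots[[k]]$fractions), frac[k, ])
  expect_equal(ds$snapshots[[2]]$total_fold, 1.1)
})

test_that("renormalize rescales near-simplex rows proportionally, strict refuses", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  frac <- rbind(c(0.79, 0.13, 0.08), c(0.80, 0.13, 0.08))  # second sums to 1.01
  write_fixture_csv(tmp, c(0, 12), frac)
  expect_error(read_timeseries(tmp, "strict"), "strict")
  expect_warning(ds <- read_timeseries(tmp, "renormalize"), "renormalizing")
  expect_equal(unname(ds$snapshots[[2]]$fractions),
               c(0.792079207920792, 0.128712871287129, 0.0792079207920792),
               tolerance = 1e-12)
  # ratios preserved
  f <- ds$snapshots[[2]]$fractions
  expect_equal(unname(f[1] / f[2]), 0.80 / 0.13, tolerance = 1e-12)
})

test_that("off-simplex beyond 0.02 and non-monotonic inputs are rejected", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  frac <- rbind(c(0.79, 0.13, 0.08), c(0.85, 0.13, 0.08))  # off by 0.06
  write_fixture_csv(tmp, c(0, 12), frac)
  expect_error(suppressWarnings(read_timeseries(tmp, "renormalize")), "0.02")
  # missing required column
  df <- utils::read.csv(tmp)
  df$fraction <- NULL
  utils::write.csv(df, tmp, row.names = FALSE)
  expect_error(read_timeseries(tmp), "fraction")
})

test_that("replicates average into mean snapshots with SD metadata", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  f1 <- rbind(c(0.78, 0.14, 0.08), c(0.5, 0.3, 0.2))
  f2 <- rbind(c(0.80, 0.12, 0.08), c(0.6, 0.2, 0.2))
  frac <- rbind(f1, f2)
  df <- data.frame(condition = "c", time_h = rep(rep(c(0, 12), each = 3), 2),
                   state = rep(unclass(canonical), 4),
                   fraction = as.numeric(t(frac)),
                   replicate = rep(1:2, each = 6))
  utils::write.csv(df, tmp, row.names = FALSE)
  ds <- read_timeseries(tmp)
  expect_equal(unname(ds$snapshots[[1]]$fractions), c(0.79, 0.13, 0.08))
  expect_equal(unname(ds$snapshots[[2]]$fractions), c(0.55, 0.25, 0.2))
  expect_equal(unname(ds$snapshots[[2]]$sd[1]), stats::sd(c(0.5, 0.6)))
})

test_that("schedules, flux tables, fits and diagrams round-trip to 1e-12", {
  run <- simulate_condition(dose = 10, mode = "expectation", replicates = 1,
                            noise_cv = 0)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_result(run$schedule, tmp)
  s2 <- read_schedule(tmp)
  for (k in seq_along(s2$intervals)) {
    expect_equal(s2$intervals[[k]]$P, run$schedule$intervals[[k]]$P,
                 tolerance = 1e-12)
    expect_equal(s2$intervals[[k]]$d, run$schedule$intervals[[k]]$d,
                 tolerance = 1e-12)
  }
  fl <- normalized_flux(run$schedule, run$dataset)
  write_result(fl, tmp)
  f2 <- read_flux(tmp)
  expect_equal(f2$intervals[[3]]$F, fl$intervals[[3]]$F, tolerance = 1e-12)
  # 9 paths x 5 intervals = 45 data rows
  expect_equal(nrow(utils::read.csv(tmp)), 45)

  S <- seq(0.05, 1, length.out = 20)
  hf <- fit_hill(S, 0.05 + 0.9 * S^4 / (0.4^4 + S^4))
  tj <- withr::local_tempfile(fileext = ".json")
  write_result(hf, tj)
  h2 <- read_hill_fit(tj)
  expect_equal(h2$h, hf$h, tolerance = 1e-12)
  expect_equal(h2$K, hf$K, tolerance = 1e-12)

  pd <- potentials(untreated_fractions())
  write_result(pd, tj)
  p2 <- read_potential_diagram(tj)
  expect_equal(p2$potentials, pd$potentials, tolerance = 1e-12)
  # JSON carries the three U values
  expect_length(jsonlite::read_json(tj, simplifyVector = TRUE)$potentials, 3)
})

test_that("DOT export styles edges by the emphasis thresholds", {
  # all flux on self paths -> no cross edges drawn
  ivs <- lapply(0:1, function(k)
    interval_params(k * 12, (k + 1) * 12, diag(3), states = canonical))
  ds <- stationary_dataset(times = c(0, 12, 24))
  fl <- normalized_flux(transition_schedule(ivs), ds)
  dot <- export_diagram(fl, c(0.5, 0.2), exclude_self = TRUE)
  expect_false(any(grepl("->", dot)))
  dot_self <- export_diagram(fl, c(0.5, 0.2), exclude_self = FALSE)
  expect_true(any(grepl("cobble -> cobble", dot_self)))

  # a 0.6 cross edge with thresholds (0.5, 0.2) is dominant-styled
  P <- diag(3); P[1, 3] <- 0.6; P[1, 1] <- 0.4
  iv <- interval_params(0, 12, P, states = canonical)
  ds2 <- stationary_dataset(fractions = c(0.999998, 1e-6, 1e-6),
                            times = c(0, 12))
  fl2 <- normalized_flux(transition_schedule(list(iv)), ds2)
  dot2 <- export_diagram(fl2, c(0.5, 0.2))
  edge <- grep("cobble -> circular", dot2, value = TRUE)
  expect_match(edge, "color=black")
  expect_error(export_diagram(fl2, c(0.2, 0.5)), "decreasing")
  expect_error(export_diagram(fl2, c(1.5, 0.2)), "decreasing|\\(0, 1\\]")
})
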