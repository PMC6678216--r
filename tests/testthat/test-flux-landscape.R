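test_that("flux matches direct arithmetic and normalizes to 1", {
  # identity transitions, no death: all flux sits on the self paths
  id <- interval_params(0, 12, diag(3), states = canonical)
  ds <- stationary_dataset(fractions = c(0.6, 0.3, 0.1), times = c(0, 12))
  fl <- normalized_flux(transition_schedule(list(id)), ds)
  expect_equal(unname(diag(fl$intervals[[1]]$F)), c(0.6, 0.3, 0.1))
  expect_equal(sum(fl$intervals[[1]]$F), 1, tolerance = 1e-12)

  # n = (60, 30, 10), cobble splits half to circular: F = 30/100
  P <- diag(3); P[1, ] <- c(0.5, 0, 0.5)
  iv <- interval_params(0, 12, P, states = canonical)
  ds2 <- stationary_dataset(fractions = c(0.6, 0.3, 0.1), times = c(0, 12))
  fl2 <- normalized_flux(transition_schedule(list(iv)), ds2)
  expect_equal(fl2$intervals[[1]]$F["cobble", "circular"], 0.30,
               tolerance = 1e-12)
})

test_that("flux normalization holds across many random schedules", {
  # oracle sweep: random parameters, random populations
  morphostate:::with_seed(123, {
    for (r in 1:1000) {
      iv <- random_interval()
      f0 <- stats::rgamma(3, 1); f0 <- f0 / sum(f0)
      ds <- stationary_dataset(fractions = f0, times = c(0, 12))
      fl <- normalized_flux(transition_schedule(list(iv)), ds)
      expect_equal(sum(fl$intervals[[1]]$F), 1, tolerance = 1e-9)
    }
  })
})

test_that("excluding self paths keeps the denominator fixed", {
  iv <- random_interval(seed = 7)
  ds <- stationary_dataset(times = c(0, 12))
  with_self <- normalized_flux(transition_schedule(list(iv)), ds,
                               include_self = TRUE)
  no_self <- normalized_flux(transition_schedule(list(iv)), ds,
                             include_self = FALSE)
  Fs <- with_self$intervals[[1]]$F
  Fn <- no_self$intervals[[1]]$F
  expect_true(all(is.na(diag(Fn))))
  off <- row(Fs) != col(Fs)
  expect_equal(Fn[off], Fs[off], tolerance = 1e-12)
})

test_that("rank-1 path equals the argmax of the raw path-count oracle", {
  for (s in 1:10) {
    iv <- random_interval(seed = 40 + s)
    f0 <- morphostate:::with_seed(s, { g <- stats::rgamma(3, 1); g / sum(g) })
    ds <- stationary_dataset(fractions = f0, times = c(0, 12))
    fl <- normalized_flux(transition_schedule(list(iv)), ds)
    top <- dominant_paths(fl, k = 1)
    M <- path_counts_expectation(f0, iv)
    diag(M) <- -Inf
    idx <- which(M == max(M), arr.ind = TRUE)[1, ]
    expect_equal(c(top$from_state, top$to_state),
                 c(rownames(M)[idx[1]], colnames(M)[idx[2]]))
  }
})

test_that("dominant-path output is equivariant under state relabeling", {
  iv <- random_interval(seed = 77)
  f0 <- c(0.5, 0.3, 0.2)
  ds <- stationary_dataset(fractions = f0, times = c(0, 12))
  fl <- normalized_flux(transition_schedule(list(iv)), ds)
  top <- dominant_paths(fl, k = 3)
  # permute the state space and rebuild
  perm <- c(3, 1, 2)
  states_p <- state_space(unclass(canonical)[perm])
  iv_p <- interval_params(0, 12, iv$P[perm, perm], iv$d[perm], iv$b[perm],
                          states = states_p)
  snaps <- lapply(c(0, 12), function(t)
    population_snapshot(t, f0[perm], 1, 0, states = states_p))
  ds_p <- timeseries_dataset(snaps)
  fl_p <- normalized_flux(transition_schedule(list(iv_p)), ds_p)
  top_p <- dominant_paths(fl_p, k = 3)
  # same (from, to, flux) triples up to ordering of ties
  a <- top[order(top$from_state, top$to_state), c("from_state", "to_state", "flux")]
  b <- top_p[order(top_p$from_state, top_p$to_state),
             c("from_state", "to_state", "flux")]
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("potentials follow U = -ln(f) and invert exactly", {
  pd <- potentials(c(cobble = 0.79, spindle = 0.13, circular = 0.08))
  expect_equal(unname(pd$potentials),
               c(0.23572233352107, 2.04022082852655, 2.52572864430826),
               tolerance = 1e-12)
  expect_equal(pd$states_by_potential, c("cobble", "spindle", "circular"))
  expect_equal(unname(exp(-pd$potentials)), unname(pd$fractions),
               tolerance = 1e-12)
  expect_equal(sum(exp(-pd$potentials)), 1, tolerance = 1e-9)

  uni <- potentials(rep(1 / 3, 3))
  expect_equal(unname(uni$potentials), rep(log(3), 3), tolerance = 1e-12)

  expect_error(potentials(c(0.5, 0.5, 0)), "> 0")
  expect_error(potentials(c(0.5, 0.3, 0.3)), "sum to 1")
})

test_that("the excitation/relaxation path rule classifies intervals correctly", {
  run <- simulate_condition(dose = 10, mode = "expectation", replicates = 1,
                            noise_cv = 0)
  fl <- normalized_flux(run$schedule, run$dataset)
  pd <- potentials(untreated_fractions())
  rep_ <- check_path_rule(fl, pd, run$signal,
                          hill_mid = coupling_params()$hill_k)
  # generator built to satisfy the rule: no violations end to end
  expect_true(attr(rep_, "rule_consistent"))
  expect_equal(rep_$switch[1], "ON")
  expect_true(all(rep_$switch[-1] == "OFF"))

  # hand-built violation: OFF interval dominated by circular -> cobble
  P <- diag(3); P[3, 1] <- 0.5; P[3, 3] <- 0.5
  iv <- interval_params(0, 12, P, states = canonical)
  ds <- stationary_dataset(times = c(0, 12))
  fl_bad <- normalized_flux(transition_schedule(list(iv)), ds)
  low_sig <- signal_trajectory(signal_params(), 0, grid = seq(0, 12, 1))
  rep_bad <- check_path_rule(fl_bad, pd, low_sig, hill_mid = 0.35)
  expect_false(attr(rep_bad, "rule_consistent"))
  expect_equal(nrow(attr(rep_bad, "violations")), 1)
})

test_that("trajectory summary chains the rank-1 paths across intervals", {
  run <- simulate_condition(dose = 10, mode = "expectation", replicates = 1,
                            noise_cv = 0)
  fl <- normalized_flux(run$schedule, run$dataset)
  tr <- path_trajectory(fl)
  expect_equal(tr$label, "cobble -> circular -> spindle -> cobble")
  high <- simulate_condition(dose = 25, mode = "expectation", replicates = 1,
                             noise_cv = 0)
  fl_h <- normalized_flux(high$schedule, high$dataset)
  expect_equal(path_trajectory(fl_h)$label, "cobble -> circular")
})
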