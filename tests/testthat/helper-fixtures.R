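# shared fixture builders; everything is generated in code at test time

canonical <- state_space()

# stationary dataset with constant fractions, growing or flat totals
stationary_dataset <- function(fractions = c(0.5, 0.3, 0.2),
                               times = seq(0, 48, by = 12),
                               fold_rate = 0, dead = 0) {
  snaps <- lapply(seq_along(times), function(k)
    population_snapshot(times[k], fractions,
                        total_fold = (1 + fold_rate)^(k - 1),
                        dead_fraction = dead, states = canonical))
  timeseries_dataset(snaps, condition = list(label = "stationary"))
}

# random row-stochastic interval parameters (Dirichlet-style rows)
random_interval <- function(t0 = 0, t1 = 12, seed = NULL, max_d = 0.3,
                            max_b = 0.3) {
  draw <- function() {
    P <- t(replicate(3, {
      g <- stats::rgamma(3, shape = 1)
      g / sum(g)
    }))
    interval_params(t0, t1, P, d = stats::runif(3, 0, max_d),
                    b = stats::runif(3, 0, max_b), states = canonical)
  }
  if (is.null(seed)) draw() else morphostate:::with_seed(seed, draw())
}

# sparse ground truth: one dominant off-diagonal path per interval
sparse_truth_schedule <- function(seed, n_intervals = 5, dt = 12,
                                  d = 0.01, b = 0.02) {
  morphostate:::with_seed(seed, {
    ivs <- lapply(seq_len(n_intervals), function(k) {
      P <- diag(3)
      j <- sample(1:3, 1)
      i <- sample(setdiff(1:3, j), 1)
      p <- stats::runif(1, 0.4, 0.6)
      P[j, i] <- p
      P[j, j] <- 1 - p
      interval_params((k - 1) * dt, k * dt, P, d = d, b = b,
                      states = canonical)
    })
    transition_schedule(ivs)
  })
}

# off-diagonal argmax as a (from, to) label pair
dominant_cross_path <- function(P) {
  Q <- P
  diag(Q) <- -Inf
  idx <- which(Q == max(Q), arr.ind = TRUE)[1, ]
  c(rownames(P)[idx[1]], colnames(P)[idx[2]])
}

# tidy CSV written from a fraction matrix (rows = times)
write_fixture_csv <- function(path, times, frac, condition = "fix",
                              total_fold = NULL, replicate = NULL) {
  states <- unclass(canonical)
  df <- data.frame(condition = condition,
                   time_h = rep(times, each = length(states)),
                   state = rep(states, length(times)),
                   fraction = as.numeric(t(frac)))
  if (!is.null(total_fold)) df$total_fold <- rep(total_fold, each = length(states))
  if (!is.null(replicate)) df$replicate <- replicate
  utils::write.csv(df, path, row.names = FALSE)
  path
}
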