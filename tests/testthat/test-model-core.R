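consts <- synaptic_constants()

test_that("firing rate handles the removable singularity and its neighborhood", {
  x_star <- consts$b / consts$a
  expect_identical(firing_rate(x_star), 1 / consts$d)
  # continuity: approaching from both sides stays at the limit
  eps <- c(-1e-9, -1e-12, 1e-12, 1e-9)
  expect_equal(firing_rate(x_star + eps), rep(1 / consts$d, 4),
               tolerance = 1e-6)
})

test_that("firing rate matches direct formula evaluation away from threshold", {
  # far above threshold the rate is asymptotically linear: a x - b
  expect_equal(firing_rate(10), consts$a * 10 - consts$b,
               tolerance = 1e-6)
  # at zero input the printed formula gives ~6.5e-6 Hz
  u <- -consts$b
  oracle <- u / (1 - exp(-consts$d * u))
  expect_equal(firing_rate(0), oracle, tolerance = 1e-12)
  expect_lt(firing_rate(0), 1e-5)
  expect_gt(firing_rate(0), 0)
})

test_that("firing rate is strictly increasing and positive on a fine grid", {
  x <- seq(-1, 2, by = 1e-3)
  h <- firing_rate(x)
  expect_true(all(h > 0))
  expect_true(all(diff(h) > 0))
  expect_error(firing_rate(NaN), "finite")
})

test_that("total input matches hand evaluation and a double-loop oracle", {
  # with all gating at zero only the subcortical drive remains
  sc <- tiny_sc(4)
  p <- baseline_params(4, I = 0.27)
  expect_equal(total_input(rep(0, 4), p, sc), rep(0.27, 4))

  # two fully coupled regions at S = 1: x = 2 J = 0.5218 nA
  C2 <- matrix(c(0, 1, 1, 0), 2, 2)
  p2 <- regional_parameters(w = c(1, 1), I = c(0, 0), G = 1, sigma = 0)
  expect_equal(total_input(c(1, 1), p2, C2), rep(2 * consts$J, 2),
               tolerance = 1e-12)
  expect_equal(2 * consts$J, 0.5218, tolerance = 1e-12)

  # random instances against an explicit elementwise loop
  for (seed in 1:3) {
    withr::with_seed(seed, {
      n <- sample(3:20, 1)
      C <- abs(matrix(rnorm(n^2), n, n)); C <- (C + t(C)) / 2; diag(C) <- 0
      p <- regional_parameters(w = runif(n), I = runif(n), G = runif(1, 0, 2),
                               sigma = 0)
      S <- runif(n)
      x <- total_input(S, p, C)
      oracle <- numeric(n)
      for (i in seq_len(n)) {
        acc <- 0
        for (j in seq_len(n)) acc <- acc + C[i, j] * S[j]
        oracle[i] <- p$w[i] * consts$J * S[i] + p$G * consts$J * acc + p$I[i]
      }
      expect_equal(x, oracle, tolerance = 1e-12)
    })
  }
  expect_error(total_input(rep(0.1, 3), baseline_params(4), tiny_sc(4)),
               "mismatch")
})

test_that("a deterministic fixed point is stationary under neural_step", {
  # single uncoupled region: S*/tau_s = r (1 - S*) H(w J S* + I)
  p <- regional_parameters(w = 0.9, I = 0.32, G = 0, sigma = 0)
  C1 <- matrix(0, 1, 1)
  g <- function(S) {
    -S / consts$tau_s +
      consts$r * (1 - S) * firing_rate(p$w * consts$J * S + p$I)
  }
  root <- uniroot(g, c(1e-6, 1 - 1e-6), tol = 1e-14)$root
  st <- neural_state(root)
  out <- neural_step(st, p, C1, consts, dt = 0.01, noise = 0)
  expect_equal(out$S, root, tolerance = 1e-10)

  # and the integrated trajectory converges to the same root
  traj <- simulate_neural(p, C1, duration = 60, dt = 0.01, burn_in = 0,
                          seed = 1)
  expect_equal(tail(traj$S_series[, 1], 1), root, tolerance = 1e-6)
})

test_that("noise-free simulation converges with an inactive clamp", {
  sc <- tiny_sc(6)
  withr::with_seed(3, {
    p <- regional_parameters(w = runif(6, 0.1, 0.9), I = runif(6, 0.1, 0.35),
                             G = 0.5, sigma = 0)
  })
  traj <- simulate_neural(p, sc, duration = 60, dt = 0.01, burn_in = 0,
                          seed = 1)
  expect_identical(traj$clamp_count, 0)
  # terminal drift residual per region
  S_end <- traj$S_series[nrow(traj$S_series), ]
  x <- total_input(S_end, p, sc)
  drift <- -S_end / consts$tau_s + consts$r * (1 - S_end) * firing_rate(x)
  expect_lt(max(abs(drift)), 1e-6)
})

test_that("simulation is seed-reproducible and noise is active", {
  sc <- tiny_sc(5)
  p <- baseline_params(5)
  a <- simulate_neural(p, sc, duration = 5, dt = 0.01, burn_in = 1, seed = 7)
  b <- simulate_neural(p, sc, duration = 5, dt = 0.01, burn_in = 1, seed = 7)
  c <- simulate_neural(p, sc, duration = 5, dt = 0.01, burn_in = 1, seed = 8)
  expect_identical(a$S_series, b$S_series)
  expect_false(identical(a$S_series, c$S_series))
  expect_true(all(a$S_series >= 0 & a$S_series <= 1))
})

test_that("compiled and pure-R integration loops agree exactly", {
  sc <- tiny_sc(4)
  p <- baseline_params(4, sigma = 0.02)
  fast <- simulate_neural(p, sc, duration = 2, dt = 0.01, burn_in = 0.5,
                          seed = 11, use_compiled = TRUE)
  slow <- simulate_neural(p, sc, duration = 2, dt = 0.01, burn_in = 0.5,
                          seed = 11, use_compiled = FALSE)
  expect_equal(fast$S_series, slow$S_series, tolerance = 1e-12)
  expect_equal(fast$clamp_count, slow$clamp_count)
})

test_that("halving dt halves the noise-free integration error", {
  sc <- tiny_sc(5)
  p <- baseline_params(5, sigma = 0)
  endpoint <- function(dt) {
    tr <- simulate_neural(p, sc, duration = 2, dt = dt, burn_in = 0, seed = 1)
    tr$S_series[nrow(tr$S_series), ]
  }
  e1 <- endpoint(0.02); e2 <- endpoint(0.01); e3 <- endpoint(0.005)
  # successive step-halving differences shrink by the order of the scheme
  d1 <- sqrt(sum((e1 - e2)^2))
  d2 <- sqrt(sum((e2 - e3)^2))
  expect_gt(d1 / d2, 1.6)
  expect_lt(d1 / d2, 2.4)
})

test_that("simulation argument contracts are enforced", {
  sc <- tiny_sc(3)
  p <- baseline_params(3)
  expect_error(simulate_neural(p, sc, duration = -1), "must be")
  expect_error(simulate_neural(p, sc, duration = 5, burn_in = 5), "exceed")
  expect_error(neural_step(neural_state(rep(0.1, 3)), p, sc, consts,
                           dt = 0.01, noise = c(0, 0)), "length")
})
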