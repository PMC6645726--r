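test_that("zero-production circuits decay in closed form", {
  circ <- decay_circuit(c(a = 0.1, b = 0.2))
  sched <- stage_schedule()
  tr <- simulate_nucleus(circ, NULL, 50, c(10, 5), sched,
                         output_times = c(0, 5, 16, 21, 40, 71))
  exact <- cbind(10 * exp(-0.1 * tr$times), 5 * exp(-0.2 * tr$times))
  expect_lt(max(abs(tr$states - exact) / exact), 1e-6)
})

test_that("the compiled integrator agrees with an independent deSolve run", {
  circ <- random_circuit(11)
  grad <- generate_synthetic_gradients(seed = 11)
  sched <- c14a_schedule()
  pos <- 53
  g0 <- c(40, 5, 90)
  times <- seq(sched$c14a_start, sched$c14a_end, length.out = 9)

  tr <- simulate_nucleus(circ, grad, pos, g0, sched, output_times = times)
  ode_rhs <- function(t, y, parms) {
    # lsoda probes slightly beyond the final time; clamp to profile support
    tc <- min(max(t, min(grad$times)), max(grad$times))
    list(unname(circuit_derivatives(tc, y, circ, grad, pos, "interphase")))
  }
  ref <- deSolve::ode(y = g0, times = times, func = ode_rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(tr$states), unname(ref[, -1]), tolerance = 1e-6)
})

test_that("concentrations are non-increasing during the mitosis window", {
  circ <- random_circuit(3)
  grad <- generate_synthetic_gradients(seed = 3)
  sched <- stage_schedule()
  times <- seq(16, 21, by = 0.5)  # the C13 mitosis window
  tr <- simulate_nucleus(circ, grad, 47, c(30, 80, 10), sched,
                         output_times = times)
  expect_true(all(diff(tr$states) <= 1e-10))
})

test_that("a row of nuclei equals independent per-nucleus simulation", {
  circ <- random_circuit(21, n_g = 4)
  grad <- generate_synthetic_gradients(seed = 21)
  sched <- stage_schedule()
  mids <- time_class_midpoints(sched)
  init <- matrix(0, 21, 4)
  row <- simulate_row(circ, grad, c13_positions(), init, sched,
                      output_times = mids)
  expect_length(row, 41L)
  expect_equal(as.integer(names(row)), c14a_positions())
  for (p in c(35, 36, 52, 74, 75)) {
    single <- simulate_nucleus(circ, grad, p, rep(0, 4), sched,
                               output_times = mids)
    expect_lt(max(abs(row[[as.character(p)]]$states - single$states)), 1e-8)
  }
  # a single-nucleus row reduces to simulate_nucleus
  one <- simulate_row(circ, grad, 41, matrix(0, 1, 4), sched,
                      output_times = mids)
  single <- simulate_nucleus(circ, grad, 41, rep(0, 4), sched,
                             output_times = mids)
  expect_equal(one[[1]]$states, single$states)
  expect_error(simulate_row(circ, grad, c(41, 41), matrix(0, 2, 4), sched,
                            output_times = mids),
               "duplicate")
})

test_that("the diffusion-less row over 35-75% is 41 independent 4-gene systems", {
  circ <- generate_ground_truth_circuit("full", seed = 1)
  grad <- generate_synthetic_gradients(seed = 1)
  sched <- stage_schedule()
  row <- simulate_row(circ, grad, schedule = sched,
                      initial_states = matrix(0, 21, 4),
                      output_times = sched$c14a_end)
  expect_length(row, 41L)
  n_state_vars <- sum(vapply(row, function(tr) ncol(tr$states), integer(1)))
  expect_equal(n_state_vars, 164L)
})

test_that("trajectories are bounded by R/lambda and non-negative", {
  for (seed in 1:5) {
    circ <- random_circuit(seed)
    grad <- generate_synthetic_gradients(seed = seed)
    sched <- stage_schedule()
    set.seed(seed)
    g0 <- runif(3, 0, circ$R / circ$lambda)
    tr <- simulate_nucleus(circ, grad, 55, g0, sched,
                           output_times = seq(0, 71, by = 2))
    cap <- pmax(g0, circ$R / circ$lambda) * (1 + 1e-6)
    expect_true(all(sweep(tr$states, 2, cap, "<=")))
    expect_true(all(tr$states >= -1e-8))
  }
})

test_that("with constant inputs the simulation converges to a root of the frozen field", {
  circ <- random_circuit(31)
  mv <- c(Bcd = 12, Cad = 70)
  mat <- const_maternal(mv, times = c(0, 2000))
  sched <- stage_schedule(c13_interphase = 1, c13_mitosis = 1,
                          c14a = 1998, include_c13 = FALSE)
  tr <- simulate_nucleus(circ, mat, 50, c(5, 5, 5), sched,
                         output_times = c(1950, 2000))
  field <- frozen_field(circ, mv)
  expect_lt(max(abs(field(tr$states[2, ]))), 1e-6)
  # and the endpoint coincides with a Newton-Raphson steady state
  ss <- find_steady_states(circ, mv)
  dists <- vapply(ss, function(s) max(abs(s$location - tr$states[2, ])),
                  numeric(1))
  expect_lt(min(dists), 1e-4 * max(circ$R / circ$lambda))
})

test_that("out-of-range output times and coverage gaps are rejected", {
  circ <- random_circuit(5)
  grad <- generate_synthetic_gradients(seed = 5)
  sched <- stage_schedule()
  expect_error(simulate_nucleus(circ, grad, 50, rep(0, 3), sched,
                                output_times = c(0, 100)),
               "schedule span")
  expect_error(simulate_nucleus(circ, grad, 50, rep(0, 3), sched,
                                output_times = c(10, 5)),
               "increasing")
  expect_error(simulate_nucleus(circ, NULL, 50, rep(0, 3), sched,
                                output_times = 10),
               "maternal")
})
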