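test_that("regime classification reads portraits correctly", {
  # toggle: 2 point attractors + saddle -> multistable
  expect_equal(classify_regime(toggle_circuit(), cycle_check = FALSE)$label,
               "multistable")
  # rotational 2-gene circuit: single spiral sink -> monostable damped
  sp <- spiral_circuit()
  port <- instantaneous_portrait(sp, numeric())
  expect_equal(vapply(port$steady_states, `[[`, character(1), "label"),
               "spiral sink")
  expect_equal(classify_regime(sp, portrait = port, cycle_check = FALSE)$label,
               "monostable-damped-oscillatory")
  # three uncoupled genes -> monostable
  expect_equal(classify_regime(simplified_acdc(0, 0))$label, "monostable")
})

test_that("limit-cycle detection distinguishes cycles from convergence", {
  # linear decay-only field: no oscillation
  lc <- detect_limit_cycle(decay_circuit())
  expect_false(lc$cycle)
  expect_equal(max(lc$amplitude), 0)

  # repressilator-like corner: sustained, stationary oscillation
  rep3 <- simplified_acdc(0, 0.05)
  lc <- detect_limit_cycle(rep3)
  expect_true(lc$cycle)
  expect_gt(max(lc$amplitude), 0.5 * max(rep3$R / rep3$lambda) * 0.2)
  expect_true(is.finite(lc$period) && lc$period > 0)

  # globally attracting fixed point: false from 10 seeded random starts
  mono <- simplified_acdc(0, 0)
  set.seed(5)
  ics <- matrix(runif(30, 0, 200), 10, 3)
  lc0 <- detect_limit_cycle(mono, initial_conditions = ics)
  expect_false(lc0$cycle)
})

test_that("oscillation period-amplitude stationarity holds over ten cycles", {
  rep3 <- simplified_acdc(0, 0.05)
  lc <- detect_limit_cycle(rep3)
  # re-measure amplitudes per period on a fresh long simulation
  horizon <- lc$period * 26
  times <- seq(horizon / 2, horizon, length.out = 4000)
  tr <- gapdyn:::simulate_frozen_series(rep3, numeric(),
                                        c(150, 20, 80), times)
  v <- tr[, which.max(apply(tr, 2, function(x) max(x) - min(x)))]
  peaks <- which(diff(sign(diff(v))) == -2) + 1
  troughs <- which(diff(sign(diff(v))) == 2) + 1
  amps <- vapply(seq_len(min(10, length(peaks) - 1)), function(k) {
    tr_in <- troughs[troughs > peaks[k] & troughs < peaks[k + 1]]
    v[peaks[k]] - min(v[tr_in])
  }, numeric(1))
  expect_gte(length(amps), 10)
  expect_lt(max(abs(diff(amps)) / amps[-length(amps)]), 0.05)
})

test_that("simplified AC/DC circuits span the expected regimes", {
  # both controls zero: uncoupled and globally monostable
  base <- simplified_acdc(0, 0)
  expect_length(attractors(instantaneous_portrait(base, numeric())), 1L)
  # strong positive feedback, no cycle: multistable (toggle + free gene)
  expect_equal(classify_regime(simplified_acdc(0.05, 0))$label, "multistable")
  # strong cyclic repression, no positive feedback: sustained oscillation
  expect_equal(classify_regime(simplified_acdc(0, 0.05))$label, "limit-cycle")
  # strong positive feedback quenches the oscillation: no limit cycle
  # anywhere along the strong-positive edge, and the strong-positive corner
  # is the multistable switch
  for (neg in c(0, 0.02, 0.05))
    expect_false(classify_regime(simplified_acdc(0.06, neg))$label ==
                   "limit-cycle")
  expect_error(simplified_acdc(-1, 0))
})

test_that("the control-parameter map is consistent and cycle-free without negative feedback", {
  pos <- seq(0, 0.06, by = 0.02)
  neg <- seq(0, 0.06, by = 0.02)
  cm <- control_parameter_map(pos, neg)
  expect_equal(nrow(cm), length(pos) * length(neg))
  expect_true(all(c("monostable", "multistable", "limit-cycle") %in% cm$label))
  # no cyclic repression, no limit cycle
  expect_false(any(cm$label[cm$negative == 0] == "limit-cycle"))
  # single-cell consistency with a standalone classification
  cell <- cm[cm$positive == 0.04 & cm$negative == 0.04, ]
  direct <- classify_regime(simplified_acdc(0.04, 0.04))
  expect_equal(cell$label, direct$label)
  expect_error(control_parameter_map(c(0.02, 0.01), neg), "increasing")
})

test_that("maternal phase diagrams respect the circuit's maternal couplings", {
  grad <- generate_synthetic_gradients(seed = 1)
  # all maternal weights zero: label constant along the varied axis
  sub0 <- extract_subcircuit(generate_ground_truth_circuit("full", seed = 1),
                             c("hb", "Kr", "kni"))
  sub0$E[] <- 0
  dg0 <- maternal_phase_diagram(sub0, grad, positions = 52, varied = "Bcd",
                                values = seq(0, 30, by = 5))
  expect_length(unique(dg0$label), 1L)

  # a Bcd-activated toggle subcircuit crosses a single threshold
  sub <- extract_subcircuit(generate_ground_truth_circuit("full", seed = 1),
                            c("hb", "Kr", "kni"))
  dg <- maternal_phase_diagram(sub, grad, positions = 52, varied = "Bcd",
                               values = seq(0, 30, by = 0.5))
  multi <- startsWith(dg$label, "multistable")
  expect_equal(sum(abs(diff(multi))), 1L)  # exactly one regime flip
  thr <- regime_boundary(dg, axis = "value")
  expect_true(is.finite(thr) && thr > 0 && thr < 30)
  expect_error(maternal_phase_diagram(sub, grad, 52, varied = "Bcd",
                                      values = numeric()), "empty")
})

test_that("weight sweeps refine consistently and reduce to direct classification", {
  grad <- generate_synthetic_gradients(seed = 1)
  sub <- extract_subcircuit(generate_ground_truth_circuit("full", seed = 1),
                            c("hb", "Kr", "kni"))
  # width-zero sweep at the current value equals direct classification
  cur <- sub$W["Kr", "hb"]
  one <- weight_phase_diagram(sub, c("Kr", "hb"), list(cur), grad,
                              positions = 50)
  t1 <- time_class_midpoints(stage_schedule())[["T1"]]
  mv <- interpolate_maternal(grad, 50, t1, sub$maternal)
  expect_equal(one$label, classify_regime(sub, mv, cycle_check = FALSE)$label)

  # refining the step never changes labels at previously computed values
  coarse_vals <- seq(-0.003, 0, by = 0.001)
  fine_vals <- seq(-0.003, 0, by = 0.0005)
  coarse <- weight_phase_diagram(sub, c("Kr", "hb"), list(coarse_vals), grad,
                                 positions = 49:52)
  fine <- weight_phase_diagram(sub, c("Kr", "hb"), list(fine_vals), grad,
                               positions = 49:52)
  merged <- merge(coarse, fine, by = c("position", "w1"),
                  suffixes = c(".c", ".f"))
  expect_equal(nrow(merged), nrow(coarse))
  expect_equal(merged$label.c, merged$label.f)
  expect_error(weight_phase_diagram(sub, c("Kr", "zz"), list(0), grad, 50),
               "unknown weight")
})
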