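test_that("subcircuit extraction is the exact parameter restriction", {
  circ <- generate_ground_truth_circuit("full", seed = 6)
  sub <- extract_subcircuit(circ, c("hb", "Kr", "kni"))
  expect_equal(sub$genes, c("hb", "Kr", "kni"))
  expect_equal(sub$W, circ$W[c("hb", "Kr", "kni"), c("hb", "Kr", "kni")])
  expect_equal(sub$E, circ$E[, c("hb", "Kr", "kni")])
  expect_equal(diag(sub$W), diag(circ$W)[c("hb", "Kr", "kni")])  # auto kept
  # extracting the full gene set returns an identical circuit
  all4 <- extract_subcircuit(circ, circ$genes)
  expect_true(isTRUE(all.equal(all4, circ)))
  expect_error(extract_subcircuit(circ, c("hb", "zz")), "unknown gene")
})

test_that("the canonical AC/DC assignments cover the trunk with 1-nucleus gaps", {
  asg <- acdc_assignments()
  expect_equal(asg$name, c("acdc1", "acdc2", "acdc3"))
  expect_equal(lengths(asg$genes), rep(3L, 3))
  expect_equal(asg$from, c(35, 49, 61))
  expect_equal(asg$to, c(47, 59, 75))
  # regions are disjoint; 48% and 60% belong to none
  covered <- unlist(lapply(seq_len(3), function(i) seq(asg$from[i], asg$to[i])))
  expect_false(anyDuplicated(covered) > 0)
  expect_false(48 %in% covered)
  expect_false(60 %in% covered)
})

test_that("a subcircuit excluding an inert gene reproduces the full model exactly", {
  genes <- c("g1", "g2", "g3")
  W <- matrix(0, 3, 3, dimnames = list(genes, genes))
  W["g1", "g2"] <- -0.015
  W["g2", "g1"] <- -0.004
  E <- matrix(0, 2, 3, dimnames = list(c("Bcd", "Cad"), genes))
  E["Bcd", "g1"] <- 0.1
  E["Cad", "g2"] <- 0.03
  circ <- gene_circuit(genes, c("Bcd", "Cad"), R = c(18, 18, 0),
                       lambda = rep(0.1, 3), h = c(-2, -2, -50), W = W, E = E)
  grad <- generate_synthetic_gradients(seed = 13)
  sched <- stage_schedule()
  mids <- time_class_midpoints(sched)
  full <- simulate_nucleus(circ, grad, 45, c(12, 3, 0), sched,
                           output_times = c(sched$c14a_start, mids))
  g_t1 <- full$states[1, c("g1", "g2")]  # state at C14A onset
  sub <- extract_subcircuit(circ, c("g1", "g2"))
  st <- simulate_subcircuit(sub, grad, 45, g_t1, sched, output_times = mids)
  expect_lt(max(abs(st$states - full$states[-1, c("g1", "g2")])), 1e-6)
  d <- compare_trajectories(st, full)
  expect_lt(d$overall, 1e-8)
})

test_that("subcircuit simulations cover C14A only", {
  sub <- extract_subcircuit(generate_ground_truth_circuit("full", seed = 1),
                            c("hb", "Kr", "gt"))
  grad <- generate_synthetic_gradients(seed = 1)
  sched <- stage_schedule()
  tr <- simulate_subcircuit(sub, grad, 40, c(10, 10, 10), sched)
  expect_gte(min(tr$times), sched$c14a_start)
  expect_true(all(tr$time_class %in% paste0("T", 1:8)))
  expect_error(simulate_subcircuit(sub, grad, 40, c(10, 10, 10), sched,
                                   output_times = 5),
               "schedule span")
})

test_that("trajectory comparison is range-normalised per gene", {
  genes <- c("a", "b")
  t8 <- 1:8
  base <- matrix(c(seq(0, 140, length.out = 8), seq(50, 10, length.out = 8)),
                 8, 2, dimnames = list(NULL, genes))
  full <- trajectory(50, t8, base)
  expect_equal(compare_trajectories(full, full)$overall, 0)

  # offsetting one gene by its full-model dynamic range gives distance 1
  shifted <- base
  shifted[, "a"] <- shifted[, "a"] + (max(base[, "a"]) - min(base[, "a"]))
  d <- compare_trajectories(trajectory(50, t8, shifted), full)
  expect_equal(unname(d$per_gene["a"]), 1, tolerance = 1e-12)
  expect_equal(unname(d$per_gene["b"]), 0)
  expect_equal(d$overall, 1, tolerance = 1e-12)
  expect_error(compare_trajectories(full, trajectory(50, t8,
    matrix(1, 8, 1, dimnames = list(NULL, "zz")))), "no shared genes")
})

test_that("within its region a ground-truth subcircuit tracks the full model", {
  circ <- generate_ground_truth_circuit("full", seed = 1)
  grad <- generate_synthetic_gradients(seed = 1)
  sched <- stage_schedule()
  mids <- time_class_midpoints(sched)
  prof <- sensitivity_scan(circ, grad)
  regions <- insensitive_regions(prof)
  kni_reg <- regions[regions$gene == "kni", ][1, ]  # anterior region
  p_in <- floor((kni_reg$from + kni_reg$to) / 2)

  full <- simulate_row(circ, grad, schedule = sched,
                       initial_states = matrix(0, 21, 4),
                       output_times = c(sched$c14a_start, mids))
  sub <- extract_subcircuit(circ, c("hb", "Kr", "gt"))

  dist_at <- function(p) {
    ftr <- full[[as.character(p)]]
    s0 <- ftr$states[1, c("hb", "Kr", "gt")]  # state at C14A onset
    st <- simulate_subcircuit(sub, grad, p, s0, sched, output_times = mids)
    compare_trajectories(st, ftr, times = mids)$overall
  }
  d_in <- dist_at(p_in)
  expect_lt(d_in, 0.1)
  # far outside the region (posterior, where kni is essential) the same
  # 3-gene subcircuit deviates much more
  d_out <- dist_at(71)
  expect_gt(d_out, d_in)
})
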