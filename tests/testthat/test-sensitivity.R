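mk_traj <- function(states, genes, times = 21 + (1:8 - 0.5) * 6.25) {
  colnames(states) <- genes
  trajectory(50, times, states)
}

test_that("the node-sensitivity metric matches its closed forms", {
  set.seed(8)
  a <- mk_traj(matrix(runif(32, 0, 100), 8, 4), c("hb", "Kr", "kni", "gt"))
  expect_identical(node_sensitivity(a, a), 0)

  # constant offset delta in one gene at all 8 classes gives d = delta
  b <- a
  b$states[, "Kr"] <- b$states[, "Kr"] + 7.5
  expect_equal(node_sensitivity(a, b), 7.5, tolerance = 1e-12)
  expect_equal(node_sensitivity(b, a), node_sensitivity(a, b))  # symmetry

  # two-time-class toy table against hand-summed arithmetic
  t2 <- c(1, 2)
  x <- mk_traj(matrix(c(1, 2, 3, 4), 2, 2), c("u", "v"), times = t2)
  y <- mk_traj(matrix(c(2, 0, 3, 1), 2, 2), c("u", "v"), times = t2)
  hand <- sqrt(((1 - 2)^2 + (3 - 3)^2 + (2 - 0)^2 + (4 - 1)^2) / 2)
  expect_equal(node_sensitivity(x, y, times = t2), hand, tolerance = 1e-12)

  # a gene absent from the reduced trajectory enters as zero
  z <- mk_traj(matrix(c(1, 2), 2, 1), "u", times = t2)
  hand0 <- sqrt(((1 - 1)^2 + (2 - 2)^2 + 3^2 + 4^2) / 2)
  expect_equal(node_sensitivity(x, z, times = t2), hand0, tolerance = 1e-12)

  expect_error(node_sensitivity(a, mk_traj(matrix(1, 3, 1), "q",
                                           times = c(1, 2, 3))),
               "8 time-class")
})

test_that("the metric satisfies the triangle inequality on random triples", {
  set.seed(123)
  genes <- c("hb", "Kr", "kni", "gt")
  for (k in 1:100) {
    a <- mk_traj(matrix(runif(32, 0, 150), 8, 4), genes)
    b <- mk_traj(matrix(runif(32, 0, 150), 8, 4), genes)
    c <- mk_traj(matrix(runif(32, 0, 150), 8, 4), genes)
    expect_lte(node_sensitivity(a, c),
               node_sensitivity(a, b) + node_sensitivity(b, c) + 1e-12)
  }
})

test_that("removing a node erases exactly its parameters", {
  circ <- generate_ground_truth_circuit("full", seed = 4)
  red <- remove_node(circ, "kni")
  keep <- c("hb", "Kr", "gt")
  expect_equal(red$genes, keep)
  expect_equal(dim(red$W), c(3L, 3L))
  expect_equal(red$W, circ$W[keep, keep])
  expect_equal(red$E, circ$E[, keep])
  expect_equal(red$R, circ$R[keep])
  expect_error(remove_node(circ, "nope"), "unknown gene")
})

test_that("removing an inert gene leaves the others' dynamics bit-identical", {
  # gene g3 has zero in/out gap weights, zero maternal input, h so negative
  # it is never expressed
  genes <- c("g1", "g2", "g3")
  W <- matrix(0, 3, 3, dimnames = list(genes, genes))
  W["g1", "g2"] <- -0.01
  W["g2", "g1"] <- -0.01
  E <- matrix(c(0.1, 0.05, 0, 0.01, 0.02, 0), 2, 3, byrow = FALSE,
              dimnames = list(c("Bcd", "Cad"), genes))
  E[, "g3"] <- 0
  circ <- gene_circuit(genes, c("Bcd", "Cad"), R = c(20, 20, 0),
                       lambda = c(0.1, 0.1, 0.1), h = c(-1, -1, -50), W = W,
                       E = E)
  grad <- generate_synthetic_gradients(seed = 9)
  sched <- c14a_schedule()
  mids <- time_class_midpoints(sched)
  full <- simulate_nucleus(circ, grad, 50, c(10, 20, 0), sched, mids)
  red <- simulate_nucleus(remove_node(circ, "g3"), grad, 50, c(10, 20), sched,
                          mids)
  expect_equal(full$states[, c("g1", "g2")], red$states)
  expect_lt(node_sensitivity(full, red, times = mids), 1e-6)
})

test_that("the sensitivity scan flags inert genes as dispensable everywhere", {
  genes <- c("g1", "g2", "g3")
  W <- matrix(0, 3, 3, dimnames = list(genes, genes))
  W["g1", "g2"] <- -0.02
  E <- matrix(0, 2, 3, dimnames = list(c("Bcd", "Cad"), genes))
  E["Bcd", "g1"] <- 0.1
  E["Cad", "g2"] <- 0.03
  circ <- gene_circuit(genes, c("Bcd", "Cad"), R = c(20, 20, 0),
                       lambda = rep(0.1, 3), h = c(-2, -2, -50), W = W, E = E)
  grad <- generate_synthetic_gradients(seed = 2)
  init <- matrix(0, 41, 3)
  prof <- sensitivity_scan(circ, grad, initial_states = init)
  d3 <- prof$d[prof$gene == "g3"]
  expect_true(all(d3 < 1e-6))
  regions <- insensitive_regions(prof, threshold = 1)
  g3reg <- regions[regions$gene == "g3", ]
  expect_equal(nrow(g3reg), 1L)
  expect_equal(c(g3reg$from, g3reg$to), c(35, 75))
})

test_that("insensitive regions are empty at threshold zero and nest monotonically", {
  circ <- generate_ground_truth_circuit("full", seed = 1)
  grad <- generate_synthetic_gradients(seed = 1)
  prof <- sensitivity_scan(circ, grad)
  expect_true(all(prof$d >= 0))
  expect_equal(nrow(insensitive_regions(prof, threshold = 0)), 0L)
  covered <- function(th) {
    r <- insensitive_regions(prof, threshold = th)
    unlist(lapply(seq_len(nrow(r)), function(i)
      paste(r$gene[i], seq(r$from[i], r$to[i]))))
  }
  lo <- covered(0.02 * max(prof$d))
  hi <- covered(0.10 * max(prof$d))
  expect_true(all(lo %in% hi))
})

test_that("the scan on a ground-truth circuit recovers the constructed regions", {
  # by construction the full archetype expresses kni only posteriorly and
  # hb only anteriorly, so kni must be dispensable in the anterior and hb in
  # the posterior
  circ <- generate_ground_truth_circuit("full", seed = 1)
  grad <- generate_synthetic_gradients(seed = 1)
  prof <- sensitivity_scan(circ, grad)
  regions <- insensitive_regions(prof)
  kni <- regions[regions$gene == "kni", ]
  hb <- regions[regions$gene == "hb", ]
  expect_true(nrow(kni) >= 1 && kni$from[1] == 35)   # anterior kni region
  expect_true(nrow(hb) >= 1 && max(hb$to) == 75)     # posterior hb region
  # and the two regions do not overlap
  expect_lt(max(kni$to), min(hb$from))
})
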