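test_that("the frozen field evaluates the model equations at fixed maternal input", {
  circ <- random_circuit(17)
  mv <- c(Bcd = 15, Cad = 80)
  field <- frozen_field(circ, mv)
  set.seed(17)
  g <- runif(3, 0, 150)
  # scalar-loop oracle
  hand <- numeric(3)
  for (a in seq_len(3)) {
    u <- circ$h[a]
    for (b in seq_len(3)) u <- u + circ$W[b, a] * g[b]
    for (m in seq_len(2)) u <- u + circ$E[m, a] * mv[m]
    hand[a] <- circ$R[a] * regulation_expression(u) - circ$lambda[a] * g[a]
  }
  expect_equal(unname(field(g)), hand, tolerance = 1e-12)

  # zero maternal values are the same as zeroing E (product structure)
  circ0 <- circ
  circ0$E[] <- 0
  expect_equal(unname(frozen_field(circ, c(Bcd = 0, Cad = 0))(g)),
               unname(frozen_field(circ0, c(Bcd = 0, Cad = 0))(g)))
})

test_that("the analytic Jacobian matches closed forms and finite differences", {
  # all weights zero: diagonal -lambda
  circ0 <- gene_circuit(c("a", "b"), character(), R = c(3, 4),
                        lambda = c(0.2, 0.5), h = c(1, -1),
                        W = matrix(0, 2, 2))
  expect_equal(unname(circuit_jacobian(circ0, numeric(), c(1, 1))),
               diag(c(-0.2, -0.5)), tolerance = 1e-14)

  circ <- random_circuit(23)
  mv <- c(Bcd = 10, Cad = 60)
  set.seed(23)
  g <- runif(3, 0, 100)
  J <- circuit_jacobian(circ, mv, g)
  field <- frozen_field(circ, mv)
  eps <- 1e-5
  for (b in 1:3) {
    e <- rep(0, 3); e[b] <- eps
    fd <- (field(g + e) - field(g - e)) / (2 * eps)
    expect_equal(unname(J[, b]), unname(fd), tolerance = 1e-6)
  }
})

test_that("steady-state search finds the closed-form single-gene root", {
  circ <- gene_circuit("a", character(), R = 2, lambda = 1, h = 0,
                       W = matrix(0, 1, 1))
  ss <- find_steady_states(circ)
  expect_length(ss, 1L)
  expect_equal(unname(ss[[1]]$location), 1, tolerance = 1e-9)
  expect_lt(ss[[1]]$residual, 1e-9)
  expect_equal(ss[[1]]$label, "point attractor")
})

test_that("a strong toggle has two attractors and one saddle, matching a basin census", {
  circ <- toggle_circuit()
  ss <- find_steady_states(circ)
  labels <- sort(vapply(ss, `[[`, character(1), "label"))
  expect_equal(labels, c("point attractor", "point attractor", "saddle"))
  expect_true(all(vapply(ss, `[[`, numeric(1), "residual") < 1e-9))

  att <- attractors(ss)
  census <- basin_census(circ, n_per = 20)
  scale <- max(circ$R / circ$lambda)
  expect_true(points_match(lapply(att, `[[`, "location"), census, scale))
})

test_that("Newton-Raphson census equals the basin census on seeded AC/DC circuits", {
  # subset of the full 20-circuit acceptance check, kept small here
  for (seed in 1:5) {
    circ <- generate_ground_truth_circuit("acdc", seed = seed)
    mv <- c(Bcd = 5 + 3 * seed, Cad = 50 + 5 * seed)
    ss <- find_steady_states(circ, mv)
    att <- attractors(ss)
    census <- basin_census(circ, mv, n_per = 12)
    scale <- max(circ$R / circ$lambda)
    expect_true(points_match(lapply(att, `[[`, "location"), census, scale),
                info = sprintf("seed %d", seed))
  }
})

test_that("increasing seed density never removes roots and keeps classifications", {
  circ <- generate_ground_truth_circuit("acdc", seed = 3)
  mv <- c(Bcd = 20, Cad = 70)
  coarse <- find_steady_states(circ, mv, n_seed_grid = 5)
  fine <- find_steady_states(circ, mv, n_seed_grid = 8)
  expect_gte(length(fine), length(coarse))
  scale <- max(circ$R / circ$lambda)
  for (s in coarse) {
    match_idx <- which(vapply(fine, function(f)
      all(abs(f$location - s$location) <= 1e-3 * scale), logical(1)))
    expect_length(match_idx, 1L)
    expect_equal(fine[[match_idx]]$label, s$label)
  }
})

test_that("eigenvalue classification covers all label cases", {
  expect_equal(classify_steady_state(c(-1, -2, -3))$label, "point attractor")
  expect_equal(classify_steady_state(c(-1 + 2i, -1 - 2i, -3))$label,
               "spiral sink")
  expect_equal(classify_steady_state(c(1, -1, -2))$label, "saddle")
  expect_equal(classify_steady_state(c(1, 2, 3))$label, "unstable node")
  expect_equal(classify_steady_state(c(0.5 + 1i, 0.5 - 1i, 2))$label,
               "unstable focus")
  near <- classify_steady_state(c(-1e-9, -2, -3))
  expect_true(near$near_bifurcation)
  expect_false(classify_steady_state(c(-1, -2))$near_bifurcation)
  expect_error(classify_steady_state(complex(0)), "non-empty")
})

test_that("portrait series are constant for constant maternal input", {
  circ <- generate_ground_truth_circuit("acdc", seed = 2)
  mat <- const_maternal(c(Bcd = 10, Cad = 80))
  series <- portrait_series(circ, mat, 50)
  expect_length(series, 8L)
  locs <- lapply(series, function(p)
    lapply(p$steady_states, `[[`, "location"))
  for (k in 2:8) expect_equal(locs[[k]], locs[[1]], tolerance = 1e-6)
})

test_that("a portrait contains an analytically placed fixed point at every time", {
  # choose h so that u = 0 at the target point: then g* = R phi(0) / lambda
  circ <- random_circuit(41, with_maternal = FALSE)
  gstar <- circ$R / (2 * circ$lambda)
  circ$h[] <- -drop(gstar %*% circ$W)
  field <- frozen_field(circ, numeric())
  expect_lt(max(abs(field(gstar))), 1e-12)
  port <- instantaneous_portrait(circ, numeric())
  scale <- max(circ$R / circ$lambda)
  hit <- any(vapply(port$steady_states, function(s)
    all(abs(s$location - gstar) <= 1e-6 * scale), logical(1)))
  expect_true(hit)
})
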