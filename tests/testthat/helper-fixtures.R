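# Shared fixtures: small circuits and maternal profiles built in code.

# Pure-decay circuit (R = 0): closed-form solutions for solver checks.
decay_circuit <- function(lambda = c(a = 0.1, b = 0.2)) {
  n <- length(lambda)
  gene_circuit(names(lambda), character(), R = rep(0, n), lambda = lambda,
               h = rep(0, n), W = matrix(0, n, n))
}

# Two-gene toggle switch: strong mutual repression, no maternal inputs.
toggle_circuit <- function(w = 0.05, R = 20, lambda = 0.1, h = 2) {
  genes <- c("x", "y")
  W <- matrix(c(0, -w, -w, 0), 2, 2, dimnames = list(genes, genes))
  gene_circuit(genes, character(), R = rep(R, 2), lambda = rep(lambda, 2),
               h = rep(h, 2), W = W)
}

# Two-gene damped oscillator: rotational coupling gives a spiral sink.
spiral_circuit <- function(a = 0.05, R = 20, lambda = 0.1) {
  genes <- c("x", "y")
  W <- matrix(0, 2, 2, dimnames = list(genes, genes))
  W["x", "y"] <- a   # x activates y
  W["y", "x"] <- -a  # y represses x
  gene_circuit(genes, character(), R = rep(R, 2), lambda = rep(lambda, 2),
               h = rep(0, 2), W = W)
}

# Constant-in-space-and-time maternal profiles over the trunk box.
const_maternal <- function(values, times = c(0, 71),
                           positions = c(35, 75)) {
  genes <- names(values)
  vals <- array(rep(values, each = length(positions) * length(times)),
                c(length(positions), length(times), length(genes)))
  maternal_profiles(vals, positions = positions, times = times, genes = genes)
}

# Seeded random dense circuit for property tests (weights small enough to
# stay well-behaved; includes maternal inputs).
random_circuit <- function(seed, n_g = 3, with_maternal = TRUE) {
  set.seed(seed)
  genes <- paste0("g", seq_len(n_g))
  mats <- if (with_maternal) c("Bcd", "Cad") else character()
  W <- matrix(runif(n_g^2, -0.03, 0.015), n_g, n_g,
              dimnames = list(genes, genes))
  E <- matrix(runif(length(mats) * n_g, 0, 0.05), length(mats), n_g,
              dimnames = list(mats, genes))
  gene_circuit(genes, mats, R = runif(n_g, 10, 25),
               lambda = runif(n_g, 0.08, 0.15), h = runif(n_g, -3, 0),
               W = W, E = E)
}

# Dense initial-condition grid census of attractors of a frozen field:
# integrate from an n_per^n_g grid (with a small asymmetric offset so grid
# points do not sit exactly on invariant manifolds), cluster the endpoints.
# Independent of the Newton-Raphson path.
basin_census <- function(circuit, maternal_values = numeric(), n_per = 20,
                         t_max = NULL, match_tol = 1e-2) {
  upper <- circuit$R / circuit$lambda
  n_g <- length(circuit$genes)
  if (is.null(t_max)) t_max <- 200 / min(circuit$lambda)
  offs <- (seq_len(n_g) - 1) * 1e-4 + 1e-4
  axes <- lapply(seq_len(n_g), function(a)
    seq(0, upper[a], length.out = n_per) + offs[a] * upper[a])
  grid <- t(as.matrix(do.call(expand.grid, axes)))
  ends <- gapdyn:::integrate_frozen(circuit, maternal_values, grid, t_max)
  scale <- pmax(upper, 1e-12)
  centers <- list()
  for (j in seq_len(ncol(ends))) {
    hit <- FALSE
    for (k in seq_along(centers)) {
      if (all(abs(ends[, j] - centers[[k]]) <= match_tol * scale)) {
        hit <- TRUE
        break
      }
    }
    if (!hit) centers[[length(centers) + 1L]] <- ends[, j]
  }
  centers
}

# Match two lists of points under a per-axis relative tolerance.
points_match <- function(a, b, scale, tol = 2e-2) {
  if (length(a) != length(b)) return(FALSE)
  used <- rep(FALSE, length(b))
  for (p in a) {
    found <- FALSE
    for (k in seq_along(b)) {
      if (!used[k] && all(abs(p - b[[k]]) <= tol * scale)) {
        used[k] <- TRUE
        found <- TRUE
        break
      }
    }
    if (!found) return(FALSE)
  }
  TRUE
}
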