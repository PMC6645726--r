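#' Frozen-time (autonomous) vector field of a circuit
#'
#' Freezes the maternal inputs at fixed values, turning the non-autonomous
#' circuit into an autonomous vector field over gap concentrations:
#' `f_a(g) = R_a phi(u_a) - lambda_a g_a` with
#' `u_a = sum_b W[b, a] g_b + heff_a` and the maternal contribution folded
#' into an effective threshold `heff_a = h_a + sum_m E[m, a] m_m`. This is
#' the field whose steady states make up an instantaneous phase portrait.
#'
#' @param circuit a [gene_circuit()].
#' @param maternal_values fixed maternal concentrations (one per circuit
#'   maternal input; finite, `>= 0`).
#' @return A function `f(g)` returning the named rate vector, with attributes
#'   `circuit`, `heff`, and class `frozen_field`.
#' @export
frozen_field <- function(circuit, maternal_values = numeric()) {
  stopifnot(inherits(circuit, "gene_circuit"))
  mv <- align_vec(maternal_values, circuit$maternal, "maternal_values")
  if (length(mv) && (any(!is.finite(mv)) || any(mv < 0)))
    stop("frozen maternal values must be finite and >= 0")
  heff <- circuit$h +
    (if (length(circuit$maternal)) drop(mv %*% circuit$E) else 0)
  f <- function(g) {
    g <- align_vec(g, circuit$genes, "state")
    u <- drop(g %*% circuit$W) + heff
    setNames(circuit$R * regulation_expression(u) - circuit$lambda * g,
             circuit$genes)
  }
  structure(f, circuit = circuit, maternal_values = mv, heff = heff,
            class = c("frozen_field", "function"))
}

#' Analytic Jacobian of the frozen circuit field
#'
#' Entry `(a, b)` is `R_a phi'(u_a) W[b, a] - lambda_a delta_ab`, i.e. the
#' derivative of gene `a`'s rate with respect to gene `b`'s concentration,
#' with `phi'(u) = 1 / (2 (u^2 + 1)^(3/2))`.
#'
#' @inheritParams frozen_field
#' @param point gap concentration vector at which to evaluate.
#' @return Square matrix (rows = equations, columns = variables).
#' @export
circuit_jacobian <- function(circuit, maternal_values = numeric(), point) {
  field <- frozen_field(circuit, maternal_values)
  heff <- attr(field, "heff")
  g <- align_vec(point, circuit$genes, "point")
  u <- drop(g %*% circuit$W) + heff
  dp <- circuit$R * regulation_expression_deriv(u)
  J <- dp * t(circuit$W)  # J[a, b] = dp[a] * W[b, a]
  diag(J) <- diag(J) - circuit$lambda
  dimnames(J) <- list(circuit$genes, circuit$genes)
  J
}

#' Classify a steady state by its Jacobian eigenvalues
#'
#' Labels follow the attractor taxonomy used for instantaneous phase
#' portraits: all real parts negative gives a `point attractor` (real
#' eigenvalues) or `spiral sink` (a complex pair); mixed signs give a
#' `saddle`; all positive give an `unstable node` or `unstable focus`.
#' Eigenvalues with `|Re| <= real_tol` put the state near a bifurcation: the
#' base label is still assigned from the signs, but the `near_bifurcation`
#' flag is set rather than silently trusting the classification.
#'
#' @param eigenvalues complex (or numeric) eigenvalue vector, non-empty.
#' @param real_tol tolerance on real parts.
#' @param imag_tol magnitudes of imaginary parts at or below this are treated
#'   as real.
#' @return List with `label` (one of `"point attractor"`, `"spiral sink"`,
#'   `"saddle"`, `"unstable node"`, `"unstable focus"`) and logical
#'   `near_bifurcation`.
#' @export
classify_steady_state <- function(eigenvalues, real_tol = 1e-6,
                                  imag_tol = 1e-9) {
  if (length(eigenvalues) == 0L) stop("eigenvalue list must be non-empty")
  ev <- as.complex(eigenvalues)
  re <- Re(ev)
  complex_pair <- any(abs(Im(ev)) > imag_tol)
  near <- any(abs(re) <= real_tol)
  label <- if (all(re < real_tol)) {
    if (complex_pair) "spiral sink" else "point attractor"
  } else if (all(re > -real_tol)) {
    if (complex_pair) "unstable focus" else "unstable node"
  } else "saddle"
  list(label = label, near_bifurcation = near)
}

#' Find all steady states of a frozen circuit field
#'
#' Runs Newton-Raphson from a regular grid of seeds (default 5 per gene
#' dimension) spanning `[0, R_a / lambda_a]` per gene -- since `phi < 1`,
#' every equilibrium coordinate lies in that box -- plus any user-supplied
#' extra seeds (e.g. trajectory endpoints). Converged roots (residual
#' infinity-norm `< tol`) are deduplicated at a relative spacing of
#' `dedup_rel` per axis and roots with any coordinate below `-1e-6` or above
#' `1.5 R_a / lambda_a` are discarded. Each retained root is classified via
#' [classify_steady_state()] on the analytic Jacobian.
#'
#' @inheritParams frozen_field
#' @param n_seed_grid seeds per gene dimension for the regular grid.
#' @param extra_seeds optional matrix of additional seeds (rows = seeds,
#'   columns = genes).
#' @param tol Newton residual tolerance (absolute, a.u./min).
#' @param dedup_rel dedup distance relative to `R/lambda` per axis.
#' @param real_tol,imag_tol eigenvalue tolerances for classification.
#' @param maxit Newton iteration cap per seed.
#' @return List of steady states, each a list with `location`, `residual`,
#'   `eigenvalues`, `label`, `near_bifurcation`. Attribute `none_converged`
#'   is `TRUE` (with a warning) if no seed converged.
#' @export
find_steady_states <- function(circuit, maternal_values = numeric(),
                               n_seed_grid = 5, extra_seeds = NULL,
                               tol = 1e-9, dedup_rel = 1e-4, real_tol = 1e-6,
                               imag_tol = 1e-9, maxit = 200) {
  stopifnot(inherits(circuit, "gene_circuit"), n_seed_grid >= 2)
  field <- frozen_field(circuit, maternal_values)
  heff <- attr(field, "heff")
  n_g <- length(circuit$genes)
  upper <- circuit$R / circuit$lambda
  if (any(upper <= 0)) upper[upper <= 0] <- 1

  axes <- lapply(seq_len(n_g),
                 function(a) seq(0, upper[a], length.out = n_seed_grid))
  seeds <- t(as.matrix(do.call(expand.grid, axes)))
  if (!is.null(extra_seeds)) {
    extra_seeds <- as.matrix(extra_seeds)
    if (ncol(extra_seeds) != n_g)
      stop("`extra_seeds` must have one column per gene")
    seeds <- cbind(seeds, t(extra_seeds))
  }

  res <- cpp_newton_census(seeds, unname(circuit$R), unname(circuit$lambda),
                           unname(heff), unname(circuit$W), tol,
                           as.integer(maxit))
  ok <- res$converged
  if (!any(ok)) {
    warning("no Newton-Raphson seed converged; returning empty steady-state list")
    return(structure(list(), none_converged = TRUE))
  }
  roots <- res$roots[, ok, drop = FALSE]
  resid <- res$resid[ok]
  # discard roots outside the physically admissible box
  keep <- apply(roots, 2, function(g) all(g > -1e-6) && all(g < 1.5 * upper))
  roots <- roots[, keep, drop = FALSE]
  resid <- resid[keep]
  if (ncol(roots) == 0L) return(structure(list(), none_converged = FALSE))

  # dedup: relative tolerance per axis
  scale <- pmax(upper, 1e-12)
  uniq_idx <- integer()
  for (j in seq_len(ncol(roots))) {
    dup <- FALSE
    for (k in uniq_idx) {
      if (all(abs(roots[, j] - roots[, k]) <= dedup_rel * scale)) {
        dup <- TRUE
        break
      }
    }
    if (!dup) uniq_idx <- c(uniq_idx, j)
  }

  states <- lapply(uniq_idx, function(j) {
    loc <- setNames(roots[, j], circuit$genes)
    J <- circuit_jacobian(circuit, maternal_values, loc)
    ev <- eigen(J, only.values = TRUE)$values
    cls <- classify_steady_state(ev, real_tol, imag_tol)
    list(location = loc, residual = resid[j], eigenvalues = ev,
         label = cls$label, near_bifurcation = cls$near_bifurcation)
  })
  # stable presentation order: by first gene coordinate, then second, ...
  ord <- do.call(order, as.data.frame(t(vapply(states, `[[`,
                                               numeric(n_g), "location"))))
  structure(states[ord], none_converged = FALSE,
            bounds = rbind(lower = rep(0, n_g), upper = upper))
}

#' Instantaneous phase portrait at fixed maternal values
#'
#' Bundles the steady states of the frozen field, the maternal values used,
#' and the time they were frozen at.
#'
#' @inheritParams find_steady_states
#' @param time the time (min) the maternal inputs were frozen at (or `NA`).
#' @param ... passed to [find_steady_states()].
#' @return An object of class `instantaneous_portrait`.
#' @export
instantaneous_portrait <- function(circuit, maternal_values = numeric(),
                                   time = NA_real_, ...) {
  ss <- find_steady_states(circuit, maternal_values, ...)
  structure(
    list(time = time, maternal_values = align_vec(maternal_values,
                                                  circuit$maternal,
                                                  "maternal_values"),
         steady_states = ss, genes = circuit$genes,
         none_converged = isTRUE(attr(ss, "none_converged"))),
    class = "instantaneous_portrait"
  )
}

#' @export
print.instantaneous_portrait <- function(x, ...) {
  cat(sprintf("<instantaneous_portrait at t = %s min: %d steady state(s)>\n",
              format(x$time), length(x$steady_states)))
  for (s in x$steady_states)
    cat(sprintf("  %-16s at (%s)%s\n", s$label,
                paste(signif(s$location, 4), collapse = ", "),
                if (s$near_bifurcation) "  [near bifurcation]" else ""))
  invisible(x)
}

#' Portrait series over the C14A time classes
#'
#' Computes one instantaneous phase portrait per requested time, freezing
#' the maternal inputs at their interpolated values at that time and
#' position.
#'
#' @inheritParams find_steady_states
#' @param maternal a [maternal_profiles()] object.
#' @param position nucleus position, percent A-P.
#' @param times times (min) at which to freeze; defaults to the T1-T8 class
#'   midpoints of `schedule`.
#' @param schedule a [stage_schedule()] (only used for the default `times`).
#' @param ... passed to [find_steady_states()].
#' @return List of [instantaneous_portrait()] objects, one per time.
#' @export
portrait_series <- function(circuit, maternal, position,
                            times = time_class_midpoints(schedule),
                            schedule = stage_schedule(), ...) {
  lapply(times, function(t) {
    mv <- if (length(circuit$maternal))
      interpolate_maternal(maternal, position, t, circuit$maternal)
    else numeric()
    instantaneous_portrait(circuit, mv, time = t, ...)
  })
}

#' Attractors of a portrait
#'
#' @param portrait an [instantaneous_portrait()] or plain steady-state list.
#' @return The subset of steady states labelled `point attractor` or
#'   `spiral sink`.
#' @export
attractors <- function(portrait) {
  ss <- if (inherits(portrait, "instantaneous_portrait"))
    portrait$steady_states else portrait
  Filter(function(s) s$label %in% c("point attractor", "spiral sink"), ss)
}
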