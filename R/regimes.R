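#' Classify the dynamical regime of a frozen circuit
#'
#' Reads the regime off an instantaneous phase portrait: one attractor
#' (point attractor or spiral sink) gives `monostable`, two or more give
#' `multistable`, with the suffix `-damped-oscillatory` whenever at least
#' one attractor is a spiral sink. When cycle checking is on and either no
#' attractor exists or an unstable focus coexists with the (bounded) flow,
#' [detect_limit_cycle()] is run and a sustained oscillation yields the
#' `limit-cycle` label.
#'
#' @param circuit a [gene_circuit()].
#' @param maternal_values frozen maternal concentrations.
#' @param portrait optional precomputed [instantaneous_portrait()] for this
#'   frozen field (computed if missing).
#' @param cycle_check run limit-cycle detection where indicated.
#' @param ... passed to [instantaneous_portrait()] / [detect_limit_cycle()].
#' @return List with `label` (one of `monostable`,
#'   `monostable-damped-oscillatory`, `multistable`,
#'   `multistable-damped-oscillatory`, `limit-cycle`) and logical
#'   `near_bifurcation`.
#' @export
classify_regime <- function(circuit, maternal_values = numeric(),
                            portrait = NULL, cycle_check = TRUE, ...) {
  if (is.null(portrait))
    portrait <- instantaneous_portrait(circuit, maternal_values)
  ss <- portrait$steady_states
  att <- attractors(portrait)
  near <- any(vapply(ss, `[[`, logical(1), "near_bifurcation"))
  has_unstable_focus <- any(vapply(ss, `[[`, character(1), "label") ==
                              "unstable focus")

  if (cycle_check && (length(att) == 0L || has_unstable_focus)) {
    lc <- detect_limit_cycle(circuit, maternal_values, ...)
    if (lc$cycle)
      return(list(label = "limit-cycle", near_bifurcation = near))
  }
  if (length(att) == 0L) {
    if (!cycle_check)
      stop("portrait has no attractor and cycle checking is off; regime unclassifiable")
    # bounded flow with neither attractor nor detected cycle: report the
    # portrait as unclassified rather than guessing
    stop("no attractor found and no sustained oscillation detected; regime unclassifiable")
  }
  damped <- any(vapply(att, `[[`, character(1), "label") == "spiral sink")
  base <- if (length(att) == 1L) "monostable" else "multistable"
  label <- if (damped) paste0(base, "-damped-oscillatory") else base
  list(label = label, near_bifurcation = near)
}

#' Detect sustained limit-cycle oscillations
#'
#' Simulates the frozen circuit from a set of initial conditions over a long
#' horizon (default `50 / min(lambda)`, i.e. fifty times the slowest decay
#' timescale), discards an initial transient fraction, and reports a
#' sustained oscillation iff (a) the post-transient peak-to-peak amplitude
#' of at least one gene exceeds 1% of its `R/lambda` scale and (b) the
#' amplitudes of successive oscillation periods are stationary (relative
#' change below 5%). Trajectories that converge to a fixed point return
#' `FALSE`.
#'
#' @inheritParams classify_regime
#' @param initial_conditions matrix (rows = starts, columns = genes); default
#'   three deterministic starts spread across the admissible box.
#' @param horizon simulation horizon, minutes.
#' @param transient_fraction fraction of the horizon discarded as transient.
#' @param amplitude_frac amplitude threshold as a fraction of `R/lambda`.
#' @param stationarity_tol maximum relative spread of successive period
#'   amplitudes.
#' @param n_samples samples along the retained window.
#' @param ... ignored (absorbs portrait arguments passed through
#'   [classify_regime()]).
#' @return List with `cycle` (logical), `amplitude` (named per-gene
#'   peak-to-peak amplitudes of the retained window), and `period`
#'   (estimated, or `NA`).
#' @export
detect_limit_cycle <- function(circuit, maternal_values = numeric(),
                               initial_conditions = NULL,
                               horizon = 50 / min(circuit$lambda),
                               transient_fraction = 0.5,
                               amplitude_frac = 0.01,
                               stationarity_tol = 0.05, n_samples = 4000,
                               ...) {
  stopifnot(inherits(circuit, "gene_circuit"))
  n_g <- length(circuit$genes)
  upper <- circuit$R / circuit$lambda
  if (is.null(initial_conditions)) {
    fr <- c(0.2, 0.5, 0.8)
    initial_conditions <- t(vapply(seq_along(fr), function(k) {
      upper * fr[(seq_len(n_g) + k - 2L) %% length(fr) + 1L]
    }, numeric(n_g)))
  }
  initial_conditions <- as.matrix(initial_conditions)
  thresh <- amplitude_frac * upper

  best <- list(cycle = FALSE, amplitude = setNames(rep(0, n_g), circuit$genes),
               period = NA_real_)
  for (r in seq_len(nrow(initial_conditions))) {
    # slow cycles can have periods comparable to the default horizon; when a
    # non-converging trajectory shows too few peaks to judge stationarity,
    # extend the horizon (up to 8x) rather than misreporting it
    h_cur <- horizon
    for (ext in 1:4) {
      t_keep0 <- h_cur * transient_fraction
      times <- seq(t_keep0, h_cur, length.out = n_samples)
      tr <- simulate_frozen_series(circuit, maternal_values,
                                   initial_conditions[r, ], times)
      amp <- apply(tr, 2, function(v) max(v) - min(v))
      if (all(amp <= thresh)) break  # converged (or converging) to a point
      lead <- which.max(amp / upper)
      chk <- cycle_stationarity(times, tr[, lead], stationarity_tol)
      if (chk$stationary) {
        return(list(cycle = TRUE, amplitude = setNames(amp, circuit$genes),
                    period = chk$period))
      }
      best$amplitude <- pmax(best$amplitude, setNames(amp, circuit$genes))
      if (chk$enough_peaks) break  # oscillation seen in full, not stationary
      h_cur <- h_cur * 2
    }
  }
  best
}

# Integrate the frozen field from one start and sample along `times`.
simulate_frozen_series <- function(circuit, maternal_values, g0, times,
                                   rtol = 1e-8, atol = 1e-10) {
  n_g <- length(circuit$genes)
  n_m <- length(circuit$maternal)
  mv <- if (n_m) align_vec(maternal_values, circuit$maternal,
                           "maternal_values") else numeric()
  res <- cpp_integrate_nuclei(
    matrix(as.numeric(g0), n_g, 1), 0, max(times), as.numeric(times), TRUE,
    unname(circuit$R), unname(circuit$lambda), unname(circuit$h),
    unname(circuit$W), matrix(unname(circuit$E), nrow = n_m, ncol = n_g),
    0, as.numeric(mv), rtol, atol)
  out <- t(array(res$states, c(n_g, length(times)))[, , drop = FALSE])
  colnames(out) <- circuit$genes
  out
}

# Peak-to-peak stationarity over successive oscillation periods of series v.
cycle_stationarity <- function(times, v, tol, min_periods = 4L) {
  n <- length(v)
  peaks <- which(diff(sign(diff(v))) == -2) + 1L
  troughs <- which(diff(sign(diff(v))) == 2) + 1L
  if (length(peaks) < min_periods + 1L || length(troughs) < min_periods)
    return(list(stationary = FALSE, period = NA_real_, enough_peaks = FALSE))
  # per-period amplitude: peak minus the deepest trough before the next peak
  amps <- numeric()
  for (k in seq_len(length(peaks) - 1L)) {
    tr <- troughs[troughs > peaks[k] & troughs < peaks[k + 1L]]
    if (!length(tr)) next
    amps <- c(amps, v[peaks[k]] - min(v[tr]))
  }
  if (length(amps) < min_periods)
    return(list(stationary = FALSE, period = NA_real_, enough_peaks = FALSE))
  amps <- utils::tail(amps, 10L)
  rel <- abs(diff(amps)) / pmax(abs(amps[-length(amps)]), 1e-12)
  period <- mean(diff(times[utils::tail(peaks, 11L)]))
  list(stationary = all(rel < tol) && all(amps > 0), period = period,
       enough_peaks = TRUE)
}

#' Phase diagram over a maternal input
#'
#' For each nucleus position and each value of the varied maternal input,
#' freezes the *other* maternal input at its value at time class T1 for that
#' position, sets the varied one to the grid value, computes the
#' instantaneous phase portrait, and classifies the regime. Default grids
#' follow the gap-gene analyses: Bcd varied from 0 to 30 a.u. in steps of
#' 0.01; Cad from 60 to 120 a.u. in steps of 0.1 (override `values` for
#' coarser sweeps).
#'
#' @param sub the (sub)circuit to classify.
#' @param maternal a [maternal_profiles()] object (for the frozen input's T1
#'   values).
#' @param positions nucleus positions (cells along the first axis).
#' @param varied which maternal input to vary (`"Bcd"` or `"Cad"`).
#' @param values grid of varied-input values; defaults as above.
#' @param schedule a [stage_schedule()]; its T1 midpoint defines "values at
#'   T1".
#' @param cycle_check passed to [classify_regime()] (off by default: these
#'   diagrams distinguish monostable from multistable regimes).
#' @param ... passed to [classify_regime()].
#' @return A `phase_diagram`: data frame with columns `position`, `value`,
#'   `label`, `near_bifurcation`, plus axis metadata attributes.
#' @export
maternal_phase_diagram <- function(sub, maternal, positions,
                                   varied = c("Bcd", "Cad"), values = NULL,
                                   schedule = stage_schedule(),
                                   cycle_check = FALSE, ...) {
  varied <- match.arg(varied, choices = sub$maternal)
  if (is.null(values))
    values <- if (varied == "Bcd") seq(0, 30, by = 0.01)
              else seq(60, 120, by = 0.1)
  if (length(values) == 0L) stop("empty sweep range for ", varied)
  t1 <- time_class_midpoints(schedule)[["T1"]]
  fixed <- setdiff(sub$maternal, varied)
  rows <- vector("list", length(positions) * length(values))
  k <- 0L
  for (p in positions) {
    mv0 <- interpolate_maternal(maternal, p, t1, sub$maternal)
    for (v in values) {
      mv <- mv0
      mv[varied] <- v
      reg <- classify_regime(sub, mv, cycle_check = cycle_check, ...)
      k <- k + 1L
      rows[[k]] <- data.frame(position = p, value = v, label = reg$label,
                              near_bifurcation = reg$near_bifurcation,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("phase_diagram", class(out)),
            axes = list(position = positions, value = values),
            varied = varied, fixed_at = "T1")
}

#' Phase diagram over regulatory weights
#'
#' Overwrites one or two named gap-gap weights on a grid, freezes the
#' maternal inputs at their T1 values, and classifies the regime of each
#' cell. With a single varied weight, nucleus position serves as the second
#' axis; with two weights, one nucleus is fixed.
#'
#' @param sub the (sub)circuit.
#' @param weights list of one or two `c(regulator, target)` pairs naming
#'   entries of `sub$W`.
#' @param values list of value grids, parallel to `weights`.
#' @param maternal a [maternal_profiles()] object.
#' @param positions positions (one-weight sweeps) or a single fixed position
#'   (two-weight sweeps).
#' @param schedule a [stage_schedule()].
#' @param cycle_check,... passed to [classify_regime()].
#' @return A `phase_diagram` data frame: columns `w1` (and `w2` or
#'   `position`), `label`, `near_bifurcation`.
#' @export
weight_phase_diagram <- function(sub, weights, values, maternal, positions,
                                 schedule = stage_schedule(),
                                 cycle_check = FALSE, ...) {
  stopifnot(inherits(sub, "gene_circuit"))
  if (is.character(weights)) weights <- list(weights)
  for (w in weights) {
    if (length(w) != 2L || !all(w %in% sub$genes))
      stop("unknown weight: ", paste(w, collapse = " -> "))
  }
  if (!is.list(values)) values <- list(values)
  if (length(values) != length(weights))
    stop("`values` must supply one grid per varied weight")
  if (any(lengths(values) == 0L)) stop("empty sweep range")
  t1 <- time_class_midpoints(schedule)[["T1"]]

  classify_cell <- function(circ, mv) {
    reg <- classify_regime(circ, mv, cycle_check = cycle_check, ...)
    reg
  }

  rows <- list()
  if (length(weights) == 1L) {
    w1 <- weights[[1]]
    for (p in positions) {
      mv <- interpolate_maternal(maternal, p, t1, sub$maternal)
      for (v in values[[1]]) {
        circ <- sub
        circ$W[w1[1], w1[2]] <- v
        reg <- classify_cell(circ, mv)
        rows[[length(rows) + 1L]] <- data.frame(
          position = p, w1 = v, label = reg$label,
          near_bifurcation = reg$near_bifurcation, stringsAsFactors = FALSE)
      }
    }
  } else {
    if (length(positions) != 1L)
      stop("two-weight sweeps fix a single nucleus position")
    mv <- interpolate_maternal(maternal, positions, t1, sub$maternal)
    w1 <- weights[[1]]; w2 <- weights[[2]]
    for (v1 in values[[1]]) for (v2 in values[[2]]) {
      circ <- sub
      circ$W[w1[1], w1[2]] <- v1
      circ$W[w2[1], w2[2]] <- v2
      reg <- classify_cell(circ, mv)
      rows[[length(rows) + 1L]] <- data.frame(
        position = positions, w1 = v1, w2 = v2, label = reg$label,
        near_bifurcation = reg$near_bifurcation, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("phase_diagram", class(out)),
            weights = weights, fixed_at = "T1")
}

#' Locate a regime boundary along a diagram axis
#'
#' On a discrete lattice/grid, the bifurcation boundary is reported as the
#' midpoint between the last multistable and the first monostable cell along
#' the chosen axis (scanning in increasing axis order). Returns `NA` if the
#' axis is single-regime.
#'
#' @param diagram a `phase_diagram` data frame.
#' @param axis column to scan along (e.g. `"position"`, `"value"`, `"w1"`).
#' @param subset optional logical vector selecting the diagram rows to scan
#'   (e.g. one row of a 2-d sweep).
#' @return Boundary location (numeric) or `NA`.
#' @export
regime_boundary <- function(diagram, axis = "position", subset = NULL) {
  df <- if (is.null(subset)) diagram else diagram[subset, ]
  df <- df[order(df[[axis]]), ]
  multi <- startsWith(df$label, "multistable")
  if (all(multi) || !any(multi)) return(NA_real_)
  flips <- which(diff(multi) != 0)
  mean(c(df[[axis]][flips[1]], df[[axis]][flips[1] + 1L]))
}

#' Simplified connectionist AC/DC circuit
#'
#' Builds the reduced three-gene AC/DC model used for regime mapping: equal
#' degradation rates for all genes, a time-constant basal activation term,
#' no auto-activation, and no maternal inputs. The two composite control
#' parameters set the interaction weights: `positive_feedback` is the
#' magnitude of both weights of the double-negative pair (g1, g3), and
#' `negative_feedback` the magnitude of the three cyclic repressions
#' g1 -| g2 -| g3 -| g1. (With both controls at zero the genes uncouple and
#' the system is globally monostable.)
#'
#' @param positive_feedback magnitude (`>= 0`) of the double-negative pair
#'   weights.
#' @param negative_feedback magnitude (`>= 0`) of the cyclic repression
#'   weights.
#' @param R production rate shared by the genes.
#' @param lambda shared degradation rate.
#' @param basal shared constant basal activation term `h`.
#' @return A [gene_circuit()] with genes `g1`, `g2`, `g3` and no maternal
#'   inputs.
#' @export
simplified_acdc <- function(positive_feedback, negative_feedback, R = 20,
                            lambda = 0.1, basal = 2) {
  stopifnot(positive_feedback >= 0, negative_feedback >= 0)
  genes <- c("g1", "g2", "g3")
  W <- matrix(0, 3, 3, dimnames = list(genes, genes))
  W["g1", "g3"] <- -positive_feedback
  W["g3", "g1"] <- -positive_feedback
  W["g1", "g2"] <- -negative_feedback
  W["g2", "g3"] <- -negative_feedback
  W["g3", "g1"] <- W["g3", "g1"] - negative_feedback
  gene_circuit(genes, character(), R = rep(R, 3), lambda = rep(lambda, 3),
               h = rep(basal, 3), W = W,
               id = sprintf("simplified-acdc-p%g-n%g", positive_feedback,
                            negative_feedback))
}

#' Regime map over the two AC/DC control parameters
#'
#' Classifies the simplified AC/DC circuit (with limit-cycle detection on)
#' at every combination of the positive- and negative-feedback control
#' values.
#'
#' @param positive_values grid of positive-feedback control values.
#' @param negative_values grid of negative-feedback control values.
#' @param ... passed to [simplified_acdc()] (circuit settings) -- use
#'   `R`, `lambda`, `basal`.
#' @return A `phase_diagram` data frame with columns `positive`, `negative`,
#'   `label`, `near_bifurcation`.
#' @export
control_parameter_map <- function(positive_values, negative_values, ...) {
  if (is.unsorted(positive_values, strictly = TRUE) ||
      is.unsorted(negative_values, strictly = TRUE))
    stop("control-parameter grids must be strictly increasing")
  rows <- list()
  for (p in positive_values) for (n in negative_values) {
    circ <- simplified_acdc(p, n, ...)
    reg <- classify_regime(circ, numeric(), cycle_check = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      positive = p, negative = n, label = reg$label,
      near_bifurcation = reg$near_bifurcation, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("phase_diagram", class(out)),
            axes = list(positive = positive_values,
                        negative = negative_values))
}
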