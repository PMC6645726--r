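#' Simulate a single nucleus through the stage schedule
#'
#' Integrates the circuit ODEs for one nucleus with time-variable maternal
#' inputs, honouring the schedule's phase structure: production is shut off
#' during mitosis, and the instantaneous division at the end of C13 mitosis
#' leaves the nucleus's concentrations unchanged (daughters inherit the
#' mother's state). When the schedule includes C13, the maternal input seen
#' before division is evaluated at the position of the nucleus's C13 mother
#' (see [mother_position()]); after division, at the nucleus's own position.
#'
#' @param circuit a [gene_circuit()].
#' @param maternal a [maternal_profiles()] object covering the schedule span
#'   at this position (`NULL` allowed only for circuits without maternal
#'   inputs).
#' @param position nucleus position, percent A-P.
#' @param initial_state concentrations at the schedule start (one per gene,
#'   `>= 0`).
#' @param schedule a [stage_schedule()].
#' @param output_times sample times, minutes, strictly increasing, within the
#'   schedule span.
#' @param rtol,atol relative/absolute solver tolerances.
#' @return A [trajectory()].
#' @examples
#' circ <- generate_ground_truth_circuit("acdc", seed = 1)
#' grad <- generate_synthetic_gradients(seed = 1)
#' sched <- stage_schedule()
#' tr <- simulate_nucleus(circ, grad, position = 50,
#'                        initial_state = rep(0, 3), schedule = sched,
#'                        output_times = time_class_midpoints(sched))
#' tr
#' @export
simulate_nucleus <- function(circuit, maternal, position, initial_state,
                             schedule, output_times, rtol = 1e-8,
                             atol = 1e-10) {
  stopifnot(inherits(circuit, "gene_circuit"),
            inherits(schedule, "stage_schedule"))
  res <- simulate_lattice(circuit, maternal, positions = position,
                          initial_states = rbind(align_vec(initial_state,
                                                           circuit$genes,
                                                           "initial_state")),
                          schedule = schedule, output_times = output_times,
                          rtol = rtol, atol = atol)
  res[[1]]
}

#' Simulate a row of independent nuclei
#'
#' Simulates every nucleus of a one-dimensional row. Without diffusion the
#' nuclei are fully independent, so the result is identical to running
#' [simulate_nucleus()] position by position. When the schedule includes C13,
#' `positions` are C13 positions (2% lattice) with one initial state each; at
#' the division event each C13 nucleus is replaced by two daughters on the 1%
#' C14A lattice, both inheriting the mother's concentrations, and one
#' trajectory per daughter is returned (its pre-division samples are the
#' mother's). With a C14A-only schedule, `positions` are taken as-is.
#'
#' @inheritParams simulate_nucleus
#' @param positions nucleus positions, percent A-P, strictly increasing. By
#'   default the C13 lattice ([c13_positions()]) when the schedule includes
#'   C13, otherwise the C14A lattice ([c14a_positions()]).
#' @param initial_states matrix with one row per nucleus in `positions` and
#'   one column per circuit gene.
#' @return A list of [trajectory()] objects (one per C14A nucleus when the
#'   schedule divides), named by position.
#' @export
simulate_row <- function(circuit, maternal, positions = NULL, initial_states,
                         schedule, output_times, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(circuit, "gene_circuit"),
            inherits(schedule, "stage_schedule"))
  if (is.null(positions))
    positions <- if (is.na(schedule$division_time)) c14a_positions()
                 else c13_positions()
  if (anyDuplicated(positions)) stop("duplicate nucleus positions")
  if (is.unsorted(positions, strictly = TRUE))
    stop("`positions` must be sorted in ascending order")
  initial_states <- as.matrix(initial_states)
  if (nrow(initial_states) != length(positions))
    stop("`initial_states` needs one row per nucleus in `positions`")
  simulate_lattice(circuit, maternal, positions, initial_states, schedule,
                   output_times, rtol, atol)
}

# Shared engine behind simulate_nucleus / simulate_row. For schedules with a
# division event, `positions` are interpreted as C14A positions when called
# from simulate_nucleus (length 1) and as C13 mother positions otherwise;
# both reduce to a per-daughter lineage whose pre-division maternal input is
# evaluated at the mother's position.
simulate_lattice <- function(circuit, maternal, positions, initial_states,
                             schedule, output_times, rtol, atol) {
  prep <- lattice_prep(circuit, maternal, positions, initial_states, schedule)
  res <- lattice_run(circuit, prep, schedule, output_times, rtol, atol)
  n_out <- length(output_times)
  n_g <- length(circuit$genes)
  out <- lapply(seq_along(prep$lineage$post), function(i) {
    st <- matrix(res[, i, ], nrow = n_out, ncol = n_g, byrow = TRUE,
                 dimnames = list(NULL, circuit$genes))
    trajectory(prep$lineage$post[i], output_times, st,
               time_class = time_class_of(output_times, schedule))
  })
  names(out) <- as.character(prep$lineage$post)
  out
}

# One-off preparation of a lattice simulation: lineage resolution, initial
# state duplication onto daughters, and maternal series packed into the
# n_m x n_knots x n_nuclei arrays the compiled integrator consumes. The
# result can be reused across repeated integrations of the same lattice
# (e.g. inside a fitting objective; the series do not depend on circuit
# parameters).
lattice_prep <- function(circuit, maternal, positions, initial_states,
                         schedule) {
  initial_states <- as.matrix(initial_states)
  n_g <- length(circuit$genes)
  n_m <- length(circuit$maternal)
  if (n_m > 0L && is.null(maternal))
    stop("circuit has maternal inputs but `maternal` is NULL")
  if (any(initial_states < 0))
    stop("initial concentrations must be >= 0")

  divides <- !is.na(schedule$division_time)
  single <- length(positions) == 1L && nrow(initial_states) == 1L
  if (divides && single) {
    # one lineage: mother position before division, own position after
    lineage <- list(pre = mother_position(positions), post = positions)
  } else if (divides) {
    kids <- daughter_positions(positions)
    lineage <- list(pre = rep(positions, lengths(kids)), post = unlist(kids))
  } else {
    lineage <- list(pre = positions, post = positions)
  }
  n_nuc <- length(lineage$post)
  g0 <- t(initial_states)  # n_g x n_mothers
  colnames(g0) <- NULL
  if (divides && !single) {
    kids <- daughter_positions(positions)
    g0 <- g0[, rep(seq_along(positions), lengths(kids)), drop = FALSE]
  }

  pack <- function(pos_vec) {
    if (n_m == 0L)
      return(list(knots = 0, vals = array(0, c(0, 1, n_nuc))))
    knots <- maternal$times
    vals <- array(NA_real_, c(n_m, length(knots), n_nuc))
    for (i in seq_len(n_nuc))
      vals[, , i] <- maternal_time_series(maternal, pos_vec[i],
                                          circuit$maternal)$values
    list(knots = knots, vals = vals)
  }
  pre <- pack(lineage$pre)
  post <- if (divides) pack(lineage$post) else pre
  list(lineage = lineage, g0 = g0, pre = pre, post = post, divides = divides)
}

# Run the phase segments of `schedule` over a prepared lattice; returns the
# state array n_genes x n_nuclei x n_output_times.
lattice_run <- function(circuit, prep, schedule, output_times, rtol, atol) {
  output_times <- as.numeric(output_times)
  if (length(output_times) == 0L) stop("`output_times` must be non-empty")
  if (is.unsorted(output_times, strictly = TRUE))
    stop("`output_times` must be strictly increasing")
  eps <- 1e-9 * max(1, abs(schedule$span[2]))
  if (min(output_times) < schedule$span[1] - eps ||
      max(output_times) > schedule$span[2] + eps)
    stop(sprintf("output times must lie within the schedule span [%g, %g] min",
                 schedule$span[1], schedule$span[2]))
  n_g <- length(circuit$genes)
  n_m <- length(circuit$maternal)
  n_nuc <- ncol(prep$g0)
  n_out <- length(output_times)
  E_mat <- matrix(unname(circuit$E), nrow = n_m, ncol = n_g)

  states <- array(NA_real_, c(n_g, n_nuc, n_out))
  recorded <- rep(FALSE, n_out)
  cur <- prep$g0
  at_start <- abs(output_times - schedule$span[1]) <= eps
  if (any(at_start)) {
    for (j in which(at_start)) states[, , j] <- cur
    recorded[at_start] <- TRUE
  }

  for (k in seq_len(nrow(schedule$phases))) {
    ph <- schedule$phases[k, ]
    if (max(output_times) < ph$start - eps) break
    sel <- !recorded & output_times > ph$start + eps &
      output_times <= ph$end + eps
    seg_out <- output_times[sel]
    use <- if (prep$divides && ph$start < schedule$division_time - eps)
      prep$pre else prep$post
    if (n_m > 0L && length(use$knots) > 1L) {
      if (ph$start < use$knots[1] - eps ||
          ph$end > use$knots[length(use$knots)] + eps)
        stop(sprintf(
          "maternal profiles cover %g-%g min but the segment needs %g-%g min",
          use$knots[1], use$knots[length(use$knots)], ph$start, ph$end))
    }
    res <- cpp_integrate_nuclei(
      cur, ph$start, ph$end, seg_out, ph$production,
      unname(circuit$R), unname(circuit$lambda), unname(circuit$h),
      unname(circuit$W), E_mat, as.numeric(use$knots), as.numeric(use$vals),
      rtol, atol)
    if (length(seg_out))
      states[, , which(sel)] <- array(res$states,
                                      c(n_g, n_nuc, length(seg_out)))
    recorded[sel] <- TRUE
    cur <- res$final
    # instantaneous division at the end of C13 mitosis: states are inherited
    # unchanged, only the maternal-input position switches (handled above)
  }
  states
}

# Integrate the frozen (autonomous) field from many initial conditions.
# g0: n_g x n_ic matrix; returns n_g x n_ic matrix of endpoint states.
integrate_frozen <- function(circuit, maternal_values, g0, t_max,
                             rtol = 1e-8, atol = 1e-10) {
  n_g <- length(circuit$genes)
  n_m <- length(circuit$maternal)
  mv <- if (n_m) align_vec(maternal_values, circuit$maternal,
                           "maternal_values") else numeric()
  res <- cpp_integrate_nuclei(
    g0, 0, t_max, numeric(), TRUE,
    unname(circuit$R), unname(circuit$lambda), unname(circuit$h),
    unname(circuit$W),
    matrix(unname(circuit$E), nrow = n_m, ncol = n_g),
    0, as.numeric(array(rep(mv, ncol(g0)), c(n_m, 1, ncol(g0)))), rtol, atol)
  res$final
}
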