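#' Remove a gene (node) from a circuit
#'
#' Erases a gap gene and all its regulatory interactions: its row and column
#' of `W`, its entries of `R`, `lambda`, `h`, and its column of the maternal
#' weight matrix `E`. All remaining parameters are unchanged.
#'
#' @param circuit a [gene_circuit()].
#' @param gene gene identifier to remove.
#' @return A [gene_circuit()] over the remaining genes.
#' @export
remove_node <- function(circuit, gene) {
  stopifnot(inherits(circuit, "gene_circuit"))
  if (length(gene) != 1L || !gene %in% circuit$genes)
    stop("unknown gene: ", paste(gene, collapse = ", "))
  keep <- setdiff(circuit$genes, gene)
  gene_circuit(
    genes = keep, maternal = circuit$maternal,
    R = circuit$R[keep], lambda = circuit$lambda[keep], h = circuit$h[keep],
    W = circuit$W[keep, keep, drop = FALSE],
    E = circuit$E[, keep, drop = FALSE],
    id = if (is.null(circuit$id)) NULL else paste0(circuit$id, "-minus-", gene)
  )
}

#' Node-sensitivity distance between two trajectories
#'
#' The distance between a full-model trajectory and a node-removed
#' trajectory, summed over the eight C14A time classes:
#' `d = sqrt( sum_i sum_a (g_a^full(T_i) - g_a^reduced(T_i))^2 / 8 )`,
#' where the removed gene's concentration in the reduced trajectory enters
#' as zero. The square root is taken once, of the time-class mean of the
#' per-gene summed squared differences, so a constant offset `delta` in a
#' single gene gives exactly `d = delta`. The metric is symmetric and zero
#' iff the compared samples coincide.
#'
#' @param full_traj,reduced_traj [trajectory()] objects sampled at the same
#'   eight time-class times (gene sets may differ; missing genes count as 0).
#' @param times the compared sample times; defaults to the intersection of
#'   both trajectories' times, which must have length 8.
#' @return The scalar distance `d` (a.u.).
#' @export
node_sensitivity <- function(full_traj, reduced_traj, times = NULL) {
  stopifnot(inherits(full_traj, "trajectory"),
            inherits(reduced_traj, "trajectory"))
  if (is.null(times)) {
    times <- intersect(full_traj$times, reduced_traj$times)
    if (length(times) != 8L)
      stop("trajectories must share exactly the 8 time-class samples; found ",
           length(times))
  }
  genes <- union(colnames(full_traj$states), colnames(reduced_traj$states))
  a <- pad_genes(states_at(full_traj, times), genes)
  b <- pad_genes(states_at(reduced_traj, times), genes)
  sqrt(sum((a - b)^2) / length(times))
}

pad_genes <- function(states, genes) {
  out <- matrix(0, nrow(states), length(genes),
                dimnames = list(NULL, genes))
  out[, colnames(states)] <- states
  out
}

#' Node-removal sensitivity scan across the trunk
#'
#' For every nucleus position and every gap gene, simulates the full circuit
#' and the node-removed circuit over C14A only (starting from the full
#' model's state at the onset of C14A) and records the node-sensitivity
#' distance [node_sensitivity()]. Small `d` at a position means the gene is
#' dispensable there -- the basis for delimiting dynamical modules' regions
#' of influence.
#'
#' @param circuit the full [gene_circuit()].
#' @param maternal a [maternal_profiles()] object.
#' @param initial_states matrix of full-model concentrations at C14A onset
#'   (one row per position, columns = circuit genes). If `NULL`, obtained by
#'   simulating the full model from zero concentrations at C13 onset.
#' @param positions nucleus positions to scan.
#' @param schedule the full [stage_schedule()] (its C14A window and class
#'   midpoints are used).
#' @param rtol,atol solver tolerances.
#' @return A `sensitivity_profile`: data frame with columns `position`,
#'   `gene` (the removed gene), and `d`, plus attributes (`circuit_id`,
#'   `times`).
#' @export
sensitivity_scan <- function(circuit, maternal, initial_states = NULL,
                             positions = c14a_positions(),
                             schedule = stage_schedule(), rtol = 1e-8,
                             atol = 1e-10) {
  stopifnot(inherits(circuit, "gene_circuit"))
  # C14A-only schedule aligned with the parent's absolute times
  c14a <- c14a_only(schedule)
  mids <- time_class_midpoints(schedule)

  if (is.null(initial_states)) {
    init0 <- matrix(0, length(c13_positions()), length(circuit$genes))
    full_c13 <- simulate_row(circuit, maternal, c13_positions(), init0,
                             schedule, output_times = schedule$c14a_start,
                             rtol = rtol, atol = atol)
    initial_states <- t(vapply(as.character(positions),
                               function(p) full_c13[[p]]$states[1, ],
                               numeric(length(circuit$genes))))
  }
  initial_states <- as.matrix(initial_states)
  if (nrow(initial_states) != length(positions))
    stop("`initial_states` needs one row per position")
  if (is.null(colnames(initial_states)))
    colnames(initial_states) <- circuit$genes

  full_trajs <- simulate_row(circuit, maternal, positions, initial_states,
                             c14a, output_times = mids, rtol = rtol,
                             atol = atol)
  rows <- list()
  for (gene in circuit$genes) {
    reduced <- remove_node(circuit, gene)
    keep <- setdiff(circuit$genes, gene)
    red_trajs <- tryCatch(
      simulate_row(reduced, maternal, positions,
                   initial_states[, keep, drop = FALSE], c14a,
                   output_times = mids, rtol = rtol, atol = atol),
      error = function(e) stop(sprintf("removal of %s: %s", gene,
                                       conditionMessage(e)), call. = FALSE))
    d <- vapply(seq_along(positions), function(i) {
      tryCatch(
        node_sensitivity(full_trajs[[i]], red_trajs[[i]], times = mids),
        error = function(e) stop(sprintf(
          "sensitivity at position %g, gene %s: %s", positions[i], gene,
          conditionMessage(e)), call. = FALSE))
    }, numeric(1))
    rows[[gene]] <- data.frame(position = positions, gene = gene, d = d,
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("sensitivity_profile", class(out)),
            circuit_id = circuit$id, times = mids)
}

# A C14A-only schedule sharing the parent schedule's absolute C14A window.
c14a_only <- function(schedule) {
  stage_schedule(
    c13_interphase = max(schedule$c14a_start, 1e-6) / 2,
    c13_mitosis = max(schedule$c14a_start, 1e-6) / 2,
    c14a = schedule$c14a_end - schedule$c14a_start,
    t0 = 0, include_c13 = FALSE)
}

#' Regions of insensitivity
#'
#' Finds, per removed gene, the maximal contiguous runs of nucleus positions
#' where the node-sensitivity distance falls below a threshold. Intervals
#' are reported closed on the nucleus lattice.
#'
#' @param profile a [sensitivity_scan()] result.
#' @param threshold sensitivity below which a gene counts as dispensable;
#'   default 5% of the maximum `d` in the scan.
#' @return Data frame with columns `gene`, `from`, `to`, `n_nuclei` (empty
#'   if nothing falls below the threshold).
#' @export
insensitive_regions <- function(profile,
                                threshold = 0.05 * max(profile$d)) {
  stopifnot(inherits(profile, "sensitivity_profile"), threshold >= 0)
  out <- list()
  for (gene in unique(profile$gene)) {
    sub <- profile[profile$gene == gene, ]
    sub <- sub[order(sub$position), ]
    low <- sub$d < threshold
    if (!any(low)) next
    r <- rle(low)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      out[[length(out) + 1L]] <- data.frame(
        gene = gene, from = sub$position[starts[k]],
        to = sub$position[ends[k]], n_nuclei = r$lengths[k],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene = character(), from = numeric(), to = numeric(),
                      n_nuclei = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
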