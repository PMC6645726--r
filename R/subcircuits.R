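#' Canonical AC/DC subcircuit assignments
#'
#' The three three-gene dynamical modules of the trunk gap gene network and
#' their regions of influence: AC/DC1 (hb, Kr, gt) over 35-47%, AC/DC2
#' (hb, Kr, kni) over 49-59%, and AC/DC3 (Kr, kni, gt) over 61-75% A-P
#' position. The nuclei at 48% and 60% separate the regions and belong to
#' none of them. A fourth subcircuit (hb, kni, gt) lies posterior of the
#' model's spatial domain and is not represented.
#'
#' @return Data frame with columns `name`, `genes` (list column of 3 gene
#'   ids), `from`, `to`.
#' @export
acdc_assignments <- function() {
  out <- data.frame(name = c("acdc1", "acdc2", "acdc3"),
                    from = c(35, 49, 61), to = c(47, 59, 75),
                    stringsAsFactors = FALSE)
  out$genes <- list(c("hb", "Kr", "gt"), c("hb", "Kr", "kni"),
                    c("Kr", "kni", "gt"))
  out[, c("name", "genes", "from", "to")]
}

#' Extract a subcircuit
#'
#' Restricts a circuit to a subset of its genes: the gap-gap weight matrix
#' is cut down to the member rows and columns (auto-activation retained),
#' while production/decay rates, thresholds, and the full maternal input
#' rows of the members are carried over unchanged.
#'
#' @param circuit the parent [gene_circuit()].
#' @param genes member gene identifiers (subset of the circuit's genes).
#' @return A [gene_circuit()] over `genes`.
#' @export
extract_subcircuit <- function(circuit, genes) {
  stopifnot(inherits(circuit, "gene_circuit"))
  miss <- setdiff(genes, circuit$genes)
  if (length(miss))
    stop("unknown gene(s): ", paste(miss, collapse = ", "))
  gene_circuit(
    genes = genes, maternal = circuit$maternal,
    R = circuit$R[genes], lambda = circuit$lambda[genes],
    h = circuit$h[genes],
    W = circuit$W[genes, genes, drop = FALSE],
    E = circuit$E[, genes, drop = FALSE],
    id = if (is.null(circuit$id)) NULL
         else paste0(circuit$id, "-sub-", paste(genes, collapse = "."))
  )
}

#' Simulate an AC/DC subcircuit over C14A
#'
#' Subcircuit simulations cover C14A only: no mitosis, no division. The
#' initial state is the full model's member-gene concentrations at the onset
#' of C14A (time class T1), and maternal inputs remain time-variable.
#'
#' @param sub the subcircuit ([extract_subcircuit()]).
#' @param maternal a [maternal_profiles()] object.
#' @param position nucleus position, percent A-P.
#' @param initial_state member-gene concentrations at C14A onset.
#' @param schedule the parent [stage_schedule()]; its C14A window is used.
#' @param output_times sample times; default the T1-T8 class midpoints.
#' @param rtol,atol solver tolerances.
#' @return A [trajectory()].
#' @export
simulate_subcircuit <- function(sub, maternal, position, initial_state,
                                schedule = stage_schedule(),
                                output_times = time_class_midpoints(schedule),
                                rtol = 1e-8, atol = 1e-10) {
  simulate_nucleus(sub, maternal, position, initial_state,
                   c14a_only(schedule), output_times, rtol, atol)
}

#' Range-normalised distance between subcircuit and full-model trajectories
#'
#' Compares a subcircuit trajectory against the full model over the shared
#' genes with the time-class distance metric of [node_sensitivity()], after
#' normalising each gene's differences by that gene's full-model dynamic
#' range across the compared samples (genes have different absolute scales;
#' what matters is the shape of the expression dynamics). A gene offset by
#' its full dynamic range at all time classes has per-gene distance exactly
#' 1.
#'
#' @param sub_traj subcircuit [trajectory()].
#' @param full_traj full-model [trajectory()].
#' @param shared_genes genes to compare; default the intersection of the two
#'   trajectories' gene sets (must be non-empty).
#' @param times compared sample times; default the intersection of sampling
#'   times.
#' @return List with `overall` (scalar) and `per_gene` (named vector).
#' @export
compare_trajectories <- function(sub_traj, full_traj, shared_genes = NULL,
                                 times = NULL) {
  stopifnot(inherits(sub_traj, "trajectory"), inherits(full_traj, "trajectory"))
  if (is.null(shared_genes))
    shared_genes <- intersect(colnames(sub_traj$states),
                              colnames(full_traj$states))
  if (length(shared_genes) == 0L) stop("no shared genes to compare")
  if (is.null(times)) {
    times <- intersect(sub_traj$times, full_traj$times)
    if (length(times) == 0L) stop("no common sampling times")
  }
  a <- states_at(sub_traj, times)[, shared_genes, drop = FALSE]
  b <- states_at(full_traj, times)[, shared_genes, drop = FALSE]
  rng <- apply(b, 2, function(v) max(v) - min(v))
  rng[rng <= 0] <- pmax(apply(b, 2, max)[rng <= 0], 1)
  z <- sweep(a - b, 2, rng, "/")
  per_gene <- sqrt(colSums(z^2) / length(times))
  list(overall = sqrt(sum(z^2) / length(times)),
       per_gene = setNames(per_gene, shared_genes))
}
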