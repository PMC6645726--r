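#' Trajectory of one nucleus
#'
#' Time-indexed state of a single nucleus's gap protein concentrations.
#'
#' @param position nucleus position, percent A-P.
#' @param times sample times, minutes, strictly increasing.
#' @param states matrix `length(times) x n_genes` of concentrations (a.u.),
#'   columns named by gene.
#' @param time_class optional character vector of time-class labels per row.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(position, times, states, time_class = NULL) {
  states <- as.matrix(states)
  if (length(times) != nrow(states))
    stop("`times` and rows of `states` must agree")
  if (is.unsorted(times, strictly = TRUE))
    stop("`times` must be strictly increasing")
  if (any(!is.finite(states)))
    stop("trajectory states must be finite")
  structure(
    list(position = position, times = as.numeric(times), states = states,
         time_class = time_class),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: nucleus at %g%% A-P, %d samples over %g-%g min, genes: %s>\n",
              x$position, length(x$times), min(x$times), max(x$times),
              paste(colnames(x$states), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  genes <- colnames(x$states)
  data.frame(
    position = x$position,
    time_min = rep(x$times, times = length(genes)),
    time_class = if (is.null(x$time_class)) NA_character_
                 else rep(x$time_class, times = length(genes)),
    gene = rep(genes, each = length(x$times)),
    concentration = as.numeric(x$states),
    stringsAsFactors = FALSE
  )
}

# States of a trajectory at given times (must be sampled there).
states_at <- function(traj, times, tol = 1e-8) {
  idx <- vapply(times, function(t) {
    j <- which(abs(traj$times - t) <= tol * max(1, abs(t)))
    if (length(j) != 1L)
      stop(sprintf("trajectory not sampled at t = %g min", t))
    j
  }, integer(1))
  traj$states[idx, , drop = FALSE]
}
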