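#' Developmental stage schedule for the hybrid circuit model
#'
#' The full model runs through cleavage cycle 13 (interphase, then mitosis
#' with production shut off), an instantaneous nuclear division at the end of
#' C13 mitosis, and the C14A interphase, which is subdivided into eight time
#' classes of equal duration (T1-T8). Durations are configurable; only the
#' relative structure matters for the analyses. Defaults: t = 0 at C13 onset,
#' 16 min C13 interphase, 5 min mitosis (division at its end), 50 min C14A
#' (so each time class lasts 6.25 min).
#'
#' @param c13_interphase duration of C13 interphase, minutes.
#' @param c13_mitosis duration of C13 mitosis, minutes.
#' @param c14a duration of C14A, minutes.
#' @param t0 time at C13 onset, minutes.
#' @param include_c13 if `FALSE`, the schedule covers C14A only (no mitosis,
#'   no division), as used for subcircuit simulations and sensitivity scans.
#' @return An object of class `stage_schedule`: a list with a `phases` data
#'   frame (`phase`, `start`, `end`, `production`), the `division_time`
#'   (`NA` when `include_c13 = FALSE`), C14A bounds, and the T1-T8 class
#'   boundaries and midpoints.
#' @examples
#' sched <- stage_schedule()
#' sched$phases
#' time_class_midpoints(sched)
#' @export
stage_schedule <- function(c13_interphase = 16, c13_mitosis = 5, c14a = 50,
                           t0 = 0, include_c13 = TRUE) {
  stopifnot(c13_interphase > 0, c13_mitosis > 0, c14a > 0)
  if (include_c13) {
    b1 <- t0 + c13_interphase
    b2 <- b1 + c13_mitosis
    b3 <- b2 + c14a
    phases <- data.frame(
      phase = c("C13", "C13_mitosis", "C14A"),
      start = c(t0, b1, b2), end = c(b1, b2, b3),
      production = c(TRUE, FALSE, TRUE),
      stringsAsFactors = FALSE
    )
    division_time <- b2
    c14a_start <- b2
  } else {
    c14a_start <- t0 + c13_interphase + c13_mitosis
    b3 <- c14a_start + c14a
    phases <- data.frame(
      phase = "C14A", start = c14a_start, end = b3, production = TRUE,
      stringsAsFactors = FALSE
    )
    division_time <- NA_real_
  }
  class_bounds <- seq(c14a_start, c14a_start + c14a, length.out = 9L)
  structure(
    list(phases = phases, division_time = division_time,
         c14a_start = c14a_start, c14a_end = c14a_start + c14a,
         class_bounds = class_bounds,
         class_midpoints = (class_bounds[-9] + class_bounds[-1]) / 2,
         span = c(phases$start[1], b3)),
    class = "stage_schedule"
  )
}

#' @rdname stage_schedule
#' @export
c14a_schedule <- function(c13_interphase = 16, c13_mitosis = 5, c14a = 50,
                          t0 = 0) {
  stage_schedule(c13_interphase, c13_mitosis, c14a, t0, include_c13 = FALSE)
}

#' @export
print.stage_schedule <- function(x, ...) {
  cat("<stage_schedule>\n")
  print(x$phases)
  if (!is.na(x$division_time))
    cat(sprintf("  division (instantaneous) at t = %g min\n", x$division_time))
  cat(sprintf("  C14A time classes T1-T8: %g min each\n",
              diff(x$class_bounds[1:2])))
  invisible(x)
}

#' Time-class midpoints T1-T8 of a schedule
#'
#' @param schedule a [stage_schedule()].
#' @return Numeric vector of 8 times (minutes), named `T1`..`T8`.
#' @export
time_class_midpoints <- function(schedule) {
  stopifnot(inherits(schedule, "stage_schedule"))
  setNames(schedule$class_midpoints, paste0("T", 1:8))
}

#' Map times to C14A time-class labels
#'
#' @param times numeric vector of times, minutes.
#' @param schedule a [stage_schedule()].
#' @return Character vector: `"T1"`..`"T8"` within C14A, `"C13"` before it,
#'   `NA` after the schedule ends.
#' @export
time_class_of <- function(times, schedule) {
  stopifnot(inherits(schedule, "stage_schedule"))
  out <- rep(NA_character_, length(times))
  out[times < schedule$c14a_start] <- "C13"
  inside <- times >= schedule$c14a_start & times <= schedule$c14a_end
  idx <- pmin(8L, pmax(1L, findInterval(times[inside], schedule$class_bounds,
                                        rightmost.closed = TRUE)))
  out[inside] <- paste0("T", idx)
  out
}

#' Nuclear lattices of the trunk region
#'
#' The model's spatial domain covers 35-75% A-P position. During C14A there
#' are 41 nuclei at integer percent positions; during C13 there are 21 nuclei
#' with 2% spacing. At division, the C13 nucleus at position `p` yields
#' daughters at `p - 0.5` and `p + 0.5`, rounded half-up to the C14A 1%
#' lattice (so `p` and `p + 1`); daughters falling outside the 35-75% domain
#' are dropped.
#'
#' @return `c14a_positions()`/`c13_positions()`: integer position vectors.
#' @export
c14a_positions <- function() 35:75

#' @rdname c14a_positions
#' @export
c13_positions <- function() seq(35L, 75L, by = 2L)

#' @rdname c14a_positions
#' @param position C14A nucleus position(s) on the integer lattice.
#' @return `mother_position()`: the C13 position whose daughter occupies
#'   `position`.
#' @export
mother_position <- function(position) {
  p <- as.integer(round(position))
  ifelse(p %% 2L == 0L, p - 1L, p)
}

#' @rdname c14a_positions
#' @param c13_position C13 nucleus position(s) on the 2%-spaced lattice.
#' @return `daughter_positions()`: list of integer daughter position vectors
#'   (clipped to the 35-75% domain).
#' @export
daughter_positions <- function(c13_position) {
  lapply(as.integer(round(c13_position)), function(p) {
    d <- c(p, p + 1L)
    d[d >= 35L & d <= 75L]
  })
}
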