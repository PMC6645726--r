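#' Maternal gradient profiles over position and time
#'
#' Stores concentrations of maternal regulators (e.g. Bcd, Cad) on a
#' position-by-time knot grid and evaluates them anywhere inside the grid's
#' bounding box by bilinear interpolation (the interpolation is exact at the
#' knots). This mirrors how quantified spatio-temporal protein data enter the
#' model: profiles are linearly interpolated between measured positions and
#' time points.
#'
#' @param values either a 3-d array `positions x times x genes`, or a long
#'   data frame with columns `position`, `time_min`, `gene`, `concentration`
#'   covering the full grid.
#' @param positions numeric vector of A-P positions (%), strictly increasing.
#'   Ignored when `values` is a data frame.
#' @param times numeric vector of times (min), strictly increasing. Ignored
#'   when `values` is a data frame.
#' @param genes character vector of maternal gene names. Ignored when
#'   `values` is a data frame.
#' @return An object of class `maternal_profiles`.
#' @export
maternal_profiles <- function(values, positions = NULL, times = NULL,
                              genes = NULL) {
  if (is.data.frame(values)) {
    need <- c("position", "time_min", "gene", "concentration")
    miss <- setdiff(need, names(values))
    if (length(miss))
      stop("maternal table lacks column(s): ", paste(miss, collapse = ", "))
    positions <- sort(unique(values$position))
    times <- sort(unique(values$time_min))
    genes <- unique(as.character(values$gene))
    arr <- array(NA_real_, c(length(positions), length(times), length(genes)),
                 dimnames = list(NULL, NULL, genes))
    ip <- match(values$position, positions)
    it <- match(values$time_min, times)
    ig <- match(as.character(values$gene), genes)
    arr[cbind(ip, it, ig)] <- values$concentration
    if (anyNA(arr))
      stop("maternal table does not cover the full position x time grid")
    values <- arr
  } else {
    values <- as.array(values)
    if (length(dim(values)) != 3L)
      stop("`values` must be a positions x times x genes array")
    if (is.null(positions) || is.null(times) || is.null(genes))
      stop("`positions`, `times` and `genes` are required with array input")
    dimnames(values) <- list(NULL, NULL, genes)
  }
  if (length(positions) != dim(values)[1] || length(times) != dim(values)[2] ||
      length(genes) != dim(values)[3])
    stop("grid dimensions do not match `values`")
  if (is.unsorted(positions, strictly = TRUE) ||
      is.unsorted(times, strictly = TRUE))
    stop("`positions` and `times` must be strictly increasing")
  if (any(!is.finite(values)) || any(values < 0))
    stop("maternal concentrations must be finite and >= 0")
  structure(
    list(positions = as.numeric(positions), times = as.numeric(times),
         genes = as.character(genes), values = values),
    class = "maternal_profiles"
  )
}

#' @export
print.maternal_profiles <- function(x, ...) {
  cat(sprintf(
    "<maternal_profiles: %s on %d positions (%g-%g%%) x %d times (%g-%g min)>\n",
    paste(x$genes, collapse = ", "), length(x$positions), min(x$positions),
    max(x$positions), length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Evaluate maternal profiles at arbitrary (position, time)
#'
#' Bilinear interpolation in position and time; exact at the knots. Queries
#' outside the bounding box of the knot grid are an error (no extrapolation).
#'
#' @param profiles a [maternal_profiles()] object.
#' @param position A-P position, percent (scalar).
#' @param time time, minutes (scalar).
#' @param genes which maternal genes to return; default all, in profile order.
#' @return Named numeric vector of concentrations.
#' @export
interpolate_maternal <- function(profiles, position, time,
                                 genes = profiles$genes) {
  stopifnot(inherits(profiles, "maternal_profiles"))
  if (!is.finite(position) || !is.finite(time))
    stop("`position` and `time` must be finite")
  eps_p <- 1e-9 * max(1, diff(range(profiles$positions)))
  eps_t <- 1e-9 * max(1, diff(range(profiles$times)))
  if (position < min(profiles$positions) - eps_p ||
      position > max(profiles$positions) + eps_p)
    stop(sprintf("position %g%% outside maternal profile support [%g, %g]",
                 position, min(profiles$positions), max(profiles$positions)))
  if (time < min(profiles$times) - eps_t || time > max(profiles$times) + eps_t)
    stop(sprintf("time %g min outside maternal profile support [%g, %g]",
                 time, min(profiles$times), max(profiles$times)))
  miss <- setdiff(genes, profiles$genes)
  if (length(miss))
    stop("unknown maternal gene(s): ", paste(miss, collapse = ", "))

  wp <- interp_weights(profiles$positions, position)
  wt <- interp_weights(profiles$times, time)
  v <- profiles$values[, , genes, drop = FALSE]
  out <- wp$w0 * (wt$w0 * v[wp$i0, wt$i0, ] + wt$w1 * v[wp$i0, wt$i1, ]) +
    wp$w1 * (wt$w0 * v[wp$i1, wt$i0, ] + wt$w1 * v[wp$i1, wt$i1, ])
  setNames(as.numeric(out), genes)
}

interp_weights <- function(knots, x) {
  n <- length(knots)
  if (n == 1L || x <= knots[1]) return(list(i0 = 1L, i1 = 1L, w0 = 1, w1 = 0))
  if (x >= knots[n]) return(list(i0 = n, i1 = n, w0 = 1, w1 = 0))
  i0 <- findInterval(x, knots)
  i1 <- i0 + 1L
  w1 <- (x - knots[i0]) / (knots[i1] - knots[i0])
  list(i0 = i0, i1 = i1, w0 = 1 - w1, w1 = w1)
}

# Time series of maternal values at one position, on the profile's native
# time knots (bilinear in (pos, time) => exactly piecewise linear in time).
# Returns list(knots, values = n_m x n_k matrix) for the compiled integrator.
maternal_time_series <- function(profiles, position, genes = profiles$genes) {
  if (length(genes) == 0L)
    return(list(knots = 0, values = matrix(0, 0, 1)))
  wp <- interp_weights(profiles$positions, position)
  v <- profiles$values[, , genes, drop = FALSE]
  slab <- wp$w0 * v[wp$i0, , , drop = TRUE] + wp$w1 * v[wp$i1, , , drop = TRUE]
  # slab: times x genes (drop may simplify when one gene)
  slab <- matrix(slab, nrow = length(profiles$times), ncol = length(genes))
  list(knots = profiles$times, values = t(slab))
}

# Constant-in-time maternal series from a named value vector.
constant_maternal_series <- function(values, genes) {
  if (length(genes) == 0L)
    return(list(knots = 0, values = matrix(0, 0, 1)))
  values <- align_vec(values, genes, "maternal_values")
  list(knots = 0, values = matrix(values, ncol = 1))
}

#' Convert maternal profiles to a long data frame
#'
#' @param x a [maternal_profiles()] object.
#' @param ... unused.
#' @return Data frame with columns `position`, `time_min`, `gene`,
#'   `concentration`.
#' @export
as.data.frame.maternal_profiles <- function(x, ...) {
  grid <- expand.grid(position = x$positions, time_min = x$times,
                      gene = x$genes, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$concentration <- as.numeric(x$values)
  grid
}
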