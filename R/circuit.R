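#' Construct a connectionist gene circuit
#'
#' A gene circuit parameterises the connectionist model of gap gene
#' regulation: each gene `a` is produced at rate `R[a] * phi(u_a)` and decays
#' at rate `lambda[a] * g_a`, where the total regulatory input
#' `u_a = sum_b W[b, a] g_b + sum_m E[m, a] g_m + h[a]` combines gap-gap
#' cross-regulation (`W`), external maternal inputs (`E`), and a basal
#' threshold (`h`), and `phi` is the sigmoid regulation-expression function
#' [regulation_expression()].
#'
#' Both interconnectivity matrices are stored **regulator-by-target**:
#' `W[b, a]` is the effect of regulator `b` on target `a` (positive =
#' activation, negative = repression). The same orientation is used by
#' [write_circuit()] and declared in its mandatory orientation header.
#'
#' @param genes character vector of gap gene identifiers (unique, non-empty).
#' @param maternal character vector of maternal regulator identifiers (may be
#'   empty).
#' @param R per-gene maximum production rate, concentration units per minute
#'   (`>= 0`).
#' @param lambda per-gene first-order decay rate, 1/min (`> 0`).
#' @param h per-gene basal threshold, dimensionless input units.
#' @param W gap-gap weight matrix, `length(genes)` square, rows = regulators,
#'   columns = targets.
#' @param E maternal weight matrix, `length(maternal)` rows (regulators),
#'   `length(genes)` columns (targets). May have zero rows.
#' @param id optional character label carried through outputs.
#' @return An object of class `gene_circuit`.
#' @examples
#' circ <- gene_circuit(
#'   genes = c("hb", "Kr"), maternal = "Bcd",
#'   R = c(hb = 20, Kr = 18), lambda = c(hb = 0.1, Kr = 0.1),
#'   h = c(hb = -2, Kr = -2),
#'   W = matrix(c(0.01, -0.03, -0.03, 0.01), 2, 2,
#'              dimnames = list(c("hb", "Kr"), c("hb", "Kr"))),
#'   E = matrix(c(0.1, 0.05), 1, 2, dimnames = list("Bcd", c("hb", "Kr")))
#' )
#' circ
#' @export
gene_circuit <- function(genes, maternal = character(), R, lambda, h, W, E = NULL,
                         id = NULL) {
  genes <- as.character(genes)
  maternal <- as.character(maternal)
  n_g <- length(genes)
  n_m <- length(maternal)
  if (n_g == 0L) stop("a circuit needs at least one gene")
  if (anyDuplicated(genes)) stop("gene identifiers must be unique")
  if (anyDuplicated(maternal)) stop("maternal identifiers must be unique")

  R <- name_vec(R, genes, "R")
  lambda <- name_vec(lambda, genes, "lambda")
  h <- name_vec(h, genes, "h")
  if (any(!is.finite(R)) || any(R < 0)) stop("production rates R must be finite and >= 0")
  if (any(!is.finite(lambda)) || any(lambda <= 0))
    stop("decay rates lambda must be finite and strictly positive")
  if (any(!is.finite(h))) stop("thresholds h must be finite")

  W <- name_mat(W, genes, genes, "W")
  if (is.null(E)) E <- matrix(0, n_m, n_g, dimnames = list(maternal, genes))
  E <- name_mat(E, maternal, genes, "E")
  if (any(!is.finite(W))) stop("W must be finite")
  if (n_m > 0 && any(!is.finite(E))) stop("E must be finite")

  structure(
    list(genes = genes, maternal = maternal, R = R, lambda = lambda, h = h,
         W = W, E = E, id = id),
    class = "gene_circuit"
  )
}

name_vec <- function(x, nms, what) {
  if (length(x) == 1L && length(nms) > 1L) x <- rep(x, length(nms))
  if (length(x) != length(nms))
    stop(sprintf("`%s` must have length %d (one per gene)", what, length(nms)))
  x <- as.numeric(x)
  names(x) <- nms
  x
}

name_mat <- function(M, rn, cn, what) {
  M <- as.matrix(M)
  if (nrow(M) != length(rn) || ncol(M) != length(cn))
    stop(sprintf("`%s` must be %d x %d (rows = regulators, cols = targets)",
                 what, length(rn), length(cn)))
  storage.mode(M) <- "double"
  dimnames(M) <- list(rn, cn)
  M
}

#' @export
print.gene_circuit <- function(x, ...) {
  cat(sprintf("<gene_circuit%s: %d genes (%s); %d maternal inputs (%s)>\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              length(x$genes), paste(x$genes, collapse = ", "),
              length(x$maternal),
              if (length(x$maternal)) paste(x$maternal, collapse = ", ") else "none"))
  cat("  R:      ", paste(signif(x$R, 4), collapse = " "), "\n")
  cat("  lambda: ", paste(signif(x$lambda, 4), collapse = " "), "\n")
  cat("  h:      ", paste(signif(x$h, 4), collapse = " "), "\n")
  cat("  W (rows = regulators, cols = targets):\n")
  print(signif(x$W, 4))
  if (length(x$maternal)) {
    cat("  E (rows = maternal regulators, cols = targets):\n")
    print(signif(x$E, 4))
  }
  invisible(x)
}

#' @exportS3Method base::all.equal
all.equal.gene_circuit <- function(target, current, ...) {
  all.equal(unclass(target)[c("genes", "maternal", "R", "lambda", "h", "W", "E")],
            unclass(current)[c("genes", "maternal", "R", "lambda", "h", "W", "E")],
            ...)
}

#' Sigmoid regulation-expression function
#'
#' Maps total regulatory input `u` to fractional promoter activity
#' `phi(u) = (u / sqrt(u^2 + 1) + 1) / 2`. Strictly increasing, with open
#' range (0, 1), `phi(0) = 1/2`, and odd symmetry about 1/2:
#' `phi(-u) = 1 - phi(u)`.
#'
#' @param u numeric vector of dimensionless regulatory inputs (finite).
#' @return Activation values in (0, 1), same shape as `u`.
#' @examples
#' regulation_expression(c(-1, 0, 1))
#' @export
regulation_expression <- function(u) {
  if (!is.numeric(u) || any(!is.finite(u)))
    stop("regulatory input `u` must be finite numeric")
  0.5 * (u / sqrt(u^2 + 1) + 1)
}

#' Derivative of the regulation-expression function
#'
#' `phi'(u) = 1 / (2 (u^2 + 1)^(3/2))`; used for analytic Jacobians.
#'
#' @inheritParams regulation_expression
#' @return Derivative values, same shape as `u`. `phi'(0) = 1/2`.
#' @export
regulation_expression_deriv <- function(u) {
  if (!is.numeric(u) || any(!is.finite(u)))
    stop("regulatory input `u` must be finite numeric")
  0.5 / (u^2 + 1)^1.5
}

#' Total regulatory input for target genes
#'
#' Computes `u_a = sum_b W[b, a] g_b + sum_m E[m, a] g_m + h_a` for one or
#' more target genes.
#'
#' @param state named (or circuit-ordered) numeric vector of gap protein
#'   concentrations, one per circuit gene.
#' @param maternal_values numeric vector of maternal regulator concentrations,
#'   one per circuit maternal input.
#' @param circuit a [gene_circuit()].
#' @param target gene identifier(s); defaults to all circuit genes.
#' @return Named numeric vector of total inputs, one per target.
#' @export
total_input <- function(state, maternal_values, circuit, target = circuit$genes) {
  stopifnot(inherits(circuit, "gene_circuit"))
  state <- align_vec(state, circuit$genes, "state")
  maternal_values <- align_vec(maternal_values, circuit$maternal, "maternal_values")
  miss <- setdiff(target, circuit$genes)
  if (length(miss))
    stop("unknown target gene(s): ", paste(miss, collapse = ", "))
  u <- drop(state %*% circuit$W[, target, drop = FALSE]) +
    (if (length(circuit$maternal))
       drop(maternal_values %*% circuit$E[, target, drop = FALSE]) else 0) +
    circuit$h[target]
  setNames(as.numeric(u), target)
}

align_vec <- function(x, nms, what) {
  if (length(x) != length(nms))
    stop(sprintf("`%s` has length %d but the circuit expects %d entries",
                 what, length(x), length(nms)))
  if (!is.null(names(x))) {
    if (!setequal(names(x), nms))
      stop(sprintf("names of `%s` do not match the circuit (%s)",
                   what, paste(nms, collapse = ", ")))
    x <- x[nms]
  }
  as.numeric(x)
}

#' Right-hand side of the circuit ODEs
#'
#' Evaluates the rate of change of gap protein concentrations at time `t` for
#' a single nucleus: `R_a phi(u_a) - lambda_a g_a` during interphase and
#' `-lambda_a g_a` during mitosis (production shut off).
#'
#' This is the plain R reference implementation of the model field; the
#' simulation functions use an equivalent compiled path.
#'
#' @param t time in minutes.
#' @param state gap protein concentrations (one per circuit gene).
#' @param circuit a [gene_circuit()].
#' @param maternal a [maternal_profiles()] object, or `NULL` when the circuit
#'   has no maternal inputs.
#' @param position nucleus position, percent A-P axis.
#' @param phase `"interphase"` or `"mitosis"`.
#' @return Named numeric vector of derivatives, concentration/min.
#' @export
circuit_derivatives <- function(t, state, circuit, maternal = NULL,
                                position = NA_real_,
                                phase = c("interphase", "mitosis")) {
  phase <- match.arg(phase)
  state <- align_vec(state, circuit$genes, "state")
  mval <- if (length(circuit$maternal)) {
    if (is.null(maternal)) stop("circuit has maternal inputs but `maternal` is NULL")
    interpolate_maternal(maternal, position, t, genes = circuit$maternal)
  } else numeric()
  u <- total_input(state, mval, circuit)
  prod <- if (phase == "interphase") circuit$R * regulation_expression(u) else 0
  setNames(prod - circuit$lambda * state, circuit$genes)
}
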