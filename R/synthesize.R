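#' Generate synthetic maternal gradients
#'
#' Builds smooth stand-ins for the two maternal morphogen gradients over the
#' trunk region (35-75% A-P) and the full C13 + C14A time span: a Bcd-like
#' profile decaying exponentially from the anterior
#' (`A exp(-(x - 35) / length_scale)`), and a Cad-like logistic profile
#' rising towards the posterior. Both are modulated mildly and smoothly over
#' time (Bcd decaying, Cad rising), emulating the qualitative behaviour of
#' the measured gradients without claiming the real data. The seed perturbs
#' the amplitudes slightly so distinct seeds give distinct (but equally
#' realistic) gradient sets.
#'
#' @param anterior_peak Bcd-like concentration at 35% A-P, a.u. (> 0).
#' @param length_scale exponential decay length of the Bcd-like profile, in
#'   percent A-P (> 0).
#' @param posterior_plateau Cad-like posterior plateau concentration, a.u.
#'   (> 0).
#' @param time_modulation fractional amplitude change across the full time
#'   span (Bcd decreases, Cad increases by this fraction).
#' @param seed integer seed for the amplitude jitter.
#' @param schedule a [stage_schedule()] whose span the gradients must cover.
#' @param positions position knots, percent A-P.
#' @return A [maternal_profiles()] object with genes `Bcd` and `Cad`.
#' @export
generate_synthetic_gradients <- function(anterior_peak = 60, length_scale = 15,
                                         posterior_plateau = 110,
                                         time_modulation = 0.15, seed = 1,
                                         schedule = stage_schedule(),
                                         positions = c14a_positions()) {
  if (anterior_peak <= 0 || length_scale <= 0 || posterior_plateau <= 0)
    stop("`anterior_peak`, `length_scale` and `posterior_plateau` must be > 0")
  if (time_modulation < 0 || time_modulation >= 1)
    stop("`time_modulation` must be in [0, 1)")
  jit <- with_seed(seed, runif(2, min = 0.95, max = 1.05))
  A <- anterior_peak * jit[1]
  P <- posterior_plateau * jit[2]
  times <- sort(unique(c(schedule$span, schedule$phases$end,
                         schedule$class_bounds, schedule$class_midpoints)))
  frac <- (times - times[1]) / (times[length(times)] - times[1])
  x <- as.numeric(positions)
  bcd_space <- A * exp(-(x - 35) / length_scale)
  cad_space <- P / (1 + exp(-(x - 45) / 6))
  vals <- array(NA_real_, c(length(x), length(times), 2L))
  for (j in seq_along(times)) {
    vals[, j, 1] <- bcd_space * (1 - time_modulation * frac[j])
    vals[, j, 2] <- cad_space * (1 - time_modulation * (1 - frac[j]))
  }
  maternal_profiles(vals, positions = x, times = times, genes = c("Bcd", "Cad"))
}

#' Generate a seeded ground-truth circuit
#'
#' Draws a biologically structured random circuit for use as simulation
#' ground truth. The `"full"` archetype has the four trunk gap genes
#' (`hb`, `Kr`, `kni`, `gt`) with strong mutual repression between the
#' non-adjacent pairs (hb, kni) and (Kr, gt) (the "alternating cushions"
#' positive feedback), weaker asymmetric repression between genes with
#' adjacent/overlapping domains, positive auto-activation, and maternal
#' activation patterned so that hb/Kr respond to the anterior (Bcd-like)
#' gradient and kni/gt to the posterior (Cad-like) gradient. The `"acdc"`
#' archetype has three genes combining one strong double-negative (positive
#' feedback) pair with a weak three-gene repression cycle.
#'
#' Magnitudes are drawn from fixed ranges under the given seed, so the same
#' seed always returns the same circuit.
#'
#' @param archetype `"full"` (4 genes) or `"acdc"` (3 genes).
#' @param seed integer seed.
#' @return A [gene_circuit()].
#' @export
generate_ground_truth_circuit <- function(archetype = c("full", "acdc"),
                                          seed = 1) {
  archetype <- match.arg(archetype)
  with_seed(seed, {
    if (archetype == "full") {
      genes <- c("hb", "Kr", "kni", "gt")
      mats <- c("Bcd", "Cad")
      R <- runif(4, 10, 16)
      lambda <- runif(4, 0.055, 0.085)
      h <- runif(4, -3.5, -2.5)
      W <- matrix(0, 4, 4, dimnames = list(genes, genes))
      strong <- function() -runif(1, 0.025, 0.045)
      weak <- function() -runif(1, 0.0015, 0.004)
      faint <- function() -runif(1, 0, 0.0008)
      # alternating-cushions double-negative pairs
      W["hb", "kni"] <- strong(); W["kni", "hb"] <- strong()
      W["Kr", "gt"] <- strong(); W["gt", "Kr"] <- strong()
      # asymmetric repression between overlapping neighbours
      W["Kr", "hb"] <- faint()   # near zero, as in the anterior trunk
      W["kni", "Kr"] <- weak()
      W["gt", "kni"] <- weak()
      W["hb", "gt"] <- weak()
      # reverse directions fainter still
      W["Kr", "kni"] <- faint()
      W["kni", "gt"] <- faint(); W["gt", "hb"] <- faint()
      # Hb represses Kr at high concentration: sets Kr's anterior boundary,
      # giving Kr its central domain
      W["hb", "Kr"] <- -runif(1, 0.015, 0.020)
      diag(W) <- runif(4, 0.005, 0.015)  # auto-activation
      E <- matrix(0, 2, 4, dimnames = list(mats, genes))
      # activation is deliberately broad (Kr reaches into the posterior via
      # Cad, gt into the anterior via Bcd) so that the staggered domain
      # arrangement is carved out by gap-gap cross-repression, not by the
      # maternal inputs alone
      E["Bcd", "hb"] <- runif(1, 0.095, 0.110)
      E["Bcd", "Kr"] <- runif(1, 0.10, 0.13)
      E["Bcd", "gt"] <- runif(1, 0.020, 0.030)
      E["Cad", "kni"] <- runif(1, 0.030, 0.045)
      E["Bcd", "kni"] <- runif(1, 0.025, 0.040)
      E["Cad", "gt"] <- runif(1, 0.025, 0.040)
      E["Cad", "Kr"] <- runif(1, 0.016, 0.026)
      gene_circuit(genes, mats, R, lambda, h, W, E,
                   id = sprintf("synthetic-full-seed%d", as.integer(seed)))
    } else {
      genes <- c("g1", "g2", "g3")
      mats <- c("Bcd", "Cad")
      R <- runif(3, 10, 16)
      lambda <- runif(3, 0.055, 0.085)
      h <- runif(3, -3.2, -2.4)
      W <- matrix(0, 3, 3, dimnames = list(genes, genes))
      # strong double-negative (positive feedback) pair g1 <-> g3
      W["g1", "g3"] <- -runif(1, 0.025, 0.045)
      W["g3", "g1"] <- -runif(1, 0.025, 0.045)
      # three-gene negative cycle g1 -| g2 -| g3 -| g1; the g3 -| g1 edge is
      # the strong one shared with the double-negative pair, the others weak
      W["g1", "g2"] <- -runif(1, 0.0015, 0.004)
      W["g2", "g3"] <- -runif(1, 0.0015, 0.004)
      diag(W) <- runif(3, 0.005, 0.015)
      E <- matrix(0, 2, 3, dimnames = list(mats, genes))
      E["Bcd", "g1"] <- runif(1, 0.10, 0.16)
      E["Bcd", "g2"] <- runif(1, 0.04, 0.08)
      E["Cad", "g2"] <- runif(1, 0.000, 0.008)
      E["Cad", "g3"] <- runif(1, 0.030, 0.045)
      gene_circuit(genes, mats, R, lambda, h, W, E,
                   id = sprintf("synthetic-acdc-seed%d", as.integer(seed)))
    }
  })
}

#' Generate a synthetic expression dataset from a known circuit
#'
#' Simulates `circuit` over the schedule for every C14A nucleus (starting
#' from zero concentrations at the schedule start), samples the trajectories
#' at the T1-T8 class midpoints, and adds independent zero-mean Gaussian
#' noise truncated at zero. With `noise_sd = 0` the dataset equals the
#' simulation samples exactly. The generation seed is recorded in the
#' result's attributes.
#'
#' @param circuit a [gene_circuit()] (the ground truth).
#' @param gradients a [maternal_profiles()] object.
#' @param noise_sd standard deviation of the additive noise, a.u. (`>= 0`).
#' @param seed integer seed for the noise.
#' @param schedule a [stage_schedule()].
#' @param positions C14A nucleus positions to sample.
#' @return An `expression_dataset`: a data frame with columns `position`,
#'   `time_class`, `gene`, `concentration`, `weight`, plus attributes
#'   `provenance` (`"synthetic"`), `seed`, and `noise_sd`.
#' @export
generate_synthetic_dataset <- function(circuit, gradients, noise_sd = 0,
                                       seed = 1, schedule = stage_schedule(),
                                       positions = c14a_positions()) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  clean <- simulate_expression(circuit, gradients, schedule, positions)
  noisy <- if (noise_sd > 0) {
    noise <- with_seed(seed, rnorm(nrow(clean), mean = 0, sd = noise_sd))
    pmax(0, clean$concentration + noise)
  } else clean$concentration
  out <- clean
  out$concentration <- noisy
  out$weight <- 1
  expression_dataset(out, provenance = "synthetic", seed = seed,
                     noise_sd = noise_sd)
}

#' Noise-free model output in dataset form
#'
#' Simulates the circuit over the schedule and returns its T1-T8 class
#' midpoint samples for each nucleus as a long table keyed like an
#' [expression_dataset()] (used both by the synthetic-data generator and as
#' the model side of the fitting objective).
#'
#' @inheritParams generate_synthetic_dataset
#' @param initial_states optional matrix of start-of-schedule concentrations
#'   (rows = nuclei on the schedule's starting lattice); zeros by default.
#' @param rtol,atol solver tolerances.
#' @return Data frame with columns `position`, `time_class`, `gene`,
#'   `concentration`.
#' @export
simulate_expression <- function(circuit, gradients,
                                schedule = stage_schedule(),
                                positions = c14a_positions(),
                                initial_states = NULL, rtol = 1e-8,
                                atol = 1e-10) {
  divides <- !is.na(schedule$division_time)
  row_pos <- if (divides) c13_positions() else positions
  if (is.null(initial_states))
    initial_states <- matrix(0, length(row_pos), length(circuit$genes))
  mids <- time_class_midpoints(schedule)
  trajs <- simulate_row(circuit, gradients, row_pos, initial_states, schedule,
                        output_times = mids, rtol = rtol, atol = atol)
  if (divides)
    trajs <- trajs[as.character(positions)]
  do.call(rbind, lapply(trajs, function(tr) {
    df <- as.data.frame(tr)
    df[, c("position", "time_class", "gene", "concentration")]
  })) -> out
  rownames(out) <- NULL
  out
}

#' Expression dataset container
#'
#' Validates and tags a long table of expression records: one record per
#' (position, time class, gene), concentrations `>= 0`, optional per-record
#' weight (defaulting to 1) used by the weighted RMS objective.
#'
#' @param df data frame with columns `position`, `time_class`, `gene`,
#'   `concentration` (and optionally `weight`).
#' @param provenance `"synthetic"` or `"measured"`.
#' @param seed generation seed (or `NA`).
#' @param noise_sd noise level used at generation (or `NA`).
#' @return The data frame with class `expression_dataset` and provenance
#'   attributes.
#' @export
expression_dataset <- function(df, provenance = c("synthetic", "measured"),
                               seed = NA, noise_sd = NA) {
  provenance <- match.arg(provenance)
  need <- c("position", "time_class", "gene", "concentration")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("expression dataset lacks column(s): ", paste(miss, collapse = ", "))
  if (!"weight" %in% names(df)) df$weight <- 1
  if (any(!is.finite(df$concentration)) || any(df$concentration < 0))
    stop("concentrations must be finite and >= 0")
  key <- paste(df$position, df$time_class, df$gene)
  if (anyDuplicated(key))
    stop("duplicate (position, time_class, gene) record(s): ",
         paste(utils::head(key[duplicated(key)], 3), collapse = "; "))
  structure(df, class = c("expression_dataset", class(df)),
            provenance = provenance, seed = seed, noise_sd = noise_sd)
}
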