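#' Simulate a one-step growth experiment
#'
#' The noise-free titer follows a plateau at `titer0` before the latent
#' period and a logistic (sigmoid) rise to `beta * titer0` afterwards:
#' `f(t) = titer0 * (1 + (beta - 1) / (1 + exp(-(t - tau_latent)/rise_sd)))`.
#' Observed titers are triplicate plaque counts drawn as
#' `Poisson(f(t)/dilution_factor) * dilution_factor`, emulating counting
#' 30-300 plaques on a diluted plate.
#'
#' @param beta Burst size, `>= 1`.
#' @param tau_latent Latent period (min); default 30.
#' @param titer0 Initial free-phage titer (pfu/ml), `> 0`.
#' @param sample_times Sampling times (min); default the classic schedule of
#'   5-min intervals to 30 min then 10-min intervals to 120 min.
#' @param dilution_factor Plated dilution: expected plaque count is
#'   `titer/dilution_factor`.
#' @param rise_sd Steepness of the logistic rise (min); default 1.
#' @param noise Draw Poisson counts (`TRUE`) or return the noise-free curve
#'   in every replicate (`FALSE`).
#' @param n_reps Replicates; default 3 (triplicate).
#' @param seed Integer seed.
#' @return A `one_step_data` object; see [one_step_data()].
#' @export
simulate_one_step <- function(beta = 39, tau_latent = 30, titer0 = 1e4,
                              sample_times = c(seq(0, 30, by = 5),
                                               seq(40, 120, by = 10)),
                              dilution_factor = 100, rise_sd = 1,
                              noise = TRUE, n_reps = 3L, seed = 1L) {
  if (beta < 1) stop("'beta' must be >= 1", call. = FALSE)
  check_pos(titer0, "titer0")
  if (!length(sample_times)) stop("empty 'sample_times'", call. = FALSE)
  check_pos(dilution_factor, "dilution_factor")
  f <- titer0 * (1 + (beta - 1) / (1 + exp(-(sample_times - tau_latent) / rise_sd)))
  set.seed(as.integer(seed))
  titers <- sapply(seq_len(n_reps), function(rep) {
    if (noise) stats::rpois(length(f), f / dilution_factor) * dilution_factor
    else f
  })
  one_step_data(times = sample_times,
                titers = matrix(titers, ncol = n_reps),
                dilution_factor = dilution_factor, moi_nominal = 0.01)
}

#' Timed plaque-titer table of a one-step growth experiment
#'
#' @param times Sampling times (min), increasing.
#' @param titers Matrix of titers (pfu/ml), rows = times, cols = replicates.
#' @param dilution_factor Dilution applied before plating.
#' @param moi_nominal Nominal multiplicity of infection of the assay.
#' @return An object of class `"one_step_data"`.
#' @export
one_step_data <- function(times, titers, dilution_factor = 1,
                          moi_nominal = NA_real_) {
  titers <- as.matrix(titers)
  if (length(times) != nrow(titers))
    stop("'times' and rows of 'titers' must match", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (any(titers < 0)) stop("titers must be >= 0", call. = FALSE)
  structure(list(times = times, titers = titers,
                 dilution_factor = dilution_factor,
                 moi_nominal = moi_nominal),
            class = "one_step_data")
}

#' Simulate a phage adsorption assay
#'
#' Free phage decay exponentially when mixed with host cells:
#' `p(t) = p0 * exp(-k * cell_density * t)`.  Observed free titers are
#' duplicate Poisson plaque counts as in [simulate_one_step()].
#'
#' Defaults reproduce an assay in which more than 99% of particles adsorb
#' by 12 minutes at a host density of 1e7 cfu/ml (`k * cell_density =
#' ln(100)/12` per min).
#'
#' @param k Adsorption rate constant (ml/min per cell); the effective
#'   first-order decay rate is `k * cell_density`.
#' @param cell_density Host density (cfu/ml).
#' @param p0 Initial free titer (pfu/ml), `> 0`.
#' @param times Sampling times (min); default every 3 min to 15 min.
#' @param dilution_factor Plated dilution for counts.
#' @param noise Poisson counts or noise-free.
#' @param n_reps Replicates; default 2 (duplicate).
#' @param seed Integer seed.
#' @return An `adsorption_data` object; see [adsorption_data()].
#' @export
simulate_adsorption <- function(k = log(100) / 12 / 1e7, cell_density = 1e7,
                                p0 = 1e6, times = seq(0, 15, by = 3),
                                dilution_factor = 200, noise = TRUE,
                                n_reps = 2L, seed = 1L) {
  check_nonneg(k, "k"); check_pos(p0, "p0"); check_pos(cell_density, "cell_density")
  if (!length(times)) stop("empty 'times'", call. = FALSE)
  f <- p0 * exp(-k * cell_density * times)
  set.seed(as.integer(seed))
  titers <- sapply(seq_len(n_reps), function(rep) {
    if (noise) stats::rpois(length(f), f / dilution_factor) * dilution_factor
    else f
  })
  adsorption_data(times = times, free_titers = matrix(titers, ncol = n_reps),
                  cell_density = cell_density, p0 = p0)
}

#' Timed free-phage titer table of an adsorption assay
#'
#' @param times Sampling times (min), increasing.
#' @param free_titers Matrix of free titers (pfu/ml), rows = times,
#'   cols = replicates.
#' @param cell_density Host density (cfu/ml).
#' @param p0 Initial titer (pfu/ml).
#' @return An object of class `"adsorption_data"`.
#' @export
adsorption_data <- function(times, free_titers, cell_density, p0) {
  free_titers <- as.matrix(free_titers)
  if (length(times) != nrow(free_titers))
    stop("'times' and rows of 'free_titers' must match", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (any(free_titers < 0)) stop("titers must be >= 0", call. = FALSE)
  check_pos(p0, "p0")
  structure(list(times = times, free_titers = free_titers,
                 cell_density = cell_density, p0 = p0),
            class = "adsorption_data")
}
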