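#' Simulate plate-reader OD590 growth/kill curves
#'
#' Integrates a deterministic bacteria-phage-antibiotic model for each
#' treatment arm and overlays multiplicative plate-reader noise per
#' replicate.  Compartments per ml: susceptible cells S, m sequential
#' infected stages I1..Im (Erlang-distributed latent period with mean
#' `tau`), phage-resistant cells R, and free phage P; two bookkeeping
#' integrals track cumulative lysed cells and adsorbed phage.
#'
#' Dynamics: logistic growth `g = r (1 - N/K)` of S and R (infected cells do
#' not divide but occupy the niche, `N = S + sum(I) + R`); a fraction `mu` of
#' S divisions yields phage-resistant daughters; mass-action adsorption
#' `delta * S * P` moves cells into stage I1; stage transit at rate `m/tau`;
#' lysis of the last stage releases `beta` phage each; antibiotic kill per
#' [antibiotic_model()] (in `"dividing"` mode the rate is scaled by
#' `max(g, 0)/r` and applies to S and R; in `"all"` mode the full rate
#' applies to S, R and every infected stage).  Observed
#' `OD = alpha * N + od0`, each replicate reading multiplied by
#' `(1 + sigma * z)` with standard normal z.
#'
#' Integration is a deterministic fixed-step classical Runge-Kutta (RK4)
#' with `substeps` internal steps per output interval.
#'
#' @param params A [growth_kill_params()].
#' @param treatments A list of [treatment()] arms.
#' @param duration Assay horizon (h); default 16.
#' @param dt Output grid spacing (h); default 1/3 (20 min). `duration/dt`
#'   must be integral.
#' @param n_reps Replicates per arm; default 3.
#' @param seed Integer seed for the observation noise.
#' @param substeps Internal RK4 steps per output interval; default 100 (12-s
#'   steps on the standard 20-min grid), enough to keep the fast adsorption
#'   dynamics of the phage-crash phase stable.
#' @return A list of `od_series` objects (one per treatment x replicate),
#'   each carrying its noise-free trajectory in attribute `"deterministic"`
#'   and the final model state in attribute `"state"`.
#' @seealso [od_series()], [growth_kill_trajectory()]
#' @export
simulate_growth_kill <- function(params, treatments, duration = 16,
                                 dt = 1 / 3, n_reps = 3L, seed = 1L,
                                 substeps = 100L) {
  stopifnot(inherits(params, "growth_kill_params"))
  if (inherits(treatments, "treatment")) treatments <- list(treatments)
  stopifnot(length(treatments) >= 1L)
  check_pos(dt, "dt")
  n_int <- duration / dt
  if (abs(n_int - round(n_int)) > 1e-9)
    stop("'duration' must be an integer multiple of 'dt'", call. = FALSE)
  if (n_reps < 1) stop("'n_reps' must be >= 1", call. = FALSE)

  out <- list()
  set.seed(as.integer(seed))
  for (tr in treatments) {
    traj <- growth_kill_trajectory(params, tr, duration, dt, substeps)
    od_det <- params$alpha * traj$cells + params$od0
    for (rep in seq_len(n_reps)) {
      noise <- 1 + params$sigma * stats::rnorm(length(od_det))
      od <- pmax(od_det * noise, 0)
      s <- od_series(times = traj$times, od = od, treatment = tr,
                     replicate = rep)
      attr(s, "deterministic") <- od_det
      attr(s, "state") <- traj$state
      out[[length(out) + 1L]] <- s
    }
  }
  out
}

#' Deterministic trajectory of the growth/kill model for one treatment
#'
#' The noise-free backbone used by [simulate_growth_kill()]; exposed for
#' model inspection and for integrator cross-checks.
#'
#' @inheritParams simulate_growth_kill
#' @param tr A single [treatment()].
#' @return A list with `times` (h), `cells` (total cell density per ml at
#'   each output time), `od` left to the caller, and `state`: the full final
#'   state vector including cumulative `lysed` and `adsorbed` tallies.
#' @export
growth_kill_trajectory <- function(params, tr, duration = 16, dt = 1 / 3,
                                   substeps = 100L) {
  stopifnot(inherits(params, "growth_kill_params"), inherits(tr, "treatment"))
  m <- params$m
  kill <- 0; mode <- "dividing"
  if (tr$antibiotic != "none") {
    model <- params$antibiotics[[tr$antibiotic]]
    if (is.null(model))
      stop(sprintf("no antibiotic model named '%s' in params", tr$antibiotic),
           call. = FALSE)
    kill <- antibiotic_kill_rate(model, tr$concentration)
    mode <- model$mode
  }
  state <- c(S = params$n0, I = rep(0, m), R = 0, P = tr$moi * params$n0,
             L = 0, A = 0)
  n_out <- round(duration / dt)
  times <- seq(0, duration, by = dt)
  cells <- numeric(n_out + 1L)
  cells[1L] <- total_cells(state, m)

  h <- dt / substeps
  for (i in seq_len(n_out)) {
    for (j in seq_len(substeps)) {
      state <- rk4_step(state, h, params, kill, mode, m)
      # densities cannot go negative; clamp integrator undershoot
      state[state < 0] <- 0
    }
    cells[i + 1L] <- total_cells(state, m)
  }
  list(times = times, cells = cells, state = state)
}

total_cells <- function(state, m) {
  unname(state[["S"]] + sum(state[2:(m + 1L)]) + state[["R"]])
}

#' Right-hand side of the growth/kill ODE system
#'
#' Exposed so an external integrator can be run on the identical vector
#' field (e.g. a fine-step reference solution).
#'
#' @param state Named state vector `c(S, I1..Im, R, P, L, A)`.
#' @param params A [growth_kill_params()].
#' @param kill Antibiotic kill rate a(c) (1/h) already evaluated at the
#'   arm's concentration.
#' @param mode `"dividing"` or `"all"`.
#' @return The derivative vector, same layout as `state`.
#' @export
growth_kill_deriv <- function(state, params, kill, mode) {
  m <- params$m
  S <- state[1L]; I <- state[2:(m + 1L)]; R <- state[m + 2L]; P <- state[m + 3L]
  N <- S + sum(I) + R
  g <- params$r * (1 - N / params$K)
  gpos <- max(g, 0)
  # antibiotic per-capita rates by compartment
  if (mode == "dividing") {
    kSR <- kill * gpos / params$r
    kI <- 0
  } else {
    kSR <- kill
    kI <- kill
  }
  ads <- params$delta * S * P
  transit <- params$m / params$tau
  dS <- g * S - params$mu * gpos * S - ads - kSR * S
  dI <- numeric(m)
  dI[1L] <- ads - transit * I[1L] - kI * I[1L]
  if (m > 1L)
    for (j in 2:m) dI[j] <- transit * (I[j - 1L] - I[j]) - kI * I[j]
  lysis <- transit * I[m]
  dR <- g * R + params$mu * gpos * S - kSR * R
  dP <- params$beta * lysis - ads
  c(dS, dI, dR, dP, lysis, ads)
}

rk4_step <- function(state, h, params, kill, mode, m) {
  k1 <- growth_kill_deriv(state, params, kill, mode)
  k2 <- growth_kill_deriv(state + h / 2 * k1, params, kill, mode)
  k3 <- growth_kill_deriv(state + h / 2 * k2, params, kill, mode)
  k4 <- growth_kill_deriv(state + h * k3, params, kill, mode)
  state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}
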