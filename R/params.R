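#' Antibiotic pharmacodynamic model
#'
#' Hill-type concentration-dependent kill used by [simulate_growth_kill()].
#' The per-capita kill rate at concentration `c` is
#' `a(c) = emax * c^hill / (ec50^hill + c^hill)`.
#'
#' Two mechanistic modes are supported. In `"dividing"` mode (a
#' carbapenem/fluoroquinolone-like drug) the kill rate is additionally scaled
#' by the current per-capita division rate relative to `r`, so only actively
#' dividing cells are killed: a culture at carrying capacity is untouched,
#' while a sparse, exponentially growing subpopulation feels the full rate.
#' In `"all"` mode (a colistin-like membrane-active drug) `a(c)` applies to
#' every cell compartment, dividing or not.
#'
#' @param emax Maximal kill rate (1/h), `>= 0`.
#' @param ec50 Concentration of half-maximal kill (mg/l), `> 0`.
#' @param hill Hill exponent (dimensionless), `> 0`.
#' @param mode `"dividing"` or `"all"`.
#' @return An object of class `"antibiotic_model"`.
#' @export
antibiotic_model <- function(emax = 1.25, ec50 = 32, hill = 2,
                             mode = c("dividing", "all")) {
  mode <- match.arg(mode)
  check_nonneg(emax, "emax")
  check_pos(ec50, "ec50")
  check_pos(hill, "hill")
  structure(list(emax = emax, ec50 = ec50, hill = hill, mode = mode),
            class = "antibiotic_model")
}

#' Per-capita antibiotic kill rate at a concentration
#'
#' @param model An [antibiotic_model()].
#' @param conc Concentration (mg/l), `>= 0`.
#' @return Kill rate (1/h).
#' @export
antibiotic_kill_rate <- function(model, conc) {
  stopifnot(inherits(model, "antibiotic_model"))
  check_nonneg(conc, "concentration")
  if (conc == 0) return(0)
  model$emax * conc^model$hill / (model$ec50^model$hill + conc^model$hill)
}

default_antibiotics <- function() {
  list(
    # ec50 values anchored at MICs typical of a carbapenemase-producing
    # A. baumannii isolate: meropenem >= 32, ciprofloxacin 0.09, colistin
    # 2 mg/l.  emax below the intrinsic growth rate keeps single-drug arms
    # growth-slowing rather than sterilizing.
    meropenem     = antibiotic_model(emax = 1.25, ec50 = 32,   hill = 2, mode = "dividing"),
    ciprofloxacin = antibiotic_model(emax = 1.0,  ec50 = 0.09, hill = 1, mode = "dividing"),
    colistin      = antibiotic_model(emax = 1.2,  ec50 = 2,    hill = 2, mode = "all")
  )
}

#' Parameters of the bacteria-phage-antibiotic growth/kill model
#'
#' Container for the mechanistic model behind [simulate_growth_kill()]:
#' logistic bacterial growth, mass-action phage adsorption, Erlang-staged
#' (m sequential infected compartments) lysis releasing `beta` progeny,
#' Hill-type antibiotic kill, and emergence of a phage-resistant
#' subpopulation at division.
#'
#' @param r Intrinsic growth rate (1/h).
#' @param K Carrying capacity (cells/ml).
#' @param delta Phage adsorption rate constant (ml/h per phage).
#' @param beta Burst size (phage released per lysed cell), `>= 1`.
#' @param tau Latent period (h), realized as `m` sequential infected stages.
#' @param m Number of Erlang stages, integer `>= 1`.
#' @param mu Per-division phage-resistance mutation probability in `[0, 1]`.
#' @param alpha OD590 per cell (OD·ml/cell).
#' @param od0 Background OD offset.
#' @param n0 Inoculum density (cells/ml) at t = 0.
#' @param sigma Multiplicative plate-reader noise s.d. on OD per reading.
#' @param antibiotics Named list of [antibiotic_model()] objects; treatment
#'   antibiotic labels are looked up here.
#' @return An object of class `"growth_kill_params"`.
#' @export
growth_kill_params <- function(r = 1.4, K = 1e9, delta = 1e-8, beta = 39,
                               tau = 0.5, m = 5L, mu = 0, alpha = 5e-10,
                               od0 = 0.03, n0 = 2.5e8, sigma = 0.01,
                               antibiotics = default_antibiotics()) {
  check_pos(r, "r"); check_pos(K, "K"); check_nonneg(delta, "delta")
  if (!is.numeric(beta) || length(beta) != 1L || beta < 1)
    stop("'beta' must be a single number >= 1", call. = FALSE)
  check_pos(tau, "tau")
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m))
    stop("'m' must be a positive integer", call. = FALSE)
  if (!is.numeric(mu) || length(mu) != 1L || mu < 0 || mu > 1)
    stop("'mu' must be a probability in [0, 1]", call. = FALSE)
  check_pos(alpha, "alpha"); check_nonneg(od0, "od0")
  check_pos(n0, "n0"); check_nonneg(sigma, "sigma")
  stopifnot(is.list(antibiotics))
  structure(list(r = r, K = K, delta = delta, beta = beta, tau = tau,
                 m = as.integer(m), mu = mu, alpha = alpha, od0 = od0,
                 n0 = n0, sigma = sigma, antibiotics = antibiotics),
            class = "growth_kill_params")
}

#' Treatment arm of a liquid infection assay
#'
#' @param strain_id Strain label (e.g. `"AB01"`).
#' @param moi Phage input multiplicity (pfu per cfu); 0 means no phage.
#' @param antibiotic Antibiotic label, or `"none"`.
#' @param concentration Antibiotic concentration (mg/l); 0 means none.
#'   `antibiotic = "none"` and `concentration = 0` must agree.
#' @return An object of class `"treatment"`.
#' @export
treatment <- function(strain_id = "AB01", moi = 0, antibiotic = "none",
                      concentration = 0) {
  check_nonneg(moi, "moi")
  check_nonneg(concentration, "concentration")
  if ((antibiotic == "none") != (concentration == 0))
    stop("antibiotic 'none' if and only if concentration is 0", call. = FALSE)
  structure(list(strain_id = strain_id, moi = moi, antibiotic = antibiotic,
                 concentration = concentration),
            class = "treatment")
}

#' A short unique label for a treatment arm
#' @param x A [treatment()].
#' @return Character scalar like `"AB01|moi=0.1|meropenem=32"`.
#' @export
treatment_label <- function(x) {
  stopifnot(inherits(x, "treatment"))
  sprintf("%s|moi=%g|%s=%g", x$strain_id, x$moi, x$antibiotic, x$concentration)
}

#' @export
print.treatment <- function(x, ...) {
  cat("<treatment>", treatment_label(x), "\n")
  invisible(x)
}

#' Parameters of the pan-genome evolution generator
#'
#' Describes tree-structured gene gain/loss across a small set of phage
#' genomes: a fixed count of single-copy core families inherited by every
#' genome, accessory families gained and lost along branches of a guide
#' tree, and private singleton families per genome.  Protein sequences
#' evolve by i.i.d. per-site substitution (no indels) over the 20-letter
#' amino-acid alphabet.
#'
#' Defaults emulate a six-genome T4-like phage cluster: 111 single-copy
#' core families, per-genome singleton means and accessory gain rates chosen
#' so the expected pan-genome totals about 650-660 distinct families.
#'
#' @param guide_tree True topology, an `ape` "phylo" object whose tip labels
#'   are the genome ids; `NULL` uses [default_guide_tree()].
#' @param n_core Number of single-copy core families, `>= 1`.
#' @param gain_rate Expected accessory-family gains per branch (Poisson).
#' @param loss_rate Per-branch probability that an accessory family present
#'   at the parent is lost, in `[0, 1]`.
#' @param n_singletons_mean Expected private families per genome (Poisson).
#' @param prot_len Mean protein length (amino acids).
#' @param divergence Per-branch substitution probability per site in `[0, 1)`.
#' @param seed Integer seed.
#' @return An object of class `"gene_evolution_params"`.
#' @export
gene_evolution_params <- function(guide_tree = NULL, n_core = 111L,
                                  gain_rate = 16, loss_rate = 0.1,
                                  n_singletons_mean = 65, prot_len = 200,
                                  divergence = 0.1, seed = 1L) {
  if (is.null(guide_tree)) guide_tree <- default_guide_tree()
  stopifnot(inherits(guide_tree, "phylo"))
  if (!is.numeric(n_core) || n_core < 1 || n_core != round(n_core))
    stop("'n_core' must be a positive integer", call. = FALSE)
  check_nonneg(gain_rate, "gain_rate")
  if (loss_rate < 0 || loss_rate > 1)
    stop("'loss_rate' must be in [0, 1]", call. = FALSE)
  check_nonneg(n_singletons_mean, "n_singletons_mean")
  check_pos(prot_len, "prot_len")
  if (divergence < 0 || divergence >= 1)
    stop("'divergence' must be in [0, 1)", call. = FALSE)
  structure(list(guide_tree = guide_tree, n_core = as.integer(n_core),
                 gain_rate = gain_rate, loss_rate = loss_rate,
                 n_singletons_mean = n_singletons_mean, prot_len = prot_len,
                 divergence = divergence, seed = as.integer(seed)),
            class = "gene_evolution_params")
}

# -- shared argument checks ---------------------------------------------------

check_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop(sprintf("'%s' must be a single non-negative number", name), call. = FALSE)
  invisible(x)
}

#' Derive a child seed from a master seed
#'
#' Deterministic derivation used throughout the package so that partial
#' re-runs of a pipeline reproduce: `(seed * 48271 + index) mod (2^31 - 1)`.
#'
#' @param seed Master integer seed.
#' @param index Non-negative integer stream index.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(index)
  as.integer(s %% 2147483647)
}
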