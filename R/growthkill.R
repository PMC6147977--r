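#' One replicate's OD590 trajectory under one treatment
#'
#' @param times Time grid (h), uniform, starting at 0.
#' @param od OD590 readings, same length as `times`, finite and `>= 0`.
#' @param treatment A [treatment()].
#' @param replicate Replicate index.
#' @return An object of class `"od_series"`.
#' @export
od_series <- function(times, od, treatment = NULL, replicate = 1L) {
  if (length(times) < 1L) stop("empty time grid", call. = FALSE)
  if (length(od) != length(times))
    stop("'od' and 'times' must have the same length", call. = FALSE)
  if (any(!is.finite(od)) || any(od < 0))
    stop("'od' must be finite and >= 0", call. = FALSE)
  if (length(times) > 1L) {
    dts <- diff(times)
    if (any(dts <= 0)) stop("'times' must be strictly increasing", call. = FALSE)
    if (max(dts) - min(dts) > 1e-9)
      stop("'times' must be a uniform grid (to 1e-9)", call. = FALSE)
  }
  structure(list(times = times, od = od,
                 dt = if (length(times) > 1L) times[2L] - times[1L] else NA_real_,
                 treatment = treatment, replicate = as.integer(replicate)),
            class = "od_series")
}

#' @export
print.od_series <- function(x, ...) {
  lab <- if (is.null(x$treatment)) "?" else treatment_label(x$treatment)
  cat(sprintf("<od_series> %s rep %d: %d points, t in [%g, %g] h, end-OD %.3f\n",
              lab, x$replicate, length(x$times), min(x$times), max(x$times),
              x$od[length(x$od)]))
  invisible(x)
}

#' Area under an OD590 curve by the trapezoid rule
#'
#' Integrates the observed curve over its n-1 measured intervals:
#' `sum_i (f(t_i) + f(t_{i+1})) / 2 * dt`, with `dt` carried as an exact
#' rational (1/3 h for the standard 20-min assay, not its printed rounding).
#' The result summarizes average suppression over the assay (OD·h).
#'
#' @param series An [od_series()] with at least 2 points on a uniform grid.
#' @return AUC in OD·h.
#' @export
auc_trapezoid <- function(series) {
  stopifnot(inherits(series, "od_series"))
  n <- length(series$od)
  if (n < 2L) stop("need at least 2 points to integrate", call. = FALSE)
  f <- series$od
  sum((f[-n] + f[-1L]) / 2) * series$dt
}

#' OD590 at the final assay time point (end-OD)
#'
#' @param series An [od_series()].
#' @return The last reading.
#' @export
end_od <- function(series) {
  stopifnot(inherits(series, "od_series"))
  series$od[length(series$od)]
}

#' Significance stars for a p-value
#' @param p P-value in `[0, 1]`.
#' @return `"***"` (p < 0.001), `"**"` (p < 0.01), `"*"` (p < 0.05) or `""`.
#' @export
stars_from_p <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' One-tailed two-sample t-test for enhanced suppression
#'
#' Tests whether the treated arm's replicate metric values (end-OD or AUC)
#' are smaller in mean than the baseline arm's, i.e. whether the combination
#' suppresses growth more strongly than the comparator.  The Welch
#' (unequal-variance) statistic is the default; the pooled-variance Student
#' test is available via `var_equal = TRUE`.
#'
#' If both arms are exactly constant with equal means the statistic is
#' undefined; by convention `t = 0`, `p = 0.5` and the result is flagged
#' degenerate.
#'
#' @param treated Numeric vector of replicate metric values (>= 2).
#' @param baseline Numeric vector of replicate metric values (>= 2).
#' @param metric Label stored on the result (`"endOD"` or `"AUC"`).
#' @param var_equal Use the pooled-variance Student test instead of Welch.
#' @param combination,baseline_treatment Optional [treatment()] metadata.
#' @return An object of class `"synergy_test"`: list with `t_stat`,
#'   `p_one_sided`, `stars`, `direction` (`"suppression-enhanced"` when the
#'   treated mean is lower), `degenerate`, plus the metadata.
#' @export
one_tailed_ttest <- function(treated, baseline, metric = "endOD",
                             var_equal = FALSE, combination = NULL,
                             baseline_treatment = NULL) {
  if (length(treated) < 2L || length(baseline) < 2L)
    stop("need >= 2 replicates per arm", call. = FALSE)
  degenerate <- FALSE
  if (stats::sd(treated) == 0 && stats::sd(baseline) == 0) {
    degenerate <- TRUE
    if (isTRUE(all.equal(mean(treated), mean(baseline)))) {
      t_stat <- 0; p <- 0.5
    } else {
      t_stat <- if (mean(treated) < mean(baseline)) -Inf else Inf
      p <- if (t_stat < 0) 0 else 1
    }
  } else {
    tt <- stats::t.test(treated, baseline, alternative = "less",
                        var.equal = var_equal)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(list(metric = metric, t_stat = t_stat, p_one_sided = p,
                 stars = stars_from_p(p),
                 direction = if (mean(treated) < mean(baseline))
                   "suppression-enhanced" else "not-enhanced",
                 degenerate = degenerate,
                 combination = combination,
                 baseline = baseline_treatment),
            class = "synergy_test")
}

#' @export
print.synergy_test <- function(x, ...) {
  cat(sprintf("<synergy_test> %s: t = %.3f, one-sided p = %.4g %s (%s)\n",
              x$metric, x$t_stat, x$p_one_sided,
              if (nzchar(x$stars)) x$stars else "ns", x$direction))
  invisible(x)
}

#' Evaluate all phage+antibiotic combinations of an experiment
#'
#' Groups replicate OD series by treatment arm, computes end-OD and AUC per
#' replicate, and for every combination arm (moi > 0 and concentration > 0)
#' runs [one_tailed_ttest()] against a baseline chosen by `baseline_rule`:
#' \describe{
#'   \item{`"phage_alone"`}{the phage-only arm at the same MOI (the Fig-6
#'     style comparison);}
#'   \item{`"best_single"`}{whichever single-agent arm (phage alone at the
#'     same MOI, or antibiotic alone at the same concentration) has the
#'     lower mean of the metric under test (the "best acting antimicrobial
#'     alone" comparison).}
#' }
#' A combination whose baseline arm is missing is skipped with a warning.
#'
#' @param experiment List of [od_series()] (all arms, in replicate).
#' @param baseline_rule `"phage_alone"` or `"best_single"`.
#' @param metrics Which metrics to test; default both.
#' @param var_equal Passed to [one_tailed_ttest()].
#' @return A data.frame with one row per combination x metric: treatment
#'   descriptors, baseline label, per-arm means, `t`, `p_one_sided`, `stars`.
#' @export
evaluate_combinations <- function(experiment,
                                  baseline_rule = c("phage_alone", "best_single"),
                                  metrics = c("endOD", "AUC"),
                                  var_equal = FALSE) {
  baseline_rule <- match.arg(baseline_rule)
  stopifnot(length(experiment) >= 1L,
            all(vapply(experiment, inherits, logical(1), "od_series")))
  metrics <- match.arg(metrics, c("endOD", "AUC"), several.ok = TRUE)

  arm_tab <- arm_table(experiment)
  labs <- vapply(experiment, function(s) treatment_label(s$treatment), character(1))
  metric_values <- function(lab, metric) {
    sel <- experiment[labs == lab]
    vapply(sel, if (metric == "endOD") end_od else auc_trapezoid, numeric(1))
  }

  combos <- arm_tab[arm_tab$moi > 0 & arm_tab$concentration > 0, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    phage_lab <- arm_tab$label[arm_tab$strain_id == cb$strain_id &
                                 arm_tab$moi == cb$moi &
                                 arm_tab$concentration == 0]
    ab_lab <- arm_tab$label[arm_tab$strain_id == cb$strain_id &
                              arm_tab$moi == 0 &
                              arm_tab$antibiotic == cb$antibiotic &
                              arm_tab$concentration == cb$concentration]
    for (metric in metrics) {
      treated <- metric_values(cb$label, metric)
      base_lab <- if (baseline_rule == "phage_alone") {
        if (length(phage_lab)) phage_lab[1L] else NA_character_
      } else {
        cand <- c(phage_lab, ab_lab)
        if (!length(cand)) NA_character_ else {
          means <- vapply(cand, function(l) mean(metric_values(l, metric)),
                          numeric(1))
          cand[which.min(means)]
        }
      }
      if (is.na(base_lab)) {
        warning(sprintf("combination %s: baseline arm missing, skipped",
                        cb$label), call. = FALSE)
        next
      }
      base <- metric_values(base_lab, metric)
      tt <- one_tailed_ttest(treated, base, metric = metric,
                             var_equal = var_equal)
      rows[[length(rows) + 1L]] <- data.frame(
        strain_id = cb$strain_id, moi = cb$moi, antibiotic = cb$antibiotic,
        concentration = cb$concentration, metric = metric,
        baseline = base_lab, mean_combo = mean(treated),
        mean_baseline = mean(base), t = tt$t_stat, p_one_sided = tt$p_one_sided,
        stars = tt$stars, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(strain_id = character(), moi = numeric(),
                      antibiotic = character(), concentration = numeric(),
                      metric = character(), baseline = character(),
                      mean_combo = numeric(), mean_baseline = numeric(),
                      t = numeric(), p_one_sided = numeric(),
                      stars = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

arm_table <- function(experiment) {
  labs <- vapply(experiment, function(s) treatment_label(s$treatment), character(1))
  keep <- !duplicated(labs)
  data.frame(
    label = labs[keep],
    strain_id = vapply(experiment[keep], function(s) s$treatment$strain_id, character(1)),
    moi = vapply(experiment[keep], function(s) s$treatment$moi, numeric(1)),
    antibiotic = vapply(experiment[keep], function(s) s$treatment$antibiotic, character(1)),
    concentration = vapply(experiment[keep], function(s) s$treatment$concentration, numeric(1)),
    stringsAsFactors = FALSE)
}

#' Write / read plate-reader OD590 CSV
#'
#' Schema: `strain, moi, antibiotic, conc_mg_l, replicate, time_h, od590`,
#' comma-separated, UTF-8, `.` decimal.  [read_plate_csv()] reconstructs the
#' list of [od_series()] and rejects files with missing columns.
#'
#' @param experiment List of [od_series()].
#' @param path File path.
#' @return `write_plate_csv`: the path, invisibly. `read_plate_csv`: a list
#'   of [od_series()].
#' @export
write_plate_csv <- function(experiment, path) {
  rows <- lapply(experiment, function(s) {
    tr <- s$treatment
    data.frame(strain = tr$strain_id, moi = tr$moi, antibiotic = tr$antibiotic,
               conc_mg_l = tr$concentration, replicate = s$replicate,
               time_h = s$times, od590 = s$od, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain", "moi", "antibiotic", "conc_mg_l", "replicate",
            "time_h", "od590")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("plate CSV '%s' lacks column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  key <- interaction(df$strain, df$moi, df$antibiotic, df$conc_mg_l,
                     df$replicate, drop = TRUE)
  lapply(split(df, key), function(g) {
    g <- g[order(g$time_h), ]
    od_series(times = g$time_h, od = g$od590,
              treatment = treatment(strain_id = g$strain[1L], moi = g$moi[1L],
                                    antibiotic = g$antibiotic[1L],
                                    concentration = g$conc_mg_l[1L]),
              replicate = g$replicate[1L])
  })
}
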