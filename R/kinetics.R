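#' Estimate burst size from a one-step growth experiment
#'
#' The burst size is the ratio of the post-burst to the pre-burst titer
#' plateau.  Plateaus are taken as the mean of the first and last `k`
#' sampled time points; the ratio is computed per replicate and summarized
#' as mean and standard deviation across replicates.
#'
#' @param data A [one_step_data()].
#' @param k Number of points defining each plateau; default 3.
#' @return List with `burst` (mean across replicates), `sd`, and the
#'   per-replicate ratios in `per_replicate`.
#' @export
burst_size <- function(data, k = 3L) {
  stopifnot(inherits(data, "one_step_data"))
  n <- nrow(data$titers)
  if (n < 2L * k)
    stop(sprintf("need >= %d time points for k = %d plateaus", 2L * k, k),
         call. = FALSE)
  first <- seq_len(k); last <- (n - k + 1L):n
  ratios <- apply(data$titers, 2L, function(x) {
    init <- mean(x[first])
    if (init == 0) stop("initial plateau mean is 0; burst size undefined",
                        call. = FALSE)
    mean(x[last]) / init
  })
  list(burst = mean(ratios), sd = stats::sd(ratios), per_replicate = ratios)
}

#' Estimate the latent period from a one-step growth experiment
#'
#' Reports the first sampled time at which the mean titer (across
#' replicates) exceeds `rise_factor` times the initial-plateau mean, at the
#' sampling resolution of the assay.  If the titer never rises, the assay
#' horizon is returned with `no_burst = TRUE`.
#'
#' @param data A [one_step_data()].
#' @param rise_factor Threshold multiple of the initial plateau; default 2.
#' @param k Points defining the initial plateau; default 3.
#' @return List with `latent_min`, `no_burst`.
#' @export
latent_period <- function(data, rise_factor = 2, k = 3L) {
  stopifnot(inherits(data, "one_step_data"))
  mean_titer <- rowMeans(data$titers)
  init <- mean(mean_titer[seq_len(min(k, length(mean_titer)))])
  hit <- which(mean_titer > rise_factor * init)
  if (!length(hit))
    return(list(latent_min = data$times[length(data$times)], no_burst = TRUE))
  list(latent_min = data$times[hit[1L]], no_burst = FALSE)
}

#' Adsorption profile: free fraction, t99, and rate constant
#'
#' Computes the fraction of free (unadsorbed) phage over time,
#' `mean free titer / p0`; `t99`, the first sampled time at which less than
#' 1% of particles remain free (no interpolation, matching the sampling
#' resolution of the assay); and `k_hat`, the first-order adsorption rate
#' from the least-squares slope of `log(fraction free)` against time over
#' time points with positive mean counts.
#'
#' @param data An [adsorption_data()].
#' @return List with `fraction_free` (per sampled time), `t99` (min, or
#'   `NA` if never below 1%), `k_hat` (1/min; `NA` with `k_undefined = TRUE`
#'   if no positive counts are available).
#' @export
adsorption_profile <- function(data) {
  stopifnot(inherits(data, "adsorption_data"))
  frac <- rowMeans(data$free_titers) / data$p0
  below <- which(frac < 0.01)
  t99 <- if (length(below)) data$times[below[1L]] else NA_real_
  pos <- which(frac > 0)
  if (length(pos) < 2L) {
    return(list(fraction_free = frac, t99 = t99, k_hat = NA_real_,
                k_undefined = TRUE))
  }
  fit <- stats::lm(log(frac[pos]) ~ data$times[pos])
  list(fraction_free = frac, t99 = t99,
       k_hat = -unname(stats::coef(fit)[2L]), k_undefined = FALSE)
}

#' Summarize a spot-assay host-range table
#'
#' For each strain class (clinical or reference), counts strains, strains
#' with a zone of clearing for the undiluted spot, and strains with
#' productive lysis (individual plaques visible upon titration), with
#' percentages rounded half-up to the nearest integer.  Productive lysis
#' implies clearing; rows violating that are rejected.
#'
#' @param table Data frame with columns `strain_id`, `strain_class`
#'   (`"clinical"` or `"reference"`), `clearing_undiluted`,
#'   `plaques_at_dilution` (logical or `"yes"`/`"no"`).
#' @return Data frame with one row per class: `strain_class`, `n`,
#'   `n_clearing`, `n_productive`, `pct_clearing`, `pct_productive`.
#' @export
host_range_summary <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) >= 1L)
  need <- c("strain_id", "strain_class", "clearing_undiluted",
            "plaques_at_dilution")
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop(sprintf("spot-assay table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  as_yes <- function(x) {
    if (is.logical(x)) x else tolower(trimws(as.character(x))) %in% c("yes", "true", "1")
  }
  clearing <- as_yes(table$clearing_undiluted)
  productive <- as_yes(table$plaques_at_dilution)
  bad <- which(productive & !clearing)
  if (length(bad))
    stop(sprintf("strain(s) %s report plaques without clearing",
                 paste(table$strain_id[bad], collapse = ", ")), call. = FALSE)
  pct <- function(num, den) if (den == 0) 0 else floor(100 * num / den + 0.5)
  out <- lapply(split(seq_len(nrow(table)), table$strain_class), function(idx) {
    n <- length(idx)
    data.frame(strain_class = table$strain_class[idx[1L]], n = n,
               n_clearing = sum(clearing[idx]),
               n_productive = sum(productive[idx]),
               pct_clearing = pct(sum(clearing[idx]), n),
               pct_productive = pct(sum(productive[idx]), n),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' CSV readers for titer and spot-assay tables
#'
#' `read_onestep_csv` expects columns `time_min` plus one `titer_rep<i>`
#' column per replicate (pfu/ml); `read_adsorption_csv` expects `time_min`
#' plus `free_titer_rep<i>` columns and takes `cell_density` and `p0` as
#' arguments (or columns of the same names, constant per file);
#' `read_spot_csv` expects the [host_range_summary()] schema.
#'
#' @param path CSV file path.
#' @param cell_density,p0 Assay constants for adsorption data; used when the
#'   file has no columns of those names.
#' @return A [one_step_data()], [adsorption_data()], or spot-assay
#'   data frame, respectively.
#' @export
read_onestep_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  reps <- grep("^titer_rep", names(df), value = TRUE)
  if (!"time_min" %in% names(df) || !length(reps))
    stop(sprintf("'%s': need columns time_min and titer_rep<i>", path),
         call. = FALSE)
  one_step_data(times = df$time_min, titers = as.matrix(df[reps]))
}

#' @rdname read_onestep_csv
#' @export
read_adsorption_csv <- function(path, cell_density = NULL, p0 = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  reps <- grep("^free_titer_rep", names(df), value = TRUE)
  if (!"time_min" %in% names(df) || !length(reps))
    stop(sprintf("'%s': need columns time_min and free_titer_rep<i>", path),
         call. = FALSE)
  if (is.null(cell_density)) cell_density <- df$cell_density[1L]
  if (is.null(p0)) p0 <- df$p0[1L]
  if (is.null(cell_density) || is.null(p0))
    stop("adsorption data need 'cell_density' and 'p0'", call. = FALSE)
  adsorption_data(times = df$time_min, free_titers = as.matrix(df[reps]),
                  cell_density = cell_density, p0 = p0)
}

#' @rdname read_onestep_csv
#' @export
read_spot_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain_id", "strain_class", "clearing_undiluted",
            "plaques_at_dilution")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("'%s' lacks column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  df
}
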