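test_that("trapezoid AUC matches closed forms exactly", {
  t49 <- assay_times()
  const <- od_series(t49, rep(0.5, 49))
  expect_equal(auc_trapezoid(const), 8, tolerance = 1e-12)
  lin <- od_series(t49, seq(0, 1, length.out = 49))
  expect_equal(auc_trapezoid(lin), 8, tolerance = 1e-12)
})

test_that("AUC agrees with an independent trapezoid oracle and is linear", {
  set.seed(101)
  for (i in 1:10) {
    od_f <- runif(49, 0, 1)
    od_g <- runif(49, 0, 1)
    t49 <- assay_times()
    expect_equal(auc_trapezoid(od_series(t49, od_f)),
                 pracma::trapz(t49, od_f), tolerance = 1e-12)
    a <- runif(1, 0.1, 3); b <- runif(1, 0.1, 3)
    expect_equal(auc_trapezoid(od_series(t49, a * od_f + b * od_g)),
                 a * auc_trapezoid(od_series(t49, od_f)) +
                   b * auc_trapezoid(od_series(t49, od_g)),
                 tolerance = 1e-10)
  }
})

test_that("end_od reads the final grid point", {
  expect_equal(end_od(od_series(assay_times(), rep(0.5, 49))), 0.5)
  rise <- seq(0.1, 0.9, length.out = 49)
  expect_equal(end_od(od_series(assay_times(), rise)), 0.9)
})

test_that("od_series rejects malformed trajectories", {
  expect_error(od_series(c(0, 1, 1.5), c(1, 2, 3)), "uniform")
  expect_error(od_series(c(0, 1), c(1, -0.1)), ">= 0")
  expect_error(od_series(c(1, 0), c(1, 2)), "increasing")
  expect_error(auc_trapezoid(od_series(0, 0.5)), "at least 2")
})

test_that("one-tailed t-test matches a hand-computed Welch statistic", {
  set.seed(7)
  treated <- c(0.1, 0.1, 0.1) + rnorm(3, sd = 1e-3)
  baseline <- c(0.5, 0.5, 0.5) + rnorm(3, sd = 1e-3)
  res <- one_tailed_ttest(treated, baseline)
  oracle <- welch_oracle(treated, baseline)
  expect_equal(res$t_stat, oracle$t, tolerance = 1e-10)
  expect_equal(res$p_one_sided, oracle$p, tolerance = 1e-10)
  expect_lt(res$p_one_sided, 0.001)
  expect_identical(res$stars, "***")
  expect_identical(res$direction, "suppression-enhanced")
})

test_that("degenerate equal constant arms give p = 0.5 and no stars", {
  res <- one_tailed_ttest(c(0.2, 0.2, 0.2), c(0.2, 0.2, 0.2))
  expect_true(res$degenerate)
  expect_equal(res$t_stat, 0)
  expect_equal(res$p_one_sided, 0.5)
  expect_identical(res$stars, "")
})

test_that("star mapping follows the significance thresholds", {
  expect_identical(stars_from_p(0.0005), "***")
  expect_identical(stars_from_p(0.005), "**")
  expect_identical(stars_from_p(0.03), "*")
  expect_identical(stars_from_p(0.05), "")
  expect_identical(stars_from_p(0.5), "")
})

make_experiment <- function(arms, seed = 1) {
  # arms: list of list(tr = treatment, end = end OD mean)
  set.seed(seed)
  out <- list()
  for (a in arms)
    out <- c(out, noisy_series(template_curve(a$end), a$tr))
  out
}

test_that("combination identical to its baseline earns no stars", {
  set.seed(55)
  phage <- noisy_series(template_curve(0.2), treatment("AB01", moi = 0.1))
  combo_tr <- treatment("AB01", moi = 0.1, antibiotic = "meropenem",
                        concentration = 32)
  combo <- lapply(phage, function(s)
    od_series(s$times, s$od, combo_tr, s$replicate))  # identical readings
  res <- evaluate_combinations(c(phage, combo), "phage_alone")
  expect_equal(nrow(res), 2L)  # endOD and AUC
  expect_true(all(res$stars == ""))
  expect_true(all(res$p_one_sided == 0.5))
})

test_that("baseline rule selects phage-alone vs best single correctly", {
  # craft: phage alone (0.4) is WORSE than antibiotic alone (0.25)
  arms <- list(
    list(tr = treatment("AB01"), end = 0.5),
    list(tr = treatment("AB01", moi = 0.1), end = 0.4),
    list(tr = treatment("AB01", antibiotic = "colistin", concentration = 8),
         end = 0.25),
    list(tr = treatment("AB01", moi = 0.1, antibiotic = "colistin",
                        concentration = 8), end = 0.05))
  exp_ <- make_experiment(arms, seed = 11)
  res_pa <- evaluate_combinations(exp_, "phage_alone", metrics = "endOD")
  res_bs <- evaluate_combinations(exp_, "best_single", metrics = "endOD")
  expect_match(res_pa$baseline, "moi=0.1\\|none")
  expect_match(res_bs$baseline, "moi=0\\|colistin=8")
  # direct enumeration: the chosen baseline has the lower arm mean
  expect_lt(res_bs$mean_baseline, res_pa$mean_baseline)
  # strong combination effect is detected against either baseline
  expect_true(all(c(res_pa$stars, res_bs$stars) != ""))
})

test_that("missing baseline arm is skipped with a warning", {
  arms <- list(
    list(tr = treatment("AB01", moi = 0.1, antibiotic = "meropenem",
                        concentration = 32), end = 0.1))
  expect_warning(res <- evaluate_combinations(make_experiment(arms),
                                              metrics = "endOD"),
                 "baseline arm missing")
  expect_equal(nrow(res), 0L)
})

test_that("evaluate_combinations is invariant to input shuffling", {
  arms <- list(
    list(tr = treatment("AB01"), end = 0.5),
    list(tr = treatment("AB01", moi = 0.1), end = 0.45),
    list(tr = treatment("AB01", antibiotic = "meropenem", concentration = 32),
         end = 0.5),
    list(tr = treatment("AB01", moi = 0.1, antibiotic = "meropenem",
                        concentration = 32), end = 0.1))
  exp_ <- make_experiment(arms, seed = 3)
  res1 <- evaluate_combinations(exp_, "best_single")
  set.seed(42)
  res2 <- evaluate_combinations(sample(exp_), "best_single")
  expect_equal(res1[order(res1$metric), ], res2[order(res2$metric), ],
               ignore_attr = TRUE)
})

test_that("plate-reader CSV round-trips losslessly", {
  arms <- list(list(tr = treatment("AB01", moi = 0.001), end = 0.3))
  exp_ <- make_experiment(arms)
  path <- tempfile(fileext = ".csv")
  write_plate_csv(exp_, path)
  back <- read_plate_csv(path)
  expect_equal(length(back), length(exp_))
  orig_end <- sort(unname(vapply(exp_, end_od, numeric(1))))
  back_end <- sort(unname(vapply(back, end_od, numeric(1))))
  expect_equal(back_end, orig_end, tolerance = 1e-12)
  expect_error(read_plate_csv({
    p2 <- tempfile(fileext = ".csv")
    write.csv(data.frame(x = 1), p2, row.names = FALSE); p2
  }), "lacks column")
})
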