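test_that("ln-ratios are computed per contrast and degenerate rows excluded", {
  tab <- make_peptide_table(3)
  tab$area_115 <- tab$area_114  # equal areas -> ln ratio 0
  out <- compute_ln_ratios(tab, channel_contrast(115, 114))
  expect_equal(out$observations$ln_ratio, rep(0, 3))

  tab2 <- make_peptide_table(1)
  tab2$area_116 <- 2718.2818
  tab2$area_117 <- 1000
  out2 <- compute_ln_ratios(tab2, channel_contrast(116, 117))
  expect_equal(out2$observations$ln_ratio, 1.0, tolerance = 1e-7)

  tab3 <- make_peptide_table(2)
  tab3$area_114[1] <- 0
  tab3$area_115[1] <- 500
  out3 <- compute_ln_ratios(tab3, channel_contrast(115, 114))
  expect_equal(nrow(out3$observations), 1)
  expect_equal(out3$exclusions$row, 1)
  expect_equal(out3$exclusions$reason, "nonpositive denominator")
  tab3$area_114[1] <- 10
  tab3$area_115[1] <- 0
  out4 <- compute_ln_ratios(tab3, channel_contrast(115, 114))
  expect_equal(out4$exclusions$reason, "nonpositive numerator")

  expect_error(compute_ln_ratios(tab, "115/114"), "configuration error")
})

test_that("a contrast not referencing 114 equals the ratio of 114-referenced ratios", {
  cfg <- simulation_config(n_proteins = 50, seed = 4)
  tab <- generate_experiment(cfg)$table
  direct <- compute_ln_ratios(tab, channel_contrast(116, 117))$observations$ln_ratio
  r116 <- compute_ln_ratios(tab, channel_contrast(116, 114))$observations$ln_ratio
  r117 <- compute_ln_ratios(tab, channel_contrast(117, 114))$observations$ln_ratio
  expect_equal(direct, r116 - r117, tolerance = 1e-12)
})

test_that("histogram defaults to 200 bins on [-1, 1] and conserves counts", {
  spec <- histogram_spec()
  h <- build_histogram(c(0.005), spec)
  expect_length(h$counts, 200)
  expect_equal(diff(h$bin_centers), rep(0.01, 199), tolerance = 1e-9)
  # 0.005 falls in the bin covering [0.00, 0.01)
  target <- which(h$bin_centers > 0 & h$bin_centers < 0.01)
  expect_equal(h$counts[target], 1)
  expect_equal(sum(h$counts), 1)

  h2 <- build_histogram(c(1.5, -2.0), spec)
  expect_equal(sum(h2$counts), 0)
  expect_equal(h2$n_out_of_range, 2)

  # half-open bins, final bin closed; sum + out-of-range = n
  vals <- c(-1, -0.005, 0, 0.005, 0.9999, 1, 1.0001, -1.2)
  h3 <- build_histogram(vals, spec)
  expect_equal(sum(h3$counts) + h3$n_out_of_range, length(vals))
  expect_equal(h3$n_out_of_range, 2)
  expect_equal(h3$counts[200], 2)  # 0.9999 and the closed upper edge 1

  expect_error(build_histogram(numeric(0), spec), "empty")
  expect_error(histogram_spec(1, -1), "configuration error")
  expect_error(histogram_spec(n_bins = 5), "configuration error")
})

test_that("Savitzky-Golay smoothing reproduces polynomials and the impulse weight", {
  spec <- smoother_spec(11, 3)
  const <- rep(5, 11)
  expect_equal(savgol_smooth(const, spec), const)

  x <- seq_len(25)
  quad <- 2 + 0.5 * x - 0.03 * x^2
  expect_equal(savgol_smooth(quad, smoother_spec(5, 2)), quad,
               tolerance = 1e-9)
  cubic <- 1 - x + 0.1 * x^2 + 0.01 * x^3
  expect_equal(savgol_smooth(cubic, spec), cubic, tolerance = 1e-8)

  # centre weight of the 5-point quadratic kernel
  imp <- savgol_smooth(c(0, 0, 1, 0, 0), smoother_spec(5, 2))
  expect_equal(imp[3], 17 / 35, tolerance = 1e-12)

  expect_error(smoother_spec(10, 3), "odd")
  expect_error(smoother_spec(5, 5), "polyorder")
  expect_error(savgol_smooth(1:3, smoother_spec(5, 2)), "shorter")
})

test_that("Savitzky-Golay matches the per-window least-squares oracle", {
  set.seed(101)
  for (case in list(c(5, 2), c(7, 3), c(9, 2), c(11, 3), c(11, 4))) {
    y <- rnorm(40)
    got <- savgol_smooth(y, smoother_spec(case[1], case[2]))
    want <- oracle_savgol(y, case[1], case[2])
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("interior points agree with signal::sgolayfilt", {
  skip_if_not_installed("signal")
  set.seed(102)
  y <- rnorm(60)
  got <- savgol_smooth(y, smoother_spec(11, 3))
  ref <- signal::sgolayfilt(y, p = 3, n = 11)
  core <- 6:55
  expect_equal(got[core], ref[core], tolerance = 1e-9)
})

test_that("Gaussian fit recovers exact and sampled null parameters", {
  spec <- histogram_spec()
  centers <- spec$lower + (seq_len(spec$n_bins) - 0.5) * spec$bin_width
  exact <- 120 * exp(-centers^2 / (2 * 0.2^2))
  fit <- fit_gaussian(centers, exact)
  expect_equal(fit$sigma, 0.2, tolerance = 1e-6)
  expect_equal(fit$mu, 0, tolerance = 1e-6)
  expect_equal(fit$amplitude, 120, tolerance = 1e-4)

  set.seed(21)
  x <- rnorm(50000, 0, 0.15)
  null <- fit_ratio_null(x)
  expect_lt(abs(null$sigma / 0.15 - 1), 0.05)
  expect_equal(null$n_in_range + null$n_out_of_range, 50000)

  expect_error(fit_gaussian(centers, rep(0, 200)), "fit error")
  expect_error(fit_gaussian(centers, rep(3, 200)), "fit error")
})

test_that("fitted sigma recovers the generating null_sigma within 5%", {
  cfg <- simulation_config(n_proteins = 1500, peptides_per_protein_mean = 4,
                           de_fraction = 0.05, effect_ln_fc = 1.0,
                           null_sigma = 0.15, seed = 13)
  tab <- generate_experiment(cfg)$table
  lr <- compute_ln_ratios(tab, channel_contrast(115, 114))$observations$ln_ratio
  expect_gte(length(lr), 5000)
  null <- fit_ratio_null(lr)
  expect_lt(abs(null$sigma / 0.15 - 1), 0.05)
})

test_that("peptide p-values follow the two-sided Gaussian tail", {
  null <- structure(list(mu = 0.02, sigma = 0.15, amplitude = 1, rss = 0,
                         n_in_range = NA_integer_, n_out_of_range = NA_integer_),
                    class = "gaussian_null")
  cfg <- calling_config()
  expect_equal(peptide_pvalue(null$mu, null, cfg), 1.0)
  # at 2.5 sigma the p-value is the complement of 98.8% confidence
  expect_equal(peptide_pvalue(null$mu + 2.5 * null$sigma, null, cfg),
               2 * pnorm(-2.5), tolerance = 1e-12)
  expect_equal(round(peptide_pvalue(null$mu + 2.5 * null$sigma, null, cfg), 4),
               0.0124)
  # monotone decreasing in the deviation
  devs <- seq(0, 1, by = 0.05)
  ps <- peptide_pvalue(null$mu + devs, null, cfg)
  expect_true(all(diff(ps) < 0))
  # p <= 0.02 exactly when the deviation reaches the inverted tail
  zc <- qnorm(1 - 0.02 / 2)
  expect_lte(peptide_pvalue(null$mu + zc * null$sigma * 1.0001, null, cfg), 0.02)
  expect_gt(peptide_pvalue(null$mu + zc * null$sigma * 0.9999, null, cfg), 0.02)
})

test_that("k x SD calls are boundary-inclusive and agree with p-values", {
  null <- structure(list(mu = 0, sigma = 0.15, amplitude = 1, rss = 0,
                         n_in_range = NA_integer_, n_out_of_range = NA_integer_),
                    class = "gaussian_null")
  cfg <- calling_config(k = 2.5)
  at <- call_significant(2.5 * 0.15, null, cfg)
  expect_true(at$significant)
  expect_equal(at$direction, "up")
  near <- call_significant(2.49 * 0.15, null, cfg)
  expect_false(near$significant)
  # far outside the histogram range still called
  far <- call_significant(1.8, null, cfg)
  expect_true(far$significant)
  expect_equal(far$direction, "up")
  down <- call_significant(-0.5, null, cfg)
  expect_equal(down$direction, "down")

  # call at k = 2.5 iff p <= 2 * (1 - pnorm(2.5))
  set.seed(33)
  x <- rnorm(2000, 0, 0.3)
  calls <- call_significant(x, null, cfg)$significant
  ps <- peptide_pvalue(x, null, cfg)
  expect_identical(calls, ps <= 2 * pnorm(-2.5) + 1e-15)
})

test_that("channel scaling shifts ln-ratios by ln(c) and equal scaling keeps calls", {
  cfg <- simulation_config(n_proteins = 300, seed = 17)
  tab <- generate_experiment(cfg)$table
  cc <- channel_contrast(115, 114)
  base <- compute_ln_ratios(tab, cc)$observations$ln_ratio

  scaled <- tab
  scaled$area_115 <- scaled$area_115 * 3
  up <- compute_ln_ratios(scaled, cc)$observations$ln_ratio
  expect_equal(up, base + log(3), tolerance = 1e-12)

  both <- tab
  both$area_114 <- both$area_114 * 3
  both$area_115 <- both$area_115 * 3
  same <- compute_ln_ratios(both, cc)$observations$ln_ratio
  expect_equal(same, base, tolerance = 1e-12)
  null <- fit_ratio_null(base)
  expect_identical(call_significant(same, null)$significant,
                   call_significant(base, null)$significant)
})
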