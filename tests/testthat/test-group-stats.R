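test_that("exact signed-rank p-values match their printed small-sample cases", {
  # five pairs, all increases: p = 2/32
  r <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10),
                            method = "exact")
  expect_equal(r$p_two_sided, 2 / 32)
  expect_equal(r$statistic, 15)
  expect_equal(r$method, "exact")

  # the same holds with tied |differences| via midrank enumeration
  rt <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), c(2, 3, 5, 7, 9),
                             method = "exact")
  expect_equal(rt$p_two_sided, 2 / 32)
  expect_true(rt$tie_correction_applied)
})

test_that("normal approximation reproduces the all-same-sign z formulas", {
  # n = 5: z = 7.5 / sqrt(13.75)
  r5 <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10),
                             method = "normal_approx")
  expect_equal(r5$p_two_sided, 2 * pnorm(-7.5 / sqrt(13.75)), tolerance = 1e-12)
  expect_equal(round(r5$p_two_sided, 3), 0.043)

  # n = 6: z = 10.5 / sqrt(22.75)
  r6 <- wilcoxon_signed_rank(1:6, 1:6 + c(1, 2, 3, 4, 5, 6.5),
                             method = "normal_approx")
  expect_equal(r6$p_two_sided, 2 * pnorm(-10.5 / sqrt(22.75)), tolerance = 1e-12)
  expect_equal(round(r6$p_two_sided, 3), 0.028)
})

test_that("exact Mann-Whitney U matches enumeration on the canonical cases", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), method = "exact")
  expect_equal(r$p_two_sided, 2 / 20)
  expect_equal(r$statistic, 0)

  sym <- mann_whitney_u(c(1, 2), c(1, 2), method = "exact")
  expect_equal(sym$p_two_sided, 1.0)
})

test_that("exact tests equal brute-force enumeration for small n", {
  set.seed(81)
  for (n in 3:10) {
    before <- rnorm(n)
    after <- before + rnorm(n)
    got <- wilcoxon_signed_rank(before, after, method = "exact")$p_two_sided
    expect_equal(got, oracle_signed_rank_p(after - before), tolerance = 1e-12)
    # and with forced ties among |differences|
    d <- sample(c(-2, -1, 1, 1, 2, 3), n, replace = TRUE)
    got_t <- suppressWarnings(
      wilcoxon_signed_rank(rep(0, n), d, method = "exact"))$p_two_sided
    expect_equal(got_t, oracle_signed_rank_p(d), tolerance = 1e-12)
  }
  for (i in 1:10) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    a <- rnorm(n1)
    b <- rnorm(n2, 0.5)
    got <- mann_whitney_u(a, b, method = "exact")$p_two_sided
    expect_equal(got, oracle_rank_sum_p(a, b), tolerance = 1e-12)
    # tied data through midranks
    a2 <- sample(1:3, n1, replace = TRUE)
    b2 <- sample(2:4, n2, replace = TRUE)
    got2 <- mann_whitney_u(a2, b2, method = "exact")$p_two_sided
    expect_equal(got2, oracle_rank_sum_p(a2, b2), tolerance = 1e-12)
  }
})

test_that("untied exact p-values agree with base R's distributions", {
  set.seed(82)
  for (i in 1:5) {
    before <- rnorm(8)
    after <- before + rnorm(8)
    got <- wilcoxon_signed_rank(before, after, method = "exact")$p_two_sided
    ref <- wilcox.test(after, before, paired = TRUE, exact = TRUE)$p.value
    expect_equal(got, ref, tolerance = 1e-12)

    a <- rnorm(5)
    b <- rnorm(6)
    gotu <- mann_whitney_u(a, b, method = "exact")$p_two_sided
    refu <- wilcox.test(a, b, exact = TRUE)$p.value
    expect_equal(gotu, refu, tolerance = 1e-12)
  }
})

test_that("two-sided p-values are invariant under sign flip and label swap", {
  set.seed(83)
  d <- rnorm(8)
  p1 <- wilcoxon_signed_rank(rep(0, 8), d, method = "exact")$p_two_sided
  p2 <- wilcoxon_signed_rank(rep(0, 8), -d, method = "exact")$p_two_sided
  expect_equal(p1, p2)

  a <- rnorm(5)
  b <- rnorm(5, 1)
  expect_equal(mann_whitney_u(a, b, method = "exact")$p_two_sided,
               mann_whitney_u(b, a, method = "exact")$p_two_sided)
  expect_equal(mann_whitney_u(a, b, method = "normal_approx")$p_two_sided,
               mann_whitney_u(b, a, method = "normal_approx")$p_two_sided)
})

test_that("degenerate inputs and fallbacks behave as specified", {
  expect_error(wilcoxon_signed_rank(1:4, 1:4), "all paired differences are zero")
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")

  # zero differences dropped and counted
  r <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6), c(1, 2, 5, 7, 9, 11),
                            method = "exact")
  expect_equal(r$zero_diffs_dropped, 2)
  expect_equal(r$n, 4)

  expect_warning(
    wilcoxon_signed_rank(rnorm(25), rnorm(25), method = "exact"),
    "falling back")
  expect_warning(
    mann_whitney_u(rnorm(10), rnorm(10), method = "exact"),
    "falling back")
})

test_that("exact signed-rank test holds its size under a continuous null", {
  set.seed(84)
  n_rep <- 800
  rejections <- 0
  for (i in seq_len(n_rep)) {
    d <- rnorm(9)
    p <- wilcoxon_signed_rank(rep(0, 9), d, method = "exact")$p_two_sided
    if (p <= 0.05) rejections <- rejections + 1
  }
  rate <- rejections / n_rep
  # achievable size at n = 9: largest exact level not exceeding 0.05
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("the normal approximation converges to the exact p as n grows", {
  # worst-case |exact - approx| over the whole statistic range shrinks with
  # n; in the decision-relevant tail (exact p <= 0.1) it is already below
  # 0.01 at n = 15
  gap <- function(n, region = 1) {
    ws <- 0:(n * (n + 1) / 2)
    pe <- vapply(ws, function(w) {
      min(1, 2 * min(psignrank(w, n),
                     psignrank(w - 1, n, lower.tail = FALSE)))
    }, 0)
    pa <- 2 * pnorm(-abs(ws - n * (n + 1) / 4) /
                      sqrt(n * (n + 1) * (2 * n + 1) / 24))
    max(abs(pe - pa)[pe <= region])
  }
  gaps <- vapply(c(15, 20, 25, 30), gap, 0)
  expect_true(all(diff(gaps) < 0))
  expect_lt(gap(15, region = 0.1), 0.01)

  # spot-check the package implementation against the same grid
  set.seed(85)
  d <- rnorm(15)
  pe <- wilcoxon_signed_rank(rep(0, 15), d, method = "exact")$p_two_sided
  pa <- wilcoxon_signed_rank(rep(0, 15), d, method = "normal_approx")$p_two_sided
  expect_lt(abs(pe - pa), 0.03)
})

test_that("group summaries report medians and ranges and pair correctly", {
  m <- data.frame(
    subject_id = c("s1", "s2", "s3", "s1", "s2", "t1", "t2", "t3"),
    group = c(rep("young_susceptible", 5), rep("young_non_susceptible", 3)),
    timepoint = c(rep("baseline", 3), rep("after_smoking", 2),
                  rep("baseline", 3)),
    analyte = "peroxiredoxin_1",
    concentration = c(1, 2, 3, 2.5, 3.5, 4, 5, 6),
    unit = "pg/mL",
    stringsAsFactors = FALSE
  )
  out <- summarize_groups(m)
  ys_base <- out$summary[out$summary$group == "young_susceptible" &
                           out$summary$timepoint == "baseline", ]
  expect_equal(ys_base$median, 2)
  expect_equal(ys_base$min, 1)
  expect_equal(ys_base$max, 3)
  expect_equal(ys_base$n, 3L)
  # s3 has no after_smoking record: paired test uses 2 pairs only
  paired <- out$paired_tests[out$paired_tests$group == "young_susceptible", ]
  expect_equal(paired$n_pairs, 2)
  # baseline comparison uses all three baseline values per group
  expect_equal(out$baseline_tests$n_a, 3)
  expect_equal(out$baseline_tests$n_b, 3)

  dup <- rbind(m, m[1, ])
  expect_error(summarize_groups(dup), "duplicate record")
  bad_unit <- m
  bad_unit$unit[1] <- "ug/mL"
  expect_error(summarize_groups(bad_unit), "inconsistent units")
})

test_that("a large injected smoke-response difference is detected with high power", {
  set.seed(86)
  n_rep <- 60
  hits <- 0
  for (i in seq_len(n_rep)) {
    n <- 7
    mk <- function(group, delta) {
      data.frame(
        subject_id = paste0(group, 1:n),
        group = group,
        timepoint = rep(c("baseline", "after_smoking"), each = n),
        analyte = "serpin_b3",
        concentration = c(rlnorm(n, 7, 0.3), rlnorm(n, 7 + delta, 0.3)),
        stringsAsFactors = FALSE
      )
    }
    m <- rbind(mk("young_susceptible", -2), mk("young_non_susceptible", 0))
    out <- summarize_groups(m)
    if (out$change_tests$p_two_sided < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})
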