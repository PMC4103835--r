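# Validation-arm nonparametric statistics on per-subject concentrations:
# exact and normal-approximation Wilcoxon signed-rank (paired before/after)
# and Mann-Whitney U (between groups), plus median (range) group summaries.

test_result <- function(statistic, p, method, n = NA_integer_,
                        n1 = NA_integer_, n2 = NA_integer_,
                        zero_diffs_dropped = 0L,
                        tie_correction_applied = FALSE, note = "") {
  structure(
    list(statistic = statistic,
         p_two_sided = min(max(p, .Machine$double.xmin), 1),
         method = method, n = n, n1 = n1, n2 = n2,
         zero_diffs_dropped = as.integer(zero_diffs_dropped),
         tie_correction_applied = isTRUE(tie_correction_applied),
         note = note),
    class = "rank_test_result"
  )
}

#' @export
print.rank_test_result <- function(x, ...) {
  size <- if (!is.na(x$n)) sprintf("n = %d", x$n) else
    sprintf("n1 = %d, n2 = %d", x$n1, x$n2)
  cat(sprintf("statistic = %g, two-sided p = %.4g (%s, %s)\n",
              x$statistic, x$p_two_sided, x$method, size))
  if (x$zero_diffs_dropped > 0) {
    cat(sprintf("  zero differences dropped: %d\n", x$zero_diffs_dropped))
  }
  if (nzchar(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

# exact distribution of the signed-rank statistic over all 2^n sign
# assignments, as a probability vector over doubled-rank support 0..sum(2r);
# valid with midranks (half-integer ranks double to integers)
signed_rank_distribution <- function(ranks2) {
  p <- numeric(sum(ranks2) + 1)
  p[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), p[seq_len(length(p) - r)])
    p <- (p + shifted) / 2
  }
  p  # index i holds P(2W = i - 1)
}

# exact distribution of the group-A rank sum over all choose(N, n1)
# assignments, over doubled-rank support (midrank-safe)
rank_sum_distribution <- function(ranks2, n1) {
  total <- sum(ranks2)
  # dp[k + 1, s + 1] = number of k-subsets with doubled-rank sum s
  dp <- matrix(0, nrow = n1 + 1, ncol = total + 1)
  dp[1, 1] <- 1
  for (r in ranks2) {
    # RHS is evaluated on the pre-update dp, so each item is used at most once
    dp[2:(n1 + 1), (r + 1):(total + 1)] <-
      dp[2:(n1 + 1), (r + 1):(total + 1)] +
      dp[1:n1, 1:(total + 1 - r), drop = FALSE]
  }
  counts <- dp[n1 + 1, ]
  counts / sum(counts)
}

two_sided_from_distribution <- function(prob, observed2) {
  support <- seq_along(prob) - 1
  lower <- sum(prob[support <= observed2 + 1e-9])
  upper <- sum(prob[support >= observed2 - 1e-9])
  min(1, 2 * min(lower, upper))
}

#' Wilcoxon signed-rank test for paired measurements
#'
#' Paired before/after test on per-subject differences. Zero differences
#' are dropped and counted. The exact method enumerates all `2^n` sign
#' assignments of the ranked absolute differences (midranks under ties, in
#' which case the exact p is conditional on the observed tie pattern and a
#' note is recorded); it is available for `n <= 20`, beyond which the test
#' falls back to the normal approximation with a warning. The normal
#' approximation uses `z = (W+ - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24 - tie
#' term)`, two-sided, without continuity correction.
#'
#' @param before,after Equal-length numeric vectors of paired measurements.
#' @param method `"exact"` or `"normal_approx"`.
#' @return A `rank_test_result` with the W+ statistic, two-sided p, the
#'   method actually used, n after dropping zero differences, and the
#'   number of zero differences dropped.
#' @export
wilcoxon_signed_rank <- function(before, after,
                                 method = c("exact", "normal_approx")) {
  method <- match.arg(method)
  if (length(before) != length(after)) {
    stop("before and after must have equal length", call. = FALSE)
  }
  d <- after - before
  if (anyNA(d)) stop("missing values in paired differences", call. = FALSE)
  zero <- d == 0
  n_zero <- sum(zero)
  d <- d[!zero]
  n <- length(d)
  if (n == 0) {
    stop("undefined test: all paired differences are zero", call. = FALSE)
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  note <- if (ties) "midranks used for tied |differences|" else ""

  if (method == "exact" && n > 20) {
    warning("exact signed-rank enumeration limited to n <= 20; falling back to normal approximation")
    method <- "normal_approx"
  }

  if (method == "exact") {
    ranks2 <- as.integer(round(2 * r))
    prob <- signed_rank_distribution(ranks2)
    p <- two_sided_from_distribution(prob, 2 * w_plus)
    if (ties) note <- paste(note, "(exact p conditional on tie pattern)")
    return(test_result(w_plus, p, "exact", n = n,
                       zero_diffs_dropped = n_zero,
                       tie_correction_applied = ties, note = note))
  }

  tie_counts <- table(abs(d))
  tie_term <- sum(tie_counts^3 - tie_counts) / 48
  mu <- n * (n + 1) / 4
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - tie_term
  if (sigma2 <= 0) {
    stop("undefined test: zero variance after tie correction", call. = FALSE)
  }
  z <- (w_plus - mu) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  test_result(w_plus, p, "normal_approx", n = n,
              zero_diffs_dropped = n_zero,
              tie_correction_applied = tie_term > 0, note = note)
}

#' Mann-Whitney U test for two independent groups
#'
#' The exact method enumerates the rank-sum distribution over all
#' `choose(n1 + n2, n1)` group assignments (midranks under ties, with the
#' exactness caveat noted); it is available for `n1 + n2 <= 14`, beyond
#' which the test falls back to the normal approximation with a warning.
#' The normal approximation uses the tie-corrected variance without
#' continuity correction. The reported statistic is `U = min(U1, U2)`.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @param method `"exact"` or `"normal_approx"`.
#' @return A `rank_test_result` with U, the two-sided p and group sizes.
#' @export
mann_whitney_u <- function(group_a, group_b,
                           method = c("exact", "normal_approx")) {
  method <- match.arg(method)
  n1 <- length(group_a)
  n2 <- length(group_b)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(group_a, group_b)
  if (anyNA(pooled)) stop("missing values in group data", call. = FALSE)
  r <- rank(pooled)
  r1 <- sum(r[seq_len(n1)])
  u1 <- r1 - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)
  ties <- anyDuplicated(pooled) > 0
  note <- if (ties) "midranks used for ties; exact p conditional on tie pattern" else ""

  if (method == "exact" && n1 + n2 > 14) {
    warning("exact rank-sum enumeration limited to n1 + n2 <= 14; falling back to normal approximation")
    method <- "normal_approx"
  }

  if (method == "exact") {
    ranks2 <- as.integer(round(2 * r))
    prob <- rank_sum_distribution(ranks2, n1)
    p <- two_sided_from_distribution(prob, 2 * r1)
    return(test_result(u, p, "exact", n1 = n1, n2 = n2,
                       tie_correction_applied = ties, note = note))
  }

  N <- n1 + n2
  tie_counts <- table(pooled)
  tie_term <- sum(tie_counts^3 - tie_counts) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * (N + 1 - tie_term)
  if (sigma2 <= 0) {
    stop("undefined test: zero variance after tie correction", call. = FALSE)
  }
  z <- (u1 - n1 * n2 / 2) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  test_result(u, p, "normal_approx", n1 = n1, n2 = n2,
              tie_correction_applied = tie_term > 0, note = note)
}

validate_measurements <- function(measurements) {
  req <- c("subject_id", "group", "timepoint", "analyte", "concentration")
  missing_cols <- setdiff(req, names(measurements))
  if (length(missing_cols) > 0) {
    stop("measurement table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(measurements$timepoint %in% c("baseline", "after_smoking"))) {
    stop("timepoint must be 'baseline' or 'after_smoking'", call. = FALSE)
  }
  if (any(measurements$concentration < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  key <- paste(measurements$subject_id, measurements$timepoint,
               measurements$analyte, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate record for a (subject, timepoint, analyte) combination",
         call. = FALSE)
  }
  if ("unit" %in% names(measurements)) {
    per_analyte <- tapply(measurements$unit, measurements$analyte,
                          function(u) length(unique(u)))
    if (any(per_analyte > 1)) {
      stop("inconsistent units within analyte: ",
           paste(names(per_analyte)[per_analyte > 1], collapse = ", "),
           call. = FALSE)
    }
  }
  measurements
}

#' Summarize concentration data and run the group comparisons
#'
#' Produces median (range) summaries per group, timepoint and analyte, and
#' runs the validation-arm comparisons: paired before/after-smoking tests
#' within each group (signed-rank, subjects present at both timepoints
#' only), between-group tests on baseline concentrations, and between-group
#' tests on per-subject changes (after minus before) — the acute
#' smoke-response comparison (Mann-Whitney U).
#'
#' @param measurements data.frame with columns `subject_id`, `group`,
#'   `timepoint` (`"baseline"` / `"after_smoking"`), `analyte`,
#'   `concentration` and optionally `unit`.
#' @param group_pairs Optional list of length-2 character vectors naming
#'   the group pairs to compare; defaults to all pairs present.
#' @param method Test method passed to the rank tests.
#' @return List of class `group_stats_summary` with data.frames `summary`,
#'   `paired_tests`, `baseline_tests` and `change_tests`.
#' @export
summarize_groups <- function(measurements, group_pairs = NULL,
                             method = c("exact", "normal_approx")) {
  method <- match.arg(method)
  measurements <- validate_measurements(measurements)

  agg <- stats::aggregate(
    concentration ~ group + timepoint + analyte, data = measurements,
    FUN = function(x) c(median = stats::median(x), min = min(x),
                        max = max(x), n = length(x))
  )
  summary_df <- cbind(agg[c("group", "timepoint", "analyte")],
                      as.data.frame(agg$concentration))
  summary_df$n <- as.integer(summary_df$n)

  run_safely <- function(expr) {
    tryCatch(suppressWarnings(expr), error = function(e) NULL)
  }

  paired_rows <- list()
  for (g in unique(measurements$group)) {
    for (an in unique(measurements$analyte)) {
      sub <- measurements[measurements$group == g &
                            measurements$analyte == an, , drop = FALSE]
      wide <- merge(
        sub[sub$timepoint == "baseline", c("subject_id", "concentration")],
        sub[sub$timepoint == "after_smoking", c("subject_id", "concentration")],
        by = "subject_id", suffixes = c("_before", "_after")
      )
      if (nrow(wide) == 0) next
      res <- run_safely(wilcoxon_signed_rank(wide$concentration_before,
                                             wide$concentration_after,
                                             method = method))
      paired_rows[[length(paired_rows) + 1]] <- data.frame(
        group = g, analyte = an, n_pairs = nrow(wide),
        statistic = if (is.null(res)) NA_real_ else res$statistic,
        p_two_sided = if (is.null(res)) NA_real_ else res$p_two_sided,
        method = if (is.null(res)) NA_character_ else res$method,
        stringsAsFactors = FALSE
      )
    }
  }

  groups <- unique(measurements$group)
  if (is.null(group_pairs)) {
    group_pairs <- if (length(groups) >= 2) {
      utils::combn(groups, 2, simplify = FALSE)
    } else list()
  }

  between <- function(value_of) {
    rows <- list()
    for (pair in group_pairs) {
      for (an in unique(measurements$analyte)) {
        va <- value_of(pair[1], an)
        vb <- value_of(pair[2], an)
        if (length(va) == 0 || length(vb) == 0) next
        res <- run_safely(mann_whitney_u(va, vb, method = method))
        rows[[length(rows) + 1]] <- data.frame(
          group_a = pair[1], group_b = pair[2], analyte = an,
          n_a = length(va), n_b = length(vb),
          statistic = if (is.null(res)) NA_real_ else res$statistic,
          p_two_sided = if (is.null(res)) NA_real_ else res$p_two_sided,
          method = if (is.null(res)) NA_character_ else res$method,
          stringsAsFactors = FALSE
        )
      }
    }
    if (length(rows) == 0) {
      data.frame(group_a = character(0), group_b = character(0),
                 analyte = character(0), n_a = integer(0), n_b = integer(0),
                 statistic = numeric(0), p_two_sided = numeric(0),
                 method = character(0), stringsAsFactors = FALSE)
    } else do.call(rbind, rows)
  }

  baseline_of <- function(g, an) {
    measurements$concentration[measurements$group == g &
                                 measurements$analyte == an &
                                 measurements$timepoint == "baseline"]
  }
  change_of <- function(g, an) {
    sub <- measurements[measurements$group == g &
                          measurements$analyte == an, , drop = FALSE]
    wide <- merge(
      sub[sub$timepoint == "baseline", c("subject_id", "concentration")],
      sub[sub$timepoint == "after_smoking", c("subject_id", "concentration")],
      by = "subject_id", suffixes = c("_before", "_after")
    )
    wide$concentration_after - wide$concentration_before
  }

  structure(
    list(summary = summary_df,
         paired_tests = if (length(paired_rows) == 0) {
           data.frame(group = character(0), analyte = character(0),
                      n_pairs = integer(0), statistic = numeric(0),
                      p_two_sided = numeric(0), method = character(0),
                      stringsAsFactors = FALSE)
         } else do.call(rbind, paired_rows),
         baseline_tests = between(baseline_of),
         change_tests = between(change_of)),
    class = "group_stats_summary"
  )
}

#' @export
print.group_stats_summary <- function(x, ...) {
  cat("Group summaries (median [min-max], n):\n")
  print(x$summary)
  cat("\nPaired before/after tests (signed-rank):\n")
  print(x$paired_tests)
  cat("\nBaseline between-group tests (Mann-Whitney U):\n")
  print(x$baseline_tests)
  cat("\nSmoke-response (change) between-group tests (Mann-Whitney U):\n")
  print(x$change_tests)
  invisible(x)
}
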