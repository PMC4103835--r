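# Null model of random reporter-ion ratio variation: per-contrast ln-ratios,
# 200-bin histogram on [-1, +1], Savitzky-Golay smoothing, Gaussian fit, and
# k x SD significance calls with per-peptide p-values.

#' Compute ln-ratios for one contrast
#'
#' For every peptide with strictly positive areas in both channels of the
#' contrast, computes `ln(area_num / area_den)`. Rows with a non-positive
#' area in either channel are excluded and logged with a reason, never
#' silently turned into NaN/Inf. A contrast not referencing channel 114 is
#' computed directly from the two areas, which equals the ratio of the two
#' 114-referenced ratios.
#'
#' @param records Validated peptide table.
#' @param contrast A [channel_contrast()].
#' @return List with `observations` (data.frame: experiment_id,
#'   protein_accession, peptide_sequence, contrast, ln_ratio) and
#'   `exclusions` (data.frame: row, protein_accession, peptide_sequence,
#'   reason).
#' @export
compute_ln_ratios <- function(records, contrast) {
  records <- validate_peptide_table(records)
  if (!inherits(contrast, "channel_contrast")) {
    stop("configuration error: 'contrast' must be a channel_contrast",
         call. = FALSE)
  }
  num <- records[[paste0("area_", contrast$numerator_channel)]]
  den <- records[[paste0("area_", contrast$denominator_channel)]]
  bad_den <- den <= 0
  bad_num <- num <= 0 & !bad_den
  ok <- !(bad_den | bad_num)

  reason <- character(0)
  rows <- which(!ok)
  if (length(rows) > 0) {
    reason <- ifelse(bad_den[rows], "nonpositive denominator",
                     "nonpositive numerator")
  }
  observations <- data.frame(
    experiment_id = records$experiment_id[ok],
    protein_accession = records$protein_accession[ok],
    peptide_sequence = records$peptide_sequence[ok],
    contrast = contrast$name,
    ln_ratio = log(num[ok] / den[ok]),
    stringsAsFactors = FALSE
  )
  exclusions <- data.frame(
    row = rows,
    protein_accession = records$protein_accession[rows],
    peptide_sequence = records$peptide_sequence[rows],
    reason = reason,
    stringsAsFactors = FALSE
  )
  list(observations = observations, exclusions = exclusions)
}

#' Histogram specification for the ratio null model
#'
#' Defaults to the null-model convention: 200 bins spanning \[-1, +1\]
#' (bin width 0.01).
#'
#' @param lower,upper Histogram range, `upper > lower`.
#' @param n_bins Number of bins, at least 10.
#' @return Object of class `histogram_spec`.
#' @export
histogram_spec <- function(lower = -1, upper = 1, n_bins = 200L) {
  n_bins <- as.integer(n_bins)
  if (!is.finite(lower) || !is.finite(upper) || upper <= lower) {
    stop("configuration error: histogram upper must exceed lower", call. = FALSE)
  }
  if (is.na(n_bins) || n_bins < 10) {
    stop("configuration error: n_bins must be at least 10", call. = FALSE)
  }
  structure(list(lower = lower, upper = upper, n_bins = n_bins,
                 bin_width = (upper - lower) / n_bins),
            class = "histogram_spec")
}

#' Build the ln-ratio histogram
#'
#' Bins are half-open `[edge_i, edge_{i+1})` with the final bin closed at
#' `upper`. Values outside `[lower, upper]` are not binned; they are counted
#' in `n_out_of_range`, so `sum(counts) + n_out_of_range` equals the number
#' of values.
#'
#' @param values Numeric vector of (finite) ln-ratios.
#' @param spec A [histogram_spec()].
#' @return List with `bin_centers`, `counts` and `n_out_of_range`.
#' @export
build_histogram <- function(values, spec = histogram_spec()) {
  stopifnot(inherits(spec, "histogram_spec"))
  if (length(values) == 0) {
    stop("cannot build a null-model histogram from an empty value list",
         call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("histogram values must be finite; exclude degenerate ratios upstream",
         call. = FALSE)
  }
  in_range <- values >= spec$lower & values <= spec$upper
  idx <- floor((values[in_range] - spec$lower) / spec$bin_width) + 1
  idx[idx > spec$n_bins] <- spec$n_bins  # upper boundary closes the last bin
  counts <- tabulate(idx, nbins = spec$n_bins)
  centers <- spec$lower + (seq_len(spec$n_bins) - 0.5) * spec$bin_width
  list(bin_centers = centers, counts = counts,
       n_out_of_range = sum(!in_range))
}

#' Savitzky-Golay smoother specification
#'
#' The smoothing window must be odd and the polynomial order smaller than
#' the window. The defaults (window 11, order 3) span 0.11 ln-units on the
#' default histogram grid: wide enough to suppress count noise, narrow
#' enough to preserve a Gaussian peak of SD 0.1-0.3.
#'
#' @param window Odd window length.
#' @param polyorder Polynomial degree, `< window`.
#' @return Object of class `smoother_spec`.
#' @export
smoother_spec <- function(window = 11L, polyorder = 3L) {
  window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  if (is.na(window) || window < 1 || window %% 2 == 0) {
    stop("configuration error: window must be a positive odd integer",
         call. = FALSE)
  }
  if (is.na(polyorder) || polyorder < 0 || polyorder >= window) {
    stop("configuration error: polyorder must be non-negative and < window",
         call. = FALSE)
  }
  structure(list(window = window, polyorder = polyorder),
            class = "smoother_spec")
}

# least-squares polynomial fit evaluated at offset 0; degree reduced if the
# window holds fewer points than degree + 1
polyfit_at_zero <- function(x, y, degree) {
  degree <- min(degree, length(x) - 1)
  A <- outer(x, 0:degree, `^`)
  beta <- qr.coef(qr(A), y)
  beta[1]
}

#' Savitzky-Golay smoothing
#'
#' Each interior point is replaced by the value, at the window centre, of
#' the least-squares polynomial of degree `polyorder` fitted to the
#' surrounding window (implemented as a convolution with the closed-form
#' least-squares weights). Near the edges the polynomial is fitted on the
#' truncated one-sided window and evaluated at the edge position. A signal
#' that is itself a polynomial of degree `<= polyorder` is reproduced
#' exactly everywhere the truncated window still supports the degree.
#'
#' @param counts Numeric signal, at least `window` long.
#' @param spec A [smoother_spec()].
#' @return Smoothed signal, same length as `counts`.
#' @export
savgol_smooth <- function(counts, spec = smoother_spec()) {
  stopifnot(inherits(spec, "smoother_spec"))
  n <- length(counts)
  if (n < spec$window) {
    stop("signal shorter than the smoothing window", call. = FALSE)
  }
  h <- (spec$window - 1L) / 2L
  x <- -h:h
  A <- outer(x, 0:spec$polyorder, `^`)
  # weights of the centre-point evaluation of the LS polynomial
  w <- solve(crossprod(A), t(A))[1, ]

  out <- numeric(n)
  if (n >= spec$window) {
    core <- (h + 1L):(n - h)
    out[core] <- vapply(core, function(i) {
      sum(w * counts[(i - h):(i + h)])
    }, 0)
  }
  for (i in seq_len(h)) {
    xs <- seq_len(i + h) - i
    out[i] <- polyfit_at_zero(xs, counts[seq_len(i + h)], spec$polyorder)
    j <- n - i + 1L
    xs <- (j - h):n - j
    out[j] <- polyfit_at_zero(xs, counts[(j - h):n], spec$polyorder)
  }
  out
}

#' Fit a Gaussian to the smoothed histogram
#'
#' Minimizes the squared residuals of `A * exp(-(x - mu)^2 / (2 sigma^2))`
#' against the smoothed counts (Levenberg-Marquardt), initialized from the
#' weighted mean and SD of the smoothed counts. If the free-centre fit
#' fails, a zero-centred two-parameter fit is retried. `sigma` is reported
#' positive; the residual sum of squares is recorded.
#'
#' @param bin_centers Bin-centre positions.
#' @param counts Smoothed counts (same length).
#' @param n_in_range,n_out_of_range Optional bookkeeping counts carried
#'   into the result.
#' @return Object of class `gaussian_null` with fields `mu`, `sigma`,
#'   `amplitude`, `rss`, `n_in_range`, `n_out_of_range`.
#' @export
fit_gaussian <- function(bin_centers, counts,
                         n_in_range = NA_integer_,
                         n_out_of_range = NA_integer_) {
  stopifnot(length(bin_centers) == length(counts))
  pos <- counts > 0
  if (sum(pos) < 5) {
    stop("fit error: fewer than 5 bins with positive counts", call. = FALSE)
  }
  if (diff(range(counts)) == 0) {
    stop("fit error: degenerate (constant) histogram counts", call. = FALSE)
  }
  w <- pmax(counts, 0)
  mu0 <- sum(w * bin_centers) / sum(w)
  sd0 <- sqrt(sum(w * (bin_centers - mu0)^2) / sum(w))
  if (!is.finite(sd0) || sd0 <= 0) sd0 <- diff(range(bin_centers)) / 10
  a0 <- max(counts)

  df <- data.frame(x = bin_centers, y = counts)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * s^2)), data = df,
                      start = list(A = a0, mu = mu0, s = sd0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-x^2 / (2 * s^2)), data = df,
                        start = list(A = a0, s = sd0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      stop("fit error: Gaussian fit did not converge (free and zero-centred)",
           call. = FALSE)
    }
    cf <- stats::coef(fit)
    cf <- c(cf["A"], mu = 0, cf["s"])
  } else {
    cf <- stats::coef(fit)
  }
  sigma <- abs(unname(cf["s"]))
  if (!is.finite(sigma) || sigma <= 0) {
    stop("fit error: fitted sigma is not positive", call. = FALSE)
  }
  structure(
    list(mu = unname(cf["mu"]),
         sigma = sigma,
         amplitude = unname(cf["A"]),
         rss = sum(stats::resid(fit)^2),
         n_in_range = as.integer(n_in_range),
         n_out_of_range = as.integer(n_out_of_range)),
    class = "gaussian_null"
  )
}

#' Fit the ratio null model from raw ln-ratios
#'
#' Convenience composition of [build_histogram()], [savgol_smooth()] and
#' [fit_gaussian()]: the full null-model estimation for one contrast in one
#' experiment. Out-of-range ln-ratios are excluded from the histogram and
#' fit but remain scorable by the fitted null.
#'
#' @param ln_ratios Finite ln-ratios.
#' @param hist_spec A [histogram_spec()].
#' @param smoother A [smoother_spec()].
#' @return A `gaussian_null` object.
#' @export
fit_ratio_null <- function(ln_ratios, hist_spec = histogram_spec(),
                           smoother = smoother_spec()) {
  h <- build_histogram(ln_ratios, hist_spec)
  smoothed <- savgol_smooth(h$counts, smoother)
  fit_gaussian(h$bin_centers, smoothed,
               n_in_range = length(ln_ratios) - h$n_out_of_range,
               n_out_of_range = h$n_out_of_range)
}

#' @export
print.gaussian_null <- function(x, ...) {
  cat(sprintf(
    "Gaussian ratio null: mu = %.4f, sigma = %.4f, amplitude = %.1f\n",
    x$mu, x$sigma, x$amplitude))
  cat(sprintf("  rss = %.3g; n in range = %s, out of range = %s\n",
              x$rss, x$n_in_range, x$n_out_of_range))
  invisible(x)
}

#' Significance-calling configuration
#'
#' `k` is the SD multiplier of the calling rule (default 2.5, a two-sided
#' confidence of 98.8%). `center_policy` selects the null centre: the
#' fitted Gaussian's `mu` (default) or 0 for sensitivity analysis.
#'
#' @param k Positive SD multiplier.
#' @param center_policy `"fitted_mu"` or `"zero"`.
#' @return Object of class `calling_config`.
#' @export
calling_config <- function(k = 2.5, center_policy = c("fitted_mu", "zero")) {
  if (!is.finite(k) || k <= 0) {
    stop("configuration error: k must be > 0", call. = FALSE)
  }
  center_policy <- match.arg(center_policy)
  structure(list(k = k, center_policy = center_policy),
            class = "calling_config")
}

null_center <- function(null, cfg) {
  if (cfg$center_policy == "zero") 0 else null$mu
}

#' Per-peptide p-value under the fitted null
#'
#' Two-sided Gaussian tail probability
#' `2 * (1 - pnorm(|ln_ratio - center| / sigma))`, monotone decreasing in
#' the deviation from the null centre. At a deviation of exactly 2.5 SD the
#' p-value is 0.0124, the complement of 98.8% confidence.
#'
#' @param ln_ratio Numeric vector of ln-ratios.
#' @param null A fitted `gaussian_null`.
#' @param cfg A [calling_config()] (supplies the centre policy).
#' @return p-values in (0, 1\].
#' @export
peptide_pvalue <- function(ln_ratio, null, cfg = calling_config()) {
  stopifnot(inherits(null, "gaussian_null"), inherits(cfg, "calling_config"))
  z <- abs(ln_ratio - null_center(null, cfg)) / null$sigma
  pmax(2 * stats::pnorm(-z), .Machine$double.xmin)
}

#' Call peptides significant at k x SD
#'
#' A peptide is significant when its ln-ratio deviates from the null centre
#' by at least `k` fitted SDs (boundary inclusive); the direction is the
#' sign of the deviation. Observations outside the histogram range are
#' scored like any other.
#'
#' @param ln_ratio Numeric vector of ln-ratios.
#' @param null A fitted `gaussian_null`.
#' @param cfg A [calling_config()].
#' @return data.frame with columns `significant` (logical) and `direction`
#'   (`"up"`, `"down"` or `"none"`).
#' @export
call_significant <- function(ln_ratio, null, cfg = calling_config()) {
  stopifnot(inherits(null, "gaussian_null"), inherits(cfg, "calling_config"))
  dev <- ln_ratio - null_center(null, cfg)
  significant <- abs(dev) >= cfg$k * null$sigma
  direction <- ifelse(!significant, "none", ifelse(dev > 0, "up", "down"))
  data.frame(significant = significant, direction = direction,
             stringsAsFactors = FALSE)
}
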