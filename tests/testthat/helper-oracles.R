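# Independent oracles: brute-force enumerations and per-window polynomial
# fits, deliberately written on a different route than the package code.

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
oracle_signed_rank_p <- function(diffs) {
  diffs <- diffs[diffs != 0]
  n <- length(diffs)
  r <- rank(abs(diffs))
  w_obs <- sum(r[diffs > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  lower <- mean(w_all <= w_obs + 1e-9)
  upper <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# exact two-sided rank-sum p by enumerating all choose(n1+n2, n1) subsets
oracle_rank_sum_p <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  subsets <- utils::combn(length(pooled), n1)
  w_all <- apply(subsets, 2, function(idx) sum(r[idx]))
  lower <- mean(w_all <= w_obs + 1e-9)
  upper <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# Savitzky-Golay oracle: explicit lm() polynomial fit per window, truncated
# one-sided at the edges, evaluated at the point position
oracle_savgol <- function(y, window, polyorder) {
  n <- length(y)
  h <- (window - 1) / 2
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - h)
    hi <- min(n, i + h)
    x <- (lo:hi) - i
    deg <- min(polyorder, length(x) - 1)
    fit <- stats::lm(y[lo:hi] ~ stats::poly(x, deg, raw = TRUE))
    unname(stats::predict(fit, newdata = data.frame(x = 0)))
  }, 0)
}

# minimal well-formed peptide table for I/O and filter tests
make_peptide_table <- function(n = 3, experiment_id = "exp1") {
  data.frame(
    experiment_id = experiment_id,
    protein_accession = paste0("P", rep(seq_len(ceiling(n / 2)), each = 2))[seq_len(n)],
    peptide_sequence = paste0("PEPTIDE", LETTERS[seq_len(n)], "K"),
    confidence_pct = rep(c(96, 97, 99), length.out = n),
    area_114 = 1000 + seq_len(n),
    area_115 = 1100 + seq_len(n),
    area_116 = 900 + seq_len(n),
    area_117 = 1050 + seq_len(n),
    stringsAsFactors = FALSE
  )
}
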