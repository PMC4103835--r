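# Synthetic iTRAQ 4-plex generator with known ground truth: pooled groups on
# channels 114-117, duplicate experiments sharing the same truth, Gaussian
# ln-ratio technical noise.

#' Simulation configuration
#'
#' Defines a synthetic 4-plex reporter-ion experiment. Each protein gets a
#' peptide count drawn from a shifted Poisson (minimum 1, mean
#' `peptides_per_protein_mean`). Reporter areas are a shared log-normal
#' peptide abundance times independent per-channel multiplicative noise with
#' ln-SD `null_sigma / sqrt(2)`, so the ln-ratio of any two channels has SD
#' `null_sigma`. A fraction `de_fraction` of proteins is truly changed: the
#' numerator channel of `effect_contrast` is scaled by
#' `exp(±effect_ln_fc)`, the sign drawn Rademacher(1/2) per protein.
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param peptides_per_protein_mean Mean peptides per protein (>= 1).
#' @param de_fraction Fraction of truly changed proteins, in \[0, 1\].
#' @param effect_ln_fc Magnitude of the true ln fold-change (> 0).
#' @param null_sigma SD of peptide-level ln-ratio technical noise (> 0).
#' @param base_area_ln_mean,base_area_ln_sd Log-normal parameters of the
#'   baseline reporter area (arbitrary units).
#' @param confidence_range Interval in (0, 100] from which simulated
#'   identification confidences are drawn uniformly.
#' @param effect_contrast Name of the channel contrast ("num/den") whose
#'   numerator channel carries the abundance change of changed proteins.
#' @param dropout_rate Probability that one random channel area of a peptide
#'   is zeroed (off by default; exercises degenerate-input handling).
#' @param seed Master seed; per-experiment noise streams are derived from it.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_proteins = 1000L,
                              peptides_per_protein_mean = 4,
                              de_fraction = 0.05,
                              effect_ln_fc = 1.0,
                              null_sigma = 0.15,
                              base_area_ln_mean = log(5000),
                              base_area_ln_sd = 1.0,
                              confidence_range = c(95, 99.9),
                              effect_contrast = "115/114",
                              dropout_rate = 0,
                              seed = 1L) {
  fail <- function(field, why) {
    stop(sprintf("configuration error in '%s': %s", field, why), call. = FALSE)
  }
  n_proteins <- as.integer(n_proteins)
  if (is.na(n_proteins) || n_proteins < 1) fail("n_proteins", "must be >= 1")
  if (!is.finite(peptides_per_protein_mean) || peptides_per_protein_mean < 1)
    fail("peptides_per_protein_mean", "must be >= 1")
  if (!is.finite(de_fraction) || de_fraction < 0 || de_fraction > 1)
    fail("de_fraction", "must lie in [0, 1]")
  if (!is.finite(effect_ln_fc) || effect_ln_fc <= 0)
    fail("effect_ln_fc", "must be > 0")
  if (!is.finite(null_sigma) || null_sigma <= 0)
    fail("null_sigma", "must be > 0")
  if (!is.finite(base_area_ln_sd) || base_area_ln_sd < 0)
    fail("base_area_ln_sd", "must be >= 0")
  if (length(confidence_range) != 2 || any(!is.finite(confidence_range)) ||
      confidence_range[1] <= 0 || confidence_range[2] > 100 ||
      confidence_range[1] > confidence_range[2])
    fail("confidence_range", "must be an interval within (0, 100]")
  if (!is.finite(dropout_rate) || dropout_rate < 0 || dropout_rate > 1)
    fail("dropout_rate", "must lie in [0, 1]")
  ec <- strsplit(effect_contrast, "/", fixed = TRUE)[[1]]
  if (length(ec) != 2 || !all(ec %in% as.character(ITRAQ_CHANNELS)) ||
      ec[1] == ec[2])
    fail("effect_contrast", "must be 'num/den' with distinct channels in 114-117")
  seed <- as.integer(seed)
  if (is.na(seed)) fail("seed", "must be an integer")
  structure(
    list(n_proteins = n_proteins,
         peptides_per_protein_mean = peptides_per_protein_mean,
         de_fraction = de_fraction,
         effect_ln_fc = effect_ln_fc,
         null_sigma = null_sigma,
         base_area_ln_mean = base_area_ln_mean,
         base_area_ln_sd = base_area_ln_sd,
         confidence_range = confidence_range,
         effect_contrast = effect_contrast,
         effect_channel = as.integer(ec[1]),
         dropout_rate = dropout_rate,
         seed = seed),
    class = "simulation_config"
  )
}

# deterministic sub-stream seed, kept within 32-bit integer range
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(as.double(seed)) * 48271 + h * 1009 + 12345) %% 2147483647)
}

# protein/peptide structure and ground truth shared by duplicate experiments
simulate_structure <- function(config) {
  set.seed(derive_seed(config$seed, "structure"))
  n <- config$n_proteins
  accession <- sprintf("SYN%05d", seq_len(n))
  n_peptides <- 1L + stats::rpois(n, config$peptides_per_protein_mean - 1)
  is_changed <- stats::runif(n) < config$de_fraction
  sign <- ifelse(stats::runif(n) < 0.5, -1, 1)
  true_ln_fc <- ifelse(is_changed, sign * config$effect_ln_fc, 0)

  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  sequences <- lapply(n_peptides, function(k) {
    s <- vapply(seq_len(k), function(i) {
      paste(sample(aa, sample(8:18, 1), replace = TRUE), collapse = "")
    }, "")
    while (anyDuplicated(s)) {
      dup <- which(duplicated(s))
      s[dup] <- vapply(dup, function(i) {
        paste(sample(aa, sample(8:18, 1), replace = TRUE), collapse = "")
      }, "")
    }
    s
  })

  truth <- data.frame(
    protein_accession = accession,
    is_changed = is_changed,
    true_ln_fc = true_ln_fc,
    contrast = config$effect_contrast,
    n_peptides = n_peptides,
    stringsAsFactors = FALSE
  )
  list(truth = truth, sequences = sequences)
}

#' Generate one synthetic iTRAQ experiment
#'
#' Produces a peptide quantification table plus the ground-truth table. The
#' protein/peptide structure and truth depend only on `config` (so duplicate
#' experiments share them); reporter-area noise and identification
#' confidences are drawn from a stream derived from `config$seed` and
#' `experiment_id`. Identical `(config, experiment_id)` give bit-identical
#' output.
#'
#' @param config A [simulation_config()].
#' @param experiment_id Identifier written into the table's
#'   `experiment_id` column and used to derive the noise stream.
#' @return List with `table` (peptide quantification data.frame) and
#'   `truth` (one row per protein: accession, is_changed, true_ln_fc,
#'   contrast, n_peptides).
#' @export
generate_experiment <- function(config, experiment_id = "exp1") {
  stopifnot(inherits(config, "simulation_config"))
  structure_ <- simulate_structure(config)
  truth <- structure_$truth

  set.seed(derive_seed(config$seed, paste0("noise:", experiment_id)))
  n_pep <- truth$n_peptides
  total <- sum(n_pep)
  prot_idx <- rep.int(seq_len(config$n_proteins), n_pep)

  base <- exp(stats::rnorm(total, config$base_area_ln_mean,
                           config$base_area_ln_sd))
  chan_sd <- config$null_sigma / sqrt(2)
  areas <- matrix(exp(stats::rnorm(total * 4L, 0, chan_sd)),
                  nrow = total, ncol = 4L) * base
  colnames(areas) <- paste0("area_", ITRAQ_CHANNELS)

  # abundance change on the effect channel for truly changed proteins
  eff_col <- match(paste0("area_", config$effect_channel), colnames(areas))
  areas[, eff_col] <- areas[, eff_col] * exp(truth$true_ln_fc[prot_idx])

  if (config$dropout_rate > 0) {
    hit <- stats::runif(total) < config$dropout_rate
    ch <- sample.int(4L, total, replace = TRUE)
    areas[cbind(which(hit), ch[hit])] <- 0
  }

  confidence <- stats::runif(total, config$confidence_range[1],
                             config$confidence_range[2])

  table <- data.frame(
    experiment_id = experiment_id,
    protein_accession = truth$protein_accession[prot_idx],
    peptide_sequence = unlist(structure_$sequences, use.names = FALSE),
    confidence_pct = confidence,
    stringsAsFactors = FALSE
  )
  table <- cbind(table, as.data.frame(areas))
  list(table = validate_peptide_table(table), truth = truth)
}

#' Generate a duplicate pair of synthetic experiments
#'
#' Both experiments share the same ground truth (same changed proteins, same
#' true ln fold-changes, same peptide structure) but independent technical
#' noise, emulating an iTRAQ experiment repeated with the same set of pooled
#' samples.
#'
#' @param config A [simulation_config()].
#' @param experiment_ids Two identifiers, default `c("exp1", "exp2")`.
#' @return List with `exp1`, `exp2` (peptide tables) and the shared `truth`.
#' @export
generate_replicate_pair <- function(config,
                                    experiment_ids = c("exp1", "exp2")) {
  stopifnot(inherits(config, "simulation_config"),
            length(experiment_ids) == 2,
            experiment_ids[1] != experiment_ids[2])
  a <- generate_experiment(config, experiment_ids[1])
  b <- generate_experiment(config, experiment_ids[2])
  list(exp1 = a$table, exp2 = b$table, truth = a$truth)
}

#' Write a simulated experiment to disk
#'
#' Writes the peptide table via [write_peptide_table()] and the truth as a
#' sidecar TSV next to it (suffix `.truth.tsv`).
#'
#' @param experiment Result of [generate_experiment()].
#' @param path Output path for the peptide table.
#' @return Character vector of the two paths written, invisibly.
#' @export
write_experiment <- function(experiment, path) {
  write_peptide_table(experiment$table, path)
  truth_path <- sub("\\.tsv$", "", path)
  truth_path <- paste0(truth_path, ".truth.tsv")
  utils::write.table(experiment$truth, truth_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(path, truth_path))
}
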