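# Peptide-to-protein rollup: median discriminatory-peptide ratios, k x SD
# calls, duplicate-experiment concordance and candidate selection.

#' Score ratio observations under a fitted null
#'
#' Attaches the per-peptide significance call, direction and p-value to a
#' set of ratio observations.
#'
#' @param observations Ratio observations from [compute_ln_ratios()].
#' @param null A fitted `gaussian_null` for the same contrast/experiment.
#' @param cfg A [calling_config()].
#' @return The observations with `significant`, `direction` and `p_value`
#'   columns appended.
#' @export
score_peptides <- function(observations, null, cfg = calling_config()) {
  calls <- call_significant(observations$ln_ratio, null, cfg)
  observations$significant <- calls$significant
  observations$direction <- calls$direction
  observations$p_value <- peptide_pvalue(observations$ln_ratio, null, cfg)
  observations
}

#' Aggregate scored peptides of one protein
#'
#' Protein-level result for one contrast: the median ratio of the
#' discriminatory peptides only, computed on the ln scale and
#' exponentiated (even count: mean of the two central ln-ratios, i.e. the
#' geometric mean of the two central ratios), the dominant direction among discriminatory
#' peptides as the call, and peptide counts. With no discriminatory peptide
#' the call is `"none"` and the median ratio is absent (NA) — the
#' aggregation never invents a ratio. An exact direction tie yields call
#' `"none"` with a conflict note. A single discriminatory peptide is
#' reported but flagged.
#'
#' @param obs Scored observations (see [score_peptides()]) sharing one
#'   accession and one contrast.
#' @return One-row data.frame with the protein result fields.
#' @export
aggregate_protein <- function(obs) {
  if (nrow(obs) == 0) {
    stop("cannot aggregate an empty observation set", call. = FALSE)
  }
  if (length(unique(obs$protein_accession)) != 1 ||
      length(unique(obs$contrast)) != 1) {
    stop("aggregate_protein expects observations of a single protein and contrast",
         call. = FALSE)
  }
  disc <- obs[obs$significant, , drop = FALSE]
  n_disc <- nrow(disc)
  note <- ""
  if (n_disc == 0) {
    call <- "none"
    median_ratio <- NA_real_
  } else {
    n_up <- sum(disc$direction == "up")
    n_down <- n_disc - n_up
    if (n_up == n_down) {
      call <- "none"
      note <- "conflict"
    } else {
      call <- if (n_up > n_down) "up" else "down"
    }
    median_ratio <- exp(stats::median(disc$ln_ratio))
  }
  data.frame(
    protein_accession = obs$protein_accession[1],
    contrast = obs$contrast[1],
    experiment_id = obs$experiment_id[1],
    median_ratio = median_ratio,
    n_peptides_total = nrow(obs),
    n_peptides_discriminatory = n_disc,
    min_peptide_p = min(obs$p_value),
    call = call,
    single_peptide_flag = n_disc == 1L,
    note = note,
    stringsAsFactors = FALSE
  )
}

#' Aggregate all proteins of one scored observation set
#'
#' @param scored Scored observations for one contrast and experiment.
#' @return data.frame with one row per protein (see [aggregate_protein()]),
#'   ordered by accession.
#' @export
aggregate_proteins <- function(scored) {
  if (nrow(scored) == 0) {
    stop("cannot aggregate an empty observation set", call. = FALSE)
  }
  parts <- split(scored, scored$protein_accession)
  out <- do.call(rbind, lapply(parts, aggregate_protein))
  rownames(out) <- NULL
  out[order(out$protein_accession), , drop = FALSE]
}

#' Duplicate-experiment concordance
#'
#' Retains proteins called significantly changed (call not `"none"`) in the
#' same direction in both experiments, per contrast. Symmetric in argument
#' order.
#'
#' @param results_exp1,results_exp2 Protein result tables from
#'   [aggregate_proteins()] computed with the same contrasts.
#' @return data.frame of concordant proteins with both experiments' fields
#'   (suffixes `_exp1`, `_exp2`) and the shared `call`.
#' @export
replicate_overlap <- function(results_exp1, results_exp2) {
  c1 <- sort(unique(results_exp1$contrast))
  c2 <- sort(unique(results_exp2$contrast))
  if (!identical(c1, c2)) {
    stop("configuration error: experiments were quantified with different contrasts",
         call. = FALSE)
  }
  m <- merge(results_exp1, results_exp2,
             by = c("protein_accession", "contrast"),
             suffixes = c("_exp1", "_exp2"))
  keep <- m$call_exp1 != "none" & m$call_exp2 != "none" &
    m$call_exp1 == m$call_exp2
  m <- m[keep, , drop = FALSE]
  m$call <- m$call_exp1
  m <- m[order(m$protein_accession, m$contrast), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Candidate-selection criteria
#'
#' Defaults encode the selection rules for differential proteins:
#' significance in the same direction in both duplicate experiments, and at
#' least 2 peptides with p-value strictly below 0.02 in each experiment.
#' (The third, biological-function criterion is a manual judgement and is
#' carried only as a free-text annotation.)
#'
#' @param require_both_experiments Require the peptide p-value rule in both
#'   experiments (default) or in at least one.
#' @param min_discriminatory_peptides Minimum peptides below `max_peptide_p`.
#' @param max_peptide_p Peptide p-value threshold (strict inequality).
#' @return Object of class `selection_criteria`.
#' @export
selection_criteria <- function(require_both_experiments = TRUE,
                               min_discriminatory_peptides = 2L,
                               max_peptide_p = 0.02) {
  if (!is.finite(max_peptide_p) || max_peptide_p <= 0 || max_peptide_p >= 1) {
    stop("configuration error: max_peptide_p must lie in (0, 1)", call. = FALSE)
  }
  min_discriminatory_peptides <- as.integer(min_discriminatory_peptides)
  if (is.na(min_discriminatory_peptides) || min_discriminatory_peptides < 1) {
    stop("configuration error: min_discriminatory_peptides must be >= 1",
         call. = FALSE)
  }
  structure(
    list(require_both_experiments = isTRUE(require_both_experiments),
         min_discriminatory_peptides = min_discriminatory_peptides,
         max_peptide_p = max_peptide_p),
    class = "selection_criteria"
  )
}

count_peptides_below <- function(scored, accession, contrast_name, p_max) {
  sum(scored$protein_accession == accession &
        scored$contrast == contrast_name &
        scored$p_value < p_max)
}

#' Select differential-protein candidates
#'
#' Applies the peptide-count criterion to the concordant proteins: a
#' candidate needs at least `min_discriminatory_peptides` peptides with
#' p-value strictly below `max_peptide_p` in each experiment (or in at
#' least one when `require_both_experiments` is FALSE). Emits a selection
#' log stating, per concordant protein, which criterion failed.
#'
#' @param concordant Output of [replicate_overlap()].
#' @param criteria A [selection_criteria()].
#' @param scored_exp1,scored_exp2 Scored peptide observations (all
#'   contrasts) of the two experiments, supplying the peptide p-values.
#' @return List with `candidates` (subset of `concordant` plus the
#'   per-experiment significant-peptide counts and an empty `annotation`
#'   column) and `log` (data.frame: protein, contrast, selected, reason).
#' @export
select_candidates <- function(concordant, criteria = selection_criteria(),
                              scored_exp1, scored_exp2) {
  stopifnot(inherits(criteria, "selection_criteria"))
  n <- nrow(concordant)
  n1 <- integer(n)
  n2 <- integer(n)
  for (i in seq_len(n)) {
    n1[i] <- count_peptides_below(scored_exp1,
                                  concordant$protein_accession[i],
                                  concordant$contrast[i],
                                  criteria$max_peptide_p)
    n2[i] <- count_peptides_below(scored_exp2,
                                  concordant$protein_accession[i],
                                  concordant$contrast[i],
                                  criteria$max_peptide_p)
  }
  need <- criteria$min_discriminatory_peptides
  pass <- if (criteria$require_both_experiments) {
    n1 >= need & n2 >= need
  } else {
    n1 >= need | n2 >= need
  }
  reason <- ifelse(pass, "selected",
                   sprintf("fewer than %d peptides with p < %.3g (exp1: %d, exp2: %d)",
                           need, criteria$max_peptide_p, n1, n2))
  log <- data.frame(
    protein_accession = concordant$protein_accession,
    contrast = concordant$contrast,
    selected = pass,
    reason = reason,
    stringsAsFactors = FALSE
  )
  candidates <- concordant[pass, , drop = FALSE]
  candidates$n_significant_peptides_exp1 <- n1[pass]
  candidates$n_significant_peptides_exp2 <- n2[pass]
  candidates$annotation <- character(nrow(candidates))
  rownames(candidates) <- NULL
  list(candidates = candidates, log = log)
}
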