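# End-to-end orchestration: filter -> ln-ratios -> null fit -> calls ->
# protein rollup -> duplicate concordance -> candidate selection, with
# per-stage logs and a reproducible run manifest.

#' Run the full quantification pipeline on duplicate experiments
#'
#' For each experiment table: applies the identification filter, computes
#' ln-ratios per contrast, fits the Gaussian ratio null (one per contrast
#' per experiment), scores and calls peptides, and aggregates to protein
#' results. With two experiments, duplicate concordance and candidate
#' selection are applied. Deterministic given inputs and configuration;
#' every dropped row appears in exactly one log with a reason.
#'
#' @param tables Named list of one or two validated peptide tables (or
#'   paths to TSV files readable by [read_peptide_table()]).
#' @param contrasts Named list of [channel_contrast()] objects; defaults to
#'   [default_contrasts()].
#' @param filter An [identification_filter()].
#' @param hist_spec A [histogram_spec()].
#' @param smoother A [smoother_spec()].
#' @param calling A [calling_config()].
#' @param criteria A [selection_criteria()].
#' @return Object of class `quant_bundle`: per-experiment/contrast null
#'   fits, scored observations, protein results, concordant overlap,
#'   candidates, logs and a run manifest.
#' @export
run_quantification <- function(tables,
                               contrasts = default_contrasts(),
                               filter = identification_filter(),
                               hist_spec = histogram_spec(),
                               smoother = smoother_spec(),
                               calling = calling_config(),
                               criteria = selection_criteria()) {
  if (!is.list(tables) || length(tables) < 1 || length(tables) > 2) {
    stop("configuration error: 'tables' must be a list of one or two peptide tables",
         call. = FALSE)
  }
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    names(tables) <- paste0("exp", seq_along(tables))
  }
  tables <- lapply(tables, function(t) {
    if (is.character(t)) read_peptide_table(t) else validate_peptide_table(t)
  })
  if (length(contrasts) == 0) {
    stop("configuration error: no contrasts supplied", call. = FALSE)
  }

  nulls <- list()
  scored <- list()
  protein_results <- list()
  filter_logs <- list()
  exclusion_logs <- list()
  conservation <- list()

  for (exp_name in names(tables)) {
    tab <- tables[[exp_name]]
    flt <- filter_identifications(tab, filter)
    filter_logs[[exp_name]] <- flt$rejections
    retained <- flt$retained

    exp_scored <- list()
    exp_results <- list()
    for (cname in names(contrasts)) {
      lr <- compute_ln_ratios(retained, contrasts[[cname]])
      exclusion_logs[[paste(exp_name, cname, sep = ":")]] <- lr$exclusions
      null <- fit_ratio_null(lr$observations$ln_ratio, hist_spec, smoother)
      nulls[[exp_name]][[cname]] <- null
      sc <- score_peptides(lr$observations, null, calling)
      exp_scored[[cname]] <- sc
      exp_results[[cname]] <- aggregate_proteins(sc)
      conservation[[paste(exp_name, cname, sep = ":")]] <- data.frame(
        experiment_id = exp_name, contrast = cname,
        n_input_peptides = nrow(tab),
        n_filtered = nrow(flt$rejections),
        n_excluded = nrow(lr$exclusions),
        n_used = nrow(sc),
        stringsAsFactors = FALSE
      )
    }
    scored[[exp_name]] <- do.call(rbind, exp_scored)
    rownames(scored[[exp_name]]) <- NULL
    protein_results[[exp_name]] <- do.call(rbind, exp_results)
    rownames(protein_results[[exp_name]]) <- NULL
  }

  overlap <- NULL
  candidates <- NULL
  selection_log <- NULL
  if (length(tables) == 2) {
    en <- names(tables)
    overlap <- replicate_overlap(protein_results[[en[1]]],
                                 protein_results[[en[2]]])
    sel <- select_candidates(overlap, criteria,
                             scored[[en[1]]], scored[[en[2]]])
    candidates <- sel$candidates
    selection_log <- sel$log
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("itraqde")),
    experiments = names(tables),
    contrasts = names(contrasts),
    filter = unclass(filter),
    hist_spec = unclass(hist_spec),
    smoother = unclass(smoother),
    calling = unclass(calling),
    criteria = unclass(criteria)
  )

  structure(
    list(nulls = nulls,
         scored = scored,
         protein_results = protein_results,
         overlap = overlap,
         candidates = candidates,
         logs = list(filter = filter_logs,
                     exclusions = exclusion_logs,
                     selection = selection_log,
                     conservation = do.call(rbind, unname(conservation))),
         manifest = manifest),
    class = "quant_bundle"
  )
}

#' Write a quantification bundle to a directory
#'
#' Protein results, candidates, logs and the manifest as TSV/YAML text
#' files.
#'
#' @param bundle A `quant_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(bundle, dir) {
  stopifnot(inherits(bundle, "quant_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  all_results <- do.call(rbind, unname(bundle$protein_results))
  wt(all_results, "protein_results.tsv")
  if (!is.null(bundle$candidates)) wt(bundle$candidates, "candidates.tsv")
  if (!is.null(bundle$logs$selection)) wt(bundle$logs$selection, "selection_log.tsv")
  wt(bundle$logs$conservation, "conservation.tsv")
  yaml::write_yaml(bundle$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Render a human-readable report of a quantification bundle
#'
#' Per-contrast median ratios per protein and experiment, with the
#' non-significant marker ("sigma < k") for proteins whose peptides did not
#' reach significance and a footnote marker (*) for single-peptide results,
#' followed by the null-fit diagnostics and the candidate list.
#'
#' @param bundle A complete `quant_bundle`.
#' @return Character vector of report lines (also printable via `cat`).
#' @export
run_report <- function(bundle) {
  if (!inherits(bundle, "quant_bundle")) {
    stop("run_report expects a quant_bundle", call. = FALSE)
  }
  required <- c("nulls", "protein_results", "logs", "manifest")
  missing_parts <- required[vapply(required, function(f) is.null(bundle[[f]]), TRUE)]
  if (length(missing_parts) > 0) {
    stop("incomplete bundle; missing: ",
         paste(missing_parts, collapse = ", "), call. = FALSE)
  }
  k <- bundle$manifest$calling$k
  fmt_cell <- function(row) {
    if (row$call == "none") return(sprintf("sigma <%.1f", k))
    paste0(sprintf("%.2f", row$median_ratio),
           if (row$single_peptide_flag) "*" else "")
  }
  lines <- c("Differential-protein quantification report",
             strrep("=", 43), "")
  for (exp_name in names(bundle$protein_results)) {
    res <- bundle$protein_results[[exp_name]]
    lines <- c(lines, sprintf("Experiment %s", exp_name))
    for (cname in unique(res$contrast)) {
      sub <- res[res$contrast == cname, , drop = FALSE]
      called <- sub[sub$call != "none", , drop = FALSE]
      lines <- c(lines, sprintf("  Contrast %s: %d proteins, %d called",
                                cname, nrow(sub), nrow(called)))
      for (i in seq_len(nrow(called))) {
        lines <- c(lines, sprintf("    %s  %s (%s, %d/%d peptides)",
                                  called$protein_accession[i],
                                  fmt_cell(called[i, ]),
                                  called$call[i],
                                  called$n_peptides_discriminatory[i],
                                  called$n_peptides_total[i]))
      }
      null <- bundle$nulls[[exp_name]][[cname]]
      lines <- c(lines, sprintf(
        "    null fit: mu = %.4f, sigma = %.4f, rss = %.3g, out of range = %d",
        null$mu, null$sigma, null$rss, null$n_out_of_range))
    }
    lines <- c(lines, "")
  }
  if (!is.null(bundle$candidates)) {
    n_cand <- nrow(bundle$candidates)
    lines <- c(lines, sprintf("Concordant duplicate candidates: %d", n_cand))
    for (i in seq_len(n_cand)) {
      ci <- bundle$candidates[i, ]
      lines <- c(lines, sprintf(
        "  %s [%s] %s: median ratio %.2f / %.2f%s",
        ci$protein_accession, ci$contrast, ci$call,
        ci$median_ratio_exp1, ci$median_ratio_exp2,
        if (ci$single_peptide_flag_exp1 || ci$single_peptide_flag_exp2) " *" else ""))
    }
    if (n_cand == 0) lines <- c(lines, "  (zero candidates)")
  }
  lines
}

#' @export
print.quant_bundle <- function(x, ...) {
  cat(run_report(x), sep = "\n")
  invisible(x)
}
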