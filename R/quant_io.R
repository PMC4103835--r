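# Reading, writing and identification-level filtering of peptide
# quantification tables (one row per identified peptide, four reporter-ion
# areas for channels 114-117).

PEPTIDE_TABLE_COLUMNS <- c(
  "experiment_id", "protein_accession", "peptide_sequence",
  "confidence_pct", "area_114", "area_115", "area_116", "area_117"
)
ITRAQ_CHANNELS <- c(114L, 115L, 116L, 117L)

#' Validate a peptide quantification table
#'
#' Checks the schema and row-level invariants of a peptide quantification
#' table: the eight canonical columns, confidence in (0, 100], non-negative
#' reporter areas, and non-empty accession/sequence strings.
#'
#' @param records data.frame of peptide records.
#' @return The validated data.frame (columns reordered canonically),
#'   invisibly usable downstream.
#' @export
validate_peptide_table <- function(records) {
  if (!is.data.frame(records)) {
    stop("peptide table must be a data.frame", call. = FALSE)
  }
  missing_cols <- setdiff(PEPTIDE_TABLE_COLUMNS, names(records))
  if (length(missing_cols) > 0) {
    stop("peptide table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- records[, PEPTIDE_TABLE_COLUMNS, drop = FALSE]
  num_cols <- c("confidence_pct", paste0("area_", ITRAQ_CHANNELS))
  for (col in num_cols) {
    v <- records[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0) {
        stop(sprintf("validation error: malformed numeric in column '%s' at row %d",
                     col, bad[1]), call. = FALSE)
      }
      v <- vn
      records[[col]] <- v
    }
    if (anyNA(v)) {
      stop(sprintf("validation error: missing value in column '%s' at row %d",
                   col, which(is.na(v))[1]), call. = FALSE)
    }
  }
  bad_conf <- which(records$confidence_pct <= 0 | records$confidence_pct > 100)
  if (length(bad_conf) > 0) {
    stop(sprintf("validation error: confidence_pct outside (0,100] at row %d",
                 bad_conf[1]), call. = FALSE)
  }
  for (ch in ITRAQ_CHANNELS) {
    col <- paste0("area_", ch)
    bad <- which(records[[col]] < 0)
    if (length(bad) > 0) {
      stop(sprintf("validation error: negative area in column '%s' at row %d",
                   col, bad[1]), call. = FALSE)
    }
  }
  for (col in c("protein_accession", "peptide_sequence", "experiment_id")) {
    records[[col]] <- as.character(records[[col]])
    bad <- which(is.na(records[[col]]) | !nzchar(records[[col]]))
    if (length(bad) > 0) {
      stop(sprintf("validation error: empty '%s' at row %d", col, bad[1]),
           call. = FALSE)
    }
  }
  records
}

#' Read a peptide quantification table
#'
#' Reads a tab-separated peptide quantification table (header row with the
#' canonical column names `experiment_id`, `protein_accession`,
#' `peptide_sequence`, `confidence_pct`, `area_114` ... `area_117`) and
#' validates every row. Malformed numerics and negative areas are rejected
#' with the offending row number; a missing column is a schema error naming
#' the column.
#'
#' @param path Path to the TSV file.
#' @param sep Field separator, tab by default.
#' @return A validated data.frame, one row per peptide, row order preserved.
#' @export
read_peptide_table <- function(path, sep = "\t") {
  if (!file.exists(path)) {
    stop("peptide table file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  validate_peptide_table(raw)
}

#' Write a peptide quantification table
#'
#' Writes the canonical tab-separated representation; `read_peptide_table()`
#' on the written file reproduces the records (within decimal text
#' representation of the numeric columns).
#'
#' @param records Validated peptide table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(records, path) {
  records <- validate_peptide_table(records)
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Convert identification confidence to ProtScore
#'
#' ProteinPilot-style identification score: `-log10(1 - confidence/100)`.
#' A 95% peptide confidence corresponds to the score cutoff 1.3.
#'
#' @param confidence_pct Confidence percentage, strictly between 0 and 100.
#' @return The score, strictly increasing in confidence.
#' @seealso [protscore_to_confidence()]
#' @export
confidence_to_protscore <- function(confidence_pct) {
  if (any(!is.finite(confidence_pct)) ||
      any(confidence_pct <= 0) || any(confidence_pct >= 100)) {
    stop("confidence_pct must lie strictly in (0, 100); the score is unbounded at 100",
         call. = FALSE)
  }
  -log10(1 - confidence_pct / 100)
}

#' Convert ProtScore back to confidence percentage
#'
#' @param protscore Positive identification score.
#' @return Confidence percentage in (0, 100).
#' @export
protscore_to_confidence <- function(protscore) {
  if (any(!is.finite(protscore)) || any(protscore <= 0)) {
    stop("protscore must be a positive finite number", call. = FALSE)
  }
  100 * (1 - 10^(-protscore))
}

#' Identification filter configuration
#'
#' Defaults follow the conventional ProteinPilot acceptance rules: peptide
#' score cutoff 1.3 (95% confidence) and protein identifications supported
#' by at least 2 unique peptides. When both `min_protscore` and
#' `min_confidence_pct` are supplied they must agree through
#' `confidence_to_protscore()` within 0.005.
#'
#' @param min_protscore Minimum peptide identification score.
#' @param min_confidence_pct Minimum peptide confidence percentage.
#' @param min_unique_peptides Minimum distinct peptide sequences per protein.
#' @return An object of class `identification_filter`.
#' @export
identification_filter <- function(min_protscore = 1.3,
                                  min_confidence_pct = 95,
                                  min_unique_peptides = 2L) {
  if (!is.null(min_protscore) && !is.null(min_confidence_pct)) {
    implied <- confidence_to_protscore(min_confidence_pct)
    if (abs(implied - min_protscore) > 0.005) {
      stop(sprintf(
        "inconsistent filter: min_confidence_pct %.4g implies protscore %.4f, got %.4f",
        min_confidence_pct, implied, min_protscore), call. = FALSE)
    }
  }
  if (is.null(min_confidence_pct)) {
    min_confidence_pct <- protscore_to_confidence(min_protscore)
  }
  if (is.null(min_protscore)) {
    min_protscore <- confidence_to_protscore(min_confidence_pct)
  }
  min_unique_peptides <- as.integer(min_unique_peptides)
  if (is.na(min_unique_peptides) || min_unique_peptides < 1) {
    stop("min_unique_peptides must be a positive integer", call. = FALSE)
  }
  structure(
    list(min_protscore = min_protscore,
         min_confidence_pct = min_confidence_pct,
         min_unique_peptides = min_unique_peptides),
    class = "identification_filter"
  )
}

#' Filter peptide identifications
#'
#' Two rules applied in sequence: (1) peptide confidence must reach
#' `min_confidence_pct`; (2) among the peptides that survive rule 1, a
#' protein must retain at least `min_unique_peptides` distinct sequences
#' (uppercased; modifications are not modelled) or all its peptides are
#' dropped. Every dropped row is logged with the rule that removed it.
#' The operation is idempotent.
#'
#' @param records Validated peptide table.
#' @param filter An [identification_filter()].
#' @return List with `retained` (peptide table) and `rejections`
#'   (data.frame: row, protein_accession, peptide_sequence, rule).
#' @export
filter_identifications <- function(records, filter = identification_filter()) {
  records <- validate_peptide_table(records)
  stopifnot(inherits(filter, "identification_filter"))
  n <- nrow(records)
  rule <- rep(NA_character_, n)

  low_conf <- records$confidence_pct < filter$min_confidence_pct
  rule[low_conf] <- "confidence"

  # unique-peptide count per (experiment, protein) among confidence survivors
  keep <- !low_conf
  if (any(keep)) {
    key <- paste(records$experiment_id, records$protein_accession, sep = "\r")
    seqs <- toupper(records$peptide_sequence)
    surv_key <- key[keep]
    n_unique <- tapply(seqs[keep], surv_key,
                       function(s) length(unique(s)))
    under <- names(n_unique)[n_unique < filter$min_unique_peptides]
    drop_protein <- keep & key %in% under
    rule[drop_protein] <- "min_unique_peptides"
  }

  rejected <- !is.na(rule)
  rejections <- data.frame(
    row = which(rejected),
    protein_accession = records$protein_accession[rejected],
    peptide_sequence = records$peptide_sequence[rejected],
    rule = rule[rejected],
    stringsAsFactors = FALSE
  )
  list(retained = records[!rejected, , drop = FALSE],
       rejections = rejections)
}

#' Define a channel contrast
#'
#' A named ratio of two iTRAQ reporter channels, numerator over denominator.
#' In the 4-plex design emulated here, channels 114-117 carry pooled
#' non-susceptible-after, non-susceptible-baseline, susceptible-after and
#' susceptible-baseline samples respectively, so e.g. `114/115` is the
#' non-susceptible after/before-smoking contrast.
#'
#' @param name Contrast identifier; defaults to "num/den".
#' @param numerator_channel,denominator_channel One of 114, 115, 116, 117;
#'   must differ.
#' @param meaning Free-text label.
#' @return An object of class `channel_contrast`.
#' @export
channel_contrast <- function(numerator_channel, denominator_channel,
                             name = NULL, meaning = "") {
  numerator_channel <- as.integer(numerator_channel)
  denominator_channel <- as.integer(denominator_channel)
  if (!numerator_channel %in% ITRAQ_CHANNELS ||
      !denominator_channel %in% ITRAQ_CHANNELS) {
    stop("channels must be one of 114, 115, 116, 117", call. = FALSE)
  }
  if (numerator_channel == denominator_channel) {
    stop("numerator and denominator channel must differ", call. = FALSE)
  }
  if (is.null(name)) {
    name <- paste0(numerator_channel, "/", denominator_channel)
  }
  structure(
    list(name = name,
         numerator_channel = numerator_channel,
         denominator_channel = denominator_channel,
         meaning = meaning),
    class = "channel_contrast"
  )
}

#' Default contrasts of the duplicate 4-plex design
#'
#' The four contrasts of interest in the emulated study design:
#' after/before smoking within each pooled group, and between-group
#' contrasts after smoking and at baseline.
#'
#' @return Named list of [channel_contrast()] objects.
#' @export
default_contrasts <- function() {
  cs <- list(
    channel_contrast(114, 115, meaning = "non-susceptible after/before smoking"),
    channel_contrast(116, 117, meaning = "susceptible after/before smoking"),
    channel_contrast(116, 114, meaning = "susceptible vs non-susceptible, after smoking"),
    channel_contrast(117, 115, meaning = "susceptible vs non-susceptible, baseline")
  )
  stats::setNames(cs, vapply(cs, `[[`, "", "name"))
}

#' Read a contrast configuration file
#'
#' YAML (or JSON, a YAML subset) file with a top-level `contrasts` list,
#' each entry holding `numerator_channel`, `denominator_channel` and
#' optionally `name` and `meaning`.
#'
#' @param path Config file path.
#' @return Named list of [channel_contrast()] objects.
#' @export
read_contrasts <- function(path) {
  cfg <- yaml::read_yaml(path)
  entries <- if (!is.null(cfg$contrasts)) cfg$contrasts else cfg
  if (length(entries) == 0) {
    stop("configuration error: no contrasts defined in ", path, call. = FALSE)
  }
  cs <- lapply(entries, function(e) {
    if (is.null(e$numerator_channel) || is.null(e$denominator_channel)) {
      stop("configuration error: contrast entry lacks numerator/denominator channel",
           call. = FALSE)
    }
    channel_contrast(e$numerator_channel, e$denominator_channel,
                     name = e$name,
                     meaning = if (is.null(e$meaning)) "" else e$meaning)
  })
  stats::setNames(cs, vapply(cs, `[[`, "", "name"))
}

#' @export
print.channel_contrast <- function(x, ...) {
  cat(sprintf("Channel contrast '%s': %d / %d%s\n", x$name,
              x$numerator_channel, x$denominator_channel,
              if (nzchar(x$meaning)) paste0("  (", x$meaning, ")") else ""))
  invisible(x)
}
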