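#' @keywords internal
"_PACKAGE"

## Shared constants and validators for the two table-shaped domain types:
## mutation tables (one amino-acid substitution per row, optionally labelled)
## and prediction tables (one tool call per row).

#' Standard amino-acid one-letter codes
#'
#' The 20 standard residues, alphabetical by one-letter code.
#'
#' @format Character vector of length 20.
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

MUTATION_LABELS <- c("neutral", "deleterious", "unknown")
PREDICTION_CLASSES <- c("neutral", "deleterious", "missing")
SCORE_KINDS <- c("continuous", "categorical")

MUTATION_COLS <- c("protein_id", "position", "wt_aa", "mut_aa", "label", "source")
PREDICTION_COLS <- c("protein_id", "position", "wt_aa", "mut_aa",
                     "tool", "predicted_class", "raw_confidence", "score_kind")

#' Mutation key
#'
#' The identity of a substitution is the exact tuple
#' (protein_id, position, wt_aa, mut_aa); protein identity is by
#' identifier, never by sequence content.
#'
#' @param x Data frame with columns `protein_id`, `position`, `wt_aa`, `mut_aa`.
#' @return Character vector of keys, one per row.
#' @export
mutation_key <- function(x) {
  paste(x$protein_id, x$position, x$wt_aa, x$mut_aa, sep = "|")
}

#' Construct a validated mutation table
#'
#' @param protein_id Character protein identifiers.
#' @param position Integer 1-based residue positions.
#' @param wt_aa,mut_aa One-letter wild-type and mutant residue codes.
#' @param label Functional label: `"neutral"`, `"deleterious"` or `"unknown"`.
#' @param source Free-text dataset tag.
#' @return A `data.frame` with the six mutation-table columns.
#' @export
mutation_table <- function(protein_id, position, wt_aa, mut_aa,
                           label = "unknown", source = "") {
  df <- data.frame(protein_id = as.character(protein_id),
                   position = as.integer(position),
                   wt_aa = as.character(wt_aa),
                   mut_aa = as.character(mut_aa),
                   label = as.character(label),
                   source = as.character(source),
                   stringsAsFactors = FALSE)
  validate_mutations(df)
}

#' Validate a mutation table
#'
#' Checks the record invariants: positions are integers >= 1, residues are
#' standard one-letter codes, the mutant residue differs from the wild type,
#' labels are known, and (when sequences are supplied) the residue found at
#' `position` equals `wt_aa`. Violations are reported with the offending
#' row numbers.
#'
#' @param df Mutation table.
#' @param sequences Optional named character vector or `AAStringSet` of
#'   protein sequences used to cross-check wild-type residues.
#' @return `df`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_mutations <- function(df, sequences = NULL) {
  miss <- setdiff(setdiff(MUTATION_COLS, c("label", "source")), names(df))
  if (length(miss) > 0) {
    stop("mutation table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"label" %in% names(df)) df$label <- "unknown"
  if (!"source" %in% names(df)) df$source <- ""
  df <- df[, MUTATION_COLS, drop = FALSE]
  df$position <- suppressWarnings(as.integer(df$position))

  bad_row <- function(what, idx) {
    if (any(idx)) {
      stop("invalid mutation record(s) at row(s) ",
           paste(utils::head(which(idx), 10), collapse = ", "),
           ": ", what, call. = FALSE)
    }
  }
  bad_row("position does not parse as an integer", is.na(df$position))
  bad_row("position must be >= 1", df$position < 1)
  bad_row("wt_aa is not a standard one-letter code", !(df$wt_aa %in% AA_STANDARD))
  bad_row("mut_aa is not a standard one-letter code", !(df$mut_aa %in% AA_STANDARD))
  bad_row("wt_aa equals mut_aa", df$wt_aa == df$mut_aa)
  bad_row("unknown label", !(df$label %in% MUTATION_LABELS))

  if (!is.null(sequences)) {
    seqs <- stats::setNames(as.character(sequences), names(sequences))
    have <- df$protein_id %in% names(seqs)
    if (any(have)) {
      at <- which(have)
      res <- substr(seqs[df$protein_id[at]], df$position[at], df$position[at])
      mism <- res != df$wt_aa[at]
      if (any(mism)) {
        stop("wild-type residue mismatch against sequence at row(s) ",
             paste(utils::head(at[mism], 10), collapse = ", "), call. = FALSE)
      }
    }
  }
  df
}

validate_predictions <- function(df) {
  miss <- setdiff(PREDICTION_COLS, names(df))
  if (length(miss) > 0) {
    stop("prediction table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- df[, PREDICTION_COLS, drop = FALSE]
  df$position <- suppressWarnings(as.integer(df$position))
  df$raw_confidence <- as.character(df$raw_confidence)

  ## empty class and empty score both encode a missing prediction
  blank_class <- is.na(df$predicted_class) | df$predicted_class == ""
  df$predicted_class[blank_class] <- "missing"
  blank_conf <- is.na(df$raw_confidence) | df$raw_confidence == ""
  df$raw_confidence[blank_conf] <- NA_character_

  coerced <- coerce_pph1(df$predicted_class, df$raw_confidence)
  df$predicted_class <- coerced$predicted_class
  df$raw_confidence <- coerced$raw_confidence

  bad <- !(df$predicted_class %in% PREDICTION_CLASSES)
  if (any(bad)) {
    stop("unknown predicted_class token(s) at row(s) ",
         paste(utils::head(which(bad), 10), collapse = ", "), ": ",
         paste(unique(df$predicted_class[bad]), collapse = ", "), call. = FALSE)
  }
  bad <- !(df$score_kind %in% SCORE_KINDS)
  if (any(bad)) {
    stop("unknown score_kind at row(s) ",
         paste(utils::head(which(bad), 10), collapse = ", "), call. = FALSE)
  }

  ## missing class <=> absent confidence
  inconsistent <- (df$predicted_class == "missing") != is.na(df$raw_confidence)
  if (any(inconsistent)) {
    stop("predicted_class/raw_confidence inconsistency at row(s) ",
         paste(utils::head(which(inconsistent), 10), collapse = ", "),
         " (missing predictions must have an absent score, and vice versa)",
         call. = FALSE)
  }

  ## score_kind is a property of the tool, constant across the table
  kinds <- tapply(df$score_kind, df$tool, function(k) length(unique(k)))
  if (any(kinds > 1)) {
    stop("tool(s) with mixed score_kind: ",
         paste(names(kinds)[kinds > 1], collapse = ", "), call. = FALSE)
  }
  df
}
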