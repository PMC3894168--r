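## Readers and writers for the tab-separated interchange tables, FASTA
## sequences, and the persisted calibration model (JSON).

read_tsv_strict <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE,
                    na.strings = NULL)
}

write_tsv_strict <- function(df, path, sep = "\t") {
  out <- df
  out[] <- lapply(out, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- ""
    col
  })
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a mutation table
#'
#' Reads a delimited text table with a mandatory header naming at least
#' `protein_id`, `position`, `wt_aa`, `mut_aa`; the `label` and `source`
#' columns are optional (absent labels become `"unknown"`). Rows violating
#' the record invariants are rejected with their row numbers.
#'
#' @param path Path to the table.
#' @param sep Field delimiter (default tab).
#' @param sequences Optional sequences for wild-type residue checking,
#'   see [validate_mutations()].
#' @return A validated mutation table (`data.frame`).
#' @export
read_mutation_table <- function(path, sep = "\t", sequences = NULL) {
  df <- read_tsv_strict(path, sep)
  validate_mutations(df, sequences = sequences)
}

#' Write a mutation table
#'
#' Inverse of [read_mutation_table()]; writing then re-reading a valid
#' table reproduces it byte-identically.
#'
#' @param df Mutation table.
#' @param path Output path.
#' @param sep Field delimiter.
#' @export
write_mutation_table <- function(df, path, sep = "\t") {
  write_tsv_strict(validate_mutations(df), path, sep)
}

#' Read a tool-prediction table
#'
#' Columns: mutation key columns plus `tool`, `predicted_class`,
#' `raw_confidence`, `score_kind`. A row with an empty class and empty
#' score encodes a missing prediction. The possibly-deleterious class of
#' PolyPhen-1-style tools is coerced at parse time (see [coerce_pph1()]),
#' so downstream code only ever sees the two classes plus `missing`.
#' A tool reporting both continuous and categorical scores in one table
#' is a format error.
#'
#' @param path Path to the table.
#' @param sep Field delimiter.
#' @return A validated prediction table (`data.frame`); `raw_confidence`
#'   is kept as character so that categorical tokens and continuous values
#'   share one column (continuous values are converted at calibration time).
#' @export
read_prediction_table <- function(path, sep = "\t") {
  validate_predictions(read_tsv_strict(path, sep))
}

#' Write a tool-prediction table
#'
#' @param df Prediction table.
#' @param path Output path.
#' @param sep Field delimiter.
#' @export
write_prediction_table <- function(df, path, sep = "\t") {
  write_tsv_strict(validate_predictions(df), path, sep)
}

#' Coerce the three-class possibly-deleterious call to two classes
#'
#' Tools in the PolyPhen-1 mould report a third class, "possibly
#' deleterious", treated here as a deleterious call carrying the reserved
#' categorical confidence token `"possibly_deleterious"`, whose calibrated
#' observed accuracy is pinned at 0.5 by [fit_categorical()]. Plain
#' neutral/deleterious/missing calls pass through untouched.
#'
#' @param predicted_class Character vector of class tokens.
#' @param raw_confidence Matching raw confidence tokens.
#' @return List with coerced `predicted_class` and `raw_confidence`.
#' @export
coerce_pph1 <- function(predicted_class, raw_confidence) {
  cls <- tolower(trimws(predicted_class))
  cls[cls %in% c("possibly deleterious", "possibly_deleterious")] <- "possibly_deleterious"
  known <- c(PREDICTION_CLASSES, "possibly_deleterious")
  bad <- !(cls %in% known)
  if (any(bad)) {
    stop("unknown class token(s): ",
         paste(unique(predicted_class[bad]), collapse = ", "), call. = FALSE)
  }
  poss <- cls == "possibly_deleterious"
  cls[poss] <- "deleterious"
  raw_confidence[poss] <- "possibly_deleterious"
  list(predicted_class = cls, raw_confidence = raw_confidence)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of amino-acid sequences (names are the
#'   first whitespace-delimited token of each description line).
#' @export
read_protein_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

CALIBRATION_SCHEMA_VERSION <- 1L

#' Persist a calibration model to JSON
#'
#' The model document carries a schema version, the binning parameters,
#' and one entry per (tool, predicted class): either a category map of
#' observed accuracies or an ordered binned curve. Numeric values are
#' serialized at 17 significant digits so that [load_calibration()]
#' reproduces the model exactly.
#'
#' @param model A `calibration_model`.
#' @param path Output path.
#' @export
persist_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  doc <- list(
    schema_version = CALIBRATION_SCHEMA_VERSION,
    n_bins = model$spec$n_bins,
    smooth_window = model$spec$smooth_window,
    min_per_bin = model$spec$min_per_bin,
    entries = lapply(model$entries, function(e) {
      out <- list(tool = e$tool, predicted_class = e$predicted_class,
                  kind = e$kind)
      if (e$kind == "categorical") {
        out$categories <- as.list(e$categories)
      } else {
        out$curve <- list(representative = e$curve$representative,
                          accuracy = e$curve$accuracy,
                          raw_accuracy = e$curve$raw_accuracy,
                          n = e$curve$n)
      }
      out$n_records <- e$n_records
      out
    })
  )
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17)), path)
  invisible(path)
}

#' Load a calibration model from JSON
#'
#' @param path Path written by [persist_calibration()].
#' @return A `calibration_model`.
#' @export
load_calibration <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path, call. = FALSE)
  doc <- tryCatch(jsonlite::fromJSON(readLines(path, warn = FALSE),
                                     simplifyVector = FALSE),
                  error = function(e) {
                    stop("cannot parse calibration file '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (is.null(doc$schema_version) || doc$schema_version != CALIBRATION_SCHEMA_VERSION) {
    stop("unsupported calibration schema version in ", path, call. = FALSE)
  }
  entries <- lapply(doc$entries, function(e) {
    out <- list(tool = e$tool, predicted_class = e$predicted_class,
                kind = e$kind)
    if (e$kind == "categorical") {
      out$categories <- unlist(e$categories)
    } else {
      out$curve <- data.frame(
        representative = as.numeric(unlist(e$curve$representative)),
        accuracy = as.numeric(unlist(e$curve$accuracy)),
        raw_accuracy = as.numeric(unlist(e$curve$raw_accuracy)),
        n = as.integer(unlist(e$curve$n)))
    }
    out$n_records <- as.integer(e$n_records)
    out
  })
  names(entries) <- vapply(entries, function(e) {
    paste(e$tool, e$predicted_class, sep = "::")
  }, character(1))
  new_calibration_model(
    entries,
    bin_spec(n_bins = as.integer(doc$n_bins),
             smooth_window = as.integer(doc$smooth_window),
             min_per_bin = as.integer(doc$min_per_bin)))
}
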