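## Calibration of raw tool confidences to observed accuracy.
##
## Continuous scores: records in one (tool, predicted class) stratum are
## sorted by raw confidence, split into equal-count bins, the per-bin
## fraction correct is smoothed by a centered moving average, and the
## resulting (representative confidence, smoothed accuracy) curve is later
## evaluated by piecewise-linear interpolation with end clamping.
## Categorical scores: observed accuracy is the exact per-category fraction
## correct. Both are fitted separately per predicted class, because the
## confidence/accuracy relationship differs between neutral and deleterious
## calls.

#' Binning specification for continuous calibration
#'
#' @param n_bins Number of equal-count bins (default 60).
#' @param smooth_window Width of the centered moving-average window in bins;
#'   odd, default 5. The window truncates at the curve ends.
#' @param min_per_bin Minimum records per bin; with fewer than
#'   `n_bins * min_per_bin` records in a stratum the bin count is reduced to
#'   `floor(n / min_per_bin)` (at least 1) so the fit never fails on small
#'   strata.
#' @return A `bin_spec` object.
#' @export
bin_spec <- function(n_bins = 60L, smooth_window = 5L, min_per_bin = 5L) {
  n_bins <- as.integer(n_bins)
  smooth_window <- as.integer(smooth_window)
  min_per_bin <- as.integer(min_per_bin)
  stopifnot(n_bins >= 1L, smooth_window >= 1L, min_per_bin >= 1L)
  if (smooth_window %% 2L == 0L) {
    stop("smooth_window must be odd", call. = FALSE)
  }
  structure(list(n_bins = n_bins, smooth_window = smooth_window,
                 min_per_bin = min_per_bin),
            class = "bin_spec")
}

new_calibration_model <- function(entries, spec) {
  structure(list(entries = entries, spec = spec), class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("calibration model:", length(x$entries), "entries;",
      x$spec$n_bins, "bins, smoothing window", x$spec$smooth_window, "\n")
  for (e in x$entries) {
    cat(sprintf("  %-12s %-11s %-11s n=%d\n",
                e$tool, e$predicted_class, e$kind, e$n_records))
  }
  invisible(x)
}

entry_key <- function(tool, predicted_class) paste(tool, predicted_class, sep = "::")

## Accuracy of a categorical confidence token is its empirical fraction
## correct, except the reserved possibly-deleterious token which is pinned
## at 0.5 by construction of that class.
fit_categorical_entry <- function(tool, predicted_class, tokens, correct) {
  by_cat <- tapply(correct, tokens, mean)
  acc <- stats::setNames(as.numeric(by_cat), names(by_cat))
  acc <- acc[order(names(acc))]
  acc[names(acc) == "possibly_deleterious"] <- 0.5
  list(tool = tool, predicted_class = predicted_class, kind = "categorical",
       categories = acc, n_records = length(tokens))
}

fit_continuous_entry <- function(tool, predicted_class, raw, correct, keys, spec) {
  n <- length(raw)
  if (any(is.na(raw))) {
    stop("non-numeric raw_confidence for continuous tool '", tool, "'",
         call. = FALSE)
  }
  b <- max(1L, min(spec$n_bins, n %/% spec$min_per_bin))
  ord <- order(raw, keys)       # stable: mutation key breaks confidence ties
  raw <- raw[ord]
  correct <- correct[ord]

  base <- n %/% b
  r <- n %% b
  sizes <- rep(base, b) + as.integer(seq_len(b) <= r)
  bin <- rep(seq_len(b), times = sizes)

  rep_conf <- as.numeric(tapply(raw, bin, mean))
  raw_acc <- as.numeric(tapply(correct, bin, mean))

  h <- (spec$smooth_window - 1L) %/% 2L
  smoothed <- vapply(seq_len(b), function(i) {
    mean(raw_acc[max(1L, i - h):min(b, i + h)])
  }, numeric(1))

  curve <- data.frame(representative = rep_conf, accuracy = smoothed,
                      raw_accuracy = raw_acc, n = sizes)
  ## heavy raw-score ties can equalize neighbouring representatives; merge
  ## such bins (record-weighted) so the curve x-values stay strictly increasing
  if (anyDuplicated(curve$representative)) {
    curve <- do.call(rbind, lapply(split(curve, curve$representative), function(g) {
      data.frame(representative = g$representative[1],
                 accuracy = stats::weighted.mean(g$accuracy, g$n),
                 raw_accuracy = stats::weighted.mean(g$raw_accuracy, g$n),
                 n = sum(g$n))
    }))
    curve <- curve[order(curve$representative), , drop = FALSE]
  }
  rownames(curve) <- NULL
  list(tool = tool, predicted_class = predicted_class, kind = "continuous",
       curve = curve, n_records = n)
}

join_correct <- function(predictions, mutations) {
  labels <- mutations$label[match(mutation_key(predictions), mutation_key(mutations))]
  keep <- predictions$predicted_class != "missing" &
    !is.na(labels) & labels != "unknown"
  df <- predictions[keep, , drop = FALSE]
  df$label <- labels[keep]
  df$correct <- df$predicted_class == df$label
  df$key <- mutation_key(df)
  df
}

#' Fit per-category observed accuracy for one tool
#'
#' Observed accuracy of a category is the number of correct predictions
#' over the number of all predictions carrying that category, computed
#' separately within each predicted-class stratum.
#'
#' @param predictions Prediction table restricted to one categorical tool.
#' @param mutations Labelled mutation table supplying the ground truth.
#' @return A `calibration_model` holding one entry per predicted class
#'   present in the data.
#' @export
fit_categorical <- function(predictions, mutations) {
  fit_calibration(predictions, mutations)
}

#' Fit the binned confidence-to-accuracy curve for one continuous tool
#'
#' @param predictions Prediction table restricted to one continuous tool.
#' @param mutations Labelled mutation table.
#' @param spec A [bin_spec()].
#' @return A `calibration_model` with one curve entry per predicted class.
#' @export
fit_continuous <- function(predictions, mutations, spec = bin_spec()) {
  fit_calibration(predictions, mutations, spec)
}

#' Fit calibration for every tool in a prediction table
#'
#' Dispatches on each tool's `score_kind` and fits one entry per
#' (tool, predicted class) pair that occurs among labelled, non-missing
#' predictions.
#'
#' @param predictions Prediction table (any number of tools).
#' @param mutations Labelled mutation table.
#' @param spec A [bin_spec()] governing continuous fits.
#' @return A `calibration_model`.
#' @export
fit_calibration <- function(predictions, mutations, spec = bin_spec()) {
  predictions <- validate_predictions(predictions)
  df <- join_correct(predictions, mutations)
  if (nrow(df) == 0) {
    stop("no labelled, non-missing predictions to fit on", call. = FALSE)
  }
  entries <- list()
  for (tl in sort(unique(df$tool))) {
    sub <- df[df$tool == tl, , drop = FALSE]
    kind <- sub$score_kind[1]
    for (cls in c("neutral", "deleterious")) {
      st <- sub[sub$predicted_class == cls, , drop = FALSE]
      if (nrow(st) == 0) next
      entry <- if (kind == "categorical") {
        fit_categorical_entry(tl, cls, st$raw_confidence, st$correct)
      } else {
        fit_continuous_entry(tl, cls,
                             suppressWarnings(as.numeric(st$raw_confidence)),
                             st$correct, st$key, spec)
      }
      entries[[entry_key(tl, cls)]] <- entry
    }
  }
  new_calibration_model(entries, spec)
}

#' Calibrate raw confidences to observed accuracy
#'
#' Categorical entries are exact lookups; continuous entries interpolate
#' piecewise-linearly between consecutive (representative confidence,
#' smoothed accuracy) bin pairs and clamp to the first/last bin value
#' outside the fitted range.
#'
#' @param model A `calibration_model`.
#' @param tool Tool identifier.
#' @param predicted_class `"neutral"` or `"deleterious"`.
#' @param raw_confidence Numeric vector (continuous tools) or character
#'   tokens (categorical tools).
#' @return Numeric vector of calibrated observed accuracies in \[0, 1\].
#' @export
transform_confidence <- function(model, tool, predicted_class, raw_confidence) {
  stopifnot(inherits(model, "calibration_model"))
  e <- model$entries[[entry_key(tool, predicted_class)]]
  if (is.null(e)) {
    stop("no calibration entry for tool '", tool, "', class '",
         predicted_class, "'", call. = FALSE)
  }
  if (e$kind == "categorical") {
    idx <- match(as.character(raw_confidence), names(e$categories))
    if (anyNA(idx)) {
      stop("unknown confidence categor",
           if (sum(is.na(idx)) > 1) "ies" else "y",
           " for tool '", tool, "': ",
           paste(unique(raw_confidence[is.na(idx)]), collapse = ", "),
           call. = FALSE)
    }
    return(unname(e$categories[idx]))
  }
  raw <- suppressWarnings(as.numeric(raw_confidence))
  if (anyNA(raw)) {
    stop("non-numeric raw confidence for continuous tool '", tool, "'",
         call. = FALSE)
  }
  crv <- e$curve
  if (nrow(crv) == 1L) return(rep(crv$accuracy, length(raw)))
  stats::approx(crv$representative, crv$accuracy, xout = raw,
                rule = 2, ties = "ordered")$y
}

#' Calibrate the consensus score's own confidence
#'
#' The absolute consensus score is treated as the raw confidence of a
#' pseudo-tool `"consensus"` and put through the identical per-class
#' binning and smoothing procedure on a labelled benchmark, yielding the
#' mapping from |score| to the consensus classifier's observed accuracy.
#'
#' @param results Consensus results (see [predict_consensus()]) with
#'   `score` and `predicted_class` columns plus the mutation key columns.
#' @param mutations Labelled mutation table.
#' @param spec A [bin_spec()].
#' @return A `calibration_model` whose entries belong to tool
#'   `"consensus"`.
#' @export
fit_consensus_calibration <- function(results, mutations, spec = bin_spec()) {
  stopifnot(all(c("score", "predicted_class") %in% names(results)))
  pseudo <- data.frame(protein_id = results$protein_id,
                       position = results$position,
                       wt_aa = results$wt_aa,
                       mut_aa = results$mut_aa,
                       tool = "consensus",
                       predicted_class = results$predicted_class,
                       raw_confidence = format(abs(results$score), digits = 17,
                                               scientific = FALSE, trim = TRUE),
                       score_kind = "continuous",
                       stringsAsFactors = FALSE)
  fit_calibration(pseudo, mutations, spec)
}
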