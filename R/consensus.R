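## The weighted majority-vote consensus: each reporting tool contributes
## its calibrated confidence C_i in [0, 1] signed by its class call
## (+1 deleterious, -1 neutral); the consensus score is the mean signed
## confidence over the N tools that returned a prediction, so it lies in
## [-1, +1]. Scores <= 0 call neutral, > 0 call deleterious; |score| is the
## consensus classifier's own raw confidence.

#' Sign of a class call
#'
#' @param predicted_class `"deleterious"` (+1) or `"neutral"` (-1);
#'   missing predictions must be filtered out by the caller.
#' @return Integer vector of +1/-1.
#' @export
prediction_sign <- function(predicted_class) {
  s <- ifelse(predicted_class == "deleterious", 1L,
              ifelse(predicted_class == "neutral", -1L, NA_integer_))
  if (anyNA(s)) {
    stop("prediction_sign is defined only for neutral/deleterious calls",
         call. = FALSE)
  }
  s
}

#' Consensus score from per-tool contributions
#'
#' @param signs Integer vector of +1/-1 class signs, one per reporting tool.
#' @param confidences Calibrated confidences in \[0, 1\], same length.
#' @return `sum(confidences * signs) / N` with `N = length(signs)`,
#'   a score in \[-1, +1\].
#' @export
consensus_score <- function(signs, confidences) {
  if (length(signs) == 0) {
    stop("no non-missing tool predictions: consensus score undefined",
         call. = FALSE)
  }
  stopifnot(length(signs) == length(confidences),
            all(signs %in% c(-1L, 1L)))
  if (any(confidences < 0 | confidences > 1)) {
    stop("calibrated confidences must lie in [0, 1]", call. = FALSE)
  }
  sum(confidences * signs) / length(signs)
}

#' Class call from a consensus score
#'
#' The neutral decision interval is closed at zero: scores in \[-1, 0\]
#' call neutral and scores in (0, +1\] call deleterious.
#'
#' @param score Numeric consensus scores in \[-1, +1\].
#' @return Character vector of `"neutral"` / `"deleterious"`.
#' @export
classify_score <- function(score) {
  if (any(score < -1 - 1e-12 | score > 1 + 1e-12)) {
    stop("consensus scores must lie in [-1, +1]", call. = FALSE)
  }
  ifelse(score > 0, "deleterious", "neutral")
}

#' Consensus prediction for every mutation in a prediction table
#'
#' Composes calibration, signing, scoring and classification: for each
#' mutation the non-missing tool calls are calibrated through `model`,
#' averaged with their signs into the consensus score, classified, and
#' (when `consensus_model` is supplied) |score| is calibrated to the
#' consensus classifier's observed accuracy for the called class.
#'
#' @param predictions Prediction table covering one or more tools.
#' @param model `calibration_model` with entries for every (tool, class)
#'   encountered.
#' @param consensus_model Optional `calibration_model` holding the
#'   `"consensus"` pseudo-tool entries (see [fit_consensus_calibration()]);
#'   without it `consensus_confidence` is `NA`.
#' @return A `data.frame` with one row per mutation: the key columns,
#'   `score`, `predicted_class`, `consensus_confidence`, `n_tools_used`,
#'   and per-tool `<tool>_class` / `<tool>_confidence` contribution columns
#'   (`NA` where the tool was missing).
#' @export
predict_consensus <- function(predictions, model, consensus_model = NULL) {
  predictions <- validate_predictions(predictions)
  predictions$key <- mutation_key(predictions)
  tools <- sort(unique(predictions$tool))

  ## calibrate all non-missing calls up front, per (tool, class) stratum
  predictions$confidence <- NA_real_
  for (tl in tools) {
    for (cls in c("neutral", "deleterious")) {
      idx <- which(predictions$tool == tl & predictions$predicted_class == cls)
      if (length(idx) == 0) next
      predictions$confidence[idx] <-
        transform_confidence(model, tl, cls, predictions$raw_confidence[idx])
    }
  }

  keys <- unique(predictions$key)
  first <- predictions[match(keys, predictions$key), c("protein_id", "position", "wt_aa", "mut_aa")]
  avail <- predictions$predicted_class != "missing"
  none <- !(keys %in% predictions$key[avail])
  if (any(none)) {
    stop("no non-missing tool prediction for mutation(s): ",
         paste(utils::head(keys[none], 5), collapse = "; "), call. = FALSE)
  }

  sub <- predictions[avail, , drop = FALSE]
  signs <- prediction_sign(sub$predicted_class)
  signed <- signs * sub$confidence
  grp <- factor(sub$key, levels = keys)
  n_used <- as.integer(tapply(signed, grp, length))
  score <- as.numeric(tapply(signed, grp, sum)) / n_used
  cls <- classify_score(score)

  res <- data.frame(first, score = score, predicted_class = cls,
                    consensus_confidence = NA_real_,
                    n_tools_used = n_used,
                    stringsAsFactors = FALSE, row.names = NULL)

  if (!is.null(consensus_model)) {
    for (ccls in unique(cls)) {
      idx <- which(cls == ccls)
      res$consensus_confidence[idx] <-
        transform_confidence(consensus_model, "consensus", ccls, abs(score[idx]))
    }
  }

  for (tl in tools) {
    rows <- predictions[predictions$tool == tl, , drop = FALSE]
    m <- match(keys, rows$key)
    tcls <- rows$predicted_class[m]
    tcls[!is.na(tcls) & tcls == "missing"] <- NA_character_
    res[[paste0(tl, "_class")]] <- tcls
    res[[paste0(tl, "_confidence")]] <- rows$confidence[m]
  }
  res
}

#' Keep the most confident fraction of consensus results
#'
#' Coverage-restricted prediction: returns the `ceiling(fraction * n)`
#' results with the largest absolute consensus score (the consensus
#' classifier's confidence), ties broken by mutation key for determinism.
#'
#' @param results Consensus results from [predict_consensus()].
#' @param fraction Fraction of results to keep, in (0, 1\].
#' @return The selected subset, in decreasing |score| order.
#' @export
select_top_confident <- function(results, fraction) {
  stopifnot(is.numeric(fraction), length(fraction) == 1,
            fraction > 0, fraction <= 1)
  n <- nrow(results)
  if (n == 0) return(results)
  k <- ceiling(fraction * n)
  ord <- order(-abs(results$score), mutation_key(results))
  out <- results[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}
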