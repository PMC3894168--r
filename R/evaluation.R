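## Evaluation metrics. Because benchmark class proportions are arbitrary,
## headline metrics are computed on a class-normalized confusion matrix in
## which both true classes carry equal mass: normalized accuracy is then
## the balanced accuracy and MCC is computed from the reweighted counts.
## The deleterious class is the positive class throughout. AUC is the
## mid-rank Mann-Whitney statistic and is unaffected by the class
## reweighting, so it is computed once from the raw scores.

#' Fraction of mutations with any prediction
#'
#' @param predictions Prediction table (optionally restricted to one tool
#'   via `tool`) or consensus results (every row counts as predicted).
#' @param mutations Mutation table defining the denominator.
#' @param tool Optional tool identifier to restrict `predictions` to.
#' @return Fraction in \[0, 1\].
#' @export
coverage <- function(predictions, mutations, tool = NULL) {
  if (nrow(mutations) == 0) stop("empty mutation set", call. = FALSE)
  if (!is.null(tool)) {
    predictions <- predictions[predictions$tool == tool, , drop = FALSE]
  }
  if ("predicted_class" %in% names(predictions)) {
    predictions <- predictions[predictions$predicted_class != "missing", , drop = FALSE]
  }
  mean(mutation_key(mutations) %in% mutation_key(predictions))
}

#' Confusion matrix with deleterious as the positive class
#'
#' @param predicted Character vector of predicted classes.
#' @param truth Matching true labels (`"neutral"`/`"deleterious"`).
#' @return A `confusion_matrix`: list with fields `tp`, `tn`, `fp`, `fn`
#'   (reals, so that normalization can reweight them).
#' @export
confusion_matrix <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  keep <- truth %in% c("neutral", "deleterious") &
    predicted %in% c("neutral", "deleterious")
  p <- predicted[keep]
  t <- truth[keep]
  cm <- list(tp = sum(p == "deleterious" & t == "deleterious"),
             tn = sum(p == "neutral" & t == "neutral"),
             fp = sum(p == "deleterious" & t == "neutral"),
             fn = sum(p == "neutral" & t == "deleterious"))
  structure(lapply(cm, as.numeric), class = "confusion_matrix")
}

cm_total <- function(cm) cm$tp + cm$tn + cm$fp + cm$fn

#' Reweight a confusion matrix to equal true-class mass
#'
#' Each true-class row is rescaled so the deleterious row (tp + fn) and the
#' neutral row (tn + fp) each sum to half the original total. Sensitivity
#' and specificity are unchanged; accuracy of the result equals
#' (sensitivity + specificity) / 2.
#'
#' @param cm A `confusion_matrix`.
#' @return The normalized `confusion_matrix`.
#' @export
normalize_confusion <- function(cm) {
  pos <- cm$tp + cm$fn
  neg <- cm$tn + cm$fp
  if (pos == 0 || neg == 0) {
    stop("cannot normalize: a true class is absent", call. = FALSE)
  }
  half <- cm_total(cm) / 2
  structure(list(tp = cm$tp * half / pos, tn = cm$tn * half / neg,
                 fp = cm$fp * half / neg, fn = cm$fn * half / pos),
            class = "confusion_matrix")
}

#' Accuracy of a confusion matrix
#'
#' @param cm A `confusion_matrix` (normalize first for the class-balanced
#'   version).
#' @return `(tp + tn) / total`.
#' @export
cm_accuracy <- function(cm) {
  total <- cm_total(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  (cm$tp + cm$tn) / total
}

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`; 0 by convention
#' when any marginal factor vanishes.
#'
#' @param cm A `confusion_matrix`.
#' @return MCC in \[-1, 1\].
#' @export
cm_mcc <- function(cm) {
  if (cm_total(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  denom2 <- (cm$tp + cm$fp) * (cm$tp + cm$fn) * (cm$tn + cm$fp) * (cm$tn + cm$fn)
  if (denom2 == 0) return(0)
  (cm$tp * cm$tn - cm$fp * cm$fn) / sqrt(denom2)
}

#' ROC curve and AUC by mid-ranks
#'
#' Higher score must mean more deleterious. AUC is the Mann-Whitney
#' statistic P(score_pos > score_neg) + 0.5 P(tie), computed from
#' mid-ranks; the ROC curve is emitted at every distinct threshold and its
#' trapezoidal area equals the AUC.
#'
#' @param scores Numeric scores, one per mutation.
#' @param labels Matching true labels (`"neutral"`/`"deleterious"`).
#' @return List with `auc` and `roc`, a `data.frame` of
#'   (`threshold`, `fpr`, `tpr`) rows from (Inf, 0, 0) to (min score, 1, 1).
#' @export
roc_auc <- function(scores, labels) {
  keep <- labels %in% c("neutral", "deleterious") & !is.na(scores)
  scores <- scores[keep]
  labels <- labels[keep]
  pos <- labels == "deleterious"
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  cum_tp <- cumsum(pos[ord])
  cum_fp <- cumsum(!pos[ord])
  last <- which(c(s[-1] != s[-length(s)], TRUE))  # last index of each distinct score
  roc <- data.frame(threshold = c(Inf, s[last]),
                    fpr = c(0, cum_fp[last] / n_neg),
                    tpr = c(0, cum_tp[last] / n_pos),
                    row.names = NULL)
  list(auc = auc, roc = roc)
}

#' Agreement between two tools' class calls
#'
#' Phi coefficient (Pearson correlation of the two binary vectors,
#' deleterious = 1) over the mutations both tools evaluated.
#'
#' @param predictions Prediction table containing both tools.
#' @param tool_a,tool_b Tool identifiers.
#' @return Phi in \[-1, 1\], or `NA` (with a warning) when a tool is
#'   constant on the shared set.
#' @export
pairwise_tool_correlation <- function(predictions, tool_a, tool_b) {
  a <- predictions[predictions$tool == tool_a &
                     predictions$predicted_class != "missing", , drop = FALSE]
  b <- predictions[predictions$tool == tool_b &
                     predictions$predicted_class != "missing", , drop = FALSE]
  m <- match(mutation_key(a), mutation_key(b))
  keep <- !is.na(m)
  if (sum(keep) < 2) {
    stop("fewer than 2 mutations predicted by both tools", call. = FALSE)
  }
  va <- as.numeric(a$predicted_class[keep] == "deleterious")
  vb <- as.numeric(b$predicted_class[m[keep]] == "deleterious")
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warning("phi undefined: a tool is constant on the shared mutation set")
    return(NA_real_)
  }
  stats::cor(va, vb)
}

#' Phi correlation matrix over all tool pairs
#'
#' @param predictions Prediction table.
#' @return Symmetric matrix of pairwise phi coefficients (diagonal 1).
#' @export
tool_correlation_matrix <- function(predictions) {
  tools <- sort(unique(predictions$tool))
  k <- length(tools)
  m <- diag(1, k)
  dimnames(m) <- list(tools, tools)
  if (k < 2) return(m)
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      phi <- suppressWarnings(
        pairwise_tool_correlation(predictions, tools[i], tools[j]))
      m[i, j] <- m[j, i] <- phi
    }
  }
  m
}

#' Amino-acid composition bias of a mutation dataset
#'
#' Tallies wild-type and mutant residues separately, compares them with
#' expected counts under supplied background frequencies, and reports the
#' Pearson correlation over the 40 pooled (wild-type + mutant)
#' observed-vs-expected count pairs, plus per-residue fold deviations.
#' Systematic mutagenesis (e.g. alanine scanning) shows up as a large
#' mutant-side fold enrichment.
#'
#' @param mutations Mutation table.
#' @param expected_freqs Named numeric vector of background frequencies for
#'   the 20 standard residues, summing to 1 (tolerance 1e-6).
#' @return List with `table` (per-residue observed/expected counts and fold
#'   deviations) and `pearson_r`.
#' @export
aa_distribution_bias <- function(mutations, expected_freqs) {
  if (nrow(mutations) == 0) stop("empty dataset", call. = FALSE)
  stopifnot(all(AA_STANDARD %in% names(expected_freqs)))
  expected_freqs <- expected_freqs[AA_STANDARD]
  if (abs(sum(expected_freqs) - 1) > 1e-6) {
    stop("expected frequencies must sum to 1", call. = FALSE)
  }
  n <- nrow(mutations)
  obs_wt <- as.numeric(table(factor(mutations$wt_aa, levels = AA_STANDARD)))
  obs_mut <- as.numeric(table(factor(mutations$mut_aa, levels = AA_STANDARD)))
  expected <- as.numeric(expected_freqs) * n
  tab <- data.frame(aa = AA_STANDARD,
                    observed_wt = obs_wt, observed_mut = obs_mut,
                    expected = expected,
                    fold_wt = obs_wt / expected,
                    fold_mut = obs_mut / expected,
                    stringsAsFactors = FALSE)
  obs <- c(obs_wt, obs_mut)
  exp2 <- c(expected, expected)
  if (stats::sd(exp2) == 0) {
    ## uniform expectation: correlation degenerates; call it 1 exactly when
    ## the observation is uniform too, otherwise it is undefined
    r <- if (stats::sd(obs) == 0) 1 else NA_real_
  } else {
    r <- stats::cor(obs, exp2)
  }
  list(table = tab, pearson_r = r)
}

#' Evaluation report for consensus results
#'
#' @param results Consensus results from [predict_consensus()].
#' @param mutations Labelled mutation table.
#' @return An `evaluation_report`: coverage, raw and normalized confusion
#'   matrices, normalized accuracy and MCC, AUC (from the signed consensus
#'   score), and per-class record counts.
#' @export
evaluate_predictions <- function(results, mutations) {
  cov <- coverage(results, mutations)
  lab <- mutations$label[match(mutation_key(results), mutation_key(mutations))]
  keep <- !is.na(lab) & lab != "unknown"
  cm <- confusion_matrix(results$predicted_class[keep], lab[keep])
  ncm <- normalize_confusion(cm)
  structure(list(
    coverage = cov,
    confusion = cm,
    confusion_normalized = ncm,
    accuracy_norm = cm_accuracy(ncm),
    mcc_norm = cm_mcc(ncm),
    auc = roc_auc(results$score[keep], lab[keep])$auc,
    n_neutral = sum(lab[keep] == "neutral"),
    n_deleterious = sum(lab[keep] == "deleterious")
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("coverage            %6.1f%%\n", 100 * x$coverage))
  cat(sprintf("accuracy (norm.)    %6.3f\n", x$accuracy_norm))
  cat(sprintf("MCC (norm.)         %6.3f\n", x$mcc_norm))
  cat(sprintf("AUC                 %6.3f\n", x$auc))
  cat(sprintf("n neutral / delet.  %d / %d\n", x$n_neutral, x$n_deleterious))
  invisible(x)
}

#' Per-tool evaluation table
#'
#' Evaluates each constituent tool over the mutations it predicted,
#' scoring AUC from the signed calibrated confidence (sign of the class
#' call times the calibrated observed accuracy) so that all tools share
#' one orientation: higher means more deleterious.
#'
#' @param predictions Prediction table.
#' @param mutations Labelled mutation table.
#' @param model `calibration_model` used to orient and weight the scores.
#' @return `data.frame` with one row per tool: coverage, normalized
#'   accuracy, normalized MCC, AUC.
#' @export
evaluate_tools <- function(predictions, mutations, model) {
  predictions <- validate_predictions(predictions)
  tools <- sort(unique(predictions$tool))
  rows <- lapply(tools, function(tl) {
    sub <- predictions[predictions$tool == tl, , drop = FALSE]
    cov <- coverage(sub, mutations)
    sub <- sub[sub$predicted_class != "missing", , drop = FALSE]
    lab <- mutations$label[match(mutation_key(sub), mutation_key(mutations))]
    keep <- !is.na(lab) & lab != "unknown"
    sub <- sub[keep, , drop = FALSE]
    lab <- lab[keep]
    conf <- rep(NA_real_, nrow(sub))
    for (cls in unique(sub$predicted_class)) {
      idx <- which(sub$predicted_class == cls)
      conf[idx] <- transform_confidence(model, tl, cls, sub$raw_confidence[idx])
    }
    signed <- prediction_sign(sub$predicted_class) * conf
    ncm <- normalize_confusion(confusion_matrix(sub$predicted_class, lab))
    data.frame(tool = tl, coverage = cov,
               accuracy_norm = cm_accuracy(ncm),
               mcc_norm = cm_mcc(ncm),
               auc = roc_auc(signed, lab)$auc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
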