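## Synthetic predictor ensembles. Each simulated tool has a stated
## class-conditional confidence distribution, an accuracy curve linking
## drawn confidence to the probability of a correct call, a missingness
## rate, and (at ensemble level) a shared per-mutation latent difficulty
## that induces positive inter-tool correlation controlled by a single
## knob rho: with probability rho a tool's correctness is decided by the
## shared latent uniform, otherwise by an independent draw, so marginal
## accuracies are untouched and rho = 0 recovers conditional independence.

## deterministic sub-seeding: one named stream per purpose/tool, so adding
## a tool never perturbs the draws of the others
sub_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131) %% 1000003
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Simulated-tool profile
#'
#' @param name Tool identifier.
#' @param score_kind `"continuous"` or `"categorical"`.
#' @param accuracy Accuracy model. Continuous tools: `list(family =
#'   "constant", a =)`, `list(family = "identity")` (P(correct | c) = c),
#'   or `list(family = "logistic", base, span, slope, mid)` giving
#'   `base + span / (1 + exp(-slope (c - mid)))`. Categorical tools:
#'   `list(family = "categorical", levels, probs, acc)` — the level
#'   sampling probabilities and per-level accuracies.
#' @param confidence Confidence distribution for continuous tools:
#'   `list(family = "uniform", lo, hi)` or `list(family = "beta", shape1,
#'   shape2)`. May be a list of two such lists named `neutral` and
#'   `deleterious` for class-conditional distributions. Ignored for
#'   categorical tools.
#' @param missing_rate Probability of returning no prediction, in \[0, 1).
#' @param class_bias Probability of calling deleterious for mutations whose
#'   true label is unknown (for labelled mutations a wrong call is forced
#'   to the opposite class, so no free choice exists). Default 0.5.
#' @return A `tool_profile`.
#' @export
tool_profile <- function(name, score_kind = "continuous",
                         accuracy = list(family = "identity"),
                         confidence = list(family = "uniform", lo = 0.5, hi = 1),
                         missing_rate = 0, class_bias = 0.5) {
  stopifnot(score_kind %in% SCORE_KINDS,
            missing_rate >= 0, missing_rate < 1,
            class_bias >= 0, class_bias <= 1)
  if (score_kind == "categorical") {
    stopifnot(identical(accuracy$family, "categorical"),
              length(accuracy$levels) == length(accuracy$probs),
              length(accuracy$levels) == length(accuracy$acc),
              all(accuracy$acc >= 0 & accuracy$acc <= 1))
  }
  structure(list(name = name, score_kind = score_kind, accuracy = accuracy,
                 confidence = confidence, missing_rate = missing_rate,
                 class_bias = class_bias),
            class = "tool_profile")
}

accuracy_at <- function(acc, c) {
  switch(acc$family,
         constant = rep(acc$a, length(c)),
         identity = c,
         logistic = acc$base + acc$span / (1 + exp(-acc$slope * (c - acc$mid))),
         stop("unknown accuracy family: ", acc$family, call. = FALSE))
}

draw_confidence <- function(conf, n) {
  switch(conf$family,
         uniform = stats::runif(n, conf$lo, conf$hi),
         beta = stats::rbeta(n, conf$shape1, conf$shape2),
         stop("unknown confidence family: ", conf$family, call. = FALSE))
}

class_conf <- function(confidence, label) {
  if (!is.null(confidence$family)) return(confidence)  # shared across classes
  if (label %in% names(confidence)) return(confidence[[label]])
  confidence[[1]]
}

#' Ensemble specification
#'
#' @param profiles List of [tool_profile()]s (default:
#'   [default_tool_profiles()], six tools echoing a realistic integrated
#'   set).
#' @param rho Shared-difficulty weight in \[0, 1) controlling pairwise
#'   tool correlation (default 0.2).
#' @param n Number of mutations.
#' @param class_balance Probability a mutation is neutral (default 0.5).
#' @param seed Integer seed; every draw is reproducible given it.
#' @return An `ensemble_spec`.
#' @export
ensemble_spec <- function(profiles = default_tool_profiles(), rho = 0.2,
                          n = 2000L, class_balance = 0.5, seed = 1L) {
  stopifnot(rho >= 0, rho < 1, n >= 1)
  structure(list(profiles = profiles, rho = rho, n = as.integer(n),
                 class_balance = class_balance, seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Default six-tool ensemble profiles
#'
#' Six heterogeneous predictors — four continuous (identity and logistic
#' accuracy curves) and two categorical — with marginal accuracies spanning
#' roughly 0.65-0.75, informative confidences, and per-tool missingness
#' from 0 to 40% (the strongest tool always reports, so the consensus
#' covers every mutation).
#'
#' @return List of six [tool_profile()]s.
#' @export
default_tool_profiles <- function() {
  list(
    tool_profile("alpha", "continuous", list(family = "identity"),
                 list(family = "uniform", lo = 0.55, hi = 0.95),
                 missing_rate = 0),
    tool_profile("bravo", "continuous",
                 list(family = "logistic", base = 0.5, span = 0.46,
                      slope = 10, mid = 0.5),
                 list(family = "beta", shape1 = 2, shape2 = 2),
                 missing_rate = 0.05),
    tool_profile("charlie", "continuous", list(family = "identity"),
                 list(family = "uniform", lo = 0.45, hi = 0.93),
                 missing_rate = 0.30),
    tool_profile("delta", "continuous", list(family = "identity"),
                 list(family = "uniform", lo = 0.42, hi = 0.90),
                 missing_rate = 0.40),
    tool_profile("echo", "categorical",
                 list(family = "categorical",
                      levels = c("low", "medium", "high"),
                      probs = c(0.3, 0.4, 0.3),
                      acc = c(0.55, 0.67, 0.80)),
                 missing_rate = 0.10),
    tool_profile("foxtrot", "categorical",
                 list(family = "categorical",
                      levels = c("c0", "c1", "c2", "c3"),
                      probs = c(0.25, 0.25, 0.25, 0.25),
                      acc = c(0.58, 0.66, 0.72, 0.84)),
                 missing_rate = 0.20)
  )
}

#' Generate a synthetic labelled mutation dataset
#'
#' Mutations are laid out over synthetic proteins (200 residues each, one
#' mutation per position, so keys never collide); wild-type residues are
#' drawn from `aa_freqs` and mutant residues from `aa_freqs` renormalized
#' without the wild type; labels are neutral with probability
#' `class_balance`.
#'
#' @param n Number of mutations.
#' @param class_balance Probability of the neutral label, in (0, 1).
#' @param seed Integer seed.
#' @param aa_freqs Named frequency vector over the 20 residues (default
#'   uniform).
#' @return A mutation table.
#' @export
generate_mutations <- function(n, class_balance = 0.5, seed = 1L,
                               aa_freqs = NULL) {
  stopifnot(n >= 1)
  if (!(class_balance > 0 && class_balance < 1)) {
    stop("class_balance must lie strictly between 0 and 1", call. = FALSE)
  }
  if (is.null(aa_freqs)) {
    aa_freqs <- stats::setNames(rep(1 / 20, 20), AA_STANDARD)
  }
  stopifnot(all(AA_STANDARD %in% names(aa_freqs)))
  aa_freqs <- aa_freqs[AA_STANDARD] / sum(aa_freqs[AA_STANDARD])

  set.seed(sub_seed(seed, "mutations"))
  idx <- seq_len(n) - 1L
  protein_id <- sprintf("SYNP%05d", idx %/% 200L + 1L)
  position <- idx %% 200L + 1L
  wt <- sample(AA_STANDARD, n, replace = TRUE, prob = aa_freqs)
  mut <- vapply(wt, function(w) {
    p <- aa_freqs
    p[w] <- 0
    sample(AA_STANDARD, 1, prob = p / sum(p))
  }, character(1))
  label <- ifelse(stats::runif(n) < class_balance, "neutral", "deleterious")
  data.frame(protein_id = protein_id, position = position,
             wt_aa = unname(wt), mut_aa = unname(mut), label = label,
             source = "simulated", stringsAsFactors = FALSE)
}

#' Simulate one tool's predictions
#'
#' For each mutation the tool is missing with `missing_rate`; otherwise a
#' confidence is drawn from the true-class confidence distribution, the
#' call is correct with probability `accuracy(c)` — decided by the shared
#' latent difficulty with probability `rho`, independently otherwise — and
#' the predicted class plus the raw confidence (numeric value or category
#' token) are emitted.
#'
#' @param profile A [tool_profile()].
#' @param mutations Mutation table (labels may include `"unknown"`; those
#'   get a coin-flip class with `class_bias` and no accuracy guarantee).
#' @param latent Optional per-mutation latent difficulty in (0, 1) shared
#'   across tools.
#' @param rho Weight of the shared latent, in \[0, 1).
#' @param seed Integer seed; the tool's stream is derived from it and the
#'   tool name.
#' @return A prediction table for this tool.
#' @export
simulate_tool <- function(profile, mutations, latent = NULL, rho = 0,
                          seed = 1L) {
  n <- nrow(mutations)
  set.seed(sub_seed(seed, paste0("tool:", profile$name)))
  if (is.null(latent)) latent <- stats::runif(n)
  stopifnot(length(latent) == n, rho >= 0, rho < 1)

  missing <- stats::runif(n) < profile$missing_rate
  labelled <- mutations$label %in% c("neutral", "deleterious")

  if (profile$score_kind == "categorical") {
    acc <- profile$accuracy
    lev <- sample(acc$levels, n, replace = TRUE, prob = acc$probs)
    p_correct <- acc$acc[match(lev, acc$levels)]
    raw <- lev
  } else {
    raw_num <- numeric(n)
    for (lab in unique(mutations$label)) {
      idx <- which(mutations$label == lab)
      raw_num[idx] <- draw_confidence(class_conf(profile$confidence, lab),
                                      length(idx))
    }
    p_correct <- accuracy_at(profile$accuracy, raw_num)
    raw <- format(raw_num, digits = 15, scientific = FALSE, trim = TRUE)
  }

  use_shared <- stats::runif(n) < rho
  u <- stats::runif(n)
  correct <- ifelse(use_shared, latent < p_correct, u < p_correct)

  predicted <- character(n)
  predicted[labelled] <- ifelse(
    correct[labelled], mutations$label[labelled],
    ifelse(mutations$label[labelled] == "neutral", "deleterious", "neutral"))
  if (any(!labelled)) {
    predicted[!labelled] <- ifelse(stats::runif(sum(!labelled)) < profile$class_bias,
                                   "deleterious", "neutral")
  }
  predicted[missing] <- "missing"
  raw[missing] <- NA_character_

  validate_predictions(data.frame(
    protein_id = mutations$protein_id, position = mutations$position,
    wt_aa = mutations$wt_aa, mut_aa = mutations$mut_aa,
    tool = profile$name, predicted_class = predicted,
    raw_confidence = raw, score_kind = profile$score_kind,
    stringsAsFactors = FALSE))
}

#' Simulate a full predictor ensemble
#'
#' One latent difficulty per mutation is shared across tools with weight
#' `rho`, inducing positive pairwise correlation between tools while
#' leaving each tool's marginal accuracy at its profile value. Fully
#' deterministic given the spec (including its seed); per-tool streams are
#' independent, so adding a profile never changes the other tools' draws.
#'
#' @param spec An [ensemble_spec()].
#' @return List with `mutations` and `predictions` (all tools stacked).
#' @export
simulate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  mutations <- generate_mutations(spec$n, spec$class_balance, seed = spec$seed)
  set.seed(sub_seed(spec$seed, "latent"))
  latent <- stats::runif(spec$n)
  preds <- lapply(spec$profiles, simulate_tool, mutations = mutations,
                  latent = latent, rho = spec$rho, seed = spec$seed)
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  list(mutations = mutations, predictions = predictions)
}
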