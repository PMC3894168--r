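# Shared fixture builders; everything is generated in code, nothing on disk.

make_mutations <- function(n, label = rep(c("neutral", "deleterious"), length.out = n),
                           source = "fix") {
  aa <- snpconsensus::AA_STANDARD
  data.frame(protein_id = sprintf("P%03d", (seq_len(n) - 1) %/% 50 + 1),
             position = (seq_len(n) - 1) %% 50 + 1,
             wt_aa = aa[(seq_len(n) - 1) %% 19 + 1],
             mut_aa = aa[(seq_len(n) - 1) %% 19 + 2],
             label = label, source = source,
             stringsAsFactors = FALSE)
}

make_predictions <- function(mutations, tool, predicted_class, raw_confidence,
                             score_kind = "continuous") {
  data.frame(protein_id = mutations$protein_id, position = mutations$position,
             wt_aa = mutations$wt_aa, mut_aa = mutations$mut_aa,
             tool = tool, predicted_class = predicted_class,
             raw_confidence = as.character(raw_confidence),
             score_kind = score_kind, stringsAsFactors = FALSE)
}

# O(n^2) all-pairs AUC oracle, independent of the rank-based implementation
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == "deleterious"]
  neg <- scores[labels == "neutral"]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# random protein sequence of length n
random_protein <- function(n) {
  paste(sample(snpconsensus::AA_STANDARD, n, replace = TRUE), collapse = "")
}
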