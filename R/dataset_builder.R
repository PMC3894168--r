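## Construction of independence-guaranteed benchmark datasets: purge
## label conflicts, drop duplicates, then remove every mutation whose
## (protein, position) maps through a sufficiently significant, sufficiently
## identical alignment fragment to a position mutated in a reference
## (training or held-out) set. Position correspondence is via alignment
## columns (non-gap/non-gap pairs), not mere fragment containment.

#' Thresholds for calling two aligned positions overlapping
#'
#' @param max_evalue Maximum fragment e-value (default 1e-10). Fragments
#'   without an e-value (the built-in aligner) are filtered by
#'   `min_length` instead.
#' @param min_identity Minimum fragment identity, inclusive (default 0.5).
#' @param min_length Minimum aligned-fragment length in columns, used in
#'   place of the e-value when none is available (default 30).
#' @return An `overlap_spec` object.
#' @export
overlap_spec <- function(max_evalue = 1e-10, min_identity = 0.5,
                         min_length = 30L) {
  stopifnot(max_evalue > 0, min_identity >= 0, min_identity <= 1,
            min_length >= 1)
  structure(list(max_evalue = max_evalue, min_identity = min_identity,
                 min_length = as.integer(min_length)),
            class = "overlap_spec")
}

#' Remove mutations with conflicting functional annotations
#'
#' Every mutation key that appears with both the neutral and the
#' deleterious label (e.g. in two source databases) is removed entirely —
#' all of its records. Idempotent.
#'
#' @param mutations Mutation table with labels in
#'   `{neutral, deleterious}`.
#' @return The purged mutation table.
#' @export
purge_conflicts <- function(mutations) {
  if (nrow(mutations) == 0) return(mutations)
  key <- mutation_key(mutations)
  n_labels <- tapply(mutations$label, key, function(l) length(unique(l)))
  conflicted <- names(n_labels)[n_labels > 1]
  out <- mutations[!(key %in% conflicted), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse duplicate mutation records
#'
#' Requires conflicts to have been purged (duplicates must agree on the
#' label). The survivor is the record whose source tag sorts first; its
#' source field lists every contributing source, comma-separated in sorted
#' order, which also makes the result independent of input order.
#'
#' @param mutations Conflict-free mutation table.
#' @return One record per mutation key.
#' @export
deduplicate <- function(mutations) {
  if (nrow(mutations) == 0) return(mutations)
  key <- mutation_key(mutations)
  n_labels <- tapply(mutations$label, key, function(l) length(unique(l)))
  if (any(n_labels > 1)) {
    stop("duplicate keys with differing labels; run purge_conflicts() first",
         call. = FALSE)
  }
  ord <- order(key, mutations$source)
  m <- mutations[ord, , drop = FALSE]
  k <- key[ord]
  first <- !duplicated(k)
  out <- m[first, , drop = FALSE]
  src <- tapply(m$source, k, function(s) paste(sort(unique(s)), collapse = ","))
  out$source <- as.character(src[out_key <- mutation_key(out)])
  out <- out[order(out_key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label a record from its activity-annotation token set
#'
#' The token `"="` means no change of activity: a record annotated only
#' `"="` is neutral, a record with any other annotation and no `"="` is
#' deleterious, and a record carrying `"="` together with another token is
#' contradictory and excluded.
#'
#' @param tokens Character vector (one record's annotation tokens) or a
#'   list of such vectors.
#' @return `"neutral"`, `"deleterious"` or `"excluded"` per record.
#' @export
label_pmd <- function(tokens) {
  one <- function(tk) {
    tk <- unique(trimws(tk))
    tk <- tk[tk != ""]
    if (length(tk) == 0) stop("empty annotation token set", call. = FALSE)
    has_eq <- "=" %in% tk
    if (has_eq && length(tk) > 1) return("excluded")
    if (has_eq) return("neutral")
    "deleterious"
  }
  if (is.list(tokens)) vapply(tokens, one, character(1)) else one(tokens)
}

#' Label a mutation from its relative activity change
#'
#' Activity changes strictly larger than the threshold (default 50%) are
#' deleterious; anything up to and including it is neutral.
#'
#' @param relative_change Non-negative fraction(s) of activity change.
#' @param threshold Decision threshold, default 0.5.
#' @return `"neutral"` or `"deleterious"` per value.
#' @export
label_by_activity <- function(relative_change, threshold = 0.5) {
  if (any(relative_change < 0)) {
    stop("relative activity change must be >= 0", call. = FALSE)
  }
  ifelse(relative_change > threshold, "deleterious", "neutral")
}

new_fragment <- function(query_id, subject_id, qstart, qend, sstart, send,
                         identity, evalue = NA_real_, qpos = NULL, spos = NULL) {
  structure(list(query_id = query_id, subject_id = subject_id,
                 qstart = qstart, qend = qend, sstart = sstart, send = send,
                 identity = identity, evalue = evalue,
                 qpos = qpos, spos = spos),
            class = "aligned_fragment")
}

#' Built-in local aligner
#'
#' Returns a pairwise local aligner (Smith-Waterman via
#' `Biostrings::pairwiseAlignment`, BLOSUM62, gap open 11 / extend 1)
#' usable wherever an external aligner's fragments are expected. It has no
#' e-value model; fragments shorter than `min_length` alignment columns
#' are dropped instead, which stands in for the significance filter at
#' desk scale.
#'
#' @param min_length Minimum alignment length in columns (default 30).
#' @return A function `(query_seqs, subject_seqs) -> list of fragments`,
#'   each fragment carrying the aligned ranges, identity (matched columns
#'   over alignment length) and the explicit column map of non-gap/non-gap
#'   position pairs.
#' @export
builtin_aligner <- function(min_length = 30L) {
  force(min_length)
  function(query_seqs, subject_seqs) {
    data_env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
    blosum <- get("BLOSUM62", envir = data_env)
    frags <- list()
    for (qid in names(query_seqs)) {
      for (sid in names(subject_seqs)) {
        pa <- Biostrings::pairwiseAlignment(
          query_seqs[[qid]], subject_seqs[[sid]], type = "local",
          substitutionMatrix = blosum, gapOpening = 11, gapExtension = 1)
        aq <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
        as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
        len <- length(aq)
        if (len < min_length) next
        qp <- cumsum(aq != "-") + Biostrings::start(Biostrings::pattern(pa)) - 1L
        sp <- cumsum(as_ != "-") + Biostrings::start(Biostrings::subject(pa)) - 1L
        both <- aq != "-" & as_ != "-"
        ident <- sum(aq == as_ & both) / len
        frags[[length(frags) + 1L]] <- new_fragment(
          qid, sid,
          qstart = min(qp[aq != "-"]), qend = max(qp[aq != "-"]),
          sstart = min(sp[as_ != "-"]), send = max(sp[as_ != "-"]),
          identity = ident, evalue = NA_real_,
          qpos = qp[both], spos = sp[both])
      }
    }
    frags
  }
}

#' Read alignment fragments from a BLAST tabular file
#'
#' Standard 12-column tabular output (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore). The tabular format
#' carries no per-column alignment, so the position map is reconstructed
#' linearly for ungapped fragments (equal query and subject span lengths);
#' gapped fragments get no column map and are treated conservatively by
#' [find_overlapping_positions()] (every position in a qualifying fragment
#' counts as overlapping).
#'
#' @param path Path to the tabular file.
#' @return List of `aligned_fragment` objects.
#' @export
read_blast_fragments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = cols, comment.char = "#")
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    ungapped <- (r$qend - r$qstart) == (r$send - r$sstart)
    qp <- sp <- NULL
    if (ungapped) {
      qp <- seq(r$qstart, r$qend)
      sp <- seq(r$sstart, r$send)
    }
    new_fragment(r$qseqid, r$sseqid, r$qstart, r$qend, r$sstart, r$send,
                 identity = r$pident / 100, evalue = r$evalue,
                 qpos = qp, spos = sp)
  })
}

fragment_qualifies <- function(frag, spec) {
  if (frag$identity < spec$min_identity) return(FALSE)
  if (!is.na(frag$evalue)) return(frag$evalue <= spec$max_evalue)
  (frag$qend - frag$qstart + 1L) >= spec$min_length
}

#' Positions of a query dataset that overlap a reference mutated-position set
#'
#' A query (protein, position) is overlapping if (a) the same protein
#' identifier is mutated at the same position in the reference (direct
#' overlap), or (b) some alignment fragment passing the `spec` thresholds
#' maps it, through its column map, to a reference mutated position.
#'
#' @param query_mutations Mutation table (only `protein_id`/`position` are
#'   used).
#' @param reference_positions `data.frame` with `protein_id` and `position`
#'   columns: the positions mutated in the reference (training/held-out)
#'   set.
#' @param query_seqs,reference_seqs Named sequence vectors, required when
#'   `aligner` is a pairwise aligner function.
#' @param aligner Either a function `(query_seqs, reference_seqs) -> list
#'   of fragments` (see [builtin_aligner()]), a pre-computed fragment list
#'   (e.g. from [read_blast_fragments()], query = query proteins, subject
#'   = reference proteins), or `NULL` for direct overlap only.
#' @param spec An [overlap_spec()].
#' @return `data.frame` of unique overlapping (protein_id, position) pairs.
#' @export
find_overlapping_positions <- function(query_mutations, reference_positions,
                                       query_seqs = NULL, reference_seqs = NULL,
                                       aligner = NULL, spec = overlap_spec()) {
  qpos_tab <- unique(data.frame(protein_id = query_mutations$protein_id,
                                position = as.integer(query_mutations$position),
                                stringsAsFactors = FALSE))
  ref <- unique(data.frame(protein_id = reference_positions$protein_id,
                           position = as.integer(reference_positions$position),
                           stringsAsFactors = FALSE))
  pp <- function(d) paste(d$protein_id, d$position, sep = "|")
  hits <- qpos_tab[pp(qpos_tab) %in% pp(ref), , drop = FALSE]

  frags <- NULL
  if (is.function(aligner)) {
    if (is.null(query_seqs) || is.null(reference_seqs)) {
      stop("sequences are required to run the aligner", call. = FALSE)
    }
    need_q <- unique(qpos_tab$protein_id)
    need_r <- unique(ref$protein_id)
    miss <- c(setdiff(need_q, names(query_seqs)),
              setdiff(need_r, names(reference_seqs)))
    if (length(miss) > 0) {
      stop("missing sequence for protein(s): ",
           paste(unique(miss), collapse = ", "), call. = FALSE)
    }
    frags <- aligner(query_seqs[need_q], reference_seqs[need_r])
  } else if (is.list(aligner)) {
    frags <- aligner
  }

  for (frag in frags) {
    if (!fragment_qualifies(frag, spec)) next
    ref_here <- ref$position[ref$protein_id == frag$subject_id]
    if (length(ref_here) == 0) next
    if (!is.null(frag$spos)) {
      mapped_q <- frag$qpos[frag$spos %in% ref_here]
    } else {
      ## gapped fragment without a column map: conservative containment
      if (!any(ref_here >= frag$sstart & ref_here <= frag$send)) next
      mapped_q <- seq(frag$qstart, frag$qend)
    }
    if (length(mapped_q) == 0) next
    add <- qpos_tab[qpos_tab$protein_id == frag$query_id &
                      qpos_tab$position %in% mapped_q, , drop = FALSE]
    hits <- rbind(hits, add)
  }
  hits <- unique(hits)
  hits <- hits[order(hits$protein_id, hits$position), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Drop mutations at overlapping positions
#'
#' @param mutations Mutation table.
#' @param overlapping_positions Output of [find_overlapping_positions()].
#' @return The filtered table; attribute `"removed_per_source"` carries the
#'   per-source removal counts.
#' @export
remove_overlaps <- function(mutations, overlapping_positions) {
  pp <- paste(mutations$protein_id, mutations$position, sep = "|")
  drop <- pp %in% paste(overlapping_positions$protein_id,
                        overlapping_positions$position, sep = "|")
  out <- mutations[!drop, , drop = FALSE]
  rownames(out) <- NULL
  removed <- mutations[drop, , drop = FALSE]
  attr(out, "removed_per_source") <-
    if (nrow(removed) > 0) table(removed$source) else table(character(0))
  out
}

#' Build an independent benchmark dataset
#'
#' The full workflow: concatenate the labelled sources, purge conflicting
#' annotations, deduplicate, then remove every mutation at a position
#' overlapping the training reference set and (optionally) a held-out
#' reference set. An audit table records the record count after each stage.
#'
#' @param sources List of labelled mutation tables.
#' @param training_refs,holdout_refs Lists with elements `positions`
#'   (protein/position `data.frame`) and optionally `seqs`;
#'   `holdout_refs` may be `NULL`.
#' @param query_seqs Sequences for the query-side proteins (needed when a
#'   pairwise aligner runs).
#' @param aligner Passed to [find_overlapping_positions()].
#' @param spec An [overlap_spec()].
#' @return List with `dataset` (the surviving records) and `audit`
#'   (`data.frame` of stage name and record count).
#' @export
build_independent_dataset <- function(sources, training_refs,
                                      holdout_refs = NULL,
                                      query_seqs = NULL, aligner = NULL,
                                      spec = overlap_spec()) {
  ds <- do.call(rbind, lapply(sources, validate_mutations))
  rownames(ds) <- NULL
  audit <- data.frame(stage = "concatenated", n = nrow(ds),
                      stringsAsFactors = FALSE)
  note <- function(stage, d) {
    audit <<- rbind(audit, data.frame(stage = stage, n = nrow(d)))
    d
  }
  ds <- note("conflicts_purged", purge_conflicts(ds))
  ds <- note("deduplicated", deduplicate(ds))
  ov <- find_overlapping_positions(ds, training_refs$positions,
                                   query_seqs = query_seqs,
                                   reference_seqs = training_refs$seqs,
                                   aligner = aligner, spec = spec)
  ds <- note("training_overlap_removed", remove_overlaps(ds, ov))
  if (!is.null(holdout_refs)) {
    ov <- find_overlapping_positions(ds, holdout_refs$positions,
                                     query_seqs = query_seqs,
                                     reference_seqs = holdout_refs$seqs,
                                     aligner = aligner, spec = spec)
    ds <- note("holdout_overlap_removed", remove_overlaps(ds, ov))
  }
  list(dataset = ds, audit = audit)
}
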