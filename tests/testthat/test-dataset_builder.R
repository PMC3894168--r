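test_that("conflicting annotations are purged entirely, idempotently", {
  a <- mutation_table("P1", 1, "A", "C", "neutral", "srcA")
  b <- mutation_table("P1", 1, "A", "C", "deleterious", "srcB")
  c1 <- mutation_table("P2", 5, "G", "H", "neutral", "srcA")
  d <- mutation_table("P3", 7, "K", "L", "deleterious", "srcB")
  e <- mutation_table("P2", 5, "G", "H", "neutral", "srcB")
  all5 <- rbind(a, b, c1, d, e)

  purged <- purge_conflicts(all5)
  expect_equal(nrow(purged), 3)                 # the conflicting pair is gone
  expect_false(any(mutation_key(purged) == mutation_key(a)))
  expect_equal(purge_conflicts(purged), purged) # idempotent
  expect_equal(purge_conflicts(rbind(c1, d)), rbind(c1, d))
})

test_that("deduplication keeps one record per key and merges sources", {
  x <- rbind(mutation_table("P1", 1, "A", "C", "neutral", "srcC"),
             mutation_table("P1", 1, "A", "C", "neutral", "srcA"),
             mutation_table("P1", 1, "A", "C", "neutral", "srcB"),
             mutation_table("P2", 2, "D", "E", "deleterious", "srcA"))
  dd <- deduplicate(x)
  expect_equal(nrow(dd), 2)
  expect_equal(dd$source[dd$protein_id == "P1"], "srcA,srcB,srcC")
  expect_equal(deduplicate(dd), dd)

  conflict <- rbind(mutation_table("P1", 1, "A", "C", "neutral", "s1"),
                    mutation_table("P1", 1, "A", "C", "deleterious", "s2"))
  expect_error(deduplicate(conflict), "purge_conflicts")
})

test_that("purge and dedup are idempotent and order-invariant on random fixtures", {
  set.seed(23)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    x <- make_mutations(sample(5:15, 1))
    x <- x[sample(nrow(x), n, replace = TRUE), ]
    x$label <- sample(c("neutral", "deleterious"), n, replace = TRUE)
    x$source <- sample(c("s1", "s2", "s3"), n, replace = TRUE)
    once <- deduplicate(purge_conflicts(x))
    twice <- deduplicate(purge_conflicts(once))
    expect_equal(twice, once)
    shuffled <- deduplicate(purge_conflicts(x[sample(n), ]))
    expect_equal(shuffled, once)
  }
})

test_that("activity-annotation token sets label records per the = convention", {
  expect_equal(label_pmd("="), "neutral")
  expect_equal(label_pmd("++"), "deleterious")
  expect_equal(label_pmd(c("=", "++")), "excluded")
  expect_equal(label_pmd(list(c("--"), c("="), c("+", "="))),
               c("deleterious", "neutral", "excluded"))
  expect_error(label_pmd(character(0)), "empty")
})

test_that("activity change labels are deleterious strictly above the threshold", {
  expect_equal(label_by_activity(0.51), "deleterious")
  expect_equal(label_by_activity(0.50), "neutral")
  expect_equal(label_by_activity(0), "neutral")
  expect_equal(label_by_activity(c(0.2, 0.8)), c("neutral", "deleterious"))
  expect_equal(label_by_activity(0.3, threshold = 0.25), "deleterious")
  expect_error(label_by_activity(-0.1), ">= 0")
})

test_that("identical proteins overlap directly at mutated positions", {
  q <- mutation_table("P1", 10, "A", "C", "neutral", "q")
  ref <- data.frame(protein_id = "P1", position = 10)
  ov <- find_overlapping_positions(q, ref)
  expect_equal(ov, data.frame(protein_id = "P1", position = 10L))
  expect_equal(nrow(find_overlapping_positions(
    q, data.frame(protein_id = "P1", position = 11))), 0)
})

test_that("alignment fragments map reference positions through their columns", {
  set.seed(29)
  core <- random_protein(60)
  qseq <- c(Q1 = paste0(random_protein(15), core, random_protein(10)))
  rseq <- c(R1 = paste0(random_protein(5), core, random_protein(20)))
  # reference mutated inside the shared core at core offset 30:
  # reference position 5 + 30, matching query position 15 + 30
  ref <- data.frame(protein_id = "R1", position = 35)
  q <- mutation_table("Q1", c(45, 3), c("A", "A"), c("C", "C"), "neutral", "q")
  q$wt_aa <- substr(paste0(qseq), q$position, q$position)
  q$mut_aa <- ifelse(q$wt_aa == "C", "G", "C")
  ov <- find_overlapping_positions(q, ref, query_seqs = qseq,
                                   reference_seqs = rseq,
                                   aligner = builtin_aligner())
  expect_equal(ov$position, 45L)  # 3 lies outside the aligned core

  # unrelated random sequences produce no qualifying fragment
  u1 <- c(U1 = random_protein(200))
  u2 <- c(U2 = random_protein(200))
  qq <- mutation_table("U1", 100, substr(u1, 100, 100),
                       ifelse(substr(u1, 100, 100) == "A", "C", "A"), "neutral", "q")
  ov2 <- find_overlapping_positions(qq, data.frame(protein_id = "U2", position = 100),
                                    query_seqs = u1, reference_seqs = u2,
                                    aligner = builtin_aligner())
  expect_equal(nrow(ov2), 0)

  expect_error(find_overlapping_positions(q, ref, query_seqs = qseq["none"],
                                          reference_seqs = rseq,
                                          aligner = builtin_aligner()),
               "missing sequence")
})

test_that("the identity threshold is inclusive at 0.50 and e-values filter fragments", {
  frag <- function(identity, evalue) {
    snpconsensus:::new_fragment("Q", "R", 1, 50, 1, 50, identity, evalue,
                                qpos = 1:50, spos = 1:50)
  }
  q <- mutation_table("Q", 10, "A", "C", "neutral", "q")
  ref <- data.frame(protein_id = "R", position = 10)
  ov_at <- find_overlapping_positions(q, ref, aligner = list(frag(0.50, 1e-12)))
  expect_equal(nrow(ov_at), 1)                      # 0.50 passes "at least 50%"
  ov_below <- find_overlapping_positions(q, ref, aligner = list(frag(0.49, 1e-12)))
  expect_equal(nrow(ov_below), 0)
  ov_eval <- find_overlapping_positions(q, ref, aligner = list(frag(0.9, 1e-5)))
  expect_equal(nrow(ov_eval), 0)                    # insignificant fragment
})

test_that("tightening the overlap spec never shrinks the overlap set", {
  set.seed(31)
  frags <- lapply(1:30, function(i) {
    snpconsensus:::new_fragment("Q", "R", 1, 50, 1, 50,
                                identity = runif(1, 0.3, 1),
                                evalue = 10^runif(1, -20, -5),
                                qpos = 1:50, spos = 1:50)
  })
  q <- do.call(rbind, lapply(1:50, function(p) {
    mutation_table("Q", p, "A", "C", "neutral", "q")
  }))
  ref <- data.frame(protein_id = "R", position = sample(1:50, 10))
  strict <- find_overlapping_positions(q, ref, aligner = frags,
                                       spec = overlap_spec(1e-10, 0.5))
  loose <- find_overlapping_positions(q, ref, aligner = frags,
                                      spec = overlap_spec(1e-8, 0.4))
  expect_true(all(paste(strict$protein_id, strict$position) %in%
                    paste(loose$protein_id, loose$position)))
})

test_that("BLAST tabular fragments parse with linear maps for ungapped hits", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Q1\tR1\t95.0\t40\t2\t0\t11\t50\t1\t40\t1e-20\t80.5",
               "Q2\tR2\t60.0\t30\t8\t1\t1\t30\t5\t33\t1e-12\t45.0"), path)
  frags <- read_blast_fragments(path)
  expect_equal(length(frags), 2)
  expect_equal(frags[[1]]$identity, 0.95)
  expect_equal(frags[[1]]$qpos, 11:50)
  expect_equal(frags[[1]]$spos, 1:40)
  expect_null(frags[[2]]$qpos)   # gapped: no column map, containment applies

  # the gapped fragment conservatively maps its whole range
  q <- mutation_table("Q2", 15, "A", "C", "neutral", "q")
  ov <- find_overlapping_positions(q, data.frame(protein_id = "R2", position = 20),
                                   aligner = frags)
  expect_equal(ov$position, 15L)
})

test_that("the build pipeline reproduces planted stage counts and guarantees independence", {
  set.seed(37)
  seq_shared <- random_protein(80)
  qseqs <- c(QP1 = seq_shared, QP2 = random_protein(80))
  rseqs <- c(TR1 = seq_shared)

  wt_at <- function(seqs, id, pos) substr(seqs[[id]], pos, pos)
  mk <- function(id, pos, label, source, seqs = qseqs) {
    wt <- wt_at(seqs, id, pos)
    mutation_table(id, pos, wt, ifelse(wt == "C", "G", "C"), label, source)
  }
  # plant: 1 conflicting key (2 records), 1 duplicated key (2 records),
  # 2 unique clean records on QP2, 1 record on QP1 at a position mutated in
  # the training reference (QP1 == TR1, overlap at position 40)
  srcA <- rbind(mk("QP2", 1, "neutral", "A"),
                mk("QP2", 2, "deleterious", "A"),
                mk("QP1", 40, "neutral", "A"),
                mk("QP1", 10, "neutral", "A"),
                mk("QP2", 9, "neutral", "A"))
  srcB <- rbind(mk("QP1", 10, "deleterious", "B"),   # conflicts with srcA
                mk("QP2", 9, "neutral", "B"))        # duplicates srcA
  refs <- list(positions = data.frame(protein_id = "TR1", position = 40),
               seqs = rseqs)

  built <- build_independent_dataset(list(srcA, srcB), refs,
                                     query_seqs = qseqs,
                                     aligner = builtin_aligner())
  audit <- built$audit
  expect_equal(audit$n[audit$stage == "concatenated"], 7)
  expect_equal(audit$n[audit$stage == "conflicts_purged"], 5)   # -2 conflict
  expect_equal(audit$n[audit$stage == "deduplicated"], 4)       # -1 duplicate
  expect_equal(audit$n[audit$stage == "training_overlap_removed"], 3)

  # re-checking the built dataset against the reference finds nothing
  recheck <- find_overlapping_positions(built$dataset, refs$positions,
                                        query_seqs = qseqs,
                                        reference_seqs = rseqs,
                                        aligner = builtin_aligner())
  expect_equal(nrow(recheck), 0)

  # disjoint, conflict-free, non-overlapping sources pass through untouched
  clean <- build_independent_dataset(
    list(mk("QP2", 20, "neutral", "A"), mk("QP2", 21, "deleterious", "B")),
    list(positions = data.frame(protein_id = character(0),
                                position = integer(0))))
  expect_equal(nrow(clean$dataset), 2)
})

test_that("remove_overlaps drops exactly the flagged positions and reports counts", {
  muts <- make_mutations(100)
  ov <- unique(data.frame(protein_id = muts$protein_id,
                          position = muts$position))[1:23, ]
  out <- remove_overlaps(muts, ov)
  expect_equal(nrow(out), 77)
  expect_equal(sum(attr(out, "removed_per_source")), 23)
  expect_equal(nrow(remove_overlaps(muts, ov[0, ])), 100)
  expect_equal(nrow(remove_overlaps(muts, unique(
    data.frame(protein_id = muts$protein_id, position = muts$position)))), 0)
})
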