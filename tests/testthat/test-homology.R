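# ORF extraction, reciprocal hits, domain merging, meta-alignment and the
# best-homolog cascade.

test_that("longest ORF handles toy cases and strand", {
  # expected values computed with the brute-force codon-table oracle
  orf <- longest_orf("ATGCGACTCGAACATCAG", "t1")
  expect_equal(orf$frame, 1L)
  expect_equal(orf$aa_sequence, "MRLEHQ")
  expect_equal(orf$aa_end - orf$aa_start, 6L)

  # the longest stop-free stretch lives on the reverse strand
  orf2 <- longest_orf("TCGTGAACCCCCTGCACG", "t2")
  expect_equal(orf2$frame, -1L)
  expect_equal(orf2$aa_sequence, "RAGGSR")

  expect_error(longest_orf("AT"), "shorter")
})

test_that("longest ORF equals a brute-force six-frame scan", {
  set.seed(11)
  for (i in 1:25) {
    seq <- paste(sample(c("A", "C", "G", "T"), sample(30:90, 1),
                        replace = TRUE), collapse = "")
    got <- longest_orf(seq, "x")
    want <- orf_oracle(seq)
    expect_equal(nchar(got$aa_sequence), nchar(want$aa), info = seq)
    expect_equal(got$frame, want$frame, info = seq)
    expect_equal(got$aa_sequence, want$aa, info = seq)
  }
})

test_that("best reciprocal hits require mutual bests", {
  fwd <- rbind(mk_hit("q1", "h1", "blast", 1e-50, 100),
               mk_hit("q1", "h2", "blast", 1e-20, 80))
  rev <- mk_hit("h1", "q1", "blast", 1e-48, 90)
  expect_equal(best_reciprocal_hits(fwd, rev),
               data.frame(query_id = "q1", target_id = "h1",
                          stringsAsFactors = FALSE))
  # asymmetry: h1 prefers q2
  rev2 <- rbind(mk_hit("h1", "q2", "blast", 1e-60, 100),
                mk_hit("h1", "q1", "blast", 1e-48, 90))
  expect_equal(nrow(best_reciprocal_hits(fwd, rev2)), 0L)
  expect_equal(nrow(best_reciprocal_hits(fwd[0, ], rev)), 0L)
})

test_that("best reciprocal hits equal brute-force enumeration", {
  set.seed(7)
  for (trial in 1:10) {
    fwd <- do.call(rbind, lapply(1:12, function(i) mk_hit(
      sample(paste0("q", 1:4), 1), sample(paste0("h", 1:3), 1), "blast",
      signif(10^-sample(10:80, 1), 6), sample(50:300, 1))))
    fwd <- fwd[!duplicated(fwd[, c("query_id", "target_id")]), ]
    rev <- do.call(rbind, lapply(1:12, function(i) mk_hit(
      sample(paste0("h", 1:3), 1), sample(paste0("q", 1:4), 1), "blast",
      signif(10^-sample(10:80, 1), 6), sample(50:300, 1))))
    rev <- rev[!duplicated(rev[, c("query_id", "target_id")]), ]
    got <- best_reciprocal_hits(fwd, rev)
    want <- brh_oracle(fwd, rev)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want[, c("query_id", "target_id")])
    # single-table margins variant
    got1 <- best_reciprocal_hits(fwd)
    want1 <- brh_oracle(fwd)
    rownames(got1) <- rownames(want1) <- NULL
    expect_equal(got1, want1[, c("query_id", "target_id")])
  }
})

test_that("domain merging applies the three conditions", {
  # model length 100; A covers model [0,40) at seq [10,50); B covers
  # [54,95) at seq [60,100): overlap 0 < 25, unannotated 100-81 = 19,
  # gap 10 <= 19 + 25 -> merged into one annotation covering 81% of the model
  ab <- rbind(ann_row("s", "PF_X", 100L, 0L, 40L, 10L, 50L, 1e-20),
              ann_row("s", "PF_X", 100L, 54L, 95L, 60L, 100L, 1e-30))
  m <- merge_domains(ab)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$model_start, m$model_end), c(0L, 95L))
  expect_equal(c(m$seq_start, m$seq_end), c(10L, 100L))
  expect_equal(m$evalue, 1e-30)
  # covered model residues: 40 + 41 = 81 of 100 (union, not span)
  expect_equal(build_metasequence(m)$coverage, 0.81)

  # same but B covers model [10,60): overlap with [0,40) is 30 >= 25 -> kept apart
  ab2 <- rbind(ann_row("s", "PF_X", 100L, 0L, 40L, 10L, 50L),
               ann_row("s", "PF_X", 100L, 10L, 60L, 60L, 100L))
  expect_equal(nrow(merge_domains(ab2)), 2L)

  # different domains never merge
  ab3 <- rbind(ann_row("s", "PF_X", 100L, 0L, 40L, 10L, 50L),
               ann_row("s", "PF_Y", 100L, 54L, 95L, 60L, 100L))
  expect_equal(nrow(merge_domains(ab3)), 2L)

  expect_error(merge_domains(ab[2:1, ]), "sorted")
})

test_that("domain merging is idempotent and never grows", {
  set.seed(3)
  for (trial in 1:20) {
    n <- sample(2:6, 1)
    starts <- sort(sample(0:200, n))
    a <- do.call(rbind, lapply(seq_len(n), function(i) {
      w <- sample(10:40, 1)
      ms <- sample(0:50, 1)
      ann_row("s", sample(c("PF_A", "PF_B"), 1), 100L, ms,
              min(100L, ms + w), starts[i], starts[i] + w)
    }))
    m1 <- merge_domains(a)
    expect_lte(nrow(m1), nrow(a))
    m2 <- merge_domains(m1)
    expect_equal(m2, m1)
  }
})

test_that("meta-alignment reproduces the stated scoring constants", {
  one <- mk_meta("PF1", 1.0)
  expect_equal(meta_align(one, one)$score, 30)          # full-coverage match
  expect_equal(meta_align(mk_meta(character(0), numeric(0)), one)$score, -5)
  expect_equal(meta_align(mk_meta(character(0), numeric(0)),
                          mk_meta(character(0), numeric(0)))$score, 0)
  # two gaps (-10) beat one mismatch (-30)
  expect_equal(meta_align(one, mk_meta("PF2", 1.0))$score, -10)
  expect_equal(meta_align(mk_meta(c("PF1", "PF2"), c(1, 1)),
                          mk_meta("PF2", 1.0))$score, 25)
  # match reward scales with the smaller coverage
  expect_equal(meta_align(mk_meta("PF1", 0.5), one)$score, 15)
})

test_that("meta-alignment is optimal and symmetric on short architectures", {
  doms <- c("PF1", "PF2", "PF3")
  covs <- c(0.5, 1.0)
  set.seed(21)
  for (trial in 1:150) {
    la <- sample(0:3, 1); lb <- sample(0:3, 1)
    a <- mk_meta(sample(doms, la, replace = TRUE), sample(covs, la, TRUE))
    b <- mk_meta(sample(doms, lb, replace = TRUE), sample(covs, lb, TRUE))
    got <- meta_align(a, b)$score
    expect_equal(got, meta_align_oracle(a, b))
    expect_equal(got, meta_align(b, a)$score)
  }
})

test_that("best-homolog cascade fires rules in strict order", {
  # rule 1: unique EggNOG BRH
  h <- rbind(mk_hit("t", "H1", "eggnog", 1e-30, 100, is_brh = TRUE),
             mk_hit("t", "H2", "blast", 1e-60, 300))
  expect_equal(select_best_homolog("t", h)[c("human_symbol", "rule")],
               list(human_symbol = "H1", rule = 1L))
  # rule 2: H2 supported by three channels, H3 by one
  h2 <- rbind(mk_hit("t", "H2", "blast", 1e-20, 90),
              mk_hit("t", "H2", "eggnog", 1e-15, 80),
              mk_hit("t", "H2", "pfam_meta", NA, 55),
              mk_hit("t", "H3", "blast", 1e-70, 300))
  expect_equal(select_best_homolog("t", h2)[c("human_symbol", "rule")],
               list(human_symbol = "H2", rule = 2L))
  # rule 3: two proteins tied on evidence count, EggNOG E-value decides
  h3 <- rbind(mk_hit("t", "H1", "eggnog", 1e-40, 90),
              mk_hit("t", "H2", "eggnog", 1e-20, 80))
  expect_equal(select_best_homolog("t", h3)[c("human_symbol", "rule")],
               list(human_symbol = "H1", rule = 3L))
  # rule 4: only BLAST evidence, two hits
  h4 <- rbind(mk_hit("t", "H1", "blast", 1e-40, 90),
              mk_hit("t", "H2", "blast", 1e-20, 80))
  expect_equal(select_best_homolog("t", h4)[c("human_symbol", "rule")],
               list(human_symbol = "H1", rule = 4L))
  # rule 5: only meta-alignment hits; higher score wins, ties lexicographic
  h5 <- rbind(mk_hit("t", "H9", "pfam_meta", NA, 55),
              mk_hit("t", "H1", "pfam_meta", NA, 25))
  expect_equal(select_best_homolog("t", h5)[c("human_symbol", "rule")],
               list(human_symbol = "H9", rule = 5L))
  h5b <- rbind(mk_hit("t", "H9", "pfam_meta", NA, 55),
               mk_hit("t", "H1", "pfam_meta", NA, 55))
  expect_equal(select_best_homolog("t", h5b)$human_symbol, "H1")
  # rule 6: ambiguous everywhere -> discarded
  h6 <- rbind(mk_hit("t", "H1", "eggnog", 1e-20, 80),
              mk_hit("t", "H2", "eggnog", 1e-20, 80))
  expect_null(select_best_homolog("t", h6))
})

test_that("cascade result is invariant to hit ordering", {
  set.seed(5)
  h <- rbind(mk_hit("t", "H2", "blast", 1e-20, 90),
             mk_hit("t", "H2", "eggnog", 1e-15, 80),
             mk_hit("t", "H3", "blast", 1e-70, 300),
             mk_hit("t", "H3", "pfam_meta", NA, 40),
             mk_hit("t", "H4", "eggnog", 1e-25, 85))
  ref <- select_best_homolog("t", h)
  for (i in 1:10) {
    got <- select_best_homolog("t", h[sample(nrow(h)), ])
    expect_equal(got$human_symbol, ref$human_symbol)
    expect_equal(got$rule, ref$rule)
  }
})
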