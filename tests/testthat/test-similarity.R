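test_that("a query finds itself with full-length identity", {
  set.seed(21)
  s <- random_nt_seq(300)
  hits <- search_hits(list(id = "q", seq = s),
                      annotated_seqs("subj", s), "NT")
  self <- hits[hits$strand == "+", ][1, ]
  expect_equal(self$identity_pct, 100)
  expect_equal(self$aligned_length, 300L)
  expect_equal(self$raw_score, 600L)
  expect_equal(self$q_start, 0L)
  expect_equal(self$q_end, 300L)
})

test_that("a reverse-complement subject is found on the minus strand", {
  set.seed(22)
  s <- random_nt_seq(200)
  hits <- search_hits(list(id = "q", seq = s),
                      annotated_seqs("subj", reverse_complement(s)), "NT")
  expect_true(any(hits$strand == "-"))
  mh <- hits[hits$strand == "-", ][1, ]
  expect_equal(mh$identity_pct, 100)
  expect_equal(mh$aligned_length, 200L)
  expect_equal(mh$s_start, 0L)
  expect_equal(mh$s_end, 200L)
})

test_that("seeded search equals the full Smith-Waterman oracle when the optimal alignment contains a seed word", {
  set.seed(23)
  tested <- 0
  for (i in 1:80) {
    a <- random_nt_seq(sample(40:80, 1))
    b <- random_nt_seq(sample(40:80, 1))
    if (i %% 2 == 0) {   # plant a shared word in half the cases
      w <- substr(a, 5, 5 + sample(11:25, 1))
      at <- sample(seq_len(nchar(b) - nchar(w)), 1)
      substr(b, at, at + nchar(w) - 1) <- w
    }
    pa <- oracle_local_score(a, b)
    if (!oracle_alignment_has_seed(pa, 11)) next
    tested <- tested + 1
    hits <- search_hits(list(id = "q", seq = a), annotated_seqs("s", b),
                        "NT", evalue_cutoff = Inf)
    expect_true(any(hits$strand == "+"))
    expect_equal(max(hits$raw_score[hits$strand == "+"]),
                 Biostrings::score(pa))
  }
  expect_gte(tested, 20)
})

test_that("best raw score is symmetric in query and subject", {
  set.seed(24)
  for (i in 1:10) {
    a <- random_nt_seq(60); b <- a
    substr(b, 10, 20) <- random_nt_seq(11)
    h1 <- search_hits(list(id = "a", seq = a), annotated_seqs("b", b),
                      "NT", evalue_cutoff = Inf)
    h2 <- search_hits(list(id = "b", seq = b), annotated_seqs("a", a),
                      "NT", evalue_cutoff = Inf)
    expect_equal(max(h1$raw_score), max(h2$raw_score))
  }
})

test_that("raising the e-value cutoff never removes hits", {
  set.seed(25)
  a <- random_nt_seq(80)
  subs <- annotated_seqs(paste0("s", 1:6), c(
    a, substr(a, 1, 40), reverse_complement(a),
    random_nt_seq(80), random_nt_seq(80), paste0(substr(a, 20, 50),
                                                 random_nt_seq(30))))
  cuts <- c(1e-20, 1e-10, 1e-4, 1, 1e4, Inf)
  prev <- character()
  for (ct in cuts) {
    h <- search_hits(list(id = "q", seq = a), subs, "NT",
                     evalue_cutoff = ct)
    ids <- paste(h$subject_id, h$strand)
    expect_true(all(prev %in% ids))
    prev <- ids
  }
})

test_that("best_hit follows bit score, then e-value, then identity", {
  h <- data.frame(query_id = "q", subject_id = c("a", "b"),
                  bit_score = c(80, 50), e_value = c(1e-20, 1e-10),
                  identity_pct = c(90, 99), aligned_length = 100L,
                  stringsAsFactors = FALSE)
  expect_equal(best_hit(h)$subject_id, "a")
  h$bit_score <- c(50, 50)
  expect_equal(best_hit(h)$subject_id, "a")       # lower e-value wins
  h$e_value <- c(1e-10, 1e-10)
  expect_equal(best_hit(h)$subject_id, "b")       # higher identity wins
  expect_null(best_hit(h[0, ]))
  h$query_id <- c("q1", "q2")
  expect_error(best_hit(h), "single query")
})

test_that("similarity filter thresholds are inclusive on both axes", {
  mk <- function(id, len) data.frame(identity_pct = id, aligned_length = len)
  expect_true(passes_similarity_filter(mk(85, 150), 80, 100))
  expect_false(passes_similarity_filter(mk(79, 150), 80, 100))
  expect_false(passes_similarity_filter(mk(100, 99), 80, 100))
  expect_true(passes_similarity_filter(mk(80, 100), 80, 100))
})

test_that("amino-acid mode scores with BLOSUM62 and rejects mixed kinds", {
  set.seed(26)
  aa <- "MKVLITGGAGFIGSHLVDRLMAEGHEVIVLDNFFTGRKRNVE"
  hits <- search_hits(list(id = "q", seq = aa),
                      annotated_seqs("s", aa, kind = "AA"), "AA",
                      evalue_cutoff = Inf)
  expect_equal(hits$identity_pct[1], 100)
  pa <- oracle_local_score(aa, aa, "AA")
  expect_equal(hits$raw_score[1], Biostrings::score(pa))
  expect_error(
    search_hits(annotated_seqs("q", "ATGC", kind = "NT"),
                annotated_seqs("s", aa, kind = "AA"), "NT"),
    "kind")
})
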