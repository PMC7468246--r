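make_refs <- function(n = 4, len = 400) {
  set.seed(70)
  root <- random_nt_seq(len)
  seqs <- vapply(seq_len(n), function(i) {
    ch <- strsplit(root, "")[[1]]
    hit <- sample(len, round(0.1 * len))
    for (p in hit) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    paste(ch, collapse = "")
  }, character(1))
  annotated_seqs(sprintf("coi_T%d", seq_len(n)), seqs,
                 taxon = sprintf("T%d", seq_len(n)))
}

test_that("a 100-fold weaker other-taxon hit is a disregarded contaminant", {
  refs <- make_refs()
  contigs <- annotated_seqs(c("c1", "c2"),
                            c(refs$seq[1], refs$seq[2]))
  covs <- c(c1 = 5000, c2 = 30)
  rep <- barcode_check("s1", "T1", contigs, covs, refs)
  expect_equal(rep$verdict, "VERIFIED")
  expect_equal(rep$best_match_taxon, "T1")
  expect_equal(rep$hits$coverage_ratio_to_top, c(1, 30 / 5000))
  expect_equal(rep$hits$severity, c("OK", "CONTAMINANT"))
})

test_that("an other-taxon hit above the fold threshold warns but still verifies", {
  refs <- make_refs()
  contigs <- annotated_seqs(c("c1", "c2"), c(refs$seq[1], refs$seq[2]))
  rep <- barcode_check("s1", "T1", contigs, c(c1 = 5000, c2 = 200), refs)
  expect_equal(rep$verdict, "VERIFIED")
  expect_equal(rep$hits$severity[2], "WARNING")
  # raising coverage_fold never flips VERIFIED to suspect
  rep2 <- barcode_check("s1", "T1", contigs, c(c1 = 5000, c2 = 200), refs,
                        coverage_fold = 1000)
  expect_equal(rep2$verdict, "VERIFIED")
})

test_that("wrong top taxon and absent hits give the other verdicts", {
  refs <- make_refs()
  contigs <- annotated_seqs("c1", refs$seq[2])
  rep <- barcode_check("s1", "T1", contigs, c(c1 = 4000), refs)
  expect_equal(rep$verdict, "MISIDENTIFIED_SUSPECT")
  none <- annotated_seqs("c1", random_nt_seq(400))
  rep2 <- barcode_check("s1", "T1", none, c(c1 = 4000), refs)
  expect_equal(rep2$verdict, "UNVERIFIED")
  expect_error(barcode_check("s1", "T1", contigs, c(zz = 1), refs),
               "no coverage entry")
  expect_error(barcode_check("s1", "T1", contigs, c(c1 = 1), refs[0, ]),
               "empty barcode reference")
})

test_that("the 98%/200 bp qualifying rule is inclusive at both boundaries", {
  set.seed(71)
  ref <- annotated_seqs("coi_T1", random_nt_seq(400), taxon = "T1")
  # 200 columns with 196 matches = exactly 98%, 11-match tail run for
  # the seed, mismatches isolated so the full span stays optimal
  ch <- strsplit(substr(ref$seq, 1, 200), "")[[1]]
  for (p in c(48, 92, 136, 180)) {
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  }
  contig <- annotated_seqs("c1", paste(ch, collapse = ""))
  rep <- barcode_check("s1", "T1", contig, c(c1 = 10), ref,
                       min_identity = 98, min_len = 200)
  expect_equal(rep$verdict, "VERIFIED")
  rep2 <- barcode_check("s1", "T1", contig, c(c1 = 10), ref,
                        min_identity = 98.5, min_len = 200)
  expect_equal(rep2$verdict, "UNVERIFIED")
  # a 199 bp contig is ignored before alignment
  short <- annotated_seqs("c1", substr(ref$seq, 1, 199))
  expect_message(
    rep3 <- barcode_check("s1", "T1", short, c(c1 = 10), ref, min_len = 200),
    "below 200")
  expect_equal(rep3$verdict, "UNVERIFIED")
})

test_that("verdicts are invariant under contig reordering and renaming", {
  refs <- make_refs()
  contigs <- annotated_seqs(c("c1", "c2"), c(refs$seq[1], refs$seq[2]))
  covs <- c(c1 = 5000, c2 = 30)
  r1 <- barcode_check("s1", "T1", contigs, covs, refs)
  r2 <- barcode_check("s1", "T1", contigs[2:1, ], covs, refs)
  expect_equal(r1$verdict, r2$verdict)
  expect_equal(r1$hits$matched_reference_taxon,
               r2$hits$matched_reference_taxon)
  ren <- contigs; ren$id <- c("x9", "x1")
  r3 <- barcode_check("s1", "T1", ren, c(x9 = 5000, x1 = 30), refs)
  expect_equal(r3$verdict, r1$verdict)
  expect_equal(r3$hits$coverage, r1$hits$coverage)
})

test_that("coverage summaries report mean and SD per class", {
  s <- coverage_summary(data.frame(label = c("TARGET", "TARGET", "TARGET"),
                                   coverage = c(1, 2, 3)))
  expect_equal(s$mean, 2); expect_equal(s$sd, 1)
  one <- coverage_summary(data.frame(label = "COI", coverage = 5))
  expect_true(is.na(one$sd))
  two <- coverage_summary(data.frame(label = c("COI", "H3", "H3"),
                                     coverage = c(1, 4, 6)))
  expect_equal(nrow(two), 2L)
  expect_equal(two$mean[two$label == "H3"], 5)
})
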