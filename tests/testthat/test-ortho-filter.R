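make_og <- function(taxa, clades, n_codons = 60, id = "OG1") {
  cds <- vapply(seq_along(taxa), function(i) random_cds_seq(n_codons),
                character(1))
  orthogroup(id,
             aa = annotated_seqs(taxa, translate_cds(cds), taxa, clades, "AA"),
             nt = annotated_seqs(taxa, cds, taxa, clades, "NT"))
}

test_that("representation requires six scleractinians and two per clade", {
  set.seed(31)
  og <- make_og(c("r1", "r2", "r3", "c1", "c2", "c3"),
                rep(c("ROBUST", "COMPLEX"), each = 3))
  expect_true(representation_filter(og))
  og2 <- make_og(c("r1", "r2", "r3", "r4", "r5", "c1"),
                 c(rep("ROBUST", 5), "COMPLEX"))
  expect_false(representation_filter(og2))            # one Complex only
  expect_true(representation_filter(og2, min_per_clade = 1L))
  og3 <- make_og(c("r1", "r2", "c1", "c2", "o1"),
                 c("ROBUST", "ROBUST", "COMPLEX", "COMPLEX", "OUTGROUP"))
  expect_false(representation_filter(og3))            # five taxa, og excluded
})

test_that("representation counts distinct taxa and is monotone in added taxa", {
  set.seed(32)
  # paralogs: same taxon twice must not inflate the count
  og <- make_og(c("r1a", "r1b", "r2", "c1", "c2", "c3"),
                c("ROBUST", "ROBUST", "ROBUST", rep("COMPLEX", 3)))
  og$aa$taxon[1:2] <- "r1"; og$nt$taxon[1:2] <- "r1"
  expect_false(representation_filter(og))             # 5 distinct taxa
  for (i in 1:10) {
    n <- sample(3:8, 1)
    clades <- sample(c("ROBUST", "COMPLEX"), n, TRUE)
    og <- make_og(sprintf("t%d", seq_len(n)), clades)
    before <- representation_filter(og)
    extra <- make_og(c(sprintf("t%d", seq_len(n)), "zz"),
                     c(clades, sample(c("ROBUST", "COMPLEX"), 1)))
    if (before) expect_true(representation_filter(extra))
  }
})

test_that("genome anchoring is inclusive at the bit-score threshold", {
  set.seed(33)
  og <- make_og(c("r1", "r2", "r3", "c1", "c2", "c3"),
                rep(c("ROBUST", "COMPLEX"), each = 3), n_codons = 80)
  models <- list(G1 = annotated_seqs("G1_m1", og$aa$seq[1], kind = "AA"))
  expect_true(genome_anchor(og, models))              # self-match anchors
  # exact threshold: the achieved bit score itself is inclusive
  hit <- search_hits(og$aa[1, ], models$G1, "AA")
  expect_true(genome_anchor(og, models, min_bit_score = hit$bit_score[1]))
  expect_false(genome_anchor(og, models,
                             min_bit_score = hit$bit_score[1] + 0.01))
  # unrelated models anchor nothing at 50 bits
  rnd <- list(G1 = annotated_seqs("G1_r", translate_cds(random_cds_seq(80)),
                                  kind = "AA"))
  expect_false(genome_anchor(og, rnd))
})

test_that("contaminant members are removed on their single best hit only", {
  set.seed(34)
  taxa <- sprintf("t%d", 1:7)
  clades <- c(rep("ROBUST", 3), rep("COMPLEX", 4))
  cds <- vapply(taxa, function(x) random_cds_seq(80), character(1))
  backbone <- random_cds_seq(80)
  cds["t7"] <- backbone                       # t7 is the planted contaminant
  og <- orthogroup("OG1",
                   annotated_seqs(taxa, translate_cds(unname(cds)), taxa,
                                  clades, "AA"),
                   annotated_seqs(taxa, unname(cds), taxa, clades, "NT"))
  db <- annotated_seqs(
    c("cn1", "noncn1"),
    c(cds[["t1"]], backbone),                 # t1's best hit is cnidarian
    taxon = c("cn", "noncn"), clade = c("ROBUST", "OTHER"), kind = "NT")
  res <- remove_contaminant_transcripts(og, db, min_taxa = 6L)
  expect_equal(attr(res, "removed"), "t7")
  expect_false("t7" %in% res$nt$id)
  expect_true("t1" %in% res$nt$id)            # cnidarian best hit: kept
  # idempotence
  res2 <- remove_contaminant_transcripts(res, db, min_taxa = 6L)
  expect_equal(res2$nt$id, res$nt$id)
  expect_length(attr(res2, "removed"), 0L)
  # dropping a member of a six-taxon group kills the whole orthogroup
  og6 <- orthogroup("OG2",
                    og$aa[2:7, , drop = FALSE], og$nt[2:7, , drop = FALSE])
  expect_null(remove_contaminant_transcripts(og6, db, min_taxa = 6L))
})

test_that("bin assignment follows the orthogroup-wide best hit", {
  set.seed(35)
  og <- make_og(c("r1", "r2", "c1", "c2", "c3", "c4"),
                c("ROBUST", "ROBUST", rep("COMPLEX", 4)), n_codons = 70)
  near <- og$aa$seq[2]
  models <- list(
    G1 = annotated_seqs("G1_m", substr(near, 1, 40), kind = "AA"),
    G2 = annotated_seqs("G2_m", near, kind = "AA"))  # full-length: best
  got <- assign_bin(og, models)
  expect_equal(got$bin, "G2")
  expect_equal(attr(got, "bin_hit")$subject_id, "G2_m")
  one <- assign_bin(og, models["G2"])
  expect_equal(one$bin, "G2")
  rnd <- list(G1 = annotated_seqs("G1_r", translate_cds(random_cds_seq(10)),
                                  kind = "AA"))
  expect_error(assign_bin(og, rnd), "no gene-model hit")
})
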