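bait_df <- function(seqs, ids = sprintf("L|0-240|tile%d|t|target",
                                        seq_along(seqs))) {
  data.frame(bait_id = ids, tile_index = seq_along(seqs), start = 0L,
             source_taxon = "t", sequence = seqs, label = "TARGET",
             region_id = "L|0-240", stringsAsFactors = FALSE)
}

test_that("symbiont screen flags verbatim copies and spares weak matches", {
  set.seed(61)
  refs <- annotated_seqs(c("S1", "S2"),
                         c(random_nt_seq(800), random_nt_seq(800)))
  planted <- substr(refs$seq[1], 101, 220)
  clean <- random_nt_seq(120)
  flags <- symbiont_screen(bait_df(c(planted, clean),
                                   c("L|0-240|tile1|t|target",
                                     "L|0-240|tile2|t|target")), refs)
  expect_equal(as.character(flags), "L|0-240|tile1|t|target")
  expect_equal(attr(flags, "criterion"), "SYMBIONT_MAP")
})

test_that("the 70% length criterion is inclusive at 84 of 120 positions", {
  set.seed(62)
  bait <- random_nt_seq(120)
  ref84 <- annotated_seqs("S", substr(bait, 1, 84))
  ref83 <- annotated_seqs("S", substr(bait, 1, 83))
  # blast criterion disabled so only the mapping rule decides
  expect_length(symbiont_screen(bait_df(bait), ref84, blast_evalue = 0), 1L)
  expect_length(symbiont_screen(bait_df(bait), ref83, blast_evalue = 0), 0L)
})

test_that("the 70% identity criterion is inclusive at exactly 70%", {
  set.seed(63)
  bait <- random_nt_seq(120)
  # subject = 90 aligned columns with 63 matches = exactly 70% identity;
  # mismatches spread so the full span is the optimal local alignment,
  # with an 11-match tail run so the word seed fires
  ch <- strsplit(substr(bait, 1, 90), "")[[1]]
  flip <- c(seq(3, 78, 3), 79)               # 27 interior mismatches
  for (p in flip) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  subj <- annotated_seqs("S", paste(ch, collapse = ""))
  flags70 <- symbiont_screen(bait_df(bait), subj, map_identity = 70,
                             blast_evalue = 0)
  flags71 <- symbiont_screen(bait_df(bait), subj, map_identity = 70.1,
                             blast_evalue = 0)
  expect_length(flags70, 1L)
  expect_length(flags71, 0L)
})

test_that("region pruning follows the >=3-removed or <=1-remaining rule", {
  mk_region <- function(n, locus = "L") {
    baits <- bait_df(vapply(seq_len(n), function(i) random_nt_seq(120),
                            character(1)),
                     sprintf("%s|0-240|tile%d|t|target", locus, seq_len(n)))
    baits$region_id <- paste0(locus, "|0-240")
    structure(list(locus_id = locus, region_id = paste0(locus, "|0-240"),
                   window_start = 0L, window_end = 240L,
                   window_length = 240L, n_tiles = n,
                   mean_identity = 1, bin = NULL, label = "TARGET",
                   baits = baits[, -7]), class = "bait_region")
  }
  set.seed(64)
  r7 <- mk_region(7)
  pr <- prune_regions(list(r7), r7$baits$bait_id[1:3])
  expect_length(pr$regions, 0L)                       # 3 flagged: dropped
  pr2 <- prune_regions(list(r7), r7$baits$bait_id[1:2])
  expect_length(pr2$regions, 1L)
  expect_equal(nrow(pr2$regions[[1]]$baits), 5L)      # 2 flagged: kept
  r2 <- mk_region(2, "M")
  pr3 <- prune_regions(list(r2), r2$baits$bait_id[1])
  expect_length(pr3$regions, 0L)                      # one survivor: dropped
  # monotone: adding a flag never resurrects a region
  surviving_ids <- function(fl) vapply(prune_regions(list(r7), fl)$regions,
                                       `[[`, character(1), "region_id")
  for (i in 1:5) {
    f1 <- sample(r7$baits$bait_id, sample(0:6, 1))
    f2 <- unique(c(f1, sample(r7$baits$bait_id, 1)))
    expect_true(all(surviving_ids(f2) %in% surviving_ids(f1)))
  }
})

test_that("duplicate removal keeps first occurrences and is idempotent", {
  set.seed(65)
  s <- random_nt_seq(120)
  baits <- bait_df(c(s, random_nt_seq(120), s),
                   c("a|0-240|tile1|t|target", "b|0-240|tile1|t|target",
                     "c|0-240|tile1|t|target"))
  dd <- dedup_baits(baits)
  expect_equal(dd$removed, "c|0-240|tile1|t|target")
  expect_equal(dedup_baits(dd$baits)$removed, character(0))
  uniq <- bait_df(c(random_nt_seq(120), random_nt_seq(120)))
  expect_equal(nrow(dedup_baits(uniq)$baits), 2L)
})

test_that("self-hybridization screen matches the brute-force rc-substring oracle", {
  set.seed(66)
  seqs <- vapply(1:12, function(i) random_nt_seq(120), character(1))
  seqs[5] <- reverse_complement(seqs[2])               # an rc pair
  substr(seqs[9], 50, 74) <- reverse_complement(substr(seqs[9], 10, 34))
  ids <- sprintf("L%02d|0-240|tile1|t|target", 1:12)
  baits <- bait_df(seqs, ids)
  got <- sort(self_hyb_screen(baits, 21))
  want <- sort(brute_force_self_hyb(seqs, ids, 21))
  expect_equal(got, want)
  expect_true(ids[5] %in% got)                         # later id flagged
  expect_false(ids[2] %in% got)
  expect_true(ids[9] %in% got)                         # palindromic run
  both <- self_hyb_screen(baits, 21, resolution = "both")
  expect_true(all(c(ids[2], ids[5]) %in% both))
  # unrelated random baits never collide at 21 nt
  clean <- bait_df(vapply(1:10, function(i) random_nt_seq(120),
                          character(1)))
  expect_length(self_hyb_screen(clean, 21), 0L)
})

test_that("the full screen conserves counts and is idempotent", {
  ws <- small_design()
  screen <- ws$screen
  n_in <- unname(screen$counts["input"])
  n_out <- unname(screen$counts["surviving"])
  n_removed <- sum(screen$removed$unit == "bait")
  expect_equal(n_in, n_out + n_removed)
  expect_equal(n_removed, unname(screen$counts["removed"]))
  # every removed id existed in the input
  all_ids <- baits_table(ws$regions)$bait_id
  expect_true(all(screen$removed$id[screen$removed$unit == "bait"]
                  %in% all_ids))
  # rerunning the cascade on its own survivors removes nothing
  symb <- read_fasta(file.path(small_workspace()$dir, "symbionts.fasta"),
                     "NT")
  again <- screen_baits(screen$regions, symb)
  expect_equal(nrow(again$removed), 0L)
  expect_equal(again$counts[["surviving"]], n_out)
})
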