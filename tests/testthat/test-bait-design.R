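test_that("tiling yields 7/5/3/1 baits for 240/200/160/120 bp windows", {
  sch <- tiling_scheme()
  expect_equal(tile_positions(240, sch), seq(0, 120, 20))
  expect_length(tile_positions(240, sch), 7L)
  expect_length(tile_positions(200, sch), 5L)
  expect_length(tile_positions(160, sch), 3L)
  expect_equal(tile_positions(120, sch), 0L)
  expect_error(tile_positions(100, sch), "shorter than a bait")
  expect_error(tiling_scheme(window_lengths = c(250, 240)), "")
})

test_that("a gap-free single-exon alignment hosts a 240 bp window", {
  set.seed(51)
  loc <- toy_codon_alignment(n_rows = 4, n_codons = 100)   # 300 nt columns
  emap <- cbind(start = 0L, end = 300L)
  w <- find_window(loc, emap)
  expect_equal(w$length, 240L)
  reg <- make_region(loc, w)
  expect_equal(reg$n_tiles, 7L)
  expect_true(all(nchar(reg$baits$sequence) == 120L))
  expect_false(any(grepl("[-N]", reg$baits$sequence)))
})

test_that("short exons force the shortest window and exons are never crossed", {
  set.seed(52)
  loc <- toy_codon_alignment(n_rows = 3, n_codons = 100)
  emap <- cbind(start = c(0L, 132L), end = c(132L, 282L))  # 132 and 150 nt
  w <- find_window(loc, emap)
  expect_equal(w$length, 120L)
  # the window sits wholly inside one exon span
  spans <- project_exons(loc, emap)
  inside <- any(w$start >= spans[, "start"] & w$end <= spans[, "end"])
  expect_true(inside)
})

test_that("windows respect the strict gap rule", {
  rows <- c(a = paste0(strrep("ACG", 50), strrep("-", 60)),
            b = paste0(strrep("-", 60), strrep("ACG", 50)))
  aa <- vapply(rows, function(s) strrep("X", nchar(s) / 3), character(1))
  loc <- codon_alignment("L", rows, aa, ref_taxon = "r",
                         ref_aa_row = strrep("X", 70))
  expect_null(find_window(loc, cbind(start = 0L, end = 210L)))
})

test_that("find_window is invariant under row order", {
  set.seed(53)
  loc <- toy_codon_alignment(n_rows = 5, n_codons = 120)
  emap <- cbind(start = 0L, end = 360L)
  w1 <- find_window(loc, emap)
  perm <- sample(length(loc$rows))
  loc2 <- codon_alignment(loc$locus_id, loc$rows[perm], loc$aa_rows[perm],
                          ref_taxon = loc$ref_taxon,
                          ref_aa_row = loc$ref_aa_row)
  w2 <- find_window(loc2, emap)
  expect_equal(w1[c("start", "end", "length", "mean_identity")],
               w2[c("start", "end", "length", "mean_identity")])
})

test_that("tiles collapse duplicates and skip gapped rows per tile", {
  base <- random_cds_seq(80)                 # 240 nt
  rows <- c(a = base, b = base)
  aa <- setNames(translate_cds(rows), names(rows))
  loc <- codon_alignment("L", rows, aa)
  w <- list(start = 0L, end = 240L, length = 240L, mean_identity = 1)
  reg <- make_region(loc, w)
  expect_equal(nrow(reg$baits), 7L)          # identical rows collapse
  expect_true(all(reg$baits$source_taxon == "a"))
  # one mismatch inside every tile doubles the count
  b2 <- base
  for (p in c(60, 180)) {                    # two positions cover all 7 tiles
    old <- substr(b2, p, p)
    substr(b2, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  loc2 <- codon_alignment("L", c(a = base, b = b2),
                          setNames(translate_cds(c(base, b2)), c("a", "b")))
  reg2 <- make_region(loc2, w)
  expect_equal(nrow(reg2$baits), 14L)
  # a central gap in one row removes only the overlapping tiles
  b3 <- base; substr(b3, 118, 120) <- "---"
  loc3 <- codon_alignment("L", c(a = base, b = b3),
                          setNames(c(translate_cds(base), sub("X", "-",
                            translate_cds(sub("---", "NNN", b3)))), c("a", "b")))
  reg3 <- make_region(loc3, w)
  from_b <- reg3$baits[reg3$baits$source_taxon == "b", ]
  overlapping <- which(vapply(seq(0, 120, 20), function(s)
    s < 120 && s + 120 > 117, logical(1)))
  expect_false(any(from_b$tile_index %in% overlapping))
})

test_that("the best region prefers longer, then more conserved, then leftmost", {
  mk <- function(len, ident, start) {
    w <- list(start = start, end = start + len, length = len,
              mean_identity = ident)
    structure(list(locus_id = "L", region_id = sprintf("L|%d", start),
                   window_start = start, window_end = start + len,
                   window_length = len, n_tiles = (len - 120L) %/% 20L + 1L,
                   mean_identity = ident, bin = NULL, label = "TARGET",
                   baits = data.frame()), class = "bait_region")
  }
  expect_equal(best_region_per_locus(list(mk(240L, .9, 0), mk(160L, .99, 0)))
               $window_length, 240L)
  expect_equal(best_region_per_locus(list(mk(160L, .91, 40),
                                          mk(160L, .98, 80)))$window_start, 80)
  expect_equal(best_region_per_locus(list(mk(120L, .5, 7)))$window_start, 7)
  expect_error(best_region_per_locus(list()), "no candidate")
})

test_that("barcode baits tile whole genes with an anchored final tile", {
  set.seed(54)
  g600 <- c(x = random_nt_seq(600))
  reg <- design_barcode_baits(g600, "COI")
  expect_equal(reg$n_tiles, 25L)             # floor((600-120)/20)+1
  expect_equal(nrow(reg$baits), 25L)
  g130 <- c(x = random_nt_seq(130))
  reg2 <- design_barcode_baits(g130, "H3")
  expect_equal(sort(unique(reg2$baits$start)), c(0L, 10L))
  expect_error(design_barcode_baits(c(x = random_nt_seq(100)), "COI"),
               "shorter than a bait")
  # divergent sequences produce variant baits on divergent tiles
  a <- random_nt_seq(200)
  b <- a; substr(b, 100, 100) <- setdiff(c("A", "C", "G", "T"),
                                         substr(a, 100, 100))[1]
  reg3 <- design_barcode_baits(c(a = a, b = b), "COI")
  expect_gt(nrow(reg3$baits), reg3$n_tiles)
  expect_true(all(reg3$baits$label == "COI"))
})
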