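library(ape)

test_that("low-support branches collapse without changing the tip set", {
  tr <- read.tree(text = "((A:1,B:1)95:1,(C:1,D:1)5:1,E:1);")
  out <- collapse_low_support(tr, 10)
  expect_equal(sort(out$tip.label), sort(tr$tip.label))
  expect_equal(out$Nnode, tr$Nnode - 1L)       # one polytomy created
  full <- read.tree(text = "((A:1,B:1)95:1,(C:1,D:1)80:1,E:1);")
  expect_equal(collapse_low_support(full, 10)$Nnode, full$Nnode)
  star <- read.tree(text = "(A:1,B:1,C:1,D:1);")
  expect_equal(collapse_low_support(star, 10)$Nnode, 1L)
})

test_that("Type I paralogs resolve to .main, then 0.0, then untagged", {
  expect_equal(resolve_type1_paralogs(c("X.main", "X.0.0"))$keep, "X.main")
  r <- resolve_type1_paralogs(c("X.0.0", "X.0.1"))
  expect_equal(r$keep, "X.0.0"); expect_equal(r$drop, "X.0.1")
  expect_equal(resolve_type1_paralogs("X")$keep, "X")
  expect_error(resolve_type1_paralogs(c("X.0.1", "X.1.1")), "neither")
  tags <- parse_paralog_tags(c("Acropora.main", "Porites.0.1", "Galaxea"))
  expect_equal(tags$taxon, c("Acropora", "Porites", "Galaxea"))
  expect_equal(tags$tag, c("main", "0.1", ""))
})

test_that("deep duplications are flagged, taxon-local ones are not", {
  deep <- read.tree(text = "((A.0.0:1,B.0.0:1)90:1,(A.0.1:1,B.0.1:1)90:1);")
  expect_true(flag_type2_paralogy(deep))
  shallow <- read.tree(text = "((A.main:1,A.0.0:1)90:1,(B:1,C:1)90:1);")
  expect_false(flag_type2_paralogy(shallow))
  single <- read.tree(text = "((A:1,B:1)90:1,(C:1,D:1)90:1);")
  expect_false(flag_type2_paralogy(single))
})

clades6 <- c(R1 = "ROBUST", R2 = "ROBUST", R3 = "ROBUST",
             C1 = "COMPLEX", C2 = "COMPLEX", C3 = "COMPLEX",
             C4 = "COMPLEX", O1 = "OUTGROUP", O2 = "OUTGROUP")

test_that("a taxon in the wrong major clade is removed (criterion b)", {
  tr <- read.tree(text = paste0(
    "((R1:.05,R2:.05,R3:.05,C4:.05)100:.1,",
    "(C1:.05,C2:.05,C3:.05)100:.1,(O1:.05,O2:.05)100:.1);"))
  rem <- apply_contamination_criteria(tr, clades6)
  expect_equal(rem$label, "C4")
  expect_equal(rem$criterion, "CRIT_B")
})

test_that("the wrong-clade copy of a paralog pair is removed (criterion a)", {
  cl <- c(clades6, X = "COMPLEX")
  tr <- read.tree(text = paste0(
    "((R1:.05,R2:.05,R3:.05,X.0.1:.05)100:.1,",
    "(C1:.05,C2:.05,C3:.05,X.0.0:.05)100:.1,(O1:.05,O2:.05)100:.1);"))
  rem <- apply_contamination_criteria(tr, cl)
  expect_equal(rem$label, "X.0.1")
  expect_equal(rem$criterion, "CRIT_A")
})

test_that("unusually long pendant branches are removed (criterion c)", {
  tr <- read.tree(text = paste0(
    "((R1:.05,R2:.05,R3:.5)100:.1,",
    "(C1:.05,C2:.05,C3:.05)100:.1,(O1:.05,O2:.05)100:.1);"))
  rem <- apply_contamination_criteria(tr, clades6, long_branch_factor = 5)
  expect_true("R3" %in% rem$label)
  expect_equal(rem$criterion[rem$label == "R3"], "CRIT_C")
  even <- read.tree(text = paste0(
    "((R1:.05,R2:.05,R3:.05)100:.1,",
    "(C1:.05,C2:.05,C3:.05)100:.1,(O1:.05,O2:.05)100:.1);"))
  expect_equal(nrow(apply_contamination_criteria(even, clades6)), 0L)
})

test_that("curation conserves tips between survivors and the removal log", {
  set.seed(81)
  tr <- read.tree(text = paste0(
    "((R1:.05,R2:.05,R3:.05,C4:.05)100:.1,",
    "(C1:.05,C2:.05,C3.main:.05,C3.0.0:.05)100:.1,",
    "(O1:.05,O2:.05)100:.1);"))
  seqs <- setNames(vapply(tr$tip.label, function(x) random_cds_seq(60),
                          character(1)), tr$tip.label)
  cur <- curate_locus("L1", tr, seqs, clades6, min_pi_sites = 0L)
  expect_true(cur$kept)
  removed_tips <- cur$removal_log$id[cur$removal_log$unit == "tip"]
  kept_taxa <- names(cur$sequences)
  expect_setequal(c(removed_tips, paste0(kept_taxa,
                    ifelse(kept_taxa == "C3", ".main", ""))),
                  tr$tip.label)
  expect_true("C4" %in% removed_tips)          # criterion (b)
  expect_true("C3.0.0" %in% removed_tips)      # paralog resolved
  expect_false("C3.0.0" %in% kept_taxa)
})

test_that("locus-level filters drop sparse and uninformative loci", {
  cl <- c(A = "ROBUST", B = "COMPLEX", C = "COMPLEX", D = "ROBUST",
          O = "OUTGROUP")
  two <- setNames(rep("ACGTACGT", 3), c("A", "B", "O"))
  expect_equal(locus_level_filter(two, cl)$reason, "LOW_TAXA")
  flat <- setNames(rep("ACGTACGT", 4), c("A", "B", "C", "D"))
  expect_equal(locus_level_filter(flat, cl)$reason, "UNINFORMATIVE")
  set.seed(82)
  base <- random_nt_seq(60)
  varied <- vapply(1:4, function(i) {
    ch <- strsplit(base, "")[[1]]
    if (i > 2) ch[1:30] <- rev(ch[1:30])
    paste(ch, collapse = "")
  }, character(1))
  names(varied) <- c("A", "B", "C", "D")
  expect_true(locus_level_filter(varied, cl)$keep)
})
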