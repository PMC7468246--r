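# Independent oracles and small generators shared across the suite.

random_nt_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                          replace = TRUE), collapse = "")

random_cds_seq <- function(n_codons) {
  nonstop <- setdiff(apply(expand.grid(c("T", "C", "A", "G"),
                                       c("T", "C", "A", "G"),
                                       c("T", "C", "A", "G")),
                           1, paste, collapse = ""),
                     c("TAA", "TAG", "TGA"))
  paste(sample(nonstop, n_codons, replace = TRUE), collapse = "")
}

# full (unseeded) local-alignment oracle via Biostrings, scores only
oracle_local_score <- function(a, b, mode = "NT") {
  if (mode == "NT") {
    sub <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                    baseOnly = TRUE)
  } else {
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    sub <- get("BLOSUM62", envir = e)
  }
  pa <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                      substitutionMatrix = sub,
                                      gapOpening = 5, gapExtension = 2)
  pa
}

# does the optimal local alignment contain an exact run of >= k matches?
oracle_alignment_has_seed <- function(pa, k) {
  p <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
  if (!length(p)) return(FALSE)
  runs <- rle(p == s & p != "-")
  any(runs$lengths[runs$values] >= k)
}

# brute-force reverse-complement run scan for the self-hyb oracle:
# do a and b share a k-mer after reverse-complementing b?
rc_oracle <- function(a, b, k) {
  rcb <- chartr("ACGT", "TGCA", b)
  rcb <- paste(rev(strsplit(rcb, "")[[1]]), collapse = "")
  ka <- substring(a, 1:(nchar(a) - k + 1), k:nchar(a))
  kb <- substring(rcb, 1:(nchar(rcb) - k + 1), k:nchar(rcb))
  any(ka %in% kb)
}

brute_force_self_hyb <- function(seqs, ids, k) {
  flagged <- character()
  n <- length(seqs)
  for (i in seq_len(n)) {
    if (rc_oracle(seqs[i], seqs[i], k)) flagged <- c(flagged, ids[i])
    if (i < n) for (j in (i + 1):n) {
      if (rc_oracle(seqs[i], seqs[j], k)) flagged <- c(flagged, ids[max(i, j)])
    }
  }
  unique(flagged)
}

# exhaustive per-column parsimony-informative census
brute_force_pi <- function(rows) {
  mat <- do.call(rbind, strsplit(unname(rows), ""))
  n <- 0L
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    col <- col[!col %in% c("-", "?", "N")]
    if (length(col) && sum(table(col) >= 2) >= 2) n <- n + 1L
  }
  n
}

# a tiny hand-rolled codon alignment with a reference row
toy_codon_alignment <- function(n_rows = 4, n_codons = 100, locus = "L1",
                                mutate = 0.05) {
  base <- random_cds_seq(n_codons)
  rows <- setNames(vapply(seq_len(n_rows), function(i) {
    ch <- strsplit(base, "")[[1]]
    hit <- which(stats::runif(length(ch)) < mutate)
    for (p in hit) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    s <- paste(ch, collapse = "")
    # repair any stop created by mutation
    cod <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    cod[cod %in% c("TAA", "TAG", "TGA")] <-
      paste0(substr(cod[cod %in% c("TAA", "TAG", "TGA")], 1, 2), "C")
    paste(cod, collapse = "")
  }, character(1)), paste0("t", seq_len(n_rows)))
  aa <- setNames(translate_cds(rows), names(rows))
  codon_alignment(locus, rows, aa, ref_taxon = "ref", ref_aa_row = aa[[1]])
}

# cached small fixture workspace + pipeline runs, shared across tests
.test_cache <- new.env(parent = emptyenv())

small_workspace <- function() {
  if (!is.null(.test_cache$small)) return(.test_cache$small)
  dir <- file.path(tempdir(), "coralbaits-small-ws")
  unlink(dir, recursive = TRUE)
  cfg <- fixture_config(seed = 11L, n_robust = 5L, n_complex = 5L,
                        n_outgroup = 2L, n_loci = 6L,
                        locus_length_range = c(100L, 180L),
                        n_type2_loci = 1L, n_misplaced = 1L)
  sim <- make_fixture_workspace(cfg, dir)
  .test_cache$small <- list(dir = dir, cfg = cfg, sim = sim)
  .test_cache$small
}

small_design <- function() {
  if (!is.null(.test_cache$small_design)) return(.test_cache$small_design)
  ws <- small_workspace()
  .test_cache$small_design <- run_design(file.path(ws$dir, "config.yaml"))
  .test_cache$small_design
}
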