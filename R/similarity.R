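#' Scoring schemes for the local-alignment engine
#'
#' A scheme bundles substitution scores, affine gap penalties and the
#' Karlin-Altschul parameters used to convert raw Smith-Waterman scores
#' into bit scores and e-values:
#' `bit = (lambda * S - ln K) / ln 2` and
#' `e = K * m * n * exp(-lambda * S)` with `m` the query length and `n`
#' the total subject length.
#'
#' Defaults: nucleotide match +2 / mismatch -3, gap open 5 / extend 2,
#' `lambda = 0.625`, `K = 0.41`; amino-acid mode uses BLOSUM62 with the
#' published gapped values `lambda = 0.267`, `K = 0.041`.  A gap of
#' length L costs `gap_open + L * gap_extend`.
#'
#' @param match,mismatch integer substitution scores (NT mode).
#' @param gap_open,gap_extend nonnegative integer gap penalties.
#' @param lambda,K positive Karlin-Altschul parameters.
#' @param seed_length exact-word seed length gating alignment.
#' @return a `scoring_scheme` list.
#' @export
nt_scheme <- function(match = 2L, mismatch = -3L, gap_open = 5L,
                      gap_extend = 2L, lambda = 0.625, K = 0.41,
                      seed_length = 11L) {
  stopifnot(match > 0L, mismatch < 0L, gap_open >= 0L, gap_extend >= 0L,
            lambda > 0, K > 0, seed_length >= 1L)
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(as.integer(mismatch), 5L, 5L, dimnames = list(letters, letters))
  diag(m) <- as.integer(match)
  m["N", ] <- as.integer(mismatch); m[, "N"] <- as.integer(mismatch)
  structure(list(kind = "NT", matrix = m, gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend), lambda = lambda,
                 K = K, seed_length = as.integer(seed_length), band = 32L),
            class = "scoring_scheme")
}

#' @rdname nt_scheme
#' @param aa_matrix name of the substitution matrix (only `"BLOSUM62"`
#'   ships with the package's dependencies).
#' @export
aa_scheme <- function(aa_matrix = "BLOSUM62", gap_open = 5L, gap_extend = 2L,
                      lambda = 0.267, K = 0.041, seed_length = 4L) {
  stopifnot(lambda > 0, K > 0, seed_length >= 1L)
  e <- new.env()
  utils::data(list = aa_matrix, package = "Biostrings", envir = e)
  m <- get(aa_matrix, envir = e)
  structure(list(kind = "AA", matrix = m, gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend), lambda = lambda,
                 K = K, seed_length = as.integer(seed_length), band = 32L),
            class = "scoring_scheme")
}

bit_score <- function(raw, scheme) (scheme$lambda * raw - log(scheme$K)) / log(2)
e_value <- function(raw, m, n, scheme) scheme$K * m * n * exp(-scheme$lambda * raw)

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             identity_pct = numeric(), aligned_length = integer(),
             mismatches = integer(), gap_opens = integer(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             e_value = numeric(), bit_score = numeric(),
             raw_score = integer(), strand = character(),
             stringsAsFactors = FALSE)
}

#' Seeded local-alignment search
#'
#' A BLAST-like homology search: a subject is aligned only when it
#' shares an exact seed word with the query (11 nt in NT mode, 4 aa in
#' AA mode; both strands in NT mode), in which case the optimal local
#' (Smith-Waterman, affine-gap) alignment is computed in full and
#' reported as a single hit per subject and strand.  Identity is
#' measured over all alignment columns including gap columns.
#'
#' @param query a single-row [annotated_seqs] table (or a list with
#'   `id` and `seq`).
#' @param subjects an [annotated_seqs] table.
#' @param mode `"NT"` or `"AA"`; must match both inputs.
#' @param evalue_cutoff report only hits with `e_value <=` this value.
#' @param scheme a [nt_scheme]/[aa_scheme]; defaults by mode.
#' @return a hit table (12-column BLAST-style ordering plus `raw_score`
#'   and `strand`), 0-based half-open coordinates, sorted best-first
#'   under the [best_hit] order.
#' @export
search_hits <- function(query, subjects, mode = c("NT", "AA"),
                        evalue_cutoff = 1e-6, scheme = NULL) {
  mode <- match.arg(mode)
  if (is.data.frame(query)) {
    stopifnot(nrow(query) == 1L)
    if (!is.null(query$kind) && query$kind[1] != mode)
      stop("query kind ", query$kind[1], " does not match mode ", mode)
    query <- list(id = query$id[1], seq = query$seq[1])
  }
  if (NROW(subjects) == 0L) return(empty_hits())
  if (!is.null(subjects$kind) && any(subjects$kind != mode))
    stop("subject kind does not match mode ", mode)
  if (is.null(scheme)) scheme <- if (mode == "NT") nt_scheme() else aa_scheme()
  stopifnot(inherits(scheme, "scoring_scheme"), scheme$kind == mode)

  qseq <- toupper(query$seq)
  sseq <- toupper(subjects$seq)
  n_total <- sum(nchar(sseq))
  m_len <- nchar(qseq)
  k <- scheme$seed_length

  strands <- if (mode == "NT") c("+", "-") else "+"
  band <- scheme$band %||% 32L
  rows <- list()
  for (strand in strands) {
    target <- if (strand == "+") sseq else reverse_complement(sseq)
    diags <- .seed_diags_cpp(qseq, target, k)
    for (i in which(diags[, 1] == 1L)) {
      # gapped extension banded around the seed diagonals; recompute
      # unbanded when the optimal path touches the band boundary
      ambig <- if (mode == "NT") "N" else "X"
      al <- .sw_align_cpp(qseq, target[i], scheme$matrix,
                          scheme$gap_open, scheme$gap_extend,
                          diags[i, 2] - band, diags[i, 3] + band, ambig)
      if (isTRUE(al$band_edge))
        al <- .sw_align_cpp(qseq, target[i], scheme$matrix,
                            scheme$gap_open, scheme$gap_extend,
                            NA_integer_, NA_integer_, ambig)
      if (al$score <= 0L) next
      ev <- e_value(al$score, m_len, n_total, scheme)
      if (ev > evalue_cutoff) next
      slen <- nchar(target[i])
      s_start <- if (strand == "+") al$s_start else slen - al$s_end
      s_end <- if (strand == "+") al$s_end else slen - al$s_start
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = query$id, subject_id = subjects$id[i],
        identity_pct = 100 * al$matches / al$aligned_length,
        aligned_length = al$aligned_length, mismatches = al$mismatches,
        gap_opens = al$gap_opens, q_start = al$q_start, q_end = al$q_end,
        s_start = s_start, s_end = s_end, e_value = ev,
        bit_score = bit_score(al$score, scheme), raw_score = al$score,
        strand = strand, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_hits())
  hits <- do.call(rbind, rows)
  hits[hit_order(hits), , drop = FALSE]
}

hit_order <- function(hits) {
  order(-hits$bit_score, hits$e_value, -hits$identity_pct, hits$subject_id)
}

#' Single best hit under the published sorting rule
#'
#' Orders hits by highest bit score, then lowest e-value, then highest
#' percentage identity (subject id ascending as a final deterministic
#' tie-break) and returns the first; `NULL` for an empty table.
#'
#' @param hits a hit table for a single query.
#' @return a one-row hit table or `NULL`.
#' @export
best_hit <- function(hits) {
  if (NROW(hits) == 0L) return(NULL)
  if (length(unique(hits$query_id)) > 1L)
    stop("best_hit() expects hits from a single query")
  hits[hit_order(hits)[1L], , drop = FALSE]
}

#' Identity/length similarity filter
#'
#' @param hit a one-row hit table.
#' @param min_identity_pct minimum percent identity (inclusive).
#' @param min_length minimum alignment length in columns (inclusive).
#' @return `TRUE` iff both thresholds are met.
#' @export
passes_similarity_filter <- function(hit, min_identity_pct, min_length) {
  if (NROW(hit) == 0L) return(FALSE)
  hit$identity_pct[1] >= min_identity_pct && hit$aligned_length[1] >= min_length
}

#' Write hits as BLAST-style 12-column TSV
#'
#' Column order mirrors `blastn -outfmt 6`; a leading comment line notes
#' that coordinates are 0-based half-open.
#'
#' @param hits a hit table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# qid sid pident length mismatches gapopens qstart qend",
                   "sstart send evalue bitscore (coordinates 0-based half-open)"),
             con)
  cols <- c("query_id", "subject_id", "identity_pct", "aligned_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start",
            "s_end", "e_value", "bit_score")
  write.table(hits[, cols], con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
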