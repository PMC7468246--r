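#' Verify a sample's identity from barcode-matching contigs
#'
#' Contigs shorter than `min_len` are ignored.  Each retained contig's
#' single best hit against the barcode references must reach
#' `min_identity` percent identity (inclusive) over an alignment of at
#' least `min_len` columns to qualify.  The qualifying hit with the
#' highest contig coverage is the top hit; the verdict is:
#'
#' * `VERIFIED` — the top hit's reference taxon equals `expected_taxon`.
#'   Qualifying hits to other taxa are listed in the report: those with
#'   coverage at least `coverage_fold` times lower than the top hit are
#'   disregarded contaminants (severity `CONTAMINANT`); an other-taxon
#'   hit above that ratio does not flip the verdict but is reported with
#'   severity `WARNING`.
#' * `MISIDENTIFIED_SUSPECT` — the top hit belongs to another taxon.
#' * `UNVERIFIED` — no qualifying hit.
#'
#' @param sample_id sample identifier.
#' @param expected_taxon the taxon the sample is labelled as.
#' @param contigs an [annotated_seqs] NT table of assembled contigs.
#' @param coverages named numeric vector (contig id -> k-mer or
#'   read-depth coverage); every retained contig must be present.
#' @param references an [annotated_seqs] NT table of barcode sequences
#'   with `taxon=` tags.
#' @param locus barcode locus label (`"COI"` or `"H3"`), recorded in the
#'   report.
#' @param min_identity,min_len qualifying thresholds (default 98, 200).
#' @param coverage_fold ratio above which an other-taxon hit is
#'   disregarded (default 100).
#' @param scheme optional [nt_scheme].
#' @return a `barcode_report` list: `sample_id`, `locus`, `verdict`,
#'   `best_match_taxon`, and `hits` (data.frame sorted by coverage
#'   descending, with `coverage_ratio_to_top` and `severity`).
#' @export
barcode_check <- function(sample_id, expected_taxon, contigs, coverages,
                          references, locus = "COI", min_identity = 98,
                          min_len = 200L, coverage_fold = 100,
                          scheme = NULL) {
  if (NROW(references) == 0L) stop("empty barcode reference set")
  if (is.null(scheme)) scheme <- nt_scheme()
  keep <- nchar(contigs$seq) >= min_len
  if (any(!keep))
    message(sum(!keep), " contig(s) below ", min_len, " bp ignored for ",
            sample_id)
  contigs <- contigs[keep, , drop = FALSE]
  missing_cov <- setdiff(contigs$id, names(coverages))
  if (length(missing_cov))
    stop("no coverage entry for contig ", missing_cov[1])

  rows <- list()
  for (i in seq_len(NROW(contigs))) {
    hits <- search_hits(contigs[i, ], references, mode = "NT",
                        evalue_cutoff = Inf, scheme = scheme)
    bh <- best_hit(hits)
    if (is.null(bh)) next
    if (!passes_similarity_filter(bh, min_identity, min_len)) next
    ref_taxon <- references$taxon[match(bh$subject_id, references$id)]
    rows[[length(rows) + 1L]] <- data.frame(
      contig_id = contigs$id[i], matched_reference_taxon = ref_taxon,
      identity_pct = bh$identity_pct, aligned_length = bh$aligned_length,
      coverage = unname(coverages[contigs$id[i]]), stringsAsFactors = FALSE)
  }

  if (!length(rows)) {
    return(structure(list(sample_id = sample_id, locus = locus,
                          verdict = "UNVERIFIED", best_match_taxon = NULL,
                          hits = NULL), class = "barcode_report"))
  }
  hits <- do.call(rbind, rows)
  hits <- hits[order(-hits$coverage, hits$contig_id), , drop = FALSE]
  top <- hits[1L, ]
  hits$coverage_ratio_to_top <- hits$coverage / top$coverage
  other <- hits$matched_reference_taxon != top$matched_reference_taxon
  hits$severity <- "OK"
  hits$severity[other] <- ifelse(
    hits$coverage_ratio_to_top[other] <= 1 / coverage_fold,
    "CONTAMINANT", "WARNING")
  verdict <- if (top$matched_reference_taxon == expected_taxon)
    "VERIFIED" else "MISIDENTIFIED_SUSPECT"
  rownames(hits) <- NULL
  structure(list(sample_id = sample_id, locus = locus, verdict = verdict,
                 best_match_taxon = top$matched_reference_taxon,
                 hits = hits), class = "barcode_report")
}

#' @export
print.barcode_report <- function(x, ...) {
  cat(sprintf("<barcode_report %s [%s]: %s (best match: %s)>\n",
              x$sample_id, x$locus, x$verdict,
              x$best_match_taxon %||% "none"))
  if (!is.null(x$hits)) print(x$hits)
  invisible(x)
}

#' Per-class coverage summary
#'
#' Arithmetic mean and sample standard deviation of coverage per label
#' class (for example `TARGET` vs `COI` vs `H3`).  A class with a single
#' observation reports `NA` for the SD; empty classes are simply absent.
#'
#' @param coverage data.frame with columns `label` and `coverage`
#'   (nonnegative).
#' @return data.frame with columns `label`, `n`, `mean`, `sd`.
#' @export
coverage_summary <- function(coverage) {
  stopifnot(all(c("label", "coverage") %in% names(coverage)),
            all(coverage$coverage >= 0))
  out <- do.call(rbind, lapply(split(coverage$coverage, coverage$label),
                               function(v) data.frame(
                                 n = length(v), mean = mean(v),
                                 sd = if (length(v) > 1L) sd(v) else NA_real_)))
  out <- cbind(label = rownames(out), out)
  rownames(out) <- NULL
  out[NROW(out) > 0, , drop = FALSE]
}

#' Flatten barcode reports to a table
#' @param reports list of `barcode_report`s.
#' @return data.frame, one row per report.
#' @export
barcode_report_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) data.frame(
    sample_id = r$sample_id, locus = r$locus, verdict = r$verdict,
    best_match_taxon = r$best_match_taxon %||% NA_character_,
    n_contaminant = if (is.null(r$hits)) 0L else
      sum(r$hits$severity == "CONTAMINANT"),
    n_warning = if (is.null(r$hits)) 0L else
      sum(r$hits$severity == "WARNING"),
    stringsAsFactors = FALSE)))
}
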