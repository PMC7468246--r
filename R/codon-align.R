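#' Codon alignment container
#'
#' Holds the gapped nucleotide rows of one locus together with the
#' amino-acid alignment they were derived from.  Every NT row has equal
#' length, equal to 3x the AA alignment length, and degapping an NT row
#' recovers the original coding sequence.  A reference gene-model row
#' (AA only, used for exon projection) may ride along; it has no NT row.
#'
#' @param locus_id locus id.
#' @param rows named character vector of gapped NT rows (taxon -> row).
#' @param aa_rows named character vector of gapped AA rows.
#' @param ref_taxon,ref_aa_row optional reference gene-model id and its
#'   gapped AA row in the same alignment.
#' @param bin optional reference-genome id.
#' @return a `codon_alignment` object.
#' @export
codon_alignment <- function(locus_id, rows, aa_rows, ref_taxon = NULL,
                            ref_aa_row = NULL, bin = NULL) {
  stopifnot(length(rows) >= 1L, identical(names(rows), names(aa_rows)))
  len <- unique(nchar(rows))
  if (length(len) != 1L) stop("NT rows of ", locus_id, " differ in length")
  if (len != 3L * unique(nchar(aa_rows))[1])
    stop("NT alignment length must be 3 x AA alignment length")
  structure(list(locus_id = locus_id, rows = rows, aa_rows = aa_rows,
                 ref_taxon = ref_taxon, ref_aa_row = ref_aa_row,
                 bin = bin, length = len),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment %s: %d rows x %d nt columns%s>\n",
              x$locus_id, length(x$rows), x$length,
              if (is.null(x$ref_taxon)) "" else
                paste0(", reference ", x$ref_taxon)))
  invisible(x)
}

#' Back-translate an amino-acid alignment to codons
#'
#' Each amino-acid residue column expands to its source codon and each
#' gap to `---`.  For every taxon the ungapped AA row times three must
#' equal the coding-sequence length (trailing stop codons are stripped
#' first) and the CDS must translate to the ungapped AA row under the
#' standard code (`X` is tolerated wherever the codon contains `N`, and
#' wherever the aligner emitted `X`).  Mismatches abort with the taxon
#' and codon index rather than auto-correcting, since a silent frame
#' error would corrupt every bait designed downstream.
#'
#' @param aa_alignment named character vector of gapped AA rows.
#' @param cds named character vector of coding sequences covering every
#'   aligned taxon.
#' @param locus_id id for the resulting alignment.
#' @param ref_taxon,ref_aa_row,bin passed through to [codon_alignment].
#' @return a [codon_alignment].
#' @export
back_translate <- function(aa_alignment, cds, locus_id = "locus",
                           ref_taxon = NULL, ref_aa_row = NULL, bin = NULL) {
  stopifnot(length(aa_alignment) >= 1L, !is.null(names(aa_alignment)))
  missing <- setdiff(names(aa_alignment), names(cds))
  if (length(missing)) stop("no CDS for taxon ", missing[1])
  rows <- character(length(aa_alignment))
  names(rows) <- names(aa_alignment)
  for (tx in names(aa_alignment)) {
    aa <- toupper(aa_alignment[[tx]])
    nt <- strip_stop(toupper(cds[[tx]]))
    aa_res <- gsub("-", "", aa, fixed = TRUE)
    if (nchar(nt) != 3L * nchar(aa_res))
      stop(sprintf("taxon %s: CDS length %d != 3 x %d ungapped AA residues",
                   tx, nchar(nt), nchar(aa_res)))
    codons <- substring(nt, seq(1L, nchar(nt), 3L), seq(3L, nchar(nt), 3L))
    trans <- translate_cds(nt)
    trans_res <- strsplit(trans, "")[[1]]
    aa_vec <- strsplit(aa_res, "")[[1]]
    bad <- which(trans_res != aa_vec & trans_res != "X" & aa_vec != "X")
    if (length(bad))
      stop(sprintf("taxon %s: codon %d ('%s') translates to '%s', not '%s'",
                   tx, bad[1], codons[bad[1]], trans_res[bad[1]], aa_vec[bad[1]]))
    out <- character(nchar(aa))
    chars <- strsplit(aa, "")[[1]]
    ci <- 0L
    for (p in seq_along(chars)) {
      if (chars[p] == "-") out[p] <- "---"
      else { ci <- ci + 1L; out[p] <- codons[ci] }
    }
    rows[tx] <- paste(out, collapse = "")
  }
  codon_alignment(locus_id, rows, aa_alignment[names(rows)],
                  ref_taxon = ref_taxon, ref_aa_row = ref_aa_row, bin = bin)
}

#' Remove gaps from alignment rows
#' @param rows character vector of gapped sequences.
#' @return ungapped sequences.
#' @export
degap <- function(rows) gsub("-", "", rows, fixed = TRUE)

#' Multiple alignment of amino-acid sequences
#'
#' When all sequences already share one length they are taken as aligned
#' (the synthetic generator and many ortholog pipelines emit equal-length
#' members).  Otherwise the sequences are aligned with the external
#' `mafft` program (L-INS-i), which must be on the `PATH`; input order
#' is preserved and the call is deterministic for a fixed input.
#'
#' @param seqs named character vector of ungapped AA sequences.
#' @param method `"auto"` (passthrough when equal-length), `"mafft"`
#'   (always align).
#' @return named character vector of gapped rows, equal lengths.
#' @export
align_amino_acids <- function(seqs, method = c("auto", "mafft")) {
  method <- match.arg(method)
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  if (method == "auto" && length(unique(nchar(seqs))) == 1L)
    return(toupper(seqs))
  if (Sys.which("mafft") == "")
    stop("sequences are unaligned and 'mafft' is not on the PATH")
  tmp_in <- tempfile(fileext = ".fasta")
  tmp_out <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(tmp_in, tmp_out)), add = TRUE)
  # placeholder names avoid mafft mangling user ids
  ph <- sprintf("s%06d", seq_along(seqs))
  writeLines(paste0(">", ph, "\n", toupper(seqs)), tmp_in)
  status <- system2("mafft", c("--localpair", "--maxiterate", "1000",
                               "--anysymbol", "--quiet", tmp_in),
                    stdout = tmp_out)
  if (!identical(status, 0L)) stop("mafft failed with status ", status)
  aln <- read_fasta(tmp_out, "AA")
  setNames(toupper(aln$seq[match(ph, aln$id)]), names(seqs))
}
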