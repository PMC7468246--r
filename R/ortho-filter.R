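#' Construct an orthogroup
#'
#' Bundles the amino-acid members of one orthogroup with their parallel
#' coding sequences.  AA and NT members correspond 1:1 by id and the NT
#' length must be 3x the AA length (a trailing stop codon is stripped).
#' Member taxa need not be unique (upstream paralogs are allowed).
#'
#' @param id orthogroup id.
#' @param aa an [annotated_seqs] table of kind `"AA"`.
#' @param nt an [annotated_seqs] table of kind `"NT"` with matching ids.
#' @param bin optional reference-genome id assigned by [assign_bin].
#' @return an `orthogroup` object.
#' @export
orthogroup <- function(id, aa, nt, bin = NULL) {
  stopifnot(is.character(id), length(id) == 1L)
  nt$seq <- strip_stop(nt$seq)
  if (!setequal(aa$id, nt$id))
    stop("orthogroup ", id, ": AA and NT member ids do not match")
  nt <- nt[match(aa$id, nt$id), , drop = FALSE]
  aa$seq <- sub("\\*$", "", aa$seq)
  bad <- nchar(nt$seq) != 3L * nchar(aa$seq)
  if (any(bad))
    stop("orthogroup ", id, ": NT length != 3 x AA length for member ",
         aa$id[which(bad)[1]])
  structure(list(id = id, aa = aa, nt = nt, bin = bin), class = "orthogroup")
}

#' @export
print.orthogroup <- function(x, ...) {
  cat(sprintf("<orthogroup %s: %d members, %d taxa%s>\n", x$id, nrow(x$aa),
              length(unique(x$aa$taxon)),
              if (is.null(x$bin)) "" else paste0(", bin ", x$bin)))
  invisible(x)
}

scleractinian <- function(clade) clade %in% c("ROBUST", "COMPLEX")

#' Taxon-representation filter
#'
#' Keeps an orthogroup only when it is represented by at least
#' `min_taxa` distinct scleractinian taxa of which at least
#' `min_per_clade` belong to the "Robust" clade and at least
#' `min_per_clade` to the "Complex" clade (set `min_per_clade = 0` to
#' require the clade condition on neither side).  Distinctness counts
#' taxon labels, not sequences, so paralogs do not inflate the count.
#'
#' @param og an [orthogroup].
#' @param min_taxa minimum distinct scleractinian taxa (default 6).
#' @param min_per_clade minimum distinct taxa required from each of the
#'   Robust and Complex clades (default 2).
#' @return `TRUE` iff the orthogroup passes.
#' @export
representation_filter <- function(og, min_taxa = 6L, min_per_clade = 2L) {
  aa <- og$aa
  scler <- unique(aa$taxon[scleractinian(aa$clade)])
  n_rob <- length(unique(aa$taxon[aa$clade == "ROBUST"]))
  n_com <- length(unique(aa$taxon[aa$clade == "COMPLEX"]))
  length(scler) >= min_taxa && n_rob >= min_per_clade && n_com >= min_per_clade
}

#' Genome anchoring filter
#'
#' An orthogroup is anchored when at least one member has a hit to any
#' reference gene model with bit score at or above `min_bit_score`
#' (inclusive) at the given e-value cutoff.
#'
#' @param og an [orthogroup].
#' @param gene_models named list of [annotated_seqs] AA tables, one per
#'   reference genome.
#' @param min_bit_score minimum bit score (default 50).
#' @param evalue e-value cutoff for the underlying search (default 1e-6).
#' @param scheme optional [aa_scheme].
#' @return `TRUE` iff any member anchors.
#' @export
genome_anchor <- function(og, gene_models, min_bit_score = 50,
                          evalue = 1e-6, scheme = NULL) {
  stopifnot(length(gene_models) > 0L)
  if (is.null(scheme)) scheme <- aa_scheme()
  models <- do.call(rbind, unname(gene_models))
  for (i in seq_len(nrow(og$aa))) {
    hits <- search_hits(og$aa[i, ], models, mode = "AA",
                        evalue_cutoff = evalue, scheme = scheme)
    if (any(hits$bit_score >= min_bit_score)) return(TRUE)
  }
  FALSE
}

#' Remove non-cnidarian contaminant transcripts
#'
#' Each member's single best blast-like hit (under the [best_hit] order)
#' against a labelled reference nucleotide set is evaluated: members
#' whose best hit is non-cnidarian with identity `>= min_identity` over
#' an alignment length `>= min_len` are removed.  If removal leaves
#' fewer than `min_taxa` distinct taxa the whole orthogroup is dropped
#' (`NULL`).  Records of the reference set are treated as cnidarian when
#' their clade tag is `ROBUST`, `COMPLEX` or `OUTGROUP`, and as
#' non-cnidarian when it is `OTHER`.
#'
#' @param og an [orthogroup].
#' @param noncnidarian_db an [annotated_seqs] NT table with clade tags.
#' @param min_identity,min_len removal thresholds (default 80, 100).
#' @param evalue e-value cutoff (default 1e-6).
#' @param min_taxa minimum surviving distinct taxa (default 6).
#' @param scheme optional [nt_scheme].
#' @return the filtered [orthogroup], or `NULL` if dropped; the returned
#'   object carries a `removed` attribute listing removed member ids.
#' @export
remove_contaminant_transcripts <- function(og, noncnidarian_db,
                                           min_identity = 80, min_len = 100,
                                           evalue = 1e-6, min_taxa = 6L,
                                           scheme = NULL) {
  if (is.null(scheme)) scheme <- nt_scheme()
  drop <- logical(nrow(og$nt))
  for (i in seq_len(nrow(og$nt))) {
    hits <- search_hits(og$nt[i, ], noncnidarian_db, mode = "NT",
                        evalue_cutoff = evalue, scheme = scheme)
    bh <- best_hit(hits)
    if (is.null(bh)) next
    subj_clade <- noncnidarian_db$clade[match(bh$subject_id, noncnidarian_db$id)]
    if (subj_clade == "OTHER" &&
        passes_similarity_filter(bh, min_identity, min_len))
      drop[i] <- TRUE
  }
  removed <- og$nt$id[drop]
  aa <- og$aa[!drop, , drop = FALSE]
  nt <- og$nt[!drop, , drop = FALSE]
  if (length(unique(aa$taxon)) < min_taxa) return(NULL)
  out <- orthogroup(og$id, aa, nt, bin = og$bin)
  attr(out, "removed") <- removed
  out
}

#' Assign an orthogroup to a reference-genome bin
#'
#' The bin is the genome holding the orthogroup-wide best hit (under the
#' [best_hit] order over all member x gene-model hits).
#'
#' @inheritParams genome_anchor
#' @return the [orthogroup] with its `bin` field set; an attribute
#'   `bin_hit` carries the winning hit joined with the model id.
#' @export
assign_bin <- function(og, gene_models, evalue = 1e-6, scheme = NULL) {
  if (is.null(scheme)) scheme <- aa_scheme()
  all_hits <- list()
  for (g in names(gene_models)) {
    for (i in seq_len(nrow(og$aa))) {
      hits <- search_hits(og$aa[i, ], gene_models[[g]], mode = "AA",
                          evalue_cutoff = evalue, scheme = scheme)
      if (NROW(hits)) {
        hits$genome <- g
        all_hits[[length(all_hits) + 1L]] <- hits
      }
    }
  }
  if (!length(all_hits))
    stop("orthogroup ", og$id, " has no gene-model hit; ",
         "genome_anchor() should have failed")
  hits <- do.call(rbind, all_hits)
  top <- hits[hit_order(hits)[1L], , drop = FALSE]
  og$bin <- top$genome
  attr(og, "bin_hit") <- top
  og
}

#' Read an orthogroup directory
#'
#' Expects `<og>.aa.fasta` / `<og>.nt.fasta` pairs with matching ids.
#'
#' @param dir directory path.
#' @return named list of [orthogroup] objects.
#' @export
read_orthogroup_dir <- function(dir) {
  aa_files <- sort(list.files(dir, pattern = "\\.aa\\.fasta$", full.names = TRUE))
  if (!length(aa_files)) stop("no input loci: no *.aa.fasta in ", dir)
  ogs <- lapply(aa_files, function(f) {
    id <- sub("\\.aa\\.fasta$", "", basename(f))
    ntf <- file.path(dir, paste0(id, ".nt.fasta"))
    if (!file.exists(ntf)) stop("missing NT file for orthogroup ", id)
    orthogroup(id, read_fasta(f, "AA"), read_fasta(ntf, "NT"))
  })
  setNames(ogs, vapply(ogs, `[[`, character(1), "id"))
}
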