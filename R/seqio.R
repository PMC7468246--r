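#' Construct a table of annotated sequences
#'
#' The basic sequence container used throughout the package: a
#' `data.frame` with one row per record and columns `id`, `taxon`,
#' `clade`, `kind`, `seq`.  Residues are stored uppercase; `clade` is one
#' of `ROBUST`, `COMPLEX`, `OUTGROUP`, `OTHER`.
#'
#' @param id character vector of record ids (no whitespace, unique).
#' @param seq character vector of residues.
#' @param taxon taxon labels; defaults to `id`.
#' @param clade clade labels, recycled; defaults to `"OTHER"`.
#' @param kind `"NT"` or `"AA"`.
#' @return a `data.frame` of class `annotated_seqs`.
#' @export
annotated_seqs <- function(id, seq, taxon = id, clade = "OTHER", kind = "NT") {
  kind <- match.arg(kind, c("NT", "AA"))
  if (length(id) == 0L) {
    df <- data.frame(id = character(), taxon = character(),
                     clade = character(), kind = character(),
                     seq = character(), stringsAsFactors = FALSE)
    class(df) <- c("annotated_seqs", "data.frame")
    return(df)
  }
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate sequence ids: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(grepl("[[:space:]]", id))) stop("sequence ids must not contain whitespace")
  seq <- toupper(as.character(seq))
  if (any(!nzchar(seq))) stop("empty residue string for id ",
                              id[which(!nzchar(seq))[1]])
  clade <- rep_len(as.character(clade), length(id))
  bad <- !clade %in% CLADE_LEVELS
  if (any(bad)) stop("unknown clade label: ", clade[which(bad)[1]])
  validate_residues(seq, kind, id)
  df <- data.frame(id = id, taxon = rep_len(as.character(taxon), length(id)),
                   clade = clade, kind = kind, seq = seq,
                   stringsAsFactors = FALSE)
  class(df) <- c("annotated_seqs", "data.frame")
  df
}

validate_residues <- function(seq, kind, id) {
  alpha <- if (kind == "NT") NT_ALPHABET else AA_ALPHABET
  pat <- paste0("[^", paste(alpha, collapse = ""), "]")
  hit <- regexpr(pat, seq)
  bad <- which(hit > 0L)
  if (length(bad)) {
    stop(sprintf("illegal %s residue '%s' in record '%s' at position %d",
                 kind, substr(seq[bad[1]], hit[bad[1]], hit[bad[1]]),
                 id[bad[1]], hit[bad[1]]))
  }
  invisible(TRUE)
}

parse_header_tags <- function(headers) {
  # dialect: "id key=value;key=value" after the first whitespace;
  # unknown keys are ignored so files stay valid FASTA for other tools.
  ids <- sub("[[:space:]].*$", "", headers)
  rest <- ifelse(grepl("[[:space:]]", headers),
                 sub("^[^[:space:]]+[[:space:]]+", "", headers), "")
  taxon <- ids
  clade <- rep("OTHER", length(headers))
  for (i in seq_along(rest)) {
    if (!nzchar(rest[i])) next
    kv <- strsplit(rest[i], ";", fixed = TRUE)[[1]]
    kv <- kv[grepl("=", kv, fixed = TRUE)]
    if (!length(kv)) next
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    if ("taxon" %in% keys) taxon[i] <- vals[match("taxon", keys)]
    if ("clade" %in% keys) {
      cl <- toupper(vals[match("clade", keys)])
      if (cl %in% CLADE_LEVELS) clade[i] <- cl
    }
  }
  list(id = ids, taxon = taxon, clade = clade)
}

#' Read a FASTA file of annotated sequences
#'
#' Headers may carry `taxon=...;clade=...` key-value tags after the id;
#' untagged records get `clade = "OTHER"` and `taxon = id`.  Residues are
#' parsed case-insensitively and stored uppercase.
#'
#' @param path path to a FASTA file.
#' @param kind `"NT"` or `"AA"`; residues are validated against the
#'   corresponding alphabet and an illegal residue is an error naming the
#'   record and position.
#' @return an [annotated_seqs] table.
#' @export
read_fasta <- function(path, kind = c("NT", "AA")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  tags <- parse_header_tags(names(set))
  annotated_seqs(id = tags$id, seq = as.character(set),
                 taxon = tags$taxon, clade = tags$clade, kind = kind)
}

#' Write annotated sequences to FASTA
#'
#' Output is deterministic; headers encode `taxon=` / `clade=` tags
#' whenever the taxon differs from the id or the clade is not `OTHER`.
#'
#' @param records an [annotated_seqs] table (nonempty, unique ids).
#' @param path output path.
#' @param line_width positive integer wrap width (default 80).
#' @return the path, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 80L) {
  if (NROW(records) == 0L) stop("nothing to write: empty record set")
  if (anyDuplicated(records$id))
    stop("duplicate sequence ids: ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  stopifnot(line_width >= 1L)
  hdr <- records$id
  tagged <- records$taxon != records$id | records$clade != "OTHER"
  hdr[tagged] <- sprintf("%s taxon=%s;clade=%s", records$id[tagged],
                         records$taxon[tagged], records$clade[tagged])
  set <- Biostrings::BStringSet(setNames(records$seq, hdr))
  Biostrings::writeXStringSet(set, filepath = path, width = line_width)
  invisible(path)
}

#' Reverse complement of nucleotide sequences
#'
#' Length-preserving involution over the `A,C,G,T,N,-` alphabet
#' (vectorized); `N` and `-` map to themselves.
#'
#' @param seq character vector of NT sequences.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  if (!is.character(seq)) stop("reverse_complement() expects character input")
  validate_residues(toupper(seq), "NT", seq_along(seq))
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", toupper(seq))
  vapply(comp, function(s) rawToChar(rev(charToRaw(s))), character(1),
         USE.NAMES = FALSE)
}

#' Read a per-contig coverage table
#'
#' @param path TSV with header `contig_id<TAB>coverage`.
#' @return a named numeric vector of nonnegative coverages keyed by
#'   contig id.
#' @export
read_coverage_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "numeric"))
  if (!identical(names(df)[1:2], c("contig_id", "coverage")))
    stop("coverage table must have header 'contig_id<TAB>coverage'")
  if (nrow(df) == 0L) return(setNames(numeric(0), character(0)))
  if (anyDuplicated(df$contig_id))
    stop("duplicate contig id in coverage table: ",
         df$contig_id[duplicated(df$contig_id)][1])
  if (any(is.na(df$coverage)) || any(df$coverage < 0))
    stop("coverage must be a nonnegative number for every contig")
  setNames(df$coverage, df$contig_id)
}

#' Read exon maps from a BED-like TSV
#'
#' Format: `gene_id<TAB>start<TAB>end`, 0-based half-open on the
#' gene-model coding sequence; exons of one gene must be nonempty,
#' sorted and disjoint.
#'
#' @param path input TSV (a header line is optional).
#' @return named list of integer matrices with columns `start`, `end`.
#' @export
read_exon_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, header = FALSE, sep = "\t", comment.char = "#",
                   col.names = c("gene_id", "start", "end"),
                   colClasses = c("character", "character", "character"))
  if (nrow(df) && df$gene_id[1] == "gene_id") df <- df[-1, , drop = FALSE]
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  out <- lapply(split(df, df$gene_id), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    m <- cbind(start = g$start, end = g$end)
    if (any(m[, "end"] - m[, "start"] < 1L))
      stop("exon of length < 1 for gene ", g$gene_id[1])
    if (nrow(m) > 1L && any(m[-1L, "start"] < m[-nrow(m), "end"]))
      stop("overlapping exons for gene ", g$gene_id[1])
    m
  })
  out[order(names(out))]
}

#' Write exon maps to a BED-like TSV
#' @param maps named list of matrices as returned by [read_exon_map].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_exon_map <- function(maps, path) {
  rows <- do.call(rbind, lapply(names(maps), function(g)
    data.frame(gene_id = g, start = maps[[g]][, "start"],
               end = maps[[g]][, "end"], stringsAsFactors = FALSE)))
  write.table(rows, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Translate coding sequences under the standard genetic code
#'
#' Codons containing `N` translate to `X`; a trailing stop codon is kept
#' (strip it upstream if unwanted).
#'
#' @param cds character vector of NT sequences with length a multiple
#'   of 3.
#' @return character vector of amino-acid sequences.
#' @export
translate_cds <- function(cds) {
  code <- Biostrings::GENETIC_CODE
  vapply(toupper(cds), function(s) {
    if (nchar(s) %% 3L != 0L)
      stop("CDS length ", nchar(s), " is not a multiple of 3")
    cod <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    aa <- unname(code[cod])
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

strip_stop <- function(cds) {
  last <- substring(cds, nchar(cds) - 2L, nchar(cds))
  ifelse(nchar(cds) >= 3L & last %in% c("TAA", "TAG", "TGA"),
         substring(cds, 1L, nchar(cds) - 3L), cds)
}
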