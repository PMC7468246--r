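#' Trim gappy alignment columns
#'
#' Columns whose gap fraction (`-` and `?`) exceeds `max_gap_frac` are
#' removed; row order is preserved.  A transparent stand-in for heuristic
#' alignment trimmers: the criterion is a single per-column census.
#'
#' @param rows named character vector of equal-length aligned sequences.
#' @param max_gap_frac maximum tolerated gap fraction per column
#'   (default 0.8).
#' @return trimmed rows (possibly zero-length strings when everything
#'   is gap).
#' @export
trim_alignment <- function(rows, max_gap_frac = 0.8) {
  stopifnot(length(unique(nchar(rows))) == 1L)
  mat <- do.call(rbind, strsplit(unname(rows), ""))
  keep <- colMeans(mat == "-" | mat == "?") <= max_gap_frac
  setNames(apply(mat[, keep, drop = FALSE], 1, paste, collapse = ""),
           names(rows))
}

#' Concatenate curated loci into a supermatrix
#'
#' Loci are laid out in input order; a taxon absent from a locus is
#' padded with `?` across that partition.  Partition coordinates are
#' 0-based half-open on the concatenation.
#'
#' @param loci named list: locus id -> named character vector (taxon ->
#'   aligned sequence, equal lengths within a locus).
#' @param taxa optional taxon universe (row order); defaults to the
#'   union of locus taxa in order of first appearance.
#' @return a `supermatrix` list: `taxa`, `partitions` (data.frame
#'   `locus_id`/`start`/`end`), `rows` (named character vector),
#'   `length`.
#' @export
concatenate_loci <- function(loci, taxa = NULL) {
  stopifnot(length(loci) >= 1L, !is.null(names(loci)))
  if (is.null(taxa)) taxa <- unique(unlist(lapply(loci, names)))
  pieces <- matrix("", nrow = length(taxa), ncol = length(loci),
                   dimnames = list(taxa, names(loci)))
  starts <- integer(length(loci)); ends <- integer(length(loci))
  pos <- 0L
  for (j in seq_along(loci)) {
    locus <- loci[[j]]
    if (anyDuplicated(names(locus)))
      stop("duplicate taxon within locus ", names(loci)[j], ": ",
           names(locus)[duplicated(names(locus))][1])
    L <- unique(nchar(locus))
    if (length(L) != 1L)
      stop("locus ", names(loci)[j], " rows are not aligned")
    filler <- strrep("?", L)
    col <- setNames(rep(filler, length(taxa)), taxa)
    present <- intersect(names(locus), taxa)
    col[present] <- locus[present]
    pieces[, j] <- col
    starts[j] <- pos; pos <- pos + L; ends[j] <- pos
  }
  rows <- setNames(apply(pieces, 1, paste, collapse = ""), taxa)
  structure(list(taxa = taxa,
                 partitions = data.frame(locus_id = names(loci),
                                         start = starts, end = ends,
                                         stringsAsFactors = FALSE),
                 rows = rows, length = pos),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix: %d taxa x %d sites, %d partitions>\n",
              length(x$taxa), x$length, nrow(x$partitions)))
  invisible(x)
}

#' Supermatrix summary statistics
#'
#' Missing data counts both `?` (absent locus) and `-` (alignment gap)
#' cells; set `count_gaps = FALSE` to count only `?`.  A column is
#' parsimony-informative when at least two distinct non-missing states
#' each occur in at least two rows; the PI census is matrix-wide.
#'
#' @param m a `supermatrix`.
#' @param count_gaps include `-` in the missing-data census (default
#'   `TRUE`).
#' @return list with `missing_pct`, `n_pi_sites`, `pi_pct`, `n_taxa`,
#'   `length`, and `locus_length` (list: `mean`, `sd`, `min`, `max`).
#' @export
matrix_stats <- function(m, count_gaps = TRUE) {
  mat <- do.call(rbind, strsplit(unname(m$rows), ""))
  miss <- mat == "?"
  if (count_gaps) miss <- miss | mat == "-"
  missing_pct <- 100 * sum(miss) / length(mat)
  n_pi <- count_pi_sites(m$rows)
  lens <- m$partitions$end - m$partitions$start
  list(missing_pct = missing_pct, n_pi_sites = n_pi,
       pi_pct = 100 * n_pi / m$length, n_taxa = length(m$taxa),
       length = m$length,
       locus_length = list(mean = mean(lens),
                           sd = if (length(lens) > 1L) sd(lens) else NA_real_,
                           min = min(lens), max = max(lens)))
}

#' Write a RAxML-style partition file
#'
#' Lines are `DNA, <locus_id> = <start>-<end>` in 1-based inclusive
#' coordinates, the dialect downstream ML tools expect.
#'
#' @param m a `supermatrix`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_partitions <- function(m, path) {
  writeLines(sprintf("DNA, %s = %d-%d", m$partitions$locus_id,
                     m$partitions$start + 1L, m$partitions$end), path)
  invisible(path)
}

#' Parse a RAxML-style partition file back to 0-based coordinates
#' @param path partition file written by [write_partitions].
#' @return data.frame `locus_id`/`start`/`end`, 0-based half-open.
#' @export
read_partitions <- function(path) {
  lines <- readLines(path)
  m <- regmatches(lines, regexec("^DNA, (\\S+) = (\\d+)-(\\d+)$", lines))
  ok <- lengths(m) == 4L
  if (!all(ok)) stop("unparseable partition line: ", lines[!ok][1])
  data.frame(locus_id = vapply(m, `[`, character(1), 2),
             start = as.integer(vapply(m, `[`, character(1), 3)) - 1L,
             end = as.integer(vapply(m, `[`, character(1), 4)),
             stringsAsFactors = FALSE)
}

#' Write a supermatrix as FASTA and relaxed PHYLIP
#'
#' @param m a `supermatrix`.
#' @param fasta_path,phylip_path output paths (`NULL` skips either).
#' @return invisibly, the paths written.
#' @export
write_supermatrix <- function(m, fasta_path = NULL, phylip_path = NULL) {
  if (!is.null(fasta_path))   # rows may contain '?', so bypass NT validation
    Biostrings::writeXStringSet(
      Biostrings::BStringSet(m$rows[m$taxa]), filepath = fasta_path, width = 80L)
  if (!is.null(phylip_path)) {
    con <- file(phylip_path, "w")
    on.exit(close(con))
    writeLines(sprintf("%d %d", length(m$taxa), m$length), con)
    writeLines(sprintf("%s  %s", m$taxa, m$rows[m$taxa]), con)
  }
  invisible(c(fasta_path, phylip_path))
}
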