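#' Tiling scheme for bait design
#'
#' The default scheme designs 120 bp baits at a 20 bp offset, trying
#' windows of 240, 200, 160 and finally 120 bp, which tile into 7, 5, 3
#' and 1 baits respectively.
#'
#' @param bait_length bait length in bp (default 120).
#' @param offset spacing between consecutive bait starts (default 20).
#' @param window_lengths strictly decreasing window lengths to try; each
#'   must satisfy `(W - bait_length) %% offset == 0`.
#' @return a `tiling_scheme` list.
#' @export
tiling_scheme <- function(bait_length = 120L, offset = 20L,
                          window_lengths = c(240L, 200L, 160L, 120L)) {
  stopifnot(bait_length >= 1L, offset >= 1L,
            all(window_lengths >= bait_length),
            all(diff(window_lengths) < 0L),
            all((window_lengths - bait_length) %% offset == 0L))
  structure(list(bait_length = as.integer(bait_length),
                 offset = as.integer(offset),
                 window_lengths = as.integer(window_lengths)),
            class = "tiling_scheme")
}

#' Tile start offsets within a window
#'
#' @param window_length one of `scheme$window_lengths`.
#' @param scheme a [tiling_scheme].
#' @return integer vector of start offsets `0, offset, ...,
#'   window_length - bait_length`; of length
#'   `(window_length - bait_length)/offset + 1`.
#' @export
tile_positions <- function(window_length, scheme = tiling_scheme()) {
  if (window_length < scheme$bait_length)
    stop("window_length ", window_length, " is shorter than a bait (",
         scheme$bait_length, ")")
  if (!window_length %in% scheme$window_lengths)
    stop("window_length ", window_length, " is not part of the scheme")
  seq.int(0L, window_length - scheme$bait_length, by = scheme$offset)
}

#' Project exon coordinates onto alignment columns
#'
#' Exon coordinates live on the reference gene-model coding sequence
#' (0-based half-open, NT).  Reference-row alignment columns inherit the
#' exon of their coding-sequence position; insertion columns (reference
#' gaps) inherit the preceding reference position's exon, so each
#' projected span is contiguous.  Exon boundaries that fall inside a
#' codon are rounded inward to whole codons.
#'
#' @param locus a [codon_alignment] carrying `ref_aa_row`.
#' @param exons integer matrix with columns `start`, `end` (one exon per
#'   row) on the reference CDS.
#' @return integer matrix with columns `start`, `end`: projected spans
#'   in NT alignment columns (0-based half-open); exons that project to
#'   nothing are dropped.
#' @export
project_exons <- function(locus, exons) {
  if (is.null(locus$ref_aa_row))
    stop("locus ", locus$locus_id, " has no reference row to project through")
  ref <- strsplit(locus$ref_aa_row, "")[[1]]
  res_col <- which(ref != "-")          # alignment AA column of residue i
  spans <- list()
  for (r in seq_len(nrow(exons))) {
    aa_s <- ceiling(exons[r, "start"] / 3)          # first whole codon
    aa_e <- floor(exons[r, "end"] / 3)              # past-last whole codon
    if (aa_e <= aa_s) next
    if (aa_e > length(res_col)) aa_e <- length(res_col)
    if (aa_s >= aa_e) next
    c0 <- res_col[aa_s + 1L]                        # 1-based AA columns
    c1 <- res_col[aa_e]
    spans[[length(spans) + 1L]] <- c(start = 3L * (c0 - 1L), end = 3L * c1)
  }
  if (!length(spans))
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end"))))
  do.call(rbind, spans)
}

# per-column validity under the gap rule, and pairwise-identity score
column_profiles <- function(locus, gap_rule = c("strict", "tolerant")) {
  gap_rule <- match.arg(gap_rule)
  mat <- do.call(rbind, strsplit(unname(locus$rows), ""))
  n <- nrow(mat)
  gap_frac <- colMeans(mat == "-")
  valid <- if (gap_rule == "strict") gap_frac == 0 else gap_frac <= 0.5
  score <- vapply(seq_len(ncol(mat)), function(j) {
    ch <- mat[, j]
    ch <- ch[ch != "-"]
    if (length(ch) < 2L) return(0)
    tab <- table(ch)
    sum(choose(tab, 2)) / choose(length(ch), 2)
  }, numeric(1))
  list(valid = valid, score = score, n_rows = n)
}

#' Locate the best bait window on a codon alignment
#'
#' Windows are tried longest-first (240, 200, 160, 120 bp by default); a
#' window is valid iff it lies wholly inside one projected exon span and
#' every column in it passes the gap rule (`"strict"`: no gap in any
#' row; `"tolerant"`: at most 50% gaps per column).  Among valid windows
#' of the first length that yields any, the one maximizing mean pairwise
#' identity wins, ties going to the leftmost.
#'
#' @param locus a [codon_alignment] with a reference row.
#' @param exon_map exon matrix for the reference gene (see
#'   [read_exon_map]).
#' @param scheme a [tiling_scheme].
#' @param gap_rule `"strict"` (default) or `"tolerant"`.
#' @param exon_subset optional indices restricting which projected exon
#'   spans are searched (used for per-exon design).
#' @return `NULL` when no window fits at any length, otherwise a list
#'   with `start`, `end` (NT alignment columns, 0-based half-open),
#'   `length`, `mean_identity` and `exon`.
#' @export
find_window <- function(locus, exon_map, scheme = tiling_scheme(),
                        gap_rule = c("strict", "tolerant"),
                        exon_subset = NULL) {
  gap_rule <- match.arg(gap_rule)
  spans <- project_exons(locus, exon_map)
  if (!is.null(exon_subset)) spans <- spans[exon_subset, , drop = FALSE]
  if (!nrow(spans)) return(NULL)
  prof <- column_profiles(locus, gap_rule)
  cs_valid <- cumsum(c(0L, !prof$valid))   # invalid-column count prefix
  cs_score <- cumsum(c(0, prof$score))
  for (W in scheme$window_lengths) {
    best <- NULL
    for (r in seq_len(nrow(spans))) {
      a <- spans[r, "start"]; b <- spans[r, "end"]
      if (b - a < W) next
      starts <- a:(b - W)                  # 0-based window starts
      ok <- cs_valid[starts + W + 1L] - cs_valid[starts + 1L] == 0L
      if (!any(ok)) next
      starts <- starts[ok]
      sc <- (cs_score[starts + W + 1L] - cs_score[starts + 1L]) / W
      i <- which.max(sc)                   # which.max takes the leftmost tie
      cand <- list(start = starts[i], end = starts[i] + W, length = W,
                   mean_identity = sc[i], exon = r)
      if (is.null(best) || cand$mean_identity > best$mean_identity ||
          (cand$mean_identity == best$mean_identity && cand$start < best$start))
        best <- cand
    }
    if (!is.null(best)) return(best)
  }
  NULL
}

new_bait_region <- function(locus_id, window, baits, bin = NULL,
                            label = "TARGET", scheme = tiling_scheme()) {
  region_id <- sprintf("%s|%d-%d", locus_id, window$start, window$end)
  structure(list(locus_id = locus_id, region_id = region_id,
                 window_start = window$start, window_end = window$end,
                 window_length = window$length,
                 n_tiles = (window$length - scheme$bait_length) %/%
                   scheme$offset + 1L,
                 mean_identity = window$mean_identity %||% NA_real_,
                 bin = bin, label = label, baits = baits),
            class = "bait_region")
}

#' @export
print.bait_region <- function(x, ...) {
  cat(sprintf("<bait_region %s: %d bp window, %d tiles, %d baits>\n",
              x$region_id, x$window_length, x$n_tiles, nrow(x$baits)))
  invisible(x)
}

#' Tile a window into baits
#'
#' For each tile position, each distinct gap-free `bait_length`-mer
#' among the member rows becomes one bait (duplicates within a tile
#' collapse to the first contributing taxon in input order).  Rows with
#' a gap or `N` inside a tile contribute no bait for that tile only.
#'
#' @param locus a [codon_alignment].
#' @param window a window as returned by [find_window].
#' @param scheme a [tiling_scheme].
#' @param label bait label: `"TARGET"`, `"COI"` or `"H3"`.
#' @return a `bait_region`.
#' @export
make_region <- function(locus, window, scheme = tiling_scheme(),
                        label = "TARGET") {
  offs <- seq.int(0L, window$length - scheme$bait_length, by = scheme$offset)
  baits <- tile_baits(locus$rows, window$start, offs, scheme$bait_length,
                      locus$locus_id, window, label)
  new_bait_region(locus$locus_id, window, baits, bin = locus$bin,
                  label = label, scheme = scheme)
}

tile_baits <- function(rows, window_start, tile_offsets, bait_length,
                       locus_id, window, label) {
  taxa <- names(rows)
  out <- list()
  for (k in seq_along(tile_offsets)) {
    s <- window_start + tile_offsets[k]          # 0-based alignment column
    piece <- substr(rows, s + 1L, s + bait_length)
    ok <- !grepl("[-N]", piece) & nchar(piece) == bait_length
    if (!any(ok)) next
    keep <- !duplicated(piece[ok])
    seqs <- piece[ok][keep]
    src <- taxa[ok][keep]
    out[[k]] <- data.frame(
      bait_id = sprintf("%s|%d-%d|tile%d|%s|%s", locus_id, window$start,
                        window$end, k, src, tolower(label)),
      tile_index = k, start = s, source_taxon = src, sequence = seqs,
      label = label, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(bait_id = character(), tile_index = integer(),
                      start = integer(), source_taxon = character(),
                      sequence = character(), label = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Design bait regions for one locus
#'
#' With `multi_exon = TRUE` (the default) the best window is selected
#' independently inside every projected exon span, reproducing the
#' one-locus-many-regions structure of exon-aware designs; with
#' `multi_exon = FALSE` a single best window is chosen for the locus.
#'
#' @inheritParams find_window
#' @param multi_exon design one region per hosting exon?
#' @param label bait label.
#' @return list of `bait_region` objects (possibly empty).
#' @export
design_regions <- function(locus, exon_map, scheme = tiling_scheme(),
                           gap_rule = "strict", multi_exon = TRUE,
                           label = "TARGET") {
  spans <- project_exons(locus, exon_map)
  if (!nrow(spans)) return(list())
  idx <- if (multi_exon) as.list(seq_len(nrow(spans))) else list(NULL)
  regions <- list()
  for (i in idx) {
    w <- find_window(locus, exon_map, scheme, gap_rule, exon_subset = i)
    if (is.null(w)) next
    reg <- make_region(locus, w, scheme, label)
    if (nrow(reg$baits)) regions[[length(regions) + 1L]] <- reg
  }
  regions
}

#' Keep the single best region for a locus
#'
#' Selection order: longest window first, then maximal mean pairwise
#' identity, then leftmost window start.
#'
#' @param regions nonempty list of `bait_region`s for one locus.
#' @return the winning `bait_region`.
#' @export
best_region_per_locus <- function(regions) {
  if (!length(regions)) stop("no candidate regions")
  key <- order(-vapply(regions, function(r) as.numeric(r$window_length),
                       numeric(1)),
               -vapply(regions, function(r) as.numeric(r$mean_identity),
                       numeric(1)),
               vapply(regions, function(r) as.numeric(r$window_start),
                      numeric(1)))
  regions[[key[1L]]]
}

#' Design barcode baits across a whole gene
#'
#' Tiles 120 bp baits at a 20 bp offset across the entire alignment
#' length; when the length is not offset-aligned a final tile is
#' anchored at `length - 120` so the last bases stay covered.  Per tile,
#' distinct gap-free variants become baits labelled `coi` or `h3`.
#'
#' @param rows named character vector of aligned NT rows (or a
#'   [codon_alignment], whose rows are used).
#' @param label `"COI"` or `"H3"`.
#' @param gene_id id used in bait headers.
#' @param scheme a [tiling_scheme]; only `bait_length` and `offset` are
#'   used.
#' @return a single `bait_region` spanning the gene.
#' @export
design_barcode_baits <- function(rows, label = c("COI", "H3"),
                                 gene_id = tolower(label),
                                 scheme = tiling_scheme()) {
  label <- match.arg(label)
  if (inherits(rows, "codon_alignment")) rows <- rows$rows
  L <- unique(nchar(rows))
  stopifnot(length(L) == 1L)
  if (L < scheme$bait_length)
    stop("gene alignment (", L, " columns) is shorter than a bait")
  offs <- seq.int(0L, L - scheme$bait_length, by = scheme$offset)
  if (offs[length(offs)] != L - scheme$bait_length)
    offs <- c(offs, L - scheme$bait_length)
  window <- list(start = 0L, end = L, length = L, mean_identity = NA_real_)
  baits <- tile_baits(rows, 0L, offs, scheme$bait_length, gene_id,
                      window, label)
  reg <- new_bait_region(gene_id, window, baits, label = label,
                         scheme = scheme)
  reg$n_tiles <- length(offs)
  reg
}

#' Flatten bait regions into one table
#' @param regions list of `bait_region`s.
#' @return a data.frame of baits with a `region_id` column.
#' @export
baits_table <- function(regions) {
  rows <- lapply(regions, function(r) {
    if (!nrow(r$baits)) return(NULL)
    cbind(r$baits, region_id = r$region_id, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(bait_id = character(), tile_index = integer(),
                      start = integer(), source_taxon = character(),
                      sequence = character(), label = character(),
                      region_id = character(), stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

#' Region manifest table
#' @param regions list of `bait_region`s.
#' @return data.frame with one row per region.
#' @export
region_manifest <- function(regions) {
  do.call(rbind, lapply(regions, function(r)
    data.frame(region_id = r$region_id, locus_id = r$locus_id,
               bin = r$bin %||% NA_character_,
               window_start = r$window_start, window_end = r$window_end,
               window_length = r$window_length, n_tiles = r$n_tiles,
               n_baits = nrow(r$baits), mean_identity = r$mean_identity,
               label = r$label, stringsAsFactors = FALSE)))
}
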