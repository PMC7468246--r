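#' Symbiont cross-hybridization screen
#'
#' A bait is flagged when either of two criteria fires against the
#' symbiont reference set: (i) the mapping criterion — its best hit has
#' identity at or above `map_identity` percent spanning at least
#' `ceiling(map_length_frac * bait length)` bait positions (70% of a
#' 120 bp bait = 84 positions); or (ii) the blast criterion — any hit
#' with e-value at or below `blast_evalue`.  Both thresholds are
#' inclusive.
#'
#' @param baits bait table (see [baits_table]) or any data.frame with
#'   `bait_id` and `sequence`.
#' @param symbiont_refs an [annotated_seqs] NT table.
#' @param map_identity percent identity threshold (default 70).
#' @param map_length_frac fraction of the bait that must be aligned
#'   (default 0.70).
#' @param blast_evalue e-value threshold (default 1e-4).
#' @param scheme optional [nt_scheme].
#' @return character vector of flagged bait ids.
#' @export
symbiont_screen <- function(baits, symbiont_refs, map_identity = 70,
                            map_length_frac = 0.70, blast_evalue = 1e-4,
                            scheme = NULL) {
  if (is.null(scheme)) scheme <- nt_scheme()
  if (NROW(baits) == 0L || NROW(symbiont_refs) == 0L)
    return(structure(character(), criterion = character()))
  flagged <- character(); criterion <- character()
  for (i in seq_len(nrow(baits))) {
    q <- list(id = baits$bait_id[i], seq = baits$sequence[i])
    min_span <- ceiling(map_length_frac * nchar(q$seq))
    # search unfiltered by e-value; the two criteria threshold separately
    hits <- search_hits(q, symbiont_refs, mode = "NT",
                        evalue_cutoff = Inf, scheme = scheme)
    if (!NROW(hits)) next
    bh <- best_hit(hits)
    map_hit <- bh$identity_pct >= map_identity &&
      (bh$q_end - bh$q_start) >= min_span
    blast_hit <- any(hits$e_value <= blast_evalue)
    if (map_hit || blast_hit) {
      flagged <- c(flagged, q$id)
      criterion <- c(criterion,
                     if (map_hit) "SYMBIONT_MAP" else "SYMBIONT_BLAST")
    }
  }
  structure(flagged, criterion = criterion)
}

#' Prune bait regions after a screen
#'
#' A region is dropped whole when at least `max_removed` of its baits
#' were flagged, or when flag removal would leave at most
#' `min_remaining - 1` baits (default: one lone survivor is not worth a
#' region); otherwise only the flagged baits are dropped.
#'
#' @param regions list of `bait_region`s.
#' @param flagged character vector of flagged bait ids.
#' @param max_removed region-kill threshold on flagged count (default 3).
#' @param min_remaining minimum surviving baits a kept region must have
#'   (default 2).
#' @return list with `regions` (survivors, flagged baits removed) and
#'   `report` (data.frame of removed baits/regions with reasons).
#' @export
prune_regions <- function(regions, flagged, max_removed = 3L,
                          min_remaining = 2L) {
  survivors <- list()
  rep_rows <- list()
  note <- function(id, unit, reason)
    data.frame(id = id, unit = unit, reason = reason, stringsAsFactors = FALSE)
  crit <- attr(flagged, "criterion") %||%
    rep("SYMBIONT_MAP", length(flagged))
  reason_of <- function(ids)
    ifelse(ids %in% flagged, crit[match(ids, flagged)], "REGION_PRUNED")
  for (r in regions) {
    hit <- r$baits$bait_id %in% flagged
    n_flag <- sum(hit)
    n_left <- nrow(r$baits) - n_flag
    if (n_flag >= max_removed || n_left < min_remaining) {
      rep_rows[[length(rep_rows) + 1L]] <-
        note(r$region_id, "region", "REGION_PRUNED")
      rep_rows[[length(rep_rows) + 1L]] <-
        note(r$baits$bait_id, "bait", reason_of(r$baits$bait_id))
      next
    }
    if (n_flag > 0L) {
      rep_rows[[length(rep_rows) + 1L]] <-
        note(r$baits$bait_id[hit], "bait", reason_of(r$baits$bait_id[hit]))
      r$baits <- r$baits[!hit, , drop = FALSE]
    }
    survivors[[length(survivors) + 1L]] <- r
  }
  list(regions = survivors,
       report = if (length(rep_rows)) do.call(rbind, rep_rows) else
         note(character(), character(), character()))
}

#' Remove exact duplicate baits
#'
#' Exact-sequence duplicates collapse to the first occurrence in input
#' order; the operation is idempotent.
#'
#' @param baits a bait table.
#' @return list with `baits` (survivors) and `removed` (bait ids).
#' @export
dedup_baits <- function(baits) {
  dup <- duplicated(baits$sequence)
  list(baits = baits[!dup, , drop = FALSE], removed = baits$bait_id[dup])
}

#' Self-hybridization screen
#'
#' Two baits can self-hybridize when one contains an exact run of at
#' least `min_rc_match` bases reverse-complementary to a run in the
#' other — equivalently, when bait i and the reverse complement of bait
#' j share a `min_rc_match`-mer.  For each such unordered pair the bait
#' with the later id (input order) is flagged; a bait whose own sequence
#' contains a reverse-complementary (palindromic) run of that length is
#' flagged too.  With `resolution = "both"` both members of a pair are
#' flagged.
#'
#' @param baits a deduplicated bait table.
#' @param min_rc_match minimum reverse-complementary run (default 21 nt,
#'   roughly one blastn seed plus extension).
#' @param resolution `"later"` (default) or `"both"`.
#' @return character vector of flagged bait ids.
#' @export
self_hyb_screen <- function(baits, min_rc_match = 21L,
                            resolution = c("later", "both")) {
  resolution <- match.arg(resolution)
  n <- NROW(baits)
  if (n == 0L) return(character())
  k <- as.integer(min_rc_match)
  seqs <- baits$sequence
  rcs <- reverse_complement(seqs)
  kmers <- function(s) if (nchar(s) < k) character() else
    substring(s, 1:(nchar(s) - k + 1L), k:nchar(s))
  fwd <- lapply(seqs, kmers)
  # index: kmer -> bait indices whose forward sequence contains it
  idx <- new.env(parent = emptyenv())
  for (i in seq_len(n)) for (w in unique(fwd[[i]]))
    assign(w, c(get0(w, envir = idx, ifnotfound = integer()), i), envir = idx)
  flagged <- logical(n)
  for (j in seq_len(n)) {
    partners <- integer()
    for (w in unique(kmers(rcs[j])))
      partners <- c(partners, get0(w, envir = idx, ifnotfound = integer()))
    partners <- unique(partners)
    for (i in partners) {
      if (i == j) { flagged[j] <- TRUE; next }   # palindromic run
      if (resolution == "both") flagged[i] <- flagged[j] <- TRUE
      else flagged[max(i, j)] <- TRUE
    }
  }
  baits$bait_id[flagged]
}

#' Full post-design bait screen
#'
#' Applies the screening cascade in a fixed order: symbiont screen,
#' region prune, duplicate removal, self-hybridization removal, and
#' (optionally) a final region-prune re-check so the region invariant
#' (at least `min_remaining` baits, fewer than `max_removed` losses)
#' still holds after the later stages.
#'
#' @param regions list of `bait_region`s (targets and barcode regions).
#' @param symbiont_refs an [annotated_seqs] NT table; `NULL` skips the
#'   symbiont screen.
#' @param map_identity,map_length_frac,blast_evalue see
#'   [symbiont_screen].
#' @param max_removed,min_remaining see [prune_regions].
#' @param min_rc_match,resolution see [self_hyb_screen].
#' @param final_recheck re-apply the region prune after dedup/self-hyb
#'   losses (default `TRUE`).
#' @param scheme optional [nt_scheme].
#' @return a `screen_report` list: `regions` (survivors), `baits`
#'   (surviving bait table), `removed` (data.frame id/unit/reason),
#'   `counts` (named integer summary).
#' @export
screen_baits <- function(regions, symbiont_refs = NULL, map_identity = 70,
                         map_length_frac = 0.70, blast_evalue = 1e-4,
                         max_removed = 3L, min_remaining = 2L,
                         min_rc_match = 21L, resolution = "later",
                         final_recheck = TRUE, scheme = NULL) {
  input <- baits_table(regions)
  removed <- list()
  keep_note <- function(df) if (NROW(df)) removed[[length(removed) + 1L]] <<- df

  # 1. symbiont screen + region prune
  flagged <- if (is.null(symbiont_refs)) character() else
    symbiont_screen(input, symbiont_refs, map_identity, map_length_frac,
                    blast_evalue, scheme)
  pr <- prune_regions(regions, flagged, max_removed, min_remaining)
  regions <- pr$regions
  keep_note(pr$report)

  # 2. duplicate removal
  bt <- baits_table(regions)
  dd <- dedup_baits(bt)
  if (length(dd$removed))
    keep_note(data.frame(id = dd$removed, unit = "bait",
                         reason = "DUPLICATE", stringsAsFactors = FALSE))
  regions <- drop_baits(regions, dd$removed)

  # 3. self-hybridization removal
  bt <- baits_table(regions)
  hyb <- self_hyb_screen(bt, min_rc_match, resolution)
  if (length(hyb))
    keep_note(data.frame(id = hyb, unit = "bait", reason = "SELF_HYB",
                         stringsAsFactors = FALSE))
  regions <- drop_baits(regions, hyb)

  # 4. final region re-check: dedup/self-hyb losses count against the
  # region exactly like screen losses did
  if (final_recheck) {
    pr2 <- recheck_regions(regions, flagged_hist = c(flagged, dd$removed, hyb),
                           max_removed = max_removed,
                           min_remaining = min_remaining)
    regions <- pr2$regions
    keep_note(pr2$report)
  }

  out_baits <- baits_table(regions)
  removed_df <- if (length(removed)) do.call(rbind, removed) else
    data.frame(id = character(), unit = character(), reason = character(),
               stringsAsFactors = FALSE)
  rownames(removed_df) <- NULL
  bait_removed <- removed_df[removed_df$unit == "bait", , drop = FALSE]
  counts <- c(input = nrow(input), surviving = nrow(out_baits),
              removed = nrow(bait_removed))
  structure(list(regions = regions, baits = out_baits,
                 removed = removed_df, counts = counts),
            class = "screen_report")
}

# drop baits by id from a region list, keeping empty regions out
drop_baits <- function(regions, ids) {
  out <- list()
  for (r in regions) {
    r$baits <- r$baits[!r$baits$bait_id %in% ids, , drop = FALSE]
    out[[length(out) + 1L]] <- r
  }
  out
}

# re-apply the region rule using cumulative losses across the cascade
recheck_regions <- function(regions, flagged_hist, max_removed, min_remaining) {
  survivors <- list(); rep_rows <- list()
  lost <- table(region_of_bait(flagged_hist))
  for (r in regions) {
    n_lost <- lost[r$region_id]
    n_lost <- if (is.na(n_lost)) 0L else as.integer(n_lost)
    if (n_lost >= max_removed || nrow(r$baits) < min_remaining) {
      if (nrow(r$baits))
        rep_rows[[length(rep_rows) + 1L]] <-
          data.frame(id = r$baits$bait_id, unit = "bait",
                     reason = "REGION_PRUNED", stringsAsFactors = FALSE)
      rep_rows[[length(rep_rows) + 1L]] <-
        data.frame(id = r$region_id, unit = "region",
                   reason = "REGION_PRUNED", stringsAsFactors = FALSE)
      next
    }
    survivors[[length(survivors) + 1L]] <- r
  }
  list(regions = survivors,
       report = if (length(rep_rows)) do.call(rbind, rep_rows) else
         data.frame(id = character(), unit = character(),
                    reason = character(), stringsAsFactors = FALSE))
}

region_of_bait <- function(bait_ids) {
  # bait headers are "<locus>|<start>-<end>|tile<k>|<taxon>|<label>"
  vapply(strsplit(bait_ids, "|", fixed = TRUE),
         function(p) paste(p[1:2], collapse = "|"), character(1))
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report: %d in, %d surviving, %d removed>\n",
              x$counts["input"], x$counts["surviving"], x$counts["removed"]))
  if (NROW(x$removed)) print(table(x$removed$reason[x$removed$unit == "bait"]))
  invisible(x)
}

#' Write a bait table to FASTA
#' @param baits a bait table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bait_fasta <- function(baits, path) {
  write_fasta(annotated_seqs(id = baits$bait_id, seq = baits$sequence,
                             kind = "NT"), path)
}
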