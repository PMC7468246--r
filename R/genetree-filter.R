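#' Parse paralog tags from tip labels
#'
#' Tip labels are `<taxon>`, `<taxon>.main` or `<taxon>.<i>.<j>` (for
#' example `Acropora.0.0`).
#'
#' @param labels character vector of tip labels.
#' @return data.frame with columns `label`, `taxon`, `tag` (`""` for
#'   untagged tips).
#' @export
parse_paralog_tags <- function(labels) {
  tag <- rep("", length(labels))
  taxon <- labels
  is_main <- grepl("\\.main$", labels)
  taxon[is_main] <- sub("\\.main$", "", labels[is_main])
  tag[is_main] <- "main"
  is_num <- grepl("\\.[0-9]+\\.[0-9]+$", labels) & !is_main
  taxon[is_num] <- sub("\\.[0-9]+\\.[0-9]+$", "", labels[is_num])
  tag[is_num] <- sub("^.*?\\.([0-9]+\\.[0-9]+)$", "\\1", labels[is_num])
  data.frame(label = labels, taxon = taxon, tag = tag,
             stringsAsFactors = FALSE)
}

#' Collapse low-support branches to polytomies
#'
#' Internal edges whose bootstrap support is below `min_support` are
#' contracted; the tip set never changes and contracted edge lengths are
#' added to the child edges so root-to-tip path lengths are preserved.
#' Edges without a numeric support value are kept.
#'
#' @param tree an `ape::phylo` with supports in `node.label`.
#' @param min_support support threshold; branches strictly below it are
#'   removed (default 10).
#' @return the collapsed tree.
#' @export
collapse_low_support <- function(tree, min_support = 10) {
  if (is.null(tree$node.label)) return(tree)
  lab <- suppressWarnings(as.numeric(tree$node.label))
  if (all(is.na(lab))) return(tree)
  lab[is.na(lab)] <- min_support            # absent support = keep edge
  tree$node.label <- lab
  out <- phangorn::pruneTree(tree, min_support)
  out
}


#' Resolve Type I paralogs
#'
#' Per taxon, keep the `.main` copy if present, else the `0.0` copy,
#' else the untagged copy; all other copies are logged as resolved
#' paralogs.  A taxon with copies but none of those three is an error
#' (ill-formed input).
#'
#' @param labels character vector of tip/sequence labels with paralog
#'   tags.
#' @return list with `keep` (labels kept, one per taxon) and `drop`
#'   (labels removed).
#' @export
resolve_type1_paralogs <- function(labels) {
  tags <- parse_paralog_tags(labels)
  keep <- character(); drop <- character()
  for (tx in unique(tags$taxon)) {
    rows <- tags[tags$taxon == tx, , drop = FALSE]
    pick <- if ("main" %in% rows$tag) rows$label[rows$tag == "main"][1]
    else if ("0.0" %in% rows$tag) rows$label[rows$tag == "0.0"][1]
    else if ("" %in% rows$tag) rows$label[rows$tag == ""][1]
    else stop("taxon ", tx, " has neither a '.main', '0.0' nor untagged copy")
    keep <- c(keep, pick)
    drop <- c(drop, setdiff(rows$label, pick))
  }
  list(keep = keep, drop = drop)
}

#' Flag Type II (deep) paralogy
#'
#' A locus shows deep paralogy when at least two taxa each carry
#' multiple copies and some branch of the tree separates their copies
#' into two multi-taxon groups — the signature of a duplication
#' predating the sampled taxa.  Operationally: `TRUE` iff some internal
#' bipartition splits the copies of two or more multi-copy taxa onto
#' both sides.
#'
#' @param tree an `ape::phylo` (at least 4 tips for a meaningful call).
#' @return `TRUE` when the locus should be removed whole.
#' @export
flag_type2_paralogy <- function(tree) {
  tags <- parse_paralog_tags(tree$tip.label)
  multi <- names(which(table(tags$taxon) > 1L))
  if (length(multi) < 2L || ape::Ntip(tree) < 4L) return(FALSE)
  ntip <- ape::Ntip(tree)
  for (node in (ntip + 2L):(ntip + tree$Nnode)) {    # skip the root
    inside <- tree$tip.label[phangorn::Descendants(tree, node, "tips")[[1]]]
    in_tax <- tags$taxon[match(inside, tags$label)]
    split_taxa <- 0L
    for (tx in multi) {
      n_in <- sum(in_tax == tx)
      if (n_in > 0L && n_in < sum(tags$taxon == tx)) split_taxa <- split_taxa + 1L
    }
    if (split_taxa >= 2L) return(TRUE)
  }
  FALSE
}

#' Apply the gene-tree contamination criteria
#'
#' Each tip is assigned an observed major clade from its local
#' neighborhood: the `neighborhood` nearest other tips by patristic
#' (path-length) distance, including every tip tied at the k-th
#' distance.  A call is made only
#' when the neighbors' expected clades are unanimous — a mixed
#' neighborhood (as around tips of small or partly sampled groups) is
#' uninformative, not evidence, and gives no call.  Removals:
#'
#' * (a) a taxon with two copies whose observed clades differ loses the
#'   copy whose observed clade is not its expected clade;
#' * (b) a single-copy tip whose observed clade differs from its
#'   expected clade is removed;
#' * (c) a tip whose pendant branch exceeds `long_branch_factor` times
#'   the median pendant branch length (computed on the tree before any
#'   removal) is removed.
#'
#' Trees with fewer than 4 tips skip (a)/(b).
#'
#' @param tree an `ape::phylo`.
#' @param expected_clades named character vector taxon -> clade.
#' @param long_branch_factor multiplier for criterion (c) (default 5).
#' @param neighborhood number of nearest tips consulted for a tip's
#'   observed clade (default 3).
#' @return data.frame with columns `label` and `criterion`
#'   (`CRIT_A`/`CRIT_B`/`CRIT_C`), possibly empty.
#' @export
apply_contamination_criteria <- function(tree, expected_clades,
                                         long_branch_factor = 5,
                                         neighborhood = 3L) {
  removals <- data.frame(label = character(), criterion = character(),
                         stringsAsFactors = FALSE)
  tags <- parse_paralog_tags(tree$tip.label)
  expected <- unname(expected_clades[tags$taxon])

  # (c) on the pre-removal tree; pendant edges only
  if (!is.null(tree$edge.length)) {
    ntip <- ape::Ntip(tree)
    pend <- tree$edge[, 2] <= ntip
    plen <- tree$edge.length[pend]
    names(plen) <- tree$tip.label[tree$edge[pend, 2]]
    med <- median(plen)
    long <- names(plen)[plen > long_branch_factor * med]
    if (length(long))
      removals <- rbind(removals, data.frame(label = long,
                                             criterion = "CRIT_C",
                                             stringsAsFactors = FALSE))
  }

  if (ape::Ntip(tree) >= 4L) {
    obs <- observed_clades(tree, expected_clades, neighborhood)
    obs <- obs[match(tags$label, names(obs))]
    copies <- table(tags$taxon)
    for (i in seq_along(tags$label)) {
      if (is.na(expected[i]) || is.na(obs[i])) next
      if (obs[i] == expected[i]) next
      if (copies[tags$taxon[i]] > 1L) {
        # (a): only fires when the copies disagree in observed clade
        others <- obs[tags$taxon == tags$taxon[i]]
        if (length(unique(others[!is.na(others)])) > 1L)
          removals <- rbind(removals, data.frame(label = tags$label[i],
                                                 criterion = "CRIT_A",
                                                 stringsAsFactors = FALSE))
      } else {
        removals <- rbind(removals, data.frame(label = tags$label[i],
                                               criterion = "CRIT_B",
                                               stringsAsFactors = FALSE))
      }
    }
  }
  removals[!duplicated(removals$label), , drop = FALSE]
}

observed_clades <- function(tree, expected_clades, neighborhood = 3L) {
  tags <- parse_paralog_tags(tree$tip.label)
  ntip <- ape::Ntip(tree)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  D <- ape::cophenetic.phylo(tree)
  out <- setNames(rep(NA_character_, ntip), tree$tip.label)
  for (i in seq_len(ntip)) {
    lab <- tree$tip.label[i]
    d <- D[lab, setdiff(colnames(D), lab)]
    if (length(d) < neighborhood) next
    kth <- sort(d)[neighborhood]
    near <- names(d)[d <= kth + 1e-9]   # all tips tied at the k-th distance
    cl <- expected_clades[tags$taxon[match(near, tags$label)]]
    cl <- cl[!is.na(cl)]
    if (length(cl) < neighborhood) next
    # unanimity required: a mixed neighborhood is uninformative
    if (length(unique(cl)) == 1L) out[i] <- cl[1]
  }
  out
}

#' Curate one locus with its gene tree
#'
#' The full curation cascade: collapse low-support branches, drop the
#' locus whole on deep (Type II) paralogy, apply contamination criteria
#' (a)-(c), resolve Type I paralogs, rename surviving tips to bare taxon
#' names, and apply the locus-level filters (minimum scleractinian taxa,
#' minimum parsimony-informative sites).
#'
#' @param locus_id locus id.
#' @param tree the locus gene tree (`ape::phylo`).
#' @param sequences named character vector label -> NT sequence for the
#'   tree's tips.
#' @param expected_clades named character vector taxon -> clade.
#' @param min_support,long_branch_factor,neighborhood see the individual
#'   steps.
#' @param min_scleractinians minimum Robust+Complex taxa to keep the
#'   locus (default 3).
#' @param min_pi_sites minimum parsimony-informative sites on the
#'   curated (aligned or equal-length) sequences; 0 disables the check.
#' @param quarantine character vector of locus ids to drop on sight
#'   (the escape hatch for topologies judged spurious by eye).
#' @return a `curated_locus` list: `locus_id`, `sequences` (taxon ->
#'   sequence; `NULL` when dropped), `removal_log` (data.frame
#'   `unit`/`id`/`criterion`), `kept` flag.
#' @export
curate_locus <- function(locus_id, tree, sequences, expected_clades,
                         min_support = 10, long_branch_factor = 5,
                         neighborhood = 3L, min_scleractinians = 3L,
                         min_pi_sites = 1L, quarantine = character()) {
  log_rows <- list()
  note <- function(unit, id, criterion)
    log_rows[[length(log_rows) + 1L]] <<-
      data.frame(unit = unit, id = id, criterion = criterion,
                 stringsAsFactors = FALSE)
  done <- function(kept, seqs = NULL) {
    structure(list(locus_id = locus_id, sequences = seqs,
                   removal_log = if (length(log_rows))
                     do.call(rbind, log_rows) else
                       data.frame(unit = character(), id = character(),
                                  criterion = character(),
                                  stringsAsFactors = FALSE),
                   kept = kept), class = "curated_locus")
  }

  if (locus_id %in% quarantine) {
    note("locus", locus_id, "QUARANTINED")
    return(done(FALSE))
  }
  tree <- collapse_low_support(tree, min_support)
  if (flag_type2_paralogy(tree)) {
    note("locus", locus_id, "PARALOG_TYPE2_LOCUS")
    return(done(FALSE))
  }
  rem <- apply_contamination_criteria(tree, expected_clades,
                                      long_branch_factor, neighborhood)
  if (nrow(rem)) for (i in seq_len(nrow(rem)))
    note("tip", rem$label[i], rem$criterion[i])
  keep_labels <- setdiff(tree$tip.label, rem$label)

  res <- resolve_type1_paralogs(keep_labels)
  if (length(res$drop)) note("tip", res$drop, "PARALOG_RESOLVED")
  tags <- parse_paralog_tags(res$keep)
  seqs <- sequences[res$keep]
  if (any(is.na(seqs))) stop("locus ", locus_id, ": no sequence for tip ",
                             res$keep[which(is.na(seqs))[1]])
  names(seqs) <- tags$taxon

  clades <- expected_clades[names(seqs)]
  n_scler <- sum(clades %in% c("ROBUST", "COMPLEX"), na.rm = TRUE)
  if (n_scler < min_scleractinians) {
    note("locus", locus_id, "LOW_TAXA")
    return(done(FALSE))
  }
  if (min_pi_sites > 0L && length(unique(nchar(seqs))) == 1L) {
    if (count_pi_sites(seqs) < min_pi_sites) {
      note("locus", locus_id, "UNINFORMATIVE")
      return(done(FALSE))
    }
  }
  done(TRUE, seqs)
}

#' @export
print.curated_locus <- function(x, ...) {
  cat(sprintf("<curated_locus %s: %s, %d sequences, %d log entries>\n",
              x$locus_id, if (x$kept) "kept" else "dropped",
              length(x$sequences), nrow(x$removal_log)))
  invisible(x)
}

#' Locus-level informativeness filter
#'
#' @param sequences named character vector taxon -> sequence for a
#'   curated locus.
#' @param expected_clades named character vector taxon -> clade.
#' @param min_scleractinians minimum Robust+Complex taxa (default 3).
#' @param min_pi_sites minimum parsimony-informative sites (only
#'   checked when sequences share one length).
#' @return list with `keep` (logical) and `reason` (`NA`, `"LOW_TAXA"`
#'   or `"UNINFORMATIVE"`).
#' @export
locus_level_filter <- function(sequences, expected_clades,
                               min_scleractinians = 3L, min_pi_sites = 1L) {
  clades <- expected_clades[names(sequences)]
  n_scler <- sum(clades %in% c("ROBUST", "COMPLEX"), na.rm = TRUE)
  if (n_scler < min_scleractinians)
    return(list(keep = FALSE, reason = "LOW_TAXA"))
  if (min_pi_sites > 0L && length(unique(nchar(sequences))) == 1L &&
      count_pi_sites(sequences) < min_pi_sites)
    return(list(keep = FALSE, reason = "UNINFORMATIVE"))
  list(keep = TRUE, reason = NA_character_)
}

#' Count parsimony-informative sites
#'
#' A column is parsimony-informative when at least two distinct
#' non-missing states (`-`, `?`, `N` excluded) each occur in at least
#' two rows.
#'
#' @param rows character vector of equal-length sequences.
#' @return integer count.
#' @export
count_pi_sites <- function(rows) {
  if (length(rows) < 4L) return(0L)
  mat <- do.call(rbind, strsplit(unname(toupper(rows)), ""))
  sum(apply(mat, 2, function(col) {
    col <- col[!col %in% c("-", "?", "N")]
    if (!length(col)) return(FALSE)
    tab <- table(col)
    sum(tab >= 2L) >= 2L
  }))
}
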