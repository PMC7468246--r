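read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

align_nt_rows <- function(seqs) {
  if (length(unique(nchar(seqs))) == 1L) return(toupper(seqs))
  if (Sys.which("mafft") == "")
    stop("sequences are unaligned and 'mafft' is not on the PATH")
  tmp_in <- tempfile(fileext = ".fasta"); tmp_out <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(tmp_in, tmp_out)), add = TRUE)
  ph <- sprintf("s%06d", seq_along(seqs))
  writeLines(paste0(">", ph, "\n", toupper(seqs)), tmp_in)
  # progressive FFT-NS-2: plenty for closely related coding sequences
  # whose indels are whole missing exons
  status <- system2("mafft", c("--retree", "2", "--quiet", tmp_in),
                    stdout = tmp_out)
  if (!identical(status, 0L)) stop("mafft failed with status ", status)
  aln <- read_fasta(tmp_out, "NT")
  setNames(toupper(aln$seq[match(ph, aln$id)]), names(seqs))
}

read_genome_packages <- function(genome_dir) {
  aa_files <- sort(list.files(genome_dir, pattern = "\\.aa\\.fasta$",
                              full.names = TRUE))
  if (!length(aa_files)) stop("no genome packages in ", genome_dir)
  models <- list(); exons <- list()
  for (f in aa_files) {
    g <- sub("\\.aa\\.fasta$", "", basename(f))
    models[[g]] <- read_fasta(f, "AA")
    ef <- file.path(genome_dir, paste0(g, ".exons.tsv"))
    if (!file.exists(ef)) stop("missing exon map for genome ", g)
    exons <- c(exons, read_exon_map(ef))
  }
  list(models = models, exons = exons)
}

#' Run the design-time workflow
#'
#' Executes the full bait-design pipeline: orthogroup filtering (taxon
#' representation, genome anchoring, contaminant-transcript removal, bin
#' assignment), codon alignment, exon-aware bait tiling, barcode-bait
#' design, and the post-design screening cascade.  Writes the final bait
#' FASTA, region manifest, screen ledger and a run-summary JSON with
#' stage-by-stage counts.
#'
#' @param config a config list or path to a YAML file; the `design`
#'   section (or the list itself) must name `orthogroup_dir`,
#'   `genome_dir`, `contaminant_db`, `symbiont_db`, `barcode_refs`
#'   (named list of FASTA paths) and `out_dir`.  Optional keys override
#'   the published thresholds (`min_taxa`, `min_per_clade`,
#'   `min_bit_score`, `contaminant_identity`, `contaminant_length`,
#'   `map_identity`, `map_length_frac`, `blast_evalue`, `max_removed`,
#'   `min_remaining`, `min_rc_match`, `multi_exon`, `gap_rule`).
#' @return invisibly, a list with `summary`, `regions`, `screen`,
#'   `contaminant_log`.
#' @export
run_design <- function(config) {
  config <- read_pipeline_config(config)
  cf <- config$design %||% config
  out_dir <- cf$out_dir %||% stop("config must name design$out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  opt <- function(key, default) cf[[key]] %||% default

  ogs <- stage("read_orthogroups", read_orthogroup_dir(cf$orthogroup_dir))
  n_initial <- length(ogs)
  if (!n_initial) stop("no input loci")

  ogs <- stage("representation_filter",
               Filter(function(og) representation_filter(
                 og, opt("min_taxa", 6L), opt("min_per_clade", 2L)), ogs))
  n_repr <- length(ogs)

  gp <- stage("read_genomes", read_genome_packages(cf$genome_dir))
  ogs <- stage("genome_anchor",
               Filter(function(og) genome_anchor(
                 og, gp$models, opt("min_bit_score", 50)), ogs))
  n_anchor <- length(ogs)

  db <- stage("read_contaminant_db", read_fasta(cf$contaminant_db, "NT"))
  contaminant_log <- list()
  ogs <- stage("contaminant_filter", {
    kept <- list()
    for (og in ogs) {
      res <- remove_contaminant_transcripts(
        og, db, opt("contaminant_identity", 80),
        opt("contaminant_length", 100), min_taxa = opt("min_taxa", 6L))
      removed <- if (is.null(res)) og$nt$id else attr(res, "removed")
      if (length(removed))
        contaminant_log[[length(contaminant_log) + 1L]] <- data.frame(
          orthogroup = og$id,
          action = if (is.null(res)) "LOCUS_DROPPED" else "MEMBER_REMOVED",
          member = removed, stringsAsFactors = FALSE)
      if (!is.null(res)) kept[[res$id]] <- res
    }
    kept
  })
  n_contam <- length(ogs)
  contaminant_log <- if (length(contaminant_log))
    do.call(rbind, contaminant_log) else
      data.frame(orthogroup = character(), action = character(),
                 member = character(), stringsAsFactors = FALSE)

  ogs <- stage("assign_bins", lapply(ogs, assign_bin, gene_models = gp$models))

  scheme <- tiling_scheme()
  regions <- stage("bait_design", {
    out <- list()
    for (og in ogs) {
      ref_id <- attr(og, "bin_hit")$subject_id
      ref_aa <- gp$models[[og$bin]]$seq[gp$models[[og$bin]]$id == ref_id]
      aa_in <- c(setNames(og$aa$seq, og$aa$id), .ref. = ref_aa)
      aln <- align_amino_acids(aa_in)
      locus <- back_translate(
        aln[names(aln) != ".ref."], setNames(og$nt$seq, og$nt$id),
        locus_id = og$id, ref_taxon = ref_id, ref_aa_row = aln[[".ref."]],
        bin = og$bin)
      regs <- design_regions(locus, gp$exons[[ref_id]], scheme,
                             gap_rule = opt("gap_rule", "strict"),
                             multi_exon = opt("multi_exon", TRUE))
      if (length(regs) && !isTRUE(opt("multi_exon", TRUE)))
        regs <- list(best_region_per_locus(regs))
      out <- c(out, regs)
    }
    out
  })
  target_loci <- unique(vapply(regions, `[[`, character(1), "locus_id"))

  barcode_regions <- stage("barcode_baits", {
    out <- list()
    for (label in names(cf$barcode_refs %||% list())) {
      refs <- read_fasta(cf$barcode_refs[[label]], "NT")
      rows <- align_nt_rows(setNames(refs$seq, refs$id))
      out[[label]] <- design_barcode_baits(rows, label,
                                           gene_id = tolower(label))
    }
    out
  })

  all_regions <- c(regions, unname(barcode_regions))
  n_designed <- nrow(baits_table(all_regions))

  symb <- stage("read_symbionts", read_fasta(cf$symbiont_db, "NT"))
  screen <- stage("bait_screen", screen_baits(
    all_regions, symb, opt("map_identity", 70), opt("map_length_frac", 0.70),
    opt("blast_evalue", 1e-4), opt("max_removed", 3L),
    opt("min_remaining", 2L), opt("min_rc_match", 21L)))

  write_bait_fasta(baits_table(all_regions),
                   file.path(out_dir, "baits_designed.fasta"))
  write_bait_fasta(screen$baits, file.path(out_dir, "baits_final.fasta"))
  write.table(region_manifest(all_regions),
              file.path(out_dir, "regions.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(screen$removed, file.path(out_dir, "screen_removed.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(contaminant_log, file.path(out_dir, "contaminant_log.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(
    initial_loci = n_initial, post_representation = n_repr,
    post_anchor = n_anchor, post_contaminant = n_contam,
    loci_with_regions = length(target_loci),
    regions_designed = length(regions),
    baits_designed = n_designed,
    barcode_baits = nrow(baits_table(unname(barcode_regions))),
    baits_retained = nrow(screen$baits),
    removed_by_reason = as.list(table(
      screen$removed$reason[screen$removed$unit == "bait"])))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(summary = summary, regions = all_regions, screen = screen,
                 contaminant_log = contaminant_log))
}

#' Run the post-capture workflow
#'
#' Barcode QC on every sample, gene-tree curation of every locus, and
#' supermatrix construction.  The matrix is refused when any sample is a
#' misidentification suspect unless `force = TRUE`.
#'
#' @param config a config list or YAML path; the `postcapture` section
#'   must name `genetree_dir`, `locus_seq_dir`, `contig_dir`,
#'   `coverage_dir`, `sample_sheet`, `barcode_refs` (named list),
#'   `expected_clades` and `out_dir`.  Optional threshold overrides:
#'   `min_identity`, `min_len`, `coverage_fold`, `min_support`,
#'   `long_branch_factor`, `min_scleractinians`, `min_pi_sites`,
#'   `max_gap_frac`, `quarantine` (locus ids).
#' @param force build the matrix even when a sample fails QC.
#' @return invisibly, a list with `barcode_reports`, `curated`,
#'   `matrix`, `stats`, `removal_log`.
#' @export
run_postcapture <- function(config, force = FALSE) {
  config <- read_pipeline_config(config)
  cf <- config$postcapture %||% config
  out_dir <- cf$out_dir %||% stop("config must name postcapture$out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  opt <- function(key, default) cf[[key]] %||% default

  sheet <- stage("read_sample_sheet",
                 read.delim(cf$sample_sheet, stringsAsFactors = FALSE))
  refs <- stage("read_barcode_refs",
                lapply(cf$barcode_refs, read_fasta, kind = "NT"))

  reports <- stage("barcode_qc", {
    out <- list()
    for (i in seq_len(nrow(sheet))) {
      sid <- sheet$sample_id[i]
      contigs <- read_fasta(file.path(cf$contig_dir,
                                      paste0(sid, ".fasta")), "NT")
      covs <- read_coverage_table(file.path(cf$coverage_dir,
                                            paste0(sid, ".tsv")))
      for (label in names(refs))
        out[[paste(sid, label)]] <- barcode_check(
          sid, sheet$expected_taxon[i], contigs, covs, refs[[label]],
          locus = label, min_identity = opt("min_identity", 98),
          min_len = opt("min_len", 200L),
          coverage_fold = opt("coverage_fold", 100))
    }
    out
  })
  rep_table <- barcode_report_table(reports)
  write.table(rep_table, file.path(out_dir, "barcode_reports.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    lapply(reports, function(r) list(
      sample_id = r$sample_id, locus = r$locus, verdict = r$verdict,
      best_match_taxon = r$best_match_taxon, hits = r$hits)),
    file.path(out_dir, "barcode_reports.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  suspects <- unique(rep_table$sample_id[
    rep_table$verdict == "MISIDENTIFIED_SUSPECT"])
  if (length(suspects) && !force)
    stop("QC failure: misidentification suspect(s): ",
         paste(suspects, collapse = ", "), " (use force = TRUE to override)")

  clades_df <- stage("read_expected_clades",
                     read.delim(cf$expected_clades, stringsAsFactors = FALSE))
  expected <- setNames(clades_df$clade, clades_df$taxon)

  tree_files <- sort(list.files(cf$genetree_dir, pattern = "\\.nwk$",
                                full.names = TRUE))
  if (!length(tree_files)) stop("no gene trees in ", cf$genetree_dir)
  curated <- stage("genetree_curation", {
    out <- list()
    for (f in tree_files) {
      locus <- sub("\\.nwk$", "", basename(f))
      tree <- ape::read.tree(f)
      seqs <- read_fasta(file.path(cf$locus_seq_dir,
                                   paste0(locus, ".fasta")), "NT")
      out[[locus]] <- curate_locus(
        locus, tree, setNames(seqs$seq, seqs$id), expected,
        min_support = opt("min_support", 10),
        long_branch_factor = opt("long_branch_factor", 5),
        min_scleractinians = opt("min_scleractinians", 3L),
        min_pi_sites = opt("min_pi_sites", 1L),
        quarantine = opt("quarantine", character()))
    }
    out
  })
  removal_log <- do.call(rbind, lapply(curated, function(cl)
    if (nrow(cl$removal_log))
      cbind(locus = cl$locus_id, cl$removal_log) else NULL))
  write.table(removal_log, file.path(out_dir, "removal_log.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  kept <- Filter(function(cl) cl$kept, curated)
  writeLines(setdiff(names(curated), names(kept)),
             file.path(out_dir, "dropped_loci.txt"))
  if (!length(kept)) stop("no loci survived curation")

  sm <- stage("supermatrix", {
    loci <- lapply(kept, function(cl) {
      aln <- align_nt_rows(cl$sequences)
      trim_alignment(aln, opt("max_gap_frac", 0.8))
    })
    loci <- Filter(function(x) nchar(x[1]) > 0L, loci)
    concatenate_loci(loci, taxa = sheet$sample_id)
  })
  stats <- matrix_stats(sm)
  write_supermatrix(sm, file.path(out_dir, "supermatrix.fasta"),
                    file.path(out_dir, "supermatrix.phy"))
  write_partitions(sm, file.path(out_dir, "partitions.txt"))
  stats_out <- stats
  if (length(suspects))
    stats_out$warning <- paste("QC override: suspect sample(s)",
                               paste(suspects, collapse = ", "))
  jsonlite::write_json(stats_out, file.path(out_dir, "matrix_stats.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(barcode_reports = reports, curated = curated, matrix = sm,
                 stats = stats, removal_log = removal_log))
}
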