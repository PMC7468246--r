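#' Configuration for the synthetic-data generator
#'
#' The generator emulates the design-time input universe (orthogroups
#' across Robust, Complex and outgroup taxa with reference genomes,
#' a labelled contamination-screen database and symbiont references)
#' and the post-capture universe (per-sample contigs with coverages,
#' barcode references, gene trees), planting anomalies whose identities
#' are recorded in a truth ledger so recovery can be scored exactly.
#'
#' @param seed integer fixing all randomness.
#' @param n_robust,n_complex,n_outgroup taxon counts (defaults 8/8/4).
#' @param n_loci number of orthogroups (default 60).
#' @param locus_length_range codon-count range per locus (default
#'   120-400).
#' @param tree_depth expected substitutions per site root-to-tip
#'   (default 0.3).
#' @param contaminant_fraction fraction of loci receiving one planted
#'   non-cnidarian member (default 0.1).
#' @param symbiont_insert_fraction fraction of loci receiving a planted
#'   symbiont-derived 120-mer (default 0.1).
#' @param paralog_fraction fraction of loci with a planted Type I
#'   paralog pair (default 0.1).
#' @param n_type2_loci loci with a planted deep duplication (default 2).
#' @param n_misplaced planted gene-tree misplacements (default 3).
#' @param exon_break_prob per-codon-boundary probability of an exon
#'   break in reference gene models (default 0.05).
#' @param long_exon_fraction fraction of loci guaranteed a >= 240 nt
#'   exon so every tiling window length is exercised (default 0.8).
#' @param exon_loss_prob per-taxon-per-exon probability that a lineage
#'   lacks an exon, creating alignment gap structure (default 0.03).
#' @param n_genomes reference genomes (default 3).
#' @param n_symbiont_refs,symbiont_ref_length symbiont reference count
#'   and length (defaults 6, 2000).
#' @param dropout per-sample-per-locus capture dropout (default 0.1).
#' @param barcode_coverage coverage of the true barcode contig
#'   (default 5000).
#' @param barcode_contam_ratio coverage fold between the true barcode
#'   and the planted cross-contaminant (default 150).
#' @return a `fixture_config` list.
#' @export
fixture_config <- function(seed = 42L, n_robust = 8L, n_complex = 8L,
                           n_outgroup = 4L, n_loci = 60L,
                           locus_length_range = c(120L, 400L),
                           tree_depth = 0.3, contaminant_fraction = 0.1,
                           symbiont_insert_fraction = 0.1,
                           paralog_fraction = 0.1, n_type2_loci = 2L,
                           n_misplaced = 3L, exon_break_prob = 0.05,
                           long_exon_fraction = 0.8, exon_loss_prob = 0.03,
                           n_genomes = 3L, n_symbiont_refs = 6L,
                           symbiont_ref_length = 2000L, dropout = 0.1,
                           barcode_coverage = 5000,
                           barcode_contam_ratio = 150) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_loci >= 1L, all(unlist(cfg[c(
    "contaminant_fraction", "symbiont_insert_fraction", "paralog_fraction",
    "exon_break_prob", "long_exon_fraction", "exon_loss_prob",
    "dropout")]) >= 0),
    cfg$contaminant_fraction <= 1, cfg$symbiont_insert_fraction <= 1,
    cfg$dropout < 1, cfg$barcode_contam_ratio > 1)
  structure(cfg, class = "fixture_config")
}

NONSTOP_CODONS <- setdiff(
  apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                    c("T", "C", "A", "G")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

random_cds <- function(n_codons)
  paste(sample(NONSTOP_CODONS, n_codons, replace = TRUE), collapse = "")

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# per-site substitution with probability p; internal stop codons are
# repaired deterministically (third base -> C)
evolve_cds <- function(cds, p) {
  ch <- strsplit(cds, "")[[1]]
  hit <- which(stats::runif(length(ch)) < p)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  n_cod <- length(ch) %/% 3L
  for (k in seq_len(n_cod)) {
    cod <- paste(ch[(3L * k - 2L):(3L * k)], collapse = "")
    if (cod %in% c("TAA", "TAG", "TGA")) ch[3L * k] <- "C"
  }
  paste(ch, collapse = "")
}

evolve_nt <- function(seq, p) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < p)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

fixture_taxa <- function(cfg) {
  data.frame(
    taxon = c(sprintf("R%02d", seq_len(cfg$n_robust)),
              sprintf("C%02d", seq_len(cfg$n_complex)),
              sprintf("O%02d", seq_len(cfg$n_outgroup))),
    clade = rep(c("ROBUST", "COMPLEX", "OUTGROUP"),
                c(cfg$n_robust, cfg$n_complex, cfg$n_outgroup)),
    stringsAsFactors = FALSE)
}

#' Simulate the design-time input universe
#'
#' Coding sequences evolve along a fixed ((Robust),(Complex),outgroup)
#' topology under an equal-rates substitution model with no indels in
#' coding positions; alignment gap structure arises only from
#' lineage-specific exon presence.  Planted anomalies: non-cnidarian
#' contaminant members at ~95% identity to a labelled database record,
#' and symbiont-derived 120-mers shared verbatim with a symbiont
#' reference.  Everything written is listed in the returned truth
#' ledger.
#'
#' @param cfg a [fixture_config].
#' @param dir output directory (created).
#' @return invisibly, a list with `dir`, `truth` (data.frame), `taxa`.
#' @export
simulate_orthogroups <- function(cfg, dir) {
  set.seed(cfg$seed)
  dir.create(file.path(dir, "orthogroups"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "genomes"), showWarnings = FALSE)
  taxa <- fixture_taxa(cfg)
  loci <- sprintf("OG%04d", seq_len(cfg$n_loci))
  genomes <- sprintf("G%02d", seq_len(cfg$n_genomes))
  truth <- list()
  note <- function(type, locus = NA, member = NA, detail = NA)
    truth[[length(truth) + 1L]] <<-
      data.frame(type = type, locus = locus, member = member,
                 detail = as.character(detail), stringsAsFactors = FALSE)

  # disjoint anomaly locus sets, chosen up front
  n_cont <- floor(cfg$contaminant_fraction * cfg$n_loci)
  n_symb <- floor(cfg$symbiont_insert_fraction * cfg$n_loci)
  pool <- sample(loci)
  cont_loci <- head(pool, n_cont); pool <- setdiff(pool, cont_loci)
  symb_loci <- head(pool, n_symb)

  # symbiont references
  sym_ids <- sprintf("Sym%d", seq_len(cfg$n_symbiont_refs))
  sym_seqs <- setNames(vapply(sym_ids, function(i)
    random_nt(cfg$symbiont_ref_length), character(1)), sym_ids)

  db_rows <- list()
  locus_cds <- list()     # locus -> named vector taxon -> CDS (truth)
  exon_maps <- setNames(vector("list", cfg$n_genomes), genomes)

  for (li in seq_along(loci)) {
    locus <- loci[li]
    n_cod <- sample(cfg$locus_length_range[1]:cfg$locus_length_range[2], 1L)
    depth <- cfg$tree_depth
    root <- random_cds(n_cod)
    ing <- evolve_cds(root, 0.3 * depth)
    anc <- list(ROBUST = evolve_cds(ing, 0.2 * depth),
                COMPLEX = evolve_cds(ing, 0.2 * depth))
    cds <- setNames(character(nrow(taxa)), taxa$taxon)
    for (i in seq_len(nrow(taxa))) {
      cds[i] <- if (taxa$clade[i] == "OUTGROUP") evolve_cds(root, depth)
      else evolve_cds(anc[[taxa$clade[i]]], 0.5 * depth)
    }

    # reference gene model: a mild divergence of the locus root
    g <- genomes[(li - 1L) %% cfg$n_genomes + 1L]
    model_cds <- evolve_cds(root, 0.05)
    model_id <- sprintf("%s_%s", g, locus)
    # exon structure on the model CDS, codon-boundary breaks
    breaks <- which(stats::runif(n_cod - 1L) < cfg$exon_break_prob)
    if (stats::runif(1) < cfg$long_exon_fraction)
      breaks <- breaks[breaks >= 80L]           # first exon >= 240 nt
    bounds <- c(0L, breaks * 3L, n_cod * 3L)
    emap <- cbind(start = bounds[-length(bounds)], end = bounds[-1])
    exon_maps[[g]][[model_id]] <- emap

    # lineage-specific exon presence
    keep_cod <- setNames(rep(list(seq_len(n_cod)), nrow(taxa)), taxa$taxon)
    if (cfg$exon_loss_prob > 0 && nrow(emap) > 1L) {
      for (tx in taxa$taxon) {
        lost <- which(stats::runif(nrow(emap)) < cfg$exon_loss_prob)
        for (e in lost) {
          drop_cod <- (emap[e, "start"] / 3L + 1L):(emap[e, "end"] / 3L)
          keep_cod[[tx]] <- setdiff(keep_cod[[tx]], drop_cod)
        }
      }
    }
    take_codons <- function(s, idx) {
      cods <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
      paste(cods[idx], collapse = "")
    }
    for (tx in taxa$taxon) cds[tx] <- take_codons(cds[tx], keep_cod[[tx]])

    # planted non-cnidarian contaminant member: replace one taxon's
    # transcript with a ~95%-identity relative of a labelled db record
    if (locus %in% cont_loci) {
      victim <- sample(taxa$taxon[taxa$clade != "OUTGROUP"], 1L)
      backbone <- random_cds(n_cod)
      cds[victim] <- evolve_cds(backbone, 0.05)
      db_rows[[length(db_rows) + 1L]] <- data.frame(
        id = sprintf("db_noncn_%s", locus), taxon = "noncnidarian",
        clade = "OTHER", seq = backbone, stringsAsFactors = FALSE)
      note("CONTAMINANT_MEMBER", locus, victim)
    }

    # planted symbiont-derived 120-mer shared verbatim with a reference
    if (locus %in% symb_loci) {
      host <- sample(taxa$taxon[taxa$clade != "OUTGROUP"], 1L)
      n_host <- nchar(cds[host]) %/% 3L
      if (n_host >= 44L) {
        p <- sample.int(n_host - 40L, 1L)       # codon offset, 1-based
        seg <- random_cds(40L)                  # stop-free in host frame
        substr(cds[host], 3L * (p - 1L) + 1L, 3L * (p + 39L)) <- seg
        ref <- sample(sym_ids, 1L)
        o <- sample.int(cfg$symbiont_ref_length - 120L, 1L)
        substr(sym_seqs[ref], o, o + 119L) <- seg
        note("SYMBIONT_INSERT", locus, host,
             sprintf("%s:cds_nt_start=%d", ref, 3L * (p - 1L)))
      }
    }

    # a cnidarian database record per locus (the locus root)
    db_rows[[length(db_rows) + 1L]] <- data.frame(
      id = sprintf("db_cn_%s", locus), taxon = "cnidarian",
      clade = "ROBUST", seq = root, stringsAsFactors = FALSE)

    locus_cds[[locus]] <- cds
    nt <- annotated_seqs(id = taxa$taxon, seq = unname(cds),
                         taxon = taxa$taxon, clade = taxa$clade, kind = "NT")
    aa <- annotated_seqs(id = taxa$taxon, seq = translate_cds(unname(cds)),
                         taxon = taxa$taxon, clade = taxa$clade, kind = "AA")
    write_fasta(nt, file.path(dir, "orthogroups",
                              paste0(locus, ".nt.fasta")))
    write_fasta(aa, file.path(dir, "orthogroups",
                              paste0(locus, ".aa.fasta")))

    # accumulate gene models per genome
    attr(exon_maps[[g]], "seqs") <-
      c(attr(exon_maps[[g]], "seqs") %||% character(),
        setNames(translate_cds(model_cds), model_id))
  }

  # unrelated non-cnidarian decoys exercise the no-hit path
  for (d in 1:3)
    db_rows[[length(db_rows) + 1L]] <- data.frame(
      id = sprintf("db_decoy_%d", d), taxon = "noncnidarian",
      clade = "OTHER", seq = random_cds(150L), stringsAsFactors = FALSE)
  db <- do.call(rbind, db_rows)
  write_fasta(annotated_seqs(id = db$id, seq = db$seq, taxon = db$taxon,
                             clade = db$clade, kind = "NT"),
              file.path(dir, "contaminant_db.fasta"))

  write_fasta(annotated_seqs(id = sym_ids, seq = unname(sym_seqs),
                             kind = "NT"),
              file.path(dir, "symbionts.fasta"))

  for (g in genomes) {
    seqs <- attr(exon_maps[[g]], "seqs")
    write_fasta(annotated_seqs(id = names(seqs), seq = unname(seqs),
                               kind = "AA"),
                file.path(dir, "genomes", paste0(g, ".aa.fasta")))
    maps <- exon_maps[[g]]
    attr(maps, "seqs") <- NULL
    write_exon_map(maps, file.path(dir, "genomes", paste0(g, ".exons.tsv")))
  }

  write.table(taxa, file.path(dir, "expected_clades.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(type = character(), locus = character(), member = character(),
               detail = character(), stringsAsFactors = FALSE)
  saved <- list(dir = dir, truth = truth_df, taxa = taxa,
                locus_cds = locus_cds)
  invisible(saved)
}

#' Simulate post-capture inputs
#'
#' Per-sample contigs are the true coding sequences with a known
#' dropout; each sample carries a high-coverage barcode contig (COI and
#' H3), one sample additionally a planted cross-contaminant barcode at
#' `1/barcode_contam_ratio` of the true coverage.  Gene trees follow
#' the true topology with planted Type I paralog pairs, deep (Type II)
#' duplications and clade misplacements, all listed in the ledger.
#'
#' @param sim the object returned by [simulate_orthogroups].
#' @param cfg the same [fixture_config].
#' @return invisibly, the updated `sim` with capture truth appended.
#' @export
simulate_capture <- function(sim, cfg) {
  set.seed(cfg$seed + 1L)
  dir <- sim$dir
  for (d in c("capture", "capture/contigs", "capture/coverage",
              "capture/trees", "capture/loci", "barcodes"))
    dir.create(file.path(dir, d), showWarnings = FALSE)
  taxa <- sim$taxa
  loci <- names(sim$locus_cds)
  truth <- sim$truth
  note <- function(type, locus = NA, member = NA, detail = NA)
    truth <<- rbind(truth, data.frame(type = type, locus = locus,
                                      member = member,
                                      detail = as.character(detail),
                                      stringsAsFactors = FALSE))

  # anomaly loci disjoint from each other (and their victims known)
  used <- unique(truth$locus[!is.na(truth$locus)])
  pool <- sample(setdiff(loci, used))
  n_para <- floor(cfg$paralog_fraction * length(loci))
  para_loci <- head(pool, n_para); pool <- setdiff(pool, para_loci)
  type2_loci <- head(pool, cfg$n_type2_loci)
  pool <- setdiff(pool, type2_loci)
  mis_loci <- head(pool, cfg$n_misplaced)

  scler <- taxa$taxon[taxa$clade != "OUTGROUP"]

  # presence matrix with dropout; anomaly actors never drop out
  present <- matrix(stats::runif(length(loci) * nrow(taxa)) >= cfg$dropout,
                    nrow = length(loci),
                    dimnames = list(loci, taxa$taxon))
  mis_taxon <- setNames(sample(scler, length(mis_loci), replace = TRUE),
                        mis_loci)
  for (lc in mis_loci) present[lc, mis_taxon[lc]] <- TRUE

  pend <- 0.05   # pendant branch length used throughout
  for (li in seq_along(loci)) {
    locus <- loci[li]
    cds <- sim$locus_cds[[locus]]
    tips <- taxa$taxon[present[locus, taxa$taxon]]
    if (length(tips) < 8L)   # dropout left too little: use everyone
      tips <- taxa$taxon
    seqs <- cds[tips]
    labels <- setNames(tips, tips)

    clade_of <- setNames(taxa$clade, taxa$taxon)
    groups <- split(tips, clade_of[tips])

    if (locus %in% para_loci) {
      host <- sample(intersect(tips, scler), 1L)
      main_lab <- paste0(host, ".main"); alt_lab <- paste0(host, ".0.0")
      seqs <- c(seqs, setNames(evolve_cds(cds[host], 0.02), alt_lab))
      names(seqs)[names(seqs) == host] <- main_lab
      groups <- lapply(groups, function(g) {
        g[g == host] <- sprintf("(%s:%g,%s:%g)100:%g", main_lab, pend / 2,
                                alt_lab, pend / 2, pend / 2)
        g
      })
      note("PARALOG_TYPE1", locus, host, sprintf("%s|%s", main_lab, alt_lab))
    }

    if (locus %in% mis_loci) {
      tx <- mis_taxon[locus]
      from <- clade_of[tx]
      to <- if (from == "ROBUST") "COMPLEX" else "ROBUST"
      groups[[from]] <- setdiff(groups[[from]], tx)
      groups[[to]] <- c(groups[[to]], tx)
      note("MISPLACED_TIP", locus, tx, sprintf("%s->%s", from, to))
    }

    if (locus %in% type2_loci) {
      dup <- c(sample(intersect(groups$ROBUST, scler), 2L),
               sample(intersect(groups$COMPLEX, scler), 1L))
      for (tx in dup) {
        groups[[clade_of[tx]]] <- setdiff(groups[[clade_of[tx]]], tx)
        seqs <- c(seqs, setNames(evolve_cds(cds[tx], 0.05),
                                 paste0(tx, ".0.0")),
                  setNames(evolve_cds(cds[tx], 0.05), paste0(tx, ".0.1")))
        seqs <- seqs[names(seqs) != tx]
      }
      dup_clades <- vapply(0:1, function(side) sprintf(
        "(%s)100:%g",
        paste(sprintf("%s.0.%d:%g", dup, side, pend), collapse = ","),
        0.15), character(1))
      groups$DUP <- dup_clades
      note("TYPE2_LOCUS", locus, NA, paste(dup, collapse = "|"))
    }

    clade_str <- vapply(names(groups), function(g) {
      members <- groups[[g]]
      if (!length(members)) return(NA_character_)
      if (g == "DUP") return(paste(members, collapse = ","))
      inner <- paste(ifelse(grepl("^\\(", members), members,
                            sprintf("%s:%g", members, pend)),
                     collapse = ",")
      if (length(members) == 1L) inner
      else sprintf("(%s)100:%g", inner, 0.1)
    }, character(1))
    clade_str <- clade_str[!is.na(clade_str)]
    nwk <- sprintf("(%s);", paste(clade_str, collapse = ","))
    writeLines(nwk, file.path(dir, "capture", "trees",
                              paste0(locus, ".nwk")))
    write_fasta(annotated_seqs(id = names(seqs), seq = unname(seqs),
                               kind = "NT"),
                file.path(dir, "capture", "loci", paste0(locus, ".fasta")))
  }

  # barcode references for every taxon, and per-sample contigs
  for (bc in c("coi", "h3")) {
    root <- random_nt(if (bc == "coi") 660L else 330L)
    refs <- setNames(vapply(taxa$taxon, function(tx)
      evolve_nt(root, 0.08), character(1)), taxa$taxon)
    write_fasta(annotated_seqs(id = sprintf("%s_%s", bc, taxa$taxon),
                               seq = unname(refs), taxon = taxa$taxon,
                               clade = taxa$clade, kind = "NT"),
                file.path(dir, "barcodes", paste0(bc, ".refs.fasta")))
    assign(paste0("refs_", bc), refs)
  }
  refs_coi <- get("refs_coi"); refs_h3 <- get("refs_h3")

  contam_sample <- sample(scler, 1L)
  contam_source <- sample(setdiff(scler, contam_sample), 1L)
  note("BARCODE_CONTAMINANT", NA, contam_sample,
       sprintf("source=%s;locus=COI;ratio=%g", contam_source,
               cfg$barcode_contam_ratio))

  sheet <- data.frame(sample_id = taxa$taxon, expected_taxon = taxa$taxon,
                      stringsAsFactors = FALSE)
  write.table(sheet, file.path(dir, "sample_sheet.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  for (tx in taxa$taxon) {
    ids <- c(sprintf("%s_coi", tx), sprintf("%s_h3", tx))
    seqs <- c(refs_coi[tx], refs_h3[tx])
    covs <- c(cfg$barcode_coverage, cfg$barcode_coverage)
    if (tx == contam_sample) {
      ids <- c(ids, sprintf("%s_coi_xcontam", tx))
      seqs <- c(seqs, refs_coi[contam_source])
      covs <- c(covs, cfg$barcode_coverage / cfg$barcode_contam_ratio)
    }
    write_fasta(annotated_seqs(id = ids, seq = unname(seqs), kind = "NT"),
                file.path(dir, "capture", "contigs", paste0(tx, ".fasta")))
    cov_df <- data.frame(contig_id = ids, coverage = covs)
    write.table(cov_df, file.path(dir, "capture", "coverage",
                                  paste0(tx, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  sim$truth <- truth
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(sim)
}

#' Materialize a complete fixture workspace
#'
#' Runs [simulate_orthogroups] and [simulate_capture] and writes a
#' ready-to-run `config.yaml` naming every produced file, so the whole
#' pipeline can be exercised from one call.
#'
#' @param cfg a [fixture_config].
#' @param dir workspace directory (created).
#' @return invisibly, the simulation object (with `truth` ledger).
#' @export
make_fixture_workspace <- function(cfg = fixture_config(), dir) {
  sim <- simulate_orthogroups(cfg, dir)
  sim <- simulate_capture(sim, cfg)
  config <- list(
    design = list(
      orthogroup_dir = file.path(dir, "orthogroups"),
      genome_dir = file.path(dir, "genomes"),
      contaminant_db = file.path(dir, "contaminant_db.fasta"),
      symbiont_db = file.path(dir, "symbionts.fasta"),
      barcode_refs = list(COI = file.path(dir, "barcodes", "coi.refs.fasta"),
                          H3 = file.path(dir, "barcodes", "h3.refs.fasta")),
      out_dir = file.path(dir, "design_out")),
    postcapture = list(
      genetree_dir = file.path(dir, "capture", "trees"),
      locus_seq_dir = file.path(dir, "capture", "loci"),
      contig_dir = file.path(dir, "capture", "contigs"),
      coverage_dir = file.path(dir, "capture", "coverage"),
      sample_sheet = file.path(dir, "sample_sheet.tsv"),
      barcode_refs = list(COI = file.path(dir, "barcodes", "coi.refs.fasta"),
                          H3 = file.path(dir, "barcodes", "h3.refs.fasta")),
      expected_clades = file.path(dir, "expected_clades.tsv"),
      out_dir = file.path(dir, "postcapture_out")))
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  invisible(sim)
}
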