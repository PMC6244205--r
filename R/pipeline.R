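# End-to-end analysis over a genome + gene models + annotations: the same
# stages the CLI and the synthetic-recovery tests run.

# intron positions of a model expressed in spliced-CDS coordinates: the
# number of CDS bases transcribed before each intron
intron_cds_positions <- function(model) {
  ex <- model$cds_exons
  if (nrow(ex) < 2L) return(integer(0))
  lens <- ex[, 2] - ex[, 1]
  if (model$strand == "-") lens <- rev(lens)
  cumsum(lens)[-length(lens)]
}

#' Assemble nsLTP records from a genome
#'
#' Runs extraction, 8CM scanning, maturation, type classification and
#' physicochemical profiling over a set of gene models, producing one row
#' per candidate (the family table). Candidates without an 8CM are
#' dropped; candidates with several non-overlapping 8CMs are kept but
#' flagged deferred (type `unassigned`). Candidates missing from the
#' annotation table fall back to [heuristic_maturation()].
#'
#' @param genome named character vector of chromosome sequences.
#' @param models list of [gene_model()].
#' @param annotations data frame (protein_id, signal_cleavage, gpi_omega,
#'   source) or NULL to force the heuristic fallback.
#' @param bounds [gap_bounds()] used by the scanner.
#' @param identity_override rule-4 threshold of [classify_type()].
#' @param deny_list optional ids to exclude.
#' @return list: `records` (data frame), `matches` (8CM match table),
#'   `proteins`, `mature`, `cds` (named character vectors).
#' @export
build_ltp_records <- function(genome, models, annotations = NULL,
                              bounds = gap_bounds(),
                              identity_override = 0.60,
                              deny_list = character(0)) {
  if (length(deny_list) > 0L) {
    keep <- apply_deny_list(vapply(models, `[[`, character(1),
                                   "gene_id"), deny_list)
    models <- models[keep]
  }
  ann_row <- function(id) {
    if (!is.null(annotations) && id %in% annotations$protein_id) {
      r <- annotations[annotations$protein_id == id, ]
      maturation_annotation(id, r$signal_cleavage[1], r$gpi_omega[1],
                            source = "external_table")
    } else NULL
  }
  cds <- character(0); proteins <- character(0); mature <- character(0)
  rows <- list(); match_rows <- list()
  anns <- list()
  for (model in models) {
    id <- model$gene_id
    cd <- extract_spliced_cds(model, genome)
    prot <- translate_dna(cd)
    prot <- sub("\\*$", "", prot)
    if (grepl("\\*", prot)) {
      warning(sprintf("excluding %s: internal stop codon", id))
      next
    }
    mm <- scan_eight_cm(prot, bounds, id = id)
    if (nrow(mm) == 0L) next  # hit lacking the essential cysteines
    ann <- ann_row(id)
    if (is.null(ann))
      ann <- heuristic_maturation(prot, mm$c1[1], protein_id = id)
    mat <- derive_mature_protein(prot, ann)
    cds[id] <- cd; proteins[id] <- prot; mature[id] <- mat
    anns[[id]] <- ann
    match_rows[[id]] <- mm
    rows[[id]] <- list(model = model, ann = ann, match = mm)
  }
  # reference type 2 set: intronless, non-GPI members (used by rule 4)
  ref_type2 <- character(0)
  for (id in names(rows)) {
    r <- rows[[id]]
    if (r$ann$gpi_omega == 0L &&
        length(intron_cds_positions(r$model)) == 0L)
      ref_type2 <- c(ref_type2, mature[[id]])
  }
  out <- list()
  for (id in names(rows)) {
    r <- rows[[id]]
    mm <- r$match
    m1 <- mm[1L, ]
    c8_end_nt <- 3L * (m1$c8 + 1L)
    offsets <- intron_cds_positions(r$model) - c8_end_nt
    type <- classify_type(
      gpi = r$ann$gpi_omega > 0L, intron_offsets = offsets,
      mature_sequence = mature[[id]], ref_type2 = ref_type2,
      identity_override = identity_override,
      motif_span_nt = 3L * (m1$c8 - m1$c1 + 1L),
      n_matches = nrow(mm))
    cl <- r$ann$signal_cleavage
    c1_mature0 <- m1$c1 - cl  # C1 position within the mature protein
    out[[id]] <- data.frame(
      gene_id = id, type = as.character(type),
      deferred = isTRUE(attr(type, "deferred")),
      gpi = r$ann$gpi_omega > 0L,
      maturation_source = r$ann$source,
      n_introns = length(offsets),
      intron_offsets = paste(offsets, collapse = ","),
      g1 = m1$g1, g2 = m1$g2, g3 = m1$g3, g4 = m1$g4, g5 = m1$g5,
      cxc_x = m1$cxc_x,
      hyprp = flag_hyprp(mature[[id]], max(c1_mature0, 0L)),
      mature = mature[[id]],
      mw_da = molecular_weight(mature[[id]]),
      pi = isoelectric_point(mature[[id]]),
      chrom = r$model$chrom, start = r$model$start,
      end = r$model$end, strand = r$model$strand,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, out)
  if (!is.null(records)) rownames(records) <- NULL
  list(records = records,
       matches = do.call(rbind, match_rows),
       proteins = proteins, mature = mature, cds = cds)
}

#' Run the full nsLTP pipeline on a synthetic genome
#'
#' Generates a genome from `config`, then runs the analysis stages:
#' scan + classify + physchem (`"records"`), homology/tandem/Ka-Ks
#' (`"duplication"`), UPGMA phylogeny (`"tree"`), expression clustering and
#' enrichment calls (`"expression"`), and promoter enrichment
#' (`"promoter"`). Results are returned together with the generator truth
#' and a run manifest; `out_dir` additionally writes the stage TSVs.
#'
#' @param config a [generator_config()].
#' @param stages subset of stages to run (records always runs).
#' @param k_clusters expression cluster count.
#' @param out_dir optional output directory.
#' @return list with the stage results, `truth` and `manifest`.
#' @export
run_ltp_pipeline <- function(config = generator_config(),
                             stages = c("duplication", "tree",
                                        "expression", "promoter"),
                             k_clusters = 10L, out_dir = NULL) {
  gen <- generate_genome(config)
  built <- build_ltp_records(gen$genome, gen$models, gen$annotations)
  res <- list(records = built$records, matches = built$matches,
              mature = built$mature, cds = built$cds,
              summary = summarize_family(built$records),
              truth = gen$truth)
  gene_tbl <- built$records[, c("gene_id", "chrom", "start")]
  if ("duplication" %in% stages) {
    hk <- homology_kaks_table(built$cds)
    hom <- hk$pairs[hk$pairs$homologous, , drop = FALSE]
    res$pairs <- hk$pairs
    res$kaks <- hk$kaks
    res$clusters <- find_tandem_clusters(gene_tbl, hom)
  }
  if ("tree" %in% stages) {
    dm <- pairwise_distance_matrix(built$mature)
    res$tree <- upgma(dm)
    res$newick <- tree_newick(res$tree)
  }
  if ("expression" %in% stages) {
    ex <- generate_expression_matrix(config$expression_spec,
                                     seed = config$seed + 1L,
                                     gene_ids = built$records$gene_id)
    lg <- log_transform(ex$fpkm)
    k <- min(k_clusters, max(2L, nrow(lg) - 1L))
    res$expression <- list(
      fpkm = ex$fpkm, sample_map = ex$sample_map, truth = ex$truth,
      clusters = hierarchical_cluster_genes(lg, k = k),
      enrichment = call_tissue_enriched(ex$fpkm, ex$sample_map),
      not_expressed = call_not_expressed(ex$fpkm))
  }
  if ("promoter" %in% stages) {
    pr <- generate_promoter_sets(config$promoter_spec,
                                 seed = config$seed + 2L)
    planted <- known_motif(
      if (config$promoter_spec$motif == "AGAAA") "POLLEN1LELAT52"
      else "planted_box", config$promoter_spec$motif)
    res$promoter <- list(
      sets = pr,
      known = ranksum_known_motif(pr$pos, pr$neg, planted),
      discovered = discover_motifs(pr$pos, pr$neg))
  }
  res$manifest <- list(
    package = "ltpscan",
    version = as.character(utils::packageVersion("ltpscan")),
    seed = config$seed, n_ltp_genes = config$n_ltp_genes,
    n_chromosomes = config$n_chromosomes,
    chrom_length_bp = config$chrom_length_bp,
    stages = c("records", stages),
    transcript_rule = "longest CDS per gene (single-mRNA models here)")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    if (!is.null(df))
      write.table(df, file.path(out_dir, name), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }
  w(res$records, "family.tsv")
  w(res$summary, "summary.tsv")
  w(res$matches, "matches.tsv")
  w(res$pairs, "pairs.tsv")
  w(res$kaks, "kaks.tsv")
  if (!is.null(res$clusters)) {
    cl <- do.call(rbind, lapply(seq_along(res$clusters), function(i) {
      data.frame(cluster = i, chrom = res$clusters[[i]]$chrom,
                 gene_id = res$clusters[[i]]$members,
                 stringsAsFactors = FALSE)
    }))
    w(cl, "tandem_clusters.tsv")
  }
  if (!is.null(res$newick))
    writeLines(res$newick, file.path(out_dir, "tree.nwk"))
  if (!is.null(res$expression)) {
    w(data.frame(gene = names(res$expression$clusters$assignment),
                 cluster = res$expression$clusters$assignment),
      "expression_clusters.tsv")
    w(res$expression$enrichment, "enrichment.tsv")
  }
  if (!is.null(res$promoter)) {
    w(res$promoter$known, "promoter_known.tsv")
    w(res$promoter$discovered$motifs, "promoter_discovered.tsv")
  }
  manifest <- vapply(res$manifest, function(x) paste(x, collapse = ","),
                     character(1))
  writeLines(paste(names(manifest), manifest, sep = "\t"),
             file.path(out_dir, "manifest.tsv"))
  invisible(out_dir)
}
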