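# Synthetic genomes, expression matrices and promoter sets with recorded
# ground truth, so every downstream stage is testable without downloads.

# Printed per-type spacing sets for the five variable gaps (type C, e.g.,
# is CX9 CX14,19 CC X9 CXC X12 CX6).
table2_gap_sets <- function() {
  list(
    type1 = list(g1 = 9L, g2 = c(13:15, 19L), g3 = 19:21, g4 = 20:24,
                 g5 = c(7L, 13L, 14L, 15L)),
    type2 = list(g1 = c(3L, 5L, 7L, 8:10, 17L),
                 g2 = c(11L, 12:19, 21L, 27L),
                 g3 = c(8:13, 19L),
                 g4 = c(8L, 10L, 15L, 18L, 19L, 21:27, 36L),
                 g5 = c(3:9, 11L, 13L, 15L, 16L, 17L)),
    typeC = list(g1 = 9L, g2 = c(14L, 19L), g3 = 9L, g4 = 12L, g5 = 6L),
    typeD = list(g1 = c(9L, 10L, 12L, 13L, 14L), g2 = c(14L, 16:18),
                 g3 = 9:12, g4 = c(11L, 17L, 23L, 24L, 27L),
                 g5 = c(4L, 7L, 9L, 10L, 11L, 20L)),
    typeG = list(g1 = c(6L, 9L, 10L, 12L), g2 = c(8L, 13:18, 20L),
                 g3 = c(12L, 14L, 19L), g4 = c(21:26, 29L),
                 g5 = c(5L, 6L, 8:10, 13L, 20L)))
}

# fixed 25-residue hydrophobic signal-peptide stub (external-predictor
# stand-in; the cleavage site is recorded in the annotation table)
SIGNAL_STUB <- "MARLAAVLLVAGLLAAPSALAAVLA"

CYS_FREE_POOL <- setdiff(AA20, "C")

# synonymous codons per residue, excluding TGT so that planted cysteines
# are always TGC and background never spells a cysteine codon in frame
codon_choices <- function() {
  tab <- codon_table()
  split(names(tab)[tab != "*"], tab[tab != "*"])
}

sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

# random DNA; unless allow_cys, no cysteine codon (TGT/TGC) appears as a
# substring on either strand (forbidden trigrams TGT, TGC, ACA, GCA)
random_background_dna <- function(n, gc = 0.45, allow_cys = FALSE) {
  if (n <= 0L) return("")
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  v <- sample(names(probs), n, replace = TRUE, prob = probs)
  if (!allow_cys && n >= 3L) {
    forbidden <- c("TGT", "TGC", "ACA", "GCA")
    for (iter in 1:100) {
      tri <- paste0(v[1:(n - 2L)], v[2:(n - 1L)], v[3:n])
      bad <- which(tri %in% forbidden)
      if (length(bad) == 0L) break
      v[bad + 1L] <- sample(names(probs), length(bad), replace = TRUE,
                            prob = probs)
    }
  }
  paste(v, collapse = "")
}

reverse_translate <- function(protein, choices = codon_choices()) {
  chars <- seq_chars(protein)
  paste(vapply(chars, function(aa) {
    if (aa == "C") return("TGC")
    sample1(setdiff(choices[[aa]], c("TGT")))
  }, character(1)), collapse = "")
}

random_intron <- function(len = NULL) {
  if (is.null(len)) len <- sample(60:120, 1L)
  paste0("GT", random_background_dna(len - 4L), "AG")
}

#' Generator configuration
#'
#' Bundles every knob of the synthetic genome generator. The default type
#' mix equals the wheat family composition (39:274:5:57:86 over types
#' 1, 2, C, D, G); three tandem arrays of type 2 genes with controlled
#' synonymous/non-synonymous divergence are planted by default.
#'
#' @param seed master seed; every generated artefact is a pure function of
#'   (config, seed).
#' @param n_chromosomes,chrom_length_bp genome shape.
#' @param n_ltp_genes total family size, tandem-array members included.
#' @param type_mix named proportions over
#'   `type1,type2,typeC,typeD,typeG`; must sum to 1 (tolerance 1e-9).
#' @param tandem_array_spec list of `list(chrom=, size=, syn=, nonsyn=)`
#'   entries; each array's members derive from its seed CDS via
#'   [mutate_cds_controlled()].
#' @param gc background GC content.
#' @param allow_background_cysteines re-enable cysteine codons in
#'   intergenic/filler background (spurious-motif stress mode).
#' @param expression_spec see [expression_config()].
#' @param promoter_spec see [promoter_config()].
#' @return object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_chromosomes = 3L,
                             chrom_length_bp = 100000L,
                             n_ltp_genes = 50L,
                             type_mix = c(type1 = 39, type2 = 274,
                                          typeC = 5, typeD = 57,
                                          typeG = 86) / 461,
                             tandem_array_spec = list(
                               list(chrom = "chr1", size = 3L, syn = 4L,
                                    nonsyn = 2L),
                               list(chrom = "chr2", size = 3L, syn = 2L,
                                    nonsyn = 1L),
                               list(chrom = "chr3", size = 4L, syn = 6L,
                                    nonsyn = 3L)),
                             gc = 0.45,
                             allow_background_cysteines = FALSE,
                             expression_spec = expression_config(),
                             promoter_spec = promoter_config()) {
  stopifnot(abs(sum(type_mix) - 1) <= 1e-9,
            all(sort(names(type_mix)) ==
                  c("type1", "type2", "typeC", "typeD", "typeG")))
  for (a in tandem_array_spec) {
    stopifnot(a$size >= 2L, a$syn >= 0L, a$nonsyn >= 0L,
              a$chrom %in% paste0("chr", seq_len(n_chromosomes)))
  }
  n_array_genes <- sum(vapply(tandem_array_spec, `[[`, numeric(1),
                              "size"))
  if (n_array_genes > n_ltp_genes)
    stop("tandem arrays alone exceed n_ltp_genes")
  structure(list(seed = as.integer(seed),
                 n_chromosomes = as.integer(n_chromosomes),
                 chrom_length_bp = as.integer(chrom_length_bp),
                 n_ltp_genes = as.integer(n_ltp_genes),
                 type_mix = type_mix,
                 tandem_array_spec = tandem_array_spec, gc = gc,
                 allow_background_cysteines = allow_background_cysteines,
                 expression_spec = expression_spec,
                 promoter_spec = promoter_spec),
            class = "generator_config")
}

#' Expression generator configuration
#'
#' FPKM draws are log-normal: a simple heavy-tailed stand-in for RNA-seq
#' abundance. Anther-enriched genes get a high anther mean and a low mean
#' everywhere else; background genes share one gene-level mean across all
#' tissues (exchangeable); a stated fraction is all-zero.
#'
#' @param tissues tissue labels; must contain `"anther"`.
#' @param n_reps samples (stages) per tissue.
#' @param n_genes number of genes (overridden by the pipeline with the
#'   actual family size).
#' @param frac_enriched,frac_not_expressed planted fractions.
#' @param base_meanlog,base_sdlog gene-level log-normal location spread of
#'   background genes.
#' @param noise_sdlog per-sample log-normal noise.
#' @param enriched_anther_meanlog,enriched_other_meanlog,enriched_sdlog
#'   planted anther-enriched profile parameters.
#' @return list of class `expression_config`.
#' @export
expression_config <- function(tissues = c("leaf", "root", "stem", "spike",
                                          "grain", "pistil", "anther"),
                              n_reps = 3L, n_genes = 50L,
                              frac_enriched = 17 / 461,
                              frac_not_expressed = 30 / 461,
                              base_meanlog = log(8), base_sdlog = 1,
                              noise_sdlog = 0.8,
                              enriched_anther_meanlog = log(100),
                              enriched_other_meanlog = 0,
                              enriched_sdlog = 0.4) {
  if (!("anther" %in% tissues))
    stop("tissue labels must include 'anther'")
  if (length(tissues) < 2L) stop("need at least 2 tissues")
  structure(as.list(environment()), class = "expression_config")
}

#' Promoter generator configuration
#'
#' @param motif planted motif (ACGT only).
#' @param n_pos,n_neg set sizes.
#' @param length promoter length in bp.
#' @param pos_freq,neg_freq per-sequence planting probabilities.
#' @param gc background GC content.
#' @return list of class `promoter_config`.
#' @export
promoter_config <- function(motif = "AGAAA", n_pos = 17L, n_neg = 100L,
                            length = 1000L, pos_freq = 0.9,
                            neg_freq = 0.1, gc = 0.5) {
  if (nchar(motif) < 4L) stop("planted motif must have length >= 4")
  if (grepl("[^ACGT]", toupper(motif)))
    stop("planted motif must contain only A, C, G, T")
  stopifnot(pos_freq >= 0, pos_freq <= 1, neg_freq >= 0, neg_freq <= 1)
  structure(list(motif = toupper(motif), n_pos = as.integer(n_pos),
                 n_neg = as.integer(n_neg), length = as.integer(length),
                 pos_freq = pos_freq, neg_freq = neg_freq, gc = gc),
            class = "promoter_config")
}

#' Generate one nsLTP gene with known truth
#'
#' Emits a gene locus whose encoded protein carries a 25-residue signal
#' stub, an 8CM with exactly the requested gaps, and the type-diagnostic
#' gene structure: type 2 intronless; types 1, C and D one intron 5, 1 and
#' 4 nt after the last 8CM cysteine codon; type G a GPI omega-site
#' annotation and 0-4 introns. All non-cysteine positions come from a
#' cysteine-free residue pool, so the planted motif is the only one.
#'
#' @param type one of `type1,type2,typeC,typeD,typeG` (or `1,2,C,D,G`).
#' @param gaps five integers (g1..g5) within the type's printed spacing
#'   sets; `NULL` draws them at random from those sets.
#' @param seed RNG seed; same seed, same bytes.
#' @param gene_id identifier used in the model/annotation/truth.
#' @return list: `model` (a [gene_model()] in locus coordinates),
#'   `locus_dna`, `annotation` (a [maturation_annotation()]), and `truth`
#'   (type, gaps, 0-based cysteine positions, protein, mature, cds,
#'   intron offsets, ...).
#' @export
generate_ltp_gene <- function(type, gaps = NULL, seed = 1L,
                              gene_id = "LTPsim001") {
  type <- as.character(type)
  alias <- c(`1` = "type1", `2` = "type2", C = "typeC", D = "typeD",
             G = "typeG")
  if (type %in% names(alias)) type <- alias[[type]]
  sets <- table2_gap_sets()
  if (!(type %in% names(sets))) stop(sprintf("unknown type '%s'", type))
  with_seed(seed, {
    tset <- sets[[type]]
    if (is.null(gaps))
      gaps <- vapply(tset, sample1, integer(1))
    gaps <- as.integer(gaps)
    stopifnot(length(gaps) == 5L)
    for (g in 1:5) {
      if (!(gaps[g] %in% tset[[g]]))
        stop(sprintf(
          "gap g%d = %d outside the printed spacing set for %s (%s)",
          g, gaps[g], type, paste(tset[[g]], collapse = ",")))
    }
    draw <- function(n) paste(sample(CYS_FREE_POOL, n, replace = TRUE),
                              collapse = "")
    motif <- paste0("C", draw(gaps[1]), "C", draw(gaps[2]), "CC",
                    draw(gaps[3]), "C", draw(1L), "C", draw(gaps[4]),
                    "C", draw(gaps[5]), "C")
    nterm <- draw(8L)
    gpi_omega <- 0L
    tail_aa <- if (type == "typeG") {
      pre_omega <- draw(10L)
      propep <- paste(sample(c("A", "L", "V", "G", "S"), 18L,
                             replace = TRUE), collapse = "")
      gpi_omega <- nchar(SIGNAL_STUB) + nchar(nterm) + nchar(motif) +
        nchar(pre_omega) + 1L  # the omega residue itself
      paste0(pre_omega, "G", propep)  # omega site is a glycine
    } else draw(12L)
    protein <- paste0(SIGNAL_STUB, nterm, motif, tail_aa)
    cds <- paste0(reverse_translate(protein), "TAA")

    cys0 <- which(seq_chars(protein) == "C") - 1L
    c8 <- cys0[length(cys0)]
    c8_codon_end <- 3L * (c8 + 1L)  # nt index of last base of C8 codon

    cut_points <- switch(type,
      type1 = c8_codon_end + 5L,
      typeC = c8_codon_end + 1L,
      typeD = c8_codon_end + 4L,
      type2 = integer(0),
      typeG = {
        k <- sample(0:4, 1L)
        if (k == 0L) integer(0) else {
          cand <- setdiff(seq(12L, nchar(cds) - 12L, by = 3L),
                          c8_codon_end + c(1L, 4L, 5L))
          sort(sample(cand, min(k, length(cand))))
        }
      })
    intron_offsets <- cut_points - c8_codon_end
    introns <- vapply(seq_along(cut_points), function(i) random_intron(),
                      character(1))

    flank5 <- random_background_dna(30L)
    flank3 <- random_background_dna(30L)
    pieces <- character(0)
    prev <- 0L
    exon_bounds <- list()
    offset <- nchar(flank5)
    pos <- offset
    for (i in seq_along(cut_points)) {
      exon_seq <- substr(cds, prev + 1L, cut_points[i])
      pieces <- c(pieces, exon_seq, introns[i])
      exon_bounds[[i]] <- c(pos, pos + nchar(exon_seq))
      pos <- pos + nchar(exon_seq) + nchar(introns[i])
      prev <- cut_points[i]
    }
    last_exon <- substr(cds, prev + 1L, nchar(cds))
    pieces <- c(pieces, last_exon)
    exon_bounds[[length(exon_bounds) + 1L]] <- c(pos, pos +
                                                   nchar(last_exon))
    locus <- paste0(flank5, paste(pieces, collapse = ""), flank3)
    exons <- do.call(rbind, exon_bounds)

    model <- gene_model(gene_id, chrom = gene_id, strand = "+",
                        exons = exons)
    annotation <- maturation_annotation(
      gene_id, signal_cleavage = nchar(SIGNAL_STUB),
      gpi_omega = gpi_omega, source = "external_table")
    mature <- derive_mature_protein(protein, annotation)
    list(model = model, locus_dna = locus, annotation = annotation,
         truth = list(gene_id = gene_id, type = type, gaps = gaps,
                      cys_positions = cys0, protein = protein,
                      mature = mature, cds = cds,
                      intron_offsets = intron_offsets,
                      signal_cleavage = nchar(SIGNAL_STUB),
                      gpi_omega = gpi_omega))
  })
}

#' Controlled mutation of a CDS
#'
#' Applies exactly `syn_changes` single-nucleotide substitutions that
#' preserve the encoded residue and exactly `nonsyn_changes` that alter
#' it, at distinct codons, never creating a stop codon and never touching
#' a protected codon. By default non-synonymous changes may not create a
#' cysteine either, so planted 8CMs stay the only motif instances.
#'
#' @param cds CDS string (length divisible by 3, no internal stops).
#' @param syn_changes,nonsyn_changes change counts.
#' @param seed RNG seed.
#' @param protected_codons 1-based codon indices that must not change
#'   (e.g. the 8CM cysteine codons).
#' @param forbid_new_residues residues a non-synonymous change may not
#'   create.
#' @return mutated CDS string of identical length.
#' @export
mutate_cds_controlled <- function(cds, syn_changes, nonsyn_changes,
                                  seed = 1L,
                                  protected_codons = integer(0),
                                  forbid_new_residues = "C") {
  s <- as_residues(cds, "dna")
  stopifnot(nchar(s) %% 3L == 0L)
  n <- nchar(s) %/% 3L
  codons <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  tab <- codon_table()
  bases <- c("A", "C", "G", "T")
  options_for <- function(codon, kind) {
    aa <- tab[[codon]]
    if (aa == "*") return(list())
    out <- list()
    chars <- seq_chars(codon)
    for (p in 1:3) for (nt in setdiff(bases, chars[p])) {
      mut <- chars
      mut[p] <- nt
      mcod <- paste(mut, collapse = "")
      maa <- tab[[mcod]]
      if (maa == "*") next
      ok <- if (kind == "syn") maa == aa
            else maa != aa && !(maa %in% forbid_new_residues)
      if (ok) out[[length(out) + 1L]] <- mcod
    }
    out
  }
  with_seed(seed, {
    eligible <- setdiff(seq_len(n), protected_codons)
    syn_ok <- eligible[vapply(eligible, function(i) {
      length(options_for(codons[i], "syn")) > 0L
    }, logical(1))]
    non_ok <- eligible[vapply(eligible, function(i) {
      length(options_for(codons[i], "nonsyn")) > 0L
    }, logical(1))]
    if (length(syn_ok) < syn_changes)
      stop(sprintf(
        "insufficient eligible codons: %d synonymous change(s) requested, only %d codon(s) available",
        syn_changes, length(syn_ok)))
    syn_pick <- if (syn_changes > 0L) sample(syn_ok, syn_changes)
                else integer(0)
    non_avail <- setdiff(non_ok, syn_pick)
    if (length(non_avail) < nonsyn_changes)
      stop(sprintf(
        "insufficient eligible codons: %d non-synonymous change(s) requested, only %d codon(s) available",
        nonsyn_changes, length(non_avail)))
    non_pick <- if (nonsyn_changes > 0L) sample(non_avail, nonsyn_changes)
                else integer(0)
    for (i in syn_pick)
      codons[i] <- sample1(unlist(options_for(codons[i], "syn")))
    for (i in non_pick)
      codons[i] <- sample1(unlist(options_for(codons[i], "nonsyn")))
    paste(codons, collapse = "")
  })
}

place_on_chromosome <- function(model, locus_len, offset, strand,
                                chrom) {
  ex <- model$exons
  if (strand == "-") {
    ex <- cbind(offset + locus_len - ex[, 2],
                offset + locus_len - ex[, 1])
  } else {
    ex <- ex + offset
  }
  gene_model(model$gene_id, chrom = chrom, strand = strand, exons = ex)
}

#' Generate a synthetic genome with planted nsLTP genes
#'
#' Places `n_ltp_genes` genes non-overlapping across the configured
#' chromosomes: the tandem arrays first (adjacent intronless type 2 genes
#' on one chromosome, each member derived from the array seed CDS by
#' [mutate_cds_controlled()]), then singleton genes with types drawn from
#' `type_mix` and random strands. Intergenic background is random
#' cysteine-codon-free DNA at the configured GC.
#'
#' @param config a [generator_config()].
#' @return list of class `synthetic_genome`: `genome` (named chromosome
#'   sequences), `models` (list of [gene_model()]), `annotations` (data
#'   frame: protein_id, signal_cleavage, gpi_omega, source), `gff3`
#'   (character lines) and `truth` (list: `genes` data frame with
#'   type/gaps/positions/sequences per gene, `clusters` tandem truth,
#'   `pairs` applied (syn, nonsyn) per array pair).
#' @export
generate_genome <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    n_array_genes <- sum(vapply(config$tandem_array_spec, `[[`,
                                numeric(1), "size"))
    n_single <- config$n_ltp_genes - n_array_genes
    gene_no <- 0L
    next_id <- function() {
      gene_no <<- gene_no + 1L
      sprintf("LTPsim%03d", gene_no)
    }
    # per-chromosome queues of gene entries
    queue <- setNames(vector("list", length(chroms)), chroms)
    truth_rows <- list()
    pair_rows <- list()
    cluster_truth <- list()

    add_entry <- function(chrom, entry) {
      queue[[chrom]][[length(queue[[chrom]]) + 1L]] <<- entry
    }
    gene_entry <- function(gen, strand) {
      list(gen = gen, strand = strand, len = nchar(gen$locus_dna))
    }

    # tandem arrays: adjacent, plus strand, intronless type 2
    for (ai in seq_along(config$tandem_array_spec)) {
      spec <- config$tandem_array_spec[[ai]]
      seed_id <- next_id()
      seed_gene <- generate_ltp_gene("type2", seed = sample.int(2^30, 1L),
                                     gene_id = seed_id)
      members <- list(seed_gene)
      cys_codons <- seed_gene$truth$cys_positions + 1L  # aa = codon index
      for (m in 2:spec$size) {
        mid <- next_id()
        mcds <- mutate_cds_controlled(
          seed_gene$truth$cds, spec$syn, spec$nonsyn,
          seed = sample.int(2^30, 1L), protected_codons = cys_codons)
        mgene <- rebuild_intronless_gene(seed_gene, mcds, mid)
        members[[m]] <- mgene
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          gene_a = seed_id, gene_b = mid, syn = spec$syn,
          nonsyn = spec$nonsyn, stringsAsFactors = FALSE)
      }
      for (m in members) add_entry(spec$chrom, gene_entry(m, "+"))
      cluster_truth[[ai]] <- list(
        chrom = spec$chrom,
        members = vapply(members, function(m) m$truth$gene_id,
                         character(1)))
    }
    # singleton genes, round-robin over chromosomes, random strand
    if (n_single > 0L) {
      types <- sample(names(config$type_mix), n_single, replace = TRUE,
                      prob = config$type_mix)
      for (i in seq_len(n_single)) {
        gid <- next_id()
        gen <- generate_ltp_gene(types[i], seed = sample.int(2^30, 1L),
                                 gene_id = gid)
        strand <- sample(c("+", "-"), 1L)
        add_entry(chroms[1L + (i - 1L) %% length(chroms)],
                  gene_entry(gen, strand))
      }
    }
    # assemble chromosomes
    genome <- setNames(character(length(chroms)), chroms)
    models <- list()
    for (ch in chroms) {
      entries <- queue[[ch]]
      spacers <- vapply(seq_len(length(entries) + 1L), function(i) {
        random_background_dna(sample(150:400, 1L), gc = config$gc,
                              allow_cys = config$allow_background_cysteines)
      }, character(1))
      used <- sum(vapply(entries, `[[`, numeric(1), "len")) +
        sum(nchar(spacers))
      if (used > config$chrom_length_bp)
        stop(sprintf(
          "genes do not fit: %s needs %d bp but chrom_length_bp is %d",
          ch, used, config$chrom_length_bp))
      pieces <- character(0)
      pos <- 0L
      for (i in seq_along(entries)) {
        pieces <- c(pieces, spacers[i])
        pos <- pos + nchar(spacers[i])
        e <- entries[[i]]
        locus <- if (e$strand == "-") revcomp(e$gen$locus_dna)
                 else e$gen$locus_dna
        pieces <- c(pieces, locus)
        model <- place_on_chromosome(e$gen$model, e$len, pos, e$strand,
                                     ch)
        models[[model$gene_id]] <- model
        tr <- e$gen$truth
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          gene_id = tr$gene_id, type = tr$type, chrom = ch,
          start = model$start, end = model$end, strand = e$strand,
          g1 = tr$gaps[1], g2 = tr$gaps[2], g3 = tr$gaps[3],
          g4 = tr$gaps[4], g5 = tr$gaps[5],
          signal_cleavage = tr$signal_cleavage,
          gpi_omega = tr$gpi_omega,
          n_introns = length(tr$intron_offsets),
          protein = tr$protein, mature = tr$mature, cds = tr$cds,
          stringsAsFactors = FALSE)
        pos <- pos + e$len
      }
      pieces <- c(pieces, spacers[length(spacers)])
      tail_n <- config$chrom_length_bp - pos -
        nchar(spacers[length(spacers)])
      pieces <- c(pieces, random_background_dna(
        tail_n, gc = config$gc,
        allow_cys = config$allow_background_cysteines))
      genome[[ch]] <- paste(pieces, collapse = "")
    }
    genes_truth <- do.call(rbind, truth_rows)
    genes_truth <- genes_truth[order(genes_truth$chrom,
                                     genes_truth$start), ]
    rownames(genes_truth) <- NULL
    models <- models[genes_truth$gene_id]
    annotations <- data.frame(
      protein_id = genes_truth$gene_id,
      signal_cleavage = genes_truth$signal_cleavage,
      gpi_omega = genes_truth$gpi_omega,
      source = "external_table", stringsAsFactors = FALSE)
    structure(list(
      genome = genome, models = models, annotations = annotations,
      gff3 = write_gff3_gene_models(models),
      truth = list(genes = genes_truth, clusters = cluster_truth,
                   pairs = do.call(rbind, pair_rows) %||%
                     data.frame(gene_a = character(0),
                                gene_b = character(0),
                                syn = integer(0), nonsyn = integer(0)))),
      class = "synthetic_genome")
  })
}

# rebuild an intronless gene around a mutated CDS, keeping the seed
# gene's annotation geometry
rebuild_intronless_gene <- function(seed_gene, cds, gene_id) {
  protein <- sub("\\*$", "", translate_dna(cds))
  flank5 <- random_background_dna(30L)
  flank3 <- random_background_dna(30L)
  locus <- paste0(flank5, cds, flank3)
  model <- gene_model(gene_id, chrom = gene_id, strand = "+",
                      exons = cbind(nchar(flank5),
                                    nchar(flank5) + nchar(cds)))
  annotation <- maturation_annotation(
    gene_id, signal_cleavage = seed_gene$annotation$signal_cleavage,
    gpi_omega = 0L, source = "external_table")
  truth <- seed_gene$truth
  truth$gene_id <- gene_id
  truth$protein <- protein
  truth$cds <- cds
  truth$mature <- derive_mature_protein(protein, annotation)
  truth$cys_positions <- which(seq_chars(protein) == "C") - 1L
  list(model = model, locus_dna = locus, annotation = annotation,
       truth = truth)
}

#' Generate a tissue x gene FPKM matrix with planted truth
#'
#' @param config an [expression_config()].
#' @param seed RNG seed.
#' @param gene_ids optional gene names (defaults to `gene001`...).
#' @return list: `fpkm` (genes x samples matrix), `sample_map` (sample,
#'   tissue, stage) and `truth` (gene, anther_enriched, not_expressed).
#' @export
generate_expression_matrix <- function(config = expression_config(),
                                       seed = 1L, gene_ids = NULL) {
  stopifnot(inherits(config, "expression_config"))
  with_seed(seed, {
    n <- if (is.null(gene_ids)) config$n_genes else length(gene_ids)
    if (is.null(gene_ids)) gene_ids <- sprintf("gene%03d", seq_len(n))
    samples <- as.vector(t(outer(config$tissues,
                                 seq_len(config$n_reps),
                                 function(tt, r) paste0(tt, "_S", r))))
    sample_map <- data.frame(
      sample = samples,
      tissue = rep(config$tissues, each = config$n_reps),
      stage = paste0("S", rep(seq_len(config$n_reps),
                              times = length(config$tissues))),
      stringsAsFactors = FALSE)
    n_enr <- round(config$frac_enriched * n)
    n_null <- round(config$frac_not_expressed * n)
    status <- rep("background", n)
    picks <- sample(n, n_enr + n_null)
    status[picks[seq_len(n_enr)]] <- "enriched"
    if (n_null > 0L) status[picks[n_enr + seq_len(n_null)]] <- "null"
    mat <- matrix(0, nrow = n, ncol = length(samples),
                  dimnames = list(gene_ids, samples))
    anther_cols <- sample_map$tissue == "anther"
    for (i in seq_len(n)) {
      if (status[i] == "null") next
      if (status[i] == "enriched") {
        mat[i, anther_cols] <- rlnorm(sum(anther_cols),
                                      config$enriched_anther_meanlog,
                                      config$enriched_sdlog)
        mat[i, !anther_cols] <- rlnorm(sum(!anther_cols),
                                       config$enriched_other_meanlog,
                                       config$enriched_sdlog)
      } else {
        mu <- rnorm(1, config$base_meanlog, config$base_sdlog)
        mat[i, ] <- rlnorm(length(samples), mu, config$noise_sdlog)
      }
    }
    list(fpkm = mat, sample_map = sample_map,
         truth = data.frame(gene = gene_ids,
                            anther_enriched = status == "enriched",
                            not_expressed = status == "null",
                            stringsAsFactors = FALSE))
  })
}

#' Generate positive/negative promoter sets with planted motif
#'
#' Positive and negative promoters are i.i.d. background DNA; with the
#' configured per-set frequency a single motif occurrence is planted at a
#' random position (overwriting the background). Placements are recorded.
#'
#' @param config a [promoter_config()].
#' @param seed RNG seed.
#' @return list: `pos`, `neg` (named character vectors) and `placements`
#'   (data frame: set, seq_id, position (0-based), motif).
#' @export
generate_promoter_sets <- function(config = promoter_config(),
                                   seed = 1L) {
  stopifnot(inherits(config, "promoter_config"))
  with_seed(seed, {
    k <- nchar(config$motif)
    make_set <- function(n, freq, prefix) {
      seqs <- character(n)
      rows <- list()
      for (i in seq_len(n)) {
        s <- random_background_dna(config$length, gc = config$gc,
                                   allow_cys = TRUE)
        if (runif(1) < freq) {
          at <- sample.int(config$length - k + 1L, 1L)
          substr(s, at, at + k - 1L) <- config$motif
          rows[[length(rows) + 1L]] <- data.frame(
            set = prefix, seq_id = paste0(prefix, i),
            position = at - 1L, motif = config$motif,
            stringsAsFactors = FALSE)
        }
        seqs[i] <- s
      }
      names(seqs) <- paste0(prefix, seq_len(n))
      list(seqs = seqs, rows = rows)
    }
    p <- make_set(config$n_pos, config$pos_freq, "pos")
    n <- make_set(config$n_neg, config$neg_freq, "neg")
    list(pos = p$seqs, neg = n$seqs,
         placements = do.call(rbind, c(p$rows, n$rows)) %||%
           data.frame(set = character(0), seq_id = character(0),
                      position = integer(0), motif = character(0)))
  })
}

#' Write the synthetic genome artefacts to a directory
#'
#' Emits genome FASTA, gene-model GFF3, maturation-annotation TSV and the
#' ground-truth TSV.
#'
#' @param gen a `synthetic_genome`.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_synthetic_genome <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             gff3 = file.path(dir, "genes.gff3"),
             annotations = file.path(dir, "annotations.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_fasta(gen$genome, paths["genome"])
  writeLines(gen$gff3, paths["gff3"])
  write.table(gen$annotations, paths["annotations"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(gen$truth$genes, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
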