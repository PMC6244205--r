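# Standard-format I/O and coordinate conventions.
#
# Internal coordinates are 0-based half-open throughout; GFF3 (1-based
# inclusive) and BED (0-based half-open) are converted only at the I/O
# boundary.

#' A genomic interval
#'
#' 0-based, half-open interval on a named chromosome.
#'
#' @param chrom chromosome name.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must satisfy `0 <= start < end`.
#' @param strand `"+"` or `"-"`.
#' @return an object of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  stopifnot(is.character(chrom), length(chrom) == 1L,
            strand %in% c("+", "-"))
  start <- as.integer(start); end <- as.integer(end)
  if (!(0L <= start && start < end))
    stop(sprintf("invalid interval [%d, %d)", start, end))
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' A gene model
#'
#' Exons are stored as a two-column integer matrix (`start`, `end`) of
#' 0-based half-open intervals, non-overlapping and sorted by start;
#' `cds_exons` is the subset carrying the coding sequence. Introns are the
#' gaps between consecutive exons.
#'
#' @param gene_id transcript/gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix of exon intervals.
#' @param cds_exons two-column matrix of CDS intervals (defaults to exons).
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds_exons = exons) {
  exons <- exon_matrix(exons)
  cds_exons <- exon_matrix(cds_exons)
  stopifnot(strand %in% c("+", "-"))
  if (any(exons[, 2] <= exons[, 1]))
    stop("exon end must exceed start")
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1] < exons[-nrow(exons), 2]))
    stop(sprintf("overlapping or unsorted exons in %s", gene_id))
  if (sum(cds_exons[, 2] - cds_exons[, 1]) %% 3L != 0L)
    stop(sprintf("CDS length of %s not divisible by 3", gene_id))
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 start = min(exons[, 1]), end = max(exons[, 2]),
                 exons = exons, cds_exons = cds_exons),
            class = "gene_model")
}

exon_matrix <- function(x) {
  m <- matrix(as.integer(x), ncol = 2L,
              dimnames = list(NULL, c("start", "end")))
  m[order(m[, 1]), , drop = FALSE]
}

#' Intron intervals of a gene model
#'
#' @param model a `gene_model`.
#' @return two-column matrix of 0-based half-open intron intervals (gaps
#'   between consecutive exons); zero rows for intronless genes.
#' @export
gene_introns <- function(model) {
  ex <- model$exons
  if (nrow(ex) < 2L)
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  cbind(start = ex[-nrow(ex), 2], end = ex[-1L, 1])
}

#' A maturation annotation
#'
#' External-predictor (or heuristic) calls for the signal-peptide cleavage
#' site and the GPI omega-site of one protein. Positions are 1-based; 0
#' means absent.
#'
#' @param protein_id protein identifier.
#' @param signal_cleavage position after which the signal peptide ends.
#' @param gpi_omega omega-site position (0 = no GPI anchor).
#' @param source `"external_table"` or `"heuristic"`.
#' @return an object of class `maturation_annotation`.
#' @export
maturation_annotation <- function(protein_id, signal_cleavage = 0L,
                                  gpi_omega = 0L,
                                  source = c("external_table", "heuristic")) {
  source <- match.arg(source)
  signal_cleavage <- as.integer(signal_cleavage)
  gpi_omega <- as.integer(gpi_omega)
  stopifnot(signal_cleavage >= 0L, gpi_omega >= 0L)
  if (gpi_omega > 0L && signal_cleavage >= gpi_omega)
    stop("signal cleavage site must precede the GPI omega-site")
  structure(list(protein_id = protein_id,
                 signal_cleavage = signal_cleavage,
                 gpi_omega = gpi_omega, source = source),
            class = "maturation_annotation")
}

gff3_attr <- function(attrs, key) {
  m <- regexpr(paste0("(^|;)", key, "=[^;]+"), attrs)
  out <- rep(NA_character_, length(attrs))
  out[m > 0L] <- sub(paste0("^;?", key, "="), "", regmatches(attrs, m))
  out
}

#' Parse gene models from GFF3
#'
#' Reads a GFF3 text (gene/mRNA/exon/CDS subset) and returns one
#' `gene_model` per mRNA. 1-based inclusive GFF3 coordinates are converted
#' to the internal 0-based half-open convention. mRNAs whose spliced CDS
#' length is not divisible by 3 are excluded with a warning; a CDS or exon
#' whose Parent is unknown is a parse error naming the offending line.
#'
#' @param gff3 GFF3 text (single string or character vector of lines) or a
#'   path to a GFF3 file.
#' @return list of `gene_model`, ordered by (chrom, start, gene_id).
#' @export
parse_gff3_gene_models <- function(gff3) {
  if (length(gff3) == 1L && !grepl("\n", gff3) && file.exists(gff3))
    gff3 <- readLines(gff3)
  if (length(gff3) == 1L) gff3 <- strsplit(gff3, "\n", fixed = TRUE)[[1]]
  keep <- nzchar(gff3) & !startsWith(gff3, "#")
  lines <- gff3[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) return(list())
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 9L))
    stop(sprintf("malformed GFF3 line %d: expected 9 fields",
                 lineno[which(lengths(f) != 9L)[1]]))
  f <- do.call(rbind, f)
  type <- f[, 3]
  start0 <- as.integer(f[, 4]) - 1L  # 1-based inclusive -> 0-based
  end0 <- as.integer(f[, 5])
  id <- gff3_attr(as.vector(f[, 9]), "ID")
  parent <- gff3_attr(as.vector(f[, 9]), "Parent")

  mrna_idx <- which(type == "mRNA")
  mrna_ids <- id[mrna_idx]
  models <- list()
  for (k in seq_along(mrna_idx)) {
    i <- mrna_idx[k]
    mid <- mrna_ids[k]
    if (is.na(mid)) stop(sprintf("mRNA without ID at line %d", lineno[i]))
    ex <- which(type == "exon" & parent == mid)
    cds <- which(type == "CDS" & parent == mid)
    if (length(ex) == 0L && length(cds) == 0L) next
    if (length(ex) == 0L) ex <- cds
    cds_len <- sum(end0[cds] - start0[cds])
    if (length(cds) > 0L && cds_len %% 3L != 0L) {
      warning(sprintf("excluding %s: CDS length %d not divisible by 3",
                      mid, cds_len))
      next
    }
    models[[mid]] <- gene_model(
      gene_id = mid, chrom = f[i, 1], strand = f[i, 7],
      exons = cbind(start0[ex], end0[ex]),
      cds_exons = if (length(cds) > 0L) cbind(start0[cds], end0[cds])
                  else cbind(start0[ex], end0[ex]))
  }
  orphan <- which(type %in% c("CDS", "exon") &
                  !(parent %in% mrna_ids) & !is.na(parent))
  # tolerate exon/CDS children of genes only when an mRNA level is absent
  orphan <- orphan[!(parent[orphan] %in% id[type == "gene"])]
  if (length(orphan) > 0L)
    stop(sprintf("%s without a parent mRNA at line %d",
                 type[orphan[1]], lineno[orphan[1]]))
  ord <- order(vapply(models, `[[`, character(1), "chrom"),
               vapply(models, `[[`, integer(1), "start"),
               vapply(models, `[[`, character(1), "gene_id"))
  models[ord]
}

#' Serialize gene models to GFF3 text
#'
#' Inverse of [parse_gff3_gene_models()]: emits gene/mRNA/exon/CDS rows in
#' 1-based inclusive GFF3 coordinates.
#'
#' @param models list of `gene_model`.
#' @return character vector of GFF3 lines (including the version pragma).
#' @export
write_gff3_gene_models <- function(models) {
  out <- "##gff-version 3"
  for (m in models) {
    gid <- paste0(m$gene_id, ".gene")
    row <- function(type, s0, e0, attrs) {
      paste(m$chrom, "ltpscan", type, s0 + 1L, e0, ".", m$strand, ".",
            attrs, sep = "\t")
    }
    out <- c(out,
             row("gene", m$start, m$end, paste0("ID=", gid)),
             row("mRNA", m$start, m$end,
                 paste0("ID=", m$gene_id, ";Parent=", gid)))
    for (i in seq_len(nrow(m$exons)))
      out <- c(out, row("exon", m$exons[i, 1], m$exons[i, 2],
                        paste0("ID=", m$gene_id, ".exon", i,
                               ";Parent=", m$gene_id)))
    for (i in seq_len(nrow(m$cds_exons)))
      out <- c(out, row("CDS", m$cds_exons[i, 1], m$cds_exons[i, 2],
                        paste0("ID=", m$gene_id, ".cds", i,
                               ";Parent=", m$gene_id)))
  }
  out
}

#' Six-frame translation
#'
#' Translates a DNA sequence in all six reading frames using the standard
#' genetic code. Frames `+1,+2,+3` read the given strand from offsets
#' 0,1,2; frames `-1,-2,-3` read the reverse complement likewise. Stop
#' codons render `*`, codons containing N render `X`, and trailing partial
#' codons are dropped.
#'
#' @param dna DNA string or `seq_record`.
#' @return named character vector of 6 protein strings
#'   (`"+1","+2","+3","-1","-2","-3"`).
#' @export
six_frame_translate <- function(dna) {
  s <- as_residues(dna, "dna")
  rc <- revcomp(s)
  frames <- c(`+1` = substr(s, 1L, nchar(s)),
              `+2` = substr(s, 2L, nchar(s)),
              `+3` = substr(s, 3L, nchar(s)),
              `-1` = substr(rc, 1L, nchar(rc)),
              `-2` = substr(rc, 2L, nchar(rc)),
              `-3` = substr(rc, 3L, nchar(rc)))
  vapply(frames, translate_dna, character(1))
}

#' Extract a spliced CDS from a genome
#'
#' Concatenates the CDS exons of a gene model 5'->3'; minus-strand genes
#' are reverse-complemented. The result length equals the sum of CDS exon
#' lengths and is divisible by 3.
#'
#' @param gene a `gene_model`.
#' @param genome named character vector of chromosome sequences (or a
#'   single `seq_record` whose id is the chromosome).
#' @return CDS DNA string.
#' @export
extract_spliced_cds <- function(gene, genome) {
  if (inherits(genome, "seq_record"))
    genome <- setNames(genome$residues, genome$id)
  if (!(gene$chrom %in% names(genome)))
    stop(sprintf("chromosome %s not present in genome", gene$chrom))
  chrom <- genome[[gene$chrom]]
  cds <- gene$cds_exons
  if (any(cds[, 1] < 0L) || any(cds[, 2] > nchar(chrom)))
    stop(sprintf("%s: CDS exon out of bounds of %s",
                 gene$gene_id, gene$chrom))
  pieces <- substring(chrom, cds[, 1] + 1L, cds[, 2])
  spliced <- paste(pieces, collapse = "")
  if (gene$strand == "-") spliced <- revcomp(spliced)
  spliced
}

#' Export a chromosome map of family members
#'
#' @param records data frame with columns `gene_id`, `chrom`, `start`,
#'   `end`, `strand` (one row per gene; NA location rows are skipped with a
#'   warning, mirroring family members that cannot be placed).
#' @param chrom_lengths named numeric vector of chromosome lengths in bp
#'   (used for the per-Mbp density column; optional).
#' @return list with `bed` (character vector of BED6 lines sorted by
#'   (chrom, start)) and `density` (data frame: chrom, n_genes, and, when
#'   lengths are given, length_bp and genes_per_mbp).
#' @export
export_chromosome_map <- function(records, chrom_lengths = NULL) {
  if (nrow(records) == 0L)
    return(list(bed = character(0),
                density = data.frame(chrom = character(0),
                                     n_genes = integer(0))))
  miss <- is.na(records$chrom) | is.na(records$start) | is.na(records$end)
  if (any(miss)) {
    warning(sprintf("skipping %d record(s) without a physical location",
                    sum(miss)))
    records <- records[!miss, , drop = FALSE]
  }
  records <- records[order(records$chrom, records$start,
                           records$gene_id), , drop = FALSE]
  bed <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", records$chrom,
                 as.integer(records$start), as.integer(records$end),
                 records$gene_id, 0L,
                 ifelse(is.na(records$strand), "+", records$strand))
  tab <- as.data.frame(table(chrom = records$chrom),
                       stringsAsFactors = FALSE)
  names(tab)[2] <- "n_genes"
  if (!is.null(chrom_lengths)) {
    tab$length_bp <- unname(chrom_lengths[tab$chrom])
    tab$genes_per_mbp <- tab$n_genes / (tab$length_bp / 1e6)
  }
  list(bed = bed, density = tab)
}
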