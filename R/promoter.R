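# Promoter motif enrichment: rank-sum testing of known boxes (AME-style)
# and de novo k-mer discovery with E-values (DREME-style).

IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

iupac_revcomp <- function(motif) {
  paste(rev(seq_chars(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
                             toupper(motif)))), collapse = "")
}

#' A known cis-element
#'
#' @param name element name (e.g. `POLLEN1LELAT52`).
#' @param consensus IUPAC DNA consensus, length >= 4.
#' @return object of class `known_motif`.
#' @export
known_motif <- function(name, consensus) {
  consensus <- toupper(consensus)
  if (nchar(consensus) < 4L) stop("motif consensus must have length >= 4")
  bad <- setdiff(unique(seq_chars(consensus)), names(IUPAC_DNA))
  if (length(bad) > 0L)
    stop(sprintf("invalid IUPAC letter(s): %s", paste(bad, collapse = ",")))
  structure(list(name = name, consensus = consensus),
            class = "known_motif")
}

#' Count motif occurrences in promoters
#'
#' Counts overlapping occurrences on both strands, with IUPAC codes
#' expanded positionally. A palindromic consensus (equal to its own
#' reverse complement) is counted once per site.
#'
#' @param promoters character vector of DNA sequences (named or not), or a
#'   single string.
#' @param motif a [known_motif()] or IUPAC consensus string.
#' @return integer vector of per-promoter occurrence counts.
#' @export
scan_motif <- function(promoters, motif) {
  consensus <- if (inherits(motif, "known_motif")) motif$consensus
               else toupper(motif)
  set <- Biostrings::DNAStringSet(toupper(promoters))
  fwd <- Biostrings::vcountPattern(consensus, set, fixed = FALSE)
  rc <- iupac_revcomp(consensus)
  if (rc == consensus) return(fwd)
  fwd + Biostrings::vcountPattern(rc, set, fixed = FALSE)
}

#' Rank-sum enrichment test of a known motif
#'
#' AME-style: each promoter is scored by its motif occurrence count (both
#' strands) and positives are compared to negatives with a one-sided
#' Wilcoxon rank-sum test (normal approximation with tie correction).
#'
#' @param pos,neg character vectors of promoter sequences.
#' @param motif a [known_motif()] or consensus string.
#' @param alpha significance threshold.
#' @return data frame row: motif, test, p_value, significant, degenerate
#'   (TRUE with p = 1 when the motif occurs in no sequence of either set).
#' @export
ranksum_known_motif <- function(pos, neg, motif, alpha = 0.05) {
  stopifnot(length(pos) > 0L, length(neg) > 0L)
  name <- if (inherits(motif, "known_motif")) motif$name else motif
  consensus <- if (inherits(motif, "known_motif")) motif$consensus
               else toupper(motif)
  ps <- scan_motif(pos, consensus)
  ns <- scan_motif(neg, consensus)
  if (all(ps == 0L) && all(ns == 0L)) {
    return(data.frame(motif = name, consensus = consensus,
                      test = "ranksum", p_value = 1,
                      significant = FALSE, degenerate = TRUE,
                      stringsAsFactors = FALSE))
  }
  p <- suppressWarnings(
    wilcox.test(ps, ns, alternative = "greater", exact = FALSE,
                correct = FALSE)$p.value)
  data.frame(motif = name, consensus = consensus, test = "ranksum",
             p_value = p, significant = p < alpha, degenerate = FALSE,
             stringsAsFactors = FALSE)
}

#' Screen a panel of pollen boxes
#'
#' Applies the rank-sum test to each box of a panel, at a per-box threshold
#' without multiple-testing correction (a note to that effect is attached
#' as an attribute). Promoters shorter than a box yield a degenerate p = 1
#' row for it.
#'
#' @param pos,neg promoter sets.
#' @param boxes list of [known_motif()] or a data frame with columns
#'   `name`, `consensus` (defaults to the shipped editable panel,
#'   [default_pollen_boxes()]).
#' @param alpha per-box significance threshold.
#' @return data frame with one row per box (see [ranksum_known_motif()]).
#' @export
pollen_box_screen <- function(pos, neg, boxes = default_pollen_boxes(),
                              alpha = 0.05) {
  if (is.data.frame(boxes))
    boxes <- Map(known_motif, boxes$name, boxes$consensus)
  if (length(boxes) == 0L)
    return(data.frame(motif = character(0), consensus = character(0),
                      test = character(0), p_value = numeric(0),
                      significant = logical(0), degenerate = logical(0)))
  out <- do.call(rbind, lapply(boxes, function(b) {
    ranksum_known_motif(pos, neg, b, alpha)
  }))
  rownames(out) <- NULL
  attr(out, "note") <-
    "per-box threshold, no multiple-testing correction"
  out
}

#' The shipped pollen-box panel
#'
#' An editable table of nine candidate cis-elements associated with
#' anther/pollen-enriched expression. `POLLEN1LELAT52` (AGAAA) is the only
#' literature-anchored entry; the remaining rows are placeholders meant to
#' be replaced with the user's own panel
#' (`inst/extdata/pollen_boxes.tsv`).
#'
#' @return data frame: name, consensus.
#' @export
default_pollen_boxes <- function() {
  path <- system.file("extdata", "pollen_boxes.tsv", package = "ltpscan")
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

# canonical form of a k-mer: lexicographically smaller of itself and its
# reverse complement (vectorised)
canonical_kmer <- function(kmers) {
  if (length(kmers) == 0L) return(character(0))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  ifelse(kmers <= rc, kmers, rc)
}

# distinct k-mers present in one sequence (ignoring windows containing
# non-ACGT characters, e.g. erased sites)
seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  km <- substring(s, starts, starts + k - 1L)
  unique(km[!grepl("[^ACGT]", km)])
}

# per-candidate (canonical k-mer) presence counts over a set of sequences
presence_counts <- function(seqs, k) {
  per_seq <- lapply(seqs, seq_kmers, k = k)
  all <- unlist(per_seq)
  if (length(all) == 0L) return(setNames(integer(0), character(0)))
  can <- canonical_kmer(all)
  seq_idx <- rep(seq_along(per_seq), lengths(per_seq))
  keep <- !duplicated(paste0(seq_idx, "\r", can))
  tab <- table(can[keep])
  setNames(as.integer(tab), names(tab))
}

# sequence-level presence of an IUPAC motif on either strand
iupac_presence <- function(seqs, consensus) {
  set <- Biostrings::DNAStringSet(seqs)
  hits <- Biostrings::vcountPattern(consensus, set, fixed = FALSE) > 0L
  rc <- iupac_revcomp(consensus)
  if (rc != consensus)
    hits <- hits | (Biostrings::vcountPattern(rc, set, fixed = FALSE) > 0L)
  hits
}

# one-sided Fisher p (enrichment in positives) from presence counts,
# computed as the hypergeometric tail; vectorised over candidates
fisher_tail_p <- function(pos_hits, neg_hits, n_pos, n_neg) {
  phyper(pos_hits - 1L, pos_hits + neg_hits,
         n_pos + n_neg - pos_hits - neg_hits, n_pos, lower.tail = FALSE)
}

#' De novo discovery of enriched k-mer motifs
#'
#' DREME-style greedy discovery. Each round enumerates every canonical
#' k-mer (both strands collapsed) present in at least one positive
#' promoter for each k in `k_range`, scores candidates by a one-sided
#' Fisher exact test on sequence-level presence (positives vs negatives),
#' and converts the best p-value to an E-value by multiplying with the
#' number of candidates tested that round. Optionally the best exact k-mer
#' is generalised by at most one IUPAC wildcard position (each tried
#' variant counts as an additional tested candidate). If the E-value is at
#' or below `e_threshold` the motif is accepted, its sites are erased from
#' the positive set, and the search repeats until `max_motifs` or no
#' candidate passes.
#'
#' @param pos,neg character vectors of promoter sequences.
#' @param k_range candidate widths.
#' @param e_threshold E-value acceptance threshold.
#' @param max_motifs maximum number of motifs to report.
#' @param generalize try single-position IUPAC generalisations.
#' @return list: `motifs` (data frame: consensus, width, p_value, e_value,
#'   pos_hits, neg_hits, n_candidates) and `pcm` (named list of 4 x width
#'   position-count matrices of the accepted motifs' matched sites, in
#'   MEME-minimal orientation).
#' @export
discover_motifs <- function(pos, neg, k_range = 4:8, e_threshold = 0.05,
                            max_motifs = 10L, generalize = TRUE) {
  stopifnot(length(pos) > 0L, length(neg) > 0L)
  work <- toupper(pos)
  neg <- toupper(neg)
  n_pos <- length(pos); n_neg <- length(neg)
  neg_counts <- lapply(k_range, function(k) presence_counts(neg, k))
  names(neg_counts) <- as.character(k_range)
  rows <- list(); pcms <- list()
  repeat {
    if (length(rows) >= max_motifs) break
    best <- NULL
    n_candidates <- 0L
    for (k in k_range) {
      pc <- presence_counts(work, k)
      if (length(pc) == 0L) next
      n_candidates <- n_candidates + length(pc)
      nc <- neg_counts[[as.character(k)]]
      nh <- ifelse(names(pc) %in% names(nc), nc[names(pc)], 0L)
      pvals <- fisher_tail_p(pc, as.integer(nh), n_pos, n_neg)
      o <- order(pvals, names(pc))[1L]
      cand <- list(consensus = names(pc)[o], k = k, p = pvals[[o]],
                   pos_hits = pc[[o]], neg_hits = as.integer(nh[[o]]))
      if (is.null(best) || cand$p < best$p ||
          (cand$p == best$p && cand$consensus < best$consensus))
        best <- cand
    }
    if (is.null(best) || n_candidates == 0L) break
    if (generalize) {
      chars <- seq_chars(best$consensus)
      wild <- setdiff(names(IUPAC_DNA), c("A", "C", "G", "T"))
      for (posn in seq_along(chars)) {
        for (code in wild) {
          if (!(chars[posn] %in% IUPAC_DNA[[code]])) next
          var <- chars
          var[posn] <- code
          var <- paste(var, collapse = "")
          n_candidates <- n_candidates + 1L
          ph <- sum(iupac_presence(work, var))
          nh <- sum(iupac_presence(neg, var))
          pv <- fisher_tail_p(ph, nh, n_pos, n_neg)
          if (pv < best$p) {
            best <- list(consensus = var, k = best$k, p = pv,
                         pos_hits = ph, neg_hits = nh)
          }
        }
      }
    }
    e <- best$p * n_candidates
    if (e > e_threshold) break
    rows[[length(rows) + 1L]] <- data.frame(
      consensus = best$consensus, width = best$k, p_value = best$p,
      e_value = e, pos_hits = best$pos_hits, neg_hits = best$neg_hits,
      n_candidates = n_candidates, stringsAsFactors = FALSE)
    erased <- erase_motif_sites(work, best$consensus)
    pcms[[best$consensus]] <- erased$pcm
    work <- erased$seqs
  }
  list(motifs = do.call(rbind, rows) %||%
         data.frame(consensus = character(0), width = integer(0),
                    p_value = numeric(0), e_value = numeric(0),
                    pos_hits = integer(0), neg_hits = integer(0),
                    n_candidates = integer(0)),
       pcm = pcms)
}

# erase all (both-strand) occurrences of an IUPAC motif from sequences and
# accumulate the position-count matrix of the erased sites (sites on the
# reverse strand contribute their reverse complement)
erase_motif_sites <- function(seqs, consensus) {
  k <- nchar(consensus)
  pcm <- matrix(0L, nrow = 4L, ncol = k,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  rc <- iupac_revcomp(consensus)
  pats <- unique(c(consensus, rc))
  out <- vapply(seqs, function(s) {
    chars <- seq_chars(s)
    for (pi in seq_along(pats)) {
      m <- Biostrings::matchPattern(pats[pi], Biostrings::DNAString(s),
                                    fixed = FALSE)
      for (st in Biostrings::start(m)) {
        site <- chars[st:(st + k - 1L)]
        if (any(site == ".")) next  # already erased by an earlier site
        oriented <- if (pi == 1L) site
                    else rev(seq_chars(chartr("ACGT", "TGCA",
                                              paste(site, collapse = ""))))
        for (j in seq_len(k))
          if (oriented[j] %in% rownames(pcm))
            pcm[oriented[j], j] <<- pcm[oriented[j], j] + 1L
        chars[st:(st + k - 1L)] <- "."
      }
    }
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  list(seqs = out, pcm = pcm)
}

#' Write discovered motifs in MEME-minimal text format
#'
#' @param discovery result of [discover_motifs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_meme_minimal <- function(discovery, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", ""), con)
  for (nm in names(discovery$pcm)) {
    pcm <- discovery$pcm[[nm]]
    nsites <- max(colSums(pcm))
    pwm <- sweep(pcm, 2L, pmax(colSums(pcm), 1L), "/")
    writeLines(c(sprintf("MOTIF %s", nm),
                 sprintf(
                   "letter-probability matrix: alength= 4 w= %d nsites= %d",
                   ncol(pcm), nsites)), con)
    for (j in seq_len(ncol(pwm)))
      writeLines(paste(sprintf("%.6f", pwm[, j]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}
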