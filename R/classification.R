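# Type assignment (1, 2, C, D, G) and family composition.

LTP_TYPES <- c("type1", "type2", "typeC", "typeD", "typeG", "unassigned")

# Global protein alignment (BLOSUM62, affine gaps) with identity computed
# over aligned columns excluding terminal-gap columns.
align_protein_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence in alignment")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1)
  pa <- seq_chars(as.character(Biostrings::alignedPattern(al)))
  sb <- seq_chars(as.character(Biostrings::alignedSubject(al)))
  keep <- trim_terminal_gap_cols(pa, sb)
  if (!any(keep)) return(0)
  mean(pa[keep] == sb[keep])
}

# columns belonging to a leading/trailing gap run of either sequence
trim_terminal_gap_cols <- function(a_chars, b_chars) {
  n <- length(a_chars)
  keep <- rep(TRUE, n)
  for (chars in list(a_chars, b_chars)) {
    nong <- which(chars != "-")
    if (length(nong) == 0L) return(rep(FALSE, n))
    keep[seq_len(n) < nong[1] | seq_len(n) > nong[length(nong)]] <- FALSE
  }
  keep
}

#' Derive the mature protein
#'
#' Removes the N-terminal signal peptide (residues up to and including the
#' cleavage site) and, when a GPI omega-site is annotated, the C-terminal
#' pro-peptide (residues after the omega-site).
#'
#' @param protein full-length protein string or `seq_record`.
#' @param annotation a [maturation_annotation()].
#' @return mature protein string.
#' @export
derive_mature_protein <- function(protein, annotation) {
  s <- as_residues(protein, "protein")
  n <- nchar(s)
  cl <- annotation$signal_cleavage
  om <- annotation$gpi_omega
  if (cl >= n) stop("signal cleavage site at or beyond protein end")
  if (om > n) stop("GPI omega-site beyond protein end")
  substr(s, cl + 1L, if (om > 0L) om else n)
}

#' Heuristic maturation fallback
#'
#' For candidates lacking external predictor annotations: calls the signal
#' peptide as the first 16-30 residue window with at least 70% hydrophobic
#' residues that ends before the first cysteine of the 8CM; no GPI call is
#' made. The result is flagged `source = "heuristic"` so downstream tables
#' mark these records as lower confidence.
#'
#' @param protein full-length protein string.
#' @param c1_pos0 0-based position of the first 8CM cysteine.
#' @param min_len,max_len window bounds in residues.
#' @param min_hydrophobic minimum hydrophobic fraction of the window.
#' @param protein_id id recorded in the annotation.
#' @return a `maturation_annotation` (cleavage 0 when no window qualifies).
#' @export
heuristic_maturation <- function(protein, c1_pos0, min_len = 16L,
                                 max_len = 30L, min_hydrophobic = 0.70,
                                 protein_id = "protein") {
  chars <- seq_chars(as_residues(protein, "protein"))
  upper <- min(max_len, c1_pos0)  # window must end before C1
  best <- 0L
  for (len in seq_len(upper)) {
    if (len < min_len) next
    if (mean(chars[seq_len(len)] %in% HYDROPHOBIC_SET) >= min_hydrophobic)
      best <- len
  }
  maturation_annotation(protein_id, signal_cleavage = best,
                        gpi_omega = 0L, source = "heuristic")
}

#' Classify an nsLTP candidate into a type
#'
#' Decision cascade: (1) GPI-anchored -> type G; (2) no intron within or
#' downstream of the 8CM -> type 2; (3) a single such intron at offset 5, 1
#' or 4 nt after the last 8CM cysteine codon -> type 1, C or D
#' respectively; (4) a single intron elsewhere downstream of the 8CM exon
#' whose mature protein aligns to a reference set of intronless type 2
#' members at identity >= `identity_override` -> type 2; (5) otherwise
#' unassigned. Intron offsets are measured in spliced-CDS coordinates from
#' the last base of the last 8CM cysteine codon to the first intron base
#' (negative when upstream).
#'
#' @param gpi logical; is a GPI omega-site annotated?
#' @param intron_offsets integer vector of intron offsets (see above).
#' @param mature_sequence mature protein (only needed for rule 4).
#' @param ref_type2 character vector of reference intronless type 2 mature
#'   proteins (only needed for rule 4).
#' @param identity_override identity threshold for rule 4.
#' @param motif_span_nt span of the 8CM in nt; introns entirely upstream of
#'   the motif (offset <= -span) are ignored by the cascade. Default `Inf`
#'   treats every supplied offset as relevant.
#' @param n_matches number of distinct 8CM matches in the protein; anything
#'   other than 1 defers classification (returns `"unassigned"` with
#'   attribute `deferred = TRUE`).
#' @return one of `"type1","type2","typeC","typeD","typeG","unassigned"`.
#' @export
classify_type <- function(gpi, intron_offsets, mature_sequence = NULL,
                          ref_type2 = character(0),
                          identity_override = 0.60,
                          motif_span_nt = Inf, n_matches = 1L) {
  if (n_matches != 1L)
    return(structure("unassigned", deferred = TRUE))
  if (isTRUE(gpi)) return("typeG")
  rel <- intron_offsets[intron_offsets > -motif_span_nt]
  if (length(rel) == 0L) return("type2")
  if (length(rel) == 1L) {
    if (rel == 5L) return("type1")
    if (rel == 1L) return("typeC")
    if (rel == 4L) return("typeD")
    if (rel > 0L && !is.null(mature_sequence) && length(ref_type2) > 0L) {
      ids <- vapply(ref_type2, align_protein_identity,
                    numeric(1), a = mature_sequence)
      if (max(ids) >= identity_override) return("type2")
    }
  }
  "unassigned"
}

#' Flag proline-rich (HyPRP-like) members
#'
#' TRUE when the region from the mature N-terminus to the first 8CM
#' cysteine is at least `min_len` residues long and at least `p_frac` of it
#' is proline.
#'
#' @param mature_sequence mature protein string.
#' @param c1_pos0 0-based position of C1 within the mature protein.
#' @param min_len minimum N-terminal region length.
#' @param p_frac minimum proline fraction.
#' @return logical.
#' @export
flag_hyprp <- function(mature_sequence, c1_pos0, min_len = 15L,
                       p_frac = 0.20) {
  stopifnot(c1_pos0 >= 0L, c1_pos0 <= nchar(mature_sequence))
  if (c1_pos0 < min_len) return(FALSE)
  region <- seq_chars(substr(mature_sequence, 1L, c1_pos0))
  mean(region == "P") >= p_frac
}

#' Summarise family composition
#'
#' Per-type counts and percentages (rounded to 2 decimals) plus the number
#' of unique mature proteins (exact string collapse) when mature sequences
#' are supplied.
#'
#' @param types character vector of type labels, or a records data frame
#'   with a `type` column (and optionally `mature`).
#' @param mature optional character vector of mature sequences parallel to
#'   `types`.
#' @return data frame (type, n, pct) with attributes `total` and, when
#'   mature sequences are given, `n_unique_mature`.
#' @export
summarize_family <- function(types, mature = NULL) {
  if (is.data.frame(types)) {
    mature <- types$mature
    types <- types$type
  }
  lev <- c(setdiff(LTP_TYPES, "unassigned"),
           if ("unassigned" %in% types) "unassigned")
  counts <- table(factor(types, levels = lev))
  total <- sum(counts)
  out <- data.frame(type = names(counts), n = as.integer(counts),
                    pct = if (total > 0L)
                            round(100 * as.integer(counts) / total, 2L)
                          else rep(0, length(counts)),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- total
  if (!is.null(mature))
    attr(out, "n_unique_mature") <- length(unique(mature))
  out
}

#' Apply a deny-list of sequence ids
#'
#' Drops candidates whose id (or description) matches an entry of a plain
#' text deny-list, mirroring manual exclusion of inhibitor/seed-storage
#' look-alikes.
#'
#' @param ids character vector of candidate ids.
#' @param deny_list character vector of ids (or a path to a text file, one
#'   id per line, `#` comments allowed).
#' @return logical vector: TRUE for candidates to keep.
#' @export
apply_deny_list <- function(ids, deny_list) {
  if (length(deny_list) == 1L && file.exists(deny_list)) {
    deny_list <- readLines(deny_list)
    deny_list <- trimws(sub("#.*$", "", deny_list))
    deny_list <- deny_list[nzchar(deny_list)]
  }
  !(ids %in% deny_list)
}
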