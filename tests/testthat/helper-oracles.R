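# Independent oracles used to cross-check the package implementations.

# codon -> residue lookup written out from the standard code in TCAG
# order, independent of the implementation's table
oracle_codon_table <- function() {
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  stats::setNames(aas, codons)
}

oracle_translate <- function(dna) {
  tab <- oracle_codon_table()
  n <- nchar(dna) %/% 3L
  if (n == 0L) return("")
  codons <- substring(dna, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- unname(tab[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]),
        collapse = "")
}

# exhaustive 8CM enumeration over all increasing 8-tuples of cysteine
# indices satisfying the CC / CXC anchors and the gap bounds
oracle_scan_8cm <- function(protein, bounds = gap_bounds()) {
  chars <- strsplit(protein, "")[[1]]
  cys <- which(chars == "C") - 1L
  out <- list()
  if (length(cys) >= 8L) {
    combos <- utils::combn(cys, 8L)
    for (j in seq_len(ncol(combos))) {
      p <- combos[, j]
      if (p[4] != p[3] + 1L) next
      if (p[6] != p[5] + 2L) next
      g <- c(p[2] - p[1] - 1L, p[3] - p[2] - 1L, p[5] - p[4] - 1L,
             p[7] - p[6] - 1L, p[8] - p[7] - 1L)
      ok <- TRUE
      for (i in 1:5) {
        b <- bounds[[paste0("g", i)]]
        if (g[i] < b[1] || g[i] > b[2]) ok <- FALSE
      }
      if (ok) out[[length(out) + 1L]] <- c(p, g)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(c1 = integer(0), c2 = integer(0), c3 = integer(0),
                      c4 = integer(0), c5 = integer(0), c6 = integer(0),
                      c7 = integer(0), c8 = integer(0), g1 = integer(0),
                      g2 = integer(0), g3 = integer(0), g4 = integer(0),
                      g5 = integer(0)))
  }
  m <- do.call(rbind, out)
  df <- as.data.frame(m)
  names(df) <- c(paste0("c", 1:8), paste0("g", 1:5))
  span <- df$c8 - df$c1 + 1L
  df <- df[order(df$c1, span, df$c2, df$c3, df$c5, df$c7, df$c8), ]
  rownames(df) <- NULL
  df
}

# naive UPGMA: cluster distance recomputed each step as the plain mean of
# the ORIGINAL pairwise distances across the two clusters (an equivalent
# but independent formulation of the weighted-average update); returns the
# cophenetic matrix
oracle_upgma_cophenetic <- function(dm) {
  labels <- rownames(dm)
  clusters <- as.list(labels)
  coph <- matrix(0, nrow(dm), ncol(dm), dimnames = dimnames(dm))
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        dij <- mean(dm[clusters[[i]], clusters[[j]]])
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        better <- is.null(best) || dij < best$d - 1e-15 ||
          (abs(dij - best$d) <= 1e-15 &&
             (key[1] < best$key[1] ||
                (key[1] == best$key[1] && key[2] < best$key[2])))
        if (better) best <- list(i = i, j = j, d = dij, key = key)
      }
    }
    for (a in clusters[[best$i]]) for (b in clusters[[best$j]])
      coph[a, b] <- coph[b, a] <- best$d
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  coph
}

# naive per-position IUPAC motif count on both strands (palindromes once)
oracle_scan_motif <- function(s, consensus) {
  classes <- list(A = "A", C = "C", G = "G", T = "T",
                  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                  B = c("C", "G", "T"), D = c("A", "G", "T"),
                  H = c("A", "C", "T"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "T"))
  count_one <- function(target, motif) {
    mchars <- strsplit(motif, "")[[1]]
    tchars <- strsplit(target, "")[[1]]
    k <- length(mchars)
    n <- length(tchars)
    if (n < k) return(0L)
    hits <- 0L
    for (i in seq_len(n - k + 1L)) {
      ok <- TRUE
      for (j in seq_len(k)) {
        if (!(tchars[i + j - 1L] %in% classes[[mchars[j]]])) {
          ok <- FALSE
          break
        }
      }
      if (ok) hits <- hits + 1L
    }
    hits
  }
  rc_consensus <- paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN",
                                            "TGCAYRSWMKVHDBN",
                                            consensus), "")[[1]]),
                        collapse = "")
  total <- count_one(s, consensus)
  if (rc_consensus != consensus)
    total <- total + count_one(oracle_revcomp(s), consensus)
  total
}

# IUPAC-aware check that a discovered consensus matches (a substring of)
# the planted motif or its reverse complement
matches_planted_motif <- function(consensus, motif) {
  classes <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]",
               Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]",
               M = "[AC]", B = "[CGT]", D = "[AGT]", H = "[ACT]",
               V = "[ACG]", N = "[ACGT]")
  as_regex <- function(x) paste(classes[strsplit(x, "")[[1]]],
                                collapse = "")
  rc <- function(x) paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN",
                                              "TGCAYRSWMKVHDBN", x),
                                       "")[[1]]), collapse = "")
  targets <- c(motif, rc(motif))
  any(vapply(c(consensus, rc(consensus)), function(cc) {
    any(grepl(as_regex(cc), targets))
  }, logical(1)))
}

random_protein <- function(n, pool = c("A", "D", "E", "F", "G", "H",
                                       "I", "K", "L", "M", "N", "P",
                                       "Q", "R", "S", "T", "V", "W",
                                       "Y")) {
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# random stop-free CDS of n codons (terminator included)
random_cds <- function(n_codons) {
  tab <- oracle_codon_table()
  sense <- names(tab)[tab != "*"]
  paste(c(sample(sense, n_codons - 1L, replace = TRUE), "TAA"),
        collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small, fast generator configuration shared by integration tests
small_config <- function(seed = 1L) {
  generator_config(
    seed = seed, n_chromosomes = 1L, chrom_length_bp = 40000L,
    n_ltp_genes = 12L,
    tandem_array_spec = list(list(chrom = "chr1", size = 3L, syn = 3L,
                                  nonsyn = 1L)),
    expression_spec = expression_config(n_genes = 12L),
    promoter_spec = promoter_config(n_pos = 8L, n_neg = 20L,
                                    length = 200L))
}
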