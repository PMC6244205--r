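# Homology detection (80/80 rule), tandem clusters, NG86 Ka/Ks and
# duplication dating.

# coverage / identity / codon-pair projection from two aligned strings
cds_stats_from_aligned <- function(a, b, pa, sb) {
  pa <- seq_chars(pa); sb <- seq_chars(sb)
  both <- pa != "-" & sb != "-"
  coverage <- sum(both) / min(nchar(a), nchar(b))
  identity <- if (any(both)) mean(pa[both] == sb[both]) else 0
  pos_a <- cumsum(pa != "-")[both]
  pos_b <- cumsum(sb != "-")[both]
  cod_a <- (pos_a - 1L) %/% 3L
  cod_b <- (pos_b - 1L) %/% 3L
  pairs <- matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("a", "b")))
  if (length(pos_a) > 0L) {
    grp <- split(seq_along(pos_a), cod_a)
    keep <- vapply(grp, function(ix) {
      length(ix) == 3L && length(unique(cod_b[ix])) == 1L &&
        all(sort(pos_b[ix] - 3L * cod_b[ix][1]) == 1:3)
    }, logical(1))
    ca <- as.integer(names(grp))[keep]
    cb <- vapply(grp[keep], function(ix) cod_b[ix][1], integer(1))
    pairs <- cbind(a = substring(a, 3L * ca + 1L, 3L * ca + 3L),
                   b = substring(b, 3L * cb + 1L, 3L * cb + 3L))
  }
  list(coverage = coverage, identity = identity, codon_pairs = pairs)
}

#' Globally align two coding sequences
#'
#' Nucleotide global alignment (match +1, mismatch -1, gap open -5, gap
#' extend -1) with a codon-aware projection: aligned columns are grouped
#' back into codon pairs, and codons interrupted by gaps (in either
#' sequence) are excluded from the codon pairing used for Ka/Ks.
#'
#' @param cds_a,cds_b CDS strings, lengths divisible by 3.
#' @return list: `coverage` (fraction of the shorter CDS aligned without
#'   gaps), `identity` (fraction identical over gap-free aligned columns),
#'   `codon_pairs` (2-column character matrix of gap-free codon pairs) and
#'   the aligned strings.
#' @export
align_cds_pair <- function(cds_a, cds_b) {
  a <- as_residues(cds_a, "dna"); b <- as_residues(cds_b, "dna")
  if (!nzchar(a) || !nzchar(b)) stop("empty CDS in alignment")
  stopifnot(nchar(a) %% 3L == 0L, nchar(b) %% 3L == 0L)
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = sub, gapOpening = 5, gapExtension = 1)
  pa <- as.character(Biostrings::alignedPattern(al))
  sb <- as.character(Biostrings::alignedSubject(al))
  c(cds_stats_from_aligned(a, b, pa, sb),
    list(aligned_a = pa, aligned_b = sb))
}

#' 80/80 homology rule
#'
#' A pair is homologous when coverage of the shorter CDS is at least
#' `cov_min` and alignment identity is strictly above `id_min`.
#'
#' @param coverage,identity alignment statistics (see [align_cds_pair()]);
#'   `coverage` may also be the list returned by [align_cds_pair()].
#' @param cov_min,id_min thresholds.
#' @return logical.
#' @export
is_homologous_pair <- function(coverage, identity = NULL, cov_min = 0.80,
                               id_min = 0.80) {
  if (is.list(coverage)) {
    identity <- coverage$identity
    coverage <- coverage$coverage
  }
  coverage >= cov_min && identity > id_min
}

#' Detect tandem duplication clusters
#'
#' Two or more adjacent homologous family genes on a single chromosome.
#' Genes are ordered by start position per chromosome; two genes chain into
#' one cluster when they are homologous and separated by at most
#' `max_intervening` family genes in that order (single linkage). Clusters
#' are maximal chains and pairwise disjoint.
#'
#' @param genes data frame with columns `gene_id`, `chrom`, `start`.
#' @param pairs data frame of homologous pairs with columns `gene_a`,
#'   `gene_b` (unordered).
#' @param max_intervening maximum number of intervening family genes.
#' @return list of clusters, each `list(chrom =, members =)` with members
#'   in chromosome order.
#' @export
find_tandem_clusters <- function(genes, pairs, max_intervening = 0L) {
  out <- list()
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    g <- g[order(g$start, g$gene_id), , drop = FALSE]
    n <- nrow(g)
    if (n < 2L) next
    rank <- setNames(seq_len(n), g$gene_id)
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    if (nrow(pairs) > 0L) for (p in seq_len(nrow(pairs))) {
      ia <- rank[pairs$gene_a[p]]; ib <- rank[pairs$gene_b[p]]
      if (is.na(ia) || is.na(ib)) next  # not both on this chromosome
      if (abs(ia - ib) <= max_intervening + 1L)
        parent[find(ia)] <- find(ib)
    }
    comp <- vapply(seq_len(n), find, integer(1))
    for (cl in split(seq_len(n), comp)) {
      if (length(cl) >= 2L)
        out[[length(out) + 1L]] <- list(chrom = ch,
                                        members = g$gene_id[sort(cl)])
    }
  }
  out
}

# --- NG86 ---------------------------------------------------------------

aa_of <- function(codon) {
  tab <- codon_table()
  unname(tab[codon])
}

# synonymous site count of one codon (0..3): per position, the fraction of
# the three possible single-nucleotide changes that preserve the residue;
# changes to a stop codon count non-synonymous.
ng86_syn_sites <- function(codon) {
  tab <- codon_table()
  aa <- tab[codon]
  bases <- c("A", "C", "G", "T")
  chars <- seq_chars(codon)
  s <- 0
  for (pos in 1:3) {
    for (nt in setdiff(bases, chars[pos])) {
      mut <- chars
      mut[pos] <- nt
      maa <- tab[paste(mut, collapse = "")]
      if (!is.na(maa) && maa == aa && maa != "*") s <- s + 1 / 3
    }
  }
  unname(s)
}

# average (syn, nonsyn) difference counts over all minimal mutational
# pathways between two codons; steps whose residues match (and are not
# stops) are synonymous, every other step non-synonymous.
ng86_path_diffs <- function(ca, cb) {
  a <- seq_chars(ca); b <- seq_chars(cb)
  diffpos <- which(a != b)
  nd <- length(diffpos)
  if (nd == 0L) return(c(syn = 0, nonsyn = 0))
  tab <- codon_table()
  orders <- if (nd == 1L) list(diffpos) else {
    perms <- list()
    permute <- function(v, acc = integer(0)) {
      if (length(v) == 0L) perms[[length(perms) + 1L]] <<- acc
      else for (i in seq_along(v)) permute(v[-i], c(acc, v[i]))
    }
    permute(diffpos)
    perms
  }
  syn <- 0; nonsyn <- 0
  for (ord in orders) {
    cur <- a
    for (pos in ord) {
      nxt <- cur
      nxt[pos] <- b[pos]
      aa1 <- tab[paste(cur, collapse = "")]
      aa2 <- tab[paste(nxt, collapse = "")]
      if (!is.na(aa1) && !is.na(aa2) && aa1 == aa2 && aa1 != "*")
        syn <- syn + 1
      else nonsyn <- nonsyn + 1
      cur <- nxt
    }
  }
  c(syn = syn / length(orders), nonsyn = nonsyn / length(orders))
}

#' Nei-Gojobori (1986) Ka/Ks
#'
#' Pathway-counting Ka/Ks with Jukes-Cantor correction. Synonymous site
#' fractions come from the standard genetic code and are averaged over the
#' two sequences; multiple-hit codons are resolved by averaging over all
#' minimal mutational pathways; proportions are corrected by
#' `d = -(3/4) ln(1 - 4p/3)`. A proportion of 3/4 or more cannot be
#' corrected and flags the corresponding rate as saturated. Codon pairs
#' containing a stop codon are excluded with a warning.
#'
#' @param cds_a CDS string, or a 2-column codon-pair matrix as produced by
#'   [align_cds_pair()] (then `cds_b` is ignored).
#' @param cds_b CDS string of equal length.
#' @return object of class `kaks_result`: list with `ka`, `ks`, `ratio`
#'   (NA when Ks is 0 or saturated), raw counts `sd`, `nd`, site counts
#'   `s_sites`, `n_sites`, proportions `ps`, `pn`, `n_codons`, and the
#'   `saturated_ks` / `saturated_ka` flags.
#' @export
ng86_kaks <- function(cds_a, cds_b = NULL) {
  if (is.matrix(cds_a)) {
    pairs <- cds_a
  } else {
    a <- as_residues(cds_a, "dna"); b <- as_residues(cds_b, "dna")
    stopifnot(nchar(a) == nchar(b), nchar(a) %% 3L == 0L)
    n <- nchar(a) %/% 3L
    pairs <- cbind(a = substring(a, 3L * seq_len(n) - 2L, 3L * seq_len(n)),
                   b = substring(b, 3L * seq_len(n) - 2L, 3L * seq_len(n)))
  }
  tab <- codon_table()
  is_stop <- tab[pairs[, 1]] == "*" | tab[pairs[, 2]] == "*"
  bad <- is.na(is_stop) | is_stop
  if (any(bad)) {
    # a stop pair in the terminal position is the expected CDS terminator
    if (any(which(bad) != nrow(pairs)))
      warning(sprintf(
        "excluding %d internal codon pair(s) containing a stop codon",
        sum(which(bad) != nrow(pairs))))
    pairs <- pairs[!bad, , drop = FALSE]
  }
  if (nrow(pairs) == 0L) stop("no gap-free, stop-free codon pairs")

  s_a <- sum(vapply(pairs[, 1], ng86_syn_sites, numeric(1)))
  s_b <- sum(vapply(pairs[, 2], ng86_syn_sites, numeric(1)))
  s_sites <- (s_a + s_b) / 2
  n_sites <- 3 * nrow(pairs) - s_sites
  diffs <- vapply(seq_len(nrow(pairs)), function(i) {
    ng86_path_diffs(pairs[i, 1], pairs[i, 2])
  }, numeric(2))
  sd <- sum(diffs["syn", ]); nd <- sum(diffs["nonsyn", ])
  ps <- if (s_sites > 0) sd / s_sites else 0
  pn <- if (n_sites > 0) nd / n_sites else 0
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  ks <- jc(ps); ka <- jc(pn)
  structure(list(
    ka = ka, ks = ks,
    ratio = if (is.na(ka) || is.na(ks) || ks == 0) NA_real_ else ka / ks,
    sd = sd, nd = nd, s_sites = s_sites, n_sites = n_sites,
    ps = ps, pn = pn, n_codons = nrow(pairs),
    saturated_ks = is.na(ks), saturated_ka = is.na(ka)),
    class = "kaks_result")
}

#' Divergence time from Ks
#'
#' `T = Ks / (2r)`, reported in million years (MYA).
#'
#' @param ks synonymous substitutions per synonymous site (>= 0).
#' @param r divergence rate per site per year.
#' @return time in MYA.
#' @export
#' @examples
#' divergence_time_mya(0.7007)  # ~53.9 MYA
divergence_time_mya <- function(ks, r = 6.5e-9) {
  stopifnot(r > 0)
  if (any(ks < 0, na.rm = TRUE)) stop("Ks must be non-negative")
  ks / (2 * r) * 1e-6
}

#' All-against-all homology and Ka/Ks over a CDS set
#'
#' Convenience wrapper over the pairwise search: pairs sharing no `seed_k`-mer
#' are rejected without a full alignment (the behaviour of a seeded
#' homology search, which needs an exact word hit to trigger); the remaining
#' pairs are globally aligned, the 80/80 rule is applied, and NG86 Ka/Ks
#' plus divergence times are computed for homologous pairs.
#'
#' @param cds named character vector of CDS strings.
#' @param cov_min,id_min homology thresholds (see [is_homologous_pair()]).
#' @param r divergence rate for dating.
#' @param seed_k word size of the seed prefilter; `0` disables it.
#' @return list: `pairs` (data frame gene_a, gene_b, coverage, identity,
#'   homologous; seed-rejected pairs carry NA statistics) and `kaks`
#'   (data frame for homologous pairs: ka, ks, ratio, t_mya, sd, nd,
#'   saturated).
#' @export
homology_kaks_table <- function(cds, cov_min = 0.80, id_min = 0.80,
                                r = 6.5e-9, seed_k = 8L) {
  ids <- names(cds)
  stopifnot(!is.null(ids))
  n <- length(ids)
  words <- if (seed_k > 0L) lapply(cds, function(s) {
    starts <- seq_len(max(nchar(s) - seed_k + 1L, 0L))
    unique(substring(s, starts, starts + seed_k - 1L))
  })
  rows <- list(); krows <- list()
  set <- Biostrings::DNAStringSet(cds)
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                  mismatch = -1,
                                                  baseOnly = TRUE)
  for (j in seq_len(n)[-1L]) {
    prior <- seq_len(j - 1L)
    seeded <- if (seed_k > 0L) {
      vapply(prior, function(i) {
        any(words[[i]] %in% words[[j]])
      }, logical(1))
    } else rep(TRUE, length(prior))
    for (i in prior[!seeded]) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = ids[i], gene_b = ids[j], coverage = NA_real_,
        identity = NA_real_, homologous = FALSE,
        stringsAsFactors = FALSE)
    }
    todo <- prior[seeded]
    if (length(todo) == 0L) next
    al <- Biostrings::pairwiseAlignment(
      set[todo], set[[j]], type = "global", substitutionMatrix = sub,
      gapOpening = 5, gapExtension = 1)
    pa <- as.character(Biostrings::alignedPattern(al))
    sb <- as.character(Biostrings::alignedSubject(al))
    for (k in seq_along(todo)) {
      i <- todo[k]
      st <- cds_stats_from_aligned(cds[[i]], cds[[j]], pa[k], sb[k])
      hom <- is_homologous_pair(st$coverage, st$identity, cov_min,
                                id_min)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = ids[i], gene_b = ids[j], coverage = st$coverage,
        identity = st$identity, homologous = hom,
        stringsAsFactors = FALSE)
      if (hom) {
        kk <- ng86_kaks(st$codon_pairs)
        krows[[length(krows) + 1L]] <- data.frame(
          gene_a = ids[i], gene_b = ids[j], ka = kk$ka, ks = kk$ks,
          ratio = kk$ratio,
          t_mya = if (kk$saturated_ks) NA_real_
                  else divergence_time_mya(kk$ks, r),
          sd = kk$sd, nd = kk$nd,
          saturated = kk$saturated_ks || kk$saturated_ka,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(pairs = do.call(rbind, rows) %||%
         data.frame(gene_a = character(0), gene_b = character(0),
                    coverage = numeric(0), identity = numeric(0),
                    homologous = logical(0)),
       kaks = do.call(rbind, krows) %||%
         data.frame(gene_a = character(0), gene_b = character(0),
                    ka = numeric(0), ks = numeric(0), ratio = numeric(0),
                    t_mya = numeric(0), sd = numeric(0), nd = numeric(0),
                    saturated = logical(0)))
}
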