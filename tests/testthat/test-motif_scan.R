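test_that("a canonical type-C peptide yields one match with its gaps", {
  pep <- paste0(strrep("M", 10), "C", strrep("A", 9), "C",
                strrep("A", 14), "CC", strrep("A", 9), "C", "A", "C",
                strrep("A", 12), "C", strrep("A", 6), "C")
  m <- scan_eight_cm(pep)
  expect_identical(nrow(m), 1L)
  expect_identical(unlist(m[1, paste0("g", 1:5)], use.names = FALSE),
                   c(9L, 14L, 9L, 12L, 6L))
  expect_identical(m$c1, 10L)
  expect_identical(m$cxc_x, "A")
})

test_that("fewer than eight cysteines can never match", {
  pep <- paste0("M", strrep("A", 5), paste(rep(c("C", "AAA"), 7),
                                           collapse = ""))
  expect_identical(nrow(scan_eight_cm(pep)), 0L)
})

test_that("the scanner equals exhaustive enumeration on random fixtures", {
  set.seed(90)
  bounds <- gap_bounds()
  for (rep in 1:50) {
    # random 300-aa background with a planted motif and a few extra
    # cysteines to create overlapping candidates
    gaps <- c(sample(3:21, 1), sample(8:29, 1), sample(8:23, 1),
              sample(8:38, 1), sample(3:22, 1))
    motif <- paste0("C", random_protein(gaps[1]), "C",
                    random_protein(gaps[2]), "CC",
                    random_protein(gaps[3]), "C", random_protein(1),
                    "C", random_protein(gaps[4]), "C",
                    random_protein(gaps[5]), "C")
    chars <- strsplit(paste0(random_protein(60), motif,
                             random_protein(60)), "")[[1]]
    extra <- sample(length(chars), 4)
    chars[extra] <- "C"
    pep <- paste(chars, collapse = "")
    got <- scan_eight_cm(pep, bounds, all_candidates = TRUE)
    want <- oracle_scan_8cm(pep, bounds)
    expect_identical(got[, c(paste0("c", 1:8), paste0("g", 1:5))],
                     want)
    # resolved matches are a non-overlapping subset of the enumeration
    res <- scan_eight_cm(pep, bounds)
    if (nrow(res) > 1L)
      expect_true(all(res$c1[-1] > res$c8[-nrow(res)]))
  }
})

test_that("planted 8CMs are recovered with recall 1 and stay in-gene", {
  gen <- generate_genome(small_config(seed = 12))
  tr <- gen$truth$genes
  for (i in seq_len(nrow(tr))) {
    m <- scan_eight_cm(tr$protein[i], id = tr$gene_id[i])
    expect_identical(nrow(m), 1L)
    expect_identical(unlist(m[1, paste0("g", 1:5)], use.names = FALSE),
                     c(tr$g1[i], tr$g2[i], tr$g3[i], tr$g4[i], tr$g5[i]))
  }
  # DNA-mode scan: every match lies within a single planted gene span
  dnam <- scan_dna_six_frame(seq_record("chr1", gen$genome[["chr1"]],
                                        "dna"))
  if (!is.null(dnam) && nrow(dnam) > 0L) {
    for (j in seq_len(nrow(dnam))) {
      # protein position -> approximate nt span on the chromosome
      fr <- dnam$frame[j]
      off <- abs(as.integer(substr(fr, 2, 2))) - 1L
      L <- nchar(gen$genome[["chr1"]])
      nt1 <- 3L * dnam$c1[j] + off
      nt2 <- 3L * (dnam$c8[j] + 1L) + off
      if (startsWith(fr, "-")) {
        tmp <- nt1
        nt1 <- L - nt2
        nt2 <- L - tmp
      }
      inside <- any(tr$start <= nt1 & nt2 <= tr$end)
      expect_true(inside)
    }
  }
})

test_that("spacing signatures render multisets and unique values", {
  matches <- data.frame(
    type = c(rep("typeC", 5), "type1"),
    g1 = c(rep(9L, 5), 9L), g2 = c(14L, 19L, 14L, 14L, 19L, 13L),
    g3 = c(rep(9L, 5), 20L), g4 = c(rep(12L, 5), 21L),
    g5 = c(rep(6L, 5), 7L))
  sig <- spacing_signature(matches)
  expect_identical(sort(unique(sig$typeC$gaps$g4)), 12L)
  expect_identical(sig$typeC$pattern, "CX9CX14,19CCX9CXCX12CX6C")
  # 12 is unique to type C among these matches
  expect_identical(sig$typeC$unique_values$g4, 12L)
  single <- spacing_signature(data.frame(type = "typeD", g1 = 9L,
                                         g2 = 16L, g3 = 10L, g4 = 17L,
                                         g5 = 4L))
  expect_identical(single$typeD$pattern, "CX9CX16CCX10CXCX17CX4C")
})

test_that("CXC polarity counts hydrophobic X residues", {
  m <- data.frame(type = rep("type2", 4), cxc_x = c("L", "L", "L", "L"))
  expect_equal(cxc_polarity(m)$fraction_hydrophobic, 1.0)
  m2 <- data.frame(type = c("type1", "type1"), cxc_x = c("L", "S"))
  expect_equal(cxc_polarity(m2)$fraction_hydrophobic, 0.5)
  m3 <- data.frame(type = "typeG", cxc_x = "X")
  expect_warning(out <- cxc_polarity(m3), "unknown")
  expect_identical(nrow(out), 0L)
  # draws from a known mixture: the reported fraction equals an
  # independent direct count, and stays inside wide binomial bounds of
  # the mixture's hydrophobic mass
  set.seed(31)
  pool <- c("L", "V", "S", "T", "D")  # hydrophobic mass 2/5
  x <- sample(pool, 5000, replace = TRUE)
  frac <- cxc_polarity(data.frame(type = "t", cxc_x = x,
                                  stringsAsFactors = FALSE))
  expect_equal(frac$fraction_hydrophobic,
               sum(x %in% c("L", "V")) / length(x))
  band <- stats::qbinom(c(1e-5, 1 - 1e-5), 5000, 0.4) / 5000
  expect_gte(frac$fraction_hydrophobic, band[1])
  expect_lte(frac$fraction_hydrophobic, band[2])
})

test_that("position-count matrices count what covers each column", {
  gen_gaps <- list(c(9, 14, 9, 12, 6), c(9, 19, 9, 12, 6))
  seqs <- character(0)
  for (i in seq_along(gen_gaps)) {
    g <- gen_gaps[[i]]
    seqs[paste0("p", i)] <- paste0(
      "MM", "C", random_protein(g[1]), "C", random_protein(g[2]), "CC",
      random_protein(g[3]), "C", "L", "C", random_protein(g[4]), "C",
      random_protein(g[5]), "C", "DD")
  }
  matches <- scan_eight_cm_set(seqs)
  matches$type <- "typeC"
  pcm <- position_counts(matches, seqs)$typeC
  expect_identical(unname(pcm["C", "C1"]), 2L)
  # cysteine columns contain only C
  for (cc in paste0("C", 1:8))
    expect_equal(sum(pcm[, cc]), pcm["C", cc])
  # g2 runs to 19; columns beyond 14 are covered by one sequence only
  expect_equal(unname(colSums(pcm)[["g2.14"]]), 2)
  expect_equal(unname(colSums(pcm)[["g2.15"]]), 1)
  expect_equal(unname(colSums(pcm)[["X"]]), 2)
  expect_identical(unname(pcm["L", "X"]), 2L)
})
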