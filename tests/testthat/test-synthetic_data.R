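test_that("generated genes carry the requested 8CM and gene structure", {
  g <- generate_ltp_gene("typeC", gaps = c(9, 14, 9, 12, 6), seed = 2)
  m <- scan_eight_cm(g$truth$protein)
  expect_identical(nrow(m), 1L)
  expect_identical(unlist(m[1, paste0("g", 1:5)], use.names = FALSE),
                   c(9L, 14L, 9L, 12L, 6L))
  expect_identical(g$truth$intron_offsets, 1L)  # type C diagnostic offset
  g2 <- generate_ltp_gene("type2", seed = 2)
  expect_identical(nrow(gene_introns(g2$model)), 0L)
  expect_identical(g2$truth$intron_offsets, integer(0))
  g1 <- generate_ltp_gene("type1", seed = 2)
  expect_identical(g1$truth$intron_offsets, 5L)
  gD <- generate_ltp_gene("typeD", seed = 2)
  expect_identical(gD$truth$intron_offsets, 4L)
  gG <- generate_ltp_gene("typeG", seed = 2)
  expect_gt(gG$truth$gpi_omega, 0L)
  expect_lte(length(gG$truth$intron_offsets), 4L)
})

test_that("gap requests outside the printed spacing sets are rejected", {
  expect_error(generate_ltp_gene("typeC", gaps = c(9, 14, 9, 13, 6)),
               "outside the printed spacing set")
})

test_that("the generator is a pure function of its seed", {
  expect_identical(generate_ltp_gene("typeG", seed = 7),
                   generate_ltp_gene("typeG", seed = 7))
  expect_identical(generate_genome(small_config(seed = 4)),
                   generate_genome(small_config(seed = 4)))
  cfg <- promoter_config(n_pos = 5, n_neg = 5, length = 100)
  expect_identical(generate_promoter_sets(cfg, seed = 3),
                   generate_promoter_sets(cfg, seed = 3))
})

test_that("truth tables agree with what is measurable from the files", {
  for (tp in c("type1", "type2", "typeC", "typeD", "typeG")) {
    g <- generate_ltp_gene(tp, seed = 11)
    # gaps recorded in truth equal gaps measured from the protein
    m <- scan_eight_cm(g$truth$protein)
    expect_identical(unlist(m[1, paste0("g", 1:5)], use.names = FALSE),
                     g$truth$gaps)
    expect_identical(which(strsplit(g$truth$protein, "")[[1]] == "C") - 1L,
                     g$truth$cys_positions)
    # CDS on the locus translates back to the protein
    cds <- extract_spliced_cds(
      g$model, stats::setNames(g$locus_dna, g$model$chrom))
    expect_identical(sub("\\*$", "", translate_dna(cds)),
                     g$truth$protein)
    expect_identical(
      derive_mature_protein(g$truth$protein, g$annotation),
      g$truth$mature)
  }
})

test_that("controlled mutation applies exact change counts", {
  cds <- strrep("AAA", 10)
  expect_identical(mutate_cds_controlled(cds, 0, 0, seed = 1), cds)
  one_syn <- mutate_cds_controlled(cds, 1, 0, seed = 5)
  # AAG is the only Lys-preserving change of AAA
  expect_identical(sort(unique(substring(one_syn, seq(1, 28, 3),
                                         seq(3, 30, 3)))),
                   c("AAA", "AAG"))
  expect_identical(translate_dna(one_syn), translate_dna(cds))
  set.seed(400)
  for (rep in 1:10) {
    base <- random_cds(40)
    s <- sample(0:4, 1); n <- sample(0:3, 1)
    mut <- mutate_cds_controlled(base, s, n, seed = rep)
    expect_identical(nchar(mut), nchar(base))
    p0 <- strsplit(translate_dna(base), "")[[1]]
    p1 <- strsplit(translate_dna(mut), "")[[1]]
    expect_identical(sum(p0 != p1), n)  # residue-diff oracle
    expect_false(grepl("\\*", substr(translate_dna(mut), 1,
                                     nchar(base) / 3 - 1)))
    nt_diff <- sum(strsplit(base, "")[[1]] != strsplit(mut, "")[[1]])
    expect_identical(nt_diff, s + n)
  }
})

test_that("mutation reports the deficit when sites run out", {
  expect_error(mutate_cds_controlled("ATGTAA", 5, 0, seed = 1),
               "insufficient eligible codons")
})

test_that("tandem arrays land adjacent on one chromosome with truth", {
  gen <- generate_genome(small_config(seed = 6))
  expect_length(gen$truth$clusters, 1L)
  cl <- gen$truth$clusters[[1]]
  expect_identical(cl$chrom, "chr1")
  expect_length(cl$members, 3L)
  tr <- gen$truth$genes
  ranks <- match(cl$members, tr$gene_id[order(tr$start)])
  expect_identical(sort(diff(sort(ranks))), rep(1L, 2))  # adjacent
  expect_identical(nrow(gen$truth$pairs), 2L)
  expect_true(all(gen$truth$pairs$syn == 3L))
})

test_that("a pure type-2 mix yields only type-2 truth", {
  cfg <- generator_config(seed = 2, n_chromosomes = 1,
                          chrom_length_bp = 30000, n_ltp_genes = 8,
                          type_mix = c(type1 = 0, type2 = 1, typeC = 0,
                                       typeD = 0, typeG = 0),
                          tandem_array_spec = list())
  gen <- generate_genome(cfg)
  expect_true(all(gen$truth$genes$type == "type2"))
})

test_that("realized type counts respect the configured mix", {
  # aggregate singleton draws across seeds; compare each type's count to
  # its 99.9% binomial band under the default wheat mix
  counts <- c(type1 = 0, type2 = 0, typeC = 0, typeD = 0, typeG = 0)
  n_seeds <- 30
  cfg0 <- generator_config()
  n_single <- cfg0$n_ltp_genes -
    sum(vapply(cfg0$tandem_array_spec, `[[`, numeric(1), "size"))
  for (s in seq_len(n_seeds)) {
    gen <- generate_genome(generator_config(seed = 1000 + s))
    tab <- table(gen$truth$genes$type)
    for (nm in names(tab)) counts[nm] <- counts[nm] + tab[[nm]]
  }
  counts["type2"] <- counts["type2"] -
    n_seeds * sum(vapply(cfg0$tandem_array_spec, `[[`, numeric(1),
                         "size"))
  total <- n_seeds * n_single
  for (nm in names(counts)) {
    p <- cfg0$type_mix[[nm]]
    lo <- stats::qbinom(5e-4, total, p)
    hi <- stats::qbinom(1 - 5e-4, total, p)
    expect_gte(counts[[nm]], lo)
    expect_lte(counts[[nm]], hi)
  }
})

test_that("expression truth flags match the planted construction", {
  ex <- generate_expression_matrix(expression_config(), seed = 5)
  anther <- ex$sample_map$sample[ex$sample_map$tissue == "anther"]
  for (i in which(ex$truth$anther_enriched)) {
    g <- ex$truth$gene[i]
    expect_gt(mean(ex$fpkm[g, anther]),
              4 * max(ex$fpkm[g, setdiff(colnames(ex$fpkm), anther)]))
  }
  for (i in which(ex$truth$not_expressed))
    expect_true(all(ex$fpkm[ex$truth$gene[i], ] == 0))
  expect_error(generate_expression_matrix(
    expression_config(tissues = c("leaf", "root"))), "anther")
})

test_that("promoter planting respects frequencies and exchangeability", {
  all_in <- generate_promoter_sets(
    promoter_config(pos_freq = 1, n_pos = 10, n_neg = 5, length = 150),
    seed = 8)
  expect_true(all(scan_motif(all_in$pos, "AGAAA") >= 1))
  expect_error(promoter_config(motif = "AGRAA"), "only A, C, G, T")
  # equal frequencies -> the two sets are exchangeable: pooled counts from
  # both labels come from one distribution
  pos_counts <- integer(0); neg_counts <- integer(0)
  for (s in 1:15) {
    pp <- generate_promoter_sets(
      promoter_config(pos_freq = 0.5, neg_freq = 0.5, n_pos = 10,
                      n_neg = 10, length = 300), seed = 100 + s)
    pos_counts <- c(pos_counts, scan_motif(pp$pos, "AGAAA"))
    neg_counts <- c(neg_counts, scan_motif(pp$neg, "AGAAA"))
  }
  p <- suppressWarnings(stats::ks.test(pos_counts, neg_counts)$p.value)
  expect_gt(p, 0.01)
})
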