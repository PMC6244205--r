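test_that("CDS alignment reports coverage, identity and codon pairs", {
  cds <- random_cds(100)
  al <- align_cds_pair(cds, cds)
  expect_equal(al$coverage, 1.0)
  expect_equal(al$identity, 1.0)
  expect_identical(nrow(al$codon_pairs), 100L)
  expect_error(align_cds_pair("", cds), "empty")
  # planted substitutions, gap-free: identity = 1 - edits/length
  set.seed(51)
  for (rep in 1:5) {
    base <- random_cds(80)
    s <- sample(1:5, 1); n <- sample(1:4, 1)
    mut <- mutate_cds_controlled(base, s, n, seed = rep)
    al <- align_cds_pair(base, mut)
    expect_equal(al$identity, 1 - (s + n) / nchar(base))
    expect_equal(al$coverage, 1.0)
  }
})

test_that("the 80/80 rule uses >= coverage and strictly > identity", {
  expect_true(is_homologous_pair(0.95, 0.90))
  expect_false(is_homologous_pair(0.95, 0.80))  # "above 80%" is strict
  expect_false(is_homologous_pair(0.79, 0.99))
  expect_true(is_homologous_pair(0.80, 0.801))
})

test_that("pairs without a shared seed word are rejected cheaply", {
  a <- strrep("ATGGCC", 20)
  b <- strrep("CCGTTA", 20)
  hk <- homology_kaks_table(c(x = a, y = b))
  expect_false(hk$pairs$homologous[1])
  expect_true(is.na(hk$pairs$coverage[1]))
})

test_that("tandem clusters chain adjacent homologous genes per chromosome", {
  genes <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                      chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
                      start = c(100, 500, 900, 5000, 100),
                      stringsAsFactors = FALSE)
  pairs <- data.frame(gene_a = c("a", "b", "a"),
                      gene_b = c("b", "c", "e"),
                      stringsAsFactors = FALSE)
  cl <- find_tandem_clusters(genes, pairs)
  expect_length(cl, 1L)  # a-b-c chained; a-e crosses chromosomes
  expect_identical(cl[[1]]$members, c("a", "b", "c"))
  # non-adjacent homologues join only when intervening genes are allowed
  pairs2 <- data.frame(gene_a = "c", gene_b = "d",  # one gene apart? no:
                       stringsAsFactors = FALSE)    # ranks 3 and 4, adjacent
  cl2 <- find_tandem_clusters(genes, rbind(pairs, pairs2))
  expect_identical(cl2[[1]]$members, c("a", "b", "c", "d"))
  skip_pairs <- data.frame(gene_a = "a", gene_b = "c",
                           stringsAsFactors = FALSE)
  expect_length(find_tandem_clusters(genes, skip_pairs,
                                     max_intervening = 0L), 0L)
  cl3 <- find_tandem_clusters(genes, skip_pairs, max_intervening = 1L)
  expect_identical(cl3[[1]]$members, c("a", "c"))
  # partition: no gene in two clusters
  all_members <- unlist(lapply(cl2, `[[`, "members"))
  expect_identical(anyDuplicated(all_members), 0L)
})

test_that("NG86 reproduces the hand-computed single-change example", {
  a <- strrep("AAA", 10)
  b <- paste0(strrep("AAA", 9), "AAG")
  k <- ng86_kaks(a, b)
  expect_equal(k$s_sites, 10 / 3)
  expect_equal(k$ps, 0.3)
  expect_equal(k$ks, -0.75 * log(0.6))
  expect_equal(k$ka, 0)
  expect_true(is.na(ng86_kaks(a, a)$ratio))  # Ks = 0 -> undefined ratio
  expect_identical(ng86_kaks(a, a)$sd + ng86_kaks(a, a)$nd, 0)
})

test_that("NG86 is symmetric and averages multi-hit pathways", {
  set.seed(67)
  for (rep in 1:5) {
    x <- random_cds(40)
    y <- mutate_cds_controlled(x, 3, 2, seed = rep)
    kxy <- ng86_kaks(x, y)
    kyx <- ng86_kaks(y, x)
    expect_equal(kxy$ks, kyx$ks)
    expect_equal(kxy$ka, kyx$ka)
    expect_equal(kxy$sd, 3)
    expect_equal(kxy$nd, 2)
  }
  # a two-hit codon: AAA vs GGA averages over both orders
  k2 <- ng86_kaks("AAA", "GGA")
  expect_equal(k2$sd + k2$nd, 2)
})

test_that("saturation flags replace uncorrectable proportions", {
  # maximally diverged codons drive pn >= 3/4
  a <- strrep("AAA", 4)
  b <- strrep("GGG", 4)
  k <- suppressWarnings(ng86_kaks(a, b))
  expect_true(k$saturated_ka)
  expect_true(is.na(k$ka))
})

test_that("divergence dating is the closed form T = Ks/2r", {
  expect_equal(divergence_time_mya(0), 0)
  expect_equal(divergence_time_mya(0.7007), 53.9, tolerance = 1e-3)
  expect_equal(divergence_time_mya(0.013), 1.0, tolerance = 1e-9)
  expect_error(divergence_time_mya(-0.1), "non-negative")
  # linear in Ks, inversely linear in r
  expect_equal(divergence_time_mya(0.2), 2 * divergence_time_mya(0.1))
  expect_equal(divergence_time_mya(0.2, r = 1.3e-8),
               divergence_time_mya(0.2) / 2)
})

test_that("synthetic tandem arrays are recovered exactly", {
  gen <- generate_genome(small_config(seed = 18))
  built <- build_ltp_records(gen$genome, gen$models, gen$annotations)
  hk <- homology_kaks_table(built$cds)
  clusters <- find_tandem_clusters(
    built$records[, c("gene_id", "chrom", "start")],
    hk$pairs[hk$pairs$homologous, ])
  expect_length(clusters, length(gen$truth$clusters))
  expect_setequal(
    vapply(clusters, function(x) paste(sort(x$members), collapse = ","),
           character(1)),
    vapply(gen$truth$clusters, function(x)
      paste(sort(x$members), collapse = ","), character(1)))
  # planted change counts come back as uncorrected differences
  for (i in seq_len(nrow(gen$truth$pairs))) {
    tp <- gen$truth$pairs[i, ]
    row <- hk$kaks[(hk$kaks$gene_a == tp$gene_a &
                      hk$kaks$gene_b == tp$gene_b) |
                     (hk$kaks$gene_a == tp$gene_b &
                        hk$kaks$gene_b == tp$gene_a), ]
    expect_identical(nrow(row), 1L)
    expect_equal(row$sd, tp$syn)
    expect_equal(row$nd, tp$nonsyn)
  }
})
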