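test_that("GFF3 coordinates convert to 0-based half-open and back", {
  gff <- c("##gff-version 3",
           "chr1\tsrc\tgene\t101\t300\t.\t+\t.\tID=g1",
           "chr1\tsrc\tmRNA\t101\t300\t.\t+\t.\tID=m1;Parent=g1",
           "chr1\tsrc\texon\t101\t200\t.\t+\t.\tID=m1.e1;Parent=m1",
           "chr1\tsrc\texon\t261\t289\t.\t+\t.\tID=m1.e2;Parent=m1",
           "chr1\tsrc\tCDS\t101\t200\t.\t+\t.\tID=m1.c1;Parent=m1",
           "chr1\tsrc\tCDS\t261\t289\t.\t+\t.\tID=m1.c2;Parent=m1")
  models <- parse_gff3_gene_models(gff)
  expect_length(models, 1L)
  m <- models[[1]]
  expect_identical(m$exons[1, ], c(start = 100L, end = 200L))
  expect_identical(m$exons[2, ], c(start = 260L, end = 289L))
  introns <- gene_introns(m)
  expect_identical(introns[1, ], c(start = 200L, end = 260L))
  rt <- parse_gff3_gene_models(write_gff3_gene_models(models))
  expect_identical(rt[[1]]$exons, m$exons)
  expect_identical(rt[[1]]$cds_exons, m$cds_exons)
})

test_that("two-exon gene at 1..30 and 61..90 has one internal intron", {
  gff <- c("chrX\ts\tmRNA\t1\t90\t.\t+\t.\tID=t1",
           "chrX\ts\texon\t1\t30\t.\t+\t.\tID=e1;Parent=t1",
           "chrX\ts\texon\t61\t90\t.\t+\t.\tID=e2;Parent=t1",
           "chrX\ts\tCDS\t1\t30\t.\t+\t.\tID=c1;Parent=t1",
           "chrX\ts\tCDS\t61\t90\t.\t+\t.\tID=c2;Parent=t1")
  m <- parse_gff3_gene_models(gff)[[1]]
  expect_identical(unname(gene_introns(m)[1, ]), c(30L, 60L))
})

test_that("malformed hierarchy and frameshifted CDS are handled", {
  orphan <- c("chr1\ts\tmRNA\t1\t90\t.\t+\t.\tID=t1",
              "chr1\ts\tCDS\t1\t30\t.\t+\t.\tID=c1;Parent=ghost")
  expect_error(parse_gff3_gene_models(orphan), "line 2")
  badlen <- c("chr1\ts\tmRNA\t1\t10\t.\t+\t.\tID=t1",
              "chr1\ts\texon\t1\t10\t.\t+\t.\tID=e1;Parent=t1",
              "chr1\ts\tCDS\t1\t10\t.\t+\t.\tID=c1;Parent=t1")
  expect_warning(out <- parse_gff3_gene_models(badlen),
                 "divisible by 3")
  expect_length(out, 0L)
})

test_that("synthetic GFF3 round-trips to identical gene models", {
  gen <- generate_genome(small_config(seed = 3L))
  models2 <- parse_gff3_gene_models(gen$gff3)
  expect_identical(length(models2), length(gen$models))
  for (id in names(gen$models)) {
    expect_identical(models2[[id]]$exons, gen$models[[id]]$exons)
    expect_identical(models2[[id]]$cds_exons, gen$models[[id]]$cds_exons)
    expect_identical(models2[[id]]$strand, gen$models[[id]]$strand)
    expect_identical(models2[[id]]$chrom, gen$models[[id]]$chrom)
  }
})

test_that("six-frame translation follows the standard code", {
  tr <- six_frame_translate("ATGAAATGA")
  expect_identical(tr[["+1"]], "MK*")
  expect_identical(tr[["-1"]], "SFH")
  expect_identical(translate_dna("GGNAAA"), "XK")  # N in a codon -> X
})

test_that("six-frame translation matches a per-codon oracle", {
  set.seed(71)
  for (rep in 1:5) {
    s <- random_dna(300)
    tr <- six_frame_translate(s)
    rc <- oracle_revcomp(s)
    expect_identical(tr[["+1"]], oracle_translate(s))
    expect_identical(tr[["+2"]], oracle_translate(substr(s, 2, 300)))
    expect_identical(tr[["+3"]], oracle_translate(substr(s, 3, 300)))
    expect_identical(tr[["-1"]], oracle_translate(rc))
    expect_identical(tr[["-2"]], oracle_translate(substr(rc, 2, 300)))
    # frame symmetry: -k of s equals +k of revcomp(s)
    expect_identical(six_frame_translate(rc)[c("+1", "+2", "+3")],
                     stats::setNames(tr[c("-1", "-2", "-3")],
                                     c("+1", "+2", "+3")))
  }
})

test_that("spliced CDS extraction honours strand and exon structure", {
  genome <- c(chr1 = "ATGGCCTAA")
  plus <- gene_model("gp", "chr1", "+", cbind(0L, 9L))
  minus <- gene_model("gm", "chr1", "-", cbind(0L, 9L))
  expect_identical(extract_spliced_cds(plus, genome), "ATGGCCTAA")
  expect_identical(extract_spliced_cds(minus, genome), "TTAGGCCAT")
  out_of_bounds <- gene_model("gb", "chr1", "+", cbind(3L, 12L))
  expect_error(extract_spliced_cds(out_of_bounds, genome), "bounds")
})

test_that("planted genes give back the generator's stored CDS", {
  gen <- generate_genome(small_config(seed = 9L))
  tr <- gen$truth$genes
  for (i in seq_len(nrow(tr))) {
    model <- gen$models[[tr$gene_id[i]]]
    cds <- extract_spliced_cds(model, gen$genome)
    expect_identical(cds, tr$cds[i])
    expect_identical(nchar(cds),
                     sum(model$cds_exons[, 2] - model$cds_exons[, 1]))
  }
})

test_that("chromosome map export produces sorted BED6 and densities", {
  recs <- data.frame(
    gene_id = c("g3", "g1", "g2"), chrom = "chr1",
    start = c(250e6, 10e6, 20e6), end = c(250.1e6, 10.1e6, 20.1e6),
    strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  out <- export_chromosome_map(recs, c(chr1 = 300e6))
  expect_identical(length(out$bed), 3L)
  expect_match(out$bed[1], "^chr1\t10000000\t")
  expect_equal(out$density$genes_per_mbp, 3 / 300)  # 1 gene / 100 Mbp
  # round-trip through a BED parser
  parsed <- read.delim(text = paste(out$bed, collapse = "\n"),
                       header = FALSE)
  expect_identical(as.integer(parsed$V2), c(10000000L, 20000000L,
                                            250000000L))
  empty <- export_chromosome_map(recs[0, ])
  expect_length(empty$bed, 0L)
  expect_identical(nrow(empty$density), 0L)
  recs$chrom[2] <- NA
  expect_warning(skipped <- export_chromosome_map(recs),
                 "without a physical location")
  expect_length(skipped$bed, 2L)
})

test_that("sequence records validate alphabets and FASTA round-trips", {
  expect_error(seq_record("x", "ATGB", "dna"), "invalid dna")
  expect_error(seq_record("x", "MKV#", "protein"), "invalid protein")
  expect_identical(seq_record("x", "atgn", "dna")$residues, "ATGN")
  expect_error(seq_record("x", "", "dna"), "non-empty")
  seqs <- c(a = strrep("ACGT", 40), b = "TTTTAAAA")
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, path)
  expect_identical(read_fasta(path, "dna"), seqs)
})
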