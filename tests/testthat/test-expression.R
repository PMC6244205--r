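make_profiles <- function() {
  # three groups peaked in different tissues, plus noise
  tissues <- c("leaf", "root", "anther")
  samples <- paste0(rep(tissues, each = 2), "_S", 1:2)
  map <- data.frame(sample = samples,
                    tissue = rep(tissues, each = 2),
                    stage = "S1", stringsAsFactors = FALSE)
  list(samples = samples, map = map)
}

test_that("log transform is the stated pseudocount transform", {
  m <- matrix(c(0, 7, 15, 1), 2, dimnames = list(c("a", "b"), NULL))
  lt <- log_transform(m)
  expect_equal(unname(lt["a", 1]), 0)
  expect_equal(unname(lt["a", 2]), 4)   # log2(16)
  expect_equal(unname(log_transform(matrix(7, 1, 1,
                                           dimnames = list("g",
                                                           NULL)))[1, 1]),
               3)
  expect_error(log_transform(matrix(-1, 1, 1)), "non-negative")
  # monotone: column ordering preserved
  col <- matrix(runif(10, 0, 50), 10, 1, dimnames = list(letters[1:10],
                                                         NULL))
  expect_identical(order(log_transform(col)[, 1]), order(col[, 1]))
})

test_that("identical within-group profiles are recovered exactly", {
  p <- make_profiles()
  prof1 <- c(10, 10, 1, 1, 1, 1)
  prof2 <- c(1, 1, 1, 1, 12, 12)
  m <- rbind(g1 = prof1, g2 = prof1, g3 = prof1,
             g4 = prof2, g5 = prof2)
  colnames(m) <- p$samples
  cl <- hierarchical_cluster_genes(log_transform(m), k = 2)
  a <- cl$assignment
  expect_identical(length(unique(a[c("g1", "g2", "g3")])), 1L)
  expect_identical(length(unique(a[c("g4", "g5")])), 1L)
  expect_false(a[["g1"]] == a[["g4"]])
  # duplicate rows always share a cluster
  expect_identical(a[["g1"]], a[["g2"]])
  expect_error(hierarchical_cluster_genes(log_transform(m), k = 1),
               "at least 2")
})

test_that("cluster assignment ignores input row order and rescaling", {
  set.seed(37)
  p <- make_profiles()
  m <- matrix(rlnorm(60, 2, 1), 10, 6,
              dimnames = list(sprintf("g%02d", 1:10), p$samples))
  m[1:4, 1:2] <- m[1:4, 1:2] * 40
  m[5:8, 5:6] <- m[5:8, 5:6] * 40
  a1 <- hierarchical_cluster_genes(log_transform(m), k = 3)$assignment
  a2 <- hierarchical_cluster_genes(log_transform(m[sample(10), ]),
                                   k = 3)$assignment
  expect_identical(a1, a2[names(a1)])
  # per-gene constant scaling leaves correlation-distance clusters alone
  scaled <- m * matrix(runif(10, 0.5, 2), 10, 6)
  a3 <- hierarchical_cluster_genes(log_transform(scaled),
                                   k = 3)$assignment
  expect_identical(a1, a3)
})

test_that("constant-profile genes fall back to the nearest centroid", {
  p <- make_profiles()
  m <- rbind(g1 = c(64, 64, 1, 1, 1, 1), g2 = c(60, 66, 1, 1, 1, 1),
             g3 = c(1, 1, 1, 1, 70, 72), g4 = c(1, 1, 1, 1, 80, 60),
             flat = c(50, 50, 50, 50, 50, 50))
  colnames(m) <- p$samples
  cl <- hierarchical_cluster_genes(log_transform(m), k = 2)
  expect_identical(length(cl$assignment), 5L)
  expect_true(cl$assignment[["flat"]] %in% 1:2)
})

test_that("planted cluster structure is recovered with high agreement", {
  skip_if_not_installed("mclust")
  p <- make_profiles()
  aris <- numeric(20)
  for (s in 1:20) {
    set.seed(s)
    truth <- rep(1:3, each = 8)
    m <- matrix(rlnorm(24 * 6, 1, 0.4), 24, 6,
                dimnames = list(sprintf("g%02d", 1:24), p$samples))
    for (i in 1:24) {
      peak_cols <- switch(truth[i], 1:2, 3:4, 5:6)
      m[i, peak_cols] <- m[i, peak_cols] * 50
    }
    a <- hierarchical_cluster_genes(log_transform(m), k = 3)$assignment
    aris[s] <- mclust::adjustedRandIndex(a[rownames(m)], truth)
  }
  expect_gte(mean(aris), 0.9)
})

test_that("anther-enrichment calls follow the min-FPKM and fold rules", {
  p <- make_profiles()
  m <- rbind(hit = c(2, 2, 2, 2, 80, 80),
             flat = c(10, 10, 10, 10, 10, 10),
             silent = c(0, 0, 0.2, 0, 0, 0),
             low = c(0.1, 0.1, 0.1, 0.1, 1.5, 1.9))
  colnames(m) <- p$samples
  calls <- call_tissue_enriched(m, p$map)
  expect_identical(calls$status[calls$gene == "hit"], "anther_enriched")
  expect_identical(calls$status[calls$gene == "flat"], "other")
  expect_identical(calls$status[calls$gene == "silent"], "not_expressed")
  expect_identical(calls$status[calls$gene == "low"], "other")
  expect_equal(calls$fold_change[calls$gene == "hit"], 40)
  expect_error(call_tissue_enriched(m, p$map, tissue = "petal"),
               "not present")
  # the not-expressed threshold flips membership exactly at max_fpkm
  expect_identical(call_not_expressed(m), "silent")
  expect_identical(call_not_expressed(m, max_fpkm = 0.2), character(0))
  expect_setequal(call_not_expressed(m, max_fpkm = 2),
                  c("silent", "low"))
  # enrichment and silence are disjoint when min_fpkm > max_fpkm
  expect_false(any(calls$status == "anther_enriched" &
                     calls$gene %in% call_not_expressed(m)))
})

test_that("planted enrichment flags are recovered across seeds", {
  tp <- fp <- fn <- tn <- 0
  for (s in 1:10) {
    ex <- generate_expression_matrix(expression_config(), seed = 600 + s)
    called <- call_tissue_enriched(ex$fpkm, ex$sample_map)$status ==
      "anther_enriched"
    truth <- ex$truth$anther_enriched
    tp <- tp + sum(called & truth); fn <- fn + sum(!called & truth)
    fp <- fp + sum(called & !truth); tn <- tn + sum(!called & !truth)
  }
  expect_gte(tp / (tp + fn), 0.95)
  expect_gte(tn / (tn + fp), 0.95)
})
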