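test_that("aggregate_cells: identity, additivity and overlap rejection", {
  counts <- matrix(1:12, nrow = 3,
                   dimnames = list(paste0("pk", 1:3), paste0("c", 1:4)))
  emb <- cbind(c(0, 10, 20, 30), 0)
  expect_error(aggregate_cells(counts, emb, k = 5), "exceeds")

  # k = 1: every bin is a single cell's counts
  a1 <- aggregate_cells(counts, emb, k = 1, seed = 3)
  expect_identical(nrow(a1$bins), 4L)
  for (i in seq_along(a1$members))
    expect_equal(unname(a1$bins[i, ]),
                 unname(counts[, a1$members[[i]]]))

  # duplicate cells, k = 2: bin counts double the single-cell counts
  counts2 <- counts[, c(1, 1, 2, 2)]
  emb2 <- cbind(c(0, 0.001, 50, 50.001), 0)
  a2 <- aggregate_cells(counts2, emb2, k = 2, seed = 3)
  for (i in seq_along(a2$members)) {
    cells <- a2$members[[i]]
    expect_equal(unname(a2$bins[i, ]), unname(2 * counts2[, cells[1]]))
  }
  # two identical seeds -> one bin kept (100% shared membership)
  expect_lte(nrow(a2$bins), 2L)
})

test_that("penalty -> 0 partial correlations match the dense inverse oracle", {
  set.seed(51)
  p <- 6
  X <- matrix(rnorm(400 * p), 400, p)
  X[, 2] <- X[, 1] * 0.6 + rnorm(400, 0, 0.8)
  X[, 5] <- X[, 4] * -0.5 + rnorm(400, 0, 0.9)
  peaks <- data.table::data.table(
    peak_id = paste0("pk", 1:p), chrom = "chr1",
    start = seq(0L, by = 50000L, length.out = p),
    end = seq(500L, by = 50000L, length.out = p))
  bins <- X - min(X) + 0.1    # make counts-like, totals vary
  colnames(bins) <- peaks$peak_id
  sc <- coaccessibility_scores(bins, peaks, window_bp = 1e6, penalty = 0)
  # oracle: dense inverse covariance (below sf_min_peaks no size factors
  # are estimated, so the input enters the window as-is)
  S <- cor(bins)
  Theta <- solve(S)
  d <- sqrt(diag(Theta))
  parcor <- -Theta / outer(d, d)
  for (i in 1:(p - 1)) for (j in (i + 1):p) {
    got <- sc[peak_a == paste0("pk", i) & peak_b == paste0("pk", j), score]
    expect_equal(got, parcor[i, j], tolerance = 1e-3)
  }
})

test_that("coaccessibility scores are symmetric, bounded, near zero on null", {
  set.seed(53)
  p <- 8
  bins <- matrix(rpois(500 * p, 10), 500, p)
  peaks <- data.table::data.table(
    peak_id = paste0("pk", 1:p), chrom = "chr1",
    start = seq(0L, by = 60000L, length.out = p),
    end = seq(500L, by = 60000L, length.out = p))
  colnames(bins) <- peaks$peak_id
  sc <- coaccessibility_scores(bins, peaks, penalty = 1.5)
  expect_true(all(abs(sc$score) <= 1))
  expect_lt(max(abs(sc$score)), 0.05)
  # pair ordering canonical: peak_a < peak_b, each unordered pair once
  expect_identical(anyDuplicated(sc[, .(peak_a, peak_b)]), 0L)
  expect_true(all(sc$peak_a < sc$peak_b))
})

test_that("filter_links applies the score, distance and replication gates", {
  scores <- data.table::data.table(
    peak_a = c("p1", "p3", "p5", "p7"),
    peak_b = c("p2", "p4", "p6", "p8"),
    score = c(0.9, 0.06, 0.06, 0.04),
    distance = c(5000, 50000, 50000, 50000))
  ps <- lapply(1:10, function(i) {
    data.table::data.table(peak_a = c("p3", "p5"), peak_b = c("p4", "p6"),
                           score = c(if (i <= 3) 0.06 else 0.01, 0.06),
                           distance = 50000)
  })
  links <- filter_links(scores, ps, threshold = 0.05,
                        min_distance = 10000, min_replication = 4)
  key <- paste(links$peak_a, links$peak_b)
  expect_false("p1 p2" %in% key)  # 5 kb: below min distance despite 0.9
  expect_false("p3 p4" %in% key)  # replicated in only 3 samples
  expect_true("p5 p6" %in% key)   # all gates pass
  expect_false("p7 p8" %in% key)  # pooled score below threshold
  expect_true(all(links$distance > 10000))
})

test_that("annotate_promoters uses the 2 kb TSS window", {
  peaks <- data.table::data.table(
    peak_id = c("pkA", "pkB", "pkC"), chrom = "chr1",
    start = c(1000L, 60000L, 98500L), end = c(1400L, 60500L, 99000L))
  tss <- data.table::data.table(
    gene_id = c("g1", "g2"), chrom = "chr1", pos = c(2900L, 100000L))
  ann <- annotate_promoters(peaks, tss, window = 2000)
  # pkA's edge is 1.5 kb from g1 -> promoter
  expect_identical(ann[peak_id == "pkA", class], "promoter")
  expect_identical(ann[peak_id == "pkA", genes], "g1")
  expect_identical(ann[peak_id == "pkB", class], "distal")
  expect_identical(ann[peak_id == "pkC", class], "promoter")
  # a peak overlapping two TSS windows carries both genes
  tss2 <- rbind(tss, data.table::data.table(gene_id = "g3", chrom = "chr1",
                                            pos = 1100L))
  ann2 <- annotate_promoters(peaks, tss2)
  expect_setequal(strsplit(ann2[peak_id == "pkA", genes], ",")[[1]],
                  c("g1", "g3"))
  bad <- data.table::copy(peaks)[1, start := 2000L][1, end := 1000L]
  expect_error(annotate_promoters(bad, tss), "malformed")
})

test_that("link_caqtls_to_promoters classifies the four cases", {
  ann <- data.table::data.table(
    peak_id = c("prom1", "prom2", "dist1", "dist2", "dist3"),
    class = c("promoter", "promoter", "distal", "distal", "distal"),
    genes = c("g1", "g2", "", "", ""))
  links <- data.table::data.table(
    peak_a = c("dist1", "prom1"), peak_b = c("prom1", "prom2"))
  caqtls <- data.table::data.table(
    peak_id = c("prom1", "dist1", "dist2", "prom2"),
    variant_id = paste0("v", 1:4),
    significant = c(TRUE, TRUE, TRUE, TRUE))
  cls <- link_caqtls_to_promoters(caqtls, links, ann)
  expect_identical(cls[peak_id == "dist1", class], "distal-linked")
  expect_identical(cls[peak_id == "dist1", n_promoters], 1L)
  expect_identical(cls[peak_id == "dist2", class], "unlinked")
  expect_identical(cls[peak_id == "prom1", class], "promoter-promoter-linked")
  expect_identical(cls[peak_id == "prom2", class], "promoter-promoter-linked")
  # promoter caQTL with no links at all -> promoter-direct
  cls2 <- link_caqtls_to_promoters(caqtls[1], links[0], ann)
  expect_identical(cls2$class, "promoter-direct")
})

test_that("interaction_overlap_enrichment computes the Fisher table", {
  # table [[30,70],[10,190]] -> OR = (30*190)/(70*10) = 8.14 (sample OR)
  expect_equal((30 * 190) / (70 * 10), 8.142857, tolerance = 1e-6)
  peaks <- data.table::data.table(
    peak_id = paste0("pk", 1:6), chrom = "chr1",
    start = seq(0L, by = 50000L, length.out = 6),
    end = seq(1000L, by = 50000L, length.out = 6))
  loops <- data.table::data.table(
    chrom_a = "chr1", start_a = 0L, end_a = 1000L,
    chrom_b = "chr1", start_b = 50000L, end_b = 51000L)
  pairs <- data.table::data.table(
    peak_a = c("pk1", "pk1", "pk3"), peak_b = c("pk2", "pk3", "pk4"),
    linked = c(TRUE, FALSE, TRUE))
  res <- interaction_overlap_enrichment(pairs, peaks, loops)
  expect_true(res$evaluable)
  expect_true(is.finite(res$odds_ratio))
  # zero candidates -> not evaluable
  far <- data.table::copy(loops)[, `:=`(chrom_a = "chr9", chrom_b = "chr9")]
  res0 <- interaction_overlap_enrichment(pairs, peaks, far)
  expect_false(res0$evaluable)
})
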