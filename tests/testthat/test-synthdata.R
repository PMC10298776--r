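test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_samples = 1), "n_samples")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(pi_effect_range = c(0.5, 1.0)), "pi_effect_range")
  expect_error(sim_config(cell_types = c(A = 0.5, B = 0.6)), "sum to 1")
  expect_error(sim_config(frac_caqtl_peaks = 1.2), "frac_caqtl_peaks")
})

test_that("simulate_genotypes: determinism, LD structure, dosage domain", {
  cfg <- small_sim_config(seed = 7)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosage, g2$dosage)
  expect_true(all(g1$dosage %in% 0:2))
  # positions strictly increasing within chromosome
  ok <- g1$variants[, all(diff(pos) > 0), by = chrom]$V1
  expect_true(all(ok))
  expect_true(all(g1$variants$ref != g1$variants$alt))

  # within-block r2 is high, across-block r2 is low on a large cohort
  big <- simulate_genotypes(sim_config(seed = 2, n_samples = 400,
                                       n_variants = 120, n_peaks = 40,
                                       ld_block_size = 6))
  v <- big$variants
  r2_of <- function(i, j) cor(big$dosage[, i], big$dosage[, j])^2
  same_block <- 0; cross_block <- 0
  set.seed(1)
  for (k in 1:50) {
    blk <- sample(unique(v$block), 1)
    vi <- v[block == blk, variant_id]
    if (length(vi) >= 2) same_block <- same_block + r2_of(vi[1], vi[2]) / 50
    other <- v[block != blk & chrom == v[block == blk, chrom][1], variant_id]
    cross_block <- cross_block + r2_of(vi[1], other[length(other)]) / 50
  }
  expect_gt(same_block, 0.3)
  expect_lt(cross_block, 0.1)
})

test_that("ld_block_size = 1 gives independent variants", {
  cfg <- sim_config(seed = 3, n_samples = 500, n_variants = 60, n_peaks = 30,
                    ld_block_size = 1)
  g <- simulate_genotypes(cfg)
  set.seed(5)
  r2 <- replicate(100, {
    ij <- sample(ncol(g$dosage), 2)
    cor(g$dosage[, ij[1]], g$dosage[, ij[2]])^2
  })
  expect_lt(mean(r2, na.rm = TRUE), 0.02)
})

test_that("empirical MAF matches the recorded target at n = 500", {
  cfg <- sim_config(seed = 11, n_samples = 500, n_variants = 120,
                    n_peaks = 40)
  g <- simulate_genotypes(cfg)
  emp <- colMeans(g$dosage) / 2
  emp_maf <- pmin(emp, 1 - emp)
  tgt_maf <- pmin(g$variants$maf, 1 - g$variants$maf)
  expect_true(all(abs(emp_maf - tgt_maf) <= 0.05))
})

test_that("simulate_peak_counts: genotype-group mean ratio follows pi", {
  # pi = 0.75, g in {0, 2}: mean(g=2)/mean(g=0) = pi/(1-pi) = 3
  # oracle: plug into the mean formula, verify on 10,000 simulated samples
  n <- 10000
  set.seed(21)
  g <- rep(c(0, 2), each = n / 2)
  pi <- 0.75
  m <- (2 - g) * (1 - pi) + g * pi
  y <- rnbinom(n, size = 10, mu = 100 * m)
  ratio <- mean(y[g == 2]) / mean(y[g == 0])
  expect_lt(abs(ratio - 3) / 3, 0.05)

  # and the generator itself reproduces it through its planted truth
  cfg <- sim_config(seed = 4, n_samples = 300, n_peaks = 20, n_variants = 60,
                    frac_caqtl_peaks = 0.5, pi_effect_range = c(0.75, 0.75),
                    psi_range = c(0.5, 0.5), delta_range = c(0, 0),
                    shared_fraction = 1)
  gt <- simulate_genotypes(cfg)
  tr <- simulate_truth(gt, cfg)
  tn <- simulate_peak_counts(gt, tr, cfg)
  ca <- tr$caqtl[1]
  y <- tn[[1]]$totals[ca$peak_id, ] / tn[[1]]$offsets
  g <- gt$dosage[, ca$variant_id]
  expect_true(sum(g == 0) >= 20 && sum(g == 2) >= 20)
  ratio <- mean(y[g == 2]) / mean(y[g == 0])
  expect_lt(abs(log(ratio) - log(ca$pi / (1 - ca$pi))), log(1.35))
})

test_that("allelic counts: closed-form p and null case", {
  # p = pi(1-psi) / (pi(1-psi) + (1-pi)psi): pi=.5, psi=.2 -> 0.8
  p <- 0.5 * 0.8 / (0.5 * 0.8 + 0.5 * 0.2)
  expect_equal(p, 0.8)
  # null case: pi=.5, psi=.5, delta=0 -> alt fraction 0.5 at het samples
  cfg <- sim_config(seed = 8, n_samples = 50, n_peaks = 20, n_variants = 60,
                    frac_caqtl_peaks = 0, psi_range = c(0.5, 0.5),
                    delta_range = c(0, 0))
  gt <- simulate_genotypes(cfg)
  tr <- simulate_truth(gt, cfg)
  tn <- simulate_peak_counts(gt, tr, cfg)
  al <- tn[[1]]$allelic
  frac <- sum(al$alt_count) / sum(al$alt_count + al$ref_count)
  expect_lt(abs(frac - 0.5), 0.03)
  # allelic records only at het samples, depth bounded by totals
  tot_at <- tn[[1]]$totals[cbind(al$peak_id, al$sample)]
  expect_true(all(al$ref_count + al$alt_count <= tot_at))
  het_ok <- vapply(seq_len(nrow(al)), function(i)
    gt$dosage[al$sample[i], al$variant_id[i]] == 1L, TRUE)
  expect_true(all(het_ok))
})

test_that("generative model matches the fitted likelihood at truth", {
  # average log-likelihood at true parameters >= at perturbed pi (+-0.2)
  set.seed(31)
  diffs <- replicate(200, {
    pi0 <- runif(1, 0.35, 0.65)
    pk <- sim_one_peak(n = 10, depth = 300, pi = pi0)
    ll <- function(pi_) oracle_objective(
      pk$y, rep(1, 10), pk$g, pk$al$alt_count,
      pk$al$ref_count + pk$al$alt_count, pi_, 0.5, 0, 300, 0.1, 0.02)
    ll(pi0) - max(ll(min(pi0 + 0.2, 0.99)), ll(max(pi0 - 0.2, 0.01)))
  })
  expect_gt(mean(diffs), 0)
})

test_that("simulate_single_cells: module correlation and degenerate input", {
  cfg <- small_sim_config(seed = 6)
  gt <- simulate_genotypes(cfg)
  tr <- simulate_truth(gt, cfg)
  sc <- simulate_single_cells(tr, cfg)
  expect_identical(ncol(sc$counts), nrow(sc$cells))
  # two peaks of one module are positively correlated per cell
  mod <- tr$coaccess_modules[[1]]
  ct <- cor.test(sc$counts[mod[1], ], sc$counts[mod[2], ])
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
  # zero cells -> empty matrix, no error
  cfg0 <- small_sim_config(seed = 6)
  cfg0$n_cells_per_sample <- 0L
  sc0 <- simulate_single_cells(tr, cfg0)
  expect_identical(ncol(sc0$counts), 0L)
  # unknown peak in module -> error
  tr_bad <- tr
  tr_bad$coaccess_modules <- list(c(1L, nrow(tr$peaks) + 5L))
  expect_error(simulate_single_cells(tr_bad, cfg), "unknown peak")
})

test_that("simulate_gwas: LD-faithful marginals and SE model", {
  cfg <- sim_config(seed = 13, n_samples = 300)
  gt <- simulate_genotypes(cfg)
  tr <- simulate_truth(gt, cfg)
  gw <- simulate_gwas(gt, tr, cfg)
  expect_true(all(gw$stats$se > 0))
  # r = 1 variants carry beta ~= beta_c; r ~ 0 variants beta ~= 0
  sig <- tr$gwas[1]
  st <- gw$stats[signal_id == sig$signal_id]
  g_c <- gt$dosage[, sig$variant_id]
  r <- vapply(st$variant_id, function(v) cor(gt$dosage[, v], g_c), 0)
  hi <- which(abs(r) > 0.999)
  expect_true(all(abs(st$beta[hi] * sign(r[hi]) - sig$beta) <
                  4 * st$se[hi] + 1e-9))
  lo <- which(abs(r) < 0.05)
  if (length(lo) >= 5)
    expect_lt(median(abs(st$beta[lo])), 4 * median(st$se[lo]))
  # N quadrupled -> SE halves at fixed maf (closed form)
  se1 <- 1 / sqrt(2 * 10000 * 0.3 * 0.7)
  se4 <- 1 / sqrt(2 * 40000 * 0.3 * 0.7)
  expect_equal(se4, se1 / 2)
})

test_that("all generators are byte-reproducible under a fixed seed", {
  cfg <- small_sim_config(seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$tensor[[1]]$totals, b$tensor[[1]]$totals)
  expect_identical(a$tensor[[2]]$allelic, b$tensor[[2]]$allelic)
  expect_identical(a$sc$counts, b$sc$counts)
  expect_identical(a$gwas$stats, b$gwas$stats)
})
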