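# Cross-cell-type heterogeneity of caQTL effects: variance-stabilized
# normalization, nested interaction models, pairwise effect correlation,
# and Storey's pi1 sharing statistic.

#' Normalize a count tensor across cell types
#'
#' Builds a peaks x (sample, cell type) matrix, computes median-of-ratios
#' size factors (columns with no positive geometric-mean overlap fall back to
#' total-count ratios) and returns `log2(count / size_factor + 1)`.
#'
#' @param tensor a `peak_count_tensor`
#' @return list with `mat` (normalized matrix), `meta` (data.table: column,
#'   sample, cell_type), `size_factors`
#' @export
vst_normalize <- function(tensor) {
  cts <- names(tensor)
  mats <- lapply(cts, function(ct) tensor[[ct]]$totals)
  mat <- do.call(cbind, mats)
  stop_if(ncol(mat) < 2L, "need at least two columns to normalize")
  stop_if(all(mat == 0), "all-zero count matrix")
  meta <- rbindlist(lapply(cts, function(ct)
    data.table(sample = colnames(tensor[[ct]]$totals), cell_type = ct)))
  meta[, column := paste(sample, cell_type, sep = ".")]
  colnames(mat) <- meta$column

  log_geo <- rowMeans(log(mat + 0L))          # -Inf where any zero
  use <- is.finite(log_geo)
  sf <- if (any(use)) {
    apply(mat, 2, function(col)
      median(exp(log(col[use]) - log_geo[use]), na.rm = TRUE))
  } else rep(NA_real_, ncol(mat))
  bad <- !is.finite(sf) | sf <= 0
  if (any(bad)) {
    tot <- colSums(mat)
    if (all(bad)) sf <- tot / exp(mean(log(pmax(tot, 1))))
    else sf[bad] <- tot[bad] * mean(sf[!bad] / tot[!bad])
  }
  norm <- log2(sweep(mat, 2, sf, "/") + 1)
  list(mat = norm, meta = meta[, .(column, sample, cell_type)],
       size_factors = sf)
}

#' Test caQTL leads for cell-type-dependent effects
#'
#' For each peak-lead pair, fits linear models of normalized accessibility on
#' genotype, cell type and covariates, with and without a genotype x cell
#' type interaction, and compares them with a nested-model F test (ANOVA).
#' Benjamini-Hochberg FDR is applied across pairs.
#'
#' @param norm a [vst_normalize()] result
#' @param dosage sample x variant dosage matrix
#' @param pairs data.table(peak_id, variant_id) of leads to test
#' @param covariates optional data.frame of per-column covariates aligned
#'   with `norm$meta` (e.g. age, sex, genotype PCs, accessibility PCs)
#' @return data.table(peak_id, variant_id, f_stat, df1, df2, p, fdr)
#' @export
interaction_test <- function(norm, dosage, pairs, covariates = NULL) {
  meta <- norm$meta
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    pk <- pairs$peak_id[i]; vid <- pairs$variant_id[i]
    if (!pk %in% rownames(norm$mat) || !vid %in% colnames(dosage)) next
    df <- data.frame(value = norm$mat[pk, meta$column],
                     genotype = dosage[meta$sample, vid],
                     celltype = factor(meta$cell_type))
    if (!is.null(covariates)) df <- cbind(df, covariates)
    if (length(unique(df$genotype)) < 2L || nlevels(df$celltype) < 2L) next
    cov_terms <- if (is.null(covariates)) ""
                 else paste("+", paste(colnames(covariates), collapse = " + "))
    full <- try(lm(stats::as.formula(paste(
      "value ~ genotype * celltype", cov_terms)), data = df), silent = TRUE)
    red <- try(lm(stats::as.formula(paste(
      "value ~ genotype + celltype", cov_terms)), data = df), silent = TRUE)
    if (inherits(full, "try-error") || inherits(red, "try-error")) {
      warning("rank-deficient design for pair ", pk, "/", vid, "; skipped")
      next
    }
    a <- anova(red, full)
    out[[i]] <- data.table(peak_id = pk, variant_id = vid,
                           f_stat = a$F[2], df1 = a$Df[2],
                           df2 = a$Res.Df[2], p = a$`Pr(>F)`[2])
  }
  res <- rbindlist(out)
  if (nrow(res)) res[, fdr := bh_adjust(p)]
  res[]
}

#' Pairwise Spearman correlation of allelic effects across cell types
#'
#' For each pair of cell types, restricts to peak-variant pairs significant
#' in at least one of the two and correlates the allelic effects `pi_hat`.
#'
#' @param results_by_celltype named list of [map_caqtl()] result tables
#' @param min_shared minimum number of shared pairs (fewer gives NA)
#' @return symmetric matrix of Spearman correlations with unit diagonal
#' @export
effect_correlation <- function(results_by_celltype, min_shared = 3L) {
  cts <- names(results_by_celltype)
  m <- matrix(NA_real_, length(cts), length(cts), dimnames = list(cts, cts))
  diag(m) <- 1
  for (i in seq_along(cts)) for (j in seq_along(cts)) {
    if (j <= i) next
    a <- results_by_celltype[[i]]; b <- results_by_celltype[[j]]
    key_a <- paste(a$peak_id, a$variant_id)
    key_b <- paste(b$peak_id, b$variant_id)
    sig <- union(key_a[a$significant], key_b[b$significant])
    shared <- intersect(intersect(key_a, key_b), sig)
    if (length(shared) < min_shared) next
    r <- cor(a$pi_hat[match(shared, key_a)], b$pi_hat[match(shared, key_b)],
             method = "spearman")
    m[i, j] <- m[j, i] <- r
  }
  m
}

#' Storey's pi1 sharing statistic
#'
#' Estimates the proportion of true associations among replication p-values
#' as `1 - pi0`, with `pi0` from Storey's bootstrap method:
#' `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))` over the grid
#' lambda = 0.05, 0.10, ..., 0.95, selecting the lambda whose bootstrap mean
#' squared error against the grid minimum is smallest.
#'
#' @param p replication p-values of discovery-set associations
#' @param n_boot bootstrap rounds (default 100)
#' @param seed RNG seed
#' @return pi1 in \[0, 1\]
#' @export
pi1_sharing <- function(p, n_boot = 100L, seed = 1L) {
  stop_if(length(p) == 0L, "empty p-value vector")
  p <- p[is.finite(p)]
  m <- length(p)
  lambdas <- seq(0.05, 0.95, by = 0.05)
  pi0_of <- function(pv) {
    vapply(lambdas, function(l) sum(pv > l) / (length(pv) * (1 - l)), 0)
  }
  pi0s <- pi0_of(p)
  min_pi0 <- min(pi0s)
  set.seed(child_seed(seed, 211L))
  mse <- numeric(length(lambdas))
  for (b in seq_len(n_boot)) {
    pb <- sample(p, m, replace = TRUE)
    mse <- mse + (pi0_of(pb) - min_pi0)^2
  }
  pi0 <- pi0s[which.min(mse)]
  min(max(1 - pi0, 0), 1)
}
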