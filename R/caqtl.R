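# caQTL mapping: joint total-count (negative binomial) + allelic-count
# (beta binomial) cis-effect model, per-peak lead selection, and
# genotype-permutation empirical FDR.

#' Enumerate testable peak-variant pairs
#'
#' A pair is testable when the peak's mean total count across samples exceeds
#' 5 reads, the variant lies inside the peak itself or inside another peak
#' whose span intersects the tested peak extended by `window_bp`, and the
#' variant is heterozygous in at least two samples.
#'
#' @param tensor_ct one cell type's slot of a `peak_count_tensor`
#' @param genotypes a `cohort_genotypes`
#' @param peaks data.table of peak intervals (peak_id, chrom, start, end;
#'   0-based half-open)
#' @param window_bp cis window around the peak (default 10 kb)
#' @param min_mean minimum mean read count per sample (default 5, strict)
#' @param min_het minimum number of heterozygous samples (default 2)
#' @return data.table(peak_id, variant_id, n_het)
#' @export
filter_testable <- function(tensor_ct, genotypes, peaks, window_bp = 10000,
                            min_mean = 5, min_het = 2L) {
  if (nrow(peaks) == 0L || length(tensor_ct$totals) == 0L)
    return(data.table(peak_id = character(), variant_id = character(),
                      n_het = integer()))
  mean_count <- rowMeans(tensor_ct$totals)
  ok_peaks <- peaks[peak_id %in% names(mean_count)[mean_count > min_mean]]
  if (nrow(ok_peaks) == 0L)
    return(data.table(peak_id = character(), variant_id = character(),
                      n_het = integer()))
  v <- genotypes$variants
  n_het <- colSums(genotypes$dosage == 1L)
  v <- v[variant_id %in% names(n_het)[n_het >= min_het]]

  out <- vector("list", nrow(ok_peaks))
  for (i in seq_len(nrow(ok_peaks))) {
    pk <- ok_peaks[i]
    # peaks whose span intersects pk +/- window (same chromosome)
    near <- peaks[chrom == pk$chrom &
                  start < pk$end + window_bp &
                  end > pk$start - window_bp]
    vv <- v[chrom == pk$chrom & peak_id %in% near$peak_id]
    if (nrow(vv) == 0L) next
    out[[i]] <- data.table(peak_id = pk$peak_id, variant_id = vv$variant_id,
                           n_het = n_het[vv$variant_id])
  }
  res <- rbindlist(out)
  if (nrow(res) == 0L)
    res <- data.table(peak_id = character(), variant_id = character(),
                      n_het = integer())
  res[]
}

#' Fit the joint cis-effect model for one peak-variant pair
#'
#' Maximizes the penalized log-likelihood
#' \deqn{\sum_j \log NB(y_j; \mu_j, \phi) + \sum_{j \in het}
#'   \log BB(a_j; d_j, p', \theta) + \log prior(\psi, \partial)}
#' with \eqn{\mu_j = s_j \lambda e^{x_j'\gamma}[(2-g_j)(1-\pi)+g_j\pi]},
#' \eqn{p = \pi(1-\psi)/(\pi(1-\psi)+(1-\pi)\psi)} and
#' \eqn{p' = p(1-2\partial)+\partial}, by a bounded Brent profile over
#' \eqn{\pi \in [0.001, 0.999]} with inner coordinate ascent over nuisances.
#' The reference-bias prior Beta(`psi_prior`, `psi_prior`) and error prior
#' Beta(1, `delta_prior`) keep \eqn{\psi} and \eqn{\partial} identifiable
#' from a single variant's allelic counts.  The p-value is from the
#' likelihood-ratio statistic \eqn{2(L(\hat\pi) - L(\pi = 0.5))} against
#' chi-square with 1 df.
#'
#' @param totals integer vector of per-sample total counts for the peak
#' @param allelic data.table(sample, ref_count, alt_count) at het samples
#'   (may be empty)
#' @param dosage per-sample dosage in 0..2 at the candidate variant
#' @param offsets per-sample positive library-size factors
#' @param covariates optional sample x k matrix
#' @param pop_only drop the allelic (beta-binomial) component
#' @param psi_prior,delta_prior prior shape parameters (see details)
#' @return one-row data.table: pi_hat, psi_hat, delta_hat, lambda_hat,
#'   phi_hat, theta_hat, loglik, objective, lrt, lrt_p, converged
#' @export
fit_joint_model <- function(totals, allelic, dosage, offsets,
                            covariates = NULL, pop_only = FALSE,
                            psi_prior = 10, delta_prior = 19) {
  n <- length(totals)
  stop_if(any(offsets <= 0), "offsets must be positive")
  X <- covariates %||% matrix(0, n, 0)
  if (is.null(allelic) || nrow(allelic) == 0L) {
    a_alt <- numeric(0); d_tot <- numeric(0)
  } else {
    a_alt <- as.numeric(allelic$alt_count)
    d_tot <- as.numeric(allelic$ref_count + allelic$alt_count)
  }
  fit1 <- .cpp_fit_joint(as.numeric(totals), as.numeric(offsets),
                         as.numeric(dosage), X, a_alt, d_tot,
                         pop_only, NA_real_, TRUE, psi_prior, delta_prior)
  fit0 <- .cpp_fit_joint(as.numeric(totals), as.numeric(offsets),
                         as.numeric(dosage), X, a_alt, d_tot,
                         pop_only, 0.5, TRUE, psi_prior, delta_prior)
  lrt <- 2 * (fit1$objective - fit0$objective)
  converged <- TRUE
  if (!is.finite(lrt) || lrt < -1e-6) {
    converged <- FALSE
    lrt <- 0
    fit1 <- fit0
  }
  lrt <- max(lrt, 0)
  data.table(pi_hat = fit1$pi, psi_hat = fit1$psi, delta_hat = fit1$delta,
             lambda_hat = fit1$lambda, phi_hat = fit1$phi,
             theta_hat = fit1$theta, loglik = fit1$loglik,
             objective = fit1$objective, lrt = lrt,
             lrt_p = if (converged) pchisq(lrt, 1, lower.tail = FALSE) else 1,
             converged = converged)
}

#' Population-only cis model
#'
#' [fit_joint_model()] with the beta-binomial component dropped; only the
#' genotype effect on total counts is used.
#'
#' @inheritParams fit_joint_model
#' @export
fit_population_only <- function(totals, dosage, offsets, covariates = NULL) {
  fit_joint_model(totals, NULL, dosage, offsets, covariates,
                  pop_only = TRUE)
}

#' Within-peak multiplicity adjustment and lead selection
#'
#' Bonferroni over the number of variants tested in the peak:
#' `adj_p = min(1, lrt_p * m)`.  The lead is the variant with the smallest
#' adjusted p-value; ties are broken by smaller raw p-value, then by smaller
#' genomic position.
#'
#' @param peak_results data.table of fitted results for one peak, with
#'   columns lrt_p and pos
#' @return the input with `adj_p` and logical `lead` columns
#' @export
adjust_within_peak <- function(peak_results) {
  stop_if(nrow(peak_results) == 0L, "no tested variants for peak")
  m <- nrow(peak_results)
  res <- copy(peak_results)
  res[, adj_p := pmin(1, lrt_p * m)]
  ord <- order(res$adj_p, res$lrt_p, res$pos)
  res[, lead := FALSE]
  res[ord[1L], lead := TRUE]
  res[]
}

#' Empirical FDR from genotype-permuted reruns
#'
#' For threshold t taken over the observed q-values,
#' `FDR(t) = mean_k |{q in P_k : q <= t}| / max(1, |{q in R : q <= t}|)`;
#' the significance threshold is the largest observed q with
#' `FDR(t) <= alpha`.
#'
#' @param real_q q-values of observed lead associations
#' @param perm_q list of q-value vectors, one per permutation round
#' @param alpha target FDR (0.05, 0.10 or 0.20 are the conventional levels)
#' @return list(threshold, significant (logical), fdr_at (data.table))
#' @export
empirical_fdr <- function(real_q, perm_q, alpha = 0.10) {
  stop_if(length(perm_q) == 0L, "at least one permutation round is required")
  ts <- sort(unique(real_q))
  fdr <- vapply(ts, function(t) {
    mean(vapply(perm_q, function(p) sum(p <= t), 0)) /
      max(1, sum(real_q <= t))
  }, 0)
  ok <- ts[fdr <= alpha]
  threshold <- if (length(ok)) max(ok) else NA_real_
  sig <- if (is.na(threshold)) rep(FALSE, length(real_q))
         else real_q <= threshold
  list(threshold = threshold, significant = sig,
       fdr_at = data.table(t = ts, fdr = fdr))
}

#' Reference-bias / error-rate QC
#'
#' Flags fitted associations with reference allele mapping bias outside
#' \[0.2, 0.8\] or allele-assignment error above 0.1, which indicate
#' genotyping or mapping artifacts rather than true cis effects.
#'
#' @param results data.table with psi_hat, delta_hat
#' @return input with a logical `qc_pass` column
#' @export
qc_filter <- function(results) {
  res <- copy(results)
  res[, qc_pass := psi_hat >= 0.2 & psi_hat <= 0.8 & delta_hat <= 0.1]
  res[]
}

#' Genotype-class diagnostics of lead variants
#'
#' Classifies lead variants by the number of observed dosage classes in the
#' cohort (2 vs 3) and tests whether significant caQTLs are enriched in the
#' 3-class stratum by Fisher's exact test.
#'
#' @param results lead results with `significant` logical column
#' @param dosage sample x variant dosage matrix
#' @return list(table (2x2), odds_ratio, p, evaluable)
#' @export
genotype_class_diagnostics <- function(results, dosage) {
  n_class <- apply(dosage[, results$variant_id, drop = FALSE], 2,
                   function(x) length(unique(x)))
  keep <- n_class >= 2L
  res <- results[keep]
  cls <- factor(ifelse(n_class[keep] == 3L, "3-class", "2-class"),
                levels = c("3-class", "2-class"))
  sig <- factor(ifelse(res$significant, "sig", "nonsig"),
                levels = c("sig", "nonsig"))
  tab <- table(cls, sig)
  if (sum(tab[, "sig"]) == 0L || any(rowSums(tab) == 0L))
    return(list(table = tab, odds_ratio = NA_real_, p = NA_real_,
                evaluable = FALSE))
  ft <- fisher.test(tab)
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value,
       evaluable = TRUE)
}

fit_pairs <- function(pairs, tensor_ct, genotypes, dosage, covariates,
                      pop_only, min_allelic_depth = 1L) {
  v <- genotypes$variants
  pos_of <- setNames(v$pos, v$variant_id)
  al <- tensor_ct$allelic
  al_by_variant <- if (!pop_only && !is.null(al) && nrow(al) > 0L)
    split(al[ref_count + alt_count >= min_allelic_depth],
          by = "variant_id") else list()
  samples <- rownames(dosage)
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    pk <- pairs$peak_id[i]; vid <- pairs$variant_id[i]
    totals <- tensor_ct$totals[pk, ]
    g <- dosage[, vid]
    arec <- al_by_variant[[vid]]
    if (!is.null(arec))
      arec <- arec[sample %in% samples[g == 1L]]
    fit <- fit_joint_model(totals, arec, g, tensor_ct$offsets, covariates,
                           pop_only = pop_only)
    out[[i]] <- cbind(data.table(peak_id = pk, variant_id = vid,
                                 pos = pos_of[[vid]]),
                      fit)
  }
  rbindlist(out)
}

#' Map caQTLs for one cell type
#'
#' Full per-cell-type scan: testable-pair enumeration, joint (or
#' population-only) model fits, within-peak Bonferroni adjustment and lead
#' selection, Benjamini-Hochberg q-values over leads, genotype-permutation
#' empirical FDR, and psi/delta QC.
#'
#' Permutations shuffle the sample labels of the dosage matrix jointly across
#' all variants (preserving LD) and re-run the identical pipeline; the
#' empirical FDR compares observed lead q-values against the permuted ones.
#'
#' @param tensor a `peak_count_tensor`
#' @param genotypes a `cohort_genotypes`
#' @param cell_type name of the tensor slot to map
#' @param peaks peak intervals (defaults to `genotypes$peaks`)
#' @param window_bp cis window (default 10 kb)
#' @param fdr target empirical FDR (default 0.10)
#' @param n_perm number of genotype permutations (default 2)
#' @param pop_only drop the allelic component
#' @param covariates optional sample x k covariate matrix
#' @param seed RNG seed for the permutations
#' @return data.table of lead associations (one row per tested peak) with
#'   attributes `all_fits` (every tested pair) and `fdr` (threshold info)
#' @export
map_caqtl <- function(tensor, genotypes, cell_type, peaks = NULL,
                      window_bp = 10000, fdr = 0.10, n_perm = 2L,
                      pop_only = FALSE, covariates = NULL, seed = 1L) {
  peaks <- peaks %||% genotypes$peaks
  tensor_ct <- tensor[[cell_type]]
  stop_if(is.null(tensor_ct), paste("unknown cell type:", cell_type))
  pairs <- filter_testable(tensor_ct, genotypes, peaks, window_bp)
  if (nrow(pairs) == 0L)
    return(data.table())

  leads_of <- function(dosage) {
    fits <- fit_pairs(pairs, tensor_ct, genotypes, dosage, covariates,
                      pop_only)
    leads <- fits[, adjust_within_peak(.SD), by = peak_id][lead == TRUE]
    leads[, q := bh_adjust(adj_p)]
    list(leads = leads, fits = fits)
  }

  real <- leads_of(genotypes$dosage)
  # permuted leads are placed on the observed BH q scale (see bh_map)
  to_q <- bh_map(real$leads$adj_p)
  set.seed(child_seed(seed, 101L))
  perm_q <- lapply(seq_len(n_perm), function(k) {
    shuffle <- sample.int(nrow(genotypes$dosage))
    dperm <- genotypes$dosage[shuffle, , drop = FALSE]
    rownames(dperm) <- rownames(genotypes$dosage)
    to_q(leads_of(dperm)$leads$adj_p)
  })
  ef <- empirical_fdr(real$leads$q, perm_q, alpha = fdr)
  res <- qc_filter(real$leads)
  res[, significant := ef$significant & qc_pass]
  res[, cell_type := cell_type]
  setattr(res, "all_fits", real$fits)
  setattr(res, "fdr", ef[c("threshold", "fdr_at")])
  res[]
}
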