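# Bayesian fine-mapping of GWAS signals: LD with the index variant,
# low-LD pre-filter, Wakefield approximate Bayes factors, posterior
# probabilities of association and 99% credible sets.

#' LD (r^2) of all variants with an index variant
#'
#' Squared Pearson correlation of dosage vectors from a reference cohort,
#' restricted to variants within `window_bp` of the index.  Monomorphic
#' variants are excluded (r^2 undefined).
#'
#' @param genotypes a `cohort_genotypes` reference panel
#' @param index variant_id of the index variant
#' @param window_bp window around the index (default 2.5 Mb)
#' @return data.table(variant_id, r, r2)
#' @export
ld_r2 <- function(genotypes, index, window_bp = 2.5e6) {
  v <- genotypes$variants
  iv <- v[variant_id == index]
  stop_if(nrow(iv) == 0L, "index variant not in panel")
  g_i <- genotypes$dosage[, index]
  stop_if(var(g_i) == 0, "index variant is monomorphic in the panel")
  neigh <- v[chrom == iv$chrom & abs(pos - iv$pos) <= window_bp]
  r <- vapply(neigh$variant_id, function(id) {
    x <- genotypes$dosage[, id]
    if (var(x) == 0) NA_real_ else cor(x, g_i)
  }, 0)
  out <- data.table(variant_id = neigh$variant_id, r = r, r2 = r^2)
  out[!is.na(r)]
}

#' Low-LD pre-filter of a signal's variants
#'
#' Keeps variants in at least low LD with the index: `r2 > r2_min`
#' (strict inequality).
#'
#' @param signal data.table with variant_id and r2 columns
#' @param r2_min LD floor (default 0.1)
#' @export
prefilter_ld <- function(signal, r2_min = 0.1) {
  signal[r2 > r2_min]
}

#' Wakefield approximate Bayes factor
#'
#' With `V = se^2` and `z = beta/se`:
#' `aBF = sqrt(V/(V+W)) * exp(W z^2 / (2 (V+W)))`, in favor of association.
#'
#' @param beta effect estimate(s)
#' @param se standard error(s), positive
#' @param W prior effect variance (default 0.04)
#' @export
wakefield_abf <- function(beta, se, W = 0.04) {
  stop_if(any(se <= 0), "standard errors must be positive")
  V <- se^2
  z <- beta / se
  sqrt(V / (V + W)) * exp(W * z^2 / (2 * (V + W)))
}

#' Posterior probability of association
#'
#' Normalizes aBFs within a signal: `PPA_i = aBF_i / sum(aBF)`.
#'
#' @param abf non-negative approximate Bayes factors, not all zero
#' @export
ppa <- function(abf) {
  stop_if(length(abf) == 0L, "no variants in signal")
  stop_if(any(abf < 0) || sum(abf) == 0, "aBFs must be >= 0 and not all zero")
  abf / sum(abf)
}

#' 99% credible set
#'
#' Sorts variants by decreasing PPA and takes the smallest prefix whose
#' cumulative PPA reaches `level`.  Ties at the boundary are broken in favor
#' of the variant with the smaller genomic position.
#'
#' @param variants data.table(variant_id, pos, ppa)
#' @param level credible level (default 0.99)
#' @return the input with `in_set` logical, ordered by decreasing PPA
#' @export
credible_set <- function(variants, level = 0.99) {
  res <- copy(variants)
  setorder(res, -ppa, pos)
  n_in <- which(cumsum(res$ppa) >= level - 1e-12)[1]
  if (is.na(n_in)) n_in <- nrow(res)
  res[, in_set := seq_len(.N) <= n_in]
  res[]
}

#' Fine-map all GWAS signals
#'
#' For each signal: LD with the index variant from the reference panel,
#' `r2 > r2_min` pre-filter, Wakefield aBFs, per-signal PPA normalization
#' (after the filter), and the 99% credible set.
#'
#' @param gwas list with `stats` and `index` as produced by
#'   [simulate_gwas()], or equivalent tables read from disk
#' @param genotypes reference panel `cohort_genotypes`
#' @param W prior variance (default 0.04)
#' @param r2_min LD pre-filter (default 0.1)
#' @param window_bp LD window (default 2.5 Mb)
#' @param level credible level (default 0.99)
#' @return data.table(signal_id, variant_id, pos, beta, se, r2, abf, ppa,
#'   in_set)
#' @export
finemap_signals <- function(gwas, genotypes, W = 0.04, r2_min = 0.1,
                            window_bp = 2.5e6, level = 0.99) {
  out <- vector("list", nrow(gwas$index))
  for (i in seq_len(nrow(gwas$index))) {
    sid <- gwas$index$signal_id[i]
    idx <- gwas$index$variant_id[i]
    st <- gwas$stats[signal_id == sid]
    ld <- ld_r2(genotypes, idx, window_bp)
    st <- merge(st, ld[, .(variant_id, r2)], by = "variant_id")
    st <- prefilter_ld(st, r2_min)
    st[, abf := wakefield_abf(beta, se, W)]
    st[, ppa := ppa(abf)]
    cs <- credible_set(st[, .(variant_id, pos, ppa)], level)
    st <- merge(st, cs[, .(variant_id, in_set)], by = "variant_id")
    setorder(st, -ppa, pos)
    out[[i]] <- st[, .(signal_id, variant_id, pos, beta, se, r2, abf, ppa,
                       in_set)]
  }
  rbindlist(out)
}
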