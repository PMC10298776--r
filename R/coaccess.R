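# Single-cell co-accessibility: kNN cell aggregation, distance-penalized
# sparse partial correlations in overlapping genomic windows, link gating,
# promoter annotation, and propagation of caQTL effects to linked promoters.

#' Aggregate single cells into kNN bins
#'
#' Seed cells are visited in random order; each accepted seed contributes one
#' bin equal to the column sum of its `k` nearest cells (Euclidean distance
#' in the embedding, the seed included).  A seed is rejected when its
#' neighborhood shares more than `max_overlap` of its members with an
#' already accepted bin, limiting redundancy between bins.
#'
#' @param counts peaks x cells count matrix
#' @param embedding cells x d numeric coordinates (rows aligned with
#'   `counts` columns)
#' @param k neighbors per bin (default 30)
#' @param max_overlap maximum shared-membership fraction (default 0.8)
#' @param n_bins optional cap on the number of bins
#' @param seed RNG seed for the visiting order
#' @return list with `bins` (bins x peaks matrix) and `members` (list of
#'   cell index vectors)
#' @export
aggregate_cells <- function(counts, embedding, k = 30L, max_overlap = 0.8,
                            n_bins = NULL, seed = 1L) {
  n_cells <- ncol(counts)
  stop_if(k > n_cells, "k exceeds the number of cells")
  if (n_cells == 0L)
    return(list(bins = matrix(0, 0, nrow(counts)), members = list()))
  set.seed(child_seed(seed, 131L))
  order_seeds <- sample.int(n_cells)
  # the overlap rule bounds accepted bins at roughly n / ((1-max_overlap) k)
  bound <- 2L * ceiling(n_cells / max(1, (1 - max_overlap) * k)) + 10L
  limit <- min(n_bins %||% bound, bound, n_cells)
  emb_t <- t(embedding)
  membership <- matrix(FALSE, nrow = limit, ncol = n_cells)
  n_acc <- 0L
  accepted <- list()
  bins <- list()
  for (s in order_seeds) {
    d2 <- colSums((emb_t - embedding[s, ])^2)
    nb <- order(d2)[seq_len(k)]
    if (n_acc > 0L) {
      shared <- rowSums(membership[seq_len(n_acc), nb, drop = FALSE])
      if (any(shared > max_overlap * k)) next
    }
    n_acc <- n_acc + 1L
    membership[n_acc, nb] <- TRUE
    accepted[[length(accepted) + 1L]] <- nb
    bins[[length(bins) + 1L]] <-
      if (k == 1L) as.numeric(counts[, nb]) else rowSums(counts[, nb])
    if (length(accepted) >= limit) break
  }
  mat <- do.call(rbind, bins)
  colnames(mat) <- rownames(counts)
  list(bins = mat, members = accepted)
}

# Graphical lasso with a penalty matrix (Friedman/Hastie/Tibshirani blockwise
# coordinate descent).  S must be a correlation-scale covariance; Rho >= 0.
glasso_fit <- function(S, Rho, tol = 1e-8, maxit = 200L) {
  p <- ncol(S)
  if (p == 1L) return(matrix(1 / S[1, 1], 1, 1))
  W <- S + diag(diag(Rho), p)
  B <- matrix(0, p, p)    # column j holds beta for block j
  off <- mean(abs(S[upper.tri(S)])) + 1e-12
  for (it in seq_len(maxit)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      W11 <- W[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      r12 <- Rho[idx, j]
      beta <- B[idx, j]
      # lasso via coordinate descent: min .5 b'W11 b - s12'b + r12'|b|
      for (cd in seq_len(100L)) {
        delta <- 0
        for (u in seq_along(idx)) {
          resid <- s12[u] - sum(W11[u, ] * beta) + W11[u, u] * beta[u]
          bnew <- sign(resid) * max(abs(resid) - r12[u], 0) / W11[u, u]
          delta <- max(delta, abs(bnew - beta[u]))
          beta[u] <- bnew
        }
        if (delta < tol) break
      }
      B[idx, j] <- beta
      W[idx, j] <- W[j, idx] <- W11 %*% beta
    }
    if (mean(abs(W - W_old)[upper.tri(W)]) < tol * off) break
  }
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    t22 <- 1 / (W[j, j] - sum(W[idx, j] * B[idx, j]))
    Theta[j, j] <- t22
    Theta[idx, j] <- -B[idx, j] * t22
  }
  (Theta + t(Theta)) / 2
}

prec_to_parcor <- function(Theta) {
  d <- sqrt(diag(Theta))
  R <- -Theta / outer(d, d)
  diag(R) <- 1
  R
}

#' Distance-penalized co-accessibility scores
#'
#' Bins are first depth-normalized by median-of-ratios size factors (each
#' bin's counts divided by the median ratio of its counts to the mean bin
#' profile).  Without this, the shared per-bin sequencing-depth factor
#' induces spurious positive links between high-baseline neighbours; the
#' median is used rather than the bin total because a total is contaminated
#' by genuine co-accessible activity, which must not be normalized away.
#' Then 1 Mb windows (stride `window_bp / 2`) slide along each chromosome:
#' in each window the normalized bin counts are standardized per peak and an
#' L1-penalized inverse covariance is estimated with element-wise penalty
#' `penalty * d_ij / window_bp` (zero on the diagonal), which is converted
#' to partial correlations.  A pair's score is the mean over all windows
#' containing both peaks.
#'
#' @param bins bins x peaks matrix from [aggregate_cells()]
#' @param peaks peak intervals (peak_id, chrom, start, end)
#' @param window_bp window span (default 1 Mb)
#' @param penalty base L1 penalty (default 2.5; calibrated so that unrelated
#'   peak pairs score ~0 at aggregation noise levels, see vignette)
#' @param sf_min_peaks minimum number of peaks for size-factor estimation; a
#'   median over fewer features is itself noisy enough to induce artifact
#'   correlations, so smaller matrices are scored unnormalized
#' @return data.table(peak_a, peak_b, score, distance) with peak_a before
#'   peak_b in genome order
#' @export
coaccessibility_scores <- function(bins, peaks, window_bp = 1e6,
                                   penalty = 2.5, sf_min_peaks = 20L) {
  pk <- copy(peaks)[peak_id %in% colnames(bins)]
  pk[, mid := (start + end) / 2]
  setorder(pk, chrom, mid)
  ref <- colMeans(bins)
  use <- ref > 0
  if (sum(use) >= sf_min_peaks) {
    sf <- apply(bins[, use, drop = FALSE], 1,
                function(r) median(r / ref[use]))
    sf[!is.finite(sf) | sf <= 0] <- 1
    bins <- bins / sf
  }
  acc <- new.env(parent = emptyenv())
  for (ch in unique(pk$chrom)) {
    sub <- pk[chrom == ch]
    lo <- min(sub$mid); hi <- max(sub$mid)
    starts <- seq(lo - window_bp / 2, hi, by = window_bp / 2)
    for (w0 in starts) {
      inw <- sub[mid >= w0 & mid < w0 + window_bp]
      if (nrow(inw) < 2L) next
      X <- bins[, inw$peak_id, drop = FALSE]
      sds <- apply(X, 2, sd)
      keep <- sds > 0
      if (sum(keep) < 2L) next
      inw <- inw[keep]
      X <- scale(X[, keep, drop = FALSE])
      S <- crossprod(X) / (nrow(X) - 1L)
      D <- abs(outer(inw$mid, inw$mid, "-"))
      Rho <- penalty * D / window_bp
      diag(Rho) <- 0
      tol <- if (penalty == 0) 1e-10 else 1e-8
      R <- prec_to_parcor(glasso_fit(S, Rho, tol = tol))
      for (i in seq_len(nrow(inw) - 1L)) for (j in (i + 1L):nrow(inw)) {
        key <- paste(inw$peak_id[i], inw$peak_id[j], sep = "\r")
        prev <- acc[[key]] %||% c(0, 0, D[i, j])
        acc[[key]] <- c(prev[1] + R[i, j], prev[2] + 1, D[i, j])
      }
    }
  }
  keys <- ls(acc)
  if (length(keys) == 0L)
    return(data.table(peak_a = character(), peak_b = character(),
                      score = numeric(), distance = numeric()))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  res <- data.table(peak_a = vapply(parts, `[`, "", 1L),
                    peak_b = vapply(parts, `[`, "", 2L),
                    score = vapply(keys, function(k) acc[[k]][1] / acc[[k]][2], 0),
                    distance = vapply(keys, function(k) acc[[k]][3], 0))
  setorder(res, peak_a, peak_b)
  res[]
}

#' Gate co-accessibility scores into links
#'
#' Keeps pairs with pooled score above `threshold`, midpoint distance above
#' `min_distance`, and per-sample score above `threshold` in at least
#' `min_replication` individual samples.
#'
#' @param scores pooled [coaccessibility_scores()] table
#' @param per_sample_scores named list of per-sample score tables
#' @param threshold co-accessibility score cutoff (default 0.05)
#' @param min_distance minimum midpoint distance in bp (default 10 kb)
#' @param min_replication minimum supporting samples (default 4)
#' @return data.table of links with `n_samples_replicated`
#' @export
filter_links <- function(scores, per_sample_scores = list(),
                         threshold = 0.05, min_distance = 10000,
                         min_replication = 4L) {
  res <- scores[score > threshold & distance > min_distance]
  if (length(per_sample_scores)) {
    key <- function(dt) paste(dt$peak_a, dt$peak_b)
    rep_count <- rep(0L, nrow(res))
    rk <- key(res)
    for (ps in per_sample_scores) {
      hit <- rk %in% key(ps[score > threshold])
      rep_count <- rep_count + hit
    }
    res[, n_samples_replicated := rep_count]
    res <- res[n_samples_replicated >= min_replication]
  } else {
    res[, n_samples_replicated := NA_integer_]
  }
  res[]
}

#' Annotate peaks as promoter or distal
#'
#' A peak is a promoter peak iff its interval intersects any TSS
#' \eqn{\pm}`window` bp; it then carries all intersecting gene ids.
#'
#' @param peaks peak intervals (0-based half-open)
#' @param tss data.table(gene_id, chrom, pos) with 1-based TSS positions
#' @param window promoter window (default 2 kb)
#' @return data.table(peak_id, class, genes)
#' @export
annotate_promoters <- function(peaks, tss, window = 2000) {
  stop_if(any(peaks$start >= peaks$end), "malformed peak interval")
  ann <- data.table(peak_id = peaks$peak_id, class = "distal",
                    genes = "")
  for (ch in unique(peaks$chrom)) {
    pi_ <- which(peaks$chrom == ch)
    ti <- which(tss$chrom == ch)
    if (!length(pi_) || !length(ti)) next
    ov <- overlap_pairs(peaks$start[pi_], peaks$end[pi_],
                        tss$pos[ti] - window - 1L, tss$pos[ti] + window)
    if (nrow(ov) == 0L) next
    hits <- ov[, .(genes = paste(tss$gene_id[ti][subject], collapse = ",")),
               by = query]
    ann[pi_[hits$query], `:=`(class = "promoter", genes = hits$genes)]
  }
  ann[]
}

#' Classify caQTLs by promoter linkage
#'
#' Each significant caQTL peak is classified as promoter-direct (the peak
#' itself is a promoter), distal-linked (distal peak co-accessible with >= 1
#' promoter peak), promoter-promoter-linked, or unlinked.
#'
#' @param caqtls a [map_caqtl()] result (uses `significant` rows)
#' @param links a [filter_links()] result
#' @param annotation an [annotate_promoters()] result
#' @return data.table(peak_id, variant_id, class, n_promoters, genes)
#' @export
link_caqtls_to_promoters <- function(caqtls, links, annotation) {
  setkey(annotation, peak_id)
  prom <- annotation[class == "promoter", peak_id]
  sig <- caqtls[significant == TRUE]
  out <- vector("list", nrow(sig))
  for (i in seq_len(nrow(sig))) {
    pk <- sig$peak_id[i]
    partner <- c(links[peak_a == pk, peak_b], links[peak_b == pk, peak_a])
    linked_prom <- intersect(partner, prom)
    is_prom <- pk %in% prom
    cls <- if (is_prom && length(linked_prom)) "promoter-promoter-linked"
           else if (is_prom) "promoter-direct"
           else if (length(linked_prom)) "distal-linked"
           else "unlinked"
    genes <- annotation[linked_prom, genes]
    genes <- genes[!is.na(genes) & genes != ""]
    out[[i]] <- data.table(peak_id = pk, variant_id = sig$variant_id[i],
                           class = cls, n_promoters = length(linked_prom),
                           genes = paste(genes, collapse = ","))
  }
  rbindlist(out)
}

#' Test caQTL effect propagation to co-accessible promoters
#'
#' For each significant caQTL whose peak is linked to promoter peaks more
#' than `min_distance` away, associates the lead variant's dosage with the
#' promoter peak's total counts (population-only model; the lead is
#' generally outside the promoter peak, so no allelic reads are available
#' there), applies a genotype-permutation empirical FDR at `fdr`, and
#' reports the Pearson correlation between the caQTL-peak effect and the
#' best-associated promoter's effect, overall and by distance bin.
#'
#' @param caqtls [map_caqtl()] lead table for one cell type
#' @param links [filter_links()] table
#' @param annotation [annotate_promoters()] table
#' @param tensor_ct the matching cell-type slot of the tensor
#' @param genotypes cohort genotypes
#' @param fdr relaxed empirical FDR level (default 0.20)
#' @param n_perm permutation rounds (default 2)
#' @param min_distance minimum caQTL-promoter distance (default 10 kb)
#' @param seed RNG seed
#' @return list(pairs, pearson_r, by_distance)
#' @export
promoter_effect_test <- function(caqtls, links, annotation, tensor_ct,
                                 genotypes, fdr = 0.20, n_perm = 2L,
                                 min_distance = 10000, seed = 1L) {
  prom <- annotation[class == "promoter", peak_id]
  sig <- caqtls[significant == TRUE]
  peaks <- genotypes$peaks
  mid <- setNames((peaks$start + peaks$end) / 2, peaks$peak_id)
  cand <- list()
  for (i in seq_len(nrow(sig))) {
    pk <- sig$peak_id[i]
    partner <- c(links[peak_a == pk, peak_b], links[peak_b == pk, peak_a])
    for (pp in intersect(partner, prom)) {
      d <- abs(mid[[pp]] - mid[[pk]])
      if (d <= min_distance) next
      if (!pp %in% rownames(tensor_ct$totals)) next
      if (mean(tensor_ct$totals[pp, ]) <= 5) next   # untested under filter
      cand[[length(cand) + 1L]] <-
        data.table(peak_id = pk, variant_id = sig$variant_id[i],
                   pi_caqtl = sig$pi_hat[i], promoter_peak = pp,
                   distance = d)
    }
  }
  if (!length(cand))
    return(list(pairs = data.table(), pearson_r = NA_real_,
                by_distance = data.table()))
  cand <- rbindlist(cand)

  fit_once <- function(dosage) {
    vapply(seq_len(nrow(cand)), function(i) {
      f <- fit_population_only(tensor_ct$totals[cand$promoter_peak[i], ],
                               dosage[, cand$variant_id[i]],
                               tensor_ct$offsets)
      c(f$pi_hat, f$lrt_p)
    }, c(0, 0))
  }
  real <- fit_once(genotypes$dosage)
  cand[, `:=`(pi_promoter = real[1, ], p = real[2, ])]
  cand[, q := bh_adjust(p)]
  to_q <- bh_map(cand$p)
  set.seed(child_seed(seed, 149L))
  perm_q <- lapply(seq_len(n_perm), function(k) {
    dperm <- genotypes$dosage[sample.int(nrow(genotypes$dosage)), ,
                              drop = FALSE]
    rownames(dperm) <- rownames(genotypes$dosage)
    to_q(fit_once(dperm)[2, ])
  })
  ef <- empirical_fdr(cand$q, perm_q, alpha = fdr)
  cand[, significant := ef$significant]

  best <- cand[, .SD[which.min(p)], by = .(peak_id, variant_id)]
  r <- if (nrow(best) >= 3L && sd(best$pi_caqtl) > 1e-9 &&
           sd(best$pi_promoter) > 1e-9) {
    cor(best$pi_caqtl, best$pi_promoter)
  } else {
    warning("effect correlation not estimable (too few pairs or no variance)")
    NA_real_
  }
  breaks <- c(10, 50, 100, 200, 350, 1000) * 1e3
  best[, dist_bin := cut(distance, breaks, include.lowest = TRUE)]
  by_d <- best[, .(n = .N,
                   r = if (.N >= 3L && sd(pi_caqtl) > 1e-9 &&
                           sd(pi_promoter) > 1e-9)
                         cor(pi_caqtl, pi_promoter) else NA_real_),
               by = dist_bin]
  list(pairs = cand, pearson_r = r, by_distance = by_d)
}

#' Enrichment of links in external interval-pair interactions
#'
#' Restricts candidate peak pairs to those with at least one anchor within
#' `max_gap` of an external bait, then tests link-called vs loop-supported
#' status with Fisher's exact test.  A degenerate table gets the Haldane
#' correction (0.5 added to every cell) for the odds ratio.
#'
#' @param pairs candidate peak pairs with logical `linked`
#' @param peaks peak intervals
#' @param loops data.table of external loops (chrom_a, start_a, end_a,
#'   chrom_b, start_b, end_b), 0-based half-open
#' @param baits optional data.table(chrom, start, end) of bait intervals;
#'   defaults to the union of loop anchors
#' @param max_gap slack for anchor/bait matching in bp (default 1000)
#' @return list(table, odds_ratio, p, evaluable)
#' @export
interaction_overlap_enrichment <- function(pairs, peaks, loops,
                                           baits = NULL, max_gap = 1000) {
  if (is.null(baits))
    baits <- unique(rbind(
      loops[, .(chrom = chrom_a, start = start_a, end = end_a)],
      loops[, .(chrom = chrom_b, start = start_b, end = end_b)]))
  pk <- copy(peaks)
  setkey(pk, peak_id)
  hits_bait <- function(pids) {
    res <- rep(FALSE, length(pids))
    p <- pk[pids]
    for (ch in unique(p$chrom)) {
      ii <- which(p$chrom == ch); bi <- which(baits$chrom == ch)
      if (!length(ii) || !length(bi)) next
      ov <- overlap_pairs(p$start[ii], p$end[ii],
                          baits$start[bi], baits$end[bi],
                          maxgap = as.integer(max_gap))
      res[ii[unique(ov$query)]] <- TRUE
    }
    res
  }
  cand <- pairs[hits_bait(peak_a) | hits_bait(peak_b)]
  if (nrow(cand) == 0L)
    return(list(table = NULL, odds_ratio = NA_real_, p = NA_real_,
                evaluable = FALSE))
  loop_match <- function(pa, pb) {
    a <- pk[pa]; b <- pk[pb]
    any(loops$chrom_a == a$chrom & loops$chrom_b == b$chrom &
        loops$start_a < a$end + max_gap & loops$end_a > a$start - max_gap &
        loops$start_b < b$end + max_gap & loops$end_b > b$start - max_gap) ||
    any(loops$chrom_a == b$chrom & loops$chrom_b == a$chrom &
        loops$start_a < b$end + max_gap & loops$end_a > b$start - max_gap &
        loops$start_b < a$end + max_gap & loops$end_b > a$start - max_gap)
  }
  cand[, supported := vapply(seq_len(.N),
                             function(i) loop_match(peak_a[i], peak_b[i]),
                             TRUE)]
  tab <- table(factor(cand$linked, c(TRUE, FALSE)),
               factor(cand$supported, c(TRUE, FALSE)))
  ft <- fisher.test(tab)
  or <- unname(ft$estimate)
  if (!is.finite(or) || or == 0) {
    h <- tab + 0.5
    or <- (h[1, 1] * h[2, 2]) / (h[1, 2] * h[2, 1])
  }
  list(table = tab, odds_ratio = or, p = ft$p.value, evaluable = TRUE)
}

#' Per-sample and pooled co-accessibility mapping
#'
#' Runs [aggregate_cells()] and [coaccessibility_scores()] on all cells and
#' on each sample's cells separately, then gates links with
#' [filter_links()].
#'
#' @param sc a [simulate_single_cells()]-shaped list (counts, embedding,
#'   cells)
#' @param peaks peak intervals
#' @param k,window_bp,penalty,threshold,min_distance,min_replication
#'   parameters forwarded to the stage functions
#' @param seed RNG seed
#' @return list(links, scores, per_sample)
#' @export
coaccess_map <- function(sc, peaks, k = 30L, window_bp = 1e6, penalty = 2.5,
                         threshold = 0.05, min_distance = 10000,
                         min_replication = 4L, n_bins = 1000L, seed = 1L) {
  agg <- aggregate_cells(sc$counts, sc$embedding, k = k, n_bins = n_bins,
                         seed = seed)
  pooled <- coaccessibility_scores(agg$bins, peaks, window_bp, penalty)
  samples <- unique(sc$cells$sample)
  per_sample <- lapply(samples, function(sm) {
    idx <- which(sc$cells$sample == sm)
    ks <- min(k, length(idx))
    agg_s <- aggregate_cells(sc$counts[, idx, drop = FALSE],
                             sc$embedding[idx, , drop = FALSE],
                             k = ks, n_bins = n_bins,
                             seed = child_seed(seed, 163L))
    coaccessibility_scores(agg_s$bins, peaks, window_bp, penalty)
  })
  names(per_sample) <- samples
  links <- filter_links(pooled, per_sample, threshold, min_distance,
                        min_replication)
  list(links = links, scores = pooled, per_sample = per_sample)
}
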