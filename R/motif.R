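# Allelic TF-motif disruption: PFM -> log-odds PWM, exact score-distribution
# tail p-values by dynamic-programming convolution, per-variant allelic
# scanning on both strands, and per-motif caQTL enrichment by one-tailed
# binomial test.

BASES <- c("A", "C", "G", "T")

#' Read JASPAR-style position frequency matrices
#'
#' Parses the minimal JASPAR text dialect:
#' ```
#' >MA0001.1 NAME
#' A [ 1 2 3 ]
#' C [ 0 1 0 ]
#' ...
#' ```
#'
#' @param path file path
#' @return named list of 4 x L count matrices (rows A, C, G, T)
#' @export
read_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  stop_if(length(starts) == 0L, "no motif records found")
  out <- list()
  for (i in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[i]])
    id <- strsplit(hdr, "\\s+")[[1]][1]
    stop_row <- if (i < length(starts)) starts[i + 1] - 1L else length(lines)
    body <- lines[(starts[i] + 1L):stop_row]
    stop_if(length(body) < 4L, paste("truncated PFM record:", id))
    mat <- t(vapply(body[1:4], function(ln) {
      nums <- regmatches(ln, gregexpr("[0-9.]+", ln))[[1]]
      as.numeric(nums)
    }, numeric(length(regmatches(body[1],
                                 gregexpr("[0-9.]+", body[1]))[[1]]))))
    rownames(mat) <- BASES
    out[[id]] <- mat
  }
  out
}

#' Build a log-odds PWM from a position frequency matrix
#'
#' Per cell: `log2((count + pseudocount * bg) / (colsum + pseudocount) / bg)`
#' (bits).  The pseudocount keeps all entries finite.  Entries are quantized
#' to `resolution` bits, so every sequence score is an exact multiple of the
#' resolution and the dynamic-programming tail probabilities of
#' [exact_score_pvalue()] are exact for the reported scores (no boundary
#' ambiguity at score atoms).
#'
#' @param pfm 4 x L non-negative count matrix, rows A, C, G, T
#' @param background base frequencies (default uniform)
#' @param pseudocount total pseudocount (default 0.8)
#' @param resolution score quantization step in bits (default 1e-3)
#' @return object of class `pwm`: list(mat (4 x L, bits), score_range,
#'   background, resolution)
#' @export
build_pwm <- function(pfm, background = rep(0.25, 4), pseudocount = 0.8,
                      resolution = 1e-3) {
  stop_if(is.null(dim(pfm)) || ncol(pfm) == 0L, "zero-width PFM")
  stop_if(any(pfm < 0) || all(colSums(pfm) == 0), "PFM must be non-negative")
  stop_if(resolution <= 0, "resolution must be positive")
  bg <- background / sum(background)
  cs <- colSums(pfm)
  prob <- sweep(pfm + pseudocount * bg, 2, cs + pseudocount, "/")
  mat <- round(log2(prob / bg) / resolution) * resolution
  rownames(mat) <- BASES
  structure(list(mat = mat,
                 score_range = c(sum(apply(mat, 2, min)),
                                 sum(apply(mat, 2, max))),
                 background = bg, resolution = resolution,
                 cache = new.env(parent = emptyenv())),
            class = "pwm")
}

# discretized per-position score distribution of a PWM under background
pwm_score_distribution <- function(pwm, resolution = 1e-3) {
  mat <- round(pwm$mat / resolution)
  cur_lo <- 0L      # dist[i] = P(score at offset cur_lo + i - 1)
  dist <- c(1)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    new_lo <- cur_lo + min(col)
    new_hi <- cur_lo + length(dist) - 1L + max(col)
    new <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      sh <- (cur_lo + col[b]) - new_lo
      idx <- seq_along(dist) + sh
      new[idx] <- new[idx] + dist * pwm$background[b]
    }
    dist <- new
    cur_lo <- new_lo
  }
  list(probs = dist, scores = (cur_lo + seq_along(dist) - 1L) * resolution,
       resolution = resolution)
}

#' Exact tail p-value of a PWM score
#'
#' `P(S >= score)` for a random sequence of independent background bases,
#' computed from the discretized exact score distribution (dynamic
#' programming over positions).
#'
#' @param pwm a [build_pwm()] object
#' @param score score in bits
#' @param resolution discretization step in bits; defaults to the PWM's own
#'   quantization, at which the tail probability is exact
#' @return tail probability; exactly 0 above the attainable maximum
#' @export
exact_score_pvalue <- function(pwm, score, resolution = NULL) {
  resolution <- resolution %||% pwm$resolution %||% 1e-3
  stop_if(resolution <= 0, "resolution must be positive")
  key <- paste0("res", format(resolution))
  dist <- pwm$cache[[key]]
  if (is.null(dist)) {
    dist <- pwm_score_distribution(pwm, resolution)
    assign(key, dist, envir = pwm$cache)
  }
  vapply(score, function(s) {
    if (s > pwm$score_range[2] + resolution) return(0)
    sum(dist$probs[dist$scores >= s - resolution / 2])
  }, 0)
}

revcomp <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = ""),
    "")
}

pwm_best_score <- function(pwm, seq) {
  L <- ncol(pwm$mat)
  best <- -Inf
  for (s in c(seq, revcomp(seq))) {
    chars <- strsplit(s, "")[[1]]
    idx <- match(chars, BASES)
    if (length(idx) < L) next
    for (start in 1:(length(idx) - L + 1L)) {
      win <- idx[start:(start + L - 1L)]
      if (anyNA(win)) next
      sc <- sum(pwm$mat[cbind(win, seq_len(L))])
      if (sc > best) best <- sc
    }
  }
  best
}

#' Allelic motif disruption call for one variant
#'
#' Scores both alleles over every window covering the variant, on both
#' strands, and classifies the disruption: an allele is "bound" when its
#' best-score exact tail p-value is below `p_thresh`; the effect is
#' `strong` when exactly one allele is bound and the scaled score change
#' `|score_ref - score_alt| / (max - min attainable)` is at least
#' `strong_delta`; `weak` when both are bound and the scaled change is at
#' least `weak_delta`; otherwise `none`.
#'
#' @param ref_allele,alt_allele single bases
#' @param context sequence of length `2*(L-1) + 1` centered on the variant
#'   (carrying the reference base at the center)
#' @param pwm a [build_pwm()] object
#' @param p_thresh binding p-value threshold (default 5e-4)
#' @param strong_delta,weak_delta scaled score-change cutoffs
#' @return data.table(score_ref, score_alt, p_ref, p_alt, delta, effect)
#' @export
allelic_disruption <- function(ref_allele, alt_allele, context, pwm,
                               p_thresh = 5e-4, strong_delta = 0.15,
                               weak_delta = 0.05) {
  L <- ncol(pwm$mat)
  chars <- strsplit(toupper(context), "")[[1]]
  center <- (length(chars) + 1L) %/% 2L
  stop_if(chars[center] != toupper(ref_allele),
          "context center does not carry the reference allele")
  seq_ref <- context
  chars_alt <- chars; chars_alt[center] <- toupper(alt_allele)
  seq_alt <- paste(chars_alt, collapse = "")
  score_ref <- pwm_best_score(pwm, seq_ref)
  score_alt <- pwm_best_score(pwm, seq_alt)
  p_ref <- exact_score_pvalue(pwm, score_ref)
  p_alt <- exact_score_pvalue(pwm, score_alt)
  rng <- diff(pwm$score_range)
  delta <- abs(score_ref - score_alt) / rng
  bound_ref <- p_ref < p_thresh
  bound_alt <- p_alt < p_thresh
  effect <- if (xor(bound_ref, bound_alt) && delta >= strong_delta) "strong"
            else if (bound_ref && bound_alt && delta >= weak_delta) "weak"
            else "none"
  data.table(score_ref = score_ref, score_alt = score_alt,
             p_ref = p_ref, p_alt = p_alt, delta = delta, effect = effect)
}

#' Per-motif enrichment of disruption among caQTLs
#'
#' For each motif, compares the frequency of strong disruption among caQTL
#' variants (`k` of `n`) to the background rate among all tested variants
#' (`p0`) with a one-tailed binomial test `P(X >= k)`, BH-corrected across
#' motifs.  Also reports a global any-motif Fisher test.
#'
#' @param disruptions data.table(variant_id, motif_id, effect)
#' @param caqtl_variants character vector (subset of `tested_variants`)
#' @param tested_variants character vector of all tested variant ids
#' @return list(per_motif (motif_id, k, n, p0, p, fdr, flagged),
#'   global (odds_ratio, p))
#' @export
motif_enrichment <- function(disruptions, caqtl_variants, tested_variants) {
  stop_if(!all(caqtl_variants %in% tested_variants),
          "caQTL variants must be a subset of tested variants")
  strong <- disruptions[effect == "strong"]
  n <- length(caqtl_variants)
  n_tot <- length(tested_variants)
  per <- strong[, {
    disrupted <- unique(variant_id)
    k <- sum(caqtl_variants %in% disrupted)
    p0 <- sum(tested_variants %in% disrupted) / n_tot
    if (p0 == 0 && k > 0) {
      list(k = k, n = n, p0 = p0, p = 1 / (n + 1), flagged = TRUE)
    } else {
      list(k = k, n = n, p0 = p0,
           p = if (n > 0) binom.test(k, n, p0, alternative = "greater")$p.value
               else NA_real_,
           flagged = FALSE)
    }
  }, by = motif_id]
  if (nrow(per)) per[, fdr := bh_adjust(p)]
  any_disrupt <- unique(strong$variant_id)
  tab <- table(factor(tested_variants %in% caqtl_variants, c(TRUE, FALSE)),
               factor(tested_variants %in% any_disrupt, c(TRUE, FALSE)))
  glob <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
    ft <- fisher.test(tab)
    list(odds_ratio = unname(ft$estimate), p = ft$p.value)
  } else list(odds_ratio = NA_real_, p = NA_real_)
  list(per_motif = per[], global = glob)
}
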