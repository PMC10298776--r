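# Annotation of fine-mapped credible sets with caQTLs and permutation
# enrichment of cumulative PPA in caQTL peaks.

#' Annotate credible-set variants with caQTL status
#'
#' A credible variant is a caQTL in a cell type when it is the lead variant
#' of a significant association there, or shares the lead's q-value within
#' the same peak.  Promoter linkage of the hosting peak is carried over from
#' the co-accessibility stage.
#'
#' @param credible a [finemap_signals()] table (rows with `in_set`)
#' @param caqtl_results named list of [map_caqtl()] tables per cell type
#' @param variant_peaks data.table(variant_id, peak_id) placing variants in
#'   peaks
#' @param links optional [filter_links()] table for promoter linkage
#' @param annotation optional [annotate_promoters()] table
#' @param ppa_min PPA floor of the filtered view (default 0.01)
#' @return list(full, filtered): per-variant annotation and the
#'   `ppa > ppa_min` caQTL view with linked genes
#' @export
annotate_credible_variants <- function(credible, caqtl_results,
                                       variant_peaks, links = NULL,
                                       annotation = NULL, ppa_min = 0.01) {
  cs <- credible[in_set == TRUE]
  rows <- vector("list", nrow(cs))
  for (i in seq_len(nrow(cs))) {
    vid <- cs$variant_id[i]
    pk <- variant_peaks[variant_id == vid, peak_id]
    hit_cts <- character(0)
    for (ct in names(caqtl_results)) {
      res <- caqtl_results[[ct]]
      sig <- res[significant == TRUE]
      if (vid %in% sig$variant_id) { hit_cts <- c(hit_cts, ct); next }
      # variants sharing the lead's q-value within the same peak
      if (length(pk)) {
        all_fits <- attr(res, "all_fits")
        lead <- sig[peak_id %in% pk]
        if (nrow(lead) && !is.null(all_fits)) {
          same <- all_fits[peak_id %in% pk & variant_id == vid]
          if (nrow(same) && any(abs(same$lrt_p - lead$lrt_p) < 1e-12))
            hit_cts <- c(hit_cts, ct)
        }
      }
    }
    genes <- ""
    if (!is.null(links) && !is.null(annotation) && length(pk)) {
      prom <- annotation[class == "promoter", peak_id]
      partner <- c(links[peak_a %in% pk, peak_b], links[peak_b %in% pk, peak_a])
      gl <- annotation[peak_id %in% intersect(partner, prom), genes]
      genes <- paste(gl[gl != ""], collapse = ",")
    }
    rows[[i]] <- data.table(
      signal_id = cs$signal_id[i], variant_id = vid, ppa = cs$ppa[i],
      peak_id = if (length(pk)) pk[1] else NA_character_,
      tested = length(pk) > 0L,
      caqtl_cell_types = paste(hit_cts, collapse = ","),
      is_caqtl = length(hit_cts) > 0L, linked_genes = genes)
  }
  full <- rbindlist(rows)
  filtered <- full[is_caqtl == TRUE & ppa > ppa_min]
  list(full = full, filtered = filtered)
}

#' Permutation enrichment of cumulative credible PPA in caQTL peaks
#'
#' The observed statistic is the total PPA of credible-set variants falling
#' inside the cell type's caQTL peaks.  The null distribution draws
#' `|caQTL peaks|` peaks without replacement from the background (peaks
#' tested in the same cell type without a significant caQTL) `n_draws`
#' times and recomputes the statistic.  The empirical p-value uses the
#' add-one formula `(1 + #\{null >= obs\}) / (n_draws + 1)`.
#'
#' @param credible [finemap_signals()] table (in-set rows are used)
#' @param variant_peaks data.table(variant_id, peak_id)
#' @param caqtl_peaks character vector of significant caQTL peak ids
#' @param background_peaks character vector of tested, non-significant peaks
#'   (must be disjoint from `caqtl_peaks` and at least as large)
#' @param n_draws null draws (default 1000)
#' @param seed RNG seed
#' @return list(observed, null_stats, empirical_p, log_or, evaluable)
#' @export
cumulative_ppa_enrichment <- function(credible, variant_peaks, caqtl_peaks,
                                      background_peaks, n_draws = 1000L,
                                      seed = 1L) {
  stop_if(length(background_peaks) < length(caqtl_peaks),
          "background smaller than the caQTL peak set")
  stop_if(length(intersect(caqtl_peaks, background_peaks)) > 0L,
          "background must be disjoint from caQTL peaks")
  cs <- merge(credible[in_set == TRUE], variant_peaks, by = "variant_id")
  stat_in <- function(peak_set) sum(cs$ppa[cs$peak_id %in% peak_set])
  observed <- stat_in(caqtl_peaks)
  set.seed(child_seed(seed, 173L))
  null_stats <- vapply(seq_len(n_draws), function(k)
    stat_in(sample(background_peaks, length(caqtl_peaks))), 0)
  if (observed == 0) {
    empirical_p <- 1
  } else {
    empirical_p <- (1 + sum(null_stats >= observed)) / (n_draws + 1)
  }
  log_or <- if (mean(null_stats) > 0 && observed > 0)
    log(observed / mean(null_stats)) else NA_real_
  list(observed = observed, null_stats = null_stats,
       empirical_p = empirical_p, log_or = log_or,
       evaluable = mean(null_stats) > 0)
}
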