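# Synthetic cohort generator.
#
# Emulates the data a cell-type-resolved caQTL study produces: ~10 donors of
# European-like genotypes with blocky LD, per-cell-type peak count matrices
# with allele-specific read counts at heterozygous variants, sparse
# single-cell peak matrices with planted co-accessible modules, and GWAS
# summary statistics whose causal variants sit inside caQTL peaks.  Every
# planted quantity is recorded in a ground-truth ledger so recovery can be
# tested.

#' Simulation configuration
#'
#' Collects all knobs of the synthetic cohort with defaults matching the
#' study design the package targets: 10 donors, 4 PBMC cell types with
#' monocyte/lymphocyte-like abundances, blocky LD, ~20% of peaks carrying a
#' cis caQTL with allelic ratio \eqn{\pi} away from 0.5, mild reference bias
#' \eqn{\psi} around 0.5 and small allele-assignment error \eqn{\partial}.
#'
#' @param n_samples number of donors (>= 2)
#' @param n_variants total number of biallelic SNVs
#' @param n_peaks number of accessible peaks
#' @param n_chrom number of chromosomes the peaks are spread over
#' @param ld_block_size variants per LD block (haplotypes within a block are
#'   copies of a few founder haplotypes, giving high within-block r^2)
#' @param maf_range interval in (0, 0.5] the target minor-allele frequency is
#'   drawn from
#' @param cell_types named numeric vector of relative cell-type abundances
#'   (must sum to 1); abundance scales sequencing depth per cell type
#' @param mean_depth_per_peak expected fragments per sample per peak before
#'   cell-type abundance scaling
#' @param frac_caqtl_peaks proportion of peaks carrying a planted caQTL
#' @param pi_effect_range interval in (0.5, 1) planted allelic ratios are
#'   drawn from (a fair coin decides which allele is up)
#' @param psi_range interval for the planted reference bias
#' @param delta_range interval in \[0, 0.5) for the planted error rate
#' @param nb_dispersion negative-binomial overdispersion \eqn{\phi} of totals
#' @param bb_overdispersion beta-binomial overdispersion \eqn{\theta} of
#'   allelic counts
#' @param allelic_fraction fraction of a peak's fragments that overlap the
#'   variant and are allele-informative
#' @param shared_fraction probability a planted caQTL acts in all cell types
#'   (otherwise it acts in a single random cell type)
#' @param n_cells_per_sample single cells per donor
#' @param coaccess_module_size peaks per planted co-accessible module
#' @param n_coaccess_modules number of planted modules
#' @param gwas_n GWAS sample size used for the standard-error model
#' @param n_gwas_signals number of independent GWAS signals (one causal
#'   variant each, placed on distinct chromosomes)
#' @param seed integer RNG seed; all generators are deterministic given it
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_samples = 10L, n_variants = 360L, n_peaks = 120L,
                       n_chrom = 5L, ld_block_size = 6L,
                       maf_range = c(0.1, 0.5),
                       cell_types = c(Tcell = 0.45, Mono = 0.30,
                                      Bcell = 0.15, NK = 0.10),
                       mean_depth_per_peak = 100,
                       frac_caqtl_peaks = 0.2,
                       pi_effect_range = c(0.6, 0.85),
                       psi_range = c(0.45, 0.55),
                       delta_range = c(0, 0.05),
                       nb_dispersion = 0.1, bb_overdispersion = 0.02,
                       allelic_fraction = 0.2,
                       shared_fraction = 0.6,
                       n_cells_per_sample = 2500L,
                       coaccess_module_size = 3L, n_coaccess_modules = 6L,
                       gwas_n = 50000L, n_gwas_signals = 5L, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_variants = as.integer(n_variants),
              n_peaks = as.integer(n_peaks), n_chrom = as.integer(n_chrom),
              ld_block_size = as.integer(ld_block_size),
              maf_range = maf_range, cell_types = cell_types,
              mean_depth_per_peak = mean_depth_per_peak,
              frac_caqtl_peaks = frac_caqtl_peaks,
              pi_effect_range = pi_effect_range, psi_range = psi_range,
              delta_range = delta_range, nb_dispersion = nb_dispersion,
              bb_overdispersion = bb_overdispersion,
              allelic_fraction = allelic_fraction,
              shared_fraction = shared_fraction,
              n_cells_per_sample = as.integer(n_cells_per_sample),
              coaccess_module_size = as.integer(coaccess_module_size),
              n_coaccess_modules = as.integer(n_coaccess_modules),
              gwas_n = as.integer(gwas_n),
              n_gwas_signals = as.integer(n_gwas_signals),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_samples", "n_variants", "n_peaks", "n_chrom",
              "ld_block_size", "n_cells_per_sample", "coaccess_module_size",
              "gwas_n", "n_gwas_signals")
  for (f in counts)
    stop_if(length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L,
            paste0("invalid config: ", f, " must be a positive count"))
  stop_if(cfg$n_samples < 2L, "invalid config: n_samples must be >= 2")
  stop_if(cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5,
          "invalid config: maf_range must lie within (0, 0.5]")
  stop_if(any(cfg$pi_effect_range <= 0) || any(cfg$pi_effect_range >= 1),
          "invalid config: pi_effect_range must lie within (0, 1)")
  stop_if(any(cfg$delta_range < 0) || any(cfg$delta_range >= 0.5),
          "invalid config: delta_range must lie within [0, 0.5)")
  stop_if(abs(sum(cfg$cell_types) - 1) > 1e-8,
          "invalid config: cell_types abundances must sum to 1")
  stop_if(cfg$frac_caqtl_peaks < 0 || cfg$frac_caqtl_peaks > 1,
          "invalid config: frac_caqtl_peaks must lie in [0, 1]")
  invisible(cfg)
}

# Deterministic peak scaffold shared by genotype and truth generation:
# peaks of 300-800 bp separated by 8-25 kb gaps, split across chromosomes.
peak_scaffold <- function(config) {
  set.seed(child_seed(config$seed, 11L))
  n <- config$n_peaks
  chrom_of <- sort(rep_len(seq_len(config$n_chrom), n))
  dt <- data.table(peak_id = sprintf("peak%04d", seq_len(n)),
                   chrom = paste0("chr", chrom_of))
  dt[, width := as.integer(round(runif(.N, 300, 800)))]
  dt[, gap := as.integer(round(runif(.N, 8000, 25000)))]
  dt[, start := {
    s <- cumsum(c(10000L, head(width + gap, -1L)))
    as.integer(s)
  }, by = chrom]
  dt[, end := start + width]       # 0-based half-open
  dt[, c("width", "gap") := NULL]
  dt[]
}

#' Simulate cohort genotypes with blocky LD
#'
#' Variants are placed inside peaks (up to `n_variants`, round-robin over
#' peaks) and organized in LD blocks: within a block, sample haplotypes are
#' copies of 4 founder haplotypes drawn with block-specific weights, so
#' within-block r^2 is high and across-block genotypes are independent.  The
#' target MAF for each variant is the weighted frequency of the alt allele in
#' the founder pool, chosen as the achievable frequency closest to a draw
#' from `maf_range` and recorded in the `maf` column.
#'
#' @param config a [sim_config()]
#' @return object of class `cohort_genotypes`: list with `variants`
#'   (data.table: variant_id, chrom, pos (1-based), ref, alt, maf, block,
#'   peak_id), `dosage` (samples x variants integer matrix in 0..2) and
#'   `sample_ids`
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  peaks <- peak_scaffold(config)
  set.seed(child_seed(config$seed, 23L))
  n_v <- config$n_variants
  pk_idx <- rep_len(seq_len(nrow(peaks)), n_v)
  pk_idx <- sort(pk_idx)
  pos0 <- peaks$start[pk_idx] +
    as.integer(floor(runif(n_v) * (peaks$end[pk_idx] - peaks$start[pk_idx])))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_v, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  variants <- data.table(variant_id = sprintf("rs%05d", seq_len(n_v)),
                         chrom = peaks$chrom[pk_idx], pos = pos0 + 1L,
                         ref = ref, alt = alt,
                         peak_id = peaks$peak_id[pk_idx])
  setorder(variants, chrom, pos)
  # blocks never span chromosomes
  variants[, block := {
    b <- ceiling(seq_len(.N) / config$ld_block_size)
    paste0(.BY[[1]], "_b", b)
  }, by = chrom]

  n_hap <- 2L * config$n_samples
  n_founder <- 4L
  dosage <- matrix(0L, nrow = config$n_samples, ncol = n_v)
  maf <- numeric(n_v)
  for (blk in unique(variants$block)) {
    vi <- which(variants$block == blk)
    w <- as.numeric(rbeta(n_founder, 2, 2))
    w <- w / sum(w)
    assign_hap <- sample.int(n_founder, n_hap, replace = TRUE, prob = w)
    subsets <- as.matrix(expand.grid(rep(list(0:1), n_founder)))
    subset_freq <- drop(subsets %*% w)
    # keep variants polymorphic in the founder pool
    poly <- subset_freq >= 0.05 & subset_freq <= 0.95
    subsets <- subsets[poly, , drop = FALSE]
    subset_freq <- subset_freq[poly]
    for (v in vi) {
      target <- runif(1, config$maf_range[1], config$maf_range[2])
      k <- which.min(abs(subset_freq - target))
      founder_allele <- subsets[k, ]
      maf[v] <- subset_freq[k]
      hap_allele <- founder_allele[assign_hap]
      dosage[, v] <- hap_allele[seq(1, n_hap, by = 2)] +
        hap_allele[seq(2, n_hap, by = 2)]
    }
  }
  variants[, maf := maf]
  sample_ids <- sprintf("S%02d", seq_len(config$n_samples))
  rownames(dosage) <- sample_ids
  colnames(dosage) <- variants$variant_id
  structure(list(variants = variants, dosage = dosage,
                 sample_ids = sample_ids, peaks = peaks),
            class = "cohort_genotypes")
}

#' Plant the ground truth of a synthetic cohort
#'
#' Selects caQTL peaks and their causal variants, allelic parameters, affected
#' cell types, co-accessible peak modules (each anchored on a promoter peak),
#' promoter/TSS annotation, and GWAS causal variants (drawn from caQTL causal
#' variants, one per chromosome, so trait enrichment in caQTL peaks is real).
#'
#' @param genotypes a [simulate_genotypes()] result
#' @param config the matching [sim_config()]
#' @return object of class `ground_truth`
#' @export
simulate_truth <- function(genotypes, config) {
  peaks <- genotypes$peaks
  variants <- genotypes$variants
  set.seed(child_seed(config$seed, 37L))
  npk <- nrow(peaks)

  # baseline accessibility per peak (lognormal around the configured depth)
  lambda <- config$mean_depth_per_peak * rlnorm(npk, 0, 0.4)
  names(lambda) <- peaks$peak_id

  # TSS: every 4th peak hosts a gene TSS near its midpoint
  prom_idx <- seq(1L, npk, by = 4L)
  tss <- data.table(gene_id = sprintf("gene%03d", seq_along(prom_idx)),
                    chrom = peaks$chrom[prom_idx],
                    pos = as.integer((peaks$start[prom_idx] +
                                      peaks$end[prom_idx]) / 2) + 1L)

  # caQTL peaks: eligible peaks contain at least one variant that is
  # heterozygous in >= 2 donors (the mapping stage's testability floor;
  # effects planted on untestable variants could never be recovered)
  n_het <- colSums(genotypes$dosage == 1L)
  testable <- variants[variant_id %in% names(n_het)[n_het >= 2L]]
  eligible <- peaks$peak_id[peaks$peak_id %in% testable$peak_id]
  n_ca <- round(config$frac_caqtl_peaks * npk)
  ca_peaks <- sample(eligible, min(n_ca, length(eligible)))
  ct_names <- names(config$cell_types)
  caqtl <- rbindlist(lapply(ca_peaks, function(pk) {
    vs <- testable[peak_id == pk]
    v <- vs[sample.int(nrow(vs), 1L)]
    pi_raw <- runif(1, config$pi_effect_range[1], config$pi_effect_range[2])
    pi <- if (runif(1) < 0.5) pi_raw else 1 - pi_raw
    cts <- if (runif(1) < config$shared_fraction) ct_names
           else sample(ct_names, 1L)
    data.table(peak_id = pk, variant_id = v$variant_id, pi = pi,
               psi = runif(1, config$psi_range[1], config$psi_range[2]),
               delta = runif(1, config$delta_range[1], config$delta_range[2]),
               cell_types = paste(cts, collapse = ","))
  }))

  # co-accessible modules: promoter anchor + nearby distal peaks on the same
  # chromosome, pairwise > 10 kb apart (peak spacing guarantees non-adjacent
  # peaks are) and within 1 Mb
  modules <- list()
  used <- integer(0)
  per_chrom <- integer(0)   # at most 2 modules share a chromosome
  for (m in seq_len(config$n_coaccess_modules)) {
    pool <- setdiff(prom_idx, used)
    full <- names(per_chrom)[per_chrom >= 2L]
    pool <- pool[!peaks$chrom[pool] %in% full]
    if (!length(pool)) break
    anchor <- if (length(pool) == 1L) pool else sample(pool, 1L)
    mid_a <- (peaks$start[anchor] + peaks$end[anchor]) / 2
    cand <- which(peaks$chrom == peaks$chrom[anchor] &
                  abs((peaks$start + peaks$end) / 2 - mid_a) < 1.0e5 &
                  abs(seq_len(npk) - anchor) >= 2L)
    cand <- setdiff(cand, c(used, prom_idx))
    cand <- cand[abs(cand - anchor) %% 2 == 0]  # keep members mutually spaced
    if (length(cand) < config$coaccess_module_size - 1L) next
    members <- c(anchor, sample(cand, config$coaccess_module_size - 1L))
    modules[[length(modules) + 1L]] <- sort(members)
    used <- c(used, members)
    ch <- peaks$chrom[anchor]
    per_chrom[ch] <- (if (ch %in% names(per_chrom)) per_chrom[[ch]] else 0L) + 1L
  }

  if (is.null(caqtl) || nrow(caqtl) == 0L)
    caqtl <- data.table(peak_id = character(), variant_id = character(),
                        pi = numeric(), psi = numeric(), delta = numeric(),
                        cell_types = character())

  # GWAS causal variants: caQTL causal variants, one per chromosome
  if (nrow(caqtl)) {
    ca_v <- merge(caqtl, variants[, .(variant_id, chrom)], by = "variant_id")
    setorder(ca_v, chrom)
    picks <- ca_v[, .SD[sample.int(.N, 1L)], by = chrom]
    picks <- picks[seq_len(min(nrow(picks), config$n_gwas_signals))]
  } else {
    picks <- data.table(variant_id = character())
  }
  gwas <- data.table(signal_id = sprintf("sig%02d", seq_len(nrow(picks))),
                     variant_id = picks$variant_id,
                     beta = (2 * rbinom(nrow(picks), 1, 0.5) - 1) *
                            runif(nrow(picks), 0.04, 0.08))

  structure(list(peaks = peaks, lambda = lambda, caqtl = caqtl,
                 coaccess_modules = modules, gwas = gwas, tss = tss,
                 promoter_peaks = peaks$peak_id[prom_idx]),
            class = "ground_truth")
}

planted_pi <- function(truth, peak_id_, variant_id_, cell_type) {
  row <- truth$caqtl[peak_id == peak_id_ & variant_id == variant_id_]
  if (nrow(row) == 0L) return(NULL)
  cts <- strsplit(row$cell_types[1], ",", fixed = TRUE)[[1]]
  if (!(cell_type %in% cts)) return(NULL)
  row[1]
}

#' Simulate per-cell-type peak count matrices with allelic counts
#'
#' For each cell type and donor, total fragment counts per peak are negative
#' binomial with mean `s_j * a_ct * lambda_p * m(g, pi)` where
#' `m = (2-g)(1-pi) + g*pi`, `s_j` is a log-normal(0, 0.25) library factor and
#' `a_ct` the cell-type abundance.  At heterozygous variants, the
#' allele-informative depth is binomial(`total`, `allelic_fraction`) and the
#' alt count beta-binomial with mean `p' = p(1-2*delta) + delta`,
#' `p = pi(1-psi) / (pi(1-psi) + (1-pi)psi)`.  Non-caQTL variants (and
#' unaffected cell types) use `pi = 0.5` with their own mild reference bias.
#'
#' @param genotypes,truth,config cohort pieces from the sibling generators
#' @return object of class `peak_count_tensor`: per cell type a list with
#'   `totals` (peaks x samples), `allelic` (data.table: variant_id, peak_id,
#'   sample, ref_count, alt_count), `offsets`, `covariates`
#' @export
simulate_peak_counts <- function(genotypes, truth, config) {
  stop_if(!all(genotypes$peaks$peak_id %in% names(truth$lambda)),
          "invalid truth: peak without an assigned baseline accessibility")
  set.seed(child_seed(config$seed, 51L))
  peaks <- genotypes$peaks
  variants <- genotypes$variants
  ns <- config$n_samples
  s_j <- rlnorm(ns, 0, 0.25)
  names(s_j) <- genotypes$sample_ids

  # per-variant nuisance parameters (shared across cell types); planted
  # caQTL values override at their causal variant
  vpar <- data.table(variant_id = variants$variant_id,
                     psi = runif(nrow(variants), config$psi_range[1],
                                 config$psi_range[2]),
                     delta = runif(nrow(variants), config$delta_range[1],
                                   config$delta_range[2]))
  setkey(vpar, variant_id)

  tensor <- list()
  for (ct in names(config$cell_types)) {
    a_ct <- config$cell_types[[ct]]
    totals <- matrix(0L, nrow = nrow(peaks), ncol = ns,
                     dimnames = list(peaks$peak_id, genotypes$sample_ids))
    ca <- truth$caqtl
    pk_effect <- setNames(rep(0.5, nrow(peaks)), peaks$peak_id)
    pk_causal <- setNames(rep(NA_character_, nrow(peaks)), peaks$peak_id)
    for (i in seq_len(nrow(ca))) {
      cts <- strsplit(ca$cell_types[i], ",", fixed = TRUE)[[1]]
      if (ct %in% cts) {
        pk_effect[ca$peak_id[i]] <- ca$pi[i]
        pk_causal[ca$peak_id[i]] <- ca$variant_id[i]
      }
    }
    for (p in seq_len(nrow(peaks))) {
      pk <- peaks$peak_id[p]
      pi_p <- pk_effect[[pk]]
      g <- if (is.na(pk_causal[[pk]])) rep(1, ns)
           else genotypes$dosage[, pk_causal[[pk]]]
      m <- if (is.na(pk_causal[[pk]])) rep(1, ns)
           else (2 - g) * (1 - pi_p) + g * pi_p
      mu <- s_j * a_ct * truth$lambda[[pk]] * m
      totals[p, ] <- rnbinom(ns, size = 1 / config$nb_dispersion, mu = mu)
    }
    # allelic records at het samples for every variant inside a peak
    al <- vector("list", nrow(variants))
    for (v in seq_len(nrow(variants))) {
      vid <- variants$variant_id[v]
      pk <- variants$peak_id[v]
      het <- which(genotypes$dosage[, vid] == 1L)
      if (length(het) == 0L) next
      prow <- planted_pi(truth, pk, vid, ct)
      if (is.null(prow)) {
        pi_v <- 0.5; psi_v <- vpar[vid, psi]; del_v <- vpar[vid, delta]
      } else {
        pi_v <- prow$pi; psi_v <- prow$psi; del_v <- prow$delta
      }
      p_raw <- pi_v * (1 - psi_v) / (pi_v * (1 - psi_v) + (1 - pi_v) * psi_v)
      p_eff <- p_raw * (1 - 2 * del_v) + del_v
      tot <- totals[pk, het]
      d <- rbinom(length(het), tot, config$allelic_fraction)
      a_alt <- rbetabinom(length(het), d, p_eff, config$bb_overdispersion)
      keep <- d > 0L
      if (!any(keep)) next
      al[[v]] <- data.table(variant_id = vid, peak_id = pk,
                            sample = genotypes$sample_ids[het][keep],
                            ref_count = as.integer(d[keep] - a_alt[keep]),
                            alt_count = as.integer(a_alt[keep]))
    }
    tensor[[ct]] <- list(totals = totals, allelic = rbindlist(al),
                         offsets = s_j * a_ct,
                         covariates = matrix(0, nrow = ns, ncol = 0))
  }
  structure(tensor, class = "peak_count_tensor",
            sample_ids = genotypes$sample_ids)
}

#' Simulate a sparse single-cell peak matrix with co-accessible modules
#'
#' Cells emit Poisson counts per peak.  Each cell carries a 2-D latent
#' regulatory state; a planted module is "on" in cells on one side of a
#' module-specific hyperplane through that state, which multiplies the rate
#' of all its peaks by `module_amp` (and attenuates it otherwise).  The
#' returned embedding is 4-D: two cluster coordinates in which cells of the
#' same donor and cell type are proximal, plus the two state coordinates —
#' so kNN aggregation groups cells of similar regulatory state, the premise
#' of aggregation-based co-accessibility.
#'
#' @param truth,config cohort pieces
#' @param module_amp rate multiplier of "on" cells for module peaks
#' @return list with `counts` (peaks x cells), `embedding` (cells x 4),
#'   `cells` (data.table: cell_id, sample, cell_type)
#' @export
simulate_single_cells <- function(truth, config, module_amp = 4) {
  npk <- nrow(truth$peaks)
  bad <- unlist(truth$coaccess_modules) > npk
  stop_if(any(bad), "co-accessibility module refers to an unknown peak")
  set.seed(child_seed(config$seed, 67L))
  samples <- sprintf("S%02d", seq_len(config$n_samples))
  ct_names <- names(config$cell_types)
  n_cells <- config$n_cells_per_sample * config$n_samples
  if (n_cells == 0L) {
    return(list(counts = matrix(0L, nrow = npk, ncol = 0,
                                dimnames = list(truth$peaks$peak_id, NULL)),
                embedding = matrix(0, 0, 4),
                cells = data.table(cell_id = character(),
                                   sample = character(),
                                   cell_type = character())))
  }
  cells <- data.table(
    cell_id = sprintf("cell%05d", seq_len(n_cells)),
    sample = rep(samples, each = config$n_cells_per_sample))
  cells[, cell_type := sample(ct_names, .N, replace = TRUE,
                              prob = as.numeric(config$cell_types)),
        by = sample]

  # cluster-structured 2-D embedding per (sample, cell type)
  grid <- expand.grid(sample = samples, cell_type = ct_names,
                      stringsAsFactors = FALSE)
  centers <- as.matrix(expand.grid(seq_along(samples),
                                   seq_along(ct_names))) * 4 +
    matrix(rnorm(nrow(grid) * 2, 0, 0.5), ncol = 2)
  center_of <- match(paste(cells$sample, cells$cell_type),
                     paste(grid$sample, grid$cell_type))
  state <- matrix(rnorm(n_cells * 2), ncol = 2)
  embedding <- cbind(centers[center_of, , drop = FALSE] +
                       matrix(rnorm(n_cells * 2, 0, 0.35), ncol = 2),
                     state)
  rownames(embedding) <- cells$cell_id

  # rates: normalized baseline accessibility, mean ~0.15 fragments/cell/peak;
  # module peaks represent detectably accessible regulatory elements and get
  # a fixed representative rate (co-accessibility is only measurable at
  # peaks with enough per-cell signal)
  rate <- truth$lambda / mean(truth$lambda) * 0.15
  rate[unique(unlist(truth$coaccess_modules))] <- 0.2
  depth <- rlnorm(n_cells, 0, 0.3)
  counts <- matrix(rpois(npk * n_cells, outer(rate, depth)),
                   nrow = npk,
                   dimnames = list(truth$peaks$peak_id, cells$cell_id))
  n_mod <- length(truth$coaccess_modules)
  # modules sharing a chromosome (hence possibly a scoring window) get
  # orthogonal state directions, so their activities are independent
  mod_chrom <- vapply(truth$coaccess_modules,
                      function(m) truth$peaks$chrom[m[1]], "")
  within_idx <- stats::ave(seq_len(n_mod), mod_chrom, FUN = seq_along)
  for (m in seq_len(n_mod)) {
    mod <- truth$coaccess_modules[[m]]
    ang <- (within_idx[m] - 1L) * pi / 2
    on <- drop(state %*% c(cos(ang), sin(ang))) > 0
    amp <- ifelse(on, module_amp, 0.25)
    extra <- matrix(rpois(length(mod) * n_cells,
                          outer(rate[mod], depth * amp)),
                    nrow = length(mod))
    counts[mod, ] <- extra
  }
  list(counts = counts, embedding = embedding, cells = cells)
}

#' Simulate GWAS summary statistics with planted causal variants
#'
#' Marginal effects follow the standard single-causal model: for variant v in
#' the causal variant's \eqn{\pm}2.5 Mb neighbourhood, `beta_v = r_vc *
#' beta_c + e_v`, `SE_v = 1/sqrt(2 N maf_v (1-maf_v))`, with `r` the signed
#' dosage correlation estimated from the cohort.  The noise vector `e` is
#' drawn jointly with `cor(e_v, e_w) = r_vw` and `sd(e_v) = SE_v`: marginal
#' estimates of variants in LD come from the same phenotype data, so their
#' sampling errors are correlated — variants in perfect LD receive
#' near-identical summary statistics.  Monomorphic variants are dropped
#' (no summary statistic exists for them).  The index variant of each
#' signal maximizes `|beta/SE|`.
#'
#' @param genotypes,truth,config cohort pieces
#' @return list with `stats` (data.table: signal_id, variant_id, chrom, pos,
#'   ref, alt, beta, se) and `index` (data.table: signal_id, variant_id)
#' @export
simulate_gwas <- function(genotypes, truth, config) {
  set.seed(child_seed(config$seed, 83L))
  variants <- genotypes$variants
  stats_l <- list(); index_l <- list()
  for (i in seq_len(nrow(truth$gwas))) {
    sig <- truth$gwas[i]
    cv <- variants[variant_id == sig$variant_id]
    g_c <- genotypes$dosage[, sig$variant_id]
    stop_if(var(g_c) == 0, "GWAS causal variant is monomorphic in the cohort")
    neigh <- variants[chrom == cv$chrom & abs(pos - cv$pos) <= 2.5e6]
    G <- genotypes$dosage[, neigh$variant_id, drop = FALSE]
    poly <- apply(G, 2, var) > 0
    neigh <- neigh[poly]
    G <- G[, poly, drop = FALSE]
    R <- cor(G)
    r <- R[, cv$variant_id]
    se <- 1 / sqrt(2 * config$gwas_n * neigh$maf * (1 - neigh$maf))
    L <- chol(R + diag(1e-6, nrow(R)))
    e <- drop(crossprod(L, rnorm(nrow(neigh)))) * se
    beta <- r * sig$beta + e
    st <- data.table(signal_id = sig$signal_id,
                     variant_id = neigh$variant_id, chrom = neigh$chrom,
                     pos = neigh$pos, ref = neigh$ref, alt = neigh$alt,
                     beta = beta, se = se)
    stats_l[[i]] <- st
    index_l[[i]] <- st[which.max(abs(beta / se)),
                       .(signal_id, variant_id)]
  }
  list(stats = rbindlist(stats_l), index = rbindlist(index_l))
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper running all generators in order.
#'
#' @param config a [sim_config()]
#' @return list with `config`, `genotypes`, `truth`, `tensor`, `sc`, `gwas`
#' @export
simulate_cohort <- function(config = sim_config()) {
  genotypes <- simulate_genotypes(config)
  truth <- simulate_truth(genotypes, config)
  tensor <- simulate_peak_counts(genotypes, truth, config)
  sc <- simulate_single_cells(truth, config)
  gwas <- simulate_gwas(genotypes, truth, config)
  list(config = config, genotypes = genotypes, truth = truth,
       tensor = tensor, sc = sc, gwas = gwas)
}
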