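# File formats, run configuration and the end-to-end orchestrator.
#
# Dialects are deliberately minimal: biallelic-SNV VCF with GT only, BED
# 0-based half-open, TSV tables written by data.table.  All coordinates are
# converted at the boundary (VCF is 1-based, BED 0-based half-open).

#' Read a minimal VCF into cohort genotypes
#'
#' Accepts the biallelic-SNV dialect only: single-base REF/ALT, GT as the
#' first FORMAT field.  Multi-allelic records are rejected; `./.` genotypes
#' are treated as missing (NA dosage for that sample at that variant).
#'
#' @param path VCF file (uncompressed)
#' @return a `cohort_genotypes` (without the `peaks` element)
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  stop_if(length(hdr) != 1L, "malformed VCF: missing #CHROM header line")
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  stop_if(length(cols) < 10L, "malformed VCF: no sample columns")
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[!startsWith(body, "#")]
  n_v <- length(body)
  variants <- vector("list", n_v)
  dosage <- matrix(NA_integer_, nrow = length(samples), ncol = n_v)
  for (i in seq_len(n_v)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    lineno <- hdr + i
    stop_if(length(f) < 10L,
            paste0("malformed VCF record at line ", lineno))
    stop_if(grepl(",", f[5], fixed = TRUE),
            paste0("multi-allelic record rejected at line ", lineno,
                   " (biallelic-only dialect)"))
    stop_if(nchar(f[4]) != 1L || nchar(f[5]) != 1L,
            paste0("non-SNV record rejected at line ", lineno))
    gt <- sub(":.*$", "", f[-(1:9)])
    gt_clean <- gsub("|", "/", gt, fixed = TRUE)
    d <- ifelse(gt_clean %in% c("0/0"), 0L,
         ifelse(gt_clean %in% c("0/1", "1/0"), 1L,
         ifelse(gt_clean %in% c("1/1"), 2L, NA_integer_)))
    stop_if(any(!gt_clean %in% c("0/0", "0/1", "1/0", "1/1", "./.")),
            paste0("unparseable GT at line ", lineno))
    dosage[, i] <- d
    variants[[i]] <- data.table(variant_id = f[3], chrom = f[1],
                                pos = as.integer(f[2]), ref = f[4],
                                alt = f[5])
  }
  variants <- rbindlist(variants)
  rownames(dosage) <- samples
  colnames(dosage) <- variants$variant_id
  structure(list(variants = variants, dosage = dosage,
                 sample_ids = samples),
            class = "cohort_genotypes")
}

#' Write cohort genotypes as minimal VCF
#'
#' @param genotypes a `cohort_genotypes`
#' @param path output file
#' @export
write_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  codes <- c("0/0", "0/1", "1/1")
  gt <- matrix(codes[genotypes$dosage + 1L],
               nrow = nrow(genotypes$dosage),
               dimnames = dimnames(genotypes$dosage))
  gt[is.na(gt)] <- "./."
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", genotypes$sample_ids), collapse = "\t"))
  setorder(v, chrom, pos)
  recs <- vapply(seq_len(nrow(v)), function(i)
    paste(c(v$chrom[i], v$pos[i], v$variant_id[i], v$ref[i], v$alt[i],
            ".", "PASS", ".", "GT", gt[, v$variant_id[i]]), collapse = "\t"),
    "")
  writeLines(c(lines, recs), path)
}

#' Read a BED3+ file (0-based half-open)
#'
#' @param path BED file; column 4, when present, is taken as the interval id
#' @return data.table(chrom, start, end\[, peak_id\]) sorted by position
#' @export
read_bed <- function(path) {
  dt <- fread(path, header = FALSE)
  stop_if(ncol(dt) < 3L, "malformed BED: fewer than 3 columns")
  setnames(dt, 1:3, c("chrom", "start", "end"))
  if (ncol(dt) >= 4L) setnames(dt, 4L, "peak_id")
  stop_if(any(dt$start >= dt$end), "malformed BED: start >= end")
  setorder(dt, chrom, start, end)
  dt[]
}

#' Write intervals as BED (0-based half-open)
#'
#' @param dt data.table with chrom, start, end and optionally a name column
#' @param path output file
#' @param name_col optional column used as BED name field
#' @export
write_bed <- function(dt, path, name_col = NULL) {
  out <- dt[, .(chrom, start, end)]
  if (!is.null(name_col)) out[, name := dt[[name_col]]]
  fwrite(out, path, sep = "\t", col.names = FALSE)
}

write_tsv <- function(dt, path) fwrite(dt, path, sep = "\t")

#' Pipeline run configuration
#'
#' Assembles stage toggles and per-stage parameters with the conventional
#' defaults: 10 kb cis window, empirical FDR 0.10 (0.20 for promoter
#' propagation), k = 30 cell aggregation, 1 Mb co-accessibility window with
#' 0.05 score / 10 kb distance / 4-sample replication gates, Wakefield
#' W = 0.04 with r^2 > 0.1 within 2.5 Mb and 99% credible sets, 1,000
#' background draws for trait enrichment, and motif binding p < 5e-4.
#'
#' @param stages character vector of stages to run
#' @param out_dir output directory
#' @param seed global seed
#' @param sim a [sim_config()] for the simulate stage
#' @param ... per-stage overrides (window_bp, fdr, n_perm, k, coaccess_window,
#'   threshold, min_distance, min_replication, penalty, W, r2_min, ld_window,
#'   level, n_draws, p_thresh)
#' @return object of class `run_config`
#' @export
run_config <- function(stages = c("simulate", "map-caqtl", "heterogeneity",
                                  "coaccess", "finemap", "enrich", "motif"),
                       out_dir = tempfile("caqtlkit_run_"), seed = 1L,
                       sim = sim_config(seed = seed), ...) {
  defaults <- list(window_bp = 10000, fdr = 0.10, n_perm = 2L,
                   k = 30L, coaccess_window = 1e6, threshold = 0.05,
                   min_distance = 10000, min_replication = 4L,
                   penalty = 2.5, W = 0.04, r2_min = 0.1, ld_window = 2.5e6,
                   level = 0.99, n_draws = 1000L, p_thresh = 5e-4,
                   promoter_fdr = 0.20)
  extra <- list(...)
  unknown <- setdiff(names(extra), names(defaults))
  stop_if(length(unknown) > 0L,
          paste("unknown config keys:", paste(unknown, collapse = ", ")))
  params <- utils::modifyList(defaults, extra)
  known_stages <- c("simulate", "map-caqtl", "heterogeneity", "coaccess",
                    "finemap", "enrich", "motif")
  stop_if(!all(stages %in% known_stages),
          paste("unknown stages:", paste(setdiff(stages, known_stages),
                                         collapse = ", ")))
  structure(list(stages = stages, out_dir = out_dir, seed = as.integer(seed),
                 sim = sim, params = params),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order on a synthetic cohort:
#' simulate, per-cell-type caQTL mapping, heterogeneity, co-accessibility,
#' fine-mapping, trait enrichment, and motif disruption.  Every stage writes
#' TSV/BED/VCF outputs under `config$out_dir` plus a JSON manifest recording
#' parameters, seed and output hashes.  Reruns with the same config are
#' bit-identical.
#'
#' @param config a [run_config()]
#' @return named list of in-memory stage results (invisibly also on disk)
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- config$params
  res <- list()
  need <- function(stage, dep) {
    stop_if(!dep %in% names(res),
            paste0("stage '", stage, "' requires upstream stage '", dep, "'"))
  }

  if ("simulate" %in% config$stages) {
    cohort <- simulate_cohort(config$sim)
    res$simulate <- cohort
    write_vcf(cohort$genotypes, file.path(config$out_dir, "genotypes.vcf"))
    write_bed(cohort$genotypes$peaks, file.path(config$out_dir, "peaks.bed"),
              name_col = "peak_id")
    tssbed <- cohort$truth$tss[, .(chrom, start = pos - 1L, end = pos,
                                   gene_id)]
    write_bed(tssbed, file.path(config$out_dir, "tss.bed"),
              name_col = "gene_id")
    for (ct in names(cohort$tensor)) {
      write_tsv(data.table(peak_id = rownames(cohort$tensor[[ct]]$totals),
                           cohort$tensor[[ct]]$totals),
                file.path(config$out_dir, paste0("counts_", ct, ".tsv")))
      write_tsv(cohort$tensor[[ct]]$allelic,
                file.path(config$out_dir, paste0("allelic_", ct, ".tsv")))
    }
    write_tsv(cohort$gwas$stats, file.path(config$out_dir, "gwas.tsv"))
    truth_json <- list(
      caqtl = cohort$truth$caqtl,
      gwas = cohort$truth$gwas,
      coaccess_modules = lapply(cohort$truth$coaccess_modules,
                                function(m) cohort$truth$peaks$peak_id[m]),
      promoter_peaks = cohort$truth$promoter_peaks)
    jsonlite::write_json(truth_json,
                         file.path(config$out_dir, "ground_truth.json"),
                         dataframe = "rows")
  }

  if ("map-caqtl" %in% config$stages) {
    need("map-caqtl", "simulate")
    cohort <- res$simulate
    res[["map-caqtl"]] <- lapply(names(cohort$tensor), function(ct)
      map_caqtl(cohort$tensor, cohort$genotypes, ct,
                window_bp = p$window_bp, fdr = p$fdr, n_perm = p$n_perm,
                seed = child_seed(config$seed, 301L)))
    names(res[["map-caqtl"]]) <- names(cohort$tensor)
    for (ct in names(res[["map-caqtl"]]))
      write_tsv(res[["map-caqtl"]][[ct]],
                file.path(config$out_dir, paste0("caqtl_", ct, ".tsv")))
  }

  if ("heterogeneity" %in% config$stages) {
    need("heterogeneity", "map-caqtl")
    cohort <- res$simulate
    norm <- vst_normalize(cohort$tensor)
    leads <- unique(rbindlist(lapply(res[["map-caqtl"]], function(r)
      r[significant == TRUE, .(peak_id, variant_id)])))
    het <- interaction_test(norm, cohort$genotypes$dosage, leads)
    corr <- effect_correlation(res[["map-caqtl"]])
    res$heterogeneity <- list(interaction = het, correlation = corr)
    write_tsv(het, file.path(config$out_dir, "heterogeneity.tsv"))
    write_tsv(data.table(cell_type = rownames(corr), corr),
              file.path(config$out_dir, "effect_correlation.tsv"))
  }

  if ("coaccess" %in% config$stages) {
    need("coaccess", "simulate")
    cohort <- res$simulate
    cm <- coaccess_map(cohort$sc, cohort$genotypes$peaks, k = p$k,
                       window_bp = p$coaccess_window, penalty = p$penalty,
                       threshold = p$threshold,
                       min_distance = p$min_distance,
                       min_replication = p$min_replication,
                       seed = child_seed(config$seed, 307L))
    ann <- annotate_promoters(cohort$genotypes$peaks, cohort$truth$tss)
    res$coaccess <- c(cm, list(annotation = ann))
    pk <- cohort$genotypes$peaks
    setkey(pk, peak_id)
    bedpe <- cm$links[, .(chrom_a = pk[peak_a, chrom],
                          start_a = pk[peak_a, start],
                          end_a = pk[peak_a, end],
                          chrom_b = pk[peak_b, chrom],
                          start_b = pk[peak_b, start],
                          end_b = pk[peak_b, end],
                          score, n_samples_replicated)]
    write_tsv(bedpe, file.path(config$out_dir, "coaccess_links.tsv"))
    write_tsv(ann, file.path(config$out_dir, "promoter_annotation.tsv"))
  }

  if ("finemap" %in% config$stages) {
    need("finemap", "simulate")
    cohort <- res$simulate
    res$finemap <- finemap_signals(cohort$gwas, cohort$genotypes,
                                   W = p$W, r2_min = p$r2_min,
                                   window_bp = p$ld_window, level = p$level)
    write_tsv(res$finemap, file.path(config$out_dir, "credible_sets.tsv"))
  }

  if ("enrich" %in% config$stages) {
    need("enrich", "finemap"); need("enrich", "map-caqtl")
    cohort <- res$simulate
    vp <- cohort$genotypes$variants[, .(variant_id, peak_id)]
    enr <- rbindlist(lapply(names(res[["map-caqtl"]]), function(ct) {
      r <- res[["map-caqtl"]][[ct]]
      ca <- r[significant == TRUE, peak_id]
      bg <- setdiff(r$peak_id, ca)
      if (length(ca) == 0L || length(bg) < length(ca))
        return(data.table(cell_type = ct, observed = NA_real_,
                          empirical_p = NA_real_, log_or = NA_real_))
      e <- cumulative_ppa_enrichment(res$finemap, vp, ca, bg,
                                     n_draws = p$n_draws,
                                     seed = child_seed(config$seed, 311L))
      data.table(cell_type = ct, observed = e$observed,
                 empirical_p = e$empirical_p, log_or = e$log_or)
    }))
    res$enrich <- enr
    write_tsv(enr, file.path(config$out_dir, "trait_enrichment.tsv"))
  }

  if ("motif" %in% config$stages) {
    need("motif", "map-caqtl")
    cohort <- res$simulate
    pfms <- read_pfm(system.file("extdata", "motifs_synthetic.jaspar",
                                 package = "caqtlkit"))
    pwms <- lapply(pfms, build_pwm)
    tested <- unique(rbindlist(lapply(res[["map-caqtl"]], function(r)
      attr(r, "all_fits")[, .(variant_id)]))$variant_id)
    caqtl_v <- unique(rbindlist(lapply(res[["map-caqtl"]], function(r)
      r[significant == TRUE, .(variant_id)]))$variant_id)
    v <- cohort$genotypes$variants[variant_id %in% tested]
    Lmax <- max(vapply(pwms, function(w) ncol(w$mat), 0L))
    set.seed(child_seed(config$seed, 313L))
    calls <- rbindlist(lapply(seq_len(nrow(v)), function(i) {
      flank <- paste(sample(BASES, Lmax - 1L, replace = TRUE),
                     collapse = "")
      flank2 <- paste(sample(BASES, Lmax - 1L, replace = TRUE),
                      collapse = "")
      ctx <- paste0(flank, v$ref[i], flank2)
      rbindlist(lapply(names(pwms), function(m)
        cbind(data.table(variant_id = v$variant_id[i], motif_id = m),
              allelic_disruption(v$ref[i], v$alt[i], ctx, pwms[[m]],
                                 p_thresh = p$p_thresh))))
    }))
    res$motif <- motif_enrichment(calls, caqtl_v, tested)
    write_tsv(calls, file.path(config$out_dir, "motif_disruption.tsv"))
    write_tsv(res$motif$per_motif,
              file.path(config$out_dir, "motif_enrichment.tsv"))
  }

  outputs <- list.files(config$out_dir, full.names = TRUE)
  outputs <- sort(outputs[basename(outputs) != "manifest.json"])
  hashes <- tools::md5sum(outputs)
  names(hashes) <- basename(outputs)
  manifest <- list(seed = config$seed, stages = config$stages,
                   params = p,
                   sim = unclass(config$sim),
                   outputs = as.list(hashes))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
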