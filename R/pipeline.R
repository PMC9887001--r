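#' Run configuration with the study's default thresholds
#'
#' Collects every tunable threshold of the pipeline, pre-filled with the
#' study defaults: DEG padj < 0.05, fold > 2, FPKM >= 1 in one group; MZT
#' class FPKM >= 2; allelic p < 0.001, BH padj < 0.05, parental fold > 2,
#' >= 10 informative reads; DMS padj < 0.1, |difference| > 0.2, depth >= 5;
#' DMR gap < 500 bp, >= 3 DMSs, size > 50 bp; DHS top decile scale factor
#' and fold > 2; retrotransposon FPKM > 20 and fold >= 2.
#'
#' @param seed Seed forwarded to the simulator.
#' @param sim Named list of [sim_config()] overrides.
#' @param ... Threshold overrides; unknown names are rejected.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1, sim = list(), ...) {
  cfg <- list(
    seed = seed, sim = sim,
    deg_padj = 0.05, deg_fold = 2, deg_min_fpkm = 1,
    mzt_min_fpkm = 2, zga_expressed_min = 1,
    allelic_p = 0.001, allelic_padj = 0.05, allelic_fold = 2,
    allelic_min_reads = 10,
    site_min_depth = 3, dms_depth = 5, dms_padj = 0.1, dms_diff = 0.2,
    dmr_gap = 500, dmr_min_dms = 3, dmr_min_size = 50,
    dhs_top_frac = 0.1, dhs_fold = 2, dhs_pseudo = 0.5,
    retro_min_fpkm = 20, retro_fold = 2
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown run_config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  thr <- setdiff(names(cfg), c("seed", "sim"))
  if (any(unlist(cfg[thr]) <= 0)) {
    stop("every threshold must be positive", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()] (thresholds at the top level,
#' simulator overrides under `sim`); unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- y$seed %||% 1
  sim <- y$sim %||% list()
  y$seed <- NULL; y$sim <- NULL
  do.call(run_config, c(list(seed = seed, sim = sim), y))
}

#' Write all synthetic inputs (and truth tables) to disk
#'
#' Runs the four generators under `config$seed` and writes analysis inputs
#' under `<out_dir>/data` and ground-truth tables under `<out_dir>/truth`.
#' Analysis stages read only the `data` directory; the path separation is
#' what keeps truth out of the pipeline.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
simulate_inputs <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  data_dir <- file.path(out_dir, "data")
  truth_dir <- file.path(out_dir, "truth")
  dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(truth_dir, recursive = TRUE, showWarnings = FALSE)
  scfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))

  expr <- simulate_expression(scfg)
  write_counts_tsv(expr$counts, file.path(data_dir, "counts.tsv"))
  write_sample_sheet(expr$samples, file.path(data_dir, "samples.tsv"))
  write_bed12(genes_as_bed12(expr$genes), file.path(data_dir, "genes.bed12"))
  zga <- expr$truth$gene_id[expr$truth$class == "zga"]
  write_gene_list(zga, file.path(data_dir, "zga_list.txt"))
  readr::write_tsv(expr$truth, file.path(truth_dir, "truth_genes.tsv"))

  al <- simulate_allelic_counts(scfg)
  readr::write_tsv(al$counts, file.path(data_dir, "allelic_counts.tsv"))
  readr::write_tsv(al$truth, file.path(truth_dir, "truth_allelic.tsv"))

  me <- simulate_methylome_pair(scfg)
  write_bismark_cov(me$sample_a, file.path(data_dir, "methylome_A.cov"))
  write_bismark_cov(me$sample_b, file.path(data_dir, "methylome_B.cov"))
  readr::write_tsv(me$truth_dmrs, file.path(truth_dir, "truth_dmrs.tsv"))

  dh <- simulate_dhs_experiment(scfg)
  write_bed(dh$peaks$A, file.path(data_dir, "dhs_peaks_A.bed"))
  write_bed(dh$peaks$B, file.path(data_dir, "dhs_peaks_B.bed"))
  readr::write_tsv(dh$counts, file.path(data_dir, "dhs_counts.tsv"))
  readr::write_tsv(dh$bins, file.path(data_dir, "dhs_bins.tsv"))
  readr::write_tsv(tibble::tibble(sample = names(dh$library_sizes),
                                  library_size = unname(dh$library_sizes)),
                   file.path(data_dir, "dhs_libraries.tsv"))
  readr::write_tsv(dh$truth, file.path(truth_dir, "truth_peaks.tsv"))
  invisible(out_dir)
}

# single-exon BED12 records for simulated genes
genes_as_bed12 <- function(genes) {
  start <- seq(0, by = 20000, length.out = nrow(genes))
  tibble::tibble(
    chrom = genes$chrom, start = start, end = start + genes$length_bp,
    name = genes$gene_id, score = 0, strand = "+",
    thick_start = start, thick_end = start + genes$length_bp, rgb = "0",
    block_count = 1L, block_sizes = as.character(genes$length_bp),
    block_starts = "0"
  )
}

#' Analyse a simulated (or compatible) input directory
#'
#' Runs every analysis stage on the files under `<dir>/data` and writes
#' result tables plus a text run report under `<dir>/results`. Never touches
#' `<dir>/truth`.
#'
#' @param out_dir Directory containing `data/` (see [simulate_inputs()]).
#' @param config A [run_config()] with the thresholds to apply.
#' @return A list of class `mzt_report` with per-stage summary counts.
#' @export
analyse_dir <- function(out_dir, config = run_config()) {
  data_dir <- file.path(out_dir, "data")
  res_dir <- file.path(out_dir, "results")
  dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)
  rep <- list(thresholds = unclass(config)[setdiff(names(config), c("sim"))])

  # allele-specific expression
  al <- tsv_cols(file.path(data_dir, "allelic_counts.tsv"),
                 c("gene_id", "paternal_reads", "maternal_reads"),
                 "allelic counts")
  calls <- classify_allelic_genes(al, min_reads = config$allelic_min_reads,
                                  p_cutoff = config$allelic_p,
                                  padj_cutoff = config$allelic_padj,
                                  fold_cutoff = config$allelic_fold)
  readr::write_tsv(calls, file.path(res_dir, "allelic_calls.tsv"))
  rep$allelic <- table(calls$call)

  # expression: per-genotype 4C vs 8C, MZT classes, plus the morula contrast
  counts <- read_counts_tsv(file.path(data_dir, "counts.tsv"))
  samples <- read_sample_sheet(file.path(data_dir, "samples.tsv"))
  models <- read_bed12(file.path(data_dir, "genes.bed12"))
  lens <- bed12_gene_lengths(models)
  chroms <- stats::setNames(models$chrom, models$name)
  zga <- read_gene_list(file.path(data_dir, "zga_list.txt"))
  fpkm_grp <- merged_group_fpkm(counts, samples, lens)
  grp_samples <- function(g) {
    lab <- group_label(samples[, c("genotype", "stage", "treatment")])
    samples$sample_id[lab == g]
  }
  deg_pair <- function(ga, gb, exclude_chroms = NULL) {
    de <- differential_test(counts, grp_samples(ga), grp_samples(gb))
    call_degs(de, fpkm_grp[, c("gene_id", ga)], fpkm_grp[, c("gene_id", gb)],
              group_a = ga, group_b = gb,
              padj_cutoff = config$deg_padj, fold_cutoff = config$deg_fold,
              min_fpkm = config$deg_min_fpkm, gene_chroms = chroms,
              exclude_chroms = exclude_chroms)
  }
  rep$mzt <- list()
  for (gt in intersect(c("AG", "PG", "BI"), unique(samples$genotype))) {
    deg <- deg_pair(paste0(gt, "_4C"), paste0(gt, "_8C"))
    readr::write_tsv(deg, file.path(res_dir, paste0("deg_", gt, "_4C_8C.tsv")))
    cls <- classify_mzt(deg, fpkm_grp[, c("gene_id", paste0(gt, "_4C"))],
                        fpkm_grp[, c("gene_id", paste0(gt, "_8C"))],
                        zga_genes = zga, min_fpkm = config$mzt_min_fpkm,
                        zga_expressed_min = config$zga_expressed_min)
    readr::write_tsv(cls, file.path(res_dir, paste0("mzt_", gt, ".tsv")))
    rep$mzt[[gt]] <- table(cls$class)
  }
  if (all(c("AG", "PG") %in% samples$genotype)) {
    # X-linked genes are excluded from any comparison involving AG morulae
    deg_m <- deg_pair("AG_morula", "PG_morula", exclude_chroms = "chrX")
    readr::write_tsv(deg_m, file.path(res_dir, "deg_AG_PG_morula.tsv"))
    rep$deg_morula <- sum(deg_m$is_deg)
  }

  # methylome
  a <- read_bismark_cov(file.path(data_dir, "methylome_A.cov"))
  b <- read_bismark_cov(file.path(data_dir, "methylome_B.cov"))
  a3 <- site_methylation(a, config$site_min_depth)
  b3 <- site_methylation(b, config$site_min_depth)
  rep$global_ml <- c(A = global_methylation(a3), B = global_methylation(b3))
  dms <- call_dms(a3, b3, min_depth = config$dms_depth,
                  padj_cutoff = config$dms_padj, min_diff = config$dms_diff)
  readr::write_tsv(dms, file.path(res_dir, "dms.tsv"))
  dmrs <- merge_dmrs(dms, max_gap = config$dmr_gap,
                     min_dms = config$dmr_min_dms,
                     min_size = config$dmr_min_size,
                     min_diff = config$dms_diff,
                     padj_cutoff = config$dms_padj)
  readr::write_tsv(dmrs, file.path(res_dir, "dmrs.tsv"))
  rep$dms <- c(tested = nrow(dms), dms = sum(dms$is_dms), dmrs = nrow(dmrs))

  # chromatin accessibility
  pa <- read_bed(file.path(data_dir, "dhs_peaks_A.bed"))
  pb <- read_bed(file.path(data_dir, "dhs_peaks_B.bed"))
  dcounts <- tsv_cols(file.path(data_dir, "dhs_counts.tsv"),
                      c("chrom", "start", "end"), "DHS counts")
  libs <- tsv_cols(file.path(data_dir, "dhs_libraries.tsv"),
                   c("sample", "library_size"), "DHS libraries")
  libv <- stats::setNames(libs$library_size, libs$sample)
  master <- build_master_list(list(A = pa, B = pb))
  sig <- quantify_signal(master, dcounts, libv)
  sf <- compute_scale_factor(sig$fpkm_A, sig$fpkm_B,
                             top_frac = config$dhs_top_frac)
  dhs <- call_allelic_dhs(sig, sf, samples = c("A", "B"),
                          fold_cutoff = config$dhs_fold,
                          pseudo = config$dhs_pseudo)
  readr::write_tsv(dhs, file.path(res_dir, "dhs_calls.tsv"))
  bins <- tsv_cols(file.path(data_dir, "dhs_bins.tsv"),
                   c("chrom", "start", "end"), "bin counts")
  dens <- bin_density(bins, stats::setNames(rep(libv, each = 2),
                                            setdiff(names(bins),
                                                    c("chrom", "start", "end"))))
  rep$dhs <- list(scale_factor = sf$value, calls = table(dhs$call),
                  replicate_r = c(A = replicate_correlation(dens$A_r1, dens$A_r2),
                                  B = replicate_correlation(dens$B_r1, dens$B_r2)))
  class(rep) <- "mzt_report"
  writeLines(format(rep), file.path(res_dir, "report.txt"))
  rep
}

#' Simulate and analyse in one call
#'
#' @inheritParams simulate_inputs
#' @return The [analyse_dir()] report.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  simulate_inputs(config, out_dir)
  analyse_dir(out_dir, config)
}

#' @export
format.mzt_report <- function(x, ...) {
  fmt_tab <- function(t) paste(names(t), unname(t), sep = "=", collapse = "  ")
  out <- c("== run report ==", "thresholds:")
  thr <- x$thresholds[setdiff(names(x$thresholds), "seed")]
  out <- c(out, paste0("  ", names(thr), " = ", unlist(thr)))
  out <- c(out, paste0("seed = ", x$thresholds$seed))
  out <- c(out, paste0("allelic calls: ", fmt_tab(x$allelic)))
  for (gt in names(x$mzt)) {
    out <- c(out, paste0("MZT classes [", gt, "]: ", fmt_tab(x$mzt[[gt]])))
  }
  if (!is.null(x$deg_morula)) {
    out <- c(out, paste0("AG vs PG morula DEGs (chrX excluded): ", x$deg_morula))
  }
  out <- c(out,
           sprintf("global ML: A=%.4f B=%.4f", x$global_ml["A"], x$global_ml["B"]),
           paste0("methylation: ", fmt_tab(x$dms)),
           sprintf("DHS scale factor: %.4f", x$dhs$scale_factor),
           paste0("DHS calls: ", fmt_tab(x$dhs$calls)),
           sprintf("replicate r: A=%.4f B=%.4f",
                   x$dhs$replicate_r["A"], x$dhs$replicate_r["B"]))
  out
}

#' @export
print.mzt_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}
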