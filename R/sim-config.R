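#' Configuration for the synthetic embryo multi-omics generator
#'
#' Collects every knob of the synthetic-data module in one validated object.
#' The defaults encode the study conditions the generators emulate: a
#' parthenogenetic (PG, maternal-genome) vs androgenetic (AG, paternal-genome)
#' embryo series over the 4-cell, 8-cell and morula stages in which the major
#' zygotic genome activation (ZGA) wave fires at the 8-cell stage on the
#' paternal side but is delayed to the morula in PG embryos, and maternal RNA
#' degradation tracks ZGA.
#'
#' @param seed Integer seed; every generator derives its stream from it.
#' @param n_genes Number of simulated genes.
#' @param frac_zga,frac_decay Fractions of genes in the injected ZGA and
#'   maternal-decay programs (the rest are stably expressed);
#'   `frac_zga + frac_decay <= 1`.
#' @param genotypes Simulated genotypes; subset of `c("AG", "PG", "BI")`
#'   (BI = biparental). AG/BI activate ZGA at the 8-cell stage, PG at morula.
#' @param n_rep Replicates per stage/genotype group.
#' @param n_rep_amanitin Replicates of additional alpha-amanitin-treated
#'   8-cell samples per genotype (transcription-blocked: ZGA genes stay at
#'   pre-activation mean, maternal decay does not occur). 0 disables them.
#' @param library_size Expected reads per sample.
#' @param nb_dispersion Negative-binomial dispersion `phi` in
#'   `Var = mu + phi * mu^2`; 0 gives Poisson counts.
#' @param zga_mu_pre Pre-activation mean (in raw mean units before library
#'   scaling) of ZGA genes; post-activation mean is `zga_mu_pre * zga_fold`.
#' @param zga_fold,decay_fold Fold change of the ZGA and decay programs.
#' @param decay_mu_high 4-cell mean of maternal-decay genes (decayed mean is
#'   `decay_mu_high / decay_fold`).
#' @param stable_mu_meanlog,stable_mu_sdlog Log-normal parameters of stable
#'   gene means.
#' @param frac_chrx Fraction of genes placed on chromosome X (the rest on the
#'   toy chromosome), to exercise the X-exclusion rule for AG morulae.
#' @param gene_length_range Range (bp) of simulated gene lengths.
#' @param n_allelic_genes Number of genes in the allelic read-count generator.
#' @param frac_paternal,frac_maternal Fractions of paternally / maternally
#'   biased genes; the rest are biallelic (paternal read probability 0.5).
#' @param allelic_pi Paternal-read probability `pi` of a paternally biased
#'   gene (maternally biased genes use `1 - pi`); must be in (0.5, 1].
#' @param depth_mean,depth_min Informative-read depth per gene is
#'   `depth_min + Poisson(depth_mean - depth_min)`.
#' @param n_cpgs Number of simulated CpG sites (both methylomes).
#' @param n_dmrs,dmr_cpgs Number of injected DMRs and CpGs per DMR.
#' @param dmr_delta Methylation-level shift `delta` added to the designated
#'   hyper sample inside a DMR (clamped to \[0, 1\]).
#' @param frac_dmr_maternal Fraction of DMRs that are maternally (sample A,
#'   PG) hypermethylated; the rest are paternally (sample B, AG) hyper.
#' @param cpg_depth Mean Poisson read depth `lambda` per CpG per sample
#'   (depth-0 sites are dropped from the written coverage, as in real
#'   bisulfite coverage files).
#' @param cpg_spacing Mean spacing (bp) between adjacent CpGs.
#' @param baseline_ml Baseline methylation levels cycled across background
#'   blocks.
#' @param dmr_baseline Baseline methylation level inside DMRs before the
#'   `dmr_delta` shift.
#' @param ml_shift_b Global additive shift of sample B's background
#'   methylation (e.g. a negative value emulates global paternal
#'   hypomethylation); clamped to \[0, 1\].
#' @param n_peaks Number of DHS peaks in the accessibility generator.
#' @param frac_peak_specific Fraction of allele-specific peaks (split evenly
#'   between the two samples); specific peaks are absent from the other
#'   sample's peak-call list and carry only background signal there.
#' @param peak_mu_log,peak_sd_log Log-normal parameters of true peak signal.
#' @param peak_min_signal Detectability floor (FPKM) applied to true peak
#'   signal: a called peak must rise above background, so signal below the
#'   floor is raised to it.
#' @param peak_width_range Range (bp) of peak widths.
#' @param dhs_background Mean background signal (same units as peak signal)
#'   quantified over a peak in a sample where it is not called.
#' @param dhs_beta Signal-to-noise ratio A:B; sample B's in-peak signal is
#'   divided by `dhs_beta` before read sampling, so the top-decile scale
#'   factor (median A / median B) recovers `dhs_beta`.
#' @param dhs_library Sequencing library size used to convert signal to
#'   Poisson read counts for both samples.
#' @param chrom,chrom_size Name and size (bp) of the single toy chromosome on
#'   which all coordinate-bearing simulations live.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 200)
#' cfg$frac_zga
#' @export
sim_config <- function(seed = 1,
                       # expression
                       n_genes = 2000,
                       frac_zga = 0.15,
                       frac_decay = 0.15,
                       genotypes = c("AG", "PG"),
                       n_rep = 3,
                       n_rep_amanitin = 0,
                       library_size = 1e6,
                       nb_dispersion = 0.1,
                       zga_mu_pre = 1,
                       zga_fold = 16,
                       decay_mu_high = 100,
                       decay_fold = 16,
                       stable_mu_meanlog = log(50),
                       stable_mu_sdlog = 1,
                       frac_chrx = 0.05,
                       gene_length_range = c(500, 5000),
                       # allelic read counts
                       n_allelic_genes = 2000,
                       frac_paternal = 0.05,
                       frac_maternal = 0.05,
                       allelic_pi = 0.95,
                       depth_mean = 60,
                       depth_min = 30,
                       # methylome
                       n_cpgs = 2400,
                       n_dmrs = 100,
                       dmr_cpgs = 8,
                       dmr_delta = 0.5,
                       frac_dmr_maternal = 0.5,
                       cpg_depth = 10,
                       cpg_spacing = 55,
                       baseline_ml = c(0.2, 0.5, 0.8),
                       dmr_baseline = 0.5,
                       ml_shift_b = 0,
                       # chromatin accessibility
                       n_peaks = 2000,
                       frac_peak_specific = 0.1,
                       peak_mu_log = log(5),
                       peak_sd_log = 1,
                       peak_min_signal = 2,
                       peak_width_range = c(200, 1000),
                       dhs_background = 0.3,
                       dhs_beta = 2,
                       dhs_library = 2e7,
                       chrom = "chrS",
                       chrom_size = 10e6) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!all(ok)) stop("sim_config: ", msg, call. = FALSE)
  chk(is.finite(cfg$seed), "seed must be a finite integer")
  pos <- c("n_genes", "n_rep", "library_size", "n_allelic_genes", "depth_mean",
           "depth_min", "n_cpgs", "cpg_depth", "cpg_spacing", "n_peaks",
           "dhs_library", "chrom_size", "zga_mu_pre", "zga_fold",
           "decay_mu_high", "decay_fold", "dmr_cpgs")
  for (f in pos) chk(cfg[[f]] > 0, paste(f, "must be positive"))
  nonneg <- c("n_rep_amanitin", "nb_dispersion", "n_dmrs", "dhs_background",
              "frac_chrx")
  for (f in nonneg) chk(cfg[[f]] >= 0, paste(f, "must be non-negative"))
  chk(cfg$frac_zga >= 0 && cfg$frac_decay >= 0 &&
        cfg$frac_zga + cfg$frac_decay <= 1,
      "gene class fractions must be non-negative and sum to <= 1")
  chk(cfg$frac_paternal >= 0 && cfg$frac_maternal >= 0 &&
        cfg$frac_paternal + cfg$frac_maternal <= 1,
      "allelic bias fractions must be non-negative and sum to <= 1")
  chk(cfg$allelic_pi > 0.5 && cfg$allelic_pi <= 1, "allelic_pi must be in (0.5, 1]")
  chk(cfg$depth_min <= cfg$depth_mean, "depth_min must not exceed depth_mean")
  chk(all(cfg$genotypes %in% c("AG", "PG", "BI")) && length(cfg$genotypes) >= 1,
      "genotypes must be a non-empty subset of AG, PG, BI")
  chk(cfg$dmr_delta >= 0 && cfg$dmr_delta <= 1, "dmr_delta must be in [0, 1]")
  chk(cfg$frac_dmr_maternal >= 0 && cfg$frac_dmr_maternal <= 1,
      "frac_dmr_maternal must be in [0, 1]")
  chk(all(cfg$baseline_ml >= 0 & cfg$baseline_ml <= 1) &&
        cfg$dmr_baseline >= 0 && cfg$dmr_baseline <= 1,
      "methylation baselines must be in [0, 1]")
  chk(cfg$n_dmrs * cfg$dmr_cpgs <= cfg$n_cpgs,
      "n_dmrs * dmr_cpgs must not exceed n_cpgs")
  chk(cfg$frac_peak_specific >= 0 && cfg$frac_peak_specific <= 1,
      "frac_peak_specific must be in [0, 1]")
  chk(cfg$dhs_beta > 0, "dhs_beta must be positive")
  chk(cfg$peak_min_signal >= 0, "peak_min_signal must be non-negative")
  chk(length(cfg$gene_length_range) == 2 && diff(cfg$gene_length_range) >= 0 &&
        cfg$gene_length_range[1] > 0, "gene_length_range must be increasing positive")
  chk(length(cfg$peak_width_range) == 2 && diff(cfg$peak_width_range) >= 0 &&
        cfg$peak_width_range[1] > 0, "peak_width_range must be increasing positive")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "\n")
  cat("  expression:", x$n_genes, "genes (",
      round(100 * x$frac_zga), "% ZGA,", round(100 * x$frac_decay),
      "% maternal decay ),", paste(x$genotypes, collapse = "/"),
      "x 4C/8C/morula x", x$n_rep, "reps\n")
  cat("  allelic:", x$n_allelic_genes, "genes, pi =", x$allelic_pi, "\n")
  cat("  methylome:", x$n_cpgs, "CpGs,", x$n_dmrs, "DMRs x", x$dmr_cpgs,
      "CpGs, delta =", x$dmr_delta, ", lambda =", x$cpg_depth, "\n")
  cat("  accessibility:", x$n_peaks, "peaks, beta =", x$dhs_beta, "\n")
  invisible(x)
}

# seed-splitting scheme: each generator runs under seed + fixed offset so the
# four data types are independent but jointly reproducible from one seed
sim_seed <- function(cfg, offset) {
  (cfg$seed + offset) %% .Machine$integer.max
}
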