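#' Simulate a pair of CpG methylomes with injected DMRs
#'
#' Lays out `n_cpgs` CpG sites along the toy chromosome (mean spacing
#' `cpg_spacing` bp) as alternating background segments and `n_dmrs` injected
#' DMRs of `dmr_cpgs` consecutive CpGs each, separated by at least 500 bp of
#' margin so truth regions can never chain together. Background methylation
#' cycles through `baseline_ml` per segment in both samples; inside a DMR the
#' designated hypermethylated sample's level is shifted by `+dmr_delta`
#' (clamped to 1) from `dmr_baseline`. A fraction `frac_dmr_maternal` of DMRs
#' are sample-A (PG, maternal) hyper, the rest sample-B (AG, paternal) hyper.
#' `ml_shift_b` adds a global offset to sample B's background, emulating
#' genome-wide paternal hypomethylation.
#'
#' Per sample and site, read depth is `Poisson(cpg_depth)`; depth-0 sites are
#' omitted from that sample's table (bisulfite coverage files only list
#' covered sites) and methylated counts are `Binomial(depth, ML)`.
#'
#' @param config A [sim_config()]. Errors if the implied layout does not fit
#'   in `chrom_size` (injected DMRs would fall outside the simulated
#'   coordinate range).
#' @return A list of class `sim_methylome` with `sample_a` / `sample_b`
#'   (tibbles `chrom`, `pos` (1-based), `m`, `u`), and `truth_dmrs`
#'   (tibble `chrom`, `start`, `end` (1-based inclusive), `direction`
#'   (`"A"` or `"B"` = hyper sample), `delta`).
#' @examples
#' sim <- simulate_methylome_pair(sim_config(seed = 1, n_cpgs = 400, n_dmrs = 10))
#' nrow(sim$truth_dmrs)
#' @export
simulate_methylome_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(sim_seed(config, 303L), {
    n_dmr_sites <- config$n_dmrs * config$dmr_cpgs
    n_bg <- config$n_cpgs - n_dmr_sites
    n_seg <- config$n_dmrs + 1
    bg_per_seg <- rep(n_bg %/% n_seg, n_seg)
    extra <- n_bg %% n_seg
    if (extra > 0) bg_per_seg[seq_len(extra)] <- bg_per_seg[seq_len(extra)] + 1

    margin <- 600  # > 500 bp DMR chaining gap, so truth regions stay separate
    pos <- numeric(0)
    dmr_id <- integer(0)       # 0 = background, k = member of DMR k
    seg_id <- integer(0)       # background segment index (for baseline cycling)
    truth_start <- truth_end <- numeric(config$n_dmrs)
    cur <- 1000
    step <- function(k) cumsum(2 + stats::rexp(k, 1 / config$cpg_spacing))
    for (i in seq_len(n_seg)) {
      if (bg_per_seg[i] > 0) {
        p <- cur + step(bg_per_seg[i])
        pos <- c(pos, p); dmr_id <- c(dmr_id, rep(0L, bg_per_seg[i]))
        seg_id <- c(seg_id, rep(i, bg_per_seg[i]))
        cur <- p[length(p)]
      }
      if (i <= config$n_dmrs) {
        cur <- cur + margin
        p <- cur + step(config$dmr_cpgs)
        pos <- c(pos, p); dmr_id <- c(dmr_id, rep(i, config$dmr_cpgs))
        seg_id <- c(seg_id, rep(0L, config$dmr_cpgs))
        truth_start[i] <- round(p[1]); truth_end[i] <- round(p[length(p)])
        cur <- p[length(p)] + margin
      }
    }
    pos <- round(pos)
    pos <- pos + cumsum(c(0, as.integer(diff(pos) <= 0)))  # enforce strictly increasing
    if (max(pos) > config$chrom_size) {
      stop("simulate_methylome_pair: injected DMR layout exceeds chrom_size (",
           max(pos), " > ", config$chrom_size, ")", call. = FALSE)
    }

    n_mat_dmr <- round(config$frac_dmr_maternal * config$n_dmrs)
    # interleave directions along the chromosome
    direction <- rep("B", config$n_dmrs)
    if (n_mat_dmr > 0) {
      direction[round(seq(1, config$n_dmrs, length.out = n_mat_dmr))] <- "A"
    }

    clamp <- function(x) pmin(1, pmax(0, x))
    ml_a <- ml_b <- numeric(length(pos))
    bg <- dmr_id == 0L
    cyc <- config$baseline_ml[(seg_id[bg] - 1L) %% length(config$baseline_ml) + 1L]
    ml_a[bg] <- cyc
    ml_b[bg] <- clamp(cyc + config$ml_shift_b)
    for (k in seq_len(config$n_dmrs)) {
      idx <- dmr_id == k
      ml_a[idx] <- config$dmr_baseline
      ml_b[idx] <- config$dmr_baseline
      if (direction[k] == "A") ml_a[idx] <- clamp(config$dmr_baseline + config$dmr_delta)
      else ml_b[idx] <- clamp(config$dmr_baseline + config$dmr_delta)
    }

    draw_sample <- function(ml) {
      depth <- stats::rpois(length(pos), config$cpg_depth)
      keep <- depth > 0
      m <- stats::rbinom(sum(keep), depth[keep], ml[keep])
      tibble::tibble(chrom = config$chrom, pos = pos[keep], m = m,
                     u = depth[keep] - m)
    }
    structure(list(
      sample_a = draw_sample(ml_a),
      sample_b = draw_sample(ml_b),
      truth_dmrs = tibble::tibble(chrom = config$chrom, start = truth_start,
                                  end = truth_end, direction = direction,
                                  delta = config$dmr_delta)
    ), class = "sim_methylome")
  })
}

#' Simulate a two-sample DHS accessibility experiment
#'
#' Generates `n_peaks` non-overlapping peak intervals (0-based half-open) on
#' the toy chromosome. Shared peaks carry the same true log-normal signal in
#' both samples; allele-specific peaks carry signal only in their own sample,
#' are absent from the other sample's peak-call list, and show mean
#' `dhs_background` signal there. Sample B's in-peak signal is divided by
#' `dhs_beta` before reads are drawn, emulating a different signal-to-noise
#' ratio between the two samples; both libraries have `dhs_library` total
#' reads, so a top-decile median scale factor (A over B) should recover
#' `dhs_beta`. Per-peak read counts are Poisson around
#' `signal * width * library / 1e9` (i.e. signal is in FPKM units).
#'
#' Also emits 5-kb bin read counts for two technical replicates of each
#' sample (Poisson around a shared bin intensity) for reproducibility QC.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_dhs`:
#' \describe{
#'   \item{peaks}{named list `A` / `B` of called-peak tibbles
#'     (`chrom`, `start`, `end`).}
#'   \item{counts}{tibble `chrom`, `start`, `end`, `A`, `B` — per-interval
#'     read counts over the full peak universe.}
#'   \item{library_sizes}{named vector of total reads per sample.}
#'   \item{bins}{tibble of 5-kb bin counts `A_r1`, `A_r2`, `B_r1`, `B_r2`.}
#'   \item{truth}{tibble `chrom`, `start`, `end`, `label`
#'     (shared / a_specific / b_specific).}
#' }
#' @examples
#' sim <- simulate_dhs_experiment(sim_config(seed = 1, n_peaks = 100))
#' dplyr::count(sim$truth, label)
#' @export
simulate_dhs_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(sim_seed(config, 404L), {
    n <- config$n_peaks
    width <- round(stats::runif(n, config$peak_width_range[1],
                                config$peak_width_range[2]))
    gap <- round(stats::rexp(n, 1 / 2000)) + 500
    start <- cumsum(gap) + c(0, cumsum(width))[seq_len(n)]
    end <- start + width
    if (max(end) > config$chrom_size) {
      stop("simulate_dhs_experiment: peaks exceed chrom_size", call. = FALSE)
    }
    n_spec <- round(config$frac_peak_specific * n)
    label <- rep("shared", n)
    if (n_spec > 0) {
      idx <- sample.int(n, n_spec)
      label[idx] <- rep_len(c("a_specific", "b_specific"), n_spec)
    }
    true_sig <- pmax(stats::rlnorm(n, config$peak_mu_log, config$peak_sd_log),
                     config$peak_min_signal)
    bg <- function(k) stats::rlnorm(k, log(config$dhs_background), 0.5)
    sig_a <- ifelse(label == "b_specific", bg(n), true_sig)
    sig_b_true <- ifelse(label == "a_specific", bg(n), true_sig)
    sig_b <- sig_b_true / config$dhs_beta  # sample B's signal-to-noise penalty

    to_counts <- function(sig) {
      stats::rpois(n, sig * width * config$dhs_library / 1e9)
    }
    counts <- tibble::tibble(chrom = config$chrom, start = start, end = end,
                             A = to_counts(sig_a), B = to_counts(sig_b))
    peaks <- list(
      A = tibble::tibble(chrom = config$chrom, start = start,
                         end = end)[label != "b_specific", ],
      B = tibble::tibble(chrom = config$chrom, start = start,
                         end = end)[label != "a_specific", ]
    )
    n_bins <- 1000
    bin_mu <- stats::rlnorm(n_bins, log(20), 1)
    bins <- tibble::tibble(
      chrom = config$chrom,
      start = seq(0L, by = 5000L, length.out = n_bins),
      end = seq(5000L, by = 5000L, length.out = n_bins),
      A_r1 = stats::rpois(n_bins, bin_mu), A_r2 = stats::rpois(n_bins, bin_mu),
      B_r1 = stats::rpois(n_bins, bin_mu / config$dhs_beta),
      B_r2 = stats::rpois(n_bins, bin_mu / config$dhs_beta)
    )
    structure(list(
      peaks = peaks,
      counts = counts,
      library_sizes = c(A = config$dhs_library, B = config$dhs_library),
      bins = bins,
      truth = tibble::tibble(chrom = config$chrom, start = start, end = end,
                             label = label)
    ), class = "sim_dhs")
  })
}
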