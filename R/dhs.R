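#' Build a DHS master list from per-sample peak calls
#'
#' Concatenates the peak sets of all samples and merges any overlapping
#' intervals into one master peak (transitively). Each master peak is flagged
#' as detected in a sample when it overlaps at least one of that sample's
#' original peaks. Coordinates are 0-based half-open throughout this module.
#'
#' @param peak_sets Named list of peak tibbles (`chrom`, `start`, `end`).
#' @return Tibble `chrom`, `start`, `end`, `width` plus one logical
#'   `detected_<sample>` column per input set.
#' @examples
#' ps <- list(A = tibble::tibble(chrom = "chrS", start = 100, end = 200),
#'            B = tibble::tibble(chrom = "chrS", start = 150, end = 250))
#' build_master_list(ps)  # one master peak [100, 250)
#' @export
build_master_list <- function(peak_sets) {
  stopifnot(is.list(peak_sets), length(peak_sets) >= 1,
            !is.null(names(peak_sets)))
  for (nm in names(peak_sets)) {
    p <- peak_sets[[nm]]
    bad <- which(!(p$end > p$start) | p$start < 0)
    if (length(bad)) {
      stop("malformed interval(s) in peak set '", nm, "' at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  grs <- lapply(peak_sets, function(p) {
    GenomicRanges::GRanges(p$chrom, IRanges::IRanges(p$start + 1, p$end))
  })
  master <- GenomicRanges::reduce(do.call(c, unname(grs)))
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(master)),
    start = GenomicRanges::start(master) - 1,
    end = GenomicRanges::end(master),
    width = GenomicRanges::width(master)
  )
  for (nm in names(peak_sets)) {
    out[[paste0("detected_", nm)]] <-
      GenomicRanges::countOverlaps(master, grs[[nm]]) > 0
  }
  out
}

#' Quantify FPKM signal over master peaks
#'
#' Assigns per-interval read counts to master peaks by overlap (summing
#' counts of all overlapping count intervals) and converts to
#' `FPKM = reads * 1e9 / (width_bp * library_size)`.
#'
#' @param master Master-list tibble from [build_master_list()].
#' @param counts Tibble `chrom`, `start`, `end` plus one numeric read-count
#'   column per sample (0-based half-open intervals).
#' @param library_sizes Named vector of total mapped reads per sample; must
#'   be positive.
#' @return `master` with one `fpkm_<sample>` column per sample.
#' @export
quantify_signal <- function(master, counts, library_sizes) {
  samp <- setdiff(names(counts), c("chrom", "start", "end"))
  if (any(master$width <= 0)) stop("zero-width master peak", call. = FALSE)
  if (anyNA(library_sizes[samp]) || any(library_sizes[samp] <= 0)) {
    stop("library sizes must be positive for every sample", call. = FALSE)
  }
  gm <- GenomicRanges::GRanges(master$chrom,
                               IRanges::IRanges(master$start + 1, master$end))
  gc_ <- GenomicRanges::GRanges(counts$chrom,
                                IRanges::IRanges(counts$start + 1, counts$end))
  hits <- GenomicRanges::findOverlaps(gm, gc_)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  out <- master
  for (s in samp) {
    tot <- numeric(nrow(master))
    if (length(qi)) {
      sums <- rowsum(counts[[s]][si], qi, reorder = TRUE)
      tot[as.integer(rownames(sums))] <- sums[, 1]
    }
    out[[paste0("fpkm_", s)]] <- tot * 1e9 / (master$width * library_sizes[[s]])
  }
  out
}

#' Tag density over genome bins and replicate reproducibility
#'
#' Converts per-bin read counts to FPKM tag densities; reproducibility
#' between two replicates is the Pearson correlation of their densities.
#'
#' @param bins Tibble `chrom`, `start`, `end` plus count columns.
#' @param library_sizes Named vector of library sizes per count column.
#' @return `bins` with count columns replaced by FPKM densities.
#' @export
bin_density <- function(bins, library_sizes) {
  samp <- setdiff(names(bins), c("chrom", "start", "end"))
  w <- bins$end - bins$start
  out <- bins
  for (s in samp) out[[s]] <- bins[[s]] * 1e9 / (w * library_sizes[[s]])
  out
}

#' @rdname bin_density
#' @param x,y Density vectors of two replicates.
#' @export
replicate_correlation <- function(x, y) {
  stats::cor(x, y, method = "pearson")
}

#' Top-decile median scale factor between two samples
#'
#' Samples sequenced with different signal-to-noise ratios are made
#' comparable by assuming their brightest peaks carry equal true signal: for
#' each sample, take its own top `top_frac` of master peaks by that sample's
#' FPKM (ties broken by position order), and form the ratio of the two
#' medians. Sample B's per-peak FPKM is multiplied by the factor for
#' comparison.
#'
#' @param fpkm_a,fpkm_b Per-master-peak FPKM of the two samples (same order).
#' @param top_frac Fraction of peaks in the top set (default 0.1);
#'   `n_top = ceiling(top_frac * n)`.
#' @return Object of class `dhs_scale_factor`: list with `value`
#'   (= `median_a / median_b`), `median_a`, `median_b`, `n_top`.
#' @examples
#' sf <- compute_scale_factor(c(1:10) * 2, c(1:10))
#' sf$value
#' @export
compute_scale_factor <- function(fpkm_a, fpkm_b, top_frac = 0.1) {
  n <- length(fpkm_a)
  stopifnot(length(fpkm_b) == n)
  if (n < 10) stop("need at least 10 master peaks", call. = FALSE)
  n_top <- ceiling(top_frac * n)
  top <- function(x) x[order(-x, seq_along(x))[seq_len(n_top)]]
  med_a <- stats::median(top(fpkm_a))
  med_b <- stats::median(top(fpkm_b))
  if (med_b == 0) stop("degenerate input: median of top peaks in B is 0",
                       call. = FALSE)
  structure(list(value = med_a / med_b, median_a = med_a, median_b = med_b,
                 n_top = n_top),
            class = "dhs_scale_factor")
}

#' @export
print.dhs_scale_factor <- function(x, ...) {
  cat("<dhs_scale_factor>", format(x$value, digits = 4),
      sprintf("(median A %.3g / median B %.3g over top %d peaks)\n",
              x$median_a, x$median_b, x$n_top))
  invisible(x)
}

#' Call allele-specific DHSs after scale-factor normalization
#'
#' Sample B's FPKM is multiplied by the scale factor; a peak is A-specific
#' when it is detected only in sample A *and* the scaled fold change
#' `(fpkm_a + pseudo) / (scaled fpkm_b + pseudo)` exceeds `fold_cutoff`
#' (B-specific symmetrically); every other peak is shared. Both rules must
#' hold: a peak detected in only one sample but without the signal fold
#' change stays shared.
#'
#' @param signal Master-list tibble with `detected_<a>` / `detected_<b>` and
#'   `fpkm_<a>` / `fpkm_<b>` columns (see [quantify_signal()]).
#' @param scale_factor A [compute_scale_factor()] result (or a positive
#'   number) applied to sample B.
#' @param samples Length-2 character vector naming the two samples as used
#'   in the column suffixes (default `c("A", "B")`).
#' @param fold_cutoff Fold-change cutoff, strict (default 2).
#' @param pseudo Pseudocount added to both FPKM values (default 0.5).
#' @return Tibble of class `dhs_calls`: `signal` plus `fpkm_b_scaled`,
#'   `fold_change` (A over scaled B) and `call`
#'   (`a_specific` / `b_specific` / `shared`).
#' @export
call_allelic_dhs <- function(signal, scale_factor, samples = c("A", "B"),
                             fold_cutoff = 2, pseudo = 0.5) {
  sf <- if (inherits(scale_factor, "dhs_scale_factor")) scale_factor$value
        else as.numeric(scale_factor)
  stopifnot(is.finite(sf), sf > 0)
  col <- function(pre, s) signal[[paste0(pre, s)]]
  fa <- col("fpkm_", samples[1])
  fb <- col("fpkm_", samples[2]) * sf
  da <- col("detected_", samples[1])
  db <- col("detected_", samples[2])
  if (is.null(fa) || is.null(fb) || is.null(da) || is.null(db)) {
    stop("signal must carry detected_/fpkm_ columns for both samples",
         call. = FALSE)
  }
  fc <- (fa + pseudo) / (fb + pseudo)
  out <- signal
  out$fpkm_b_scaled <- fb
  out$fold_change <- fc
  out$call <- dplyr::case_when(
    da & !db & fc > fold_cutoff ~ "a_specific",
    db & !da & (1 / fc) > fold_cutoff ~ "b_specific",
    TRUE ~ "shared"
  )
  structure(out, class = c("dhs_calls", class(out)),
            scale_factor = sf, fold_cutoff = fold_cutoff, pseudo = pseudo,
            samples = samples)
}
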