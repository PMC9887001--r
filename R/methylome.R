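#' Per-CpG methylation levels with a depth floor
#'
#' Methylation level `ML = m / (m + u)`; sites with read depth below
#' `min_depth` (default 3) are excluded.
#'
#' @param sites Tibble with `chrom`, `pos`, `m` (methylated reads), `u`
#'   (unmethylated reads).
#' @param min_depth Minimum `m + u` to keep a site (default 3).
#' @return The kept sites with an `ml` column.
#' @examples
#' site_methylation(tibble::tibble(chrom = "chrS", pos = c(10, 20),
#'                                 m = c(3, 2), u = c(1, 0)))
#' @export
site_methylation <- function(sites, min_depth = 3) {
  sites |>
    dplyr::filter(.data$m + .data$u >= min_depth) |>
    dplyr::mutate(ml = .data$m / (.data$m + .data$u))
}

#' Pooled methylation level of genomic elements
#'
#' For each element interval, the methylation level is the ratio of
#' methylated to total read counts pooled over the covered CpGs inside it
#' (1-based inclusive coordinates). Elements covered by fewer than
#' `min_cpgs` distinct CpGs get `NA` (promoters conventionally require 5).
#'
#' @param sites CpG tibble (`chrom`, `pos`, `m`, `u`), typically already
#'   depth-filtered with [site_methylation()].
#' @param elements Tibble `chrom`, `start`, `end` (1-based inclusive) plus
#'   any annotation columns (kept).
#' @param min_cpgs Minimum number of covered CpGs to report a level
#'   (default 1; use 5 for promoters).
#' @return `elements` with `n_cpgs` and `ml` columns.
#' @export
element_methylation <- function(sites, elements, min_cpgs = 1) {
  q <- GenomicRanges::GRanges(elements$chrom,
                              IRanges::IRanges(elements$start, elements$end))
  s <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
  hits <- GenomicRanges::findOverlaps(q, s)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  n <- nrow(elements)
  agg <- function(x) as.numeric(rowsum(x[si], qi, reorder = TRUE))
  out <- elements
  out$n_cpgs <- 0L
  out$ml <- NA_real_
  if (length(qi)) {
    idx <- sort(unique(qi))
    m_sum <- agg(sites$m)
    t_sum <- agg(sites$m + sites$u)
    out$n_cpgs[idx] <- as.integer(table(factor(qi, levels = idx)))
    out$ml[idx] <- m_sum / t_sum
  }
  out$ml[out$n_cpgs < min_cpgs] <- NA_real_
  out
}

#' Global methylation level
#'
#' Pooled `sum(m) / sum(m + u)` over all (depth-filtered) CpGs.
#'
#' @param sites CpG tibble with `m`, `u`.
#' @return A single numeric level in \[0, 1\].
#' @export
global_methylation <- function(sites) {
  sum(sites$m) / sum(sites$m + sites$u)
}

#' Promoter intervals from BED12 gene models
#'
#' Promoters are TSS +/- `flank` bp (strand-aware TSS), 1-based inclusive.
#'
#' @param bed12 Tibble from [read_bed12()].
#' @param flank Half-width around the TSS (default 1000).
#' @return Tibble `chrom`, `start`, `end`, `gene_id`.
#' @export
promoters_from_bed12 <- function(bed12, flank = 1000) {
  tss0 <- ifelse(!is.na(bed12$strand) & bed12$strand == "-",
                 bed12$end - 1, bed12$start)  # 0-based TSS position
  tss <- tss0 + 1
  tibble::tibble(chrom = bed12$chrom, start = pmax(1, tss - flank),
                 end = tss + flank, gene_id = bed12$name)
}

#' Call differentially methylated sites (DMS) between two methylomes
#'
#' Sites are matched by position across the two samples; only sites with
#' read depth of at least `min_depth` (default 5) in both samples are
#' tested. Each site's 2x2 table of (methylated, unmethylated) counts is
#' tested by a two-tailed Fisher exact test, p-values are BH-adjusted over
#' all tested sites, and a site is a DMS when `padj < padj_cutoff` and the
#' methylation difference exceeds `min_diff` in absolute value.
#'
#' @param sites_a,sites_b CpG tibbles (`chrom`, `pos`, `m`, `u`) for the two
#'   samples (A conventionally PG/maternal, B AG/paternal).
#' @param min_depth Per-sample depth floor for testing (default 5).
#' @param padj_cutoff Adjusted-p cutoff (default 0.1).
#' @param min_diff Absolute methylation-difference cutoff, strict
#'   (default 0.2).
#' @param sample_names Length-2 labels used in the `direction` column (the
#'   hypermethylated sample).
#' @return Tibble of class `dms_table` with one row per tested site:
#'   `chrom`, `pos`, `m_a`, `u_a`, `m_b`, `u_b`, `ml_a`, `ml_b`,
#'   `diff` (= `ml_a - ml_b`), `p_value`, `padj`, `direction`, `is_dms`.
#'   Unmatched sites are skipped and counted in a message.
#' @export
call_dms <- function(sites_a, sites_b, min_depth = 5, padj_cutoff = 0.1,
                     min_diff = 0.2, sample_names = c("A", "B")) {
  j <- dplyr::inner_join(
    dplyr::rename(sites_a, m_a = "m", u_a = "u"),
    dplyr::rename(sites_b, m_b = "m", u_b = "u"),
    by = c("chrom", "pos"))
  n_skip <- nrow(sites_a) + nrow(sites_b) - 2 * nrow(j)
  if (n_skip > 0) message(n_skip, " unmatched site(s) skipped")
  j <- j |>
    dplyr::filter(.data$m_a + .data$u_a >= min_depth,
                  .data$m_b + .data$u_b >= min_depth)
  out <- j |>
    dplyr::mutate(
      ml_a = .data$m_a / (.data$m_a + .data$u_a),
      ml_b = .data$m_b / (.data$m_b + .data$u_b),
      diff = .data$ml_a - .data$ml_b,
      p_value = fisher_exact_p(.data$m_a, .data$u_a, .data$m_b, .data$u_b),
      padj = stats::p.adjust(.data$p_value, method = "BH"),
      direction = dplyr::case_when(.data$diff > 0 ~ sample_names[1],
                                   .data$diff < 0 ~ sample_names[2],
                                   TRUE ~ NA_character_),
      is_dms = .data$padj < padj_cutoff & abs(.data$diff) > min_diff
    ) |>
    dplyr::arrange(.data$chrom, .data$pos)
  structure(out, class = c("dms_table", class(out)),
            min_depth = min_depth, padj_cutoff = padj_cutoff,
            min_diff = min_diff, sample_names = sample_names)
}

#' Merge DMSs into differentially methylated regions (DMRs)
#'
#' Same-direction DMSs closer than `max_gap` bp (strict) are chained into
#' pre-DMRs, separately for each direction, then the two sets are combined.
#' Each pre-DMR spans its first to last member DMS (1-based inclusive;
#' size = end - start + 1). Region-level significance is a Fisher exact test
#' on the (methylated, unmethylated) counts pooled over all *tested* sites
#' inside the region, BH-adjusted across pre-DMRs (`region_test = "pooled"`,
#' the default); `region_test = "all_members"` instead requires every member
#' DMS to pass the site-level adjusted cutoff. A pre-DMR becomes a DMR when
#' it has at least `min_dms` member DMSs, region `padj < padj_cutoff`,
#' absolute pooled methylation difference above `min_diff`, and size above
#' `min_size` bp (all strict except as stated).
#'
#' @param dms A [call_dms()] result (all tested sites, DMSs flagged).
#' @param max_gap Maximum distance between adjacent same-direction DMSs to
#'   chain them (default 500, strict: a gap of exactly 500 breaks the chain).
#' @param min_dms Minimum member DMSs per region (default 3).
#' @param min_size Minimum region size in bp, strict (default 50).
#' @param min_diff Minimum absolute pooled methylation difference, strict
#'   (default 0.2).
#' @param padj_cutoff Region-level adjusted-p cutoff (default 0.1).
#' @param region_test `"pooled"` or `"all_members"` (see above).
#' @return Tibble of class `dmr_table`: `chrom`, `start`, `end`, `size_bp`,
#'   `n_dms`, `direction`, `diff` (pooled), `p_value`, `padj`.
#' @export
merge_dmrs <- function(dms, max_gap = 500, min_dms = 3, min_size = 50,
                       min_diff = 0.2, padj_cutoff = 0.1,
                       region_test = c("pooled", "all_members")) {
  region_test <- match.arg(region_test)
  site_padj_cutoff <- attr(dms, "padj_cutoff") %||% 0.1
  dms_only <- dms |>
    dplyr::filter(.data$is_dms) |>
    dplyr::arrange(.data$chrom, .data$pos)
  empty_dmrs <- function() {
    out <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), size_bp = numeric(),
                          n_dms = integer(), direction = character(),
                          diff = numeric(), p_value = numeric(),
                          padj = numeric())
    structure(out, class = c("dmr_table", class(out)))
  }
  if (nrow(dms_only) == 0) return(empty_dmrs())
  pre <- dms_only |>
    dplyr::group_by(.data$chrom, .data$direction) |>
    dplyr::group_modify(function(d, key) {
      gap_break <- c(0, cumsum(diff(d$pos) >= max_gap))
      d$chain <- gap_break
      d
    }) |>
    dplyr::group_by(.data$chrom, .data$direction, .data$chain) |>
    dplyr::summarise(start = min(.data$pos), end = max(.data$pos),
                     n_dms = dplyr::n(), max_member_padj = max(.data$padj),
                     .groups = "drop")
  if (nrow(pre) == 0) return(empty_dmrs())
  # pool counts over every tested site inside each pre-DMR
  pooled <- purrr::pmap_dfr(
    pre[, c("chrom", "start", "end")],
    function(chrom, start, end) {
      s <- dms[dms$chrom == chrom & dms$pos >= start & dms$pos <= end, ]
      tibble::tibble(m_a = sum(s$m_a), u_a = sum(s$u_a),
                     m_b = sum(s$m_b), u_b = sum(s$u_b))
    })
  pre <- dplyr::bind_cols(pre, pooled) |>
    dplyr::mutate(
      size_bp = .data$end - .data$start + 1,
      diff = .data$m_a / (.data$m_a + .data$u_a) -
        .data$m_b / (.data$m_b + .data$u_b),
      p_value = fisher_exact_p(.data$m_a, .data$u_a, .data$m_b, .data$u_b),
      padj = stats::p.adjust(.data$p_value, method = "BH")
    )
  keep_region <- if (region_test == "pooled") {
    pre$padj < padj_cutoff
  } else {
    pre$max_member_padj < site_padj_cutoff
  }
  out <- pre |>
    dplyr::filter(keep_region, .data$n_dms >= min_dms,
                  abs(.data$diff) > min_diff, .data$size_bp > min_size) |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::select("chrom", "start", "end", "size_bp", "n_dms", "direction",
                  "diff", "p_value", "padj")
  structure(out, class = c("dmr_table", class(out)),
            max_gap = max_gap, min_dms = min_dms, min_size = min_size,
            min_diff = min_diff, padj_cutoff = padj_cutoff)
}

#' Compare called DMRs with truth intervals
#'
#' Matches called and truth regions by interval overlap and reports both a
#' region-set Jaccard (matched regions over the union of region sets, the
#' primary recovery metric) and a base-pair Jaccard (intersection over union
#' of covered bases, which also penalizes boundary shrink — a called DMR
#' spans its first to last member DMS, a subset of the truth interval).
#'
#' @param called Tibble `chrom`, `start`, `end` (1-based inclusive), e.g. a
#'   [merge_dmrs()] result.
#' @param truth Tibble of truth intervals in the same convention.
#' @return One-row tibble: `n_truth`, `n_called`, `n_matched` (truth regions
#'   hit), `sensitivity`, `precision`, `region_jaccard`, `bp_jaccard`.
#' @export
dmr_recovery <- function(called, truth) {
  gr <- function(x) GenomicRanges::GRanges(x$chrom,
                                           IRanges::IRanges(x$start, x$end))
  if (nrow(called) == 0) {
    return(tibble::tibble(n_truth = nrow(truth), n_called = 0L, n_matched = 0L,
                          sensitivity = 0, precision = NA_real_,
                          region_jaccard = 0, bp_jaccard = 0))
  }
  gc_ <- gr(called); gt <- gr(truth)
  hit_t <- GenomicRanges::countOverlaps(gt, gc_) > 0
  hit_c <- GenomicRanges::countOverlaps(gc_, gt) > 0
  n_matched <- sum(hit_t)
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(gc_, gt)))
  uni <- sum(GenomicRanges::width(GenomicRanges::union(gc_, gt)))
  tibble::tibble(
    n_truth = nrow(truth), n_called = nrow(called), n_matched = n_matched,
    sensitivity = n_matched / nrow(truth),
    precision = sum(hit_c) / nrow(called),
    region_jaccard = n_matched / (nrow(truth) + nrow(called) - n_matched),
    bp_jaccard = inter / uni
  )
}
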