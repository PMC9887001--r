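#' Pooled exact rate-ratio differential expression test
#'
#' For each gene, replicates of each group are pooled: with `x_A` reads out
#' of a pooled library of `N_A` and `x_B` out of `N_B`, the p-value is the
#' two-sided exact binomial test of `x_A` successes in `x_A + x_B` trials at
#' null probability `N_A / (N_A + N_B)` (a read from this gene is equally
#' likely to come from either library, per sequenced read). The log2 fold
#' change is computed on counts rescaled to the geometric-mean library size
#' with a 0.5 pseudocount, so equal normalized rates give exactly 0.
#'
#' Genes with `x_A + x_B = 0` carry no information under this test and are
#' excluded from the result.
#'
#' @param counts Tibble `gene_id` plus one column per sample.
#' @param samples_a,samples_b Character vectors of sample (column) names in
#'   the two groups; each must contain at least one sample.
#' @param library_sizes Optional named vector of per-sample library sizes;
#'   defaults to column sums over all genes.
#' @return Tibble `gene_id`, `count_a`, `count_b` (pooled), `log2fc`,
#'   `p_value`; pooled library sizes in attributes `lib_a`, `lib_b`.
#' @examples
#' counts <- tibble::tibble(gene_id = c("g1", "g2"), a1 = c(20, 500),
#'                          b1 = c(0, 500))
#' differential_test(counts, "a1", "b1")
#' @export
differential_test <- function(counts, samples_a, samples_b,
                              library_sizes = NULL) {
  stopifnot(length(samples_a) >= 1, length(samples_b) >= 1)
  miss <- setdiff(c(samples_a, samples_b), names(counts))
  if (length(miss)) stop("samples not in counts: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(library_sizes)) {
    library_sizes <- vapply(counts[c(samples_a, samples_b)], sum, numeric(1))
  }
  x_a <- rowSums(counts[, samples_a, drop = FALSE])
  x_b <- rowSums(counts[, samples_b, drop = FALSE])
  lib_a <- sum(library_sizes[samples_a])
  lib_b <- sum(library_sizes[samples_b])
  if (lib_a <= 0 || lib_b <= 0) stop("pooled library sizes must be > 0", call. = FALSE)
  keep <- x_a + x_b > 0
  x_a <- x_a[keep]; x_b <- x_b[keep]
  k <- sqrt(lib_a * lib_b)  # common scale for the normalized fold change
  out <- tibble::tibble(
    gene_id = counts$gene_id[keep],
    count_a = x_a,
    count_b = x_b,
    log2fc = log2((x_a * k / lib_a + 0.5) / (x_b * k / lib_b + 0.5)),
    p_value = exact_binom_p(x_a, x_a + x_b, lib_a / (lib_a + lib_b))
  )
  attr(out, "lib_a") <- lib_a
  attr(out, "lib_b") <- lib_b
  out
}

#' Call differentially expressed genes
#'
#' Applies the headline DEG criteria to a [differential_test()] result:
#' BH-adjusted p-value below `padj_cutoff`, absolute fold change above
#' `fold_cutoff` (strict), and merged-replicate FPKM of at least `min_fpkm`
#' in at least one of the two groups. Genes on excluded chromosomes (e.g.
#' chromosome X when a comparison involves AG morulae, which carry no X) are
#' removed before adjustment.
#'
#' @param de Result of [differential_test()].
#' @param fpkm_a,fpkm_b Named numeric vectors (or tibbles `gene_id` + one
#'   column) of merged-replicate FPKM for the two groups.
#' @param group_a,group_b Labels used in the `direction` column.
#' @param padj_cutoff,fold_cutoff,min_fpkm DEG thresholds
#'   (defaults 0.05, 2, 1).
#' @param gene_chroms Optional named vector gene_id -> chromosome.
#' @param exclude_chroms Chromosomes to drop (requires `gene_chroms`).
#' @return Tibble of class `deg_calls`: `gene_id`, counts, `log2fc`,
#'   `p_value`, `padj`, `fpkm_a`, `fpkm_b`, `is_deg`, `direction` (the label
#'   of the higher group, `NA` for non-DEGs).
#' @export
call_degs <- function(de, fpkm_a, fpkm_b, group_a = "A", group_b = "B",
                      padj_cutoff = 0.05, fold_cutoff = 2, min_fpkm = 1,
                      gene_chroms = NULL, exclude_chroms = NULL) {
  if (!is.null(exclude_chroms) && length(exclude_chroms)) {
    if (is.null(gene_chroms)) {
      stop("exclude_chroms requires gene_chroms", call. = FALSE)
    }
    de <- de[!(gene_chroms[de$gene_id] %in% exclude_chroms), ]
  }
  fa <- fpkm_named(fpkm_a)[de$gene_id]
  fb <- fpkm_named(fpkm_b)[de$gene_id]
  out <- de |>
    dplyr::mutate(
      padj = stats::p.adjust(.data$p_value, method = "BH"),
      fpkm_a = unname(fa),
      fpkm_b = unname(fb),
      is_deg = .data$padj < padj_cutoff &
        abs(.data$log2fc) > log2(fold_cutoff) &
        pmax(.data$fpkm_a, .data$fpkm_b) >= min_fpkm,
      direction = dplyr::if_else(.data$is_deg,
                                 dplyr::if_else(.data$log2fc > 0, group_a, group_b),
                                 NA_character_)
    )
  structure(out, class = c("deg_calls", class(out)),
            group_a = group_a, group_b = group_b,
            padj_cutoff = padj_cutoff, fold_cutoff = fold_cutoff,
            min_fpkm = min_fpkm)
}

fpkm_named <- function(x) {
  if (is.data.frame(x)) {
    val <- setdiff(names(x), "gene_id")[1]
    stats::setNames(x[[val]], x$gene_id)
  } else {
    x
  }
}
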