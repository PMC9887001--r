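#' Compute FPKM from raw counts
#'
#' `FPKM = reads * 1e9 / (length_bp * total_reads)`, per gene per sample.
#'
#' @param counts Tibble `gene_id` plus one numeric column per sample.
#' @param gene_lengths Tibble with `gene_id`, `length_bp`, or a named numeric
#'   vector of lengths (bp).
#' @param library_sizes Optional named vector of total assigned reads per
#'   sample; defaults to the column sums of `counts`. Zero library sizes are
#'   an error.
#' @return Tibble with the same shape as `counts`, values in FPKM.
#' @examples
#' counts <- tibble::tibble(gene_id = "g1", s1 = 10)
#' compute_fpkm(counts, c(g1 = 1000), library_sizes = c(s1 = 1e6))  # 10
#' @export
compute_fpkm <- function(counts, gene_lengths, library_sizes = NULL) {
  samp <- setdiff(names(counts), "gene_id")
  len <- lengths_vector(gene_lengths)[counts$gene_id]
  if (anyNA(len)) stop("missing gene length for some gene_id", call. = FALSE)
  if (any(len <= 0)) stop("gene lengths must be > 0", call. = FALSE)
  if (is.null(library_sizes)) {
    library_sizes <- vapply(counts[samp], sum, numeric(1))
  }
  library_sizes <- library_sizes[samp]
  if (anyNA(library_sizes) || any(library_sizes <= 0)) {
    stop("library sizes must be positive for every sample", call. = FALSE)
  }
  out <- counts
  for (s in samp) {
    out[[s]] <- unname(counts[[s]] * 1e9 / (len * library_sizes[[s]]))
  }
  out
}

lengths_vector <- function(gene_lengths) {
  if (is.data.frame(gene_lengths)) {
    stats::setNames(gene_lengths$length_bp, gene_lengths$gene_id)
  } else {
    gene_lengths
  }
}

#' Merged-replicate FPKM per group
#'
#' Combines all replicates of each group by summing raw counts (and library
#' sizes) before recomputing FPKM, so group-level FPKM is computed on the
#' merged reads rather than averaged over replicates.
#'
#' @param counts Tibble `gene_id` plus one column per sample.
#' @param samples Sample sheet with `sample_id` and the grouping columns.
#' @param gene_lengths As in [compute_fpkm()].
#' @param group_cols Sample-sheet columns defining a group
#'   (default stage + genotype + treatment).
#' @return Tibble `gene_id` plus one FPKM column per group; group names join
#'   the grouping values with `_` (a `"none"` treatment is dropped from the
#'   name).
#' @export
merged_group_fpkm <- function(counts, samples, gene_lengths,
                              group_cols = c("genotype", "stage", "treatment")) {
  stopifnot(all(group_cols %in% names(samples)))
  grp <- samples |>
    dplyr::mutate(.group = group_label(dplyr::pick(dplyr::all_of(group_cols))))
  merged <- tibble::tibble(gene_id = counts$gene_id)
  for (g in unique(grp$.group)) {
    ids <- grp$sample_id[grp$.group == g]
    merged[[g]] <- rowSums(counts[, ids, drop = FALSE])
  }
  compute_fpkm(merged, gene_lengths)
}

group_label <- function(df) {
  vals <- lapply(df, as.character)
  lab <- do.call(paste, c(vals, sep = "_"))
  gsub("_none$|_none_", "_", lab) |> sub(pattern = "_$", replacement = "")
}

#' Gene lengths from BED12 models (union of exons)
#'
#' Effective gene length is the number of base pairs covered by the union of
#' the gene's exon blocks, strand-agnostic, pooling all transcripts with the
#' same name.
#'
#' @param bed12 Tibble as returned by [read_bed12()].
#' @return Tibble `gene_id`, `length_bp`.
#' @export
bed12_gene_lengths <- function(bed12) {
  ex <- bed12_exons(bed12)
  gr <- GenomicRanges::GRanges(ex$chrom,
                               IRanges::IRanges(ex$start + 1, ex$end))
  red <- GenomicRanges::reduce(GenomicRanges::split(gr, ex$name))
  tibble::tibble(gene_id = names(red),
                 length_bp = as.numeric(sum(GenomicRanges::width(red))))
}

# expand BED12 block fields into per-exon 0-based half-open intervals
bed12_exons <- function(bed12) {
  purrr::pmap_dfr(bed12, function(chrom, start, end, name, block_count,
                                  block_sizes, block_starts, ...) {
    sizes <- as.numeric(strsplit(block_sizes, ",")[[1]])
    offs <- as.numeric(strsplit(block_starts, ",")[[1]])
    ex_start <- start + offs
    tibble::tibble(chrom = chrom, start = ex_start, end = ex_start + sizes,
                   name = name)
  })
}
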