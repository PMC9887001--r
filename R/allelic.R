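#' Discover traceable loci from paired exome/RNA pileups
#'
#' A traceable locus is a site that is homozygous in the paternal exome but
#' shows an alternative base in embryo RNA, so the alternative base can be
#' inferred to be maternally derived and RNA reads can be assigned to the two
#' parental genomes. Filters, applied per site:
#'
#' * exome depth and RNA depth both at least `min_depth` reads ("more than
#'   10" implemented as >= 11 by default);
#' * homozygous in the exome: the majority base carries at least `hom_frac`
#'   of exome reads (tolerates sequencing error);
#' * a single alternative base in RNA with at least `alt_frac` of RNA reads
#'   and at least `alt_reads` reads. Sites where two or more alternative
#'   bases pass both sub-rules are ambiguous and are excluded (reported via a
#'   message and the `n_ambiguous` attribute).
#'
#' @param pileup Tibble with columns `chrom`, `pos`, `gene_id`, and per-base
#'   read counts `exome_a`, `exome_c`, `exome_g`, `exome_t`, `rna_a`,
#'   `rna_c`, `rna_g`, `rna_t`.
#' @param min_depth Minimum read depth in each assay (default 11).
#' @param hom_frac Minimum majority-base fraction in the exome (default 0.98).
#' @param alt_frac Minimum alternative-base read fraction in RNA (default 0.05).
#' @param alt_reads Minimum alternative-base read count in RNA (default 3).
#' @return Tibble of traceable loci: `chrom`, `pos`, `gene_id`,
#'   `paternal_base`, `maternal_base`, `paternal_reads`, `maternal_reads`;
#'   attribute `n_ambiguous` counts excluded multi-allelic sites.
#' @examples
#' p <- tibble::tibble(chrom = "chr1", pos = 100, gene_id = "G1",
#'   exome_a = 12, exome_c = 0, exome_g = 0, exome_t = 0,
#'   rna_a = 15, rna_c = 0, rna_g = 5, rna_t = 0)
#' discover_traceable_loci(p)
#' @export
discover_traceable_loci <- function(pileup, min_depth = 11, hom_frac = 0.98,
                                    alt_frac = 0.05, alt_reads = 3) {
  bases <- c("a", "c", "g", "t")
  need <- c("chrom", "pos", "gene_id", paste0("exome_", bases), paste0("rna_", bases))
  miss <- setdiff(need, names(pileup))
  if (length(miss)) stop("pileup is missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  ex <- as.matrix(pileup[paste0("exome_", bases)])
  rn <- as.matrix(pileup[paste0("rna_", bases)])
  ex_depth <- rowSums(ex)
  rn_depth <- rowSums(rn)
  maj <- max.col(ex, ties.method = "first")
  maj_frac <- ex[cbind(seq_len(nrow(ex)), maj)] / pmax(ex_depth, 1)
  eligible <- ex_depth >= min_depth & rn_depth >= min_depth & maj_frac >= hom_frac

  alt <- rn
  alt[cbind(seq_len(nrow(rn)), maj)] <- 0
  qual <- alt >= alt_reads & alt / pmax(rn_depth, 1) >= alt_frac
  n_qual <- rowSums(qual)
  ambiguous <- eligible & n_qual >= 2
  keep <- eligible & n_qual == 1
  if (any(ambiguous)) {
    message(sum(ambiguous), " site(s) with multiple qualifying alternative bases excluded")
  }
  alt_idx <- max.col(qual, ties.method = "first")
  out <- tibble::tibble(
    chrom = pileup$chrom[keep],
    pos = pileup$pos[keep],
    gene_id = pileup$gene_id[keep],
    paternal_base = toupper(bases[maj[keep]]),
    maternal_base = toupper(bases[alt_idx[keep]]),
    paternal_reads = rn[cbind(which(keep), maj[keep])],
    maternal_reads = alt[cbind(which(keep), alt_idx[keep])]
  )
  attr(out, "n_ambiguous") <- sum(ambiguous)
  out
}

#' Sum parental read counts per gene over traceable loci
#'
#' @param loci Tibble with `gene_id`, `paternal_reads`, `maternal_reads`
#'   (e.g. from [discover_traceable_loci()]). Loci without a gene annotation
#'   (`NA` gene_id) are excluded and counted in a message.
#' @return Tibble `gene_id`, `paternal_reads`, `maternal_reads` with one row
#'   per gene.
#' @export
aggregate_gene_counts <- function(loci) {
  n_na <- sum(is.na(loci$gene_id))
  if (n_na > 0) message(n_na, " locus/loci without gene annotation excluded")
  loci |>
    dplyr::filter(!is.na(.data$gene_id)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(paternal_reads = sum(.data$paternal_reads),
                     maternal_reads = sum(.data$maternal_reads),
                     .groups = "drop")
}

#' Exact binomial test of allelic balance
#'
#' Two-sided exact binomial p-value for paternal vs maternal read counts
#' under the biallelic null that a sequencing read comes from either parental
#' genome with probability 0.5. Vectorized.
#'
#' @param paternal,maternal Read counts; `paternal + maternal >= 1`.
#' @return P-values in (0, 1].
#' @examples
#' binomial_allelic_test(12, 0)  # 2 * 0.5^12
#' binomial_allelic_test(5, 5)   # 1
#' @export
binomial_allelic_test <- function(paternal, maternal) {
  exact_binom_p(paternal, paternal + maternal, 0.5)
}

#' Call parentally biased gene expression
#'
#' Tests every gene with at least `min_reads` informative reads for allelic
#' imbalance (exact binomial, null 0.5), adjusts p-values by
#' Benjamini-Hochberg over that family, and calls a gene paternally or
#' maternally expressed when `p < p_cutoff`, `padj < padj_cutoff` and the
#' parental read-count fold change exceeds `fold_cutoff`; all other tested
#' genes are biallelic. The fold change used for the cutoff is
#' `(x + 0.5) / (y + 0.5)` (larger over smaller) so genes with a zero count
#' remain comparable; raw counts are reported unchanged.
#'
#' @param counts Tibble with `gene_id`, `paternal_reads`, `maternal_reads`.
#' @param min_reads Minimum informative reads per gene to enter the tested
#'   family (default 10).
#' @param p_cutoff Raw p-value cutoff (default 0.001).
#' @param padj_cutoff BH-adjusted p-value cutoff (default 0.05).
#' @param fold_cutoff Parental fold-change cutoff, strict (default 2).
#' @return Tibble of class `allelic_calls`: input columns plus `p_value`,
#'   `padj`, `fold_change`, `call` (paternal / maternal / biallelic).
#'   Thresholds are stored as attributes.
#' @examples
#' counts <- tibble::tibble(gene_id = c("g1", "g2"),
#'                          paternal_reads = c(12, 30), maternal_reads = c(0, 20))
#' classify_allelic_genes(counts)
#' @export
classify_allelic_genes <- function(counts, min_reads = 10, p_cutoff = 0.001,
                                   padj_cutoff = 0.05, fold_cutoff = 2) {
  stopifnot(min_reads >= 1)
  out <- counts |>
    dplyr::filter(.data$paternal_reads + .data$maternal_reads >= min_reads)
  if (nrow(out) == 0) {
    out$p_value <- out$padj <- out$fold_change <- numeric(0)
    out$call <- character(0)
    return(new_allelic_calls(out, min_reads, p_cutoff, padj_cutoff, fold_cutoff))
  }
  out <- out |>
    dplyr::mutate(
      p_value = binomial_allelic_test(.data$paternal_reads, .data$maternal_reads),
      padj = stats::p.adjust(.data$p_value, method = "BH"),
      fold_change = pmax((.data$paternal_reads + 0.5) / (.data$maternal_reads + 0.5),
                         (.data$maternal_reads + 0.5) / (.data$paternal_reads + 0.5)),
      call = dplyr::case_when(
        .data$p_value < p_cutoff & .data$padj < padj_cutoff &
          .data$fold_change > fold_cutoff &
          .data$paternal_reads > .data$maternal_reads ~ "paternal",
        .data$p_value < p_cutoff & .data$padj < padj_cutoff &
          .data$fold_change > fold_cutoff &
          .data$maternal_reads > .data$paternal_reads ~ "maternal",
        TRUE ~ "biallelic"
      )
    )
  new_allelic_calls(out, min_reads, p_cutoff, padj_cutoff, fold_cutoff)
}

new_allelic_calls <- function(tbl, min_reads, p_cutoff, padj_cutoff, fold_cutoff) {
  structure(tbl, class = c("allelic_calls", class(tbl)),
            min_reads = min_reads, p_cutoff = p_cutoff,
            padj_cutoff = padj_cutoff, fold_cutoff = fold_cutoff)
}
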