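#' Classify maternal-to-zygotic transition genes for one 4-cell vs 8-cell
#' contrast
#'
#' Given DEG calls between the 4-cell (pre) and 8-cell (post) stages of one
#' genotype:
#'
#' * **maternally degraded**: 4-cell-biased DEGs with pre-stage merged FPKM
#'   of at least `min_fpkm`;
#' * **newly transcribed**: 8-cell-biased DEGs with post-stage merged FPKM of
#'   at least `min_fpkm`;
#' * **zga**: membership of an externally supplied ZGA gene list, kept only
#'   when the gene shows expression at the 8-cell stage
#'   (FPKM >= `zga_expressed_min`); reported in the `is_zga` column, and as
#'   the `class` for listed genes not otherwise classified (a ZGA-list gene
#'   can also be newly transcribed; the DEG-derived class takes precedence in
#'   the single `class` column);
#' * **other**: everything else.
#'
#' @param deg A [call_degs()] result for the pre-vs-post comparison, with
#'   group A = pre (4-cell) and group B = post (8-cell).
#' @param fpkm_pre,fpkm_post Merged-replicate FPKM for the two stages (named
#'   vectors or `gene_id` tibbles).
#' @param zga_genes Optional character vector of ZGA gene ids.
#' @param min_fpkm FPKM floor for the degraded/newly-transcribed classes
#'   (default 2).
#' @param zga_expressed_min FPKM floor defining "expressed at 8-cell" for the
#'   ZGA list intersection (default 1).
#' @return Tibble `gene_id`, `class`, `is_zga`, plus the supporting `fpkm_pre`
#'   and `fpkm_post`.
#' @export
classify_mzt <- function(deg, fpkm_pre, fpkm_post, zga_genes = NULL,
                         min_fpkm = 2, zga_expressed_min = 1) {
  if (!inherits(deg, "deg_calls")) {
    stop("classify_mzt requires a call_degs() result for the 4C vs 8C comparison",
         call. = FALSE)
  }
  ga <- attr(deg, "group_a")
  gb <- attr(deg, "group_b")
  fpre <- fpkm_named(fpkm_pre)[deg$gene_id]
  fpost <- fpkm_named(fpkm_post)[deg$gene_id]
  degraded <- deg$is_deg & !is.na(deg$direction) & deg$direction == ga &
    !is.na(fpre) & fpre >= min_fpkm
  newly <- deg$is_deg & !is.na(deg$direction) & deg$direction == gb &
    !is.na(fpost) & fpost >= min_fpkm
  is_zga <- if (is.null(zga_genes)) rep(FALSE, nrow(deg)) else {
    deg$gene_id %in% zga_genes & !is.na(fpost) & fpost >= zga_expressed_min
  }
  tibble::tibble(
    gene_id = deg$gene_id,
    class = dplyr::case_when(degraded ~ "maternally_degraded",
                             newly ~ "newly_transcribed",
                             is_zga ~ "zga",
                             TRUE ~ "other"),
    is_zga = is_zga,
    fpkm_pre = unname(fpre),
    fpkm_post = unname(fpost)
  )
}

#' Parent-specific retrotransposon subfamilies
#'
#' A subfamily is PG-specific when its PG FPKM exceeds `min_fpkm` and is at
#' least `fold` times its AG FPKM; AG-specific symmetrically; otherwise
#' neither.
#'
#' @param retro Tibble with `subfamily`, `fpkm_pg`, `fpkm_ag`.
#' @param min_fpkm Expression floor, strict (default 20).
#' @param fold Minimum ratio over the other genotype, non-strict (default 2).
#' @return The input with a `label` column in
#'   `pg_specific` / `ag_specific` / `neither`.
#' @examples
#' retro_specific_subfamilies(
#'   tibble::tibble(subfamily = c("L1X", "ERVY"),
#'                  fpkm_pg = c(25, 15), fpkm_ag = c(10, 5)))
#' @export
retro_specific_subfamilies <- function(retro, min_fpkm = 20, fold = 2) {
  retro |>
    dplyr::mutate(label = dplyr::case_when(
      .data$fpkm_pg > min_fpkm & .data$fpkm_pg >= fold * .data$fpkm_ag ~ "pg_specific",
      .data$fpkm_ag > min_fpkm & .data$fpkm_ag >= fold * .data$fpkm_pg ~ "ag_specific",
      TRUE ~ "neither"
    ))
}
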