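#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a DHS scale factor
#'
#' @param x A [compute_scale_factor()] result.
#' @param ... Unused.
#' @return One-row tibble: `scale_factor`, `median_a`, `median_b`, `n_top`.
#' @export
tidy.dhs_scale_factor <- function(x, ...) {
  tibble::tibble(scale_factor = x$value, median_a = x$median_a,
                 median_b = x$median_b, n_top = x$n_top)
}

#' One-row summaries of call tables
#'
#' `glance()` methods report the number of entities tested, the calls made
#' and the thresholds applied, one row per table.
#'
#' @param x A call table (`allelic_calls`, `deg_calls`, `dms_table`,
#'   `dmr_table` or `dhs_calls`).
#' @param ... Unused.
#' @return A one-row tibble.
#' @name glance-mztallele
NULL

#' @rdname glance-mztallele
#' @export
glance.allelic_calls <- function(x, ...) {
  tibble::tibble(
    n_tested = nrow(x),
    n_paternal = sum(x$call == "paternal"),
    n_maternal = sum(x$call == "maternal"),
    n_biallelic = sum(x$call == "biallelic"),
    p_cutoff = attr(x, "p_cutoff"), padj_cutoff = attr(x, "padj_cutoff"),
    fold_cutoff = attr(x, "fold_cutoff"), min_reads = attr(x, "min_reads")
  )
}

#' @rdname glance-mztallele
#' @export
glance.deg_calls <- function(x, ...) {
  tibble::tibble(
    n_tested = nrow(x), n_deg = sum(x$is_deg),
    n_up_a = sum(x$is_deg & x$direction == attr(x, "group_a"), na.rm = TRUE),
    n_up_b = sum(x$is_deg & x$direction == attr(x, "group_b"), na.rm = TRUE),
    padj_cutoff = attr(x, "padj_cutoff"), fold_cutoff = attr(x, "fold_cutoff"),
    min_fpkm = attr(x, "min_fpkm")
  )
}

#' @rdname glance-mztallele
#' @export
glance.dms_table <- function(x, ...) {
  tibble::tibble(
    n_tested = nrow(x), n_dms = sum(x$is_dms),
    n_hyper_a = sum(x$is_dms & x$diff > 0),
    n_hyper_b = sum(x$is_dms & x$diff < 0),
    padj_cutoff = attr(x, "padj_cutoff"), min_diff = attr(x, "min_diff"),
    min_depth = attr(x, "min_depth")
  )
}

#' @rdname glance-mztallele
#' @export
glance.dmr_table <- function(x, ...) {
  tibble::tibble(
    n_dmrs = nrow(x),
    n_hyper_a = sum(x$diff > 0), n_hyper_b = sum(x$diff < 0),
    total_bp = sum(x$size_bp), median_n_dms = stats::median(x$n_dms)
  )
}

#' @rdname glance-mztallele
#' @export
glance.dhs_calls <- function(x, ...) {
  tibble::tibble(
    n_peaks = nrow(x),
    n_a_specific = sum(x$call == "a_specific"),
    n_b_specific = sum(x$call == "b_specific"),
    n_shared = sum(x$call == "shared"),
    scale_factor = attr(x, "scale_factor"),
    fold_cutoff = attr(x, "fold_cutoff")
  )
}
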