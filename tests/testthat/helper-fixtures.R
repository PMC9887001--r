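# shared fixture builders (all synthetic, generated at test time)

small_sim_config <- function(seed = 11, ...) {
  sim_config(seed = seed, n_genes = 300, n_allelic_genes = 300,
             n_cpgs = 600, n_dmrs = 20, n_peaks = 300, ...)
}

pileup_row <- function(chrom = "chr1", pos = 100, gene_id = "G1",
                       exome = c(a = 0, c = 0, g = 0, t = 0),
                       rna = c(a = 0, c = 0, g = 0, t = 0)) {
  tibble::tibble(chrom = chrom, pos = pos, gene_id = gene_id,
                 exome_a = exome[["a"]], exome_c = exome[["c"]],
                 exome_g = exome[["g"]], exome_t = exome[["t"]],
                 rna_a = rna[["a"]], rna_c = rna[["c"]],
                 rna_g = rna[["g"]], rna_t = rna[["t"]])
}

# hand-built tested-site table in the shape call_dms() returns, for
# deterministic region-merging fixtures
dms_fixture <- function(pos, is_dms, direction = "A",
                        m_a = 10, u_a = 0, m_b = 0, u_b = 10,
                        chrom = "chrS") {
  n <- length(pos)
  tbl <- tibble::tibble(
    chrom = chrom, pos = pos,
    m_a = rep_len(m_a, n), u_a = rep_len(u_a, n),
    m_b = rep_len(m_b, n), u_b = rep_len(u_b, n)
  )
  tbl$ml_a <- tbl$m_a / (tbl$m_a + tbl$u_a)
  tbl$ml_b <- tbl$m_b / (tbl$m_b + tbl$u_b)
  tbl$diff <- tbl$ml_a - tbl$ml_b
  tbl$p_value <- fisher_exact_p(tbl$m_a, tbl$u_a, tbl$m_b, tbl$u_b)
  tbl$padj <- stats::p.adjust(tbl$p_value, "BH")
  tbl$direction <- rep_len(direction, n)
  tbl$is_dms <- rep_len(is_dms, n)
  structure(tbl, class = c("dms_table", class(tbl)), padj_cutoff = 0.1)
}
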