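test_that("traceable-locus discovery applies the depth, homozygosity and
           alternative-base rules", {
  p <- dplyr::bind_rows(
    # kept: exome 12xA, RNA 15xA + 5xG (25% >= 5%, 5 >= 3 reads)
    pileup_row(pos = 1, gene_id = "G1", exome = c(a = 12, c = 0, g = 0, t = 0),
               rna = c(a = 15, c = 0, g = 5, t = 0)),
    # excluded: exome depth 8 <= 10
    pileup_row(pos = 2, gene_id = "G2", exome = c(a = 8, c = 0, g = 0, t = 0),
               rna = c(a = 20, c = 0, g = 10, t = 0)),
    # excluded as SNP: 2 alternative reads < 3 despite 5% fraction
    pileup_row(pos = 3, gene_id = "G3", exome = c(a = 40, c = 0, g = 0, t = 0),
               rna = c(a = 38, c = 0, g = 2, t = 0)),
    # excluded: heterozygous exome (30A/10C < 98% majority)
    pileup_row(pos = 4, gene_id = "G4", exome = c(a = 30, c = 10, g = 0, t = 0),
               rna = c(a = 20, c = 20, g = 0, t = 0)),
    # excluded: RNA depth 10 <= 10
    pileup_row(pos = 5, gene_id = "G5", exome = c(a = 20, c = 0, g = 0, t = 0),
               rna = c(a = 6, c = 0, g = 4, t = 0))
  )
  loci <- discover_traceable_loci(p)
  expect_equal(loci$pos, 1)
  expect_equal(loci$paternal_base, "A")
  expect_equal(loci$maternal_base, "G")
  expect_equal(loci$paternal_reads, 15)
  expect_equal(loci$maternal_reads, 5)
})

test_that("sites with two qualifying alternative bases are ambiguous", {
  p <- pileup_row(pos = 9, exome = c(a = 30, c = 0, g = 0, t = 0),
                  rna = c(a = 10, c = 6, g = 6, t = 0))
  expect_message(loci <- discover_traceable_loci(p), "ambiguous|alternative")
  expect_equal(nrow(loci), 0)
  expect_equal(attr(loci, "n_ambiguous"), 1)
})

test_that("gene aggregation sums loci and drops unannotated ones", {
  loci <- tibble::tibble(
    gene_id = c("G1", "G1", "G2", NA),
    paternal_reads = c(10, 5, 7, 99),
    maternal_reads = c(2, 1, 0, 99))
  expect_message(agg <- aggregate_gene_counts(loci), "without gene annotation")
  expect_equal(agg$paternal_reads[agg$gene_id == "G1"], 15)
  expect_equal(agg$maternal_reads[agg$gene_id == "G1"], 3)
  expect_equal(agg$paternal_reads[agg$gene_id == "G2"], 7)
  expect_equal(nrow(agg), 2)
  expect_equal(nrow(aggregate_gene_counts(loci[0, ])), 0)
})

test_that("allelic classification applies all three criteria", {
  counts <- tibble::tibble(
    gene_id = c("pat", "bi", "mat", "low"),
    paternal_reads = c(12, 30, 0, 4),
    maternal_reads = c(0, 20, 12, 3))
  res <- classify_allelic_genes(counts)
  # single-member family facts: padj = p for the extreme genes
  expect_equal(res$p_value[res$gene_id == "pat"], 2 * 0.5^12)
  expect_equal(res$call[res$gene_id == "pat"], "paternal")
  expect_equal(res$call[res$gene_id == "mat"], "maternal")
  # (30, 20): p ~ 0.2026, fold 1.5 -> biallelic
  expect_equal(res$p_value[res$gene_id == "bi"],
               stats::binom.test(30, 50)$p.value)
  expect_equal(res$call[res$gene_id == "bi"], "biallelic")
  # gene below min_reads is not in the tested family
  expect_false("low" %in% res$gene_id)
})

test_that("swapping parental columns mirrors calls and keeps p-values", {
  set.seed(31)
  counts <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:200),
    paternal_reads = rbinom(200, 40, runif(200, 0.1, 0.9)))
  counts$maternal_reads <- 40 - counts$paternal_reads
  a <- classify_allelic_genes(counts)
  b <- classify_allelic_genes(dplyr::rename(counts,
                                            paternal_reads = "maternal_reads",
                                            maternal_reads = "paternal_reads"))
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$fold_change, b$fold_change)
  swap <- c(paternal = "maternal", maternal = "paternal",
            biallelic = "biallelic")
  expect_equal(unname(swap[a$call]), b$call)
})

test_that("BH padj never falls below p and respects rank order", {
  set.seed(32)
  counts <- tibble::tibble(gene_id = sprintf("g%03d", 1:300),
                           paternal_reads = rbinom(300, 30, 0.55),
                           maternal_reads = rbinom(300, 30, 0.45))
  res <- classify_allelic_genes(counts, min_reads = 1)
  expect_true(all(res$padj >= res$p_value - 1e-12))
  o <- order(res$p_value)
  expect_true(all(diff(res$padj[o]) >= -1e-12))
})
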