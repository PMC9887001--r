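test_that("FPKM formula, scale invariance and merged replicates", {
  counts <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(10, 90))
  f <- compute_fpkm(counts, c(g1 = 1000, g2 = 500), library_sizes = c(s1 = 1e6))
  expect_equal(f$s1[1], 10)
  # doubling every count in a sample leaves FPKM unchanged (library doubles)
  f2 <- compute_fpkm(dplyr::mutate(counts, s1 = s1 * 2), c(g1 = 1000, g2 = 500))
  expect_equal(f2$s1, compute_fpkm(counts, c(g1 = 1000, g2 = 500))$s1)
  # merged replicates: counts 4 and 6 on a 1 kb gene, libraries 1e6 each
  counts2 <- tibble::tibble(gene_id = "g1", r1 = 4, r2 = 6)
  samples <- tibble::tibble(sample_id = c("r1", "r2"), stage = "4C",
                            genotype = "AG", treatment = "none",
                            replicate = 1:2)
  m <- merged_group_fpkm(counts2, samples, c(g1 = 1000),
                         group_cols = c("genotype", "stage"))
  # library sizes default to column sums; force 1e6 via explicit computation
  merged <- compute_fpkm(tibble::tibble(gene_id = "g1", AG_4C = 10),
                         c(g1 = 1000), c(AG_4C = 2e6))
  expect_equal(merged$AG_4C, 5)
  expect_named(m, c("gene_id", "AG_4C"))
  expect_error(compute_fpkm(counts, c(g1 = 1000, g2 = 500),
                            library_sizes = c(s1 = 0)), "positive")
})

test_that("gene lengths are unions of BED12 exon blocks", {
  bed12 <- tibble::tibble(
    chrom = "chrS", start = c(100, 150), end = c(400, 500),
    name = c("g1", "g1"), score = 0, strand = "+",
    thick_start = 0, thick_end = 0, rgb = "0",
    block_count = c(2L, 1L),
    block_sizes = c("50,100", "200"),    # [100,150) [200,300) and [150,350)
    block_starts = c("0,100", "0"))
  len <- bed12_gene_lengths(bed12)
  expect_equal(len$length_bp[len$gene_id == "g1"], 250)  # union [100,350)
})

test_that("pooled exact test matches its examples and the binomial oracle", {
  counts <- tibble::tibble(gene_id = c("eq", "ext", "zero"),
                           a1 = c(50, 20, 0), b1 = c(50, 0, 0))
  de <- differential_test(counts, "a1", "b1",
                          library_sizes = c(a1 = 1e5, b1 = 1e5))
  expect_false("zero" %in% de$gene_id)  # no-information genes excluded
  expect_equal(de$log2fc[de$gene_id == "eq"], 0)
  expect_equal(de$p_value[de$gene_id == "eq"], 1)
  expect_equal(de$p_value[de$gene_id == "ext"], 2 * 0.5^20, tolerance = 1e-9)
  # unequal libraries: (20, 10) with N_A = 2 N_B is a null fold change
  de2 <- differential_test(tibble::tibble(gene_id = "g", a1 = 20, b1 = 10),
                           "a1", "b1", library_sizes = c(a1 = 2e6, b1 = 1e6))
  expect_equal(de2$log2fc, 0)
  expect_equal(de2$p_value,
               stats::binom.test(20, 30, p = 2 / 3)$p.value, tolerance = 1e-12)
})

test_that("swapping groups mirrors the fold change and keeps p", {
  set.seed(41)
  counts <- tibble::tibble(gene_id = sprintf("g%02d", 1:50),
                           a1 = rpois(50, 40), a2 = rpois(50, 40),
                           b1 = rpois(50, 60), b2 = rpois(50, 60))
  ab <- differential_test(counts, c("a1", "a2"), c("b1", "b2"))
  ba <- differential_test(counts, c("b1", "b2"), c("a1", "a2"))
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
})

test_that("DEG criteria are a conjunction and chrX exclusion works", {
  de <- tibble::tibble(gene_id = c("g1", "g2", "g3", "gx"),
                       count_a = c(200, 120, 200, 200),
                       count_b = c(20, 80, 20, 20),
                       log2fc = c(3, 0.58, 3, 3),
                       p_value = c(1e-8, 0.01, 1e-8, 1e-8))
  fpkm_a <- c(g1 = 2, g2 = 10, g3 = 0.5, gx = 5)
  fpkm_b <- c(g1 = 0.5, g2 = 10, g3 = 0.2, gx = 1)
  deg <- call_degs(de, fpkm_a, fpkm_b, group_a = "4C", group_b = "8C")
  expect_true(deg$is_deg[deg$gene_id == "g1"])
  expect_equal(deg$direction[deg$gene_id == "g1"], "4C")
  expect_false(deg$is_deg[deg$gene_id == "g2"])  # fold 1.5
  expect_false(deg$is_deg[deg$gene_id == "g3"])  # FPKM < 1 in both
  chroms <- c(g1 = "chrS", g2 = "chrS", g3 = "chrS", gx = "chrX")
  deg_x <- call_degs(de, fpkm_a, fpkm_b, gene_chroms = chroms,
                     exclude_chroms = "chrX")
  expect_false("gx" %in% deg_x$gene_id)
  expect_true("gx" %in% deg$gene_id)
  expect_error(call_degs(de, fpkm_a, fpkm_b, exclude_chroms = "chrX"),
               "gene_chroms")
})

test_that("MZT classification applies FPKM floors and the ZGA list", {
  de <- tibble::tibble(gene_id = c("new", "deg", "lowdeg", "zga", "none"),
                       count_a = c(5, 300, 300, 50, 50),
                       count_b = c(300, 5, 5, 60, 55),
                       log2fc = c(-5, 5, 5, -0.2, -0.1),
                       p_value = c(1e-9, 1e-9, 1e-9, 0.5, 0.9))
  fpkm_pre <- c(new = 0.1, deg = 30, lowdeg = 1.5, zga = 5, none = 5)
  fpkm_post <- c(new = 5, deg = 1.2, lowdeg = 0.1, zga = 6, none = 5)
  deg <- call_degs(de, fpkm_pre, fpkm_post, group_a = "4C", group_b = "8C")
  cls <- classify_mzt(deg, fpkm_pre, fpkm_post, zga_genes = c("zga", "new"))
  get <- function(g) cls$class[cls$gene_id == g]
  expect_equal(get("new"), "newly_transcribed")   # 8C-biased, FPKM 5 >= 2
  expect_equal(get("deg"), "maternally_degraded") # 4C-biased, FPKM 30 >= 2
  expect_equal(get("lowdeg"), "other")            # 4C FPKM 1.5 < 2
  expect_equal(get("zga"), "zga")
  expect_equal(get("none"), "other")
  expect_true(all(cls$is_zga[cls$gene_id %in% c("zga", "new")]))
  expect_error(classify_mzt(de, fpkm_pre, fpkm_post), "call_degs")
})

test_that("retrotransposon subfamily rules match the worked examples", {
  retro <- tibble::tibble(subfamily = c("s1", "s2", "s3", "s4"),
                          fpkm_pg = c(25, 25, 15, 10),
                          fpkm_ag = c(10, 15, 5, 45))
  lab <- retro_specific_subfamilies(retro)$label
  expect_equal(lab, c("pg_specific",  # 25 > 20 and 25 >= 2*10
                      "neither",      # 25 < 2*15
                      "neither",      # fails the 20 floor
                      "ag_specific")) # 45 > 20 and 45 >= 2*10
})
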