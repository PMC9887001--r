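test_that("generators are deterministic given the seed", {
  cfg <- small_sim_config(seed = 3)
  expect_identical(simulate_expression(cfg)$counts,
                   simulate_expression(cfg)$counts)
  expect_identical(simulate_allelic_counts(cfg)$counts,
                   simulate_allelic_counts(cfg)$counts)
  expect_identical(simulate_methylome_pair(cfg)$sample_a,
                   simulate_methylome_pair(cfg)$sample_a)
  expect_identical(simulate_dhs_experiment(cfg)$counts,
                   simulate_dhs_experiment(cfg)$counts)
  # different seeds diverge
  cfg2 <- small_sim_config(seed = 4)
  expect_false(identical(simulate_expression(cfg2)$counts,
                         simulate_expression(cfg)$counts))
})

test_that("config validation rejects inconsistent designs", {
  expect_error(sim_config(frac_zga = 0.7, frac_decay = 0.5), "sum to <= 1")
  expect_error(sim_config(allelic_pi = 0.4), "allelic_pi")
  expect_error(sim_config(dhs_beta = 0), "dhs_beta")
  expect_error(sim_config(n_rep = 0), "n_rep")
  expect_error(sim_config(n_dmrs = 100, dmr_cpgs = 50, n_cpgs = 600),
               "must not exceed n_cpgs")
  expect_error(sim_config(genotypes = "XX"), "genotypes")
  # DMR layout must fit on the simulated chromosome
  expect_error(
    simulate_methylome_pair(sim_config(n_cpgs = 5000, n_dmrs = 200,
                                       cpg_spacing = 500, chrom_size = 1e6)),
    "exceeds chrom_size")
})

test_that("group means track programmed means as replicates grow", {
  cfg <- sim_config(seed = 5, n_genes = 60, n_rep = 200, nb_dispersion = 0.02,
                    genotypes = "AG")
  sim <- simulate_expression(cfg)
  ids <- sim$samples$sample_id[sim$samples$stage == "8C"]
  obs <- rowMeans(as.matrix(sim$counts[, ids]))
  prog <- rowMeans(as.matrix(sim$programmed_mu[, ids]))
  rel <- abs(obs - prog) / prog
  expect_lt(stats::median(rel), 0.05)
  expect_lt(max(rel), 0.25)
})

test_that("the injected program follows stage, genotype and treatment", {
  cfg <- sim_config(seed = 6, n_genes = 200, n_rep_amanitin = 2)
  sim <- simulate_expression(cfg)
  mu <- sim$programmed_mu
  zga <- sim$truth$gene_id[sim$truth$class == "zga"]
  dec <- sim$truth$gene_id[sim$truth$class == "maternal_decay"]
  m <- function(genes, sample) mean(mu[[sample]][mu$gene_id %in% genes])
  # ZGA: activated at 8C in AG, still off at 8C in PG, on at PG morula
  expect_gt(m(zga, "AG_8C_r1") / m(zga, "AG_4C_r1"), 8)
  expect_lt(m(zga, "PG_8C_r1") / m(zga, "PG_4C_r1"), 2)
  expect_gt(m(zga, "PG_morula_r1") / m(zga, "PG_4C_r1"), 8)
  # maternal decay mirrors activation
  expect_gt(m(dec, "AG_4C_r1") / m(dec, "AG_8C_r1"), 8)
  expect_lt(m(dec, "PG_4C_r1") / m(dec, "PG_8C_r1"), 2)
  # alpha-amanitin blocks both programs at 8C
  expect_lt(m(zga, "AG_8C_amanitin_r1") / m(zga, "AG_4C_r1"), 2)
  expect_lt(m(dec, "AG_4C_r1") / m(dec, "AG_8C_amanitin_r1"), 2)
})

test_that("dispersion zero gives Poisson-like counts", {
  cfg <- sim_config(seed = 7, n_genes = 50, n_rep = 100, nb_dispersion = 0,
                    genotypes = "AG")
  sim <- simulate_expression(cfg)
  ids <- sim$samples$sample_id[sim$samples$stage == "4C"]
  x <- as.matrix(sim$counts[, ids])
  mu <- rowMeans(x)
  vr <- apply(x, 1, stats::var)
  # variance/mean ratio concentrates near 1 for Poisson
  expect_lt(abs(stats::median(vr / mu) - 1), 0.2)
})

test_that("fully biased allelic genes at fixed depth hit the exact tail", {
  cfg <- sim_config(seed = 8, n_allelic_genes = 50, frac_paternal = 1,
                    frac_maternal = 0, allelic_pi = 1,
                    depth_mean = 12, depth_min = 12)
  sim <- simulate_allelic_counts(cfg)
  expect_true(all(sim$counts$paternal_reads == 12))
  p <- binomial_allelic_test(sim$counts$paternal_reads,
                             sim$counts$maternal_reads)
  expect_equal(unique(p), 2 * 0.5^12)
  expect_lt(unique(p), 0.001)
})

test_that("methylome truth regions are separated and directional", {
  cfg <- small_sim_config(seed = 9)
  sim <- simulate_methylome_pair(cfg)
  tr <- sim$truth_dmrs
  expect_equal(nrow(tr), 20)
  expect_true(all(diff(tr$start) > 0))
  # >= 500 bp between consecutive truth regions so chains cannot bridge them
  expect_true(all(tr$start[-1] - tr$end[-nrow(tr)] > 500))
  expect_setequal(unique(tr$direction), c("A", "B"))
  # sites inside an A-hyper DMR are hypermethylated in sample A
  r <- tr[tr$direction == "A", ][1, ]
  a <- sim$sample_a[sim$sample_a$pos >= r$start & sim$sample_a$pos <= r$end, ]
  b <- sim$sample_b[sim$sample_b$pos >= r$start & sim$sample_b$pos <= r$end, ]
  expect_gt(sum(a$m) / sum(a$m + a$u), sum(b$m) / sum(b$m + b$u))
})

test_that("global paternal hypomethylation shows up in pooled levels", {
  cfg <- small_sim_config(seed = 10, ml_shift_b = -0.15)
  sim <- simulate_methylome_pair(cfg)
  expect_gt(global_methylation(site_methylation(sim$sample_a)),
            global_methylation(site_methylation(sim$sample_b)))
})

test_that("allele-specific peaks are absent from the other sample's calls", {
  cfg <- small_sim_config(seed = 12)
  sim <- simulate_dhs_experiment(cfg)
  spec_a <- sim$truth[sim$truth$label == "a_specific", ]
  expect_gt(nrow(spec_a), 0)
  in_b <- paste(spec_a$start, spec_a$end) %in%
    paste(sim$peaks$B$start, sim$peaks$B$end)
  expect_false(any(in_b))
  shared <- sim$truth[sim$truth$label == "shared", ]
  expect_true(all(paste(shared$start, shared$end) %in%
                    paste(sim$peaks$B$start, sim$peaks$B$end)))
})
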