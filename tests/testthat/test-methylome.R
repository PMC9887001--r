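test_that("site methylation applies the depth-3 floor", {
  s <- tibble::tibble(chrom = "chrS", pos = c(1, 2, 3),
                      m = c(3, 2, 3), u = c(0, 0, 1))
  out <- site_methylation(s)
  expect_equal(out$pos, c(1, 3))
  expect_equal(out$ml, c(1, 0.75))
})

test_that("element methylation pools counts and enforces the CpG floor", {
  sites <- tibble::tibble(chrom = "chrS", pos = c(10, 20, 100),
                          m = c(3, 1, 5), u = c(1, 3, 0))
  el <- tibble::tibble(chrom = "chrS", start = c(1, 90, 200),
                       end = c(50, 150, 250))
  out <- element_methylation(sites, el)
  expect_equal(out$ml, c(0.5, 1, NA))
  expect_equal(out$n_cpgs, c(2L, 1L, 0L))
  # promoter-style floor: fewer than 5 covered CpGs -> no value
  prom <- tibble::tibble(chrom = "chrS", start = 1, end = 50)
  expect_true(is.na(element_methylation(sites, prom, min_cpgs = 5)$ml))
  expect_equal(global_methylation(sites), 9 / 13)
})

test_that("DMS calling tests matched deep sites and applies both cutoffs", {
  a <- tibble::tibble(chrom = "chrS", pos = c(100, 200, 300, 400),
                      m = c(10, 5, 9, 9), u = c(0, 5, 1, 1))
  b <- tibble::tibble(chrom = "chrS", pos = c(100, 200, 300, 500),
                      m = c(0, 5, 2, 3), u = c(10, 5, 2, 7))
  expect_message(dms <- call_dms(a, b), "unmatched")
  # pos 400/500 unmatched, pos 300 has depth 4 < 5 in B
  expect_equal(dms$pos, c(100, 200))
  i <- which(dms$pos == 100)
  expect_equal(dms$p_value[i], 2 / choose(20, 10))
  expect_equal(dms$diff[i], 1)
  expect_true(dms$is_dms[i])
  j <- which(dms$pos == 200)
  expect_equal(dms$p_value[j], 1)
  expect_false(dms$is_dms[j])
})

test_that("DMS calls are antisymmetric in the samples", {
  set.seed(51)
  mk <- function(p) tibble::tibble(chrom = "chrS", pos = 1:80 * 10,
                                   m = rbinom(80, 12, p), u = 12 - m)
  a <- mk(0.8); b <- mk(0.3)
  ab <- call_dms(a, b)
  ba <- call_dms(b, a)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$diff, -ba$diff)
  expect_equal(ab$is_dms, ba$is_dms)
  swap <- c(A = "B", B = "A")
  expect_equal(unname(swap[ab$direction]), ba$direction)
})

test_that("DMS chaining follows the gap, count, size and difference rules", {
  # three same-direction DMSs with gaps 300 and 400 -> one region
  d <- dms_fixture(pos = c(1000, 1300, 1700), is_dms = TRUE)
  r <- merge_dmrs(d)
  expect_equal(nrow(r), 1)
  expect_equal(r$start, 1000)
  expect_equal(r$end, 1700)
  expect_equal(r$size_bp, 701)
  expect_equal(r$n_dms, 3L)
  expect_equal(r$direction, "A")
  # a gap of exactly 500 breaks the chain
  expect_equal(nrow(merge_dmrs(dms_fixture(c(1000, 1500, 2000), TRUE))), 0)
  # gap 600: two singletons, below the 3-DMS floor
  expect_equal(nrow(merge_dmrs(dms_fixture(c(1000, 1600), TRUE))), 0)
  # three DMSs spanning 41 bp fail the size rule
  expect_equal(nrow(merge_dmrs(dms_fixture(c(1000, 1020, 1040), TRUE))), 0)
  # opposite-direction sites chain separately
  mixed <- dms_fixture(c(1000, 1300, 1600, 1900, 2200, 2500), TRUE,
                       direction = rep(c("A", "B"), 3))
  mixed$diff[mixed$direction == "B"] <- -1
  mixed[mixed$direction == "B", c("m_a", "u_a", "m_b", "u_b")] <-
    list(0, 10, 10, 0)
  expect_equal(nrow(merge_dmrs(mixed)), 0)  # neither direction reaches 3 in gap
})

test_that("region filters hold on every reported DMR and order does not
           matter", {
  cfg <- small_sim_config(seed = 52)
  sim <- simulate_methylome_pair(cfg)
  dms <- call_dms(site_methylation(sim$sample_a),
                  site_methylation(sim$sample_b))
  dmrs <- merge_dmrs(dms)
  expect_gt(nrow(dmrs), 0)
  expect_true(all(dmrs$n_dms >= 3))
  expect_true(all(dmrs$size_bp > 50))
  expect_true(all(abs(dmrs$diff) > 0.2))
  expect_true(all(dmrs$padj < 0.1))
  # shuffling the tested-site order leaves the regions unchanged
  shuffled <- dms[sample.int(nrow(dms)), ]
  attr(shuffled, "padj_cutoff") <- attr(dms, "padj_cutoff")
  dmrs2 <- merge_dmrs(shuffled)
  expect_equal(as.data.frame(dmrs2), as.data.frame(dmrs))
})

test_that("the all-members region rule is stricter than the pooled rule", {
  d <- dms_fixture(pos = c(1000, 1300, 1700), is_dms = TRUE)
  d$padj[2] <- 0.5                      # one member above the site cutoff
  d$is_dms[2] <- TRUE                   # but still chained as a DMS
  pooled <- merge_dmrs(d, region_test = "pooled")
  members <- merge_dmrs(d, region_test = "all_members")
  expect_equal(nrow(pooled), 1)
  expect_equal(nrow(members), 0)
})

test_that("recovery metrics compare called and truth intervals", {
  truth <- tibble::tibble(chrom = "chrS", start = c(100, 1000, 5000),
                          end = c(400, 1400, 5400))
  called <- tibble::tibble(chrom = "chrS", start = c(150, 1100),
                           end = c(380, 1300))
  r <- dmr_recovery(called, truth)
  expect_equal(r$n_matched, 2L)
  expect_equal(r$sensitivity, 2 / 3)
  expect_equal(r$precision, 1)
  expect_equal(r$region_jaccard, 2 / 3)
  expect_equal(r$bp_jaccard, (231 + 201) / (301 + 401 + 401))
  empty <- dmr_recovery(called[0, ], truth)
  expect_equal(empty$region_jaccard, 0)
})
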