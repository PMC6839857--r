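test_that("allele spectra come from direct counting, with both multi-copy views", {
  panel <- read_haplotype_table(toy_table(), loci = toy_loci())
  sp <- allele_spectrum(panel, "DYS19")
  expect_equal(sum(sp$freq), 1)
  expect_equal(sp$count[sp$key == "14"], 2L)
  # monomorphic locus
  mono <- panel_from_columns(DYS19 = rep(14, 4))
  expect_equal(allele_spectrum(mono, "DYS19")$freq, 1)
  # multi-copy: pooled alleles n = samples x copies; combinations n = samples
  pooled <- allele_spectrum(panel, "DYS385", "allele")
  combo <- allele_spectrum(panel, "DYS385", "combination")
  expect_equal(attr(pooled, "n"), 6)
  expect_equal(attr(combo, "n"), 3)
  expect_equal(sort(combo$key), c("13-17", "13-18", "14-17"))
  expect_error(allele_spectrum(panel, "NOPE"), "unknown locus")
})

test_that("flagged genotypes are excluded per locus but kept elsewhere", {
  txt <- sub("s2\tpopA\t15", "s2\tpopA\t15,16", toy_table()) # anomaly at DYS19
  panel <- read_haplotype_table(txt, loci = toy_loci())
  expect_equal(panel_flags(panel)$flag, "copy_number_anomaly")
  expect_equal(attr(allele_spectrum(panel, "DYS19"), "n"), 2)  # s2 dropped
  expect_equal(attr(allele_spectrum(panel, "DYS390"), "n"), 3) # s2 kept
})

test_that("gene diversity follows the Nei formula with its limiting cases", {
  # monomorphic -> 0 for any n
  expect_equal(gene_diversity(c(7)), 0)
  # all observations distinct -> exactly 1
  expect_equal(gene_diversity(rep(1, 13)), 1)
  # hand-evaluated spectrum {395, 4, 1}, n = 400
  expect_equal(round_half_up(gene_diversity(c(395, 4, 1)), 4), 0.0248)
  expect_error(gene_diversity(c(1)), "n < 2")
  # invariant under relabeling; increases when a doubleton splits
  set.seed(42)
  counts <- c(5, 3, 3, 2, 1)
  expect_equal(gene_diversity(sample(counts)), gene_diversity(counts))
  expect_gt(gene_diversity(c(5, 3, 3, 1, 1, 1)), gene_diversity(counts))
})

test_that("haplotype spectra count sorted-multiset identity over locus subsets", {
  panel <- read_haplotype_table(toy_table(), loci = toy_loci())
  hs <- haplotype_spectrum(panel)
  expect_equal(nrow(hs), 3)
  # identical samples collapse
  mono <- panel_from_columns(DYS19 = rep(14, 3), DYS390 = rep(24, 3))
  hs2 <- haplotype_spectrum(mono)
  expect_equal(nrow(hs2), 1)
  expect_equal(hs2$count, 3L)
  # perturbing one allele in one sample adds one distinct haplotype
  pert <- panel_from_columns(DYS19 = c(14, 14, 15), DYS390 = rep(24, 3))
  expect_equal(nrow(haplotype_spectrum(pert)), nrow(hs2) + 1)
  # exact-mode reconstruction returns the input spectrum
  loci <- ystr_loci()
  p <- sample_from_spectrum(c(2, 1), loci)
  expect_equal(sort(haplotype_spectrum(p)$count), c(1L, 2L))
  # missing loci exclude the sample from the subset spectrum
  txt <- sub("s3\tpopB\t14", "s3\tpopB\t-", toy_table())
  pm <- read_haplotype_table(txt, loci = toy_loci())
  hm <- haplotype_spectrum(pm, c("DYS19", "DYS390"))
  expect_equal(attr(hm, "n"), 2)
  expect_equal(attr(hm, "n_excluded"), 1)
})

test_that("headline statistics reproduce the published 400-male spectrum", {
  # 392 singleton + 4 doubleton haplotypes among n = 400
  loci <- ystr_loci()
  panel <- sample_from_spectrum(c(rep(1L, 392), rep(2L, 4)), loci)
  hs <- haplotype_spectrum(panel)
  expect_equal(attr(hs, "n"), 400)
  expect_equal(nrow(hs), 396)
  expect_equal(sum(hs$count == 1), 392)
  expect_equal(match_probability(hs), 0.00255)
  expect_equal(round_half_up(match_probability(hs), 4), 0.0026)
  expect_equal(haplotype_diversity(hs), (400 / 399) * (1 - 0.00255))
  expect_equal(round_down(haplotype_diversity(hs), 4), 0.9999)
  expect_equal(discrimination_capacity(hs), 0.99)
})

test_that("HMP/HD/DC limiting cases hold", {
  expect_equal(match_probability(c(9)), 1)           # all identical
  expect_equal(haplotype_diversity(c(9)), 0)
  expect_equal(discrimination_capacity(c(9)), 1 / 9)
  expect_equal(match_probability(rep(1, 400)), 0.0025) # all unique: 1/n
  expect_equal(haplotype_diversity(rep(1, 400)), 1)
  expect_equal(discrimination_capacity(rep(1, 400)), 1)
})

test_that("HMP equals the naive pairwise-match oracle on small panels", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(5:50, 1)
    counts <- as.vector(table(sample.int(max(2, n %/% 3), n, replace = TRUE)))
    panel <- sample_from_spectrum(counts, ystr_loci())
    hs <- haplotype_spectrum(panel)
    expect_equal(match_probability(hs), hmp_pairwise_oracle(panel),
                 tolerance = 1e-12)
  }
})

test_that("forensic report fills every field and satisfies its identities", {
  loci <- toy_loci()
  panel <- read_haplotype_table(toy_table(), loci = loci)
  rep <- forensic_report(panel)
  g <- glance(rep)
  expect_equal(g$n, 3)
  expect_equal(g$k, 3)
  expect_equal(g$dc, 1)
  td <- tidy(rep)
  expect_equal(td$locus, loci$locus)
  expect_true(all(!is.na(td$gd)))
  # monomorphic panel: all diversities 0, DC = 1/n
  mono <- panel_from_columns(DYS19 = rep(14, 5), DYS390 = rep(24, 5))
  gm <- glance(forensic_report(mono))
  expect_equal(gm$hd, 0)
  expect_equal(gm$hmp, 1)
  expect_equal(gm$dc, 1 / 5)
  expect_equal(tidy(forensic_report(mono))$gd, c(0, 0))
  # JSON serialization carries the same numbers
  js <- jsonlite::fromJSON(forensic_json(rep))
  expect_equal(js$k, g$k)
  expect_equal(js$hd, g$hd, tolerance = 1e-6)
})

test_that("HD = (n/(n-1))(1-HMP) and DC*n = k on random panels", {
  for (seed in 1:20) {
    set.seed(seed)
    counts <- as.vector(table(sample.int(8, sample(6:30, 1), replace = TRUE)))
    panel <- sample_from_spectrum(counts, ystr_loci()[1:4, ])
    hs <- haplotype_spectrum(panel)
    n <- attr(hs, "n")
    expect_equal(haplotype_diversity(hs),
                 (n / (n - 1)) * (1 - match_probability(hs)), tolerance = 1e-14)
    expect_equal(discrimination_capacity(hs) * n, nrow(hs), tolerance = 1e-12)
    for (l in c("DYS19", "DYS460")) {
      expect_equal(sum(allele_spectrum(panel, l)$freq), 1, tolerance = 1e-12)
    }
  }
})
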