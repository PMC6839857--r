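test_that("squared repeat distance sums sorted-paired copy differences", {
  loci <- c("DYS19", "DYS390")
  h1 <- list(DYS19 = 14, DYS390 = 24)
  expect_equal(as.numeric(haplotype_sq_distance(h1, h1, loci)), 0)
  h2 <- list(DYS19 = 15, DYS390 = 22)
  expect_equal(as.numeric(haplotype_sq_distance(h1, h2, loci)), 5) # 1 + 4
  # multi-copy sorted pairing
  a <- list(DYS385 = c(13, 17)); b <- list(DYS385 = c(14, 18))
  expect_equal(as.numeric(haplotype_sq_distance(a, b, "DYS385")), 2)
  # pairing is on sorted order regardless of input order
  expect_equal(as.numeric(haplotype_sq_distance(list(DYS385 = c(17, 13)), b, "DYS385")), 2)
  # copy-count mismatch skips the locus and records it
  v <- haplotype_sq_distance(list(DYS527 = c(13, 14, 15), DYS19 = 14),
                             list(DYS527 = c(13, 14), DYS19 = 16),
                             c("DYS527", "DYS19"))
  expect_equal(as.numeric(v), 4)
  expect_equal(attr(v, "skipped"), "DYS527")
  # microvariants contribute literal decimal values
  expect_equal(as.numeric(haplotype_sq_distance(list(DYS458 = 17.2),
                                                list(DYS458 = 16), "DYS458")),
               1.2^2)
})

test_that("the worked four-sample AMOVA instance yields Rst = 0.8", {
  panel <- panel_from_matrices(matrix(c(10, 10), 2), matrix(c(12, 14), 2))
  r <- amova_pair(panel, "A", "B")
  expect_equal(r$ssd_total, 11)
  expect_equal(r$ssd_within, 2)
  expect_equal(r$ms_among, 9)
  expect_equal(r$ms_within, 1)
  expect_equal(r$n_c, 2)
  expect_equal(r$sigma_a, 4)
  expect_equal(r$rst, 0.8)
})

test_that("AMOVA limiting cases behave", {
  # identical populations: no between-group signal
  M <- matrix(c(10, 12, 14), 3)
  p0 <- panel_from_matrices(M, M)
  expect_equal(amova_pair(p0, "A", "B")$rst_clamped, 0)
  # two internally monomorphic, mutually different populations: Rst = 1
  p1 <- panel_from_matrices(matrix(10, 3), matrix(13, 3))
  expect_equal(amova_pair(p1, "A", "B")$rst, 1)
  expect_error(amova_pair(panel_from_matrices(matrix(10, 1), matrix(11, 3)),
                          "A", "B"), ">= 2")
})

test_that("Rst matches the first-principles ANOVA oracle on random instances", {
  for (seed in 1:12) {
    set.seed(seed)
    nA <- sample(2:6, 1); nB <- sample(2:6, 1)
    panel <- random_panel(c(nA, nB), n_loci = sample(1:4, 1), seed = seed + 100)
    r <- amova_pair(panel, "pop1", "pop2")
    expect_equal(r$rst, rst_anova_oracle(panel), tolerance = 1e-9)
  }
})

test_that("Rst is invariant under shifting every allele at a locus", {
  panel <- random_panel(c(5, 6), n_loci = 3, seed = 7)
  shifted <- as_tibble(panel)
  shifted$L2 <- lapply(shifted$L2, function(a) a + 7)
  shifted <- ystr_panel(shifted, panel_loci(panel))
  expect_equal(amova_pair(panel, "pop1", "pop2")$rst,
               amova_pair(shifted, "pop1", "pop2")$rst, tolerance = 1e-12)
})

test_that("the pairwise Rst matrix is symmetric, clamped and complete", {
  panel <- random_panel(c(4, 4, 5), n_loci = 3, seed = 21)
  m <- pairwise_rst(panel)
  expect_equal(m$rst, t(m$rst))
  expect_equal(diag(m$rst), setNames(rep(0, 3), rownames(m$rst)))
  expect_true(all(m$rst >= 0))
  expect_equal(nrow(m$pairs), 3)
  # identical populations give an all-zero matrix
  M <- matrix(c(10, 12, 14, 12), 4)
  same <- panel_from_matrices(M, M)
  same3 <- as_tibble(same)
  extra <- same3[same3$population == "A", ]
  extra$population <- "C"
  extra$sample_id <- paste0("C_", seq_len(nrow(extra)))
  same3 <- ystr_panel(dplyr::bind_rows(same3, extra), panel_loci(same))
  m0 <- pairwise_rst(same3)
  expect_true(all(m0$rst == 0))
  # PHYLIP round trip of the matrix
  f <- withr::local_tempfile()
  write_phylip(m, f)
  expect_lte(max(abs(read_phylip(f) - m$rst)), 5e-5) # 4-dp print precision
})

test_that("permutation p-values are deterministic, bounded and calibrated", {
  # two monomorphic distinct populations: no permutation beats the observed
  p1 <- panel_from_matrices(matrix(10, 10), matrix(13, 10))
  pv <- rst_permutation_pvalue(p1, "A", "B", n_perm = 999, seed = 4)
  expect_lte(pv, 0.05)
  expect_gte(pv, 1 / 1000)
  # fixed seed reproduces the p-value exactly
  panel <- random_panel(c(6, 6), n_loci = 2, seed = 30)
  expect_equal(rst_permutation_pvalue(panel, "pop1", "pop2", n_perm = 99, seed = 9),
               rst_permutation_pvalue(panel, "pop1", "pop2", n_perm = 99, seed = 9))
})

test_that("null permutation p-values are approximately uniform", {
  # panels with no real structure: labels assigned at random
  # groups of 8 keep the permutation space large enough that the add-one
  # estimator's discreteness does not dominate the KS statistic
  set.seed(202)
  pvals <- vapply(1:200, function(i) {
    M <- matrix(sample(10:18, 32, replace = TRUE), 16)
    panel <- panel_from_matrices(M[1:8, , drop = FALSE], M[9:16, , drop = FALSE])
    rst_permutation_pvalue(panel, "A", "B", n_perm = 199)
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_lt(as.numeric(ks$statistic), 0.1)
})
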