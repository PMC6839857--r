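# Shared fixture builders. Everything is generated in code; no data files.

toy_loci <- function() {
  locus_spec(c("DYS19", "DYS390", "DYS385"), copy_number = c(1L, 1L, 2L))
}

toy_table <- function() {
  paste(
    "sample_id\tpopulation\tDYS19\tDYS390\tDYS385",
    "s1\tpopA\t14\t24\t13-17",
    "s2\tpopA\t15\t24\t13-18",
    "s3\tpopB\t14\t22\t14-17",
    sep = "\n"
  )
}

# small single-population panel with given allele columns (single-copy loci)
panel_from_columns <- function(...) {
  cols <- list(...)
  n <- length(cols[[1]])
  df <- tibble::tibble(
    sample_id = sprintf("s%03d", seq_len(n)),
    population = "pop1"
  )
  for (nm in names(cols)) df[[nm]] <- lapply(cols[[nm]], identity)
  ystr_panel(df, locus_spec(names(cols)))
}

# two-population single-copy panel from two allele matrices (rows = samples)
panel_from_matrices <- function(A, B, loci_names = paste0("L", seq_len(ncol(A)))) {
  build <- function(M, pop) {
    df <- tibble::tibble(
      sample_id = sprintf("%s_%03d", pop, seq_len(nrow(M))),
      population = pop
    )
    for (j in seq_along(loci_names)) df[[loci_names[j]]] <- lapply(M[, j], identity)
    df
  }
  ystr_panel(dplyr::bind_rows(build(A, "A"), build(B, "B")),
             locus_spec(loci_names))
}

# random multi-population single-copy panel of integer repeat scores
random_panel <- function(n_per_pop = c(4, 5), n_loci = 3, seed = 1) {
  set.seed(seed)
  mats <- lapply(seq_along(n_per_pop), function(p) {
    matrix(sample(10:20, n_per_pop[p] * n_loci, replace = TRUE),
           nrow = n_per_pop[p])
  })
  loci_names <- paste0("L", seq_len(n_loci))
  rows <- lapply(seq_along(mats), function(p) {
    df <- tibble::tibble(
      sample_id = sprintf("p%d_%03d", p, seq_len(nrow(mats[[p]]))),
      population = paste0("pop", p)
    )
    for (j in seq_len(n_loci)) df[[loci_names[j]]] <- lapply(mats[[p]][, j], identity)
    df
  })
  ystr_panel(dplyr::bind_rows(rows), locus_spec(loci_names))
}

# independent HMP oracle: probability two draws (with replacement) match,
# by naive pairwise match counting over the raw haplotype keys
hmp_pairwise_oracle <- function(panel, loci = NULL) {
  loci <- loci %||% panel_loci(panel)$locus
  keys <- apply(
    sapply(loci, function(l) vapply(panel[[l]], paste, character(1), collapse = "-")),
    1, paste, collapse = "|"
  )
  n <- length(keys)
  matches <- sum(outer(keys, keys, "==")) # includes diagonal
  matches / n^2
}

# independent Rst oracle for single-copy loci: classical one-way ANOVA sums
# of squares on repeat scores, aggregated over loci (no pairwise distances)
rst_anova_oracle <- function(panel, loci = NULL) {
  loci <- loci %||% panel_loci(panel)$locus
  pop <- factor(panel$population)
  N <- nrow(panel); P <- nlevels(pop)
  ss_among <- 0; ss_within <- 0
  for (l in loci) {
    x <- vapply(panel[[l]], function(a) a[1], numeric(1))
    fit <- stats::anova(stats::lm(x ~ pop))
    ss_among <- ss_among + fit[["Sum Sq"]][1]
    ss_within <- ss_within + fit[["Sum Sq"]][2]
  }
  n_p <- as.integer(table(pop))
  ms_a <- ss_among / (P - 1)
  ms_w <- ss_within / (N - P)
  n_c <- (N - sum(n_p^2) / N) / (P - 1)
  sigma_a <- (ms_a - ms_w) / n_c
  if (sigma_a + ms_w <= 0) 0 else sigma_a / (sigma_a + ms_w)
}

# random additive tree and its exact leaf-to-leaf distance matrix
random_additive_tree <- function(n_leaves, seed) {
  set.seed(seed)
  tree <- ape::rtree(n_leaves, rooted = FALSE,
                     br = function(k) runif(k, 0.5, 3))
  D <- ape::cophenetic.phylo(tree)
  D <- D[sort(rownames(D)), sort(rownames(D))]
  list(tree = tree, D = D)
}
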