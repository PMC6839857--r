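# Pairwise Rst by two-level AMOVA on squared repeat differences.
#
# The molecular distance between two haplotypes is
#   delta^2 = sum over loci of sum over paired copies (a - b)^2,
# copies paired after ascending sort within each haplotype (the standard
# repeat-score distance behind Rst-type AMOVA on Y-STRs). Variance
# components follow the classical two-level AMOVA decomposition:
#   SSD_total  = (1/N) sum_{i<j} d2_ij         over all N samples
#   SSD_within = sum_p (1/n_p) sum_{i<j in p} d2_ij
#   SSD_among  = SSD_total - SSD_within
#   MS_among = SSD_among/(P-1);  MS_within = SSD_within/(N-P)
#   n_c = (N - sum n_p^2 / N)/(P-1)
#   sigma2_a = (MS_among - MS_within)/n_c;  sigma2_w = MS_within
#   Rst = sigma2_a / (sigma2_a + sigma2_w)

#' Squared repeat distance between two haplotypes
#'
#' Copies of multi-copy loci are paired after ascending sort; decimal
#' microvariant values contribute their literal real value. A locus where the
#' two haplotypes carry different copy counts is skipped for the pair (no
#' defined pairing) and named in the `skipped` attribute.
#'
#' @param h1,h2 haplotypes: named lists of sorted numeric allele vectors.
#' @param loci character vector of locus names to include.
#' @return The squared distance (numeric scalar) with attribute `skipped`.
#' @examples
#' haplotype_sq_distance(list(DYS19 = 14, DYS390 = 24),
#'                       list(DYS19 = 15, DYS390 = 22),
#'                       c("DYS19", "DYS390"))  # 1 + 4 = 5
#' @export
haplotype_sq_distance <- function(h1, h2, loci) {
  total <- 0
  skipped <- character()
  for (l in loci) {
    a <- h1[[l]]; b <- h2[[l]]
    if (is.null(a) || is.null(b)) abort(sprintf("haplotype incomplete at %s", l))
    if (length(a) != length(b)) {
      skipped <- c(skipped, l)
      next
    }
    total <- total + sum((sort(a) - sort(b))^2)
  }
  structure(total, skipped = skipped)
}

# N x N squared-distance matrix over complete-case rows of `panel`.
# Loci where every retained sample shows one common copy count are flattened
# into a score matrix (fast path); other loci fall back to pairwise loops
# with per-pair skipping of mismatched copy counts.
pairwise_sq_distances <- function(panel, loci) {
  n <- nrow(panel)
  D <- matrix(0, n, n)
  skipped_pairs <- 0L
  for (l in loci) {
    geno <- panel[[l]]
    lens <- map_int(geno, length)
    if (any(lens == 0L)) abort(sprintf("flagged/missing genotypes at %s; drop incomplete cases first", l))
    if (length(unique(lens)) == 1L) {
      X <- do.call(rbind, geno)          # rows already sorted ascending
      D <- D + as.matrix(stats::dist(X))^2
    } else {
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          if (lens[i] == lens[j]) {
            d <- sum((geno[[i]] - geno[[j]])^2)
            D[i, j] <- D[i, j] + d
            D[j, i] <- D[i, j]
          } else {
            skipped_pairs <- skipped_pairs + 1L
          }
        }
      }
    }
  }
  structure(D, skipped_pairs = skipped_pairs)
}

# variance components from a squared-distance matrix and group labels
rst_components <- function(d2, groups) {
  N <- length(groups)
  P <- length(unique(groups))
  upper <- upper.tri(d2)
  ssd_total <- sum(d2[upper]) / N
  ssd_within <- 0
  n_p <- integer(P)
  for (p in seq_along(unique(groups))) {
    idx <- which(groups == unique(groups)[p])
    n_p[p] <- length(idx)
    sub <- d2[idx, idx, drop = FALSE]
    ssd_within <- ssd_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ssd_among <- ssd_total - ssd_within
  ms_among <- ssd_among / (P - 1)
  ms_within <- ssd_within / (N - P)
  n_c <- (N - sum(n_p^2) / N) / (P - 1)
  sigma_a <- (ms_among - ms_within) / n_c
  sigma_w <- ms_within
  degenerate <- (sigma_a + sigma_w) <= 0
  rst <- if (degenerate) 0 else sigma_a / (sigma_a + sigma_w)
  list(sigma_a = sigma_a, sigma_w = sigma_w, rst = rst,
       rst_clamped = max(rst, 0), degenerate = degenerate,
       ssd_total = ssd_total, ssd_within = ssd_within, ssd_among = ssd_among,
       ms_among = ms_among, ms_within = ms_within, n_c = n_c, n_per_pop = n_p)
}

#' Rst between two populations by AMOVA
#'
#' Complete-case samples of the two populations (unflagged at every selected
#' locus) enter a two-level AMOVA on squared repeat differences. With
#' `n_perm > 0`, significance is assessed by permuting individuals across the
#' two population labels (group sizes preserved) and
#' `p = (1 + #\{Rst_perm >= Rst_obs\}) / (n_perm + 1)`.
#'
#' @param panel an [ystr_panel()].
#' @param pop_a,pop_b population labels present in the panel.
#' @param loci locus names used for the distance; default all panel loci.
#' @param n_perm permutation count (0 = no p-value).
#' @param seed RNG seed for the permutations.
#' @return An `ystr_rst` object: variance components `sigma_a`, `sigma_w`,
#'   `rst` (raw), `rst_clamped`, optional `p_value`, sample sizes and loci
#'   used. `tidy()`/`glance()` methods available.
#' @export
amova_pair <- function(panel, pop_a, pop_b, loci = NULL, n_perm = 0,
                       seed = NULL) {
  loci <- loci %||% panel_loci(panel)$locus
  sub <- panel_subset(panel, panel$population %in% c(pop_a, pop_b))
  keep <- sub$sample_id %in% complete_case_ids(sub, loci)
  sub <- panel_subset(sub, keep)
  groups <- sub$population
  if (min(table(groups)) < 2 || length(unique(groups)) < 2) {
    abort("both populations need >= 2 complete-case samples")
  }
  d2 <- pairwise_sq_distances(sub, loci)
  comp <- rst_components(d2, groups)
  p_value <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    obs <- comp$rst
    hits <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample(groups)
      if (rst_components(d2, perm)$rst >= obs - 1e-12) hits <- hits + 1L
    }
    p_value <- (1 + hits) / (n_perm + 1)
  }
  structure(c(comp, list(
    p_value = p_value, n_perm = as.integer(n_perm),
    populations = c(pop_a, pop_b), loci_used = loci,
    n_excluded = sum(!keep),
    skipped_pairs = attr(d2, "skipped_pairs")
  )), class = "ystr_rst")
}

#' @export
print.ystr_rst <- function(x, ...) {
  cat(sprintf("<ystr_rst> %s vs %s (n = %s)\n",
              x$populations[1], x$populations[2],
              paste(x$n_per_pop, collapse = " + ")))
  cat(sprintf("  sigma2_among = %.6g, sigma2_within = %.6g\n",
              x$sigma_a, x$sigma_w))
  cat(sprintf("  Rst = %.4f (clamped %.4f)%s\n", x$rst, x$rst_clamped,
              if (!is.na(x$p_value)) sprintf(", permutation p = %.4g", x$p_value) else ""))
  invisible(x)
}

#' Tidy methods for Rst results
#'
#' @param x an `ystr_rst`.
#' @param ... unused.
#' @return `tidy()`: variance components as rows; `glance()`: one-row summary.
#' @export
tidy.ystr_rst <- function(x, ...) {
  tibble(component = c("among_populations", "within_populations"),
         sigma2 = c(x$sigma_a, x$sigma_w),
         ssd = c(x$ssd_among, x$ssd_within),
         mean_square = c(x$ms_among, x$ms_within))
}

#' @rdname tidy.ystr_rst
#' @export
glance.ystr_rst <- function(x, ...) {
  tibble(pop_a = x$populations[1], pop_b = x$populations[2],
         rst = x$rst, rst_clamped = x$rst_clamped, p_value = x$p_value,
         sigma_a = x$sigma_a, sigma_w = x$sigma_w,
         n_a = x$n_per_pop[1], n_b = x$n_per_pop[2],
         n_loci = length(x$loci_used), degenerate = x$degenerate)
}

#' Permutation p-value for a population pair
#'
#' Convenience wrapper around [amova_pair()] returning only the permutation
#' tail probability.
#'
#' @inheritParams amova_pair
#' @return The p-value in `(0, 1]`; minimum `1/(n_perm + 1)`.
#' @export
rst_permutation_pvalue <- function(panel, pop_a, pop_b, loci = NULL,
                                   n_perm = 999, seed = NULL) {
  amova_pair(panel, pop_a, pop_b, loci, n_perm = n_perm, seed = seed)$p_value
}

#' Pairwise Rst matrix over all populations
#'
#' Runs [amova_pair()] for every unordered population pair. The matrix holds
#' clamped values (`max(Rst, 0)`, as fed to MDS and neighbor-joining); raw
#' values are retained alongside.
#'
#' @inheritParams amova_pair
#' @param multi_copy include multi-copy loci (sorted-pairing distance) or
#'   restrict to single-copy loci.
#' @return An `ystr_rst_matrix`: list with `rst` (clamped symmetric matrix),
#'   `rst_raw`, `pairs` (tibble of per-pair results).
#' @export
pairwise_rst <- function(panel, loci = NULL, n_perm = 0, seed = NULL,
                         multi_copy = TRUE) {
  spec <- panel_loci(panel)
  loci <- loci %||% spec$locus
  if (!multi_copy) {
    loci <- loci[loci %in% spec$locus[spec$copy_number == 1L & !spec$variable]]
  }
  pops <- unique(panel$population)
  if (length(pops) < 2) abort("need at least two populations")
  if (!is.null(seed)) set.seed(seed)
  pair_idx <- combn(length(pops), 2)
  pairs <- map(seq_len(ncol(pair_idx)), function(k) {
    i <- pair_idx[1, k]; j <- pair_idx[2, k]
    res <- amova_pair(panel, pops[i], pops[j], loci, n_perm = n_perm)
    glance(res)
  })
  pairs <- bind_rows(pairs)
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  raw <- m
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$pop_a[k]; j <- pairs$pop_b[k]
    m[i, j] <- m[j, i] <- pairs$rst_clamped[k]
    raw[i, j] <- raw[j, i] <- pairs$rst[k]
  }
  structure(list(rst = m, rst_raw = raw, pairs = pairs, loci_used = loci),
            class = "ystr_rst_matrix")
}

#' @export
print.ystr_rst_matrix <- function(x, ...) {
  cat(sprintf("<ystr_rst_matrix> %d populations, %d loci\n",
              nrow(x$rst), length(x$loci_used)))
  print(round(x$rst, 4))
  invisible(x)
}

#' @rdname tidy.ystr_rst
#' @export
tidy.ystr_rst_matrix <- function(x, ...) x$pairs
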