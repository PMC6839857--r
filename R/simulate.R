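# Forward-time Wright-Fisher stepwise-mutation simulator.
#
# Haploid (Y-chromosome) populations of size N reproduce by multinomial
# resampling; every allele copy mutates independently each generation with
# its locus rate, stepping +1 or -1 repeat with equal probability under the
# single-step stepwise mutation model (SMM). Repeat counts reflect at 1
# (a 1 that mutates downward goes to 2). An ancestral population founded
# monomorphic is burnt in for 4N generations to approach mutation-drift
# equilibrium, then split (star-shaped) into n_pops copies which evolve
# independently for T generations before sampling.

#' Apply one generation of stepwise mutation to allele values
#'
#' Each value mutates with probability `rate`; a mutation steps the repeat
#' count by +1 or -1 with equal probability, reflecting at the boundary 1.
#' Uses the current RNG stream.
#'
#' @param values integer-valued numeric vector of repeat counts.
#' @param rate per-copy mutation probability in `[0, 1]`.
#' @return The mutated vector.
#' @export
smm_mutate <- function(values, rate) {
  if (rate < 0 || rate > 1) abort("mutation rate must lie in [0, 1]")
  if (rate == 0 || !length(values)) return(values)
  hit <- runif(length(values)) < rate
  if (any(hit)) {
    step <- ifelse(runif(sum(hit)) < 0.5, -1, 1)
    v <- values[hit] + step
    v[v < 1] <- 2 - v[v < 1]  # reflect at 1
    values[hit] <- v
  }
  values
}

#' Simulation configuration
#'
#' @param n_pops number of populations after the (star-shaped) split.
#' @param pop_size haploid effective size N of every population.
#' @param sample_size haplotypes sampled (without replacement) per population;
#'   must not exceed `pop_size`.
#' @param split_generations generations T each population evolves
#'   independently after the split.
#' @param loci locus specification tibble; per-locus `mutation_rate` applies
#'   to each copy. Default: the 36-locus panel at rate 0.002.
#' @param founder modal repeat count of the monomorphic founder haplotype.
#' @param burn_in generations of ancestral evolution before the split;
#'   default `4 * pop_size`.
#' @param seed master RNG seed; same seed and config give identical panels.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_pops = 2, pop_size = 100, sample_size = 50,
                       split_generations = 100, loci = ystr_loci(),
                       founder = 14, burn_in = NULL, seed = 1) {
  loci <- validate_locus_spec(loci)
  cfg <- list(
    n_pops = as.integer(n_pops), pop_size = as.integer(pop_size),
    sample_size = as.integer(sample_size),
    split_generations = as.integer(split_generations),
    loci = loci, founder = as.numeric(founder),
    burn_in = as.integer(burn_in %||% (4L * as.integer(pop_size))),
    seed = as.integer(seed)
  )
  with(cfg, {
    if (n_pops < 1 || pop_size < 1 || sample_size < 1) {
      abort("all counts must be >= 1")
    }
    if (sample_size > pop_size) abort("sample_size must not exceed pop_size")
    if (split_generations < 0 || burn_in < 0) abort("generation counts must be >= 0")
  })
  structure(cfg, class = "sim_config")
}

# locus copy layout: one matrix column per allele copy
copy_layout <- function(loci) {
  tibble(
    locus = rep(loci$locus, loci$copy_number),
    rate = rep(loci$mutation_rate, loci$copy_number)
  )
}

# evolve an N x C matrix of repeat counts for `generations` WF generations
evolve_matrix <- function(mat, rates_by_col, generations) {
  n <- nrow(mat)
  rate_mat <- rep(rates_by_col, each = n)
  for (g in seq_len(generations)) {
    mat <- mat[sample.int(n, n, replace = TRUE), , drop = FALSE]
    hit <- runif(length(mat)) < rate_mat
    if (any(hit)) {
      step <- ifelse(runif(sum(hit)) < 0.5, -1, 1)
      v <- mat[hit] + step
      v[v < 1] <- 2 - v[v < 1]
      mat[hit] <- v
    }
  }
  mat
}

matrix_to_panel <- function(mats, loci, sample_sizes, pop_names = NULL) {
  layout <- copy_layout(loci)
  pop_names <- pop_names %||% paste0("pop", seq_along(mats))
  rows <- imap(mats, function(mat, i) {
    idx <- sample.int(nrow(mat), sample_sizes[[as.integer(i)]], replace = FALSE)
    sub <- mat[idx, , drop = FALSE]
    out <- tibble(
      sample_id = sprintf("%s_s%03d", pop_names[as.integer(i)], seq_along(idx)),
      population = pop_names[as.integer(i)]
    )
    for (l in loci$locus) {
      cols <- which(layout$locus == l)
      out[[l]] <- map(seq_along(idx), ~ sort(sub[.x, cols]))
    }
    out
  })
  ystr_panel(bind_rows(rows), loci)
}

#' Simulate a multi-population Y-STR panel
#'
#' Runs the Wright-Fisher / stepwise-mutation model described in
#' [sim_config()]: monomorphic founder, `burn_in` ancestral generations,
#' star split into `n_pops` populations evolving `split_generations`
#' generations, then `sample_size` haplotypes drawn per population.
#' Multi-copy loci are simulated as `copy_number` independently mutating
#' linked copies. Per-population RNG streams are derived deterministically
#' from the master seed.
#'
#' @param config a [sim_config()].
#' @return An [ystr_panel()] with populations `pop1 ... popK`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  layout <- copy_layout(config$loci)
  anc <- matrix(config$founder, nrow = config$pop_size, ncol = nrow(layout))
  anc <- evolve_matrix(anc, layout$rate, config$burn_in)
  pop_seeds <- replicate(config$n_pops, draw_subseed())
  sample_seed <- draw_subseed()
  mats <- map(seq_len(config$n_pops), function(i) {
    set.seed(pop_seeds[i])
    evolve_matrix(anc, layout$rate, config$split_generations)
  })
  set.seed(sample_seed)
  matrix_to_panel(mats, config$loci,
                  rep(config$sample_size, config$n_pops))
}

#' Build a panel realizing a haplotype frequency spectrum
#'
#' In `mode = "exact"` the returned panel contains each supplied haplotype
#' exactly `count` times, so its haplotype spectrum equals the input — used
#' to reconstruct published spectra (e.g. 392 singleton + 4 doubleton
#' haplotypes among n = 400). In `mode = "multinomial"`, `sample_size`
#' haplotypes are drawn with replacement with probabilities `count / n`.
#'
#' @param spectrum either a spectrum tibble with `key` (ignored) and `count`,
#'   a bare vector of counts, or a list of haplotypes (named lists of allele
#'   vectors) with a `counts` attribute.
#' @param loci locus specification; default the 36-locus panel.
#' @param mode `"exact"` or `"multinomial"`.
#' @param sample_size draws in multinomial mode.
#' @param population population label for all samples.
#' @param haplotypes optional list of haplotypes (named list of numeric allele
#'   vectors per locus), one per spectrum entry; defaults to
#'   [make_haplotypes()] distinct synthetic haplotypes.
#' @return An [ystr_panel()].
#' @export
sample_from_spectrum <- function(spectrum, loci = ystr_loci(),
                                 mode = c("exact", "multinomial"),
                                 sample_size = NULL, population = "pop1",
                                 haplotypes = NULL) {
  mode <- match.arg(mode)
  counts <- if (is.data.frame(spectrum)) spectrum$count else as.integer(spectrum)
  if (any(counts < 1)) abort("spectrum counts must be >= 1")
  loci <- validate_locus_spec(loci)
  haplotypes <- haplotypes %||% make_haplotypes(length(counts), loci)
  stopifnot(length(haplotypes) == length(counts))
  reps <- if (mode == "exact") {
    rep(seq_along(counts), counts)
  } else {
    if (is.null(sample_size)) abort("sample_size required in multinomial mode")
    sample.int(length(counts), sample_size, replace = TRUE,
               prob = counts / sum(counts))
  }
  out <- tibble(
    sample_id = sprintf("%s_s%04d", population, seq_along(reps)),
    population = population
  )
  for (l in loci$locus) {
    out[[l]] <- map(reps, ~ haplotypes[[.x]][[l]])
  }
  ystr_panel(out, loci)
}

#' Generate k distinct synthetic haplotypes
#'
#' Haplotypes share a baseline allele at every locus and are made distinct by
#' a mixed-radix enumeration over allele offsets at successive loci, so any
#' two differ at one or more loci. Deterministic.
#'
#' @param k number of distinct haplotypes.
#' @param loci locus specification tibble.
#' @param base baseline repeat count.
#' @param n_states allele states available per locus digit.
#' @return A list of `k` haplotypes (named lists of sorted allele vectors).
#' @export
make_haplotypes <- function(k, loci, base = 14, n_states = 10) {
  loci <- validate_locus_spec(loci)
  if (k > n_states^nrow(loci)) abort("too many haplotypes for this locus panel")
  map(seq_len(k) - 1L, function(code) {
    h <- list()
    for (i in seq_len(nrow(loci))) {
      offset <- code %% n_states
      code <- code %/% n_states
      h[[loci$locus[i]]] <- sort(base + offset + seq_len(loci$copy_number[i]) - 1)
    }
    h
  })
}
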