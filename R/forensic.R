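# Forensic summary statistics by direct counting.
#
# All diversity measures are Nei's unbiased gene diversity
#   GD = (n/(n-1)) * (1 - sum(Pi^2))
# applied either to per-locus allele frequencies (GD) or to whole-haplotype
# frequencies (HD). The haplotype match probability is HMP = sum(Pi^2) and
# the discrimination capacity DC = k/n (k distinct haplotypes, n samples).

new_spectrum <- function(counts, unit, locus = NULL) {
  counts <- counts[order(names(counts))]
  n <- sum(counts)
  structure(
    tibble(key = names(counts), count = as.integer(counts),
           freq = as.numeric(counts) / n),
    class = c("ystr_spectrum", class(tibble())),
    unit = unit, n = n, locus = locus
  )
}

spectrum_n <- function(spectrum) attr(spectrum, "n") %||% sum(spectrum$count)

#' Allele frequency spectrum of one locus
#'
#' Counts alleles by direct counting over the samples unflagged at `locus`.
#' For multi-copy loci two views exist: `unit = "allele"` pools all copies
#' (n = contributing samples x copies) while `unit = "combination"` counts
#' sorted allele multisets as units (n = contributing samples). Single-copy
#' loci give the same spectrum either way.
#'
#' @param panel an [ystr_panel()].
#' @param locus locus name present in the panel.
#' @param unit `"allele"` (pooled copies) or `"combination"` (sorted
#'   multisets, e.g. "13-17" for DYS385).
#' @return A spectrum tibble (`key`, `count`, `freq`) with attributes `n`,
#'   `unit`, `locus`; frequencies sum to 1.
#' @export
allele_spectrum <- function(panel, locus, unit = c("allele", "combination")) {
  unit <- match.arg(unit)
  if (!locus %in% panel_loci(panel)$locus) {
    abort(sprintf("unknown locus '%s'", locus))
  }
  ids <- unflagged_ids(panel, locus)
  geno <- panel[[locus]][match(ids, panel$sample_id)]
  geno <- geno[!map_lgl(geno, is.null)]
  if (!length(geno)) return(new_spectrum(integer(), unit, locus))
  keys <- if (unit == "allele") {
    as.character(unlist(geno))
  } else {
    map_chr(geno, format_allele_cell)
  }
  new_spectrum(table(keys), unit, locus)
}

#' Haplotype frequency spectrum
#'
#' Haplotype identity is the tuple of sorted allele multisets over the chosen
#' loci. Samples flagged at any selected locus are excluded (complete-case)
#' and their count reported via the `n_excluded` attribute.
#'
#' @param panel an [ystr_panel()].
#' @param loci character vector of locus names; default all panel loci.
#' @return A spectrum tibble (see [allele_spectrum()]) with `unit =
#'   "haplotype"`.
#' @export
haplotype_spectrum <- function(panel, loci = NULL) {
  loci <- loci %||% panel_loci(panel)$locus
  missing <- setdiff(loci, panel_loci(panel)$locus)
  if (length(missing)) {
    abort(paste0("unknown loci: ", paste(missing, collapse = ", ")))
  }
  ids <- complete_case_ids(panel, loci)
  rows <- match(ids, panel$sample_id)
  keys <- vapply(rows, function(r) {
    paste(map_chr(loci, ~ format_allele_cell(panel[[.x]][[r]])), collapse = "|")
  }, character(1))
  sp <- new_spectrum(table(keys), "haplotype")
  attr(sp, "n_excluded") <- nrow(panel) - length(ids)
  sp
}

check_spectrum <- function(spectrum) {
  if (is.numeric(spectrum)) {
    spectrum <- new_spectrum(setNames(spectrum, seq_along(spectrum)), "allele")
  }
  stopifnot(is.data.frame(spectrum), all(c("count", "freq") %in% names(spectrum)))
  spectrum
}

#' Nei gene diversity of a frequency spectrum
#'
#' `GD = (n/(n-1)) (1 - sum Pi^2)`; 0 for a monomorphic spectrum, exactly 1
#' when all n observations are distinct.
#'
#' @param spectrum a spectrum tibble, or a bare vector of counts.
#' @return Gene diversity in `[0, 1]`.
#' @export
gene_diversity <- function(spectrum) {
  spectrum <- check_spectrum(spectrum)
  n <- spectrum_n(spectrum)
  if (n < 2) abort("gene diversity is undefined for n < 2")
  (n / (n - 1)) * (1 - sum(spectrum$freq^2))
}

#' Haplotype diversity, match probability, discrimination capacity
#'
#' `haplotype_diversity()` applies the Nei formula to the haplotype spectrum.
#' `match_probability()` is `HMP = sum(Pi^2)`, the chance two random samples
#' share a haplotype. `discrimination_capacity()` is `DC = k/n`.
#'
#' @param spectrum a haplotype frequency spectrum ([haplotype_spectrum()]),
#'   or a bare vector of counts.
#' @return A scalar statistic.
#' @export
haplotype_diversity <- function(spectrum) gene_diversity(spectrum)

#' @rdname haplotype_diversity
#' @export
match_probability <- function(spectrum) {
  spectrum <- check_spectrum(spectrum)
  sum(spectrum$freq^2)
}

#' @rdname haplotype_diversity
#' @export
discrimination_capacity <- function(spectrum) {
  spectrum <- check_spectrum(spectrum)
  nrow(spectrum) / spectrum_n(spectrum)
}

#' Full forensic summary of a panel
#'
#' Computes, by direct counting: per-locus gene diversity (multi-copy loci on
#' the combination spectrum, matching how published tables report one GD for
#' "DYS385a/b"), haplotype diversity, match probability, discrimination
#' capacity, and allele inventory counts (both pooled-copy alleles and
#' distinct allele combinations).
#'
#' @param panel an [ystr_panel()].
#' @param loci locus subset for the haplotype-level statistics; default all.
#' @return An object of class `ystr_forensic`; see [tidy.ystr_forensic()] and
#'   [glance.ystr_forensic()].
#' @export
forensic_report <- function(panel, loci = NULL) {
  loci <- loci %||% panel_loci(panel)$locus
  spec <- panel_loci(panel)
  per_locus <- map(setNames(spec$locus, spec$locus), function(l) {
    multi <- spec$copy_number[spec$locus == l] > 1L || spec$variable[spec$locus == l]
    list(
      allele = allele_spectrum(panel, l, "allele"),
      combination = allele_spectrum(panel, l, "combination"),
      gd_unit = if (multi) "combination" else "allele"
    )
  })
  locus_tbl <- tibble(
    locus = spec$locus,
    n = unname(map_int(per_locus, ~ spectrum_n(.x$combination))),
    n_alleles = unname(map_int(per_locus, ~ nrow(.x$allele))),
    n_combinations = unname(map_int(per_locus, ~ nrow(.x$combination))),
    gd = unname(map_dbl(per_locus, function(x) {
      sp <- x[[x$gd_unit]]
      if (spectrum_n(sp) < 2) NA_real_ else gene_diversity(sp)
    }))
  )
  hap <- haplotype_spectrum(panel, loci)
  n <- spectrum_n(hap)
  hmp <- match_probability(hap)
  structure(list(
    locus_table = locus_tbl,
    haplotype_spectrum = hap,
    loci_used = loci,
    n = n,
    n_excluded = attr(hap, "n_excluded"),
    k = nrow(hap),
    n_unique = sum(hap$count == 1L),
    hd = if (n >= 2) (n / (n - 1)) * (1 - hmp) else NA_real_,
    hmp = hmp,
    dc = nrow(hap) / n,
    n_alleles_pooled = sum(locus_tbl$n_alleles),
    n_allele_combinations = sum(locus_tbl$n_combinations)
  ), class = "ystr_forensic")
}

#' @export
print.ystr_forensic <- function(x, digits = 4, ...) {
  cat(sprintf("<ystr_forensic> %d samples (%d excluded), %d loci in haplotype\n",
              x$n, x$n_excluded, length(x$loci_used)))
  cat(sprintf("  haplotypes: k = %d distinct, %d unique\n", x$k, x$n_unique))
  cat(sprintf("  HD  = %s\n  HMP = %s\n  DC  = %s\n",
              fmt_num(x$hd, digits), fmt_num(x$hmp, digits), fmt_num(x$dc, digits)))
  cat(sprintf("  per-locus GD range: %s (%s) - %s (%s)\n",
              fmt_num(min(x$locus_table$gd, na.rm = TRUE), digits),
              x$locus_table$locus[which.min(x$locus_table$gd)],
              fmt_num(max(x$locus_table$gd, na.rm = TRUE), digits),
              x$locus_table$locus[which.max(x$locus_table$gd)]))
  invisible(x)
}

#' Tidy a forensic summary
#'
#' `tidy()` returns the per-locus table (locus, n, allele counts, GD);
#' `glance()` the one-row panel-level summary (n, k, unique haplotypes, HD,
#' HMP, DC, allele inventory counts).
#'
#' @param x an `ystr_forensic` object.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.ystr_forensic <- function(x, ...) x$locus_table

#' @rdname tidy.ystr_forensic
#' @export
glance.ystr_forensic <- function(x, ...) {
  tibble(n = x$n, n_excluded = x$n_excluded, k = x$k, n_unique = x$n_unique,
         hd = x$hd, hmp = x$hmp, dc = x$dc,
         n_alleles_pooled = x$n_alleles_pooled,
         n_allele_combinations = x$n_allele_combinations)
}

#' Serialize a forensic summary to JSON
#'
#' @param x an `ystr_forensic` object.
#' @param file output path; when `NULL` the JSON string is returned.
#' @param digits decimals for the serialized statistics (internal values stay
#'   full precision).
#' @return JSON string, invisibly when written to `file`.
#' @export
forensic_json <- function(x, file = NULL, digits = 6) {
  stopifnot(inherits(x, "ystr_forensic"))
  obj <- list(
    n = x$n, n_excluded = x$n_excluded, k = x$k, n_unique = x$n_unique,
    hd = round(x$hd, digits), hmp = round(x$hmp, digits), dc = round(x$dc, digits),
    n_alleles_pooled = x$n_alleles_pooled,
    n_allele_combinations = x$n_allele_combinations,
    loci_used = x$loci_used,
    per_locus = mutate(x$locus_table, gd = round(.data$gd, digits))
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
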