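# Haplotype panel container.
#
# A panel is a tibble subclass ("ystr_panel"): one row per male sample, with
# `sample_id`, `population`, and one list-column per locus holding the sorted
# numeric allele multiset for that sample (NULL where the genotype is
# missing). Microvariant alleles keep their decimal repeat value (17.2).
# Two attributes travel with it:
#   loci  — the locus specification tibble (see locus_spec())
#   flags — tibble (sample_id, locus, flag) of quality flags:
#           "missing" or "copy_number_anomaly"

#' Construct a Y-STR haplotype panel
#'
#' @param samples a data frame with columns `sample_id`, `population`, and one
#'   list-column of numeric allele vectors per locus in `loci`. Allele vectors
#'   are sorted ascending on construction; `NULL` entries mean missing.
#' @param loci locus specification tibble ([locus_spec()]).
#' @param flags optional tibble `(sample_id, locus, flag)`; missing flags are
#'   derived from `NULL` genotype entries automatically.
#' @return A tibble of class `ystr_panel`.
#' @export
ystr_panel <- function(samples, loci, flags = NULL) {
  loci <- validate_locus_spec(loci)
  samples <- as_tibble(samples)
  if (!all(c("sample_id", "population") %in% names(samples))) {
    abort("samples must have sample_id and population columns")
  }
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample IDs")
  missing_cols <- setdiff(loci$locus, names(samples))
  if (length(missing_cols)) {
    abort(paste0("samples lack locus columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  samples <- samples[, c("sample_id", "population", loci$locus)]
  for (l in loci$locus) {
    samples[[l]] <- map(samples[[l]], function(a) {
      if (is.null(a) || !length(a) || all(is.na(a))) NULL else sort(as.numeric(a))
    })
  }
  empty_flags <- tibble(sample_id = character(), locus = character(),
                        flag = character())
  flags <- flags %||% empty_flags
  if (!all(c("sample_id", "locus", "flag") %in% names(flags))) {
    if (nrow(as_tibble(flags)) > 0) abort("flags must have sample_id, locus, flag")
    flags <- empty_flags
  }
  # derive missing flags from NULL genotypes
  for (l in loci$locus) {
    miss <- samples$sample_id[map_lgl(samples[[l]], is.null)]
    miss <- setdiff(miss, flags$sample_id[flags$locus == l])
    if (length(miss)) {
      flags <- bind_rows(flags, tibble(sample_id = miss, locus = l,
                                       flag = "missing"))
    }
  }
  structure(samples,
            class = c("ystr_panel", class(tibble())),
            loci = loci, flags = as_tibble(flags))
}

#' Panel accessors
#'
#' `panel_loci()` returns the locus specification of a panel, `panel_flags()`
#' its per-sample quality flags, and `populations()` the population labels.
#'
#' @param panel an `ystr_panel`.
#' @return A tibble (`panel_loci`, `panel_flags`) or character vector
#'   (`populations`).
#' @export
panel_loci <- function(panel) attr(panel, "loci")

#' @rdname panel_loci
#' @export
panel_flags <- function(panel) attr(panel, "flags")

#' @rdname panel_loci
#' @export
populations <- function(panel) unique(panel$population)

# sample_ids usable at a locus (no flag of any kind)
unflagged_ids <- function(panel, locus) {
  fl <- panel_flags(panel)
  setdiff(panel$sample_id, fl$sample_id[fl$locus == locus])
}

# subset panel rows, keeping attributes
panel_subset <- function(panel, idx) {
  out <- as_tibble(panel)[idx, , drop = FALSE]
  fl <- panel_flags(panel)
  ystr_panel(out, panel_loci(panel),
             flags = fl[fl$sample_id %in% out$sample_id, , drop = FALSE])
}

# rows complete (unflagged) at every locus in `loci_names`
complete_case_ids <- function(panel, loci_names) {
  fl <- panel_flags(panel)
  bad <- unique(fl$sample_id[fl$locus %in% loci_names])
  setdiff(panel$sample_id, bad)
}

#' @export
print.ystr_panel <- function(x, ...) {
  loci <- panel_loci(x)
  cat(sprintf("<ystr_panel> %d samples, %d populations, %d loci (%d multi-copy), %d flags\n",
              nrow(x), length(unique(x$population)), nrow(loci),
              sum(loci$copy_number > 1L), nrow(panel_flags(x))))
  NextMethod()
}

#' Compare two panels for genotype equality
#'
#' Panels are equal when they hold the same samples (in order), the same locus
#' panel, and identical allele multisets at every locus.
#'
#' @param a,b panels.
#' @return `TRUE` or `FALSE`.
#' @export
panel_identical <- function(a, b) {
  if (!identical(dim(a), dim(b))) return(FALSE)
  if (!identical(a$sample_id, b$sample_id)) return(FALSE)
  if (!identical(a$population, b$population)) return(FALSE)
  if (!identical(panel_loci(a)$locus, panel_loci(b)$locus)) return(FALSE)
  for (l in panel_loci(a)$locus) {
    eq <- map2(a[[l]], b[[l]], function(x, y) {
      identical(is.null(x), is.null(y)) &&
        (is.null(x) || (length(x) == length(y) && all(x == y)))
    })
    if (!all(unlist(eq))) return(FALSE)
  }
  TRUE
}
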