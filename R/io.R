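# Table, matrix and tree input/output.

MISSING_MARKERS <- c("", "-", "n", "null", "na")

#' Parse one allele cell of a haplotype table
#'
#' Multi-copy genotypes may separate alleles with "-", "," or "/"
#' (`"13-14"`, `"13,14"`, `"13/14"` are equivalent). Decimal microvariants
#' (`"17.2"`) are preserved exactly. The markers `""`, `"-"`, `"N"`, `"null"`,
#' `"NA"` (case-insensitive) denote a missing genotype. A single-copy locus
#' carrying more than one allele is flagged `copy_number_anomaly`; the alleles
#' are retained so the raw pattern still participates in haplotype identity,
#' but flagged genotypes are excluded from per-locus statistics and Rst.
#'
#' @param cell raw table token (character scalar).
#' @param copy_number expected allele count of the locus.
#' @param variable if `TRUE`, any allele count >= 1 is accepted unflagged.
#' @return `list(alleles = sorted numeric vector or NULL, flag = "ok" |
#'   "missing" | "copy_number_anomaly")`.
#' @examples
#' parse_allele_cell("13-14", copy_number = 2)
#' parse_allele_cell("17.2", copy_number = 1)
#' @export
parse_allele_cell <- function(cell, copy_number = 1L, variable = FALSE) {
  tok <- trimws(as.character(cell %||% ""))
  if (is.na(tok) || tolower(tok) %in% MISSING_MARKERS) {
    return(list(alleles = NULL, flag = "missing"))
  }
  parts <- trimws(strsplit(tok, "[-,/]")[[1]])
  parts <- parts[nzchar(parts)]
  vals <- suppressWarnings(as.numeric(parts))
  if (!length(vals) || anyNA(vals)) {
    abort(sprintf("cannot parse allele cell '%s'", tok), class = "ystr_parse_error")
  }
  if (any(vals <= 0)) {
    abort(sprintf("non-positive allele value in '%s'", tok),
          class = "ystr_parse_error")
  }
  flag <- "ok"
  if (variable) {
    # variable-copy locus: any count >= 1 acceptable
  } else if (length(vals) != copy_number) {
    flag <- "copy_number_anomaly"
  }
  list(alleles = sort(vals), flag = flag)
}

#' Read a haplotype table into a panel
#'
#' Expects a delimited text table (tab or comma; auto-detected) with a header
#' row naming a sample-ID column, an optional population column, and one
#' column per locus. Unknown locus columns are reported and skipped.
#'
#' @param file path to the table, or a literal string containing it.
#' @param loci locus specification tibble; defaults to the columns found,
#'   each treated as single-copy unless its cells carry multiple alleles.
#' @param sample_col,population_col header names; defaults are the first
#'   column and (if present, case-insensitive) a column named "population".
#' @param default_population label used when no population column exists.
#' @return An [ystr_panel()].
#' @export
read_haplotype_table <- function(file, loci = NULL,
                                 sample_col = NULL, population_col = NULL,
                                 default_population = "pop1") {
  raw <- readr::read_delim(
    file,
    delim = detect_delim(file),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (!nrow(raw) || !ncol(raw)) abort("haplotype table is empty or lacks a header")
  nm <- names(raw)
  sample_col <- sample_col %||% nm[1]
  population_col <- population_col %||%
    (if (any(tolower(nm) == "population")) nm[tolower(nm) == "population"][1] else NA)
  locus_cols <- setdiff(nm, c(sample_col, population_col))
  if (is.null(loci)) {
    multi <- map_lgl(locus_cols, ~ any(grepl("[-,/]", raw[[.x]])))
    loci <- locus_spec(locus_cols, copy_number = ifelse(multi, 2L, 1L))
  } else {
    loci <- validate_locus_spec(loci)
    unknown <- setdiff(locus_cols, loci$locus)
    if (length(unknown)) {
      inform(paste0("skipping unknown locus columns: ",
                    paste(unknown, collapse = ", ")))
    }
    absent <- setdiff(loci$locus, locus_cols)
    if (length(absent)) {
      abort(paste0("table lacks locus columns: ", paste(absent, collapse = ", ")))
    }
  }
  ids <- raw[[sample_col]]
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sample IDs: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  out <- tibble(
    sample_id = ids,
    population = if (!is.na(population_col)) raw[[population_col]] else default_population
  )
  flags <- list()
  for (i in seq_len(nrow(loci))) {
    l <- loci$locus[i]
    parsed <- map(seq_along(ids), function(r) {
      tryCatch(
        parse_allele_cell(raw[[l]][r], loci$copy_number[i], loci$variable[i]),
        ystr_parse_error = function(e) {
          abort(sprintf("row %d (sample %s), column %s: %s",
                        r, ids[r], l, conditionMessage(e)))
        }
      )
    })
    out[[l]] <- map(parsed, "alleles")
    fl <- map_chr(parsed, "flag")
    bad <- fl != "ok" & fl != "missing"
    if (any(bad)) {
      flags[[l]] <- tibble(sample_id = ids[bad], locus = l, flag = fl[bad])
    }
  }
  ystr_panel(out, loci, flags = bind_rows(flags))
}

detect_delim <- function(file) {
  first <- if (file.exists(file)) readLines(file, n = 1L) else
    strsplit(file, "\n", fixed = TRUE)[[1]][1]
  if (grepl("\t", first)) "\t" else ","
}

format_allele_cell <- function(alleles, sep = "-") {
  if (is.null(alleles)) return("")
  paste(vapply(alleles, function(a) {
    if (a == round(a)) format(as.integer(a)) else format(a)
  }, character(1)), collapse = sep)
}

#' Write a panel back to a tab-separated haplotype table
#'
#' @param panel an [ystr_panel()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_haplotype_table <- function(panel, file) {
  loci <- panel_loci(panel)
  out <- tibble(sample_id = panel$sample_id, population = panel$population)
  for (l in loci$locus) out[[l]] <- map_chr(panel[[l]], format_allele_cell)
  readr::write_tsv(out, file, progress = FALSE)
  invisible(file)
}

#' Write per-locus allele frequency tables
#'
#' Emits a tab-separated file of allele counts and frequencies per locus
#' (printed at 4 decimals), with one gene-diversity (GD) row per locus —
#' the layout of published forensic frequency tables.
#'
#' @param spectra a named list of allele frequency spectra (see
#'   [allele_spectrum()]), or a single spectrum.
#' @param file output path.
#' @param layout `"long"` (locus, allele, count, frequency rows) or `"wide"`
#'   (alleles as rows, loci as columns of frequencies).
#' @return The formatted tibble, invisibly; written to `file` when given.
#' @export
write_frequency_table <- function(spectra, file = NULL,
                                  layout = c("long", "wide")) {
  layout <- match.arg(layout)
  if (is.data.frame(spectra)) spectra <- list(spectrum = spectra)
  long <- imap(spectra, function(sp, nm) {
    lab <- attr(sp, "locus") %||% nm
    rows <- tibble(locus = lab, allele = as.character(sp$key),
                   count = sp$count,
                   frequency = fmt_num(sp$freq, 4))
    gd <- tryCatch(gene_diversity(sp), error = function(e) NA_real_)
    bind_rows(rows, tibble(locus = lab, allele = "GD", count = NA_integer_,
                           frequency = fmt_num(gd, 4)))
  })
  long <- bind_rows(long)
  out <- if (layout == "long") long else
    tidyr::pivot_wider(select(long, -"count"),
                       names_from = "locus", values_from = "frequency")
  if (!is.null(file)) readr::write_tsv(out, file, na = "", progress = FALSE)
  invisible(out)
}

#' Write / read a square PHYLIP distance matrix
#'
#' First line is the taxon count; each following line is a label and the full
#' row of distances at 4 decimals.
#'
#' @param D a labelled symmetric matrix, or an `ystr_rst_matrix`.
#' @param file output path (or, for `read_phylip`, input path).
#' @param digits decimals to print.
#' @return `write_phylip`: the text, invisibly. `read_phylip`: a labelled
#'   symmetric matrix.
#' @export
write_phylip <- function(D, file = NULL, digits = 4) {
  if (inherits(D, "ystr_rst_matrix")) D <- D$rst
  labels <- rownames(D) %||% paste0("T", seq_len(nrow(D)))
  lines <- c(format(nrow(D)),
             vapply(seq_len(nrow(D)), function(i) {
               paste(c(labels[i], formatC(D[i, ], format = "f", digits = digits)),
                     collapse = " ")
             }, character(1)))
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(file)) writeLines(lines, file)
  invisible(txt)
}

#' @rdname write_phylip
#' @export
read_phylip <- function(file) {
  lines <- if (file.exists(file)) readLines(file) else
    strsplit(file, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  ntax <- as.integer(trimws(lines[1]))
  rows <- strsplit(trimws(lines[1 + seq_len(ntax)]), "[ \t]+")
  labels <- map_chr(rows, 1)
  D <- do.call(rbind, map(rows, ~ as.numeric(.x[-1])))
  dimnames(D) <- list(labels, labels)
  D
}

#' Write / read a tree in Newick format
#'
#' Labels containing spaces or other special characters are single-quoted on
#' writing and unquoted on reading, so `read_newick(write_newick(tree))`
#' preserves labels, topology and branch lengths.
#'
#' @param tree an `ape::phylo` tree.
#' @param file file path; for `write_newick`, `NULL` returns the string.
#' @param text a Newick string (alternative to `file` for `read_newick`).
#' @return `write_newick`: the Newick string (terminated by `;`), invisibly
#'   when written to a file. `read_newick`: an `ape::phylo` tree.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  bad <- grepl("[^A-Za-z0-9_.|-]", labs)
  tree$tip.label[bad] <- sprintf("'%s'", gsub("'", "''", labs[bad]))
  txt <- ape::write.tree(tree)
  # ape replaces spaces by underscores even inside quotes; restore them
  for (i in which(bad)) {
    mangled <- sprintf("'%s'", gsub(" ", "_", gsub("'", "''", labs[i]), fixed = TRUE))
    txt <- sub(mangled, sprintf("'%s'", gsub("'", "''", labs[i])), txt, fixed = TRUE)
  }
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' @rdname write_newick
#' @export
read_newick <- function(file = NULL, text = NULL) {
  tree <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file)
  unquote_tips(tree)
}
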