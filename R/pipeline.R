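# One-command reproduction of the full analysis chain:
# counting -> diversity -> AMOVA Rst -> MDS -> neighbor-joining,
# with an artifact manifest recording inputs, seed and exclusions.

#' Pipeline configuration
#'
#' Exactly one of `input` (a haplotype table path or an [ystr_panel()]) and
#' `sim` (a [sim_config()]) must be supplied.
#'
#' @param input haplotype table path or panel.
#' @param sim a [sim_config()] to simulate the input instead.
#' @param loci locus specification tibble; defaults to the panel's loci (or
#'   auto-detection when reading a table).
#' @param rst_loci locus subset for the Rst stage: `"all"`,
#'   `"yfiler_plus"`, or a character vector of locus names.
#' @param n_perm permutation count for Rst p-values (0 disables).
#' @param seed seed recorded in the manifest and used for simulation and
#'   permutations.
#' @param out_dir output directory (created if needed).
#' @param digits decimals for printed artifacts (internal computation stays
#'   full precision).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, sim = NULL, loci = NULL,
                            rst_loci = "yfiler_plus", n_perm = 0, seed = 1,
                            out_dir = tempfile("ystr_run_"), digits = 4) {
  if (is.null(input) == is.null(sim)) {
    abort("supply exactly one of `input` and `sim`", class = "ystr_config_error")
  }
  structure(list(input = input, sim = sim, loci = loci, rst_loci = rst_loci,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 out_dir = out_dir, digits = digits),
            class = "pipeline_config")
}

resolve_rst_loci <- function(panel, rst_loci) {
  spec <- panel_loci(panel)
  if (identical(rst_loci, "all")) return(spec$locus)
  if (identical(rst_loci, "yfiler_plus")) {
    sel <- intersect(YFILER_PLUS_NAMES, spec$locus)
    if (!length(sel)) sel <- spec$locus
    return(sel)
  }
  unknown <- setdiff(rst_loci, spec$locus)
  if (length(unknown)) {
    abort(paste0("rst_loci not in panel: ", paste(unknown, collapse = ", ")))
  }
  rst_loci
}

pipeline_log <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

#' Run the full Y-STR analysis pipeline
#'
#' Stages, in order: load or simulate the panel; write per-locus frequency
#' tables; write the forensic JSON report; pairwise Rst (PHYLIP matrix);
#' classical MDS coordinates; neighbor-joining Newick tree; manifest. With a
#' single population the Rst/MDS/NJ stages are skipped with a logged notice.
#' Per-stage retained/excluded sample counts go to the log (stderr) and the
#' manifest; artifacts go to files only.
#'
#' @param config a [pipeline_config()].
#' @return The manifest as a tibble (`artifact`, `path`), invisibly, with the
#'   full manifest list in attribute `manifest`. Also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  stage_info <- list()

  panel <- withCallingHandlers({
    if (!is.null(config$sim)) {
      pipeline_log("simulate", sprintf("simulating %d populations (seed %d)",
                                       config$sim$n_pops, config$seed))
      cfg <- config$sim
      cfg$seed <- config$seed
      simulate_panel(cfg)
    } else if (inherits(config$input, "ystr_panel")) {
      config$input
    } else {
      pipeline_log("read", paste("reading", config$input))
      read_haplotype_table(config$input, loci = config$loci)
    }
  }, error = function(e) {
    abort(paste0("input stage failed: ", conditionMessage(e)),
          class = "ystr_stage_error", parent = e)
  })

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
            class = "ystr_stage_error", parent = e)
    })
  }

  spec <- panel_loci(panel)
  input_path <- if (!is.null(config$sim)) {
    p <- file.path(config$out_dir, "simulated_haplotypes.tsv")
    write_haplotype_table(panel, p)
    artifacts$haplotype_table <- p
    p
  } else if (is.character(config$input)) config$input else "<in-memory panel>"

  # frequency tables
  run_stage("freqs", {
    spectra <- map(setNames(spec$locus, spec$locus), function(l) {
      multi <- spec$copy_number[spec$locus == l] > 1L || spec$variable[spec$locus == l]
      allele_spectrum(panel, l, if (multi) "combination" else "allele")
    })
    p <- file.path(config$out_dir, "allele_frequencies.tsv")
    write_frequency_table(spectra, p)
    artifacts$frequency_table <- p
    pipeline_log("freqs", sprintf("%d loci written", length(spectra)))
  })

  # forensic report
  report <- run_stage("forensic", {
    rep <- forensic_report(panel)
    p <- file.path(config$out_dir, "forensic_report.json")
    forensic_json(rep, p)
    artifacts$forensic_report <- p
    stage_info$forensic <- list(n_retained = rep$n, n_excluded = rep$n_excluded)
    pipeline_log("forensic", sprintf("n = %d retained, %d excluded",
                                     rep$n, rep$n_excluded))
    rep
  })

  pops <- unique(panel$population)
  rst_loci <- resolve_rst_loci(panel, config$rst_loci)
  if (length(pops) < 2) {
    pipeline_log("rst", "single population: Rst/MDS/NJ stages skipped")
    stage_info$rst <- list(skipped = TRUE, reason = "single population")
  } else {
    rst <- run_stage("rst", {
      n_cc <- length(complete_case_ids(panel, rst_loci))
      stage_info$rst <- list(n_retained = n_cc,
                             n_excluded = nrow(panel) - n_cc,
                             loci = rst_loci)
      pipeline_log("rst", sprintf("%d loci, %d/%d complete cases",
                                  length(rst_loci), n_cc, nrow(panel)))
      r <- pairwise_rst(panel, loci = rst_loci, n_perm = config$n_perm,
                        seed = config$seed)
      p <- file.path(config$out_dir, "rst_matrix.phylip")
      write_phylip(r, p, digits = config$digits)
      artifacts$rst_matrix <- p
      r
    })
    run_stage("mds", {
      m <- classical_mds(rst$rst, dims = min(2, length(pops) - 1))
      p <- file.path(config$out_dir, "mds_coordinates.tsv")
      coords <- tidy(m)
      coords <- mutate(coords, across(dplyr::starts_with("dim"),
                                      ~ round(.x, config$digits)))
      readr::write_tsv(coords, p, progress = FALSE)
      pe <- file.path(config$out_dir, "mds_eigenvalues.tsv")
      readr::write_tsv(tibble(eigenvalue = round(m$eigenvalues, config$digits + 4)),
                       pe, progress = FALSE)
      artifacts$mds_coordinates <- p
      artifacts$mds_eigenvalues <- pe
      pipeline_log("mds", sprintf("%d dimensions, goodness %.3f", m$dims, m$goodness))
    })
    if (length(pops) >= 3) {
      run_stage("njtree", {
        tree <- neighbor_joining(rst$rst)
        p <- file.path(config$out_dir, "nj_tree.nwk")
        write_newick(tree, p)
        artifacts$nj_tree <- p
        pipeline_log("njtree", sprintf("%d-leaf tree written", length(pops)))
      })
    } else {
      pipeline_log("njtree", "fewer than 3 populations: NJ stage skipped")
      stage_info$njtree <- list(skipped = TRUE, reason = "fewer than 3 populations")
    }
  }

  manifest <- list(
    package = "ystrkit",
    version = as.character(utils::packageVersion("ystrkit")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    input = input_path,
    seed = config$seed,
    n_samples = nrow(panel),
    populations = pops,
    loci = spec$locus,
    rst_locus_subset = rst_loci,
    n_perm = config$n_perm,
    stages = stage_info,
    artifacts = artifacts
  )
  mp <- file.path(config$out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE), mp)
  out <- tibble(artifact = names(artifacts), path = unlist(artifacts))
  attr(out, "manifest") <- manifest
  invisible(out)
}
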