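# Locus panel definitions.
#
# A locus specification is a tibble with one row per locus:
#   locus          character, unique
#   copy_number    expected alleles per male (1 single-copy, 2 for DYS385-like)
#   variable       TRUE for loci whose copy number varies between lineages
#                  (DYF387S1, DYS527, DYF404S1): >= 1 allele accepted unflagged
#   mutation_rate  per-copy per-generation stepwise mutation probability
#                  (used only by the simulator)

GOLDENEYE_36_SINGLE <- c(
  "DYS19", "DYS460", "DYS389I", "DYS389II", "DYS390", "DYS391", "DYS392",
  "DYS393", "DYS437", "DYS438", "DYS439", "DYS448", "YGATAH4", "DYS449",
  "DYS456", "DYS458", "DYS481", "DYS533", "DYS570", "DYS627", "DYS635",
  "DYS576", "DYS388", "DYS549", "DYS444", "DYS643", "DYS447", "DYS557",
  "DYS596", "DYS593", "DYS645", "DYS518"
)
GOLDENEYE_36_MULTI <- c("DYS385", "DYF387S1", "DYS527", "DYF404S1")

# Yfiler-Plus panel content; DYS385 and DYF387S1 are two-copy, so these 25
# names are conventionally counted as "27 Y-STR loci".
YFILER_PLUS_NAMES <- c(
  "DYS19", "DYS385", "DYS389I", "DYS389II", "DYS390", "DYS391", "DYS392",
  "DYS393", "DYS437", "DYS438", "DYS439", "DYS448", "DYS449", "DYS456",
  "DYS458", "DYS460", "DYS481", "DYS518", "DYS533", "DYS570", "DYS576",
  "DYS627", "DYS635", "DYF387S1", "YGATAH4"
)

#' Build a locus specification table
#'
#' @param locus character vector of unique locus names.
#' @param copy_number integer vector (recycled), expected alleles per sample.
#' @param variable logical vector (recycled); `TRUE` marks loci whose copy
#'   number varies between lineages, so any allele count >= 1 is accepted.
#' @param mutation_rate numeric vector (recycled) in `[0, 0.1]`, per-copy
#'   per-generation stepwise mutation probability used by the simulator.
#' @return A tibble with columns `locus`, `copy_number`, `variable`,
#'   `mutation_rate`.
#' @examples
#' locus_spec(c("DYS19", "DYS385"), copy_number = c(1, 2))
#' @export
locus_spec <- function(locus, copy_number = 1L, variable = FALSE,
                       mutation_rate = 0.002) {
  if (anyDuplicated(locus)) {
    abort("locus names must be unique within a panel definition")
  }
  out <- tibble(
    locus = as.character(locus),
    copy_number = as.integer(rep_len(copy_number, length(locus))),
    variable = rep_len(as.logical(variable), length(locus)),
    mutation_rate = rep_len(as.numeric(mutation_rate), length(locus))
  )
  validate_locus_spec(out)
}

validate_locus_spec <- function(spec) {
  stopifnot(is.data.frame(spec),
            all(c("locus", "copy_number") %in% names(spec)))
  spec <- as_tibble(spec)
  if (!"variable" %in% names(spec)) spec$variable <- FALSE
  if (!"mutation_rate" %in% names(spec)) spec$mutation_rate <- 0.002
  if (any(spec$copy_number < 1L)) abort("copy_number must be >= 1")
  if (any(spec$mutation_rate < 0 | spec$mutation_rate > 0.1)) {
    abort("mutation_rate must lie in [0, 0.1]")
  }
  if (anyDuplicated(spec$locus)) abort("duplicate locus names")
  spec
}

#' Standard Y-STR locus panels
#'
#' `ystr_loci("goldeneye_36")` returns the 36-locus panel of the Goldeneye
#' Y-PLUS amplification system (32 single-copy loci plus the multi-copy
#' DYS385, DYF387S1, DYS527 and DYF404S1). `ystr_loci("yfiler_plus_27")`
#' returns the Yfiler-Plus subset (25 locus names; DYS385 and DYF387S1 carry
#' two copies, hence the customary count of 27).
#'
#' @param panel `"goldeneye_36"` or `"yfiler_plus_27"`.
#' @param mutation_rate default simulator mutation rate applied to all loci.
#' @return A locus specification tibble (see [locus_spec()]).
#' @export
ystr_loci <- function(panel = c("goldeneye_36", "yfiler_plus_27"),
                      mutation_rate = 0.002) {
  panel <- match.arg(panel)
  full <- locus_spec(
    c(GOLDENEYE_36_SINGLE, GOLDENEYE_36_MULTI),
    copy_number = c(rep(1L, length(GOLDENEYE_36_SINGLE)),
                    rep(2L, length(GOLDENEYE_36_MULTI))),
    variable = c(rep(FALSE, length(GOLDENEYE_36_SINGLE)),
                 c(FALSE, TRUE, TRUE, TRUE)),
    mutation_rate = mutation_rate
  )
  if (panel == "goldeneye_36") full else filter(full, .data$locus %in% YFILER_PLUS_NAMES)
}

#' Read / write a locus panel configuration (YAML)
#'
#' The YAML file holds a list of loci, each with `name`, `copy_number` and
#' optional `variable` / `mutation_rate` entries.
#'
#' @param path file path.
#' @return `read_locus_config()` returns a locus specification tibble.
#' @export
read_locus_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  entries <- cfg$loci %||% cfg
  locus_spec(
    locus = map_chr(entries, "name"),
    copy_number = map_int(entries, ~ as.integer(.x$copy_number %||% 1L)),
    variable = map_lgl(entries, ~ isTRUE(.x$variable)),
    mutation_rate = map_dbl(entries, ~ as.numeric(.x$mutation_rate %||% 0.002))
  )
}

#' @rdname read_locus_config
#' @param loci a locus specification tibble.
#' @export
write_locus_config <- function(loci, path) {
  loci <- validate_locus_spec(loci)
  entries <- pmap(loci, function(locus, copy_number, variable, mutation_rate) {
    list(name = locus, copy_number = copy_number,
         variable = variable, mutation_rate = mutation_rate)
  })
  yaml::write_yaml(list(loci = entries), path)
  invisible(path)
}
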