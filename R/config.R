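#' Default analysis configuration
#'
#' Returns the nested configuration list driving every stage of the pipeline.
#' Values passed in `...` (or as a nested list via `overrides`) replace the
#' defaults; unknown keys raise an error so typos do not silently revert to
#' defaults.
#'
#' Sections:
#' \describe{
#'   \item{filters}{Site-quality filters applied to the proband's variants
#'     before ROH and IR computation. `min_depth` (reads), `het_af` (closed
#'     allele-fraction band for heterozygous calls; the lower edge removes the
#'     recurrent artifact band at allele fraction ~0.2), `hom_alt_af_min`,
#'     `hom_ref_af_max`, `drop_missing`.}
#'   \item{roh}{Run-of-homozygosity caller: `min_sites` homozygous calls per
#'     segment, `max_het_interruptions` tolerated heterozygous calls inside a
#'     segment, `max_gap` (bp) between consecutive informative sites before a
#'     run is broken, `terminal_margin` (bp) for the terminal/interstitial
#'     annotation, `denominator` ("chromosome" = full build length, "span" =
#'     first-to-last variant), `min_informative` sites per chromosome below
#'     which the ROH tag is uninformative.}
#'   \item{inheritance}{`pseudocount` added to both sides of the inheritance
#'     ratio, `min_informative` exclusively-inherited sites required before an
#'     IR is reported.}
#'   \item{thresholds}{The published tagging cutoffs: ROH low < `roh_low_max`,
#'     mixed `[roh_low_max, roh_high_min]`, high > `roh_high_min`; IR high
#'     when > `ir_duo` (duos) or > `ir_trio` (trios).}
#'   \item{consanguinity}{Flag a sample when at least
#'     `min_affected_chromosomes` autosomes are ROH-tagged mixed/high, or the
#'     genome-wide ROH fraction exceeds `genome_roh_fraction`.}
#'   \item{simulate}{Synthetic-cohort generator defaults, see [sim_config()].}
#'   \item{plot}{Origin-class colors (color-blind safe) and image size.}
#' }
#'
#' @param ... named scalar overrides using `$`-paths, e.g.
#'   `filters.min_depth = 20`.
#' @param overrides optional nested list merged over the defaults.
#' @return nested configuration list.
#' @export
#' @examples
#' cfg <- upd_config(thresholds.ir_trio = 4)
#' cfg$thresholds$ir_trio
upd_config <- function(..., overrides = NULL) {
  cfg <- list(
    filters = list(
      min_depth = 10L,
      het_af = c(0.25, 0.75),
      hom_alt_af_min = 0.85,
      hom_ref_af_max = 0.15,
      drop_missing = TRUE
    ),
    roh = list(
      min_sites = 25L,
      max_het_interruptions = 1L,
      max_gap = 3e6,
      terminal_margin = 2e6,
      denominator = "chromosome",
      min_informative = 10L
    ),
    inheritance = list(
      pseudocount = 1,
      min_informative = 10L
    ),
    thresholds = list(
      roh_low_max = 0.2,
      roh_high_min = 0.7,
      ir_duo = 2,
      ir_trio = 5
    ),
    consanguinity = list(
      min_affected_chromosomes = 3L,
      genome_roh_fraction = 0.05
    ),
    simulate = list(
      n_families = 10L,
      setup_mix = c(single = 0, duo = 0, trio = 1),
      sites_per_chromosome = 1500L,
      af_beta = c(0.3, 0.3),
      af_truncation = c(0.01, 0.99),
      depth_mean = 60,
      error_rate = 0.01,
      artifact_rate = 30L,
      artifact_af_mean = 0.2,
      artifact_af_sd = 0.03,
      seg_upd_fraction = c(0.3, 0.6),
      consanguinity_fraction = 0.125
    ),
    plot = list(
      origin_colors = c(maternal_only = "#D55E00", paternal_only = "#0072B2",
                        biparental = "#009E73", neither = "#999999",
                        unknown = "#777777", not_called = "#CCCCCC"),
      width = 9, height = 5, dpi = 150
    )
  )
  cfg <- merge_config(cfg, overrides)
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stopf("configuration overrides must be named")
    for (key in names(dots)) {
      path <- strsplit(key, ".", fixed = TRUE)[[1]]
      cfg <- set_config_path(cfg, path, dots[[key]])
    }
  }
  cfg
}

merge_config <- function(base, over) {
  if (is.null(over)) return(base)
  if (!is.list(over)) stopf("configuration overrides must be a list")
  for (key in names(over)) {
    if (!key %in% names(base))
      stopf("unknown configuration key: '%s'", key)
    if (is.list(base[[key]]) && is.list(over[[key]])) {
      base[[key]] <- merge_config(base[[key]], over[[key]])
    } else {
      base[[key]] <- over[[key]]
    }
  }
  base
}

set_config_path <- function(cfg, path, value) {
  if (!path[1] %in% names(cfg))
    stopf("unknown configuration key: '%s'", path[1])
  if (length(path) == 1L) {
    cfg[[path[1]]] <- value
  } else {
    cfg[[path[1]]] <- set_config_path(cfg[[path[1]]], path[-1], value)
  }
  cfg
}

#' Read a configuration file
#'
#' Reads threshold/filter overrides from a YAML or JSON file and merges them
#' over [upd_config()] defaults. The file holds only the keys to change.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON (`.json`) file.
#' @return nested configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("configuration file not found: %s", path)
  over <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("the 'yaml' package is required to read YAML configuration")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  upd_config(overrides = over)
}

#' Genome build: autosome lengths and approximate centromeres
#'
#' Chromosome lengths are the denominator of the ROH fraction; centromere
#' intervals (approximate, rounded to 0.1 Mb) only feed the ROH location
#' annotation. GRCh37 and GRCh38 tables ship with the package; a user file
#' with columns `chrom`, `length` (and optionally `centromere_start`,
#' `centromere_end`) overrides them.
#'
#' @param name "GRCh38" (default), "GRCh37", or a path to a TSV file.
#' @return data.table with columns chrom, length, centromere_start,
#'   centromere_end; autosomes 1-22 guaranteed present with positive lengths.
#' @export
genome_build <- function(name = "GRCh38") {
  path <- if (file.exists(name)) name else
    system.file("extdata", paste0("genome_", name, ".tsv"),
                package = "updscreen")
  if (!nzchar(path) || !file.exists(path))
    stopf("unknown genome build '%s' (expected GRCh37, GRCh38 or a TSV path)",
          name)
  gb <- data.table::fread(path, sep = "\t", colClasses = list(
    character = "chrom"))
  gb[, chrom := normalize_chrom(chrom)]
  if (!all(c("chrom", "length") %in% names(gb)))
    stopf("genome build file needs columns 'chrom' and 'length': %s", path)
  if (!"centromere_start" %in% names(gb)) gb[, centromere_start := NA_real_]
  if (!"centromere_end" %in% names(gb)) gb[, centromere_end := NA_real_]
  missing <- setdiff(AUTOSOMES, gb$chrom)
  if (length(missing))
    stopf("genome build is missing autosomes: %s",
          paste(missing, collapse = ", "))
  if (any(gb$length <= 0)) stopf("genome build has non-positive lengths")
  gb[]
}

#' Build a toy genome for tests and examples
#'
#' @param lengths named numeric vector, names are chromosome names.
#' @return data.table in the [genome_build()] schema.
#' @export
toy_genome <- function(lengths) {
  data.table::data.table(chrom = normalize_chrom(names(lengths)),
                         length = as.numeric(lengths),
                         centromere_start = NA_real_,
                         centromere_end = NA_real_)
}
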