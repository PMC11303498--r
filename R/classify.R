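# Cutoff tagging, UPD candidate calls, consanguinity flagging, and the
# batch-filterable cohort table.
#
# Tagging cutoffs (tunable via upd_config()$thresholds, defaults as
# published): ROH fraction < 0.2 "low", 0.2-0.7 (closed band) "high_mixed",
# > 0.7 "high"; inheritance ratio "high" when strictly above 2 in duos or 5
# in trios. Candidate derivation: ROH high -> whole-chromosome isodisomy
# candidate; ROH high_mixed -> segmental isodisomy candidate (or mixed UPD
# when the IR is also high); IR high with low ROH -> heterodisomy candidate.

ROH_TAGS <- c("low", "high_mixed", "high", "uninformative")
IR_TAGS <- c("low", "high", "not_applicable", "uninformative")
UPD_CALLS <- c("none", "iUPD_candidate", "segmental_iUPD_candidate",
               "hUPD_candidate", "mixed_UPD_candidate")

#' Tag one chromosome with the published cutoffs
#'
#' A total, deterministic step function of (roh_fraction, ir, setup). The
#' ROH band `[roh_low_max, roh_high_min]` is closed (a fraction of exactly
#' 0.2 or 0.7 is "high_mixed"); IR thresholds are strict inequalities.
#' Single setups get `ir_tag = "not_applicable"` and can therefore never
#' produce a heterodisomy or mixed-UPD candidate: heterodisomy detection
#' requires at least one sequenced parent. Uninformative metrics (NA ROH
#' fraction or too few sites; NA IR) propagate to uninformative tags.
#'
#' @param metrics one row of [chromosome_metrics()] output (or a list with
#'   `roh_fraction`, `n_sites_used`, `ir`, `ir_direction`).
#' @param setup family setup string.
#' @param thresholds `thresholds` section of [upd_config()].
#' @param min_informative_roh sites needed for an informative ROH tag.
#' @return list: roh_tag, ir_tag, upd_call, upd_parent.
#' @export
tag_chromosome <- function(metrics, setup,
                           thresholds = upd_config()$thresholds,
                           min_informative_roh = upd_config()$roh$min_informative) {
  f <- metrics$roh_fraction
  n <- metrics$n_sites_used %||% Inf
  roh_tag <- if (is.na(f) || n < min_informative_roh) "uninformative"
    else if (f < thresholds$roh_low_max) "low"
    else if (f > thresholds$roh_high_min) "high"
    else "high_mixed"

  ir <- metrics$ir
  ir_cut <- switch(setup, trio = thresholds$ir_trio,
                   duo_mother = thresholds$ir_duo,
                   duo_father = thresholds$ir_duo, NA_real_)
  ir_tag <- if (setup == "single") "not_applicable"
    else if (is.null(ir) || is.na(ir)) "uninformative"
    else if (ir > ir_cut) "high" else "low"

  upd_call <- if (roh_tag == "high") "iUPD_candidate"
    else if (roh_tag == "high_mixed" && ir_tag == "high") "mixed_UPD_candidate"
    else if (roh_tag == "high_mixed") "segmental_iUPD_candidate"
    else if (roh_tag == "low" && ir_tag == "high") "hUPD_candidate"
    else "none"

  dir <- metrics$ir_direction
  upd_parent <- if (upd_call != "none" && ir_tag == "high" &&
                    !is.null(dir) && !is.na(dir) && dir != "none") dir
                else "unknown"
  list(roh_tag = roh_tag, ir_tag = ir_tag, upd_call = upd_call,
       upd_parent = upd_parent)
}

#' Flag suspected consanguinity
#'
#' ROH spread over several chromosomes cannot be told apart from isodisomy
#' chromosome-by-chromosome, so samples with a multi-chromosome ROH pattern
#' are flagged: at least `min_affected_chromosomes` autosomes tagged
#' high/high_mixed, or a genome-wide ROH fraction above
#' `genome_roh_fraction`. The genome-wide burden is summed ROH bp over
#' summed autosome bp *excluding the single largest per-chromosome
#' contributor*: consanguinity spreads identity-by-descent across many
#' chromosomes, whereas a genuine whole-chromosome UPD concentrates it on
#' one, and a UPD on a large chromosome must not flag the sample as
#' consanguineous. The rule is an explicit heuristic; the published screen
#' only states that such samples were excluded. Flagged samples stay in the
#' batch output with the flag set.
#'
#' @param metrics per-chromosome metrics for one sample (with roh_tag).
#' @param build [genome_build()] table.
#' @param cfg `consanguinity` section of [upd_config()].
#' @return list: flag (logical), n_affected, genome_roh_fraction.
#' @export
flag_consanguinity <- function(metrics, build,
                               cfg = upd_config()$consanguinity) {
  n_aff <- sum(metrics$roh_tag %in% c("high_mixed", "high"))
  genome_bp <- sum(build[chrom %in% AUTOSOMES, length])
  bp <- metrics$roh_bp
  drop_top <- if (length(bp)) which.max(bp) else integer(0)
  gw <- sum(bp[-drop_top]) / genome_bp
  list(flag = n_aff >= cfg$min_affected_chromosomes ||
         gw > cfg$genome_roh_fraction,
       n_affected = n_aff, genome_roh_fraction = gw)
}

#' Tag a sample's chromosomes and assemble its report
#'
#' Applies [tag_chromosome()] to every autosome, evaluates the consanguinity
#' flag, and (when flagged) downgrades ROH-driven calls (isodisomy,
#' segmental, mixed) to "none" with `upd_note = "consanguinity_suspected"`;
#' IR-driven heterodisomy candidates are unaffected by genome-wide ROH and
#' are kept.
#'
#' @param metrics [chromosome_metrics()]`$metrics` for one sample.
#' @param ped [pedigree()].
#' @param build [genome_build()] table.
#' @param cfg full [upd_config()].
#' @return list (sample report): sample, family, setup, table (metrics +
#'   tags), consanguinity (list from [flag_consanguinity()]), segments slot
#'   left to the caller.
#' @export
tag_sample <- function(metrics, ped, build, cfg = upd_config()) {
  tab <- data.table::copy(metrics)
  tags <- lapply(seq_len(nrow(tab)), function(i)
    tag_chromosome(tab[i], ped$setup, cfg$thresholds,
                   cfg$roh$min_informative))
  tab[, roh_tag := vapply(tags, `[[`, "", "roh_tag")]
  tab[, ir_tag := vapply(tags, `[[`, "", "ir_tag")]
  tab[, upd_call := vapply(tags, `[[`, "", "upd_call")]
  tab[, upd_parent := vapply(tags, `[[`, "", "upd_parent")]
  tab[, upd_note := ""]
  cons <- flag_consanguinity(tab, build, cfg$consanguinity)
  if (cons$flag) {
    roh_driven <- tab$upd_call %in% c("iUPD_candidate",
                                      "segmental_iUPD_candidate",
                                      "mixed_UPD_candidate")
    tab[roh_driven, `:=`(upd_call = "none",
                         upd_note = "consanguinity_suspected")]
  }
  tab[, consanguinity_flag := cons$flag]
  list(sample = ped$child_id, family = ped$family_id, setup = ped$setup,
       table = tab, consanguinity = cons)
}

#' Build the cohort table
#'
#' Long format, one row per (sample, chromosome), all metrics, tags and
#' calls, ordered by sample then chromosome 1..22 — the list "which can be
#' easily filtered" for candidates. Duplicate (sample, chromosome) rows are
#' an integrity error.
#'
#' @param reports list of sample reports from [tag_sample()].
#' @return data.table; attribute `summary` holds candidate counts per class.
#' @export
build_cohort_table <- function(reports) {
  if (!length(reports)) stopf("no sample reports supplied")
  tab <- data.table::rbindlist(lapply(reports, `[[`, "table"))
  if (anyDuplicated(tab[, .(sample, chrom)]))
    stopf("integrity error: duplicate (sample, chromosome) rows in cohort table")
  tab[, .chr := chrom_order(chrom)]
  data.table::setorder(tab, sample, .chr)
  tab[, .chr := NULL]
  counts <- tab[upd_call != "none", .N, by = upd_call]
  data.table::setattr(tab, "summary", counts)
  tab[]
}

#' Write the cohort table as TSV and JSON
#'
#' @param cohort [build_cohort_table()] output.
#' @param path_tsv,path_json output paths (either may be NULL to skip).
#' @param provenance optional named list written into the JSON envelope and
#'   as `# key: value` comment lines atop the TSV.
#' @export
write_cohort_table <- function(cohort, path_tsv = NULL, path_json = NULL,
                               provenance = NULL) {
  if (!is.null(path_tsv)) {
    con <- file(path_tsv, "w")
    if (!is.null(provenance))
      writeLines(sprintf("# %s: %s", names(provenance),
                         vapply(provenance, as.character, "")), con)
    close(con)
    data.table::fwrite(cohort, path_tsv, sep = "\t", na = "NA",
                       quote = FALSE, append = !is.null(provenance),
                       col.names = TRUE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(list(provenance = provenance, cohort = cohort),
                         path_json, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(cohort)
}

#' Read a cohort table written by [write_cohort_table()]
#' @param path TSV path.
#' @return data.table.
#' @export
read_cohort_table <- function(path) {
  data.table::fread(path, sep = "\t", na.strings = "NA",
                    colClasses = list(character = "chrom"), skip = "sample")
}
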