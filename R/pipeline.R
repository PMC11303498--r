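# End-to-end analysis: sites -> filters -> join -> metrics -> tags.

#' Analyze one family from site tables
#'
#' Applies the site filters to the proband, joins parental carrier status,
#' computes per-chromosome ROH and inheritance metrics, and tags every
#' autosome with the configured cutoffs. Parents are joined unfiltered:
#' carrier status is about whether the caller emitted the variant at all,
#' and filtering parents would inflate apparent non-carriage.
#'
#' @param child,mother,father site tables (parents NULL when absent).
#' @param ped [pedigree()].
#' @param build [genome_build()] table.
#' @param cfg [upd_config()].
#' @return sample report (see [tag_sample()]) with `segments` (ROH table)
#'   and `sites` (the joined, filtered site table) attached.
#' @export
analyze_family <- function(child, mother = NULL, father = NULL,
                           ped = pedigree("child"), build = genome_build(),
                           cfg = upd_config()) {
  filtered <- apply_site_filters(child, cfg$filters)
  joined <- join_family(filtered, mother, father, ped)
  cm <- chromosome_metrics(joined, ped, build, cfg)
  rep <- tag_sample(cm$metrics, ped, build, cfg)
  rep$segments <- cm$segments
  rep$sites <- joined
  rep
}

#' Analyze one family from VCF files
#'
#' @param child_vcf,mother_vcf,father_vcf VCF paths (parents NULL when
#'   absent); sample ids default to the single sample in each file.
#' @param child_id,mother_id,father_id optional sample ids within the VCFs.
#' @inheritParams analyze_family
#' @return sample report.
#' @export
analyze_family_vcf <- function(child_vcf, mother_vcf = NULL,
                               father_vcf = NULL, child_id = NULL,
                               mother_id = NULL, father_id = NULL,
                               family_id = NULL, build = genome_build(),
                               cfg = upd_config()) {
  child <- read_vcf(child_vcf, child_id)
  mother <- if (!is.null(mother_vcf)) read_vcf(mother_vcf, mother_id)
  father <- if (!is.null(father_vcf)) read_vcf(father_vcf, father_id)
  ped <- pedigree(child_id %||% basename_noext(child_vcf),
                  if (!is.null(mother_vcf))
                    mother_id %||% basename_noext(mother_vcf) else NA,
                  if (!is.null(father_vcf))
                    father_id %||% basename_noext(father_vcf) else NA,
                  family_id = family_id %||%
                    (child_id %||% basename_noext(child_vcf)))
  analyze_family(child, mother, father, ped, build, cfg)
}

basename_noext <- function(p) sub("\\.vcf(\\.b?gz)?$", "", basename(p))

#' Batch-screen a cohort from a manifest
#'
#' Reads every family named in the manifest, analyzes it, and assembles the
#' batch-filterable cohort table.
#'
#' @param manifest path to a manifest TSV ([read_manifest()] schema) or an
#'   equivalent data.frame.
#' @param build [genome_build()] table.
#' @param cfg [upd_config()].
#' @param verbose print one line per family.
#' @return list: `cohort` (long table, one row per sample x autosome),
#'   `reports` (per-family sample reports).
#' @export
run_batch <- function(manifest, build = genome_build(), cfg = upd_config(),
                      verbose = FALSE) {
  man <- if (is.character(manifest)) read_manifest(manifest)
         else data.table::as.data.table(manifest)
  if (!nrow(man)) stopf("empty manifest")
  reports <- lapply(split(man, by = "family_id", sorted = TRUE),
                    function(fm) {
    get_path <- function(r) if (any(fm$role == r)) fm[role == r, path] else NULL
    get_id <- function(r) if (any(fm$role == r)) fm[role == r, sample_id]
              else NULL
    if (verbose) message("family ", fm$family_id[1])
    analyze_family_vcf(get_path("child"), get_path("mother"),
                       get_path("father"), get_id("child"), get_id("mother"),
                       get_id("father"), family_id = fm$family_id[1],
                       build = build, cfg = cfg)
  })
  list(cohort = build_cohort_table(reports), reports = reports)
}

#' Analyze an in-memory simulated cohort
#'
#' Runs the same per-family analysis as [run_batch()] directly on
#' [simulate_cohort()] output, skipping VCF round-trips. `drop_parents`
#' re-analyzes every family as a single setup, which is how the
#' parent-dependence of heterodisomy detection is demonstrated.
#'
#' @param cohort [simulate_cohort()] output.
#' @param build,cfg as in [run_batch()].
#' @param drop_parents analyze probands only.
#' @return list: `cohort` table, `reports`.
#' @export
run_batch_cohort <- function(cohort, build = genome_build(),
                             cfg = upd_config(), drop_parents = FALSE) {
  reports <- lapply(cohort$families, function(fam) {
    ped <- fam$ped
    mother <- fam$sites$mother
    father <- fam$sites$father
    if (drop_parents) {
      ped <- pedigree(ped$child_id, family_id = ped$family_id)
      mother <- father <- NULL
    }
    analyze_family(fam$sites$child, mother, father, ped, build, cfg)
  })
  list(cohort = build_cohort_table(reports), reports = reports)
}
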