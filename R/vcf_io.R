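# VCF input, site-quality filtering, and family-wise site joining.
#
# A "site table" throughout the package is a data.table with one row per
# decomposed variant observation:
#   chrom (character, "1".."22","X","Y"), pos (integer, 1-based), ref, alt,
#   gt ("hom_ref"/"het"/"hom_alt"/"missing"), depth (total reads),
#   alt_fraction (alt reads / total reads, NA when depth is 0).
# Multi-allelic records are decomposed into one row per alternate allele; the
# allele fraction keeps the full record depth as denominator so the fractions
# of the decomposed rows sum to at most 1.

SITE_COLS <- c("chrom", "pos", "ref", "alt", "gt", "depth", "alt_fraction")

#' Read one sample's variants from a VCF
#'
#' Reads a VCF v4.x file (plain or bgzip-compressed), extracts `GT` and `AD`
#' for one sample, decomposes multi-allelic records, and normalizes
#' chromosome names ("chr1" and "1" are equivalent). Records with missing GT
#' are retained with `gt = "missing"`; explicit reference calls (GT 0/0) are
#' kept as `hom_ref` but reference calls are never imputed at uncovered
#' positions. Non-canonical contigs are dropped.
#'
#' @param path VCF file.
#' @param sample sample id to extract; default: the only (or first) sample.
#' @return site table (see module header), sorted by (chrom, pos, alt).
#' @export
read_vcf <- function(path, sample = NULL) {
  if (!file.exists(path)) stopf("VCF not found: %s", path)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown")),
    error = function(e) stopf("malformed VCF '%s': %s", path, conditionMessage(e)))
  smp <- colnames(vcf)
  if (is.null(sample)) {
    if (length(smp) > 1L)
      warnf("multi-sample VCF %s: defaulting to first sample '%s'",
            path, smp[1])
    sample <- smp[1]
  }
  if (!sample %in% smp)
    stopf("sample '%s' not found in %s (has: %s)", sample, path,
          paste(smp, collapse = ", "))
  vcf <- vcf[, sample]

  n_alt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
  # total record depth from unexpanded AD (all alleles), before decomposition
  ad_raw <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad_raw)) stopf("VCF %s lacks the AD FORMAT field", path)
  total_ad <- ad_total_per_record(ad_raw, nrow(vcf))

  ve <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(ve)
  gt_str <- as.character(VariantAnnotation::geno(ve)$GT)
  alt_index <- sequence(n_alt)              # which alt of the original record
  sites <- data.table::data.table(
    chrom = normalize_chrom(as.character(GenomicRanges::seqnames(rr))),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = as.character(rr$ALT),
    gt = gt_class(gt_str, alt_index),
    depth = rep(total_ad, n_alt),
    alt_reads = alt_reads_expanded(VariantAnnotation::geno(ve)$AD)
  )
  sites[, alt_fraction := ifelse(depth > 0, alt_reads / depth, NA_real_)]
  sites[, alt_reads := NULL]
  keep <- sites$chrom %in% CANONICAL_CHROMS
  if (any(!keep))
    message(sum(!keep), " records on non-canonical contigs dropped")
  sites <- sites[keep]
  data.table::setorder(sites[, .ord := chrom_order(chrom)], .ord, pos, alt)
  sites[, .ord := NULL]
  sites[]
}

# AD arrives either as a 3d array (uniform allele count) or a list matrix.
ad_total_per_record <- function(ad, n) {
  if (is.list(ad)) {
    vapply(seq_len(n), function(i) {
      v <- ad[[i]]
      if (all(is.na(v))) 0L else as.integer(sum(v, na.rm = TRUE))
    }, integer(1))
  } else {
    tot <- apply(ad, 1, function(v) sum(v, na.rm = TRUE))
    tot[apply(ad, 1, function(v) all(is.na(v)))] <- 0L
    as.integer(tot)
  }
}

# After expand(), AD holds (ref, this_alt) per row; take the alt column.
alt_reads_expanded <- function(ad) {
  if (is.list(ad)) {
    vapply(ad, function(v) {
      if (length(v) < 2L || is.na(v[2])) 0L else as.integer(v[2])
    }, integer(1))
  } else {
    v <- ad[, 1, 2]
    v[is.na(v)] <- 0L
    as.integer(v)
  }
}

# Genotype class of one expanded row relative to its alt allele index.
gt_class <- function(gt_str, alt_index) {
  parts <- strsplit(gt_str, "[/|]")
  vapply(seq_along(parts), function(i) {
    al <- parts[[i]]
    if (!length(al) || any(al == "." | al == ""))
      return("missing")
    al <- suppressWarnings(as.integer(al))
    if (anyNA(al)) return("missing")
    n_this <- sum(al == alt_index[i])
    if (n_this == length(al)) "hom_alt"
    else if (n_this > 0) "het"
    else if (all(al == 0)) "hom_ref"
    else "hom_ref"   # homozygous/heterozygous for *another* alt: this alt absent
  }, character(1))
}

#' Apply site-quality filters
#'
#' Removes low-confidence variant observations before ROH/IR computation:
#' depth below `min_depth`, heterozygous calls outside the allele-fraction
#' band `het_af` (the lower edge removes the recurrent artifact band around
#' allele fraction 0.2 that appears on every chromosome), homozygous-alt
#' calls below `hom_alt_af_min`, reference calls above `hom_ref_af_max`, and
#' (by default) missing genotypes. The number of removed sites per chromosome
#' is reported via `message()` when `verbose`.
#'
#' @param sites site table.
#' @param cfg `filters` section of [upd_config()].
#' @param verbose log removed-site counts per chromosome.
#' @return filtered site table (possibly empty).
#' @export
apply_site_filters <- function(sites, cfg = upd_config()$filters,
                               verbose = FALSE) {
  if (!nrow(sites)) return(sites)
  af <- sites$alt_fraction
  keep <- sites$depth >= cfg$min_depth & !is.na(af)
  keep <- keep & data.table::fcase(
    sites$gt == "het", af >= cfg$het_af[1] & af <= cfg$het_af[2],
    sites$gt == "hom_alt", af >= cfg$hom_alt_af_min,
    sites$gt == "hom_ref", af <= cfg$hom_ref_af_max,
    sites$gt == "missing", !isTRUE(cfg$drop_missing),
    default = FALSE)
  keep[is.na(keep)] <- FALSE
  if (verbose) {
    rem <- sites[!keep, .N, by = chrom]
    if (nrow(rem))
      message(paste0("filtered ", rem$N, " site(s) on chr", rem$chrom,
                     collapse = "; "))
  }
  sites[keep]
}

#' Pedigree for one family
#'
#' The family setup (single / duo / trio) is a pure function of which parent
#' ids are present.
#'
#' @param child_id,mother_id,father_id sample ids; parents may be `NA`.
#' @param family_id optional family label (defaults to the child id).
#' @return list with ids and `setup` in
#'   `c("single", "duo_mother", "duo_father", "trio")`.
#' @export
pedigree <- function(child_id, mother_id = NA, father_id = NA,
                     family_id = child_id) {
  has_m <- !is.na(mother_id) && nzchar(mother_id)
  has_f <- !is.na(father_id) && nzchar(father_id)
  setup <- if (has_m && has_f) "trio" else if (has_m) "duo_mother"
           else if (has_f) "duo_father" else "single"
  list(child_id = child_id,
       mother_id = if (has_m) mother_id else NA_character_,
       father_id = if (has_f) father_id else NA_character_,
       family_id = family_id, setup = setup)
}

#' Join child variants with parental carrier status
#'
#' One row per child site. A parent's status is `"carries"` when the parent's
#' VCF holds a variant call (het or hom_alt) at the same
#' (chrom, pos, ref, alt) after decomposition, `"does_not_carry"` when the
#' parent was sequenced but has no such call (exome VCFs emit variant sites
#' only, so absence is read as non-carriage), and `"unknown"` when that
#' parent was not sequenced. Child sites whose position collides with a
#' parent record carrying a different reference allele are dropped with a
#' warning.
#'
#' @param child site table of the proband (typically after
#'   [apply_site_filters()]).
#' @param mother,father parent site tables (unfiltered; presence of a call is
#'   the signal), or `NULL`.
#' @param ped [pedigree()] of the family.
#' @return site table with `mother_status` and `father_status` columns.
#' @export
join_family <- function(child, mother = NULL, father = NULL,
                        ped = pedigree("child")) {
  tab <- data.table::copy(child)
  has_m <- ped$setup %in% c("duo_mother", "trio")
  has_f <- ped$setup %in% c("duo_father", "trio")
  drop <- rep(FALSE, nrow(tab))
  tab[, mother_status := parent_status(tab, if (has_m) mother else NULL)]
  tab[, father_status := parent_status(tab, if (has_f) father else NULL)]
  if (has_m) drop <- drop | ref_conflict(tab, mother)
  if (has_f) drop <- drop | ref_conflict(tab, father)
  if (any(drop)) {
    warnf("%d child site(s) dropped: reference allele differs from a parent record at the same position",
          sum(drop))
    tab <- tab[!drop]
  }
  tab[]
}

parent_status <- function(child, parent) {
  if (is.null(parent)) return(rep("unknown", nrow(child)))
  carrier <- unique(parent[gt %in% c("het", "hom_alt"),
                           .(chrom, pos, ref, alt)])
  key <- paste(child$chrom, child$pos, child$ref, child$alt)
  pkey <- paste(carrier$chrom, carrier$pos, carrier$ref, carrier$alt)
  ifelse(key %in% pkey, "carries", "does_not_carry")
}

# A child site conflicts when the parent holds records at the same position
# but none with the same reference allele.
ref_conflict <- function(child, parent) {
  if (is.null(parent) || !nrow(parent)) return(rep(FALSE, nrow(child)))
  ppos <- unique(paste(parent$chrom, parent$pos))
  pref <- unique(paste(parent$chrom, parent$pos, parent$ref))
  at_pos <- paste(child$chrom, child$pos) %in% ppos
  same_ref <- paste(child$chrom, child$pos, child$ref) %in% pref
  at_pos & !same_ref
}

#' Read a cohort manifest
#'
#' TSV with columns `sample_id`, `role` (child/mother/father), `family_id`,
#' `path`. Each family must have exactly one child.
#'
#' @param path manifest TSV.
#' @return data.table, one row per individual.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  man <- data.table::fread(path, sep = "\t", colClasses = "character")
  need <- c("sample_id", "role", "family_id", "path")
  if (!all(need %in% names(man)))
    stopf("manifest must have columns: %s", paste(need, collapse = ", "))
  if (!nrow(man)) stopf("manifest is empty: %s", path)
  bad <- setdiff(unique(man$role), c("child", "mother", "father"))
  if (length(bad)) stopf("unknown role(s) in manifest: %s",
                         paste(bad, collapse = ", "))
  n_child <- man[role == "child", .N, by = family_id]
  if (any(n_child$N != 1) || !all(unique(man$family_id) %in% n_child$family_id))
    stopf("every family in the manifest needs exactly one child")
  man
}

#' Write / read the normalized site TSV
#'
#' Plain-TSV serialization of a (joined) site table; reading back reproduces
#' the table exactly.
#'
#' @param sites site table.
#' @param path output TSV.
#' @return `read_site_table` returns the site table.
#' @export
write_site_table <- function(sites, path) {
  data.table::fwrite(sites, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  sites <- data.table::fread(path, sep = "\t", na.strings = "NA",
                             colClasses = list(character = "chrom"))
  sites[, pos := as.integer(pos)]
  sites[, depth := as.integer(depth)]
  sites[, alt_fraction := as.numeric(alt_fraction)]
  sites[]
}
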