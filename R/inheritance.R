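# Parental-origin classification and the per-chromosome inheritance ratio.
#
# The inheritance ratio (IR) is the imbalance between variants attributable
# exclusively to the mother and exclusively to the father. Under biparental
# inheritance it sits near 1; a heterodisomy removes one parent's exclusive
# contribution and drives it up. Thresholds differ by setup (duo > 2,
# trio > 5) because duo attribution pools the missing parent with de novo
# variants and caller artifacts, making the denominator noisier.

#' Classify the parental origin of one child variant
#'
#' Deterministic truth table over the child genotype and the two parental
#' carrier statuses from [join_family()]:
#' \itemize{
#'   \item both parents sequenced: only mother carries -> `maternal_only`;
#'     only father -> `paternal_only`; both -> `biparental`; neither ->
#'     `neither`.
#'   \item one parent sequenced (duo): that parent carries -> attributed to
#'     that parent; otherwise attributed to the missing parent (pooled with
#'     de novo variants -- a duo cannot distinguish them).
#'   \item no parent sequenced: `unknown`.
#' }
#' Child `hom_ref`/`missing` genotypes are not variant observations and
#' return `not_called`; they are excluded from both IR numerator and
#' denominator.
#'
#' @param child_gt,mother_status,father_status character vectors (recycled to
#'   common length): gt class and statuses in
#'   `c("carries", "does_not_carry", "unknown")`.
#' @return character vector of origin calls.
#' @export
classify_origin <- function(child_gt, mother_status, father_status) {
  n <- max(length(child_gt), length(mother_status), length(father_status))
  g <- rep_len(child_gt, n)
  m <- rep_len(mother_status, n)
  f <- rep_len(father_status, n)
  mk <- m != "unknown"
  fk <- f != "unknown"
  mc <- m == "carries"
  fc <- f == "carries"
  out <- data.table::fcase(
    !(g %in% c("het", "hom_alt")), "not_called",
    !mk & !fk, "unknown",
    mk & fk & mc & !fc, "maternal_only",
    mk & fk & !mc & fc, "paternal_only",
    mk & fk & mc & fc, "biparental",
    mk & fk & !mc & !fc, "neither",
    mk & !fk, ifelse(mc, "maternal_only", "paternal_only"),
    !mk & fk, ifelse(fc, "paternal_only", "maternal_only")
  )
  out
}

#' Inheritance ratio
#'
#' Symmetric ratio of the exclusive parental counts,
#' `ir = (max(m, p) + pc) / (min(m, p) + pc)` with pseudocount `pc`
#' (default 1) so a zero denominator stays finite and uniparental patterns
#' of either parent exceed the threshold. Below `min_informative` exclusive
#' sites the ratio is undefined (`NA`) and the chromosome is flagged
#' uninformative rather than "low".
#'
#' @param maternal_only,paternal_only exclusive variant counts (>= 0).
#' @param pseudocount added to numerator and denominator.
#' @param min_informative minimum `maternal_only + paternal_only`.
#' @return list with `ir` (numeric or NA) and `ir_direction`
#'   ("maternal", "paternal", "none", or NA when uninformative).
#' @export
inheritance_ratio <- function(maternal_only, paternal_only, pseudocount = 1,
                              min_informative = 10L) {
  m <- maternal_only; p <- paternal_only
  stopifnot(is_count(m), is_count(p))
  if (m + p < min_informative)
    return(list(ir = NA_real_, ir_direction = NA_character_))
  ir <- (max(m, p) + pseudocount) / (min(m, p) + pseudocount)
  dir <- if (m > p) "maternal" else if (p > m) "paternal" else "none"
  list(ir = ir, ir_direction = dir)
}

#' Relative inheritance ratio
#'
#' Fraction of maternal over maternal + paternal exclusive variants, the
#' quantity shown in allele-fraction plot side panels. 0.5 under biparental
#' inheritance, 1 under maternal heterodisomy, 0 under paternal.
#'
#' @inheritParams inheritance_ratio
#' @return fraction in `[0, 1]`, or `NA` when `m + p = 0`.
#' @export
relative_ir <- function(maternal_only, paternal_only) {
  tot <- maternal_only + paternal_only
  ifelse(tot > 0, maternal_only / tot, NA_real_)
}

#' Per-chromosome metrics for one sample
#'
#' Runs the ROH caller and origin/IR counting on a joined, filtered site
#' table and returns one row per autosome (all 22 autosomes are present even
#' when a chromosome has no surviving sites). X and Y are parsed upstream
#' but excluded here: hemizygosity mimics ROH.
#'
#' @param tab joined site table ([join_family()] output).
#' @param ped [pedigree()] of the family.
#' @param build [genome_build()] table.
#' @param cfg full [upd_config()] list.
#' @return list with `metrics` (data.table, 22 rows) and `segments`
#'   (ROH segment table across autosomes).
#' @export
chromosome_metrics <- function(tab, ped, build, cfg = upd_config()) {
  tab <- tab[chrom %in% AUTOSOMES]
  tab[, origin := classify_origin(gt, mother_status, father_status)]
  seg_list <- list()
  rows <- lapply(AUTOSOMES, function(cc) {
    L <- build[chrom == cc, length]
    if (!length(L)) stopf("chromosome %s missing from genome build", cc)
    sub <- tab[chrom == cc]
    segs <- if (nrow(sub) >= cfg$roh$min_sites)
      call_roh_segments(sub, cfg$roh) else
      call_roh_segments(sub[0], cfg$roh)
    seg_list[[cc]] <<- segs
    denom <- if (identical(cfg$roh$denominator, "span") && nrow(sub) > 1)
      max(sub$pos) - min(sub$pos) + 1 else L
    centro <- unlist(build[chrom == cc,
                           .(centromere_start, centromere_end)])
    m <- sum(sub$origin == "maternal_only")
    p <- sum(sub$origin == "paternal_only")
    irr <- inheritance_ratio(m, p, cfg$inheritance$pseudocount,
                             cfg$inheritance$min_informative)
    data.table::data.table(
      sample = ped$child_id, family = ped$family_id, setup = ped$setup,
      chrom = cc,
      n_sites_used = nrow(sub),
      roh_fraction = roh_fraction(segs, denom),
      roh_bp = if (nrow(segs)) sum(merge_roh_segments(segs)[, end - start + 1])
               else 0,
      roh_location = roh_location_class(segs, L, centro,
                                        cfg$roh$terminal_margin),
      maternal_only = m, paternal_only = p,
      biparental = sum(sub$origin == "biparental"),
      neither = sum(sub$origin == "neither"),
      ir = irr$ir, ir_direction = irr$ir_direction,
      relative_ir = relative_ir(m, p))
  })
  metrics <- data.table::rbindlist(rows)
  segments <- data.table::rbindlist(seg_list)
  list(metrics = metrics, segments = segments)
}
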