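# Synthetic exome-style trio cohorts with ground-truth UPD events.
#
# Haplotype model: two haplotypes per parent per chromosome; the child
# inherits one whole haplotype from each parent (no recombination within a
# chromosome -- enough structure for ROH and IR, full coalescent realism is
# out of scope). Sites are independent given the haplotype assignment, with
# population alternate-allele frequencies drawn from a truncated Beta.
# Event injection:
#   iUPD      - the child receives two copies of ONE randomly chosen
#               haplotype of the designated parent (chromosome-wide
#               homozygosity for that haplotype's alleles);
#   hUPD      - the child receives BOTH haplotypes of the designated parent
#               (child genotype equals that parent's genotype; nothing is
#               transmitted from the other parent);
#   segUPD_iso - the iUPD mechanism restricted to a terminal interval
#               (mitotic recombination after trisomic rescue typically
#               produces terminal segments);
#   consanguinity - IBD segments where the transmitted paternal haplotype is
#               identical by descent to the transmitted maternal one,
#               totalling a configured fraction of the genome and spread
#               over several chromosomes (autozygosity in the child).
# Read noise: depth ~ Poisson(mean); alt reads ~ Binomial(depth, e) with
# e = error_rate, 0.5, 1 - error_rate for hom_ref / het / hom_alt; the
# recorded genotype class is re-derived from the noisy fraction with the
# vcf_io bands. A low-allele-fraction artifact band (af ~ N(0.2, 0.03)) is
# appended on every chromosome of every individual and recorded het,
# emulating the recurrent artifacts seen on all chromosomes in real calls.

#' Simulation configuration
#'
#' Thin wrapper over the `simulate` section of [upd_config()]; any field can
#' be overridden.
#'
#' @param seed integer seed; identical seed + configuration gives
#'   byte-identical cohorts.
#' @param ... overrides of the `simulate` defaults (see [upd_config()]).
#' @return list: the simulate defaults with `seed` attached.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- upd_config()$simulate
  dots <- list(...)
  for (k in names(dots)) {
    if (!k %in% names(cfg)) stopf("unknown simulate option: '%s'", k)
    cfg[[k]] <- dots[[k]]
  }
  cfg$seed <- as.integer(seed)
  cfg
}

#' Plan ground-truth events for a cohort
#'
#' Assigns whole-chromosome isodisomies, heterodisomies, terminal segmental
#' isodisomies and consanguinity to distinct families (one event per
#' family, at most one per (family, chromosome)), with random autosome and
#' random parent of origin. Uses the current RNG stream.
#'
#' @param n_families cohort size.
#' @param n_iupd,n_hupd,n_segupd,n_consanguinity event counts.
#' @param build [genome_build()] table.
#' @param scfg [sim_config()] (segment-length and consanguinity settings).
#' @return truth data.table: family_idx, chrom, event, parent, start, end,
#'   fraction.
#' @export
plan_events <- function(n_families, n_iupd = 0, n_hupd = 0, n_segupd = 0,
                        n_consanguinity = 0, build = genome_build(),
                        scfg = sim_config()) {
  n_ev <- n_iupd + n_hupd + n_segupd + n_consanguinity
  if (n_ev > n_families)
    stopf("more events (%d) than families (%d)", n_ev, n_families)
  fams <- sample.int(n_families, n_ev)
  ev <- rep(c("iUPD", "hUPD", "segUPD_iso", "consanguinity"),
            c(n_iupd, n_hupd, n_segupd, n_consanguinity))
  out <- lapply(seq_len(n_ev), function(i) {
    cc <- sample(AUTOSOMES, 1L)
    L <- build[chrom == cc, length]
    parent <- sample(c("maternal", "paternal"), 1L)
    if (ev[i] == "segUPD_iso") {
      u <- stats::runif(1, scfg$seg_upd_fraction[1], scfg$seg_upd_fraction[2])
      start <- floor(L * (1 - u)) + 1
      end <- L
      fraction <- u
    } else if (ev[i] == "consanguinity") {
      cc <- NA_character_; parent <- NA_character_
      start <- NA_real_; end <- NA_real_
      fraction <- scfg$consanguinity_fraction
    } else {
      start <- 1; end <- L; fraction <- 1
    }
    data.table::data.table(family_idx = fams[i], chrom = cc, event = ev[i],
                           parent = parent, start = start, end = end,
                           fraction = fraction)
  })
  if (!length(out))
    return(data.table::data.table(family_idx = integer(), chrom = character(),
                                  event = character(), parent = character(),
                                  start = numeric(), end = numeric(),
                                  fraction = numeric()))
  data.table::rbindlist(out)
}

# Truncated-normal artifact allele fractions.
rtrunc_norm <- function(n, mean, sd, lo = 0.01, hi = 0.99) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= lo | x >= hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Simulate one family's true genotypes
#'
#' Draws the shared site panel (positions, alleles, population frequencies),
#' parental haplotypes under Hardy-Weinberg, transmits one haplotype per
#' parent per chromosome, and injects the family's events. Uses the current
#' RNG stream; [simulate_cohort()] seeds a deterministic per-family
#' substream.
#'
#' @param events truth rows for this family (possibly empty).
#' @param build [genome_build()] table.
#' @param scfg [sim_config()].
#' @return data.table with one row per panel site: chrom, pos, ref, alt,
#'   af_pop, mother_gt, father_gt, child_gt (0/1/2 alternate-allele counts).
#' @export
simulate_family <- function(events, build = genome_build(),
                            scfg = sim_config()) {
  n <- scfg$sites_per_chromosome
  bad_ev <- events[!is.na(chrom) & !chrom %in% AUTOSOMES]
  if (nrow(bad_ev)) stopf("event chromosome outside autosomes: %s",
                          paste(bad_ev$chrom, collapse = ", "))
  # consanguinity: IBD segments totalling `fraction` of the genome
  consang <- events[event == "consanguinity"]
  ibd <- NULL
  if (nrow(consang)) {
    genome_bp <- sum(build[chrom %in% AUTOSOMES, length])
    target <- consang$fraction[1] * genome_bp
    chrs <- sample(AUTOSOMES)
    acc <- 0; rows <- list()
    for (cc in chrs) {
      if (acc >= target) break
      L <- build[chrom == cc, length]
      u <- stats::runif(1, 0.25, 0.6)
      len <- floor(u * L)
      s <- sample.int(L - len, 1L)
      rows[[cc]] <- data.table::data.table(chrom = cc, start = s,
                                           end = s + len - 1)
      acc <- acc + len
    }
    ibd <- data.table::rbindlist(rows)
  }
  per_chrom <- lapply(AUTOSOMES, function(cc) {
    L <- build[chrom == cc, length]
    pos <- sort(sample.int(L, n))
    p <- stats::rbeta(n, scfg$af_beta[1], scfg$af_beta[2])
    p <- pmin(pmax(p, scfg$af_truncation[1]), scfg$af_truncation[2])
    ra <- t(vapply(seq_len(n), function(i) sample(c("A", "C", "G", "T"), 2L),
                   character(2)))
    mh <- matrix(stats::rbinom(2L * n, 1L, p), ncol = 2)  # mother haplotypes
    fh <- matrix(stats::rbinom(2L * n, 1L, p), ncol = 2)  # father haplotypes
    mi <- sample.int(2L, 1L)   # transmitted maternal haplotype
    fi <- sample.int(2L, 1L)   # transmitted paternal haplotype
    if (!is.null(ibd) && cc %in% ibd$chrom) {
      seg <- ibd[chrom == cc]
      in_seg <- pos >= seg$start & pos <= seg$end
      fh[in_seg, fi] <- mh[in_seg, mi]   # transmitted haplotypes are IBD
    }
    child_m <- mh[, mi]
    child_p <- fh[, fi]
    ev <- events[!is.na(chrom) & chrom == cc]
    if (nrow(ev) > 1L) stopf("more than one event on chr%s in one family", cc)
    if (nrow(ev) == 1L) {
      in_iv <- pos >= ev$start & pos <= ev$end
      if (!any(in_iv))
        stopf("event interval chr%s:%d-%d contains no simulated sites",
              cc, ev$start, ev$end)
      src <- if (ev$parent == "maternal") mh else fh
      if (ev$event %in% c("iUPD", "segUPD_iso")) {
        k <- sample.int(2L, 1L)
        child_m[in_iv] <- src[in_iv, k]
        child_p[in_iv] <- src[in_iv, k]
      } else if (ev$event == "hUPD") {
        child_m[in_iv] <- src[in_iv, 1]
        child_p[in_iv] <- src[in_iv, 2]
      }
    }
    data.table::data.table(chrom = cc, pos = pos, ref = ra[, 1], alt = ra[, 2],
                           af_pop = p,
                           mother_gt = mh[, 1] + mh[, 2],
                           father_gt = fh[, 1] + fh[, 2],
                           child_gt = child_m + child_p)
  })
  data.table::rbindlist(per_chrom)
}

#' Add read-support noise and artifact sites for one individual
#'
#' Only variant genotypes (alt count > 0) are emitted, as in exome VCFs.
#' Depth is Poisson, alt reads Binomial; the recorded genotype class is
#' re-derived from the noisy allele fraction using the vcf_io bands
#' (fraction >= `hom_alt_af_min` records hom_alt, everything else het --
#' which is what pushes true het calls drifting into the artifact band out
#' through the default filters). `artifact_rate` additional het-recorded
#' sites with allele fraction ~ N(`artifact_af_mean`, `artifact_af_sd`)
#' are appended per chromosome.
#'
#' @param truth [simulate_family()] table.
#' @param gt_col which individual: "child_gt", "mother_gt" or "father_gt".
#' @param scfg [sim_config()].
#' @param filters vcf_io band settings used to re-derive genotype classes.
#' @return site table (vcf_io schema) plus logical column `artifact`.
#' @export
add_read_noise <- function(truth, gt_col, scfg = sim_config(),
                           filters = upd_config()$filters) {
  g <- truth[[gt_col]]
  emit <- truth[g > 0]
  g <- g[g > 0]
  nn <- nrow(emit)
  depth <- stats::rpois(nn, scfg$depth_mean)
  e <- c(scfg$error_rate, 0.5, 1 - scfg$error_rate)[g + 1L]
  alt_reads <- stats::rbinom(nn, depth, e)
  af <- ifelse(depth > 0, alt_reads / depth, NA_real_)
  gt <- ifelse(!is.na(af) & af >= filters$hom_alt_af_min, "hom_alt", "het")
  gt[is.na(af)] <- "missing"
  sites <- data.table::data.table(chrom = emit$chrom, pos = emit$pos,
                                  ref = emit$ref, alt = emit$alt, gt = gt,
                                  depth = depth, alt_fraction = af,
                                  artifact = FALSE)
  if (scfg$artifact_rate > 0) {
    arts <- lapply(AUTOSOMES, function(cc) {
      L <- max(truth[chrom == cc, pos])
      k <- scfg$artifact_rate
      apos <- sample.int(L, k)
      ra <- t(vapply(seq_len(k), function(i) sample(c("A", "C", "G", "T"), 2L),
                     character(2)))
      ad <- stats::rpois(k, scfg$depth_mean)
      aaf <- rtrunc_norm(k, scfg$artifact_af_mean, scfg$artifact_af_sd)
      aalt <- round(aaf * ad)
      data.table::data.table(chrom = cc, pos = apos, ref = ra[, 1],
                             alt = ra[, 2], gt = "het", depth = ad,
                             alt_fraction = ifelse(ad > 0, aalt / ad,
                                                   NA_real_),
                             artifact = TRUE)
    })
    sites <- data.table::rbindlist(c(list(sites), arts))
  }
  data.table::setorder(sites[, .ord := chrom_order(chrom)], .ord, pos, alt)
  sites[, .ord := NULL]
  sites[]
}

#' Simulate a whole cohort
#'
#' Seeds a deterministic per-family RNG substream (family output does not
#' depend on cohort ordering), simulates genotypes, injects events, applies
#' read noise per individual, and derives the family setup from the
#' configured mix (deterministically: families are assigned setups in
#' proportion, trios first).
#'
#' @param scfg [sim_config()].
#' @param build [genome_build()] table.
#' @param events truth table from [plan_events()], or NULL for an
#'   event-free cohort.
#' @return list: `families` (per family: `ped`, `sites` list of site tables
#'   keyed child/mother/father, `truth` rows), `truth` (cohort truth table
#'   with family ids), `config`.
#' @export
simulate_cohort <- function(scfg = sim_config(), build = genome_build(),
                            events = NULL) {
  n_fam <- scfg$n_families
  if (is.null(events)) events <- plan_events(0, build = build, scfg = scfg)
  mix <- scfg$setup_mix / sum(scfg$setup_mix)
  n_trio <- round(n_fam * mix[["trio"]])
  n_duo <- round(n_fam * mix[["duo"]])
  setups <- rep(c("trio", "duo_mother", "single"),
                c(n_trio, n_duo, max(0, n_fam - n_trio - n_duo)))[seq_len(n_fam)]
  fam_ids <- sprintf("F%04d", seq_len(n_fam))
  families <- lapply(seq_len(n_fam), function(i) {
    set.seed(derive_seed(scfg$seed, i))
    fid <- fam_ids[i]
    ev <- events[family_idx == i]
    truth <- simulate_family(ev, build, scfg)
    setup <- setups[i]
    ped <- pedigree(
      child_id = paste0(fid, "_c"),
      mother_id = if (setup %in% c("trio", "duo_mother"))
        paste0(fid, "_m") else NA,
      father_id = if (setup == "trio") paste0(fid, "_f") else NA,
      family_id = fid)
    sites <- list(child = add_read_noise(truth, "child_gt", scfg))
    if (!is.na(ped$mother_id))
      sites$mother <- add_read_noise(truth, "mother_gt", scfg)
    if (!is.na(ped$father_id))
      sites$father <- add_read_noise(truth, "father_gt", scfg)
    list(ped = ped, sites = sites, truth = ev, genotypes = truth)
  })
  truth <- data.table::copy(events)
  truth[, family := fam_ids[family_idx]]
  list(families = families, truth = truth[], config = scfg)
}

#' Write a simulated cohort to disk
#'
#' One VCF v4.2 per individual (GT and AD FORMAT fields), a manifest TSV in
#' the schema [read_manifest()] consumes, and a ground-truth TSV.
#'
#' @param cohort [simulate_cohort()] output.
#' @param dir output directory (created if needed).
#' @param build [genome_build()] table (contig headers).
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir, build = genome_build()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- list()
  for (fam in cohort$families) {
    ped <- fam$ped
    roles <- c(child = ped$child_id, mother = ped$mother_id,
               father = ped$father_id)
    for (role in names(fam$sites)) {
      sid <- roles[[role]]
      path <- file.path(dir, paste0(sid, ".vcf"))
      write_sites_vcf(fam$sites[[role]], sid, path, build)
      man[[length(man) + 1L]] <- data.table::data.table(
        sample_id = sid, role = role, family_id = ped$family_id, path = path)
    }
  }
  manifest <- data.table::rbindlist(man)
  man_path <- file.path(dir, "manifest.tsv")
  data.table::fwrite(manifest, man_path, sep = "\t", quote = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  data.table::fwrite(cohort$truth, truth_path, sep = "\t", quote = FALSE,
                     na = "NA")
  invisible(man_path)
}

# Minimal, deterministic VCF v4.2 writer for simulated sites.
write_sites_vcf <- function(sites, sample_id, path, build) {
  gt_str <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
              missing = "./.")[sites$gt]
  alt_reads <- ifelse(is.na(sites$alt_fraction), 0L,
                      as.integer(round(sites$alt_fraction * sites$depth)))
  ref_reads <- sites$depth - alt_reads
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=updscreen-simulator",
    sprintf("##contig=<ID=%s,length=%d>", build$chrom,
            as.integer(build$length)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_id))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:AD\t%s:%d,%d",
                  sites$chrom, sites$pos, sites$ref, sites$alt, gt_str,
                  ref_reads, alt_reads)
  writeLines(c(header, body), path)
  invisible(path)
}
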