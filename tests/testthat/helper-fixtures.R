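# Fixtures and independent oracles, built in code at test time.

# Hand-written VCF text (independent of the package's own VCF writer).
write_toy_vcf <- function(lines, path = tempfile(fileext = ".vcf"),
                          sample_id = "S1", contigs = c("1", "2", "3")) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=100000000>", contigs),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_id))
  writeLines(c(header, lines), path)
  path
}

vcf_line <- function(chrom, pos, ref, alt, gt, ad) {
  sprintf("%s\t%d\t.\t%s\t%s\t50\tPASS\t.\tGT:AD\t%s:%s",
          chrom, pos, ref, alt, gt, paste(ad, collapse = ","))
}

# Quick site-table builder for unit tests.
make_sites <- function(chrom, pos, gt, ref = "A", alt = "G",
                       depth = 30L, alt_fraction = NULL) {
  n <- length(pos)
  if (is.null(alt_fraction))
    alt_fraction <- ifelse(gt == "hom_alt", 1,
                           ifelse(gt == "het", 0.5, 0))
  data.table::data.table(chrom = rep_len(chrom, n), pos = as.integer(pos),
                         ref = rep_len(ref, n), alt = rep_len(alt, n),
                         gt = rep_len(gt, n), depth = rep_len(depth, n),
                         alt_fraction = rep_len(alt_fraction, n))
}

# --- Independent oracles -------------------------------------------------

# Site-by-site greedy ROH scanner: explicit state machine, deliberately a
# different code structure from the package's per-run scanner.
roh_oracle <- function(pos, is_hom, min_sites, max_het, max_gap) {
  segs <- list()
  first_hom <- NA_integer_; last_hom <- NA_integer_
  n_hom <- 0L; hets_used <- 0L; n_het_inside <- 0L; pending_het <- 0L
  close_run <- function() {
    if (!is.na(first_hom) && n_hom >= min_sites)
      segs[[length(segs) + 1L]] <<- data.frame(
        start = pos[first_hom], end = pos[last_hom], n_sites = n_hom,
        n_het_interruptions = n_het_inside)
    first_hom <<- NA_integer_; last_hom <<- NA_integer_
    n_hom <<- 0L; hets_used <<- 0L; n_het_inside <<- 0L; pending_het <<- 0L
  }
  for (i in seq_along(pos)) {
    if (i > 1L && pos[i] - pos[i - 1L] > max_gap) close_run()
    if (is_hom[i]) {
      if (is.na(first_hom)) first_hom <- i
      n_hom <- n_hom + 1L
      n_het_inside <- n_het_inside + pending_het
      pending_het <- 0L
      last_hom <- i
    } else if (!is.na(first_hom)) {
      if (hets_used < max_het) {
        hets_used <- hets_used + 1L
        pending_het <- pending_het + 1L
      } else {
        close_run()
      }
    }
  }
  close_run()
  if (!length(segs))
    return(data.frame(start = integer(), end = integer(),
                      n_sites = integer(), n_het_interruptions = integer()))
  do.call(rbind, segs)
}

# Per-base boolean-union coverage oracle for the ROH fraction.
coverage_oracle <- function(starts, ends, chrom_length) {
  covered <- logical(chrom_length)
  for (i in seq_along(starts)) covered[starts[i]:ends[i]] <- TRUE
  sum(covered) / chrom_length
}

# Quadratic nested-loop join oracle for parental carrier status.
join_oracle <- function(child, parent) {
  status <- character(nrow(child))
  for (i in seq_len(nrow(child))) {
    found <- FALSE
    for (j in seq_len(nrow(parent))) {
      if (child$chrom[i] == parent$chrom[j] &&
          child$pos[i] == parent$pos[j] &&
          child$ref[i] == parent$ref[j] &&
          child$alt[i] == parent$alt[j] &&
          parent$gt[j] %in% c("het", "hom_alt")) {
        found <- TRUE
        break
      }
    }
    status[i] <- if (found) "carries" else "does_not_carry"
  }
  status
}

# Tiny toy genome used across tests.
toy_build <- function(L = 1e8) {
  lens <- stats::setNames(rep(L, 22), as.character(1:22))
  updscreen::toy_genome(lens)
}

# Small simulated cohort shared by several test files (computed once).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      build <- updscreen::genome_build("GRCh38")
      scfg <- updscreen::sim_config(seed = 421, n_families = 6,
                                    sites_per_chromosome = 600)
      set.seed(99)
      ev <- updscreen::plan_events(6, n_iupd = 1, n_hupd = 1, n_segupd = 1,
                                   n_consanguinity = 1, build = build,
                                   scfg = scfg)
      cache <<- list(cohort = updscreen::simulate_cohort(scfg, build, ev),
                     events = ev, build = build, scfg = scfg)
    }
    cache
  }
})
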