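# Cutoff tagging, consanguinity flag, cohort table.

mk_metrics <- function(roh_fraction, ir = NA_real_,
                       ir_direction = NA_character_, n = 500L) {
  list(roh_fraction = roh_fraction, n_sites_used = n, ir = ir,
       ir_direction = ir_direction)
}

test_that("tags honor the published cutoffs, including boundary closure", {
  th <- upd_config()$thresholds
  eps <- 1e-9
  # ROH band edges: 0.2 and 0.7 belong to the closed high_mixed band
  expect_equal(tag_chromosome(mk_metrics(0.2 - eps), "single", th)$roh_tag,
               "low")
  expect_equal(tag_chromosome(mk_metrics(0.2), "single", th)$roh_tag,
               "high_mixed")
  expect_equal(tag_chromosome(mk_metrics(0.7), "single", th)$roh_tag,
               "high_mixed")
  expect_equal(tag_chromosome(mk_metrics(0.7 + eps), "single", th)$roh_tag,
               "high")
  # IR thresholds are strict inequalities, setup-specific
  expect_equal(tag_chromosome(mk_metrics(0.05, ir = 5, ir_direction = "maternal"),
                              "trio", th)$ir_tag, "low")
  expect_equal(tag_chromosome(mk_metrics(0.05, ir = 5 + eps,
                                         ir_direction = "maternal"),
                              "trio", th)$ir_tag, "high")
  expect_equal(tag_chromosome(mk_metrics(0.05, ir = 2 + eps,
                                         ir_direction = "paternal"),
                              "duo_mother", th)$ir_tag, "high")
  expect_equal(tag_chromosome(mk_metrics(0.05, ir = 2,
                                         ir_direction = "paternal"),
                              "duo_father", th)$ir_tag, "low")
})

test_that("candidate calls derive from the tag combination", {
  th <- upd_config()$thresholds
  t1 <- tag_chromosome(mk_metrics(0.8), "single", th)
  expect_equal(t1$roh_tag, "high")
  expect_equal(t1$upd_call, "iUPD_candidate")
  t2 <- tag_chromosome(mk_metrics(0.5), "single", th)
  expect_equal(t2$upd_call, "segmental_iUPD_candidate")
  t3 <- tag_chromosome(mk_metrics(0.05, ir = 6.2, ir_direction = "maternal"),
                       "trio", th)
  expect_equal(t3$upd_call, "hUPD_candidate")
  expect_equal(t3$upd_parent, "maternal")
  t4 <- tag_chromosome(mk_metrics(0.5, ir = 8, ir_direction = "paternal"),
                       "trio", th)
  expect_equal(t4$upd_call, "mixed_UPD_candidate")
  expect_equal(t4$upd_parent, "paternal")
  # roh high dominates: still an iUPD candidate when IR is also high
  t5 <- tag_chromosome(mk_metrics(0.9, ir = 50, ir_direction = "maternal"),
                       "trio", th)
  expect_equal(t5$upd_call, "iUPD_candidate")
  expect_equal(t5$upd_parent, "maternal")
})

test_that("uninformative metrics propagate; singles never get IR calls", {
  th <- upd_config()$thresholds
  tu <- tag_chromosome(mk_metrics(NA_real_, n = 3L), "trio", th)
  expect_equal(tu$roh_tag, "uninformative")
  expect_equal(tu$upd_call, "none")
  expect_equal(tag_chromosome(mk_metrics(0.05, ir = NA_real_), "trio",
                              th)$ir_tag, "uninformative")
  # single setup: ir_tag always not_applicable, no hUPD/mixed possible
  for (f in c(0.05, 0.5, 0.9)) {
    ts <- tag_chromosome(mk_metrics(f, ir = 100, ir_direction = "maternal"),
                         "single", th)
    expect_equal(ts$ir_tag, "not_applicable")
    expect_false(ts$upd_call %in% c("hUPD_candidate", "mixed_UPD_candidate"))
  }
})

test_that("tag transitions sit exactly at the configured thresholds", {
  th <- upd_config()$thresholds
  # sweep ROH over [0,1] and IR over [0,10] in 0.001 steps; transitions of
  # the step function must land on the printed cutoffs
  fr <- (0:1000) / 1000   # exact division; seq() accumulates float error
  roh_tags <- vapply(fr, function(f)
    tag_chromosome(mk_metrics(f), "single", th)$roh_tag, character(1))
  sw <- which(roh_tags[-1] != roh_tags[-length(roh_tags)])
  expect_equal(fr[sw + 1], c(0.2, 0.701))
  expect_equal(roh_tags[which.min(abs(fr - 0.2))], "high_mixed")
  expect_equal(roh_tags[which.min(abs(fr - 0.7))], "high_mixed")
  irs <- (0:10000) / 1000
  for (setup in c("duo_mother", "trio")) {
    cut <- if (setup == "trio") th$ir_trio else th$ir_duo
    tags <- vapply(irs, function(i)
      tag_chromosome(mk_metrics(0.05, ir = i, ir_direction = "maternal"),
                     setup, th)$ir_tag, character(1))
    sw <- which(tags[-1] != tags[-length(tags)])
    expect_equal(irs[sw + 1], cut + 0.001)   # strict: first "high" above cut
    expect_equal(tags[which.min(abs(irs - cut))], "low")
  }
})

test_that("consanguinity rule: affected-chromosome count and genome burden", {
  build <- genome_build("GRCh38")
  base <- data.table::data.table(chrom = as.character(1:22),
                                 roh_tag = "low", roh_bp = 0)
  cfg <- upd_config()$consanguinity
  # exactly one chromosome high, rest low -> not flagged (single-UPD pattern)
  m1 <- data.table::copy(base)
  m1[chrom == "1", `:=`(roh_tag = "high",
                        roh_bp = build[chrom == "1", length])]
  expect_false(flag_consanguinity(m1, build, cfg)$flag)
  # six chromosomes high_mixed -> flagged
  m2 <- data.table::copy(base)
  m2[chrom %in% as.character(1:6),
     `:=`(roh_tag = "high_mixed", roh_bp = 4e7)]
  f2 <- flag_consanguinity(m2, build, cfg)
  expect_true(f2$flag)
  expect_equal(f2$n_affected, 6L)
  # zero ROH anywhere -> not flagged
  expect_false(flag_consanguinity(base, build, cfg)$flag)
  # diffuse sub-tag burden above the genome-wide fraction still flags
  m3 <- data.table::copy(base)
  m3[, roh_bp := 0.055 * build[chrom %in% as.character(1:22),
                               sum(length)] / 21]  # top chromosome excluded
  expect_true(flag_consanguinity(m3, build, cfg)$flag)
})

test_that("consanguinity downgrades ROH-driven calls but keeps hUPD", {
  build <- genome_build("GRCh38")
  cfg <- upd_config()
  ped <- pedigree("c", "m", "f")
  metrics <- data.table::data.table(
    sample = "c", family = "F", setup = "trio",
    chrom = as.character(1:22), n_sites_used = 500L,
    roh_fraction = c(rep(0.5, 4), rep(0.01, 18)),
    roh_bp = c(rep(6e7, 4), rep(0, 18)),
    roh_location = "interstitial",
    maternal_only = 100L, paternal_only = 100L, biparental = 50L,
    neither = 5L, ir = c(rep(1, 21), 9), ir_direction = "none",
    relative_ir = 0.5)
  metrics[chrom == "22", ir_direction := "paternal"]
  rep <- tag_sample(metrics, ped, build, cfg)
  expect_true(rep$consanguinity$flag)
  expect_equal(rep$consanguinity$n_affected, 4L)
  seg_rows <- rep$table[chrom %in% as.character(1:4)]
  expect_true(all(seg_rows$upd_call == "none"))
  expect_true(all(seg_rows$upd_note == "consanguinity_suspected"))
  # the IR-driven heterodisomy candidate survives the flag
  expect_equal(rep$table[chrom == "22", upd_call], "hUPD_candidate")
})

test_that("cohort table is long, ordered, duplicate-checked", {
  build <- toy_build()
  cfg <- upd_config()
  mk_rep <- function(id) {
    metrics <- data.table::data.table(
      sample = id, family = id, setup = "single",
      chrom = as.character(1:22), n_sites_used = 100L, roh_fraction = 0.01,
      roh_bp = 0, roh_location = "none", maternal_only = 0L,
      paternal_only = 0L, biparental = 0L, neither = 0L, ir = NA_real_,
      ir_direction = NA_character_, relative_ir = NA_real_)
    tag_sample(metrics, pedigree(id), build, cfg)
  }
  tab <- build_cohort_table(list(mk_rep("s1"), mk_rep("s2")))
  expect_equal(nrow(tab), 44L)
  expect_equal(tab$chrom[1:22], as.character(1:22))   # stable ordering
  expect_error(build_cohort_table(list()), "no sample reports")
  expect_error(build_cohort_table(list(mk_rep("s1"), mk_rep("s1"))),
               "integrity error")
})

test_that("cohort tables round-trip through TSV with provenance", {
  build <- toy_build()
  metrics <- data.table::data.table(
    sample = "s1", family = "s1", setup = "single",
    chrom = as.character(1:22), n_sites_used = 100L, roh_fraction = 0.01,
    roh_bp = 0, roh_location = "none", maternal_only = 0L,
    paternal_only = 0L, biparental = 0L, neither = 0L, ir = NA_real_,
    ir_direction = NA_character_, relative_ir = NA_real_)
  tab <- build_cohort_table(list(tag_sample(metrics, pedigree("s1"), build,
                                            upd_config())))
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_cohort_table(tab, tsv, js, provenance = list(seed = 1, tool = "t"))
  back <- read_cohort_table(tsv)
  expect_equal(back$roh_fraction, tab$roh_fraction)
  expect_equal(back$upd_call, tab$upd_call)
  expect_true(jsonlite::validate(paste(readLines(js), collapse = "")))
})
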