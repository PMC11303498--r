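# Synthetic cohorts: Mendelian transmission, event injection, noise model,
# VCF round trips, determinism.

test_that("event-free transmission is Mendelian consistent", {
  build <- toy_build(5e7)
  scfg <- sim_config(seed = 3, sites_per_chromosome = 300)
  set.seed(1)
  truth <- simulate_family(plan_events(0, build = build, scfg = scfg),
                           build, scfg)
  expect_equal(nrow(truth), 22L * 300L)
  # no de novo variants in the generator: a child alt allele implies a
  # parent carries it
  bad <- truth[child_gt > 0 & mother_gt == 0 & father_gt == 0]
  expect_equal(nrow(bad), 0L)
  # hom child requires alt available from both parents
  bad2 <- truth[child_gt == 2 & (mother_gt == 0 | father_gt == 0)]
  expect_equal(nrow(bad2), 0L)
})

test_that("iUPD injection makes the interval homozygous for a parental allele", {
  build <- toy_build(5e7)
  scfg <- sim_config(seed = 3, sites_per_chromosome = 300)
  ev <- data.table::data.table(family_idx = 1L, chrom = "7", event = "iUPD",
                               parent = "maternal", start = 1,
                               end = 5e7, fraction = 1)
  set.seed(2)
  truth <- simulate_family(ev, build, scfg)
  sub <- truth[chrom == "7"]
  expect_true(all(sub$child_gt %in% c(0L, 2L)))   # homozygous throughout
  # every child alt allele is carried by the mother
  expect_true(all(sub[child_gt == 2, mother_gt] > 0))
})

test_that("hUPD injection copies the designated parent's genotypes", {
  build <- toy_build(5e7)
  scfg <- sim_config(seed = 3, sites_per_chromosome = 300)
  ev <- data.table::data.table(family_idx = 1L, chrom = "4", event = "hUPD",
                               parent = "maternal", start = 1, end = 5e7,
                               fraction = 1)
  set.seed(2)
  truth <- simulate_family(ev, build, scfg)
  sub <- truth[chrom == "4"]
  expect_equal(sub$child_gt, sub$mother_gt)
  # noise-free origin counting: paternal-exclusive variants vanish
  ped <- pedigree("c", "m", "f")
  child <- sub[child_gt > 0,
               .(chrom, pos, ref, alt,
                 gt = c("het", "hom_alt")[child_gt], depth = 100L,
                 alt_fraction = child_gt / 2)]
  mo <- sub[mother_gt > 0, .(chrom, pos, ref, alt,
                             gt = c("het", "hom_alt")[mother_gt],
                             depth = 100L, alt_fraction = mother_gt / 2)]
  fa <- sub[father_gt > 0, .(chrom, pos, ref, alt,
                             gt = c("het", "hom_alt")[father_gt],
                             depth = 100L, alt_fraction = father_gt / 2)]
  joined <- join_family(child, mo, fa, ped)
  origin <- classify_origin(joined$gt, joined$mother_status,
                            joined$father_status)
  expect_equal(sum(origin == "paternal_only"), 0L)
  expect_gt(sum(origin == "maternal_only"), 10L)
})

test_that("an event interval with no simulated sites is a configuration error", {
  build <- toy_build(5e7)
  scfg <- sim_config(seed = 3, sites_per_chromosome = 10)
  ev <- data.table::data.table(family_idx = 1L, chrom = "4", event = "iUPD",
                               parent = "maternal", start = 2, end = 3,
                               fraction = 0)
  set.seed(2)
  expect_error(simulate_family(ev, build, scfg), "no simulated sites")
})

test_that("read noise recovers genotype classes at high depth and plants artifacts", {
  build <- toy_build(5e7)
  scfg <- sim_config(seed = 3, sites_per_chromosome = 200, depth_mean = 5000,
                     error_rate = 0, artifact_rate = 0)
  set.seed(4)
  truth <- simulate_family(plan_events(0, build = build, scfg = scfg),
                           build, scfg)
  sites <- add_read_noise(truth, "child_gt", scfg)
  # error-free, deep: fractions concentrate at 0.5 and 1
  expect_true(all(sites[gt == "hom_alt", alt_fraction] == 1))
  expect_true(all(abs(sites[gt == "het", alt_fraction] - 0.5) < 0.05))
  # every emitted site is a true variant
  key <- paste(truth[child_gt > 0, chrom], truth[child_gt > 0, pos])
  expect_true(all(paste(sites$chrom, sites$pos) %in% key))
  # artifacts: exactly artifact_rate per chromosome, recorded het, af ~ 0.2
  scfg2 <- sim_config(seed = 3, sites_per_chromosome = 200,
                      artifact_rate = 30)
  set.seed(4)
  sites2 <- add_read_noise(truth, "child_gt", scfg2)
  arts <- sites2[artifact == TRUE]
  expect_equal(arts[, .N, by = chrom][, unique(N)], 30L)
  expect_true(all(arts$gt == "het"))
  expect_lt(abs(mean(arts$alt_fraction) - 0.2), 0.02)
})

test_that("default filters remove nearly all artifact sites", {
  build <- toy_build(5e7)
  scfg <- sim_config(seed = 5, sites_per_chromosome = 100, artifact_rate = 30)
  cfg <- upd_config()
  removed <- replicate(20, {
    truth <- simulate_family(plan_events(0, build = build, scfg = scfg),
                             build, scfg)
    sites <- add_read_noise(truth, "child_gt", scfg)
    kept <- apply_site_filters(sites, cfg$filters)
    1 - sum(kept$artifact) / sum(sites$artifact)
  })
  expect_gt(mean(removed), 0.9)
})

test_that("simulated cohorts are deterministic and order-independent", {
  build <- toy_build(2e7)
  scfg <- sim_config(seed = 17, n_families = 3, sites_per_chromosome = 80)
  set.seed(1); ev <- plan_events(3, n_iupd = 1, build = build, scfg = scfg)
  c1 <- simulate_cohort(scfg, build, ev)
  c2 <- simulate_cohort(scfg, build, ev)
  expect_identical(c1$families[[2]]$sites, c2$families[[2]]$sites)
  # per-family substreams: family 3 identical even if cohort is regenerated
  # with a different family count
  scfg2 <- sim_config(seed = 17, n_families = 2, sites_per_chromosome = 80)
  c3 <- simulate_cohort(scfg2, build, ev[family_idx <= 2])
  expect_identical(c1$families[[1]]$sites, c3$families[[1]]$sites)
})

test_that("write_cohort emits VCFs that round-trip through read_vcf", {
  build <- toy_build(2e7)
  scfg <- sim_config(seed = 23, n_families = 1, sites_per_chromosome = 60,
                     artifact_rate = 2)
  cohort <- simulate_cohort(scfg, build, NULL)
  dir <- file.path(tempdir(), "simrt")
  write_cohort(cohort, dir, build)
  man <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(nrow(man), 3L)   # one trio
  expect_setequal(man$role, c("child", "mother", "father"))
  child_path <- man[role == "child", path]
  back <- read_vcf(child_path)
  orig <- cohort$families[[1]]$sites$child
  expect_equal(nrow(back), nrow(orig))
  expect_equal(back$pos, orig$pos)
  expect_equal(back$gt, orig$gt)
  expect_equal(back$depth, orig$depth)
  # allele fractions survive the integer AD encoding to 1/depth precision
  expect_true(all(abs(back$alt_fraction - orig$alt_fraction) <=
                    1 / pmax(orig$depth, 1) + 1e-12))
  # byte-identical re-simulation
  dir2 <- file.path(tempdir(), "simrt2")
  write_cohort(simulate_cohort(scfg, build, NULL), dir2, build)
  f1 <- readLines(child_path)
  f2 <- readLines(file.path(dir2, basename(child_path)))
  expect_identical(f1, f2)
})

test_that("whole-chromosome iUPD and outbred chromosomes bracket the ROH bands", {
  cc <- small_cohort()
  res <- run_batch_cohort(cc$cohort, cc$build)
  tab <- res$cohort
  iupd <- cc$events[event == "iUPD"]
  fam <- sprintf("F%04d", iupd$family_idx)
  expect_gt(tab[family == fam & chrom == iupd$chrom, roh_fraction], 0.95)
  normal_fams <- setdiff(tab$family, sprintf("F%04d", cc$events$family_idx))
  expect_lt(max(tab[family %in% normal_fams, roh_fraction]), 0.1)
})
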