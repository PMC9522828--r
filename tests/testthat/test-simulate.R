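test_that("the toy reference digests back to exactly its region set", {
  toy <- make_toy_reference(seed = 5, n_regions = 10, cpg_range = c(3, 8))
  dig <- digest_reference(toy$ref)
  expect_equal(as.data.frame(dig), as.data.frame(toy$regions))
  expect_equal(nrow(dig), 10L)
  expect_true(all(dig$n_cpg >= 3 & dig$n_cpg <= 8))
  expect_true(all(dig$length < 350))
  # fixed seed -> identical sequence bytes
  toy2 <- make_toy_reference(seed = 5, n_regions = 10, cpg_range = c(3, 8))
  expect_identical(as.character(toy$ref), as.character(toy2$ref))
  expect_error(make_toy_reference(seed = 1, n_regions = 3,
                                  cpg_range = c(3, 8),
                                  region_len_range = c(10, 20)),
               "region_len_range")
})

test_that("degenerate and limiting beta-binomial levels behave as expected", {
  # m = 1 -> every read fully methylated
  tr1 <- one_region_truth(1, n_cpg = 6)
  rd <- simulate_sample(tr1, "x_normal", depth = 200, kappa = 5, seed = 2)
  expect_true(all(rd$n_cpg_meth == 6))
  tr0 <- one_region_truth(0, n_cpg = 6)
  rd0 <- simulate_sample(tr0, "x_normal", depth = 200, kappa = 5, seed = 2)
  expect_true(all(rd0$n_cpg_meth == 0))
  # kappa -> infinity: alpha concentrates on m (law of large numbers)
  trh <- one_region_truth(0.5, n_cpg = 10)
  rdh <- simulate_sample(trh, "x_normal", depth = 1e4, kappa = 1e6,
                         seed = 3)
  expect_gt(mean(rdh$n_cpg_meth / rdh$n_cpg_total), 0.49)
  expect_lt(mean(rdh$n_cpg_meth / rdh$n_cpg_total), 0.51)
  expect_error(simulate_sample(trh, "x_normal", kappa = 0), "kappa")
  expect_error(simulate_sample(trh, "nope", kappa = 1), "unknown source")
})

test_that("mean alpha per region and source converges to the configured level", {
  co <- simulate_cohort(sim_config(
    seed = 9, n_regions = 30, n_pairs_per_type = 2, n_normal_per_type = 6,
    n_cancer_plasma_per_type = 2, n_noncancer_plasma = 35, depth = 60,
    n_dmr = list(det_hyper = 2, det_hypo = 2, too_hyper_per_type = 1,
                 too_hypo_per_type = 1, tissue_hyper_per_type = 1,
                 tissue_hypo_per_type = 1)))
  at <- build_distributions(co$reads, co$regions, min_cpg = 1)
  nt <- co$meta[co$meta$condition == "normal_tissue" &
                  co$meta$type == "liver", ][["sample_id"]]
  obs <- at[at$sample_id %in% nt,
            list(m = mean(alpha), n = .N), by = "region_id"]
  lev <- co$truth$levels[obs$region_id, "liver_normal"]
  # beta-binomial alpha variance around m, three standard errors
  kap <- co$truth$cfg$kappa
  v <- lev * (1 - lev) / (kap + 1) + lev * (1 - lev) / 5
  tol <- 3 * sqrt(pmax(v, 1e-6) / obs$n) + 0.01
  expect_true(all(abs(obs$m - lev) <= tol))
})

test_that("plasma mixtures combine tumor and background directional rates", {
  # one region, distinct levels for the two sources
  regions <- data.table::data.table(
    chrom = "chrT", start = 0L, end = 100L, region_id = "chrT:0-100",
    length = 100L, n_cpg = 8L)
  lev <- matrix(c(0.9, 0.05), 1,
                dimnames = list("chrT:0-100",
                                c("liver_tumor", "liver_normal")))
  truth <- list(levels = lev, regions = regions)
  f <- 0.3; thr <- 0.8
  dir_rate <- function(rd) mean(rd$n_cpg_meth / rd$n_cpg_total >= thr)
  tum <- simulate_sample(truth, "liver_tumor", depth = 1e4, seed = 4)
  bg <- simulate_sample(truth, "liver_normal", depth = 1e4, seed = 5)
  mix <- simulate_sample(truth,
                         c(liver_tumor = f, liver_normal = 1 - f),
                         depth = 1e4, seed = 6)
  expected <- f * dir_rate(tum) + (1 - f) * dir_rate(bg)
  se <- sqrt(expected * (1 - expected) / 1e4)
  expect_lt(abs(dir_rate(mix) - expected), 4 * se + 0.01)
})

test_that("f = 0 plasma equals pure background in law: discovery finds nothing", {
  co <- simulate_cohort(sim_config(seed = 13, n_regions = 25,
                                   classes = "liver",
                                   n_pairs_per_type = 2,
                                   n_normal_per_type = 2,
                                   n_cancer_plasma_per_type = 10,
                                   n_noncancer_plasma = 10,
                                   tumor_fraction = 0,
                                   n_dmr = list(det_hyper = 3, det_hypo = 3,
                                                too_hyper_per_type = 0,
                                                too_hypo_per_type = 0,
                                                tissue_hyper_per_type = 0,
                                                tissue_hypo_per_type = 0)))
  at <- build_distributions(co$reads, co$regions, min_cpg = 3)
  ca <- co$meta[co$meta$condition == "cancer", ][["sample_id"]]
  nc <- co$meta[co$meta$condition == "noncancer", ][["sample_id"]]
  ms <- discover_markers(at, ca, nc, "hyper", pairing = NULL,
                         regions = co$regions, seed = 2)
  expect_equal(nrow(ms), 0L)
})

test_that("cohorts are reproducible and loadable through the file formats", {
  cfg <- sim_config(seed = 17, n_regions = 20, n_pairs_per_type = 2,
                    n_normal_per_type = 2, n_cancer_plasma_per_type = 2,
                    n_noncancer_plasma = 31, depth = 10,
                    n_dmr = list(det_hyper = 2, det_hypo = 2,
                                 too_hyper_per_type = 0,
                                 too_hypo_per_type = 0,
                                 tissue_hyper_per_type = 1,
                                 tissue_hypo_per_type = 1))
  co <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co$reads, co2$reads)
  expect_identical(co$truth$levels, co2$truth$levels)
  d <- file.path(tempdir(), "cohort_rt")
  write_cohort(co, d)
  rd <- parse_reads(file.path(d, "reads.tsv"))
  expect_equal(attr(rd, "n_rejected"), 0L)
  expect_equal(nrow(rd), nrow(co$reads))
  md <- parse_metadata(file.path(d, "metadata.tsv"))
  expect_equal(nrow(md), nrow(co$meta))
  reg <- read_regions_bed(file.path(d, "regions.bed"),
                          file.path(d, "regions_info.tsv"))
  expect_setequal(reg$region_id, co$regions$region_id)
  dig <- digest_reference(file.path(d, "reference.fa"))
  expect_equal(as.data.frame(dig), as.data.frame(co$regions))
})
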