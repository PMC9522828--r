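test_that("directional_count handles both directions and boundary thresholds", {
  a <- c(0.1, 0.6, 0.9, 1.0)
  expect_equal(directional_count(a, 0.8, "hyper"), 2L)
  expect_equal(directional_count(a, 0.0, "hyper"), 4L)
  expect_equal(directional_count(a, 0.1, "hypo"), 1L)
  expect_equal(directional_count(a, 1.0, "hypo"), 4L)
  # monotone in the threshold; extreme thresholds count everything
  set.seed(3)
  x <- runif(50)
  grid <- seq(0, 1, by = 0.05)
  hy <- vapply(grid, function(t) directional_count(x, t, "hyper"), 0L)
  ho <- vapply(grid, function(t) directional_count(x, t, "hypo"), 0L)
  expect_true(all(diff(hy) <= 0))
  expect_true(all(diff(ho) >= 0))
  expect_equal(hy[1], 50L)
  expect_equal(ho[length(grid)], 50L)
})

# thin access to the vectorised engine for oracle comparisons
.hyper_p_public <- function(kA, nA, kB, nB) {
  cfalpha:::.hyper_p(kA, nA, kB, nB)
}

test_that("pair_test equals the hypergeometric-tail oracle on small tables", {
  # A: 2 of 2 directional; B: 0 of 2 -> 1/6 by enumeration
  p <- pair_test(c(1, 1), c(0, 0), thr = 0.9, direction = "hyper")
  expect_equal(as.numeric(p), fisher_tail_oracle(2, 2, 0, 2))
  expect_equal(as.numeric(p), 1 / 6, tolerance = 1e-12)
  # identical distributions are not enriched
  x <- c(0.1, 0.9, 0.5, 1.0)
  expect_gte(as.numeric(pair_test(x, x, 0.8, "hyper")), 0.5)
  # strong enrichment: 10 of 20 vs 0 of 20
  a <- c(rep(1, 10), rep(0, 10)); b <- rep(0, 20)
  expect_lt(as.numeric(pair_test(a, b, 0.9, "hyper")), 0.001)
  expect_equal(as.numeric(pair_test(a, b, 0.9, "hyper")),
               fisher_tail_oracle(10, 20, 0, 20), tolerance = 1e-12)
  # zero reads on one side -> uninformative p = 1
  p0 <- pair_test(numeric(0), x, 0.5, "hyper")
  expect_equal(as.numeric(p0), 1)
  expect_true(attr(p0, "uninformative"))
  # agreement with stats::fisher.test one-sided
  ft <- stats::fisher.test(matrix(c(7, 3, 2, 8), 2, byrow = TRUE),
                           alternative = "greater")
  expect_equal(as.numeric(.hyper_p_public(7, 10, 2, 10)), ft$p.value,
               tolerance = 1e-9)
})

test_that("select_threshold maximises pair support with extreme tie-break", {
  grid <- seq(0, 1, by = 0.1)
  tum <- c(rep(1, 5), rep(0, 5)); nor <- rep(0, 10)
  pairs <- rep(list(list(case = tum, control = nor)), 3)
  sel <- select_threshold(pairs, "hyper", grid, p_cut = 0.05)
  expect_equal(sel$n_support, 3)
  expect_equal(sel$alpha_thr, 1.0)  # tie across thr > 0 broken upward
  # oracle: support at every grid point from the enumeration oracle
  sup_or <- vapply(grid, function(t) {
    k <- sum(tum >= t)
    sum(rep(fisher_tail_oracle(k, 10, sum(nor >= t), 10) < 0.05, 3))
  }, 0)
  expect_equal(sel$support, sup_or)
  # no signal -> zero support
  null <- rep(list(list(case = nor, control = nor)), 3)
  expect_equal(select_threshold(null, "hyper", grid, 0.05)$n_support, 0)
  # single pair, perfect separation, permissive cut
  one <- list(list(case = rep(1, 6), control = rep(0, 6)))
  expect_equal(select_threshold(one, "hyper", grid, p_cut = 0.5)$n_support, 1)
  # hypo ties break downward
  pairs_h <- rep(list(list(case = rep(0, 8), control = rep(1, 8))), 2)
  sel_h <- select_threshold(pairs_h, "hypo", grid, 0.05)
  expect_equal(sel_h$alpha_thr, 0.0)
})

test_that("filter_by_reference applies the directional-fraction rule", {
  # 30 reference samples, all with zero directional reads -> pass
  at <- data.table::data.table(
    region_id = "r1",
    sample_id = rep(sprintf("ref%02d", 1:30), each = 10),
    alpha = 0.1)
  data.table::setkey(at, region_id, sample_id)
  cand <- data.table::data.table(region_id = "r1", direction = "hyper",
                                 alpha_thr = 0.9)
  refs <- sprintf("ref%02d", 1:30)
  expect_true(filter_by_reference(cand, at, refs, 0.05, 0.9))
  # 15 of 30 at fraction 0.5 -> fail
  at2 <- data.table::data.table(
    region_id = "r1",
    sample_id = rep(sprintf("ref%02d", 1:30), each = 10),
    alpha = c(rep(c(0.95, 0.1), 75), rep(0.1, 150)))
  data.table::setkey(at2, region_id, sample_id)
  expect_false(filter_by_reference(cand, at2, refs, 0.05, 0.9))
  # 28 of 30 below max_frac -> pass at min_pass_frac 0.9
  at3 <- data.table::copy(at)
  at3[sample_id %in% c("ref01", "ref02"), alpha := 0.95]
  data.table::setkey(at3, region_id, sample_id)
  expect_true(filter_by_reference(cand, at3, refs, 0.05, 0.9))
  expect_error(filter_by_reference(cand, at, character(0)), "reference")
})

test_that("discover_markers recovers planted DMRs and only in the planted direction", {
  co <- small_cohort()
  at <- small_alpha_table()
  meta <- as.data.frame(co$meta)
  pairing <- tissue_pairing(meta, "liver")
  tum <- pairing$case; adj <- pairing$control
  lev <- co$truth$levels
  truth_hyper <- rownames(lev)[lev[, "liver_tumor"] -
                                 lev[, "liver_normal"] > 0.25]
  truth_hypo <- rownames(lev)[lev[, "liver_normal"] -
                                lev[, "liver_tumor"] > 0.25]
  ms_hyper <- discover_markers(at, tum, adj, "hyper", pairing = pairing,
                               regions = co$regions)
  ms_hypo <- discover_markers(at, tum, adj, "hypo", pairing = pairing,
                              regions = co$regions)
  expect_setequal(ms_hyper$region_id, truth_hyper)
  expect_setequal(ms_hypo$region_id, truth_hypo)
  # ranked by support, then effect size
  expect_true(all(diff(ms_hyper$n_support) <= 0))
  # within-set region ids unique; thresholds inside [0, 1]
  expect_false(anyDuplicated(ms_hyper$region_id) > 0)
  expect_true(all(ms_hyper$alpha_thr >= 0 & ms_hyper$alpha_thr <= 1))
  expect_error(discover_markers(at, tum[1], adj, "hyper"), "at least 2")
})

test_that("null contrasts yield no markers", {
  co <- small_cohort()
  at <- small_alpha_table()
  meta <- as.data.frame(co$meta)
  # adjacent normals of one type split into two pseudo-groups: no signal
  adj <- meta[meta$type == "colon" & meta$condition == "adjacent_normal",
              "sample_id"]
  nt <- meta[meta$type == "colon" & meta$condition == "normal_tissue",
             "sample_id"]
  ms <- discover_markers(at, adj, nt, "hyper", pairing = NULL,
                         regions = co$regions, seed = 4)
  expect_lt(nrow(ms) / nrow(co$regions), 0.05)
})

test_that("build_marker_panels assembles the three panel families", {
  co <- small_cohort()
  at <- small_alpha_table()
  refs <- co$meta[co$meta$condition == "noncancer", ][["sample_id"]][1:10]
  panels <- build_marker_panels(at, co$meta, ref_samples = refs,
                                regions = co$regions, seed = 5)
  expect_s3_class(panels$detection$cancer_hyper, "marker_set")
  # tissue panels carry at least one marker per ordered tissue pair
  for (d in c("tissue_hyper", "tissue_hypo")) {
    ms <- panels$tissue[[d]]
    expect_gt(nrow(ms), 0)
    expect_false(anyDuplicated(ms$region_id) > 0)
  }
  # merged detection panels contain each pan-cancer planted region once
  det_truth <- co$truth$dmr[co$truth$dmr$kind == "detection" &
                              co$truth$dmr$direction == "hyper", ]
  found <- panels$detection$cancer_hyper$region_id
  expect_true(all(det_truth$region_id %in% found))
  expect_equal(anyDuplicated(found), 0L)
  # top_m = 0 gives empty panels without error
  p0 <- discovery_params(top_m = 0)
  panels0 <- build_marker_panels(at, co$meta, ref_samples = refs,
                                 regions = co$regions, seed = 5,
                                 params = p0, families = "tissue")
  expect_equal(nrow(panels0$tissue$tissue_hyper), 0L)
})

test_that("marker sets merge with best-ranked duplicate collapse and serialise", {
  a <- new_marker_set(data.table::data.table(
    region_id = c("chr1:0-100", "chr1:100-200"), direction = "hyper",
    alpha_thr = 0.8, n_support = c(5, 3), n_pairs = 6L,
    mean_delta = c(0.5, 0.2), pass_reference = TRUE, contrast = "c1"))
  b <- new_marker_set(data.table::data.table(
    region_id = c("chr1:0-100", "chr1:200-300"), direction = "hyper",
    alpha_thr = 0.6, n_support = c(6, 2), n_pairs = 6L,
    mean_delta = c(0.1, 0.9), pass_reference = TRUE, contrast = "c2"))
  m <- merge_marker_sets(list(a, b))
  expect_equal(nrow(m), 3L)
  # the duplicated region keeps its higher-support instance (from b)
  expect_equal(m[m$region_id == "chr1:0-100", ][["contrast"]], "c2")
  expect_error(new_marker_set(rbind(as.data.frame(a), as.data.frame(a))),
               "unique")
  bed <- tempfile(fileext = ".bed"); side <- tempfile(fileext = ".tsv")
  write_marker_set(m, bed, side)
  expect_equal(length(readLines(bed)), 3L)
  expect_equal(nrow(data.table::fread(side)), 3L)
})
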