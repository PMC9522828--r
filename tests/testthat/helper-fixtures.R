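# shared fixtures, built in code and memoised across test files

.fixtures <- new.env(parent = emptyenv())

# small 4-type cohort with planted DMRs, strong plasma tumor fraction
small_cohort <- function() {
  if (is.null(.fixtures$co)) {
    .fixtures$co <- simulate_cohort(sim_config(
      seed = 7, n_regions = 60, n_pairs_per_type = 5,
      n_normal_per_type = 4, n_cancer_plasma_per_type = 6,
      n_noncancer_plasma = 50, depth = 30, tumor_fraction = 0.2))
  }
  .fixtures$co
}

small_alpha_table <- function() {
  if (is.null(.fixtures$at)) {
    co <- small_cohort()
    .fixtures$at <- build_distributions(co$reads, co$regions, min_cpg = 3)
  }
  .fixtures$at
}

# single-region truth object for simulate_sample unit tests
one_region_truth <- function(m, n_cpg = 10, source = "x_normal") {
  regions <- data.table::data.table(
    chrom = "chrT", start = 0L, end = 100L, region_id = "chrT:0-100",
    length = 100L, n_cpg = n_cpg)
  levels <- matrix(m, nrow = 1, dimnames = list("chrT:0-100", source))
  list(levels = levels, regions = regions)
}

# four-view Gaussian toy data with independent per-view signal
make_multiview <- function(r, d = 10, n_train = 80, n_test = 400,
                           effect = 0.6, n_signal = 3) {
  y_train <- rep(c(TRUE, FALSE), each = n_train / 2)
  y_test <- rep(c(TRUE, FALSE), each = n_test / 2)
  train <- list(); test <- list()
  for (v in 1:4) {
    set.seed(2000 + r * 10 + v)
    dims <- sample(d, n_signal)
    mk <- function(n, y) {
      mu <- matrix(0, n, d)
      mu[y, dims] <- effect
      matrix(rnorm(n * d), n, d) + mu
    }
    train[[v]] <- mk(n_train, y_train)
    test[[v]] <- mk(n_test, y_test)
  }
  names(train) <- names(test) <-
    c("cancer_hyper", "cancer_hypo", "tissue_hyper", "tissue_hypo")
  list(train = train, test = test, y_train = y_train, y_test = y_test)
}

# paired tumor/adjacent-normal pairing table from cohort metadata
tissue_pairing <- function(meta, ty) {
  tum <- meta[meta$material == "tissue" & meta$type == ty &
                meta$condition == "tumor", ]
  adj <- meta[meta$material == "tissue" & meta$type == ty &
                meta$condition == "adjacent_normal", ]
  m <- merge(tum[, c("sample_id", "pair_id")],
             adj[, c("sample_id", "pair_id")], by = "pair_id")
  data.frame(case = m$sample_id.x, control = m$sample_id.y)
}
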