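#' Discovery tuning parameters
#'
#' Knobs of the read-level marker discovery procedure. The alpha threshold
#' is grid-searched; a candidate needs a significant one-sided enrichment of
#' directional reads in at least `support_frac` of sample pairs; candidates
#' surviving reference-plasma filtration are ranked by support then effect
#' size and truncated to `top_m` per contrast.
#'
#' @param grid candidate alpha thresholds (default 0, 0.05, ..., 1).
#' @param p_cut per-pair one-sided Fisher significance cutoff.
#' @param support_frac minimum fraction of supporting pairs.
#' @param max_frac maximum directional read fraction a reference plasma
#'   sample may show before it counts against a candidate.
#' @param min_pass_frac minimum fraction of reference samples that must stay
#'   at or below `max_frac`.
#' @param top_m markers kept per contrast before merging.
#' @param min_cpg per-read CpG floor used upstream (recorded for provenance).
#' @param n_pseudo_pairings seeded random pseudo-pairings for unpaired
#'   contrasts; support is averaged across them.
#' @param fdr if `TRUE`, additionally require a Benjamini-Hochberg adjusted
#'   pooled Fisher p below `p_cut` across the region universe.
#' @return list of class `discovery_params`.
#' @export
discovery_params <- function(grid = seq(0, 1, by = 0.05), p_cut = 0.05,
                             support_frac = 2 / 3, max_frac = 0.05,
                             min_pass_frac = 0.9, top_m = 2000,
                             min_cpg = 3, n_pseudo_pairings = 5,
                             fdr = FALSE) {
  stopifnot(all(grid >= 0 & grid <= 1), p_cut > 0, p_cut <= 1,
            support_frac >= 0, support_frac <= 1, top_m >= 0)
  structure(list(grid = sort(unique(grid)), p_cut = p_cut,
                 support_frac = support_frac, max_frac = max_frac,
                 min_pass_frac = min_pass_frac, top_m = top_m,
                 min_cpg = min_cpg, n_pseudo_pairings = n_pseudo_pairings,
                 fdr = fdr),
            class = "discovery_params")
}

#' Count directional reads of an alpha distribution
#'
#' Hypermethylated reads are those with alpha at or above the threshold;
#' hypomethylated reads those at or below it.
#'
#' @param alphas numeric vector of read alpha-values.
#' @param thr alpha threshold in `[0, 1]`.
#' @param direction `"hyper"` or `"hypo"`.
#' @return integer count.
#' @export
directional_count <- function(alphas, thr, direction = c("hyper", "hypo")) {
  direction <- match.arg(direction)
  stopifnot(thr >= 0, thr <= 1)
  if (direction == "hyper") sum(alphas >= thr) else sum(alphas <= thr)
}

# one-sided hypergeometric tail P(X >= kA) for the 2x2 table
# [kA, nA - kA; kB, nB - kB]: the one-sided Fisher exact test that group A
# is enriched in directional reads. Vectorised.
.hyper_p <- function(kA, nA, kB, nB) {
  p <- phyper(kA - 1, kA + kB, (nA + nB) - (kA + kB), nA,
              lower.tail = FALSE)
  p[nA == 0 | nB == 0] <- 1
  p
}

#' One-sided Fisher exact test for directional-read enrichment
#'
#' Tests whether the directional (hyper- or hypomethylated) read count of
#' distribution A is significantly larger than that of distribution B, given
#' their total read counts: the one-sided Fisher exact (hypergeometric tail)
#' p-value of the 2x2 table of directional vs non-directional reads.
#'
#' @param dist_a,dist_b numeric vectors of read alpha-values (case and
#'   control, e.g. tumor and adjacent normal).
#' @param thr alpha threshold.
#' @param direction `"hyper"` or `"hypo"`.
#' @return p-value; if either side has zero reads, 1 with
#'   `attr(, "uninformative") = TRUE`.
#' @export
pair_test <- function(dist_a, dist_b, thr, direction = c("hyper", "hypo")) {
  direction <- match.arg(direction)
  nA <- length(dist_a); nB <- length(dist_b)
  if (nA == 0L || nB == 0L) {
    return(structure(1, uninformative = TRUE))
  }
  kA <- directional_count(dist_a, thr, direction)
  kB <- directional_count(dist_b, thr, direction)
  .hyper_p(kA, nA, kB, nB)
}

#' Grid-search the alpha threshold maximising pair support
#'
#' For each candidate threshold, counts how many case/control pairs show a
#' significant one-sided enrichment of directional reads ([pair_test()]
#' p < `p_cut`) and returns the threshold with maximal support. Ties are
#' broken toward the more extreme threshold: the largest for `hyper`, the
#' smallest for `hypo`.
#'
#' @param pairs list of pairs, each a `list(case = alphas, control =
#'   alphas)`.
#' @param direction `"hyper"` or `"hypo"`.
#' @param grid candidate thresholds.
#' @param p_cut per-pair significance cutoff.
#' @return `list(alpha_thr, n_support, support)` where `support` is the
#'   per-threshold support vector; `n_support = 0` flags a dead candidate
#'   (its `alpha_thr` is then `NA`).
#' @export
select_threshold <- function(pairs, direction = c("hyper", "hypo"),
                             grid = seq(0, 1, by = 0.05), p_cut = 0.05) {
  direction <- match.arg(direction)
  stopifnot(length(pairs) >= 1L)
  grid <- sort(unique(grid))
  support <- vapply(grid, function(thr) {
    sum(vapply(pairs, function(pr) {
      as.numeric(pair_test(pr$case, pr$control, thr, direction)) < p_cut
    }, logical(1L)))
  }, numeric(1L))
  best <- max(support)
  if (best == 0) {
    return(list(alpha_thr = NA_real_, n_support = 0, support = support))
  }
  idx <- which(support == best)
  pick <- if (direction == "hyper") max(idx) else min(idx)
  list(alpha_thr = grid[pick], n_support = best, support = support)
}

# Directional count cube: for region universe `region_ids` and `samples`,
# cnt[r, s, g] = directional reads of sample s in region r at grid[g];
# tot[r, s] = total reads. Computed by binning alphas once and cumulating
# along the grid, so cost is O(reads + R*S*G).
.dir_count_cube <- function(at, samples, region_ids, grid,
                            direction = c("hyper", "hypo")) {
  direction <- match.arg(direction)
  R <- length(region_ids); S <- length(samples); G <- length(grid)
  dt <- at[sample_id %in% samples]
  dt <- dt[region_id %in% region_ids]
  cnt <- array(0, dim = c(R, S, G))
  tot <- matrix(0, R, S)
  if (nrow(dt) > 0L) {
    ri <- match(dt$region_id, region_ids)
    si <- match(dt$sample_id, samples)
    if (direction == "hyper") {
      # alphas in half-open bins [grid[g], grid[g+1]); count >= grid[g]
      # is the tail sum over bins g..G
      b <- findInterval(dt$alpha, grid)
    } else {
      # left-open bins (grid[g], grid[g+1]]; count <= grid[g] is the head
      # sum over bins 1..g after shifting
      b <- findInterval(dt$alpha, grid, left.open = TRUE) + 1L
    }
    agg <- data.table(ri = ri, si = si, b = b)[, .N, by = c("ri", "si", "b")]
    cnt[cbind(agg$ri, agg$si, pmin(agg$b, G))] <-
      cnt[cbind(agg$ri, agg$si, pmin(agg$b, G))] + agg$N
    if (direction == "hyper") {
      for (g in seq(G - 1L, 1L)) cnt[, , g] <- cnt[, , g] + cnt[, , g + 1L]
    } else {
      # bin b = G+1 would mean alpha > grid[G]; impossible for alpha <= 1
      for (g in seq(2L, G)) cnt[, , g] <- cnt[, , g] + cnt[, , g - 1L]
    }
    tt <- data.table(ri = ri, si = si)[, .N, by = c("ri", "si")]
    tot[cbind(tt$ri, tt$si)] <- tt$N
  }
  list(cnt = cnt, tot = tot)
}

# Support and effect-size scan over the region x threshold lattice for one
# pairing. Returns support[R, G] (count of significant pairs) and
# delta[R, G] (mean directional-fraction difference case - control).
.support_scan <- function(cube, case_idx, control_idx, p_cut) {
  R <- dim(cube$cnt)[1L]; G <- dim(cube$cnt)[3L]
  support <- matrix(0, R, G)
  delta <- matrix(0, R, G)
  n_pairs <- length(case_idx)
  for (p in seq_len(n_pairs)) {
    kA <- cube$cnt[, case_idx[p], , drop = FALSE][, 1L, ]
    kB <- cube$cnt[, control_idx[p], , drop = FALSE][, 1L, ]
    dim(kA) <- c(R, G); dim(kB) <- c(R, G)
    nA <- cube$tot[, case_idx[p]]
    nB <- cube$tot[, control_idx[p]]
    pv <- .hyper_p(kA, rep(nA, G), kB, rep(nB, G))
    dim(pv) <- c(R, G)
    support <- support + (pv < p_cut)
    fA <- kA / rep(pmax(nA, 1), G); fA[nA == 0, ] <- 0
    fB <- kB / rep(pmax(nB, 1), G); fB[nB == 0, ] <- 0
    delta <- delta + (fA - fB)
  }
  list(support = support, delta = delta / max(n_pairs, 1L),
       n_pairs = n_pairs)
}

.subseed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483647)
}

#' Filter marker candidates against reference noncancer plasma
#'
#' A candidate passes if, in at least `min_pass_frac` of the reference
#' plasma samples, the directional read fraction at the candidate's learned
#' alpha threshold is at most `max_frac`. Reference samples with no reads in
#' the region have directional fraction 0 and pass.
#'
#' @param candidates `data.table` with `region_id`, `direction`,
#'   `alpha_thr` (unique regions).
#' @param at alpha table covering the reference samples.
#' @param ref_samples character vector of reference plasma sample ids.
#' @param max_frac,min_pass_frac see [discovery_params()].
#' @return logical vector parallel to `candidates`.
#' @export
filter_by_reference <- function(candidates, at, ref_samples,
                                max_frac = 0.05, min_pass_frac = 0.9) {
  if (length(ref_samples) == 0L) {
    stop("reference filtration requires at least one reference plasma sample")
  }
  candidates <- as.data.table(candidates)
  if (nrow(candidates) == 0L) return(logical(0))
  sub <- at[sample_id %in% ref_samples][region_id %in% candidates$region_id]
  n_ref <- length(ref_samples)
  if (nrow(sub) == 0L) return(rep(TRUE, nrow(candidates)))
  sub <- merge(sub, candidates[, .(region_id, alpha_thr, direction)],
               by = "region_id", allow.cartesian = TRUE)
  dirc <- ifelse(sub$direction == "hyper",
                 sub$alpha >= sub$alpha_thr, sub$alpha <= sub$alpha_thr)
  per <- data.table(region_id = sub$region_id, sample_id = sub$sample_id,
                    d = dirc)[, .(frac = mean(d)), by = c("region_id",
                                                          "sample_id")]
  n_fail <- per[frac > max_frac, .N, by = "region_id"]
  fails <- setNames(rep(0L, nrow(candidates)), candidates$region_id)
  fails[n_fail$region_id] <- n_fail$N
  (n_ref - fails) / n_ref >= min_pass_frac
}

#' Discover directional methylation markers between two sample groups
#'
#' For every region of the universe, grid-searches the alpha threshold that
#' maximises the number of case/control pairs with a significant one-sided
#' enrichment of directional reads, keeps regions supported by at least
#' `support_frac` of pairs, optionally filters against reference noncancer
#' plasma, and ranks by support then mean directional-fraction difference.
#'
#' Paired contrasts (tumor vs adjacent normal) use the given pairing.
#' Unpaired contrasts (tumor type vs tumor type, tissue vs tissue) form
#' `n_pseudo_pairings` seeded random pseudo-pairings and average the support
#' surface before threshold selection, so support may be fractional.
#'
#' @param at alpha table ([build_distributions()]).
#' @param group_a,group_b character vectors of sample ids (cases first:
#'   markers are enriched in `group_a`).
#' @param direction `"hyper"` or `"hypo"`.
#' @param pairing `data.frame(case, control)` of sample ids for paired
#'   designs, or `NULL` for seeded pseudo-pairing.
#' @param params [discovery_params()].
#' @param regions region universe: a region table or character vector of
#'   region ids; defaults to the regions present in `at`.
#' @param ref_samples optional reference plasma sample ids; when given,
#'   candidates failing [filter_by_reference()] are dropped.
#' @param seed integer seed for pseudo-pairing.
#' @param contrast free-text contrast label stored with the result.
#' @return a `marker_set`: ranked `data.table` with `region_id`,
#'   `direction`, `alpha_thr`, `n_support`, `n_pairs`, `mean_delta`,
#'   `pass_reference`, `contrast`, plus `params`/`seed` attributes.
#' @export
discover_markers <- function(at, group_a, group_b,
                             direction = c("hyper", "hypo"),
                             pairing = NULL, params = discovery_params(),
                             regions = NULL, ref_samples = NULL, seed = 1,
                             contrast = "A-vs-B") {
  direction <- match.arg(direction)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 samples")
  }
  region_ids <- if (is.null(regions)) {
    sort(unique(at$region_id))
  } else if (is.data.frame(regions)) regions$region_id else regions
  if (length(region_ids) == 0L) stop("empty region universe")
  grid <- params$grid
  samples <- unique(c(group_a, group_b))
  cube <- .dir_count_cube(at, samples, region_ids, grid, direction)

  if (!is.null(pairing)) {
    pairing <- as.data.table(pairing)
    case_idx <- match(pairing$case, samples)
    control_idx <- match(pairing$control, samples)
    if (anyNA(case_idx) || anyNA(control_idx)) {
      stop("pairing refers to samples outside the groups")
    }
    scan <- .support_scan(cube, case_idx, control_idx, params$p_cut)
    support <- scan$support; delta <- scan$delta; n_pairs <- scan$n_pairs
  } else {
    n_pairs <- min(length(group_a), length(group_b))
    reps <- params$n_pseudo_pairings
    support <- 0; delta <- 0
    for (r in seq_len(reps)) {
      set.seed(.subseed(seed, r))
      ca <- sample(group_a, n_pairs)
      co <- sample(group_b, n_pairs)
      scan <- .support_scan(cube, match(ca, samples), match(co, samples),
                            params$p_cut)
      support <- support + scan$support
      delta <- delta + scan$delta
    }
    support <- support / reps
    delta <- delta / reps
  }

  G <- length(grid)
  best <- apply(support, 1L, max)
  pick <- integer(nrow(support))
  for (r in seq_along(pick)) {
    idx <- which(support[r, ] == best[r])
    pick[r] <- if (direction == "hyper") max(idx) else min(idx)
  }
  res <- data.table(
    region_id = region_ids,
    direction = direction,
    alpha_thr = ifelse(best > 0, grid[pick], NA_real_),
    n_support = best,
    n_pairs = n_pairs,
    mean_delta = delta[cbind(seq_along(pick), pick)])
  res <- res[n_support / n_pairs >= params$support_frac & n_support > 0]

  if (params$fdr && nrow(res) > 0L) {
    # pooled one-sided Fisher across pairs at the chosen threshold,
    # BH-adjusted over the retained candidates
    pool <- vapply(seq_len(nrow(res)), function(i) {
      ridx <- match(res$region_id[i], region_ids)
      gidx <- match(res$alpha_thr[i], grid)
      ka <- sum(cube$cnt[ridx, match(group_a, samples), gidx])
      kb <- sum(cube$cnt[ridx, match(group_b, samples), gidx])
      na <- sum(cube$tot[ridx, match(group_a, samples)])
      nb <- sum(cube$tot[ridx, match(group_b, samples)])
      .hyper_p(ka, na, kb, nb)
    }, numeric(1L))
    res <- res[p.adjust(pool, "BH") < params$p_cut]
  }

  if (!is.null(ref_samples) && nrow(res) > 0L) {
    res[, pass_reference := filter_by_reference(
      res, at, ref_samples, params$max_frac, params$min_pass_frac)]
    res <- res[pass_reference == TRUE]
  } else {
    res[, pass_reference := NA]
  }
  setorder(res, -n_support, -mean_delta, region_id)
  if (nrow(res) > params$top_m) res <- head(res, params$top_m)
  res[, contrast := contrast]
  new_marker_set(res, params = params, seed = seed)
}

#' Construct a marker set
#' @param dt candidate table (ranked).
#' @param params discovery parameters used.
#' @param seed seed used.
#' @return `marker_set` object.
#' @export
new_marker_set <- function(dt, params = NULL, seed = NA) {
  dt <- as.data.table(dt)
  if (anyDuplicated(dt$region_id)) stop("region_ids must be unique")
  setattr(dt, "params", params)
  setattr(dt, "seed", seed)
  setattr(dt, "class", c("marker_set", class(dt)))
  dt[]
}

#' Merge marker sets from several contrasts
#'
#' Concatenates, re-ranks by (support desc, effect size desc) and collapses
#' duplicated regions keeping the best-ranked instance.
#'
#' @param sets list of `marker_set`s of one direction.
#' @return merged `marker_set`.
#' @export
merge_marker_sets <- function(sets) {
  sets <- Filter(function(s) nrow(s) > 0L, sets)
  if (length(sets) == 0L) return(new_marker_set(
    data.table(region_id = character(), direction = character(),
               alpha_thr = numeric(), n_support = numeric(),
               n_pairs = integer(), mean_delta = numeric(),
               pass_reference = logical(), contrast = character())))
  merged <- rbindlist(lapply(sets, as.data.table), use.names = TRUE)
  setorder(merged, -n_support, -mean_delta, region_id)
  merged <- merged[!duplicated(region_id)]
  new_marker_set(merged, params = attr(sets[[1L]], "params"))
}

#' Build the marker panels for detection, tissue-of-origin and tissue
#' deconvolution
#'
#' Runs the full marker-discovery design over a cohort's tissue samples and
#' the run's reserved reference plasma:
#' \describe{
#'   \item{detection}{per cancer type, paired tumor vs adjacent-normal
#'     discovery (hyper and hypo), reference-plasma filtration, merged
#'     across types;}
#'   \item{too}{all ordered tumor-type contrasts plus per-type tumor vs
#'     reference plasma (pseudo-paired), reference filtration, merged;}
#'   \item{tissue}{all ordered normal-tissue contrasts (pseudo-paired),
#'     merged.}
#' }
#' Each contrast is truncated to `params$top_m` before merging; duplicated
#' regions keep the best-ranked instance.
#'
#' @param at alpha table covering tissue and reference plasma samples.
#' @param meta metadata table ([parse_metadata()] columns).
#' @param ref_samples reference noncancer plasma sample ids for this run.
#' @param params [discovery_params()].
#' @param regions region universe.
#' @param seed integer seed.
#' @param families which panel families to build (subset of
#'   `c("detection", "too", "tissue")`); omitted families come back empty.
#' @return list of class `marker_panels` with elements `detection`, `too`
#'   (each `list(cancer_hyper, cancer_hypo)`) and `tissue`
#'   (`list(tissue_hyper, tissue_hypo)`).
#' @export
build_marker_panels <- function(at, meta, ref_samples,
                                params = discovery_params(), regions = NULL,
                                seed = 1,
                                families = c("detection", "too", "tissue")) {
  families <- match.arg(families, several.ok = TRUE)
  meta <- as.data.table(meta)
  tiss <- meta[material == "tissue"]
  types <- sort(unique(tiss$type))
  for (ty in types) {
    if (nrow(tiss[type == ty]) == 0L) stop("no tissue samples for type ", ty)
  }
  dirs <- c("hyper", "hypo")

  empty_set <- function(d) new_marker_set(
    data.table(region_id = character(), direction = character(),
               alpha_thr = numeric(), n_support = numeric(),
               n_pairs = integer(), mean_delta = numeric(),
               pass_reference = logical(), contrast = character()))

  # (i) detection: paired tumor vs adjacent normal per type + ref filter
  detection <- if (!"detection" %in% families) lapply(dirs, empty_set) else
    lapply(dirs, function(d) {
    per_type <- lapply(types, function(ty) {
      tum <- tiss[type == ty & condition == "tumor"]
      adj <- tiss[type == ty & condition == "adjacent_normal"]
      pairing <- merge(tum[, .(case = sample_id, pair_id)],
                       adj[, .(control = sample_id, pair_id)],
                       by = "pair_id")[, .(case, control)]
      discover_markers(at, tum$sample_id, adj$sample_id, direction = d,
                       pairing = pairing, params = params, regions = regions,
                       ref_samples = ref_samples,
                       seed = .subseed(seed, match(ty, types)),
                       contrast = paste0(ty, "-tumor-vs-adjacent"))
    })
    merge_marker_sets(per_type)
  })

  # (ii) TOO: ordered tumor-type pairs + tumor vs reference plasma
  too <- if (!"too" %in% families) lapply(dirs, empty_set) else
    lapply(dirs, function(d) {
    contrasts <- list()
    k <- 0L
    for (t1 in types) for (t2 in setdiff(types, t1)) {
      k <- k + 1L
      contrasts[[length(contrasts) + 1L]] <- discover_markers(
        at, tiss[type == t1 & condition == "tumor"]$sample_id,
        tiss[type == t2 & condition == "tumor"]$sample_id,
        direction = d, pairing = NULL, params = params, regions = regions,
        ref_samples = ref_samples, seed = .subseed(seed, 100L + k),
        contrast = paste0(t1, "-vs-", t2, "-tumor"))
    }
    for (ty in types) {
      k <- k + 1L
      contrasts[[length(contrasts) + 1L]] <- discover_markers(
        at, tiss[type == ty & condition == "tumor"]$sample_id,
        ref_samples, direction = d, pairing = NULL, params = params,
        regions = regions, ref_samples = ref_samples,
        seed = .subseed(seed, 100L + k),
        contrast = paste0(ty, "-tumor-vs-reference-plasma"))
    }
    merge_marker_sets(contrasts)
  })

  # (iii) tissue: ordered normal-tissue pairs, no reference filtration
  tissue <- if (!"tissue" %in% families) lapply(dirs, empty_set) else
    lapply(dirs, function(d) {
    contrasts <- list()
    k <- 0L
    for (t1 in types) for (t2 in setdiff(types, t1)) {
      k <- k + 1L
      contrasts[[length(contrasts) + 1L]] <- discover_markers(
        at, tiss[type == t1 & condition == "normal_tissue"]$sample_id,
        tiss[type == t2 & condition == "normal_tissue"]$sample_id,
        direction = d, pairing = NULL, params = params, regions = regions,
        seed = .subseed(seed, 200L + k),
        contrast = paste0(t1, "-vs-", t2, "-normal"))
    }
    merge_marker_sets(contrasts)
  })

  structure(list(
    detection = list(cancer_hyper = detection[[1L]],
                     cancer_hypo = detection[[2L]]),
    too = list(cancer_hyper = too[[1L]], cancer_hypo = too[[2L]]),
    tissue = list(tissue_hyper = tissue[[1L]], tissue_hypo = tissue[[2L]])),
    class = "marker_panels", seed = seed)
}

#' Write a marker set as BED6+ with a sidecar TSV
#'
#' BED columns: chrom, start, end, region_id, score (`n_support`), direction
#' (as strand-like column); the sidecar carries `alpha_thr`, `n_support`,
#' `mean_delta`, `contrast`.
#'
#' @param ms `marker_set`.
#' @param bed_path,sidecar_path output paths.
#' @return invisibly `bed_path`.
#' @export
write_marker_set <- function(ms, bed_path, sidecar_path = NULL) {
  loc <- .parse_region_ids(ms$region_id)
  bed <- data.table(chrom = loc$chrom, start = loc$start, end = loc$end,
                    name = ms$region_id, score = ms$n_support,
                    direction = ms$direction)
  fwrite(bed, bed_path, sep = "\t", col.names = FALSE)
  if (!is.null(sidecar_path)) {
    fwrite(as.data.table(ms)[, .(region_id, direction, alpha_thr, n_support,
                                 n_pairs, mean_delta, contrast)],
           sidecar_path, sep = "\t")
  }
  invisible(bed_path)
}

.parse_region_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  data.table(chrom = vapply(m, `[`, "", 2L),
             start = as.integer(vapply(m, `[`, "", 3L)),
             end = as.integer(vapply(m, `[`, "", 4L)))
}
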