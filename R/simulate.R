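#' Simulation configuration
#'
#' Defines the synthetic cohort: a toy reference digested into marker unit
#' regions; per-region, per-source methylation levels with planted
#' differentially methylated regions (DMRs); paired tumor/adjacent-normal
#' and normal solid tissues per type; and plasma samples whose reads are
#' mixtures of a tumor methylome and a tissue-blended background.
#'
#' Per-read alpha-values follow a beta-binomial molecule model: a molecule
#' level `m* ~ Beta(m k, (1 - m) k)` around the region-source level `m`
#' (concentration `kappa` controls molecule heterogeneity and creates the
#' bimodal alpha distributions read-level discovery exploits), then
#' methylated CpGs `~ Binomial(n_cpg, m*)`.
#'
#' @param seed master seed; all randomness derives from it.
#' @param classes tissue/cancer types.
#' @param n_regions marker unit regions on the toy reference.
#' @param cpg_range CpGs per region (inclusive range).
#' @param region_len_range region length range in bp (< 350).
#' @param n_pairs_per_type tumor/adjacent-normal tissue pairs per type.
#' @param n_normal_per_type normal solid tissues per type.
#' @param n_cancer_plasma_per_type cancer plasma samples per type.
#' @param n_noncancer_plasma noncancer plasma samples.
#' @param depth reads per region per sample.
#' @param kappa beta-binomial concentration (> 0).
#' @param tumor_purity tumor fraction of tumor *tissue* samples.
#' @param tumor_fraction tumor-derived read fraction of cancer plasma
#'   (scalar or vector recycled over cancer plasma samples).
#' @param background_weights named per-class weights of the plasma
#'   background tissue blend (liver-dominant by default).
#' @param delta planted methylation difference of all DMRs.
#' @param n_dmr named DMR allocation: `det_hyper`, `det_hypo` (pan-cancer),
#'   `too_hyper_per_type`, `too_hypo_per_type` (type-specific cancer),
#'   `tissue_hyper_per_type`, `tissue_hypo_per_type`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       classes = c("colon", "liver", "lung", "stomach"),
                       n_regions = 200,
                       cpg_range = c(3, 8),
                       region_len_range = c(60, 300),
                       n_pairs_per_type = 20,
                       n_normal_per_type = 10,
                       n_cancer_plasma_per_type = 15,
                       n_noncancer_plasma = 80,
                       depth = 30,
                       kappa = 5,
                       tumor_purity = 0.6,
                       tumor_fraction = 0.1,
                       background_weights = NULL,
                       delta = 0.5,
                       n_dmr = list(det_hyper = 4, det_hypo = 4,
                                    too_hyper_per_type = 2,
                                    too_hypo_per_type = 2,
                                    tissue_hyper_per_type = 2,
                                    tissue_hypo_per_type = 2)) {
  if (kappa <= 0) stop("kappa must be > 0")
  if (any(tumor_fraction < 0 | tumor_fraction > 1)) {
    stop("tumor_fraction must lie in [0, 1]")
  }
  if (depth < 1) stop("depth must be >= 1")
  if (delta < 0 || delta > 1) stop("delta must lie in [0, 1]")
  if (is.null(background_weights)) {
    background_weights <- setNames(rep(1 / length(classes),
                                       length(classes)), classes)
    if ("liver" %in% classes && length(classes) > 1L) {
      background_weights[] <- 0.45 / (length(classes) - 1)
      background_weights["liver"] <- 0.55
    }
  }
  background_weights <- background_weights / sum(background_weights)
  structure(as.list(environment()), class = "sim_config")
}

#' Build a toy reference whose MspI digest is a known region set
#'
#' Constructs one synthetic chromosome in which `CCGG` motifs are placed so
#' that in-silico digestion yields exactly `n_regions` regions below 350 bp,
#' each carrying a CpG count drawn from `cpg_range` (one CpG comes from the
#' `CGG` every region starts with; the rest are planted `CG` dinucleotides
#' flanked by A/T so no spurious cut site can arise). Digesting the
#' returned sequence with [digest_reference()] reproduces the returned
#' region table exactly.
#'
#' @param seed integer seed.
#' @param n_regions number of regions (>= 1).
#' @param cpg_range inclusive CpG-count range per region.
#' @param region_len_range inclusive region length range (bp).
#' @param chrom chromosome name.
#' @return `list(ref, regions)`: a [Biostrings::DNAStringSet] and the
#'   matching region table.
#' @export
make_toy_reference <- function(seed = 1, n_regions = 200,
                               cpg_range = c(3, 8),
                               region_len_range = c(60, 300),
                               chrom = "chrSim") {
  stopifnot(n_regions >= 1, cpg_range[1L] >= 1,
            region_len_range[2L] < 350)
  # region = "CGG" + body + "C"; body holds (n_cpg - 1) "CG" tokens,
  # each flanked by A/T filler
  min_len <- 4L + 3L * (cpg_range[2L] - 1L) + 2L
  if (region_len_range[1L] < min_len) {
    stop("region_len_range too short for cpg_range (need >= ", min_len, ")")
  }
  set.seed(seed)
  lens <- sample(seq(region_len_range[1L], region_len_range[2L]),
                 n_regions, replace = TRUE)
  ncpg <- sample(seq(cpg_range[1L], cpg_range[2L]), n_regions,
                 replace = TRUE)
  pad <- function(n) paste(sample(c("A", "T"), n, replace = TRUE),
                           collapse = "")
  bodies <- vapply(seq_len(n_regions), function(i) {
    n_cg <- ncpg[i] - 1L
    body_len <- lens[i] - 4L
    n_runs <- n_cg + 1L
    run_len <- rep(1L, n_runs)
    extra <- body_len - 2L * n_cg - n_runs
    if (extra > 0L) {
      add <- tabulate(sample.int(n_runs, extra, replace = TRUE), n_runs)
      run_len <- run_len + add
    }
    runs <- vapply(run_len, pad, "")
    paste0(paste0(runs[seq_len(n_cg)], "CG", collapse = ""), runs[n_runs])
  }, "")
  seq <- paste0(pad(20L), "CCGG",
                paste0(substr(bodies, 1L, nchar(bodies)), "CCGG",
                       collapse = ""),
                pad(20L))
  # region i content is "CGG" + body + "C"; bodies were built to
  # length len - 4, so reconstruct coordinates from motif placement
  full <- Biostrings::DNAStringSet(seq)
  names(full) <- chrom
  regions <- digest_reference(full)
  stopifnot(nrow(regions) == n_regions,
            all(regions$n_cpg == ncpg))
  list(ref = full, regions = regions)
}

# build the per-region, per-source methylation level matrix and the
# planted-DMR registry
.make_truth_levels <- function(cfg, regions) {
  set.seed(.subseed(cfg$seed, 2L))
  R <- nrow(regions)
  classes <- cfg$classes
  n <- cfg$n_dmr
  need <- n$det_hyper + n$det_hypo +
    length(classes) * (n$too_hyper_per_type + n$too_hypo_per_type +
                         n$tissue_hyper_per_type + n$tissue_hypo_per_type)
  if (need > R) stop("more planted DMRs than regions")
  slots <- sample.int(R, need)
  take <- function(k) {
    if (k == 0L) return(integer(0))
    out <- slots[seq_len(k)]
    slots <<- slots[-seq_len(k)]
    out
  }
  reg_dmr <- list()
  plant <- function(kind, type, direction, idx) {
    if (length(idx) == 0L) return()
    reg_dmr[[length(reg_dmr) + 1L]] <<- data.table(
      region_id = regions$region_id[idx], kind = kind,
      type = type %||% NA_character_, direction = direction,
      delta = cfg$delta)
  }
  det_hyper <- take(n$det_hyper); det_hypo <- take(n$det_hypo)
  plant("detection", NULL, "hyper", det_hyper)
  plant("detection", NULL, "hypo", det_hypo)
  too <- list(); tis <- list()
  for (ty in classes) {
    too[[ty]] <- list(hyper = take(n$too_hyper_per_type),
                      hypo = take(n$too_hypo_per_type))
    tis[[ty]] <- list(hyper = take(n$tissue_hyper_per_type),
                      hypo = take(n$tissue_hypo_per_type))
    plant("too", ty, "hyper", too[[ty]]$hyper)
    plant("too", ty, "hypo", too[[ty]]$hypo)
    plant("tissue", ty, "hyper", tis[[ty]]$hyper)
    plant("tissue", ty, "hypo", tis[[ty]]$hypo)
  }
  dmr <- if (length(reg_dmr)) rbindlist(reg_dmr) else
    data.table(region_id = character(), kind = character(),
               type = character(), direction = character(),
               delta = numeric())

  # bimodal baseline methylome; planted hyper targets sit on unmethylated
  # CpG-island-like baselines, hypo targets on highly methylated
  # repeat-like baselines, mirroring where such markers live in real
  # methylomes
  b <- ifelse(runif(R) < 0.5, rbeta(R, 1.5, 8), rbeta(R, 8, 1.5))
  b <- pmin(pmax(b, 0.03), 0.97)
  hyper_idx <- match(dmr[direction == "hyper"]$region_id,
                     regions$region_id)
  hypo_idx <- match(dmr[direction == "hypo"]$region_id, regions$region_id)
  b[hyper_idx] <- runif(length(hyper_idx), 0.02, 0.08)
  b[hypo_idx] <- runif(length(hypo_idx), 0.92, 0.98)

  sources <- c(paste0(classes, "_normal"), paste0(classes, "_tumor"))
  L <- matrix(rep(b, length(sources)), nrow = R,
              dimnames = list(regions$region_id, sources))
  shift <- function(v, idx, dir) {
    d <- ifelse(dir == "hyper", cfg$delta, -cfg$delta)
    v[idx] <- pmin(pmax(v[idx] + d, 0), 1)
    v
  }
  for (ty in classes) {
    nm <- paste0(ty, "_normal")
    L[, nm] <- shift(L[, nm], tis[[ty]]$hyper, "hyper")
    L[, nm] <- shift(L[, nm], tis[[ty]]$hypo, "hypo")
    # tumors inherit their tissue's normal methylome
    L[, paste0(ty, "_tumor")] <- L[, nm]
  }
  for (ty in classes) {
    tm <- paste0(ty, "_tumor")
    L[, tm] <- shift(L[, tm], det_hyper, "hyper")
    L[, tm] <- shift(L[, tm], det_hypo, "hypo")
    L[, tm] <- shift(L[, tm], too[[ty]]$hyper, "hyper")
    L[, tm] <- shift(L[, tm], too[[ty]]$hypo, "hypo")
  }
  list(levels = L, dmr = dmr)
}

#' Simulate the reads of one sample
#'
#' Each region receives `depth` reads. A read draws its source from
#' `mixture` (a named probability vector over the columns of
#' `truth$levels`), a molecule methylation level from the beta-binomial
#' molecule model around the source's region level, and a methylated-CpG
#' count from a binomial over the region's CpGs. Fragments span their whole
#' region (digested-fragment behaviour).
#'
#' @param truth `list(levels, regions)`: level matrix (regions x sources)
#'   and region table.
#' @param mixture either a single source name (pure sample) or a named
#'   numeric vector of source weights summing to 1.
#' @param depth reads per region.
#' @param kappa beta-binomial concentration (> 0).
#' @param seed integer seed.
#' @param sample_id sample id stamped on the reads.
#' @return read `data.table` in [parse_reads()] format.
#' @export
simulate_sample <- function(truth, mixture, depth = 30, kappa = 5,
                            seed = 1, sample_id = "S1") {
  if (kappa <= 0) stop("kappa must be > 0")
  if (is.character(mixture)) {
    mixture <- setNames(1, mixture)
  }
  if (!all(names(mixture) %in% colnames(truth$levels))) {
    stop("mixture refers to unknown sources: ",
         paste(setdiff(names(mixture), colnames(truth$levels)),
               collapse = ", "))
  }
  stopifnot(abs(sum(mixture) - 1) < 1e-8, all(mixture >= 0))
  regions <- as.data.table(truth$regions)
  R <- nrow(regions)
  n <- R * depth
  set.seed(seed)
  # quantile-coupled generation: each read consumes exactly three uniforms
  # (source, molecule level, methylated-CpG count), so cohorts differing
  # only in mixture weights (e.g. tumor fraction) share all remaining
  # randomness — a common-random-numbers design that makes dose-response
  # comparisons across tumor fractions low-variance
  u_src <- runif(n); u_mol <- runif(n); u_meth <- runif(n)
  cw <- cumsum(mixture) / sum(mixture)
  src <- names(mixture)[findInterval(u_src, cw, left.open = TRUE) + 1L]
  ridx <- rep(seq_len(R), each = depth)
  m <- truth$levels[cbind(ridx, match(src, colnames(truth$levels)))]
  mstar <- numeric(n)
  mid <- m > 0 & m < 1
  mstar[mid] <- stats::qbeta(u_mol[mid], m[mid] * kappa,
                             (1 - m[mid]) * kappa)
  mstar[m <= 0] <- 0
  mstar[m >= 1] <- 1
  ncpg <- regions$n_cpg[ridx]
  meth <- stats::qbinom(u_meth, ncpg, mstar)
  data.table(sample_id = sample_id,
             chrom = regions$chrom[ridx],
             start = regions$start[ridx],
             end = regions$end[ridx],
             n_cpg_meth = meth,
             n_cpg_total = ncpg)
}

#' Simulate a full cohort
#'
#' Generates, per type: paired tumor and adjacent-normal tissues (tumor
#' tissue reads are a purity-weighted mixture of tumor and matched normal
#' methylomes), normal solid tissues, and cancer plasma (tumor reads at the
#' configured tumor fraction over a tissue-blended background); plus
#' noncancer plasma (pure background). Fully determined by the config seed.
#'
#' @param cfg [sim_config()].
#' @return list of class `cfalpha_cohort`: `reads`, `meta`, `regions`,
#'   `ref` (toy reference), `truth` (`levels`, `dmr`, `cfg`).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  toy <- make_toy_reference(.subseed(cfg$seed, 1L), cfg$n_regions,
                            cfg$cpg_range, cfg$region_len_range)
  tl <- .make_truth_levels(cfg, toy$regions)
  truth <- list(levels = tl$levels, dmr = tl$dmr, regions = toy$regions,
                cfg = cfg)
  classes <- cfg$classes
  bg <- cfg$background_weights[classes]
  names(bg) <- paste0(classes, "_normal")

  specs <- list()
  add <- function(sample_id, material, type, condition, pair_id, mixture) {
    specs[[length(specs) + 1L]] <<- list(
      sample_id = sample_id, material = material, type = type,
      condition = condition, pair_id = pair_id, mixture = mixture)
  }
  for (ty in classes) {
    nm <- paste0(ty, "_normal"); tm <- paste0(ty, "_tumor")
    for (i in seq_len(cfg$n_pairs_per_type)) {
      pid <- sprintf("%s_P%02d", ty, i)
      add(sprintf("%s_T%02d", ty, i), "tissue", ty, "tumor", pid,
          setNames(c(cfg$tumor_purity, 1 - cfg$tumor_purity), c(tm, nm)))
      add(sprintf("%s_N%02d", ty, i), "tissue", ty, "adjacent_normal", pid,
          setNames(1, nm))
    }
    for (i in seq_len(cfg$n_normal_per_type)) {
      add(sprintf("%s_NT%02d", ty, i), "tissue", ty, "normal_tissue", "",
          setNames(1, nm))
    }
  }
  tf <- rep_len(cfg$tumor_fraction,
                cfg$n_cancer_plasma_per_type * length(classes))
  k <- 0L
  for (ty in classes) {
    tm <- paste0(ty, "_tumor")
    for (i in seq_len(cfg$n_cancer_plasma_per_type)) {
      k <- k + 1L
      f <- tf[k]
      add(sprintf("%s_PL%02d", ty, i), "plasma", ty, "cancer", "",
          c(setNames(f, tm), (1 - f) * bg))
    }
  }
  for (i in seq_len(cfg$n_noncancer_plasma)) {
    add(sprintf("NC_PL%03d", i), "plasma", "", "noncancer", "", bg)
  }

  reads <- rbindlist(lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    simulate_sample(truth, sp$mixture, depth = cfg$depth,
                    kappa = cfg$kappa,
                    seed = .subseed(cfg$seed, 1000L + i),
                    sample_id = sp$sample_id)
  }))
  meta <- rbindlist(lapply(specs, function(sp) data.table(
    sample_id = sp$sample_id, material = sp$material, type = sp$type,
    condition = sp$condition, pair_id = sp$pair_id, cohort_role = "",
    raw_read_count = cfg$n_regions * cfg$depth)))
  validate_metadata(meta)
  structure(list(reads = reads, meta = meta, regions = toy$regions,
                 ref = toy$ref, truth = truth),
            class = "cfalpha_cohort")
}

#' Write a cohort to disk (reads TSV, metadata TSV, FASTA, regions BED,
#' truth JSON)
#'
#' @param cohort `cfalpha_cohort`.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_reads(cohort$reads, file.path(dir, "reads.tsv"))
  fwrite(cohort$meta, file.path(dir, "metadata.tsv"), sep = "\t")
  Biostrings::writeXStringSet(cohort$ref, file.path(dir, "reference.fa"))
  write_regions_bed(cohort$regions, file.path(dir, "regions.bed"),
                    file.path(dir, "regions_info.tsv"))
  truth <- list(
    dmr = cohort$truth$dmr,
    levels = as.data.frame(cohort$truth$levels),
    region_id = rownames(cohort$truth$levels))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
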