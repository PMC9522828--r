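#' Per-read alpha-value
#'
#' The alpha-value of a sequencing read is the fraction of methylated CpGs
#' among all CpG sites the read covers. Reads covering fewer than `min_cpg`
#' CpG sites carry an almost binary, noisy alpha and are excluded (`NA`);
#' reads with zero covered CpGs are always excluded.
#'
#' @param n_cpg_meth methylated CpG calls in the read (vectorised).
#' @param n_cpg_total CpG sites covered by the read (vectorised).
#' @param min_cpg minimum CpG sites required to compute alpha (default 3).
#' @return numeric vector in `[0, 1]`, `NA` for excluded reads.
#' @examples
#' alpha_value(3, 4, min_cpg = 1)  # 0.75
#' @export
alpha_value <- function(n_cpg_meth, n_cpg_total, min_cpg = 3) {
  if (any(n_cpg_meth < 0 | n_cpg_total < 0, na.rm = TRUE)) {
    stop("negative CpG counts")
  }
  if (any(n_cpg_meth > n_cpg_total, na.rm = TRUE)) {
    stop("n_cpg_meth exceeds n_cpg_total")
  }
  ifelse(n_cpg_total >= pmax(min_cpg, 1L),
         n_cpg_meth / n_cpg_total, NA_real_)
}

.read_cols <- c("sample_id", "chrom", "start", "end",
                "n_cpg_meth", "n_cpg_total")

#' Parse a per-read methylation TSV
#'
#' The canonical interchange format is a (optionally gzipped) TSV with
#' header columns `sample_id, chrom, start, end, n_cpg_meth, n_cpg_total`;
#' one row per deduplicated fragment (read pairs merged into fragments by
#' the upstream caller). Records with `n_cpg_meth > n_cpg_total` or
#' `end <= start` are rejected and counted, not fatal.
#'
#' @param path file path.
#' @return validated `data.table` of reads; the number of rejected records
#'   is attached as `attr(, "n_rejected")` and reported via `message()`.
#' @export
parse_reads <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  missing <- setdiff(.read_cols, names(dt))
  if (length(missing) > 0L) {
    stop("read TSV is missing column(s): ", paste(missing, collapse = ", "))
  }
  dt <- dt[, .SD, .SDcols = .read_cols]
  bad <- dt$n_cpg_meth > dt$n_cpg_total | dt$end <= dt$start |
    dt$n_cpg_meth < 0 | dt$n_cpg_total < 0
  n_bad <- sum(bad)
  if (n_bad > 0L) {
    message(n_bad, " malformed read record(s) rejected")
    dt <- dt[!bad]
  }
  setattr(dt, "n_rejected", n_bad)
  dt[]
}

#' Write reads in the canonical per-read TSV format
#' @param reads read table.
#' @param path output path (".gz" suffix gzips).
#' @return invisibly, `path`.
#' @export
write_reads <- function(reads, path) {
  fwrite(as.data.table(reads)[, .SD, .SDcols = .read_cols], path, sep = "\t")
  invisible(path)
}

.meta_cols <- c("sample_id", "material", "type", "condition", "pair_id",
                "cohort_role", "raw_read_count")

#' Parse a sample metadata TSV
#'
#' Required columns: `sample_id`; `material` (`tissue`/`plasma`); `type`
#' (tissue or cancer type, empty for noncancer plasma); `condition`
#' (`tumor`, `adjacent_normal`, `normal_tissue`, `cancer`, `noncancer`);
#' `pair_id` (links a tumor to its adjacent normal; empty otherwise);
#' `cohort_role` (`discovery`, `reference_plasma`, `train`, `test`, or empty
#' when roles are assigned per run); `raw_read_count` (total mapped
#' deduplicated fragments, the sequencing-depth normaliser). `stage` is
#' optional.
#'
#' @param path TSV path.
#' @return validated metadata `data.table`.
#' @export
parse_metadata <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE,
              colClasses = list(character = c(
                "sample_id", "material", "type", "condition", "pair_id",
                "cohort_role")))
  missing <- setdiff(.meta_cols, names(dt))
  if (length(missing) > 0L) {
    stop("metadata TSV is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  validate_metadata(dt)
  dt[]
}

#' Validate metadata invariants
#' @param meta metadata table.
#' @return invisibly `TRUE`; stops on violation.
#' @export
validate_metadata <- function(meta) {
  meta <- as.data.table(meta)
  if (anyDuplicated(meta$sample_id)) stop("duplicated sample_id in metadata")
  if (any(meta$raw_read_count <= 0)) stop("raw_read_count must be > 0")
  paired <- meta$material == "tissue" &
    meta$condition %in% c("tumor", "adjacent_normal")
  has_pair <- !is.na(meta$pair_id) & meta$pair_id != ""
  if (any(paired & !has_pair)) {
    stop("tumor/adjacent_normal tissue samples must carry pair_id")
  }
  if (any(!paired & has_pair)) {
    stop("pair_id is only meaningful for tumor/adjacent_normal tissues")
  }
  invisible(TRUE)
}

#' Build per-region alpha-value distributions
#'
#' Assigns each read to a marker unit region by the midpoint rule, computes
#' its alpha-value, and returns the long table of retained read-level
#' alphas. One row is one read's alpha in one region for one sample; the
#' multiset of rows sharing (`region_id`, `sample_id`) is that sample's
#' alpha-value distribution in that region.
#'
#' @param reads read table ([parse_reads()] format).
#' @param regions region table ([digest_regions()]).
#' @param min_cpg per-read CpG floor for alpha ([alpha_value()]).
#' @return keyed `data.table` (`region_id`, `sample_id`, `alpha`) of class
#'   `alpha_table`; `attr(, "summary")` counts `included`,
#'   `excluded_min_cpg` and `outside_region` reads
#'   (included + excluded + outside = parsed total).
#' @export
build_distributions <- function(reads, regions, min_cpg = 3) {
  reads <- as.data.table(reads)
  if (nrow(reads) == 0L) {
    at <- data.table(region_id = character(), sample_id = character(),
                     alpha = numeric())
  } else {
    a <- alpha_value(reads$n_cpg_meth, reads$n_cpg_total, min_cpg)
    rid <- assign_region(reads, regions)
    keep <- !is.na(a) & !is.na(rid)
    at <- data.table(region_id = rid[keep],
                     sample_id = as.character(reads$sample_id)[keep],
                     alpha = a[keep])
  }
  setkey(at, region_id, sample_id)
  smry <- list(
    included = nrow(at),
    excluded_min_cpg = if (nrow(reads)) sum(is.na(alpha_value(
      reads$n_cpg_meth, reads$n_cpg_total, min_cpg))) else 0L,
    outside_region = 0L)
  smry$outside_region <- nrow(reads) - smry$included - smry$excluded_min_cpg
  setattr(at, "summary", smry)
  setattr(at, "class", c("alpha_table", class(at)))
  at[]
}

#' Extract one alpha-value distribution
#'
#' @param at `alpha_table` from [build_distributions()].
#' @param region,sample selectors (`region_id` / `sample_id` values).
#' @return numeric vector of read alpha-values (possibly empty).
#' @export
alpha_distribution <- function(at, region, sample) {
  at[J(region, sample), nomatch = NULL]$alpha
}
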