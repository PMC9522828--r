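#' Normalised log-transformed directional read count
#'
#' The profile value of one marker is the directional read count normalised
#' by the sample's sequencing depth and log-transformed:
#' `ln(1e9 * count / raw_total + 1)`, where `raw_total` is the sample's raw
#' mapped deduplicated fragment count.
#'
#' @param count directional reads at the marker (vectorised).
#' @param raw_total raw read count of the sample's genome (> 0).
#' @return numeric, `>= 0`; 0 exactly when `count` is 0.
#' @examples
#' profile_value(1, 1e9)  # log(2)
#' @export
profile_value <- function(count, raw_total) {
  if (any(raw_total <= 0)) stop("raw_total must be > 0")
  if (any(count < 0)) stop("count must be >= 0")
  log(1e9 * count / raw_total + 1)
}

#' Build one sample's feature profile over a marker panel
#'
#' For each marker, counts the sample's reads that are directional at the
#' marker's own learned alpha threshold (its hyper- or hypomethylated,
#' i.e. tumor- or tissue-derived reads) and applies [profile_value()].
#'
#' @param at alpha table covering the sample.
#' @param sample sample id.
#' @param marker_set `marker_set` defining markers, thresholds, directions.
#' @param raw_total the sample's raw mapped fragment count.
#' @return named numeric vector aligned to the marker-set order, with
#'   attributes `sample_id` and `panel_hash`.
#' @export
build_profile <- function(at, sample, marker_set, raw_total) {
  mat <- build_profile_matrix(at, sample, marker_set,
                              setNames(raw_total, sample))
  structure(mat[1L, ], sample_id = sample,
            panel_hash = attr(mat, "panel_hash"))
}

#' Build the samples-by-markers profile matrix for one marker type
#'
#' @param at alpha table.
#' @param samples character vector of sample ids (matrix rows).
#' @param marker_set `marker_set` (matrix columns, in panel order).
#' @param raw_totals named numeric vector of raw read counts per sample.
#' @return numeric matrix `samples x markers` with `panel_hash` attribute.
#' @export
build_profile_matrix <- function(at, samples, marker_set, raw_totals) {
  marker_set <- as.data.table(marker_set)
  if (anyNA(raw_totals[samples])) stop("raw_totals missing for some samples")
  mat <- matrix(0, nrow = length(samples), ncol = nrow(marker_set),
                dimnames = list(samples, marker_set$region_id))
  if (nrow(marker_set) > 0L && length(samples) > 0L) {
    sub <- at[sample_id %in% samples][region_id %in% marker_set$region_id]
    if (nrow(sub) > 0L) {
      sub <- merge(sub,
                   marker_set[, .(region_id, alpha_thr, direction)],
                   by = "region_id")
      dirc <- ifelse(sub$direction == "hyper",
                     sub$alpha >= sub$alpha_thr,
                     sub$alpha <= sub$alpha_thr)
      cnt <- data.table(region_id = sub$region_id,
                        sample_id = sub$sample_id,
                        d = dirc)[, .(k = sum(d)),
                                  by = c("region_id", "sample_id")]
      cnt <- cnt[k > 0]
      if (nrow(cnt) > 0L) {
        ij <- cbind(match(cnt$sample_id, samples),
                    match(cnt$region_id, marker_set$region_id))
        mat[ij] <- profile_value(cnt$k, raw_totals[cnt$sample_id])
      }
    }
  }
  structure(mat, panel_hash = panel_hash(marker_set))
}

#' Fingerprint of a marker panel
#'
#' Profiles built against different panels must never be mixed; the hash of
#' (region ids, directions, thresholds) travels with every profile matrix
#' and model and is checked at prediction time.
#'
#' @param marker_set `marker_set`.
#' @return hexadecimal string.
#' @export
panel_hash <- function(marker_set) {
  ms <- as.data.table(marker_set)
  content_hash(list(ms$region_id, ms$direction,
                    round(ms$alpha_thr, 10)))
}

#' Build the four feature-profile matrices for a task
#'
#' @param at alpha table.
#' @param samples sample ids (rows of every matrix).
#' @param panels `marker_panels` from [build_marker_panels()].
#' @param raw_totals named raw read counts.
#' @param task `"detection"` or `"too"`: selects which cancer-specific
#'   panels feed the cancer views; the tissue views are shared.
#' @return named list of 4 matrices: `cancer_hyper`, `cancer_hypo`,
#'   `tissue_hyper`, `tissue_hypo`.
#' @export
build_profile_views <- function(at, samples, panels, raw_totals,
                                task = c("detection", "too")) {
  task <- match.arg(task)
  sets <- c(panels[[task]], panels$tissue)
  lapply(sets, function(ms)
    build_profile_matrix(at, samples, ms, raw_totals))
}

#' Write a profile matrix as TSV (samples x markers)
#' @param mat profile matrix.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_profile_matrix <- function(mat, path) {
  dt <- data.table(sample_id = rownames(mat))
  dt <- cbind(dt, as.data.table(mat))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}
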