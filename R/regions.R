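#' Locate MspI cut sites on the plus strand of a sequence
#'
#' MspI recognises `CCGG` and cuts between the first and second base
#' (`C|CGG`). Because the motif is its own reverse complement, scanning the
#' plus strand finds every cut site on both strands. Positions carrying IUPAC
#' ambiguity codes (including `N`) never match.
#'
#' @param seq a DNA sequence: a character scalar or a
#'   [Biostrings::DNAString].
#' @param chrom sequence (chromosome) name attached to the result.
#' @return a `data.table` with columns `chrom` and `pos`, one row per cut
#'   site, sorted by `pos`. `pos` is the 0-based coordinate of the cut point,
#'   i.e. `motif_start + 1`, so the 4-mer starting at `pos - 1` is `CCGG`.
#' @examples
#' find_cut_sites("ACCGGT", "toy")   # one cut at pos 2
#' @export
find_cut_sites <- function(seq, chrom = "chr") {
  if (is.character(seq)) {
    if (length(seq) != 1L) stop("`seq` must be a single sequence")
    if (nchar(seq) == 0L) {
      return(data.table(chrom = character(), pos = integer()))
    }
    seq <- tryCatch(Biostrings::DNAString(toupper(seq)),
                    error = function(e) stop("non-DNA alphabet in `seq`: ",
                                             conditionMessage(e)))
  }
  if (length(seq) == 0L) {
    return(data.table(chrom = character(), pos = integer()))
  }
  m <- Biostrings::matchPattern("CCGG", seq, fixed = TRUE)
  # 1-based motif start s -> 0-based motif start s-1 -> cut at (s-1)+1 = s
  pos <- BiocGenerics::start(m)
  data.table(chrom = rep(chrom, length(pos)), pos = sort(as.integer(pos)))
}

#' Digest a chromosome into marker unit regions
#'
#' A marker unit region is the interval between two adjacent MspI cut sites
#' that is shorter than `max_len` (strictly). Coordinates are 0-based
#' half-open; both boundaries are cut coordinates, so each region starts with
#' `CGG...` and ends with `...C`. Regions overlapping a run of `n_run_len` or
#' more `N` bases are dropped when the sequence is supplied.
#'
#' @param cut_sites result of [find_cut_sites()] (single chromosome), or an
#'   integer vector of cut coordinates.
#' @param seq optional sequence (character or `DNAString`) used to count CpG
#'   dinucleotides per region and to apply the N-run filter; when `NULL`,
#'   `n_cpg` is `NA` and no N filtering happens.
#' @param max_len regions of `end - start >= max_len` are discarded
#'   (default 350 bp, strict).
#' @param n_run_len minimum N-run length that disqualifies a region.
#' @param chrom chromosome name when `cut_sites` is a bare vector.
#' @return `data.table` with columns `chrom`, `start`, `end`, `region_id`
#'   (`"chrom:start-end"`), `length`, `n_cpg`; disjoint and sorted.
#' @export
digest_regions <- function(cut_sites, seq = NULL, max_len = 350,
                           n_run_len = 10, chrom = "chr") {
  if (is.data.frame(cut_sites)) {
    if (nrow(cut_sites) == 0L) return(.empty_regions())
    stopifnot(length(unique(cut_sites$chrom)) == 1L)
    chrom <- cut_sites$chrom[1L]
    pos <- as.integer(cut_sites$pos)
  } else {
    pos <- as.integer(cut_sites)
  }
  pos <- sort(pos)
  if (length(pos) < 2L) return(.empty_regions())
  reg <- data.table(chrom = chrom,
                    start = pos[-length(pos)],
                    end   = pos[-1L])
  reg <- reg[end - start < max_len]
  if (nrow(reg) == 0L) return(.empty_regions())
  if (!is.null(seq)) {
    if (is.character(seq)) seq <- Biostrings::DNAString(toupper(seq))
    # CpG dinucleotides fully inside [start, end): 0-based CG start in
    # [start, end - 2]
    cg0 <- BiocGenerics::start(
      Biostrings::matchPattern("CG", seq, fixed = TRUE)) - 1L
    cg0 <- sort(cg0)
    reg[, n_cpg := findInterval(end - 2L, cg0) - findInterval(start - 1L, cg0)]
    # N runs >= n_run_len disqualify overlapping regions
    nhit <- Biostrings::matchPattern("N", seq, fixed = TRUE)
    if (length(nhit) > 0L) {
      runs <- IRanges::reduce(IRanges::IRanges(BiocGenerics::start(nhit),
                                               BiocGenerics::end(nhit)))
      runs <- runs[IRanges::width(runs) >= n_run_len]
      if (length(runs) > 0L) {
        rr <- IRanges::IRanges(reg$start + 1L, reg$end)  # 1-based closed
        keep <- IRanges::countOverlaps(rr, runs) == 0L
        reg <- reg[keep]
      }
    }
  } else {
    reg[, n_cpg := NA_integer_]
  }
  reg[, `:=`(region_id = paste0(chrom, ":", start, "-", end),
             length = end - start)]
  setcolorder(reg, c("chrom", "start", "end", "region_id", "length", "n_cpg"))
  reg[]
}

.empty_regions <- function() {
  data.table(chrom = character(), start = integer(), end = integer(),
             region_id = character(), length = integer(),
             n_cpg = integer())
}

#' Digest a whole reference into marker unit regions
#'
#' Convenience wrapper running [find_cut_sites()] and [digest_regions()] on
#' every sequence of a reference.
#'
#' @param ref a [Biostrings::DNAStringSet], a named character vector of
#'   sequences, or a path to a FASTA file.
#' @inheritParams digest_regions
#' @return `data.table` of regions across all sequences.
#' @export
digest_reference <- function(ref, max_len = 350, n_run_len = 10) {
  if (is.character(ref) && length(ref) == 1L && file.exists(ref)) {
    ref <- Biostrings::readDNAStringSet(ref)
    names(ref) <- sub("\\s.*$", "", names(ref))
  }
  if (is.character(ref)) ref <- Biostrings::DNAStringSet(toupper(ref))
  if (is.null(names(ref))) names(ref) <- paste0("chr", seq_along(ref))
  out <- lapply(names(ref), function(ch) {
    cs <- find_cut_sites(ref[[ch]], ch)
    digest_regions(cs, seq = ref[[ch]], max_len = max_len,
                   n_run_len = n_run_len, chrom = ch)
  })
  rbindlist(out)
}

#' Assign fragments to marker unit regions by midpoint
#'
#' A fragment belongs to the region containing its midpoint
#' (`floor((start + end) / 2)`, 0-based); fragments whose midpoint falls
#' outside every region are unassigned (`NA`).
#'
#' @param fragments `data.frame`/`data.table` with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param regions region table from [digest_regions()].
#' @return character vector of `region_id` (or `NA`) parallel to `fragments`.
#' @export
assign_region <- function(fragments, regions) {
  fragments <- as.data.table(fragments)
  if (nrow(fragments) == 0L) return(character(0))
  if (any(fragments$end <= fragments$start)) {
    stop("fragments with end <= start are invalid")
  }
  if (nrow(regions) == 0L) return(rep(NA_character_, nrow(fragments)))
  mid0 <- (fragments$start + fragments$end) %/% 2L
  q <- GenomicRanges::GRanges(fragments$chrom,
                              IRanges::IRanges(mid0 + 1L, width = 1L))
  s <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start + 1L,
                                               regions$end))
  hit <- GenomicRanges::findOverlaps(q, s, select = "first")
  regions$region_id[hit]
}

#' Write regions as BED4 plus a sidecar TSV
#'
#' @param regions region table.
#' @param bed_path output BED4 path (chrom, start, end, region_id).
#' @param sidecar_path optional TSV with `region_id`, `length`, `n_cpg`.
#' @return invisibly, `bed_path`.
#' @export
write_regions_bed <- function(regions, bed_path,
                              sidecar_path = NULL) {
  fwrite(regions[, .(chrom, start, end, region_id)], bed_path, sep = "\t",
         col.names = FALSE)
  if (!is.null(sidecar_path)) {
    fwrite(regions[, .(region_id, length, n_cpg)], sidecar_path, sep = "\t")
  }
  invisible(bed_path)
}

#' Read a BED4 region file (with optional sidecar)
#' @param bed_path BED4 file written by [write_regions_bed()].
#' @param sidecar_path optional sidecar TSV with `n_cpg` and `length`.
#' @return region `data.table`.
#' @export
read_regions_bed <- function(bed_path, sidecar_path = NULL) {
  reg <- fread(bed_path, header = FALSE,
               col.names = c("chrom", "start", "end", "region_id"))
  reg[, length := end - start]
  if (!is.null(sidecar_path)) {
    side <- fread(sidecar_path)
    reg <- merge(reg, side[, .(region_id, n_cpg)], by = "region_id",
                 sort = FALSE)
  } else {
    reg[, n_cpg := NA_integer_]
  }
  setcolorder(reg, c("chrom", "start", "end", "region_id", "length", "n_cpg"))
  reg[]
}
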