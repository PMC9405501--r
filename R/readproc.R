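#' Alignment tibbles
#'
#' Mapped reads are plain tibbles with columns `read_id`, `scaffold`,
#' `start` (0-based), `aligned_length`, `mapq`, `baseq` (Phred+33 string, one
#' character per aligned base) and `is_duplicate`, sorted by scaffold then
#' start. [simulate_mapped_reads()] produces them; [read_alignments()] reads
#' them from SAM/BAM.
#'
#' @name alignments
NULL

aln_cols <- c("read_id", "scaffold", "start", "aligned_length", "mapq",
              "baseq", "is_duplicate")

check_alignments <- function(aln, sorted = FALSE) {
  missing <- setdiff(aln_cols, names(aln))
  if (length(missing) > 0)
    abort(paste("alignment tibble lacks columns:", paste(missing, collapse = ", ")))
  if (sorted) {
    o <- order(aln$scaffold, aln$start)
    if (!identical(o, seq_len(nrow(aln))))
      abort("alignments must be sorted by (scaffold, start)",
            class = "sexratio_unsorted")
  }
  invisible(aln)
}

#' Filter alignments on mapping quality and duplicate flag
#'
#' Keeps records with `mapq >= min_mapq` that are not flagged as duplicates;
#' the standard pre-sexing filter drops everything under MAPQ 30.
#'
#' @param aln Alignment tibble.
#' @param min_mapq Minimum mapping quality retained.
#' @return Filtered alignment tibble.
#' @export
filter_alignments <- function(aln, min_mapq = 30) {
  check_alignments(aln)
  aln[aln$mapq >= min_mapq & !aln$is_duplicate, ]
}

#' Mark PCR/optical-style duplicates
#'
#' Among records sharing (scaffold, start, aligned_length) — a single-end
#' 5'-position key — all but one are flagged as duplicates. The survivor is
#' the record with the highest summed base quality; ties break on the
#' lexicographically smallest `read_id`, so the result is deterministic.
#'
#' @param aln Alignment tibble, sorted by (scaffold, start).
#' @return The tibble with `is_duplicate` set.
#' @export
mark_duplicates <- function(aln) {
  check_alignments(aln, sorted = TRUE)
  if (nrow(aln) == 0) return(aln)
  qsum <- baseq_sums(aln$baseq)
  # within each (scaffold, start, length) group: best qsum first, then
  # smallest read_id; everything after the first is a duplicate
  o <- order(aln$scaffold, aln$start, aln$aligned_length, -qsum, aln$read_id)
  key <- paste(aln$scaffold, aln$start, aln$aligned_length, sep = "\r")
  dup <- logical(nrow(aln))
  dup[o] <- duplicated(key[o])
  aln$is_duplicate <- dup
  aln
}

# summed Phred scores of quality strings
baseq_sums <- function(baseq) {
  vapply(baseq, function(q) sum(utf8ToInt(q)) - 33L * nchar(q), numeric(1),
         USE.NAMES = FALSE)
}

#' Downsample to an exact number of mapped reads
#'
#' Uniform sampling without replacement, re-sorted by coordinate;
#' deterministic per seed. Emulates reducing sequencing effort to a fixed
#' mapped-read count.
#'
#' @param aln Alignment tibble.
#' @param n Number of records to keep.
#' @param seed Integer seed.
#' @return Downsampled, coordinate-sorted alignment tibble.
#' @export
downsample_alignments <- function(aln, n, seed = 1) {
  check_alignments(aln)
  if (n < 1) abort("n must be >= 1", class = "sexratio_bad_params")
  if (n > nrow(aln))
    abort(sprintf("insufficient reads: requested %d but only %d available (deficit %d)",
                  n, nrow(aln), n - nrow(aln)),
          class = "sexratio_insufficient_reads")
  idx <- withr::with_seed(seed, sample.int(nrow(aln), n))
  dplyr::arrange(aln[idx, ], .data$scaffold, .data$start)
}

#' Per-base depth with base- and mapping-quality filters
#'
#' Computes, for every position of every scaffold, the number of alignment
#' records covering it whose mapping quality is at least `min_mapq` and whose
#' base quality at that position is at least `min_baseq` (the samtools-depth
#' convention). Positions covered by no passing base have depth 0; at very
#' low read counts almost all sites are 0 and they still count toward mean
#' coverage.
#'
#' @param aln Alignment tibble.
#' @param scaffold_lengths Named numeric vector of scaffold lengths.
#' @param min_mapq,min_baseq Quality thresholds (default 25/25).
#' @return A `depth_tracks` object: concatenated per-scaffold depth vector
#'   plus offsets, queryable with [depth_at()] or [depth_over_regions()].
#' @export
depth_tracks <- function(aln, scaffold_lengths, min_mapq = 25, min_baseq = 25) {
  check_alignments(aln)
  scafs <- names(scaffold_lengths)
  lens <- as.integer(scaffold_lengths)
  offsets <- c(0L, cumsum(lens))[seq_along(lens)]
  idx <- match(aln$scaffold, scafs)
  if (anyNA(idx)) abort("alignment on a scaffold absent from scaffold_lengths")
  depth <- cpp_depth_concat(idx, as.integer(aln$start), aln$baseq,
                            as.integer(aln$mapq), offsets, lens,
                            as.integer(min_mapq), as.integer(min_baseq),
                            sum(lens))
  structure(list(depth = depth, offsets = stats::setNames(offsets, scafs),
                 lengths = stats::setNames(lens, scafs),
                 min_mapq = min_mapq, min_baseq = min_baseq),
            class = "depth_tracks")
}

#' @export
print.depth_tracks <- function(x, ...) {
  cat(sprintf("<depth_tracks> %d scaffolds, %.2f Mb, mean depth %.4f (mapq>=%d, baseq>=%d)\n",
              length(x$lengths), sum(x$lengths) / 1e6, mean(x$depth),
              x$min_mapq, x$min_baseq))
  invisible(x)
}

#' Depth at specific sites
#'
#' @param tracks A [depth_tracks()] object.
#' @param scaffold,pos Parallel vectors of scaffold names and 0-based
#'   positions.
#' @return Integer vector of depths.
#' @export
depth_at <- function(tracks, scaffold, pos) {
  off <- tracks$offsets[scaffold]
  len <- tracks$lengths[scaffold]
  if (anyNA(off) || any(pos < 0) || any(pos >= len))
    abort("site outside the scaffold space", class = "sexratio_bad_site")
  tracks$depth[off + pos + 1]
}

#' Restrict a depth track to a region set
#'
#' Returns a depth accessor bound to a compartment (a region set or a list of
#' whole scaffolds); site queries outside the compartment are errors, and the
#' compartment's linearized coordinate space is what [sample_sites()] draws
#' from.
#'
#' @param tracks A [depth_tracks()] object (or an alignment tibble, in which
#'   case `scaffold_lengths`, `min_mapq` and `min_baseq` are used to build
#'   one).
#' @param regions Region tibble, or a character vector of scaffold names
#'   meaning the full scaffolds.
#' @param scaffold_lengths,min_mapq,min_baseq Used only when `tracks` is an
#'   alignment tibble.
#' @return A `depth_accessor` object.
#' @export
depth_over_regions <- function(tracks, regions, scaffold_lengths = NULL,
                               min_mapq = 25, min_baseq = 25) {
  if (is.data.frame(tracks)) {
    tracks <- depth_tracks(tracks, scaffold_lengths, min_mapq, min_baseq)
  }
  stopifnot(inherits(tracks, "depth_tracks"))
  if (is.character(regions)) {
    regions <- scaffolds_as_regions(regions, tracks$lengths)
  }
  if (nrow(regions) == 0)
    abort("empty region set", class = "sexratio_empty_compartment")
  regions <- merge_regions(regions)
  validate_regions(regions, tracks$lengths)
  acc <- list(tracks = tracks, regions = regions,
              total_length = sum(regions$end - regions$start))
  # linearized per-site depths of the compartment, precomputed once so
  # replicate draws are plain integer indexing
  acc$depths <- with(acc, {
    starts <- tracks$offsets[regions$scaffold] + regions$start + 1
    tracks$depth[sequence(as.integer(regions$end - regions$start),
                          from = as.integer(starts))]
  })
  structure(acc, class = "depth_accessor")
}

#' @export
print.depth_accessor <- function(x, ...) {
  cat(sprintf("<depth_accessor> %d intervals, %.0f kb, mean depth %.4f\n",
              nrow(x$regions), x$total_length / 1e3, mean(accessor_depths(x))))
  invisible(x)
}

# all depths of the compartment, in linearized region order
accessor_depths <- function(acc) acc$depths

# map linear compartment indices (1-based) to (scaffold, pos, depth)
accessor_sites <- function(acc, lin_idx) {
  reg <- acc$regions
  cum <- c(0, cumsum(reg$end - reg$start))
  iv <- findInterval(lin_idx - 1, cum, rightmost.closed = FALSE)
  pos <- reg$start[iv] + (lin_idx - 1 - cum[iv])
  tibble(scaffold = reg$scaffold[iv], pos = pos, depth = acc$depths[lin_idx])
}
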