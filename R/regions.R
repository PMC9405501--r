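#' Region sets: genomic intervals in BED coordinates
#'
#' A region set is a tibble with columns `scaffold` (character), `start` and
#' `end` (0-based, half-open integers), one row per interval. These helpers
#' merge, subtract and intersect region sets with BED semantics; the interval
#' arithmetic itself is delegated to [GenomicRanges].
#'
#' @param regions,x,y Region tibbles with columns `scaffold`, `start`, `end`.
#' @name regions
NULL

new_regions <- function(scaffold = character(), start = integer(),
                        end = integer()) {
  tibble(scaffold = as.character(scaffold),
         start = as.numeric(start), end = as.numeric(end))
}

validate_regions <- function(regions, scaffold_lengths = NULL) {
  stopifnot(is.data.frame(regions),
            all(c("scaffold", "start", "end") %in% names(regions)))
  bad <- which(!(regions$start >= 0 & regions$start < regions$end))
  if (length(bad) > 0) {
    abort(sprintf("invalid interval at row %d: start=%s end=%s (need 0 <= start < end)",
                  bad[1], format(regions$start[bad[1]], scientific = FALSE),
                  format(regions$end[bad[1]], scientific = FALSE)),
          class = "sexratio_bad_interval")
  }
  if (!is.null(scaffold_lengths)) {
    len <- scaffold_lengths[regions$scaffold]
    if (anyNA(len) || any(regions$end > len)) {
      abort("interval outside scaffold bounds", class = "sexratio_bad_interval")
    }
  }
  invisible(regions)
}

regions_to_granges <- function(regions, seqlevels = NULL) {
  GenomicRanges::GRanges(
    seqnames = factor(regions$scaffold,
                      levels = seqlevels %||% unique(regions$scaffold)),
    ranges = IRanges::IRanges(start = regions$start + 1, end = regions$end)
  )
}

granges_to_regions <- function(gr) {
  tibble(scaffold = as.character(GenomicRanges::seqnames(gr)),
         start = as.numeric(GenomicRanges::start(gr)) - 1,
         end = as.numeric(GenomicRanges::end(gr))) |>
    dplyr::arrange(.data$scaffold, .data$start)
}

#' @describeIn regions Merge overlapping or bookended intervals per scaffold.
#' @return A region tibble (`scaffold`, `start`, `end`), sorted.
#' @export
merge_regions <- function(regions) {
  if (nrow(regions) == 0) return(new_regions())
  validate_regions(regions)
  granges_to_regions(GenomicRanges::reduce(regions_to_granges(regions)))
}

#' @describeIn regions Subtract the intervals of `y` from those of `x`.
#' @export
subtract_regions <- function(x, y) {
  if (nrow(x) == 0) return(new_regions())
  if (nrow(y) == 0) return(merge_regions(x))
  lv <- union(x$scaffold, y$scaffold)
  granges_to_regions(GenomicRanges::setdiff(regions_to_granges(x, lv),
                                            regions_to_granges(y, lv)))
}

#' @describeIn regions Intersection of two region sets.
#' @export
intersect_regions <- function(x, y) {
  if (nrow(x) == 0 || nrow(y) == 0) return(new_regions())
  lv <- union(x$scaffold, y$scaffold)
  granges_to_regions(GenomicRanges::intersect(regions_to_granges(x, lv),
                                              regions_to_granges(y, lv)))
}

#' @describeIn regions Total number of bases covered (after merging).
#' @export
regions_total_length <- function(regions) {
  if (nrow(regions) == 0) return(0)
  m <- merge_regions(regions)
  sum(m$end - m$start)
}

#' Whole scaffolds as a region set
#'
#' Convenience for treating a list of scaffolds (e.g. the autosomal
#' compartment) as full-length intervals.
#'
#' @param scaffolds Character vector of scaffold names.
#' @param scaffold_lengths Named numeric vector of scaffold lengths.
#' @return A region tibble covering each scaffold end to end.
#' @export
scaffolds_as_regions <- function(scaffolds, scaffold_lengths) {
  len <- scaffold_lengths[scaffolds]
  if (anyNA(len)) abort("unknown scaffold in `scaffolds`")
  new_regions(scaffolds, 0, len)
}
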