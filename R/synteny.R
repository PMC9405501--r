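#' Drop scaffolds shorter than a minimum length
#'
#' Short scaffolds carry little syntenic signal and inflate compute; the
#' standard preprocessing drops everything under 10 kb before partitioning.
#'
#' @param assembly A named [Biostrings::DNAStringSet].
#' @param min_length Minimum scaffold length retained (bp).
#' @return The filtered assembly, original order preserved.
#' @export
filter_short_scaffolds <- function(assembly, min_length = 10000) {
  stopifnot(min_length >= 0)
  keep <- Biostrings::width(assembly) >= min_length
  if (!any(keep))
    abort("no scaffolds pass the length filter; nothing to partition",
          class = "sexratio_empty_assembly")
  assembly[keep]
}

#' Build a canonical k-mer anchor index over donor sex chromosomes
#'
#' Indexes every strand-canonical k-mer of the donor X and Y assemblies,
#' recording its positions and source label. K-mers occurring more than
#' `max_occ` times across both donors are dropped as repetitive.
#'
#' @param ref_x,ref_y Donor X and Y assemblies ([Biostrings::DNAStringSet];
#'   `ref_y` may be empty when no Y donor is available).
#' @param k Odd k-mer size in `[15, 31]`.
#' @param max_occ Maximum occurrences before a k-mer is masked as repetitive.
#' @return An `anchor_index` object (opaque; query with [map_scaffold()]).
#' @export
build_anchor_index <- function(ref_x, ref_y = Biostrings::DNAStringSet(),
                               k = 21, max_occ = 4) {
  if (k %% 2 == 0 || k < 15 || k > 31)
    abort("k must be odd and in [15, 31]", class = "sexratio_bad_params")
  seqs <- c(as.character(ref_x), as.character(ref_y))
  labels <- c(rep("X", length(ref_x)), rep("Y", length(ref_y)))
  ptr <- cpp_build_anchor_index(unname(seqs), k, max_occ)
  structure(list(ptr = ptr, k = k, max_occ = max_occ, labels = labels,
                 seq_names = names(seqs)),
            class = "anchor_index")
}

#' @export
print.anchor_index <- function(x, ...) {
  cat(sprintf("<anchor_index> k=%d max_occ=%d over %d donor sequence(s) (%d distinct k-mers)\n",
              x$k, x$max_occ, length(x$labels), cpp_index_size(x$ptr)))
  invisible(x)
}

# Greedy left-to-right collinear chaining of anchors within one
# (label, donor sequence, strand) group. Anchors sorted by (qpos, s*rpos);
# a chain extends while 0 <= dq <= gap and 0 < s*dr <= gap.
chain_group <- function(qpos, rpos, strand, chain_gap) {
  o <- order(qpos, strand * rpos)
  q <- qpos[o]; r <- rpos[o]
  dq <- diff(q)
  dr <- strand * diff(r)
  brk <- dq > chain_gap | dr <= 0 | dr > chain_gap
  chain <- cumsum(c(TRUE, brk))
  list(qpos = q, chain = chain)
}

#' Map one scaffold onto the donor sex chromosomes
#'
#' Looks up every canonical k-mer of the scaffold in the anchor index, groups
#' hits by donor label, donor sequence and strand, and chains collinear
#' anchors: consecutive anchors must be within `chain_gap` on both sequences
#' with monotone offsets (increasing on the forward strand, decreasing on the
#' reverse). Chains with at least `min_chain_anchors` anchors are emitted as
#' scaffold intervals spanning the first anchor start to the last anchor end.
#'
#' @param scaffold A single sequence (character or `DNAString`).
#' @param index An [build_anchor_index()] result.
#' @param chain_gap Maximum gap (bp) between consecutive anchors of a chain.
#' @param min_chain_anchors Minimum anchors per reported chain.
#' @return Tibble of labeled scaffold intervals (`start`, `end`, `label`,
#'   `n_anchors`), 0-based half-open; empty when nothing chains.
#' @export
map_scaffold <- function(scaffold, index, chain_gap = 5000,
                         min_chain_anchors = 5) {
  stopifnot(inherits(index, "anchor_index"))
  scaffold <- as.character(scaffold)
  if (nchar(scaffold) < index$k)
    abort("scaffold shorter than k", class = "sexratio_bad_params")
  hits <- cpp_query_anchors(index$ptr, scaffold)
  empty <- tibble(start = numeric(), end = numeric(),
                  label = character(), n_anchors = integer())
  if (nrow(hits) == 0) return(empty)
  hits$label <- index$labels[hits$ref_seq]
  k <- index$k

  out <- hits |>
    dplyr::group_by(.data$label, .data$ref_seq, .data$strand) |>
    dplyr::group_modify(function(d, key) {
      ch <- chain_group(d$qpos, d$rpos, key$strand, chain_gap)
      tibble(qpos = ch$qpos, chain = ch$chain)
    }) |>
    dplyr::group_by(.data$label, .data$ref_seq, .data$strand, .data$chain) |>
    dplyr::summarise(start = min(.data$qpos), end = max(.data$qpos) + k,
                     n_anchors = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n_anchors >= min_chain_anchors) |>
    dplyr::select("start", "end", "label", "n_anchors") |>
    dplyr::arrange(.data$label, .data$start)
  out
}

#' Partition a reference assembly into X-linked, Y-linked and autosomal parts
#'
#' Runs the anchor-chaining mapper over every scaffold of a (length-filtered)
#' reference, merges syntenic intervals per label, then removes any
#' coordinates shared between the X and Y interval sets — the pseudoautosomal
#' mask. Scaffolds with no sex-linked interval at all form the autosomal
#' complement; scaffolds whose every sex-linked interval is masked away (pure
#' pseudoautosomal scaffolds) are excluded from both compartments. Scaffolds
#' whose name matches `mito_pattern` are dropped before partitioning.
#'
#' @param refgen Reference assembly ([Biostrings::DNAStringSet]).
#' @param ref_x,ref_y Donor X / Y assemblies.
#' @param min_length Minimum scaffold length (bp) retained before mapping.
#' @param k,max_occ,chain_gap,min_chain_anchors Mapper parameters; see
#'   [build_anchor_index()] and [map_scaffold()].
#' @param mito_pattern Regex for mitochondrial scaffold names to drop.
#' @return A `scaffold_partition`: list with `x_regions` / `y_regions`
#'   (region tibbles after masking), `autosomal_scaffolds` (character),
#'   `excluded_scaffolds` (pure-PAR scaffolds), `scaffold_lengths` (named
#'   vector over retained scaffolds) and `provenance` (parameters).
#' @export
partition_assembly <- function(refgen, ref_x, ref_y = Biostrings::DNAStringSet(),
                               min_length = 10000, k = 21, max_occ = 4,
                               chain_gap = 5000, min_chain_anchors = 5,
                               mito_pattern = "MT|mito") {
  refgen <- refgen[!grepl(mito_pattern, names(refgen), ignore.case = TRUE)]
  refgen <- filter_short_scaffolds(refgen, min_length)
  index <- build_anchor_index(ref_x, ref_y, k = k, max_occ = max_occ)

  scafs <- names(refgen)
  lens <- stats::setNames(as.numeric(Biostrings::width(refgen)), scafs)
  seqs <- as.character(refgen)
  raw <- purrr::map_dfr(scafs, function(nm) {
    iv <- map_scaffold(seqs[[nm]], index, chain_gap = chain_gap,
                       min_chain_anchors = min_chain_anchors)
    if (nrow(iv) == 0) return(NULL)
    iv$scaffold <- nm
    iv
  })
  if (nrow(raw) == 0)
    abort(paste("no synteny anchors shared with the donor sex chromosomes;",
                "the donor may be too divergent"),
          class = "sexratio_no_anchors")

  x_raw <- merge_regions(raw[raw$label == "X", c("scaffold", "start", "end")])
  y_raw <- merge_regions(raw[raw$label == "Y", c("scaffold", "start", "end")])
  shared <- intersect_regions(x_raw, y_raw)
  x_regions <- subtract_regions(x_raw, shared)
  y_regions <- subtract_regions(y_raw, shared)

  sex_linked <- unique(raw$scaffold) # pre-mask ownership decides the complement
  autosomal <- setdiff(scafs, sex_linked)
  surviving <- union(unique(x_regions$scaffold), unique(y_regions$scaffold))
  excluded <- setdiff(sex_linked, surviving)

  structure(list(
    x_regions = x_regions, y_regions = y_regions,
    autosomal_scaffolds = autosomal, excluded_scaffolds = excluded,
    scaffold_lengths = lens,
    provenance = list(min_length = min_length, k = k, max_occ = max_occ,
                      chain_gap = chain_gap,
                      min_chain_anchors = min_chain_anchors,
                      mito_pattern = mito_pattern,
                      n_scaffolds = length(scafs))
  ), class = "scaffold_partition")
}

#' @export
print.scaffold_partition <- function(x, ...) {
  cat(sprintf(
    paste0("<scaffold_partition> %d scaffolds: %d X-bearing (%.0f kb), ",
           "%d Y-bearing (%.0f kb), %d autosomal, %d excluded (pure PAR)\n"),
    length(x$scaffold_lengths),
    length(unique(x$x_regions$scaffold)), regions_total_length(x$x_regions) / 1e3,
    length(unique(x$y_regions$scaffold)), regions_total_length(x$y_regions) / 1e3,
    length(x$autosomal_scaffolds), length(x$excluded_scaffolds)))
  invisible(x)
}

#' Score partition recovery against simulation truth
#'
#' For simulated references, compares a partition with the known scaffold
#' origins: the fraction of X-origin bases labeled X, and the fraction of
#' autosome-origin bases mislabeled as X or Y.
#'
#' @param partition A [partition_assembly()] result.
#' @param truth_map The `truth_map` tibble from [derive_reference()].
#' @return One-row tibble: `x_recovery`, `autosome_mislabel`,
#'   `xy_overlap_length`.
#' @export
partition_recovery <- function(partition, truth_map) {
  tm <- truth_map[truth_map$scaffold %in% names(partition$scaffold_lengths), ]
  x_scafs <- tm$scaffold[tm$source_class == "X"]
  a_scafs <- tm$scaffold[tm$source_class == "autosome"]
  x_total <- sum(tm$source_end[tm$source_class == "X"] -
                   tm$source_start[tm$source_class == "X"])
  a_total <- sum(tm$source_end[tm$source_class == "autosome"] -
                   tm$source_start[tm$source_class == "autosome"])
  sex_iv <- dplyr::bind_rows(partition$x_regions, partition$y_regions)
  tibble(
    x_recovery = regions_total_length(
      partition$x_regions[partition$x_regions$scaffold %in% x_scafs, ]) / x_total,
    autosome_mislabel = regions_total_length(
      sex_iv[sex_iv$scaffold %in% a_scafs, ]) / a_total,
    xy_overlap_length = regions_total_length(
      intersect_regions(partition$x_regions, partition$y_regions))
  )
}
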