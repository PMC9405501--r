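#' Read and write assemblies as FASTA
#'
#' Thin wrappers over [Biostrings] so sequences round-trip exactly.
#'
#' @param assembly A named [Biostrings::DNAStringSet].
#' @param path FASTA path.
#' @name assembly_io
NULL

#' @rdname assembly_io
#' @export
write_assembly <- function(assembly, path) {
  Biostrings::writeXStringSet(assembly, path)
  invisible(path)
}

#' @rdname assembly_io
#' @export
read_assembly <- function(path) {
  a <- Biostrings::readDNAStringSet(path)
  # keep only the first word of each FASTA header, as mappers do
  names(a) <- sub("\\s.*$", "", names(a))
  a
}

#' Write alignments as a SAM file
#'
#' Coordinate-sorted single-end SAM with `@HD`/`@SQ` headers. Read sequences
#' are taken from a `seq` column if present, otherwise written as `*`.
#'
#' @param aln Alignment tibble.
#' @param path Output path (`.sam`).
#' @param scaffold_lengths Named vector of scaffold lengths for the header.
#' @return The path, invisibly.
#' @export
write_sam <- function(aln, path, scaffold_lengths) {
  check_alignments(aln)
  aln <- dplyr::arrange(aln, .data$scaffold, .data$start)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(scaffold_lengths),
                      as.integer(scaffold_lengths)))
  flag <- ifelse(aln$is_duplicate, 1024L, 0L)
  seq <- if ("seq" %in% names(aln)) aln$seq else "*"
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
                  aln$read_id, flag, aln$scaffold, as.integer(aln$start) + 1L,
                  as.integer(aln$mapq), as.integer(aln$aligned_length),
                  seq, aln$baseq)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read alignments from SAM or BAM
#'
#' SAM input is converted with [Rsamtools::asBam()] and read back through
#' [Rsamtools::scanBam()]; secondary/supplementary records are skipped and
#' the duplicate bit of the FLAG populates `is_duplicate`.
#'
#' @param path A `.sam` or `.bam` file.
#' @return An alignment tibble sorted by (scaffold, start).
#' @export
read_alignments <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "qwidth", "mapq", "qual", "flag"),
    flag = flags)
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  tibble(read_id = b$qname,
         scaffold = as.character(b$rname),
         start = as.numeric(b$pos) - 1,
         aligned_length = as.numeric(b$qwidth),
         mapq = as.integer(b$mapq),
         baseq = as.character(b$qual),
         is_duplicate = bitwAnd(b$flag, 1024L) > 0) |>
    dplyr::arrange(.data$scaffold, .data$start)
}

#' Write and read scaffold partitions
#'
#' A partition is serialized as `x_linked.bed` and `y_linked.bed` (BED3,
#' 0-based half-open, tab-separated, no header), `autosomal_scaffolds.txt`
#' (one name per line), `scaffold_lengths.tsv` and a `provenance.json`
#' sidecar. The round-trip is lossless; overlapping intervals in an input
#' BED are merged on read, and malformed lines are rejected with their line
#' number.
#'
#' @param partition A `scaffold_partition`.
#' @param dir Output (or input) directory.
#' @name partition_io
#' @export
write_partition <- function(partition, dir) {
  stopifnot(inherits(partition, "scaffold_partition"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bed(partition$x_regions, file.path(dir, "x_linked.bed"))
  write_bed(partition$y_regions, file.path(dir, "y_linked.bed"))
  writeLines(partition$autosomal_scaffolds,
             file.path(dir, "autosomal_scaffolds.txt"))
  readr::write_tsv(tibble(scaffold = names(partition$scaffold_lengths),
                          length = unname(partition$scaffold_lengths)),
                   file.path(dir, "scaffold_lengths.tsv"))
  jsonlite::write_json(
    c(partition$provenance,
      list(excluded_scaffolds = partition$excluded_scaffolds)),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' @rdname partition_io
#' @export
read_partition <- function(dir) {
  lens_df <- readr::read_tsv(file.path(dir, "scaffold_lengths.tsv"),
                             col_types = "cd")
  lens <- stats::setNames(lens_df$length, lens_df$scaffold)
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"),
                              simplifyVector = TRUE)
  excluded <- prov$excluded_scaffolds %||% character()
  prov$excluded_scaffolds <- NULL
  structure(list(
    x_regions = read_bed(file.path(dir, "x_linked.bed")),
    y_regions = read_bed(file.path(dir, "y_linked.bed")),
    autosomal_scaffolds = readLines(file.path(dir, "autosomal_scaffolds.txt")),
    excluded_scaffolds = as.character(excluded),
    scaffold_lengths = lens,
    provenance = prov
  ), class = "scaffold_partition")
}

#' Read and write BED3 interval files
#'
#' Three tab-separated columns (`scaffold`, `start`, `end`), 0-based
#' half-open, no header. Reading merges overlapping intervals and rejects
#' malformed rows (non-numeric coordinates, `start >= end`) with the
#' offending line number.
#'
#' @param regions Region tibble.
#' @param path BED path.
#' @name bed_io
#' @export
write_bed <- function(regions, path) {
  readr::write_tsv(
    tibble(scaffold = regions$scaffold,
           start = format(regions$start, scientific = FALSE, trim = TRUE),
           end = format(regions$end, scientific = FALSE, trim = TRUE)),
    path, col_names = FALSE)
  invisible(path)
}

#' @rdname bed_io
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) return(new_regions())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    ok <- length(p) >= 3 && !is.na(suppressWarnings(as.numeric(p[2]))) &&
      !is.na(suppressWarnings(as.numeric(p[3]))) &&
      as.numeric(p[2]) < as.numeric(p[3]) && as.numeric(p[2]) >= 0
    if (!ok)
      abort(sprintf("malformed BED line %d in %s: %s", i, path, lines[i]),
            class = "sexratio_bed_parse")
  }
  reg <- tibble(scaffold = vapply(parts, `[`, "", 1),
                start = as.numeric(vapply(parts, `[`, "", 2)),
                end = as.numeric(vapply(parts, `[`, "", 3)))
  merge_regions(reg)
}

#' Write a sex call to JSON and TSV
#'
#' The JSON carries the full call (replicate ratios, mean, call, parameters,
#' provenance); the TSV one row per replicate.
#'
#' @param call A `sex_call`.
#' @param path_json,path_tsv Output paths (`NULL` skips).
#' @return The call, invisibly.
#' @export
write_sex_call <- function(call, path_json = NULL, path_tsv = NULL) {
  stopifnot(inherits(call, "sex_call"))
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(individual_id = call$individual_id,
           replicate_ratios = call$replicate_ratios,
           mean_ratio = call$mean_ratio,
           call = call$call,
           n_mapped_reads_used = call$n_mapped_reads_used,
           params = unclass(call$params),
           provenance = call$provenance),
      path_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(path_tsv)) readr::write_tsv(tidy(call), path_tsv)
  invisible(call)
}

#' Write a depth table over a region set
#'
#' One row per site: `scaffold`, `pos0`, `depth`.
#'
#' @param accessor A [depth_over_regions()] accessor.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_depth_table <- function(accessor, path) {
  stopifnot(inherits(accessor, "depth_accessor"))
  sites <- accessor_sites(accessor, seq_len(accessor$total_length))
  readr::write_tsv(
    tibble(scaffold = sites$scaffold, pos0 = sites$pos, depth = sites$depth),
    path)
  invisible(path)
}
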