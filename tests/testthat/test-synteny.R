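test_that("scaffolds under the length cutoff are removed, boundary kept", {
  a <- Biostrings::DNAStringSet(c(s1 = random_seq(9999, 1),
                                  s2 = random_seq(10000, 2),
                                  s3 = random_seq(50000, 3)))
  kept <- filter_short_scaffolds(a, 10000)
  expect_identical(names(kept), c("s2", "s3"))
  expect_identical(names(filter_short_scaffolds(a, 0)), names(a))
  expect_error(filter_short_scaffolds(a, 1e6),
               class = "sexratio_empty_assembly")
})

test_that("anchor index canonicalizes strands and masks repetitive k-mers", {
  donor <- random_seq(3000, 10)
  idx <- build_anchor_index(Biostrings::DNAStringSet(c(X = donor)), k = 15)
  # a forward fragment and its reverse complement both map, on opposite strands
  frag <- substr(donor, 501, 1500)
  iv_f <- map_scaffold(frag, idx, chain_gap = 100, min_chain_anchors = 5)
  iv_r <- map_scaffold(revcomp(frag), idx, chain_gap = 100, min_chain_anchors = 5)
  expect_equal(nrow(iv_f), 1)
  expect_equal(nrow(iv_r), 1)
  expect_gt(iv_f$end[1] - iv_f$start[1], 0.9 * nchar(frag))
  expect_gt(iv_r$end[1] - iv_r$start[1], 0.9 * nchar(frag))

  # a k-mer repeated 5 times with max_occ 4 anchors nothing
  unit <- random_seq(15, 99)
  rep5 <- paste(c(rep(unit, 5)), collapse = "")
  idx5 <- build_anchor_index(Biostrings::DNAStringSet(c(X = rep5)),
                             k = 15, max_occ = 4)
  hits <- map_scaffold(unit, idx5, chain_gap = 10, min_chain_anchors = 1)
  expect_equal(nrow(hits), 0)
  # with a permissive max_occ the same k-mer anchors five times
  idx6 <- build_anchor_index(Biostrings::DNAStringSet(c(X = rep5)),
                             k = 15, max_occ = 5)
  hits6 <- map_scaffold(unit, idx6, chain_gap = 10, min_chain_anchors = 1)
  expect_equal(sum(hits6$n_anchors), 5)

  expect_error(build_anchor_index(Biostrings::DNAStringSet(c(X = donor)), k = 16),
               class = "sexratio_bad_params")
})

test_that("an exact donor substring yields one near-full-length interval; random sequence yields none", {
  g <- small_genome()
  idx <- build_anchor_index(g$seq["chrX"], g$seq["chrY"])
  frag <- substr(as.character(g$seq[["chrX"]]), 30001, 80000)
  iv <- map_scaffold(frag, idx)
  expect_equal(unique(iv$label), "X")
  expect_gt(regions_total_length(iv[, c("start", "end")] |>
                                   dplyr::mutate(scaffold = "q")),
            0.9 * nchar(frag))

  noise <- random_seq(20000, 1234)
  expect_equal(nrow(map_scaffold(noise, idx)), 0)
})

test_that("chained intervals agree with the exhaustive substring-table oracle", {
  withr::with_seed(77, {
    donor_x <- random_seq(6000, 101)
    donor_y_specific <- random_seq(2500, 102)
    par <- substr(donor_x, 1, 800)
    donor_y <- paste0(par, donor_y_specific)
    # scaffold: X fragment + noise + reverse-complemented X fragment + PAR piece
    scaffold <- paste0(substr(donor_x, 1001, 2600), random_seq(700, 103),
                       revcomp(substr(donor_x, 3501, 4600)),
                       substr(donor_y, 201, 900))
    k <- 15
    idx <- build_anchor_index(Biostrings::DNAStringSet(c(X = donor_x)),
                              Biostrings::DNAStringSet(c(Y = donor_y)),
                              k = k, max_occ = 4)
    got <- map_scaffold(scaffold, idx, chain_gap = 400, min_chain_anchors = 5)
    want <- oracle_map_scaffold(scaffold, list(donor_x, donor_y), c("X", "Y"),
                                k = k, max_occ = 4, chain_gap = 400,
                                min_chain_anchors = 5)
    expect_equal(as.data.frame(got[, c("start", "end", "label")]),
                 as.data.frame(want[, c("start", "end", "label")]))
    # the PAR piece is seen under both labels over the same coordinates
    expect_setequal(unique(got$label), c("X", "Y"))
  })
})

test_that("partitioning separates compartments and masks X/Y-shared coordinates", {
  g <- small_genome()
  ref <- small_reference()
  part <- small_partition()

  expect_equal(regions_total_length(
    intersect_regions(part$x_regions, part$y_regions)), 0)

  tm <- ref$truth_map
  x_scafs <- tm$scaffold[tm$source_class == "X"]
  a_scafs <- tm$scaffold[tm$source_class == "autosome"]
  expect_true(all(part$autosomal_scaffolds %in% a_scafs))
  expect_false(any(part$x_regions$scaffold %in% a_scafs))
  expect_false(any(part$y_regions$scaffold %in% a_scafs))

  rec <- partition_recovery(part, tm)
  expect_gt(rec$x_recovery, 0.9)
  expect_lt(rec$autosome_mislabel, 0.01)
  expect_equal(rec$xy_overlap_length, 0)

  # every retained scaffold lands in exactly one bucket (or is excluded as pure PAR)
  buckets <- c(part$autosomal_scaffolds, part$excluded_scaffolds,
               union(unique(part$x_regions$scaffold),
                     unique(part$y_regions$scaffold)))
  expect_setequal(buckets, names(part$scaffold_lengths))
  expect_equal(anyDuplicated(buckets), 0)
})

test_that("a scaffold lying wholly inside the PAR is excluded from every compartment", {
  g <- small_genome()
  par_len <- g$par_length
  # one pure-PAR scaffold plus one autosomal scaffold
  par_scaf <- substr(as.character(g$seq[["chrX"]]), 1, par_len)
  auto_scaf <- substr(as.character(g$seq[["chrA1"]]), 1, 50000)
  refgen <- Biostrings::DNAStringSet(c(parscaf = par_scaf, autoscaf = auto_scaf))
  part <- partition_assembly(refgen, g$seq["chrX"], g$seq["chrY"],
                             min_length = 1000)
  expect_identical(part$excluded_scaffolds, "parscaf")
  expect_identical(part$autosomal_scaffolds, "autoscaf")
  expect_false("parscaf" %in% c(part$x_regions$scaffold,
                                part$y_regions$scaffold))
})

test_that("with no Y donor, masking is a no-op and partitioning is X-only", {
  g <- small_genome()
  x_frag <- substr(as.character(g$seq[["chrX"]]),
                   g$par_length + 1, g$par_length + 40000)
  refgen <- Biostrings::DNAStringSet(c(
    xscaf = x_frag, ascaf = substr(as.character(g$seq[["chrA2"]]), 1, 40000)))
  part <- partition_assembly(refgen, g$seq["chrX"], min_length = 1000)
  expect_equal(nrow(part$y_regions), 0)
  expect_identical(unique(part$x_regions$scaffold), "xscaf")
  expect_identical(part$autosomal_scaffolds, "ascaf")
})

test_that("mitochondrial scaffolds are dropped before partitioning and divergent donors fail loudly", {
  g <- small_genome()
  refgen <- Biostrings::DNAStringSet(c(
    scaffold_mito = random_seq(16000, 9),
    ascaf = substr(as.character(g$seq[["chrA1"]]), 1, 30000),
    xscaf = substr(as.character(g$seq[["chrX"]]), 30001, 60000)))
  part <- partition_assembly(refgen, g$seq["chrX"], g$seq["chrY"],
                             min_length = 1000)
  expect_false("scaffold_mito" %in% names(part$scaffold_lengths))
  expect_identical(part$autosomal_scaffolds, "ascaf")

  unrelated <- Biostrings::DNAStringSet(c(u = random_seq(30000, 77)))
  expect_error(partition_assembly(unrelated, g$seq["chrX"], g$seq["chrY"],
                                  min_length = 1000),
               class = "sexratio_no_anchors")
})

test_that("partitions round-trip through BED and sidecar files", {
  part <- small_partition()
  dir <- withr::local_tempdir()
  write_partition(part, dir)
  back <- read_partition(dir)
  expect_equal(back$x_regions, part$x_regions)
  expect_equal(back$y_regions, part$y_regions)
  expect_identical(back$autosomal_scaffolds, part$autosomal_scaffolds)
  expect_equal(back$scaffold_lengths, part$scaffold_lengths)

  # malformed BED lines are rejected with their line number
  bad <- file.path(dir, "bad.bed")
  writeLines(c("s1\t0\t100", "s1\t50\t50"), bad)
  expect_error(read_bed(bad), "line 2", class = "sexratio_bed_parse")
  writeLines(c("s1\tzero\t100"), bad)
  expect_error(read_bed(bad), class = "sexratio_bed_parse")
  # overlapping intervals are merged on read
  writeLines(c("s1\t0\t100", "s1\t50\t150"), bad)
  expect_equal(read_bed(bad),
               tibble::tibble(scaffold = "s1", start = 0, end = 150))
})
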