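test_that("the mapping-quality filter keeps MAPQ at or above the cutoff", {
  a <- make_aln("s", c(0, 10, 20, 30), mapq = c(0, 29, 30, 60))
  expect_equal(nrow(filter_alignments(a, 30)), 2)
  expect_equal(nrow(filter_alignments(a, 0)), 4)
  a$is_duplicate <- TRUE
  expect_equal(nrow(filter_alignments(a, 0)), 0)
})

test_that("duplicate marking keeps one read per 5'-position key, deterministically", {
  # two reads at the same key: exactly one survives
  a <- make_aln("s", c(100, 100), len = 50)
  m <- mark_duplicates(a)
  expect_equal(sum(m$is_duplicate), 1)

  # distinct starts: nothing flagged
  expect_equal(sum(mark_duplicates(make_aln("s", c(1, 2, 3)))$is_duplicate), 0)

  # three-way tie on base-quality sum: the lowest read_id survives, and the
  # outcome is invariant to input permutation within the sorted order
  ids <- c("r_b", "r_a", "r_c")
  for (perm in list(1:3, c(2, 1, 3), c(3, 2, 1))) {
    a3 <- make_aln("s", c(5, 5, 5), len = 10, read_id = ids[perm])
    m3 <- mark_duplicates(a3)
    expect_identical(m3$read_id[!m3$is_duplicate], "r_a")
  }

  # higher summed base quality beats read_id
  a4 <- tibble::tibble(read_id = c("r_a", "r_b"), scaffold = "s", start = 5,
                       aligned_length = 10, mapq = 60,
                       baseq = c(strrep("#", 10), strrep("I", 10)),
                       is_duplicate = FALSE)
  expect_identical(mark_duplicates(a4)$read_id[!mark_duplicates(a4)$is_duplicate],
                   "r_b")

  expect_error(mark_duplicates(make_aln("s", c(10, 1))[2:1, ]),
               class = "sexratio_unsorted")
})

test_that("downsampling is exact, seed-deterministic and unbiased", {
  a <- make_aln("s", 0:9999, len = 30)
  expect_equal(dplyr::arrange(downsample_alignments(a, nrow(a), 1), start),
               dplyr::arrange(a, start))
  d1 <- downsample_alignments(a, 1000, seed = 1)
  d2 <- downsample_alignments(a, 1000, seed = 2)
  expect_equal(nrow(d1), 1000)
  expect_false(identical(d1$read_id, d2$read_id))
  expect_identical(downsample_alignments(a, 1000, seed = 1)$read_id, d1$read_id)
  err <- expect_error(downsample_alignments(a, 10001, 1),
                      class = "sexratio_insufficient_reads")
  expect_match(conditionMessage(err), "deficit 1")

  # inclusion frequency of a fixed record over many draws ~ n/N
  small <- make_aln("s", 0:199, len = 30)
  hits <- sum(vapply(1:500, function(s) {
    "r001" %in% downsample_alignments(small, 20, seed = s)$read_id
  }, logical(1)))
  p <- 20 / 200
  expect_lt(abs(hits / 500 - p), 4 * sqrt(p * (1 - p) / 500))
})

test_that("depth honours geometry and both quality thresholds", {
  a <- make_aln("s", 100, len = 50)
  tr <- depth_tracks(a, c(s = 300))
  expect_equal(depth_at(tr, "s", 120), 1L)
  expect_equal(depth_at(tr, "s", 200), 0L)
  expect_equal(depth_at(tr, "s", 99), 0L)
  expect_equal(depth_at(tr, "s", 149), 1L)
  expect_error(depth_at(tr, "s", 300), class = "sexratio_bad_site")

  # MAPQ 20 under a 25 cutoff contributes nowhere
  low <- make_aln("s", 100, len = 50, mapq = 20)
  expect_equal(sum(depth_tracks(low, c(s = 300))$depth), 0)

  # base quality below the cutoff suppresses single positions
  mixed <- make_aln("s", 0, len = 5)
  mixed$baseq <- paste0("II", rawToChar(as.raw(33 + 10)), "II") # Q40,Q40,Q10,Q40,Q40
  trm <- depth_tracks(mixed, c(s = 10), min_baseq = 25)
  expect_equal(as.integer(trm$depth[1:6]), c(1L, 1L, 0L, 1L, 1L, 0L))
})

test_that("depth matches a brute-force interval-stabbing oracle on a random fixture", {
  withr::with_seed(99, {
    a <- make_aln(sample(c("s1", "s2"), 200, TRUE),
                  sample(0:950, 200, TRUE),
                  len = sample(20:50, 200, TRUE),
                  mapq = sample(c(10, 20, 30, 60), 200, TRUE),
                  baseq_char = sample(c("I", "5", "#"), 200, TRUE))
    lens <- c(s1 = 1000, s2 = 1000)
    tr <- depth_tracks(a, lens, min_mapq = 25, min_baseq = 25)
    sites <- tibble::tibble(scaffold = sample(names(lens), 1000, TRUE),
                            pos = sample(0:999, 1000, TRUE))
    got <- depth_at(tr, sites$scaffold, sites$pos)
    want <- vapply(seq_len(nrow(sites)), function(i) {
      oracle_depth(a, sites$scaffold[i], sites$pos[i])
    }, integer(1))
    expect_identical(as.integer(got), want)

    # conservation: total depth equals total passing bases within bounds
    pass <- a[a$mapq >= 25, ]
    n_bases <- sum(vapply(seq_len(nrow(pass)), function(i) {
      q <- utf8ToInt(pass$baseq[i]) - 33L
      sum(q >= 25)
    }, numeric(1)))
    expect_equal(sum(tr$depth), n_bases)

    # monotonicity: raising either threshold never increases depth anywhere
    tr_hi <- depth_tracks(a, lens, min_mapq = 40, min_baseq = 25)
    tr_bq <- depth_tracks(a, lens, min_mapq = 25, min_baseq = 40)
    expect_true(all(tr_hi$depth <= tr$depth))
    expect_true(all(tr_bq$depth <= tr$depth))
  })
})

test_that("downsampling leaves the X-compartment read share unbiased", {
  g <- small_genome()
  ref <- small_reference()
  ind <- simulate_mapped_reads(g, ref, "female", 20000, small_params(), seed = 55)
  full_share <- mean(ind$alignments$origin_class == "X")
  shares <- vapply(1:30, function(s) {
    d <- downsample_alignments(ind$alignments, 2000, seed = s)
    mean(d$origin_class == "X")
  }, numeric(1))
  se <- sqrt(full_share * (1 - full_share) / 2000) / sqrt(30)
  expect_lt(abs(mean(shares) - full_share), 4 * se)
})

test_that("depth accessors bind a compartment and reject sites outside it", {
  a <- make_aln("s", c(0, 40), len = 20)
  tr <- depth_tracks(a, c(s = 100))
  acc <- depth_over_regions(tr, tibble::tibble(scaffold = "s", start = 10,
                                               end = 30))
  expect_equal(acc$total_length, 20)
  expect_equal(length(acc$depths), 20)
  expect_error(depth_over_regions(tr, tibble::tibble(scaffold = character(),
                                                     start = numeric(),
                                                     end = numeric())),
               class = "sexratio_empty_compartment")
  expect_error(depth_over_regions(tr, tibble::tibble(scaffold = "s",
                                                     start = 50, end = 200)),
               class = "sexratio_bad_interval")
})
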