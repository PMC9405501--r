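# Shared small-scale fixtures, built once per test run on first use.
.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(build)
  .fx[[name]]
}

small_params <- function(...) {
  sim_params(n_autosomes = 2, autosome_length = 2e5, x_length = 1e5,
             y_length = 3e4, read_length = 50, target_n50 = 2e5, ...)
}

small_genome <- function() {
  fixture("small_genome", build_truth_genome(small_params(), seed = 11))
}

small_reference <- function() {
  fixture("small_reference", {
    derive_reference(small_genome(), divergence = 0, target_n50 = 2e5, seed = 12)
  })
}

small_partition <- function() {
  fixture("small_partition", {
    ref <- small_reference()
    g <- small_genome()
    partition_assembly(ref$assembly, g$seq["chrX"], g$seq["chrY"],
                       min_length = 1000)
  })
}

# a tiny hand-built alignment tibble
make_aln <- function(scaffold, start, len = 50, mapq = 60, baseq_char = "H",
                     read_id = NULL, is_duplicate = FALSE) {
  n <- max(length(scaffold), length(start))
  scaffold <- rep_len(scaffold, n); start <- rep_len(start, n)
  len <- rep_len(len, n); mapq <- rep_len(mapq, n)
  baseq_char <- rep_len(baseq_char, n)
  tibble::tibble(
    read_id = read_id %||% sprintf("r%03d", seq_len(n)),
    scaffold = scaffold, start = start, aligned_length = len,
    mapq = mapq, baseq = strrep(baseq_char, len),
    is_duplicate = rep_len(is_duplicate, n)
  ) |> dplyr::arrange(scaffold, start)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_seq <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = ""))
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
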