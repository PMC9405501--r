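#' Identify the sex of one individual from mapped reads
#'
#' The full single-individual pipeline: MAPQ filter, duplicate marking and
#' removal, optional downsampling to an exact mapped-read count, per-base
#' depth with base/mapping-quality 25 thresholds, replicated random-site X:A
#' ratios, and classification of the mean ratio. Every seed and parameter is
#' recorded in the returned call's provenance.
#'
#' @param aln Alignment tibble (e.g. a `sim_individual$alignments`, or
#'   [read_alignments()] output).
#' @param partition A [partition_assembly()] result.
#' @param n_reads Downsample to exactly this many mapped reads after
#'   filtering and duplicate removal; `NULL` uses all surviving reads.
#' @param params A [ratio_params()] object.
#' @param min_mapq Pre-filter mapping-quality threshold (default 30).
#' @param depth_min_mapq,depth_min_baseq Quality thresholds of the depth pass
#'   (default 25/25).
#' @param seed Integer seed (downsampling and site replicates).
#' @param id Individual identifier carried into the call.
#' @return A `sex_call` object.
#' @export
identify_sex <- function(aln, partition, n_reads = NULL,
                         params = ratio_params(), min_mapq = 30,
                         depth_min_mapq = 25, depth_min_baseq = 25,
                         seed = 1, id = "individual") {
  stopifnot(inherits(partition, "scaffold_partition"))
  aln <- filter_alignments(aln, min_mapq = min_mapq)
  aln <- mark_duplicates(aln)
  aln <- aln[!aln$is_duplicate, ]
  if (!is.null(n_reads)) {
    aln <- downsample_alignments(aln, n_reads, seed = seed)
  }
  known <- aln$scaffold %in% names(partition$scaffold_lengths)
  tracks <- depth_tracks(aln[known, ], partition$scaffold_lengths,
                         min_mapq = depth_min_mapq, min_baseq = depth_min_baseq)
  if (nrow(partition$x_regions) == 0)
    abort("partition has no X-linked regions", class = "sexratio_empty_compartment")
  if (length(partition$autosomal_scaffolds) == 0)
    abort("partition has no autosomal scaffolds", class = "sexratio_empty_compartment")
  acc_x <- depth_over_regions(tracks, partition$x_regions)
  acc_a <- depth_over_regions(tracks, partition$autosomal_scaffolds)
  ratios <- replicate_ratios(acc_x, acc_a, params = params, seed = seed)
  new_sex_call(id, ratios, params, n_reads %||% nrow(aln),
               provenance = list(seed = seed, min_mapq = min_mapq,
                                 depth_min_mapq = depth_min_mapq,
                                 depth_min_baseq = depth_min_baseq,
                                 partition = partition$provenance))
}

#' Define a factorial sexing experiment
#'
#' A grid crossing reference-assembly variants (target N50 and divergence)
#' with mapped-read counts over a simulated cohort, mirroring the standard
#' design for assessing a sexing method's accuracy against sequencing effort
#' and reference quality.
#'
#' @param read_counts Mapped-read counts to evaluate (descending ladder).
#' @param reference_variants Tibble with columns `label`, `target_n50`,
#'   `divergence`, one row per reference assembly variant.
#' @param n_females,n_males Cohort sizes per cell.
#' @param sim A [sim_params()] object for the underlying genome and reads.
#' @param seed Base integer seed.
#' @return An `experiment_grid` object.
#' @export
experiment_grid <- function(read_counts = c(100000, 50000, 10000, 5000, 2500, 1000),
                            reference_variants = tibble(
                              label = c("contiguous", "fragmented"),
                              target_n50 = c(1e6, 4e4),
                              divergence = c(0, 0)),
                            n_females = 5, n_males = 5,
                            sim = sim_params(), seed = 1) {
  stopifnot(length(read_counts) > 0, nrow(reference_variants) > 0,
            n_females >= 1, n_males >= 1,
            all(c("label", "target_n50", "divergence") %in% names(reference_variants)))
  structure(list(read_counts = sort(unique(read_counts), decreasing = TRUE),
                 reference_variants = reference_variants,
                 n_females = n_females, n_males = n_males,
                 sim = sim, seed = as.integer(seed)),
            class = "experiment_grid")
}

#' Run a factorial sexing experiment
#'
#' Builds one truth genome, derives each reference variant, partitions it
#' against the truth X and Y as donors, simulates the cohort at slightly more
#' than the largest read count, then for every (variant, read count,
#' individual) cell downsamples and runs [identify_sex()]. Cell failures
#' (e.g. insufficient reads) are recorded, not fatal.
#'
#' @param grid An [experiment_grid()] object.
#' @param params Ratio parameters applied to every call.
#' @param quiet Suppress progress messages?
#' @return A `sexing_experiment`: list with `calls` (tibble, one row per
#'   cell) and `report` (the [accuracy_report()] of those calls).
#' @export
run_experiment <- function(grid, params = ratio_params(), quiet = TRUE) {
  stopifnot(inherits(grid, "experiment_grid"))
  genome <- build_truth_genome(grid$sim, seed = grid$seed)
  ref_x <- genome$seq["chrX"]
  ref_y <- genome$seq["chrY"]
  n_max <- max(grid$read_counts)
  n_sim <- n_max + max(1000, ceiling(0.05 * n_max))
  cohort <- tibble(
    true_sex = rep(c("female", "male"), c(grid$n_females, grid$n_males)),
    ind = seq_len(grid$n_females + grid$n_males))

  calls <- purrr::pmap_dfr(grid$reference_variants, function(label, target_n50,
                                                            divergence, ...) {
    if (!quiet) message("reference variant: ", label)
    ref <- derive_reference(genome, divergence = divergence,
                            target_n50 = target_n50,
                            seed = grid$seed + 101L)
    part <- partition_assembly(ref$assembly, ref_x, ref_y)
    purrr::pmap_dfr(cohort, function(true_sex, ind) {
      ind_seed <- grid$seed + 1000L * ind + if (true_sex == "male") 500L else 0L
      indiv <- simulate_mapped_reads(genome, ref, sex = true_sex,
                                     n_reads = n_sim, params = grid$sim,
                                     seed = ind_seed,
                                     id = sprintf("%s_%02d", true_sex, ind))
      purrr::map_dfr(grid$read_counts, function(nr) {
        res <- tryCatch(
          suppressWarnings(identify_sex(indiv$alignments, part, n_reads = nr,
                                        params = params,
                                        seed = ind_seed + nr %% 997L,
                                        id = indiv$id)),
          error = function(e) e)
        if (inherits(res, "error")) {
          tibble(variant = label, read_count = nr, individual_id = indiv$id,
                 true_sex = true_sex, mean_ratio = NA_real_,
                 call = NA_character_, error = conditionMessage(res))
        } else {
          tibble(variant = label, read_count = nr, individual_id = indiv$id,
                 true_sex = true_sex, mean_ratio = res$mean_ratio,
                 call = res$call, error = NA_character_)
        }
      })
    })
  })
  structure(list(calls = calls, report = accuracy_report(calls), grid = grid),
            class = "sexing_experiment")
}

#' @export
print.sexing_experiment <- function(x, ...) {
  cat(sprintf("<sexing_experiment> %d calls over %d variants x %d read counts\n",
              nrow(x$calls), nrow(x$grid$reference_variants),
              length(x$grid$read_counts)))
  print(format_accuracy_cells(x$report))
  invisible(x)
}

#' @export
tidy.sexing_experiment <- function(x, ...) x$calls

#' Dual accuracy accounting over a table of calls
#'
#' For every (variant, read count) cell: the number of correct, undetermined
#' and incorrect calls; strict accuracy (correct over all individuals, so an
#' undetermined call counts against the method) and lenient accuracy (correct
#' over determined individuals only). Failed cells (`NA` call) count as
#' undetermined.
#'
#' @param calls Tibble with columns `variant`, `read_count`, `true_sex`,
#'   `call`.
#' @return An `accuracy_report` tibble, one row per cell.
#' @export
accuracy_report <- function(calls) {
  out <- calls |>
    dplyr::group_by(.data$variant, .data$read_count) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_correct = sum(.data$call == .data$true_sex, na.rm = TRUE),
      n_undetermined = sum(is.na(.data$call) | .data$call == "undetermined"),
      n_incorrect = n - n_correct - n_undetermined,
      accuracy_strict = 100 * n_correct / n,
      accuracy_lenient = ifelse(n == n_undetermined, NA_real_,
                                100 * n_correct / (n - n_undetermined)),
      .groups = "drop") |>
    dplyr::arrange(.data$variant, dplyr::desc(.data$read_count))
  class(out) <- c("accuracy_report", class(out))
  out
}

#' Format accuracy cells in the strict/lenient convention
#'
#' Percentages are rounded to whole numbers; a cell prints a single value
#' when both accountings agree and `"strict/lenient"` (e.g. `"80/89"`) when
#' they differ.
#'
#' @param report An [accuracy_report()] tibble.
#' @return A tibble (`variant`, `read_count`, `cell`).
#' @export
format_accuracy_cells <- function(report) {
  s <- round(report$accuracy_strict)
  l <- round(report$accuracy_lenient)
  cell <- ifelse(is.na(l) | s == l, as.character(s), paste0(s, "/", l))
  tibble(variant = report$variant, read_count = report$read_count, cell = cell)
}

#' Write an accuracy report to TSV and JSON
#'
#' Deterministic serialization: the TSV holds the formatted cells in a
#' variant-by-read-count matrix; the JSON holds the full counts.
#'
#' @param report An [accuracy_report()] tibble.
#' @param path_tsv,path_json Output paths (either may be `NULL` to skip).
#' @return The report, invisibly.
#' @export
write_accuracy_report <- function(report, path_tsv = NULL, path_json = NULL) {
  if (!is.null(path_tsv)) {
    wide <- format_accuracy_cells(report) |>
      tidyr::pivot_wider(names_from = "variant", values_from = "cell") |>
      dplyr::arrange(dplyr::desc(.data$read_count))
    readr::write_tsv(wide, path_tsv)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(as.data.frame(report), path_json,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}

#' Agreement between calls made with two different donor partitions
#'
#' Given two call tables produced from the same individuals and read counts
#' but different donor X/Y partitions, reports the fraction of identical
#' calls and a breakdown of the disagreements.
#'
#' @param calls_a,calls_b Call tibbles (as in `sexing_experiment$calls`).
#' @return One-row tibble: `n_compared`, `fraction_identical`,
#'   `n_contradictory` (female vs male), `n_one_undetermined`.
#' @export
compare_partition_calls <- function(calls_a, calls_b) {
  key <- c("variant", "read_count", "individual_id")
  m <- dplyr::inner_join(calls_a, calls_b, by = key, suffix = c("_a", "_b"))
  determined <- c("female", "male")
  tibble(
    n_compared = nrow(m),
    fraction_identical = mean(m$call_a == m$call_b, na.rm = TRUE),
    n_contradictory = sum(m$call_a %in% determined & m$call_b %in% determined &
                            m$call_a != m$call_b, na.rm = TRUE),
    n_one_undetermined = sum(xor(m$call_a == "undetermined",
                                 m$call_b == "undetermined"), na.rm = TRUE))
}

#' Plot accuracy against sequencing effort
#'
#' One line per reference variant; strict accuracy on the y axis, mapped
#' reads (log scale) on the x axis.
#'
#' @param object An `accuracy_report` (or `sexing_experiment`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.accuracy_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$read_count,
                                       y = .data$accuracy_strict,
                                       colour = .data$variant)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mapped reads", y = "strict accuracy (%)",
                  colour = "reference") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sexing_experiment <- function(object, ...) autoplot(object$report, ...)
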