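#' Parameters of the replicated X:A ratio estimator
#'
#' @param n_sites Sites drawn per compartment per replicate (default 10
#'   million, clamped to the compartment size with a warning on small data).
#' @param n_replicates Number of independent site draws (default 10).
#' @param female_min Mean-ratio threshold at or above which the call is
#'   female (default 0.8).
#' @param male_max Mean-ratio threshold at or below which the call is male
#'   (default 0.7). Ratios strictly between the two are undetermined.
#' @return A `ratio_params` object.
#' @export
ratio_params <- function(n_sites = 1e7, n_replicates = 10,
                         female_min = 0.8, male_max = 0.7) {
  if (!(male_max < female_min) || male_max <= 0)
    abort("need 0 < male_max < female_min", class = "sexratio_bad_params")
  if (n_sites < 1 || n_replicates < 1)
    abort("n_sites and n_replicates must be >= 1", class = "sexratio_bad_params")
  structure(list(n_sites = n_sites, n_replicates = as.integer(n_replicates),
                 female_min = female_min, male_max = male_max),
            class = "ratio_params")
}

#' Sample random sites from a compartment
#'
#' Draws sites uniformly without replacement across the linearized coordinate
#' space of a depth accessor's region set. When the compartment holds fewer
#' positions than `n_sites`, every position is used exactly once and a
#' warning of class `sexratio_site_exhaustion` is raised — the estimator
#' then degenerates gracefully to the exhaustive mean.
#'
#' @param accessor A [depth_over_regions()] accessor (or a region tibble plus
#'   `tracks`).
#' @param n_sites Number of sites to draw.
#' @param seed Integer seed.
#' @return Tibble (`scaffold`, `pos`, `depth`), one row per sampled site.
#' @export
sample_sites <- function(accessor, n_sites, seed = 1) {
  accessor_sites(accessor, sample_lin(accessor, n_sites, seed))
}

# linear compartment indices of a site draw; shared by sample_sites() and the
# ratio fast path so both consume the RNG identically
sample_lin <- function(accessor, n_sites, seed) {
  stopifnot(inherits(accessor, "depth_accessor"))
  total <- accessor$total_length
  if (total < 1)
    abort("empty compartment; partition failed upstream",
          class = "sexratio_empty_compartment")
  if (total < n_sites) {
    warn(sprintf("compartment holds %s sites < n_sites = %s; using every site once",
                 format(total, big.mark = ","), format(n_sites, big.mark = ",")),
         class = "sexratio_site_exhaustion")
    seq_len(total)
  } else {
    withr::with_seed(seed, sample.int(total, n_sites))
  }
}

#' X:A coverage ratio from two depth samples
#'
#' Mean depth over the sampled X-linked sites divided by mean depth over the
#' sampled autosomal sites. Zero-coverage sites count: both means are over
#' all sampled positions.
#'
#' @param depth_x,depth_auto Site tibbles from [sample_sites()] (need a
#'   `depth` column).
#' @return The ratio (numeric scalar).
#' @export
xa_ratio <- function(depth_x, depth_auto) {
  if (nrow(depth_x) == 0 || nrow(depth_auto) == 0)
    abort("empty depth sample", class = "sexratio_empty_compartment")
  ma <- mean(depth_auto$depth)
  if (ma == 0)
    abort("mean autosomal depth is zero: too few reads to form an X:A ratio",
          class = "sexratio_undefined_ratio")
  mean(depth_x$depth) / ma
}

#' Replicated X:A ratios
#'
#' Repeats the (sample X sites, sample autosomal sites, take the ratio of
#' mean depths) step `n_replicates` times with per-replicate seeds
#' `seed + i`, so replicates are independent yet reproducible.
#'
#' @param acc_x,acc_auto Depth accessors for the X-linked and autosomal
#'   compartments.
#' @param params A [ratio_params()] object.
#' @param seed Base integer seed.
#' @return Numeric vector of length `n_replicates`, in replicate order.
#' @export
replicate_ratios <- function(acc_x, acc_auto, params = ratio_params(),
                             seed = 1) {
  stopifnot(inherits(params, "ratio_params"))
  warned <- FALSE
  out <- numeric(params$n_replicates)
  for (i in seq_len(params$n_replicates)) {
    r <- withCallingHandlers({
      mx <- mean(acc_x$depths[sample_lin(acc_x, params$n_sites, seed = seed + i)])
      ma <- mean(acc_auto$depths[sample_lin(acc_auto, params$n_sites,
                                            seed = seed + 1000L + i)])
      if (ma == 0)
        abort(sprintf("replicate %d: mean autosomal depth is zero: too few reads to form an X:A ratio", i),
              class = "sexratio_undefined_ratio")
      mx / ma
    },
    sexratio_site_exhaustion = function(w) {
      # one warning per call is enough; replicates repeat the same message
      if (warned) invokeRestart("muffleWarning")
      warned <<- TRUE
    })
    out[i] <- r
  }
  out
}

#' Classify a mean X:A ratio into a sex call
#'
#' At or above `female_min` the individual carries two X doses (female); at
#' or below `male_max`, one dose (male); the band strictly in between is
#' undetermined.
#'
#' @param mean_ratio Mean of the replicate ratios (>= 0).
#' @param params A [ratio_params()] object.
#' @return `"female"`, `"male"` or `"undetermined"`.
#' @export
classify_sex <- function(mean_ratio, params = ratio_params()) {
  stopifnot(mean_ratio >= 0)
  dplyr::case_when(mean_ratio >= params$female_min ~ "female",
                   mean_ratio <= params$male_max ~ "male",
                   TRUE ~ "undetermined")
}

new_sex_call <- function(id, ratios, params, n_reads, provenance) {
  structure(list(individual_id = id,
                 replicate_ratios = ratios,
                 mean_ratio = mean(ratios),
                 call = classify_sex(mean(ratios), params),
                 n_mapped_reads_used = n_reads,
                 params = params,
                 provenance = provenance),
            class = "sex_call")
}

#' @export
print.sex_call <- function(x, ...) {
  cat(sprintf("<sex_call> %s: %s (mean X:A = %.3f over %d replicates, %s mapped reads)\n",
              x$individual_id, toupper(x$call), x$mean_ratio,
              length(x$replicate_ratios),
              format(x$n_mapped_reads_used, big.mark = ",")))
  invisible(x)
}

#' @rdname sex_call_tidiers
#' @export
tidy.sex_call <- function(x, ...) {
  tibble(individual_id = x$individual_id,
         replicate = seq_along(x$replicate_ratios),
         ratio = x$replicate_ratios)
}

#' Tidiers for sex calls
#'
#' `tidy()` returns one row per replicate ratio; `glance()` a one-row summary
#' (mean ratio, call, reads used).
#'
#' @param x A `sex_call`.
#' @param ... Unused.
#' @name sex_call_tidiers
#' @export
glance.sex_call <- function(x, ...) {
  tibble(individual_id = x$individual_id,
         mean_ratio = x$mean_ratio,
         call = x$call,
         n_replicates = length(x$replicate_ratios),
         n_mapped_reads_used = x$n_mapped_reads_used)
}

#' Plot the replicate ratios of a sex call
#'
#' Dots are per-replicate X:A ratios, the solid line their mean; the shaded
#' band is the undetermined zone between the male and female thresholds.
#'
#' @param object A `sex_call`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sex_call <- function(object, ...) {
  d <- tidy(object)
  p <- object$params
  ggplot2::ggplot(d, ggplot2::aes(x = .data$replicate, y = .data$ratio)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = p$male_max, ymax = p$female_min,
                      alpha = 0.15, fill = "grey40") +
    ggplot2::geom_hline(yintercept = object$mean_ratio, linewidth = 0.4) +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = d$replicate) +
    ggplot2::labs(x = "replicate", y = "X:A coverage ratio",
                  title = sprintf("%s: %s (mean X:A = %.3f)",
                                  object$individual_id, object$call,
                                  object$mean_ratio)) +
    ggplot2::theme_minimal()
}
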