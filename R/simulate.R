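#' Simulation parameters
#'
#' Bundles the knobs of the genome/read simulator. Defaults describe a
#' desk-scale mammalian analog: a few megabase autosomes, an X about half an
#' autosome, a small Y sharing a pseudoautosomal (PAR) prefix with the X.
#'
#' @param n_autosomes Number of autosomes (>= 1).
#' @param autosome_length,x_length,y_length Chromosome lengths in bp.
#' @param divergence Expected substitutions per site between the truth genome
#'   and a derived reference assembly; must be in `[0, 0.25)`. Regimes of
#'   interest span roughly 0 (conspecific) to 0.17 (distant relative).
#' @param target_n50 Target scaffold N50 of a derived reference, in bp; must
#'   not exceed the longest chromosome.
#' @param read_length Read length in bp (>= 30, the minimum usable read).
#' @param base_error_rate Per-base sequencing error probability.
#' @param base_quality Constant Phred base quality assigned to simulated reads.
#' @param par_fraction Fraction of the X whose prefix is copied onto the Y as a
#'   pseudoautosomal analog (default 2%).
#' @param low_mapq_frac Fraction of reads given a random mapping quality in
#'   `[0, 29]` instead of 60, to exercise MAPQ filters.
#' @param mismap_frac Fraction of reads relocated uniformly at random across
#'   the reference, emulating mismapping.
#' @param mito_length Length of an optional mitochondrial chromosome (0 = none).
#' @return An object of class `sim_params` (a validated list).
#' @export
sim_params <- function(n_autosomes = 3,
                       autosome_length = 1e6,
                       x_length = 5e5,
                       y_length = 1e5,
                       divergence = 0,
                       target_n50 = autosome_length,
                       read_length = 70,
                       base_error_rate = 0.002,
                       base_quality = 37,
                       par_fraction = 0.02,
                       low_mapq_frac = 0,
                       mismap_frac = 0,
                       mito_length = 0) {
  p <- list(n_autosomes = as.integer(n_autosomes),
            autosome_length = autosome_length, x_length = x_length,
            y_length = y_length, divergence = divergence,
            target_n50 = target_n50, read_length = as.integer(read_length),
            base_error_rate = base_error_rate, base_quality = as.integer(base_quality),
            par_fraction = par_fraction, low_mapq_frac = low_mapq_frac,
            mismap_frac = mismap_frac, mito_length = mito_length)
  if (p$n_autosomes < 1) abort("need at least one autosome", class = "sexratio_bad_params")
  if (p$divergence < 0 || p$divergence >= 0.25)
    abort("divergence must be in [0, 0.25)", class = "sexratio_bad_params")
  if (p$read_length < 30)
    abort("read_length must be >= 30 bp", class = "sexratio_bad_params")
  longest <- max(p$autosome_length, p$x_length, p$y_length)
  if (p$target_n50 > longest)
    abort("target_n50 exceeds the longest chromosome", class = "sexratio_bad_params")
  if (any(c(p$autosome_length, p$x_length, p$y_length) <= 0))
    abort("chromosome lengths must be positive", class = "sexratio_bad_params")
  if (p$par_fraction < 0 || p$par_fraction * p$x_length > p$y_length)
    abort("PAR longer than the Y chromosome", class = "sexratio_bad_params")
  structure(p, class = "sim_params")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build a ground-truth genome
#'
#' Generates uniform-random chromosome sequences: `n_autosomes` autosomes, one
#' X, one Y (and optionally a mitochondrial chromosome). The first
#' `par_fraction * x_length` bases of the X are copied onto the start of the Y
#' so the pseudoautosomal masking stage downstream has real shared sequence to
#' find. Deterministic for a fixed seed.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @return A `truth_genome`: list with `info` (tibble of name/class/length)
#'   and `seq` (a [Biostrings::DNAStringSet]).
#' @export
build_truth_genome <- function(params, seed = 1) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(seed, {
    names_auto <- sprintf("chrA%d", seq_len(params$n_autosomes))
    seqs <- c(
      lapply(rep(params$autosome_length, params$n_autosomes), random_dna),
      list(random_dna(params$x_length), random_dna(params$y_length))
    )
    names(seqs) <- c(names_auto, "chrX", "chrY")
    classes <- c(rep("autosome", params$n_autosomes), "X", "Y")
    par_len <- round(params$par_fraction * params$x_length)
    if (par_len > 0) {
      seqs$chrY <- paste0(substr(seqs$chrX, 1, par_len),
                          substr(seqs$chrY, par_len + 1, params$y_length))
    }
    if (params$mito_length > 0) {
      seqs$chrMT <- random_dna(params$mito_length)
      classes <- c(classes, "mito")
    }
  })
  info <- tibble(name = names(seqs), class = classes,
                 length = vapply(seqs, nchar, numeric(1), USE.NAMES = FALSE))
  structure(list(info = info,
                 seq = Biostrings::DNAStringSet(unlist(seqs)),
                 par_length = round(params$par_fraction * params$x_length),
                 params = params, seed = seed),
            class = "truth_genome")
}

#' @export
print.truth_genome <- function(x, ...) {
  cat(sprintf("<truth_genome> %d chromosomes, %.2f Mb, PAR %s bp\n",
              nrow(x$info), sum(x$info$length) / 1e6,
              format(x$par_length, big.mark = ",")))
  print(x$info)
  invisible(x)
}

# i.i.d. substitutions to one of the 3 alternative bases, at `rate` per site.
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  r <- charToRaw(seq)
  n <- length(r)
  idx <- which(stats::runif(n) < rate)
  if (length(idx) == 0) return(seq)
  # alt[byte, j] = byte code of the j-th alternative base
  bases <- as.integer(charToRaw("ACGT"))
  alt <- matrix(0L, 256, 3)
  for (b in seq_along(bases)) alt[bases[b], ] <- bases[-b]
  pick <- sample.int(3, length(idx), replace = TRUE)
  new <- alt[cbind(as.integer(r[idx]), pick)]
  keep <- new == 0L # non-ACGT bytes (should not occur) are left untouched
  new[keep] <- as.integer(r[idx][keep])
  r[idx] <- as.raw(new)
  rawToChar(r)
}

# Draw sequential fragment lengths for one chromosome from a lognormal whose
# length-weighted median approximates the target N50.
cut_points <- function(chrom_len, target_n50, sdlog = 0.6, min_piece = 1000) {
  if (target_n50 >= chrom_len) return(chrom_len)
  meanlog <- log(target_n50) - sdlog^2
  lens <- numeric(0)
  remaining <- chrom_len
  while (remaining > 0) {
    l <- round(stats::rlnorm(1, meanlog, sdlog))
    l <- max(l, min_piece)
    if (l >= remaining - min_piece) l <- remaining
    lens <- c(lens, l)
    remaining <- remaining - l
  }
  lens
}

#' Assembly N50
#'
#' The scaffold length at which the cumulative sum of sorted-descending
#' lengths first reaches half the assembly total.
#'
#' @param lengths Numeric vector of scaffold lengths (or a `DNAStringSet`).
#' @return The N50 in bp.
#' @export
assembly_n50 <- function(lengths) {
  if (methods::is(lengths, "XStringSet")) lengths <- Biostrings::width(lengths)
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Derive a diverged, fragmented reference assembly from a truth genome
#'
#' Applies i.i.d. substitutions at the given per-site rate (no indels, so
#' truth coordinates stay exact), then cuts each chromosome into scaffolds
#' whose lengths are drawn from a lognormal tuned so the realized N50 lands
#' within 25% of `target_n50` (re-drawn with adjusted location up to
#' `max_tries` times). Scaffold order is shuffled. A mitochondrial chromosome
#' is kept whole and named so downstream mito exclusion can recognize it.
#'
#' @param genome A [build_truth_genome()] result.
#' @param divergence Substitutions per site, `[0, 0.25)`.
#' @param target_n50 Target scaffold N50 (bp).
#' @param seed Integer seed.
#' @param max_tries Fragmentation re-draws allowed to hit the N50 window.
#' @return A list with `assembly` (named [Biostrings::DNAStringSet]) and
#'   `truth_map`, a tibble (`scaffold`, `source_chrom`, `source_class`,
#'   `source_start`, `source_end`; 0-based half-open) recording each
#'   scaffold's true origin.
#' @export
derive_reference <- function(genome, divergence = 0, target_n50 = NULL,
                             seed = 1, max_tries = 40) {
  stopifnot(inherits(genome, "truth_genome"))
  target_n50 <- target_n50 %||% max(genome$info$length)
  if (divergence < 0 || divergence >= 0.25)
    abort("divergence must be in [0, 0.25)", class = "sexratio_bad_params")
  if (target_n50 > max(genome$info$length))
    abort("target_n50 exceeds the longest chromosome", class = "sexratio_bad_params")

  withr::with_seed(seed, {
    seqs <- as.character(genome$seq)
    seqs <- vapply(seqs, mutate_sequence, character(1), rate = divergence,
                   USE.NAMES = TRUE)

    nuclear <- genome$info$name[genome$info$class != "mito"]
    for (try in seq_len(max_tries)) {
      pieces <- lapply(nuclear, function(nm) {
        cut_points(nchar(seqs[[nm]]), target_n50)
      })
      realized <- assembly_n50(unlist(pieces))
      if (abs(realized - target_n50) <= 0.25 * target_n50) break
      if (try == max_tries)
        abort("could not reach target N50; adjust target_n50 or sdlog",
              class = "sexratio_n50_failure")
    }

    rows <- purrr::map2_dfr(nuclear, pieces, function(nm, lens) {
      ends <- cumsum(lens)
      tibble(source_chrom = nm,
             source_start = ends - lens,
             source_end = ends)
    })
    rows <- rows[sample.int(nrow(rows)), ]
    rows$scaffold <- sprintf("scaf_%04d", seq_len(nrow(rows)))
    if (any(genome$info$class == "mito")) {
      mt <- genome$info$name[genome$info$class == "mito"]
      rows <- dplyr::bind_rows(rows, tibble(
        source_chrom = mt, source_start = 0,
        source_end = genome$info$length[genome$info$class == "mito"],
        scaffold = "scaffold_mito"))
    }
    class_of <- stats::setNames(genome$info$class, genome$info$name)
    truth_map <- tibble(scaffold = rows$scaffold,
                        source_chrom = rows$source_chrom,
                        source_class = unname(class_of[rows$source_chrom]),
                        source_start = rows$source_start,
                        source_end = rows$source_end)
    assembly <- Biostrings::DNAStringSet(vapply(seq_len(nrow(rows)), function(i) {
      substr(seqs[[rows$source_chrom[i]]], rows$source_start[i] + 1, rows$source_end[i])
    }, character(1)))
    names(assembly) <- rows$scaffold
  })
  list(assembly = assembly, truth_map = truth_map)
}

# Dosage (copies per chromosome) under an XY system.
dosage_weights <- function(info, sex) {
  dplyr::case_when(
    info$class == "autosome" ~ 2,
    info$class == "X" ~ if (sex == "female") 2 else 1,
    info$class == "Y" ~ if (sex == "female") 0 else 1,
    TRUE ~ 0 # mito excluded from the read model
  )
}

#' Simulate mapped shotgun reads for one individual
#'
#' Places single-end reads uniformly over the truth genome, weighted by
#' chromosome dosage for the given sex (XX females: autosomes x2, X x2, Y x0;
#' XY males: autosomes x2, X x1, Y x1), then emits them directly as alignments
#' on the reference scaffolds via the truth map — a "perfect mapping" that
#' keeps coordinates exact with no external mapper. Reads crossing a scaffold
#' cut are truncated at the scaffold end. Mapping quality is 60 except for a
#' configurable low-MAPQ fraction; a configurable mismapping fraction
#' relocates reads uniformly. Per-base sequencing errors at `base_error_rate`
#' affect the read bases only, which are materialized lazily (see `with_seq`);
#' base qualities are a constant `base_quality`.
#'
#' @param genome A `truth_genome`.
#' @param ref A [derive_reference()] result (assembly + truth_map).
#' @param sex `"female"` or `"male"`.
#' @param n_reads Number of mapped reads to emit (exactly).
#' @param params The [sim_params()] used (read length, error rate, ...).
#' @param seed Integer seed.
#' @param id Individual identifier.
#' @param with_seq Materialize read sequences (with base errors) now? Depth
#'   and ratio computations never need them; SAM export does.
#' @return A `sim_individual`: list with `id`, `true_sex`, `alignments`
#'   (tibble: `read_id`, `scaffold`, `start`, `aligned_length`, `mapq`,
#'   `baseq`, `is_duplicate`, `origin_class`, optionally `seq`), sorted by
#'   scaffold then start, plus the generating seed and params.
#' @export
simulate_mapped_reads <- function(genome, ref, sex, n_reads, params,
                                  seed = 1, id = NULL, with_seq = FALSE) {
  stopifnot(inherits(genome, "truth_genome"))
  if (!sex %in% c("female", "male"))
    abort("sex must be \"female\" or \"male\"", class = "sexratio_bad_params")
  if (n_reads < 1) abort("n_reads must be >= 1", class = "sexratio_bad_params")
  id <- id %||% sprintf("%s_seed%d", sex, seed)
  rl <- params$read_length
  info <- genome$info
  tm <- ref$truth_map

  withr::with_seed(seed, {
    w <- dosage_weights(info, sex) * info$length
    chrom_idx <- sample.int(nrow(info), n_reads, replace = TRUE, prob = w)
    # uniform start; keep the read inside the chromosome
    pos <- floor(stats::runif(n_reads) * (info$length[chrom_idx] - rl + 1))

    # project truth coordinates onto reference scaffolds
    aln <- tibble(origin_chrom = info$name[chrom_idx],
                  origin_class = info$class[chrom_idx],
                  tpos = pos)
    tm_by_chrom <- split(tm, tm$source_chrom)
    aln <- dplyr::group_by(aln, .data$origin_chrom) |>
      dplyr::group_modify(function(d, key) {
        seg <- tm_by_chrom[[key$origin_chrom[1]]]
        seg <- seg[order(seg$source_start), ]
        i <- findInterval(d$tpos, seg$source_start)
        d$scaffold <- seg$scaffold[i]
        d$start <- d$tpos - seg$source_start[i]
        d$aligned_length <- pmin(rl, seg$source_end[i] - d$tpos)
        d
      }) |>
      dplyr::ungroup()

    aln$mapq <- 60L
    if (params$low_mapq_frac > 0) {
      low <- stats::runif(n_reads) < params$low_mapq_frac
      aln$mapq[low] <- sample(0:29, sum(low), replace = TRUE)
    }
    if (params$mismap_frac > 0) {
      mis <- which(stats::runif(n_reads) < params$mismap_frac)
      if (length(mis) > 0) {
        slen <- Biostrings::width(ref$assembly)
        s <- sample.int(length(slen), length(mis), replace = TRUE, prob = slen)
        aln$scaffold[mis] <- names(ref$assembly)[s]
        aln$start[mis] <- floor(stats::runif(length(mis)) *
                                  pmax(1, slen[s] - rl + 1))
        aln$aligned_length[mis] <- pmin(rl, slen[s] - aln$start[mis])
        aln$origin_class[mis] <- "mismapped"
      }
    }
    aln$read_id <- sprintf("%s_r%07d", id, seq_len(n_reads))
    aln$baseq <- strrep(rawToChar(as.raw(params$base_quality + 33L)), aln$aligned_length)
    aln$is_duplicate <- FALSE
  })

  aln <- dplyr::arrange(aln, .data$scaffold, .data$start)
  aln <- aln[, c("read_id", "scaffold", "start", "aligned_length", "mapq",
                 "baseq", "is_duplicate", "origin_class", "origin_chrom", "tpos")]
  ind <- structure(list(id = id, true_sex = sex, alignments = aln,
                        seed = seed, params = params),
                   class = "sim_individual")
  if (with_seq) ind$alignments$seq <- read_sequences(ind, genome)
  ind
}

#' Materialize read sequences with base errors
#'
#' Extracts each read's bases from its truth-genome origin and applies i.i.d.
#' base errors at `base_error_rate` (each error substitutes one of the three
#' alternative bases). Deterministic given the individual's stored seed.
#'
#' @param individual A `sim_individual`.
#' @param genome The `truth_genome` it was simulated from.
#' @return Character vector of read sequences, in alignment order.
#' @export
read_sequences <- function(individual, genome) {
  aln <- individual$alignments
  seqs <- as.character(genome$seq)
  out <- substr(seqs[aln$origin_chrom], aln$tpos + 1,
                aln$tpos + aln$aligned_length)
  # mismapped reads keep their origin bases; that is what mismapping means
  withr::with_seed(individual$seed + 7777L, {
    err <- individual$params$base_error_rate
    if (err > 0) {
      out <- vapply(out, mutate_sequence, character(1), rate = err,
                    USE.NAMES = FALSE)
    }
  })
  out
}

#' @export
print.sim_individual <- function(x, ...) {
  cat(sprintf("<sim_individual> %s (true sex: %s), %d mapped reads\n",
              x$id, x$true_sex, nrow(x$alignments)))
  invisible(x)
}
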