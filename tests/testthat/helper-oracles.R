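# Independent oracles, written as plain loops so they share no code path with
# the package implementation.

# Brute-force interval-stabbing depth: count reads covering a site with the
# quality filters applied base by base.
oracle_depth <- function(aln, scaffold, pos, min_mapq = 25, min_baseq = 25) {
  d <- 0L
  for (i in seq_len(nrow(aln))) {
    if (aln$scaffold[i] != scaffold) next
    if (aln$mapq[i] < min_mapq) next
    off <- pos - aln$start[i]
    if (off < 0 || off >= aln$aligned_length[i]) next
    q <- utf8ToInt(substr(aln$baseq[i], off + 1, off + 1)) - 33L
    if (q >= min_baseq) d <- d + 1L
  }
  d
}

# All-k-mer anchor finding by exhaustive substring tables (forward and
# reverse-complement), then greedy collinear chaining as a plain loop.
oracle_map_scaffold <- function(scaffold, donors, labels, k, max_occ = 4,
                                chain_gap = 5000, min_chain_anchors = 5) {
  canon <- function(s) {
    r <- revcomp(s)
    if (s <= r) list(key = s, fwd = TRUE) else list(key = r, fwd = FALSE)
  }
  # donor k-mer table
  tab <- list()
  for (d in seq_along(donors)) {
    seq <- donors[[d]]
    for (p in seq_len(nchar(seq) - k + 1)) {
      cm <- canon(substr(seq, p, p + k - 1))
      tab[[cm$key]] <- rbind(tab[[cm$key]],
                             data.frame(donor = d, rpos = p - 1, fwd = cm$fwd))
    }
  }
  tab <- tab[vapply(tab, nrow, 0L) <= max_occ]
  # query anchors
  anchors <- NULL
  for (p in seq_len(nchar(scaffold) - k + 1)) {
    cm <- canon(substr(scaffold, p, p + k - 1))
    hit <- tab[[cm$key]]
    if (is.null(hit)) next
    for (j in seq_len(nrow(hit))) {
      anchors <- rbind(anchors, data.frame(
        qpos = p - 1, donor = hit$donor[j], rpos = hit$rpos[j],
        strand = if (cm$fwd == hit$fwd[j]) 1L else -1L))
    }
  }
  out <- NULL
  if (is.null(anchors)) {
    return(tibble::tibble(start = numeric(), end = numeric(),
                          label = character()))
  }
  for (d in unique(anchors$donor)) for (s in c(1L, -1L)) {
    a <- anchors[anchors$donor == d & anchors$strand == s, ]
    if (nrow(a) == 0) next
    a <- a[order(a$qpos, s * a$rpos), ]
    chain_start <- 1
    flush <- function(from, to) {
      if (to - from + 1 >= min_chain_anchors) {
        out <<- rbind(out, data.frame(start = a$qpos[from],
                                      end = a$qpos[to] + k,
                                      label = labels[d]))
      }
    }
    if (nrow(a) == 1) { flush(1, 1) } else {
      for (i in 2:nrow(a)) {
        dq <- a$qpos[i] - a$qpos[i - 1]
        dr <- s * (a$rpos[i] - a$rpos[i - 1])
        if (dq > chain_gap || dr <= 0 || dr > chain_gap) {
          flush(chain_start, i - 1)
          chain_start <- i
        }
      }
      flush(chain_start, nrow(a))
    }
  }
  if (is.null(out)) {
    return(tibble::tibble(start = numeric(), end = numeric(),
                          label = character()))
  }
  tibble::as_tibble(out[order(out$label, out$start), ])
}

# interval merging by position scan (oracle for merge_regions / BED reading)
oracle_merge <- function(regions) {
  out <- NULL
  for (sc in sort(unique(regions$scaffold))) {
    r <- regions[regions$scaffold == sc, ]
    r <- r[order(r$start), ]
    cur_s <- r$start[1]; cur_e <- r$end[1]
    if (nrow(r) > 1) {
      for (i in 2:nrow(r)) {
        if (r$start[i] <= cur_e) cur_e <- max(cur_e, r$end[i])
        else { out <- rbind(out, data.frame(scaffold = sc, start = cur_s, end = cur_e)); cur_s <- r$start[i]; cur_e <- r$end[i] }
      }
    }
    out <- rbind(out, data.frame(scaffold = sc, start = cur_s, end = cur_e))
  }
  tibble::as_tibble(out)
}
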